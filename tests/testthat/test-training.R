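# Losses, metrics, splitting, and the optimization loop.

test_that("instance loss matches hand arithmetic and weighting rules", {
  # N=1, M=2, y=1, preds (0,2), alpha (.5,.5): 0.5*1 + 0.5*1 = 1
  expect_equal(instance_loss(1, matrix(c(0, 2), 1), matrix(c(.5, .5), 1)),
               1.0)
  # perfect conformer predictions
  expect_equal(instance_loss(2, matrix(c(2, 2), 1), matrix(c(.3, .7), 1)),
               0)
  # attention mask: alpha (1,0) ignores the second conformer entirely
  expect_equal(instance_loss(1, matrix(c(1, 99), 1), matrix(c(1, 0), 1)),
               0)
  # reduces to plain MSE when one conformer holds all attention
  y <- c(1, 2)
  yGm <- matrix(c(1.5, 7, 2.5, -3), 2, 2)
  alpha <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(instance_loss(y, yGm, alpha),
               bag_loss(yGm[, 1], y))
  expect_error(instance_loss(c(1, 2), matrix(0, 1, 2), matrix(1, 1, 2)),
               class = "equivs_shape_error")
})

test_that("bag loss is the mean squared error with its edge cases", {
  expect_equal(bag_loss(c(2, 2), c(1, 3)), 1.0)
  expect_equal(bag_loss(c(1, 3), c(1, 3)), 0)
  r <- c(0.3, -1.2, 4)
  expect_equal(bag_loss(2 * r, numeric(3)), 4 * bag_loss(r, numeric(3)))
  expect_error(bag_loss(numeric(0), numeric(0)),
               class = "equivs_empty_batch_error")
})

test_that("combined loss is the stated convex combination", {
  expect_equal(combined_loss(2, 4, beta = 0.5), 3.0)
  expect_equal(combined_loss(2, 4, beta = 0), 4)
  expect_equal(combined_loss(2, 4, beta = 1), 2)
  expect_true(combined_loss(3, 4, 0.5) >= combined_loss(2, 4, 0.5))
})

test_that("metrics match hand arithmetic and a brute-force oracle", {
  m <- evaluate_predictions(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$mse, 2 / 3)
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$r2, 0)
  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect[, c("r2", "mse", "mae")]),
               c(r2 = 1, mse = 0, mae = 0))
  expect_warning(cm <- evaluate_predictions(c(2, 2), c(1, 3)),
                 "constant")
  expect_true(is.na(cm$r2))
  # brute-force elementwise oracle on random vectors
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    y <- rnorm(n); yh <- rnorm(n)
    got <- evaluate_predictions(y, yh)
    mse_o <- sum((y - yh)^2) / n
    mae_o <- sum(abs(y - yh)) / n
    r2_o <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
    expect_equal(got$mse, mse_o, tolerance = 1e-12)
    expect_equal(got$mae, mae_o, tolerance = 1e-12)
    expect_equal(got$r2, r2_o, tolerance = 1e-12)
  }
})

test_that("dataset splitting is an exact, deterministic 8:1:1 partition", {
  data <- tibble::tibble(molecule_id = sprintf("m%03d", 1:100))
  s1 <- split_dataset(data, seed = 5)
  expect_equal(as.integer(table(s1$.split)), c(80L, 10L, 10L))
  s2 <- split_dataset(data, seed = 5)
  expect_identical(s1$.split, s2$.split)
  s3 <- split_dataset(data, seed = 6)
  expect_false(identical(s1$.split, s3$.split))
  expect_setequal(data$molecule_id, s1$molecule_id)
  expect_error(split_dataset(data[1:2, ]), class = "equivs_split_error")
})

test_that("a short training run returns finite history and a checkpoint", {
  data <- tiny_graphs() |> split_dataset(ratios = c(0.7, 0.15, 0.15),
                                         seed = 3)
  cfg <- equivs_config(hidden_dim = 8, n_layers = 2)
  fit <- equivs_train(data, config = cfg,
                      control = train_control(epochs = 3, batch_size = 4,
                                              seed = 3))
  expect_s3_class(fit, "equivs_fit")
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(fit$best_epoch >= 1)
  pr <- predict(fit, data)
  expect_equal(nrow(pr), nrow(data))
  expect_true(all(is.finite(pr$.pred)))
  expect_length(pr$.alpha[[1]], data$graph[[1]]$M)
  # training losses trend downward from the random start
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
  # broom-style accessors
  expect_equal(nrow(tidy(fit)), 3L)
  expect_equal(glance(fit)$variant, "full")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("checkpoints survive a save/load round trip", {
  data <- tiny_graphs() |> split_dataset(ratios = c(0.7, 0.15, 0.15),
                                         seed = 3)
  cfg <- equivs_config(hidden_dim = 8, n_layers = 2)
  fit <- equivs_train(data, config = cfg,
                      control = train_control(epochs = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_equivs_fit(fit, path)
  back <- load_equivs_fit(path)
  expect_identical(predict(back, data)$.pred, predict(fit, data)$.pred)
})

test_that("training is deterministic under a fixed seed", {
  data <- tiny_graphs() |> split_dataset(seed = 4)
  cfg <- equivs_config(hidden_dim = 8, n_layers = 1)
  ctl <- train_control(epochs = 2, seed = 11)
  f1 <- equivs_train(data, config = cfg, control = ctl)
  f2 <- equivs_train(data, config = cfg, control = ctl)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, data)$.pred, predict(f2, data)$.pred)
})
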