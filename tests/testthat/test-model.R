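# Network forward/backward: shapes, closed-form oracles, symmetry
# properties, gradient correctness.

small_config <- function(...) {
  equivs_config(hidden_dim = 8, n_layers = 2, dropout = 0, ...)
}

test_that("forward output shapes and attention normalization hold", {
  g <- tiny_graphs()$graph[[1]]
  cfg <- small_config()
  params <- init_equivs_params(cfg, seed = 1)
  out <- equivs_forward(g, params, cfg)
  expect_length(out$H1, 8)
  expect_equal(dim(out$HGm), c(g$M, 2 * 8))  # skip concat: L x hidden
  expect_length(out$yGm, g$M)
  expect_length(out$alpha, g$M)
  expect_true(all(out$alpha > 0))
  expect_equal(sum(out$alpha), 1, tolerance = 1e-12)
  expect_true(is.finite(out$yG))
  # slicing the skip concatenation recovers per-layer readouts
  expect_equal(out$HGm[, 1:8] + out$HGm[, 9:16],
               out$HGm %*% rbind(diag(8), diag(8)))
})

test_that("softmax matches its closed form", {
  expect_equal(equivs:::softmax(c(log(2), log(1))), c(2 / 3, 1 / 3))
  expect_equal(sum(equivs:::softmax(rnorm(10))), 1)
  expect_equal(equivs:::softmax(rep(0.7, 10)), rep(0.1, 10))
})

test_that("zero heads reduce predictions to their biases", {
  g <- tiny_graphs()$graph[[1]]
  cfg <- small_config()
  params <- init_equivs_params(cfg, seed = 1)
  zero <- lapply(params, function(x) x * 0)
  zero$bag_b2 <- 3.25
  zero$ins_b2 <- -1.5
  out <- equivs_forward(g, zero, cfg)
  expect_equal(out$yG, 3.25)
  expect_equal(out$yGm, rep(-1.5, g$M))
  expect_equal(out$alpha, rep(1 / g$M, g$M))  # identical representations
})

test_that("coordinate update follows its closed form on a two-atom system", {
  prep <- prep_smiles("CC")  # two heavy atoms, one bond
  g <- assemble_graph(prep$ensemble[[1]])
  cfg <- equivs_config(hidden_dim = 4, n_layers = 1, dropout = 0)
  params <- init_equivs_params(cfg, seed = 3)
  # phi_x == 0: coordinates unchanged (residual form)
  p0 <- params
  p0$egnn1_wx <- p0$egnn1_wx * 0
  p0$egnn1_bx <- 0
  out0 <- equivs_forward(g, p0, cfg, return_coords = TRUE)
  expect_equal(out0$coords_final, g$coords, tolerance = 1e-12)
  # phi_x == c: x_i' = x_i + C * c * (x_i - x_j), C = 1/(n-1) = 1
  cc <- 0.37
  pc <- p0
  pc$egnn1_bx <- cc
  outc <- equivs_forward(g, pc, cfg, return_coords = TRUE)
  for (m in seq_len(g$M)) {
    x <- g$coords[[m]]
    expected <- x + cc * rbind(x[1, ] - x[2, ], x[2, ] - x[1, ])
    expect_equal(outc$coords_final[[m]], expected, tolerance = 1e-10)
  }
})

test_that("messages depend on coordinates only through distance", {
  g <- tiny_graphs()$graph[[2]]
  cfg <- small_config()
  params <- init_equivs_params(cfg, seed = 5)
  base <- equivs_forward(g, params, cfg)
  moved <- transform_graph_coords(g, seed = 17, per_conformer = TRUE)
  out <- equivs_forward(moved, params, cfg)
  expect_equal(out$yG, base$yG, tolerance = 1e-5)
  expect_equal(out$yGm, base$yGm, tolerance = 1e-5)
  expect_equal(out$alpha, base$alpha, tolerance = 1e-5)
  expect_equal(out$HGm, base$HGm, tolerance = 1e-5)
})

test_that("coordinate outputs are E(3)-equivariant", {
  g <- tiny_graphs()$graph[[3]]
  cfg <- small_config()
  params <- init_equivs_params(cfg, seed = 6)
  base <- equivs_forward(g, params, cfg, return_coords = TRUE)
  motion <- random_rigid_motion(23)
  moved <- g
  moved$coords <- lapply(g$coords, apply_rigid, motion = motion)
  moved$HC <- do.call(cbind, moved$coords)
  out <- equivs_forward(moved, params, cfg, return_coords = TRUE)
  for (m in seq_len(g$M)) {
    expect_equal(out$coords_final[[m]],
                 apply_rigid(base$coords_final[[m]], motion),
                 tolerance = 1e-8)
  }
})

test_that("predictions are invariant under atom relabeling", {
  ens <- tiny_prep()$ensemble[[4]]
  set.seed(12)
  perm <- sample(ens$perception$n_heavy)
  g0 <- assemble_graph(ens)
  g1 <- assemble_graph(permute_ensemble(ens, perm))
  cfg <- small_config()
  params <- init_equivs_params(cfg, seed = 8)
  out0 <- equivs_forward(g0, params, cfg)
  out1 <- equivs_forward(g1, params, cfg)
  expect_equal(out1$yG, out0$yG, tolerance = 1e-9)
  expect_equal(out1$H1, out0$H1, tolerance = 1e-9)
  expect_equal(out1$alpha, out0$alpha, tolerance = 1e-9)
})

test_that("ablation variants change the architecture as specified", {
  g <- tiny_graphs()$graph[[1]]
  # no_aa: unweighted sum aggregation, no attention coefficients
  cfg <- small_config(variant = "no_aa")
  p <- init_equivs_params(cfg, seed = 2)
  out <- equivs_forward(g, p, cfg)
  expect_null(out$alpha)
  expect_equal(out$HG, colSums(out$HGm))
  expect_error(
    rank_conformers(tibble::tibble(molecule_id = "a",
                                   .pred_conformer = list(out$yGm),
                                   .alpha = list(out$alpha))),
    class = "equivs_attention_unavailable"
  )
  # single: only the first conformer enters, attention collapses to 1
  cfg_s <- small_config(variant = "single")
  p_s <- init_equivs_params(cfg_s, seed = 2)
  out_s <- equivs_forward(g, p_s, cfg_s)
  expect_equal(out_s$alpha, 1)
  expect_equal(nrow(out_s$HGm), 1L)
  # no_ip: conformer-level head disabled
  cfg_i <- small_config(variant = "no_ip")
  p_i <- init_equivs_params(cfg_i, seed = 2)
  expect_null(equivs_forward(g, p_i, cfg_i)$yGm)
  # no_skip: final readout only
  cfg_k <- small_config(variant = "no_skip")
  p_k <- init_equivs_params(cfg_k, seed = 2)
  expect_equal(ncol(equivs_forward(g, p_k, cfg_k)$HGm), 8L)
  # no_gcn: linear encoder still yields a finite prediction
  cfg_g <- small_config(variant = "no_gcn")
  p_g <- init_equivs_params(cfg_g, seed = 2)
  expect_true(is.finite(equivs_forward(g, p_g, cfg_g)$yG))
})

test_that("analytic gradients match finite differences and reach layer 1", {
  graphs <- tiny_graphs()$graph[1:2]
  y <- tiny_graphs()$value_logM[1:2]
  cfg <- small_config()
  params <- init_equivs_params(cfg, seed = 4)
  beta <- 0.5
  loss_fn <- function(p) {
    tot <- 0
    for (k in 1:2) {
      out <- equivs_forward(graphs[[k]], p, cfg)
      li <- sum(out$alpha * (y[k] - out$yGm)^2)
      tot <- tot + beta * li + (1 - beta) * (y[k] - out$yG)^2
    }
    tot / 2
  }
  grads <- NULL
  for (k in 1:2) {
    out <- equivs_forward(graphs[[k]], params, cfg, training = TRUE)
    dp <- equivs:::loss_partials(out, y[k], beta, 2, cfg)
    gr <- equivs:::equivs_backward(out, params, cfg, dp$dyG, dp$dyGm,
                                   dp$dalpha)
    grads <- if (is.null(grads)) gr else equivs:::add_grads(grads, gr)
  }
  # skip connections keep gradient flowing into the first EGNN layer
  expect_gt(max(abs(grads$egnn1_We)), 0)
  expect_gt(max(abs(grads$gcn_We)), 0)
  set.seed(9)
  eps <- 1e-6
  for (nm in names(params)) {
    i <- sample(length(params[[nm]]), 1)
    p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
    p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
    num <- (loss_fn(p_hi) - loss_fn(p_lo)) / (2 * eps)
    ana <- grads[[nm]][i]
    # relative error with an absolute floor (finite differences are noisy
    # around zero gradients)
    rel <- abs(ana - num) / max(1e-4, abs(ana) + abs(num))
    expect_lt(rel, 1e-3, label = sprintf("grad %s[%d] rel err", nm, i))
  }
})
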