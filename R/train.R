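# Optimization loop: Adam over mini-batches of molecules, combined
# bag/instance loss, best-validation-MSE model selection.

#' Training hyper-parameters
#'
#' Defaults follow the reference protocol for this architecture: Adam with
#' learning rate 0.001, 200 epochs, batch size 128, loss mixing factor
#' beta = 0.5.
#'
#' @param lr Adam learning rate.
#' @param epochs Number of passes over the training set.
#' @param batch_size Molecules per gradient step.
#' @param beta Instance-loss weight in the combined loss (in \[0, 1\]).
#' @param seed Seed controlling shuffling, dropout and initialization.
#' @param verbose Print per-epoch losses.
#' @return A `train_control` list.
#' @export
train_control <- function(lr = 0.001, epochs = 200, batch_size = 128,
                          beta = 0.5, seed = 1, verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, beta >= 0, beta <= 1)
  structure(
    list(lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), beta = beta,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "train_control"
  )
}

#' Random train/validation/test split
#'
#' Randomly partitions molecules with the given ratios (default 8:1:1).
#' The partition is disjoint, exhaustive and deterministic for a fixed
#' seed.
#'
#' @param data A data frame (one row per molecule).
#' @param ratios Length-3 numeric summing to 1.
#' @param seed Integer seed.
#' @return `data` with a `.split` factor column
#'   (`train` / `valid` / `test`).
#' @export
split_dataset <- function(data, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(is.data.frame(data), length(ratios) == 3,
            abs(sum(ratios) - 1) < 1e-8, all(ratios >= 0))
  n <- nrow(data)
  if (n < 3) {
    abort("need at least 3 records to split.", class = "equivs_split_error")
  }
  n_train <- floor(n * ratios[1])
  n_valid <- floor(n * ratios[2])
  idx <- with_seed(seed, sample.int(n))
  split <- rep("test", n)
  split[idx[seq_len(n_train)]] <- "train"
  if (n_valid > 0) split[idx[n_train + seq_len(n_valid)]] <- "valid"
  data$.split <- factor(split, levels = c("train", "valid", "test"))
  as_tibble(data)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# loss gradient partials for one molecule within a batch of size nb
loss_partials <- function(out, y, beta, nb, config) {
  dyG <- -2 * (1 - beta) * (y - out$yG) / nb
  dyGm <- NULL
  dalpha <- NULL
  if (config$variant != "no_ip" && beta > 0) {
    alpha_w <- out$alpha %null% rep(1 / length(out$yGm), length(out$yGm))
    dyGm <- -2 * beta * alpha_w * (y - out$yGm) / nb
    if (!is.null(out$alpha)) {
      dalpha <- beta * (y - out$yGm)^2 / nb
    }
  }
  list(dyG = dyG, dyGm = dyGm, dalpha = dalpha)
}

batch_loss <- function(outs, y, beta, config) {
  yG <- vapply(outs, `[[`, numeric(1), "yG")
  l_bag <- bag_loss(yG, y)
  if (config$variant == "no_ip" || beta == 0) {
    return(combined_loss(0, l_bag, beta = 0))
  }
  yGm <- do.call(rbind, lapply(outs, `[[`, "yGm"))
  alpha <- do.call(rbind, lapply(outs, function(o) {
    o$alpha %null% rep(1 / length(o$yGm), length(o$yGm))
  }))
  combined_loss(instance_loss(y, yGm, alpha), l_bag, beta = beta)
}

#' Train the conformer-ensemble bioactivity model
#'
#' Optimizes the combined bag/instance loss with Adam on mini-batches of
#' molecules. The checkpoint with the best validation MSE across epochs is
#' returned (final-epoch parameters when no validation split is given).
#'
#' @param data A data frame with a `graph` list-column (see
#'   [build_graphs()]) and a label column; typically carries the `.split`
#'   column from [split_dataset()], in which case the `train` rows are used
#'   for optimization and the `valid` rows for model selection.
#' @param label Column with labels in -logM (tidy-eval; default
#'   `value_logM`).
#' @param config Model architecture, an [equivs_config()].
#' @param control Optimization settings, a [train_control()].
#' @return An `equivs_fit` with elements `params` (best checkpoint),
#'   `config`, `control`, `history` (per-epoch train loss and validation
#'   MSE), `best_epoch`.
#' @examples
#' \dontrun{
#' task <- make_regression_task(40, noise_sigma = 0.1, seed = 1)
#' data <- task |> prepare_conformers(seed = 1) |> build_graphs() |>
#'   split_dataset(seed = 1)
#' fit <- equivs_train(data, control = train_control(epochs = 5, seed = 1))
#' predict(fit, dplyr::filter(data, .split == "test"))
#' }
#' @export
equivs_train <- function(data, label = value_logM,
                         config = equivs_config(),
                         control = train_control()) {
  stopifnot(is.data.frame(data), "graph" %in% names(data))
  label_col <- rlang::enquo(label)
  y_all <- dplyr::pull(data, !!label_col)
  if (anyNA(y_all)) abort("labels contain NA.")
  if (".split" %in% names(data)) {
    tr <- data$.split == "train"
    va <- data$.split == "valid"
  } else {
    tr <- rep(TRUE, nrow(data))
    va <- rep(FALSE, nrow(data))
  }
  graphs_tr <- data$graph[tr]
  y_tr <- y_all[tr]
  graphs_va <- data$graph[va]
  y_va <- y_all[va]
  if (length(graphs_tr) == 0L) abort("no training molecules.")

  params <- init_equivs_params(config, seed = control$seed)
  state <- adam_init(params)
  n_tr <- length(graphs_tr)
  history <- vector("list", control$epochs)
  best <- list(params = params, valid_mse = Inf, epoch = 0L)

  with_seed(control$seed + 1L, {
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      epoch_loss <- 0
      for (b in batches) {
        nb <- length(b)
        grads <- NULL
        outs <- vector("list", nb)
        for (k in seq_len(nb)) {
          gk <- graphs_tr[[b[k]]]
          out <- equivs_forward(gk, params, config, training = TRUE)
          outs[[k]] <- out[c("yG", "yGm", "alpha")]
          dp <- loss_partials(out, y_tr[b[k]], control$beta, nb, config)
          gr <- equivs_backward(out, params, config, dp$dyG, dp$dyGm,
                                dp$dalpha)
          grads <- if (is.null(grads)) gr else add_grads(grads, gr)
        }
        lb <- batch_loss(outs, y_tr[b], control$beta, config)
        if (!is.finite(lb)) {
          abort(sprintf("training diverged at epoch %d (non-finite loss).",
                        epoch),
                class = "equivs_training_diverged")
        }
        epoch_loss <- epoch_loss + lb * nb
        upd <- adam_step(params, grads, state, lr = control$lr)
        params <- upd$params
        state <- upd$state
      }
      epoch_loss <- epoch_loss / n_tr
      valid_mse <- NA_real_
      if (length(graphs_va) > 0) {
        yhat_va <- vapply(graphs_va, function(gr) {
          equivs_forward(gr, params, config)$yG
        }, numeric(1))
        valid_mse <- mean((y_va - yhat_va)^2)
        if (valid_mse < best$valid_mse) {
          best <- list(params = params, valid_mse = valid_mse,
                       epoch = epoch)
        }
      }
      history[[epoch]] <- tibble(epoch = epoch, train_loss = epoch_loss,
                                 valid_mse = valid_mse)
      if (control$verbose) {
        inform(sprintf("epoch %3d  train %.4f  valid %.4f",
                       epoch, epoch_loss, valid_mse))
      }
    }
  })
  if (!is.finite(best$valid_mse)) {
    best <- list(params = params, valid_mse = NA_real_,
                 epoch = control$epochs)
  }
  structure(
    list(params = best$params, config = config, control = control,
         history = dplyr::bind_rows(history), best_epoch = best$epoch,
         best_valid_mse = best$valid_mse),
    class = "equivs_fit"
  )
}

#' @export
print.equivs_fit <- function(x, ...) {
  cat(sprintf(
    "<equivs_fit> variant '%s', hidden %d, %d EGNN layers; %d epochs, best epoch %d (valid MSE %.4g)\n",
    x$config$variant, x$config$hidden_dim, x$config$n_layers,
    nrow(x$history), x$best_epoch, x$best_valid_mse
  ))
  invisible(x)
}

#' Predict bioactivities for prepared molecules
#'
#' @param object An `equivs_fit`.
#' @param data A data frame with a `graph` list-column.
#' @param conformers Also return nested per-conformer predictions and
#'   attention coefficients (default TRUE).
#' @param ... Unused.
#' @return A tibble with `molecule_id`, `.pred` (molecule-level -logM
#'   prediction) and, when `conformers`, list-columns `.pred_conformer`
#'   and `.alpha` (NULL entries for variants without the corresponding
#'   head).
#' @export
predict.equivs_fit <- function(object, data, conformers = TRUE, ...) {
  stopifnot(is.data.frame(data), "graph" %in% names(data))
  outs <- lapply(data$graph, equivs_forward, params = object$params,
                 config = object$config)
  res <- tibble(
    molecule_id = vapply(data$graph, `[[`, character(1), "id"),
    .pred = vapply(outs, `[[`, numeric(1), "yG")
  )
  if (conformers) {
    res$.pred_conformer <- lapply(outs, `[[`, "yGm")
    res$.alpha <- lapply(outs, `[[`, "alpha")
  }
  res
}
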