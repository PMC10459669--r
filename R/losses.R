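# Multiple-instance training losses and evaluation metrics.

#' Attention-weighted conformer-level (instance) loss
#'
#' Mean over molecules of the attention-weighted squared conformer
#' prediction errors: `1/N * sum_n sum_m alpha[n,m] * (y[n] - yGm[n,m])^2`.
#' Attention weights are normalized within each molecule, never across the
#' batch.
#'
#' @param y Numeric vector of molecule labels (-logM), length N.
#' @param yGm N x M matrix of conformer-level predictions.
#' @param alpha N x M matrix of attention coefficients (rows sum to 1).
#' @return Non-negative scalar.
#' @export
instance_loss <- function(y, yGm, alpha) {
  yGm <- rbind(yGm)
  alpha <- rbind(alpha)
  if (length(y) != nrow(yGm) || !all(dim(yGm) == dim(alpha))) {
    abort("shape mismatch between labels, predictions and attention.",
          class = "equivs_shape_error")
  }
  mean(rowSums(alpha * (y - yGm)^2))
}

#' Molecule-level (bag) loss
#'
#' Plain mean squared error of the molecule-level predictions.
#'
#' @param yG Numeric vector of molecule-level predictions.
#' @param y Numeric vector of labels (-logM).
#' @return Non-negative scalar.
#' @export
bag_loss <- function(yG, y) {
  if (length(y) == 0L) {
    abort("empty batch.", class = "equivs_empty_batch_error")
  }
  if (length(yG) != length(y)) {
    abort("prediction/label length mismatch.", class = "equivs_shape_error")
  }
  mean((y - yG)^2)
}

#' Combined training loss
#'
#' Convex combination `beta * instance + (1 - beta) * bag`; `beta = 0`
#' disables the instance term (the `no_ip` variant trains with this path).
#'
#' @param l_ins Instance loss.
#' @param l_bag Bag loss.
#' @param beta Contribution factor in \[0, 1\] (default 0.5).
#' @return Scalar loss.
#' @export
combined_loss <- function(l_ins, l_bag, beta = 0.5) {
  stopifnot(beta >= 0, beta <= 1)
  beta * l_ins + (1 - beta) * l_bag
}

# closed-form metrics on plain vectors
eval_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  mse <- mean((y_true - y_pred)^2)
  mae <- mean(abs(y_true - y_pred))
  tss <- sum((y_true - mean(y_true))^2)
  r2 <- if (tss > 0) 1 - sum((y_true - y_pred)^2) / tss else {
    warn("R^2 undefined for constant labels; reported as NA.")
    NA_real_
  }
  c(r2 = r2, mse = mse, mae = mae)
}

#' Evaluate predictions against labels
#'
#' Computes the coefficient of determination R^2, mean squared error and
#' mean absolute error. R^2 is reported as NA (with a warning) when the
#' labels are constant.
#'
#' @param data A data frame holding truth and estimate columns, or a
#'   numeric vector of labels (then `truth` is the prediction vector).
#' @param truth,estimate Columns with labels and predictions (tidy-eval;
#'   defaults `value_logM` and `.pred`).
#' @return One-row tibble with `r2`, `mse`, `mae`, `n`.
#' @export
evaluate_predictions <- function(data, truth = value_logM,
                                 estimate = .pred) {
  if (is.numeric(data)) {
    y <- data
    yhat <- rlang::eval_tidy(rlang::enquo(truth))
  } else {
    y <- dplyr::pull(data, !!rlang::enquo(truth))
    yhat <- dplyr::pull(data, !!rlang::enquo(estimate))
  }
  m <- eval_metrics(y, yhat)
  tibble(r2 = m[["r2"]], mse = m[["mse"]], mae = m[["mae"]],
         n = length(y))
}
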