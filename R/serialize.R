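# Checkpoint serialization: a single file with a format-version tag and
# the full model/training configuration embedded.

EQUIVS_CHECKPOINT_VERSION <- "equivs-checkpoint-1"

#' Save a fitted model to a checkpoint file
#'
#' @param fit An `equivs_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_equivs_fit <- function(fit, path) {
  stopifnot(inherits(fit, "equivs_fit"))
  saveRDS(list(version = EQUIVS_CHECKPOINT_VERSION, fit = fit), path)
  invisible(path)
}

#' Load a fitted model from a checkpoint file
#'
#' @param path Checkpoint file written by [save_equivs_fit()].
#' @return The `equivs_fit`.
#' @export
load_equivs_fit <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, EQUIVS_CHECKPOINT_VERSION)) {
    abort(sprintf("unrecognized checkpoint version in %s", path))
  }
  obj$fit
}
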