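# Attention-based optimal-conformer discovery: rank conformers of each
# molecule by attention coefficient and relate attention to per-conformer
# prediction accuracy.

#' Rank conformers by attention coefficient
#'
#' Orders each molecule's conformers by attention coefficient (descending,
#' ties broken by conformer index ascending) and flags coefficients at or
#' below the uniform average 1/M.
#'
#' @param predictions Output of [predict.equivs_fit()] with
#'   `conformers = TRUE` from a model with an attention head.
#' @return A `conformer_ranking` tibble with columns `molecule_id`,
#'   `conformer` (1-based index), `alpha`, `.pred_conformer` and
#'   `below_uniform`.
#' @export
rank_conformers <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  if (!".alpha" %in% names(predictions) ||
      any(vapply(predictions$.alpha, is.null, logical(1)))) {
    abort(
      "attention coefficients unavailable (no_aa variant or conformers = FALSE).",
      class = "equivs_attention_unavailable"
    )
  }
  rows <- purrr::pmap(
    list(predictions$molecule_id, predictions$.alpha,
         predictions$.pred_conformer %null%
           rep(list(NULL), nrow(predictions))),
    function(id, alpha, yGm) {
      m <- length(alpha)
      tibble(
        molecule_id = id,
        conformer = seq_len(m),
        alpha = alpha,
        .pred_conformer = if (is.null(yGm)) NA_real_ else yGm,
        below_uniform = alpha <= 1 / m + 1e-12
      )
    }
  )
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$molecule_id, dplyr::desc(.data$alpha),
                   .data$conformer)
  class(out) <- c("conformer_ranking", class(out))
  out
}

#' Per-conformer interpretation report
#'
#' Joins conformer rankings with molecule labels and reports the absolute
#' per-conformer prediction error next to the attention coefficient,
#' enabling the attention-vs-accuracy consistency analysis. An optional
#' external score column (e.g. user-supplied docking scores) is carried
#' through.
#'
#' @param ranking A `conformer_ranking` from [rank_conformers()].
#' @param data A data frame with `molecule_id` and a label column.
#' @param label Label column (tidy-eval; default `value_logM`).
#' @param external_scores Optional data frame with `molecule_id`,
#'   `conformer` and `external_score` columns to merge.
#' @return A tibble with `molecule_id`, `conformer`, `alpha`,
#'   `.pred_conformer`, `value_logM`, `abs_error`, `below_uniform` and
#'   (when supplied) `external_score`.
#' @export
interpretation_report <- function(ranking, data, label = value_logM,
                                  external_scores = NULL) {
  stopifnot(is.data.frame(ranking), is.data.frame(data))
  label_col <- rlang::enquo(label)
  labels <- dplyr::select(data, "molecule_id",
                          value_logM = !!label_col)
  out <- ranking |>
    dplyr::left_join(labels, by = "molecule_id") |>
    dplyr::mutate(abs_error = abs(.data$value_logM -
                                    .data$.pred_conformer))
  if (!is.null(external_scores)) {
    out <- dplyr::left_join(out, external_scores,
                            by = c("molecule_id", "conformer"))
  }
  dplyr::relocate(out, "molecule_id", "conformer", "alpha",
                  ".pred_conformer", "value_logM", "abs_error")
}

#' Attention profile plot
#'
#' Bar plot of attention coefficients per conformer for each molecule,
#' with the uniform level 1/M marked.
#'
#' @param object A `conformer_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conformer_ranking <- function(object, ...) {
  m_typ <- max(object$conformer)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$conformer),
                               y = .data$alpha)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / m_typ, linetype = 2) +
    ggplot2::facet_wrap(~molecule_id) +
    ggplot2::labs(x = "conformer", y = "attention coefficient") +
    ggplot2::theme_minimal()
}
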