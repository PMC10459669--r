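# Bioactivity-table curation: activity-type and match-label filtering,
# bucketed value integration, active/inactive classification, and
# target-scale filtering. Values are in -logM units throughout (negative
# decadic logarithm of a molar concentration; 1 uM = 6 -logM).

ACTIVITY_TYPES <- c("IC50", "Ki", "Kd", "EC50", "Potency")
MATCH_LABELS <- c("1 structure", "match")

#' Convert concentrations to -logM units
#'
#' @param value Numeric concentrations.
#' @param unit Unit of `value`: molar (`"M"`) or a metric submultiple.
#' @return `-log10` of the molar concentration.
#' @examples
#' to_logm(1, "uM")  # 6
#' @export
to_logm <- function(value, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[unit]]
  -log10(value * scale)
}

#' Filter bioactivity records by activity type and structure-match label
#'
#' Keeps the five canonical activity types (IC50, Ki, Kd, EC50, Potency)
#' and, when a `match_label` column is present, only records whose
#' structures were matched across sources ("1 structure" or "match").
#' Records with missing or non-finite values are also dropped. The
#' operation is idempotent.
#'
#' @param data A bioactivity data frame with columns `activity_type`,
#'   `value_logM` and optionally `match_label`.
#' @param activity_types Allowed activity types.
#' @param match_labels Allowed structure-match labels.
#' @return Filtered tibble; dropped counts are reported via a message.
#' @export
filter_records <- function(data, activity_types = ACTIVITY_TYPES,
                           match_labels = MATCH_LABELS) {
  stopifnot(is.data.frame(data))
  n0 <- nrow(data)
  out <- dplyr::filter(data, .data$activity_type %in% activity_types)
  if ("match_label" %in% names(data)) {
    out <- dplyr::filter(out, .data$match_label %in% match_labels)
  }
  if ("value_logM" %in% names(out)) {
    out <- dplyr::filter(out, is.finite(.data$value_logM))
  }
  if (nrow(out) < n0) {
    inform(sprintf("filter_records: dropped %d of %d records.",
                   n0 - nrow(out), n0))
  }
  as_tibble(out)
}

#' Integrate replicate bioactivity values by unit-width buckets
#'
#' Values (in -logM) are binned into half-open unit buckets `[k, k+1)` on
#' integer edges; the integrated value is the mean of the values in the
#' most populated bucket. Frequency ties go to the more potent (higher
#' -logM) bucket.
#'
#' @param values Non-empty numeric vector of -logM values.
#' @return Scalar integrated value, always within `range(values)`.
#' @examples
#' bucket_integrate(c(5.2, 5.7, 6.3))  # bucket [5,6) wins -> 5.45
#' @export
bucket_integrate <- function(values) {
  if (length(values) == 0L || all(is.na(values))) {
    abort("no values to integrate.", class = "equivs_empty_input_error")
  }
  values <- values[is.finite(values)]
  bucket <- floor(values)
  counts <- table(bucket)
  top <- max(counts)
  winners <- as.numeric(names(counts)[counts == top])
  win <- max(winners)  # tie -> more potent bucket
  mean(values[bucket == win])
}

#' Integrate replicate records per molecule-target pair
#'
#' Grouped wrapper around [bucket_integrate()]: collapses replicate
#' measurements of the same molecule, target and activity type into one
#' record with the bucket-integrated value.
#'
#' @param data A bioactivity data frame with `value_logM`.
#' @param ... Grouping columns (tidy-eval); defaults to `molecule_id`,
#'   `target_id` and `activity_type` (those present).
#' @return Tibble with one row per group, columns from `...` plus
#'   `value_logM` and `n_measurements`.
#' @export
integrate_bioactivities <- function(data, ...) {
  stopifnot(is.data.frame(data), "value_logM" %in% names(data))
  groups <- rlang::enquos(...)
  if (length(groups) == 0L) {
    keys <- intersect(c("molecule_id", "smiles", "target_id",
                        "activity_type"), names(data))
    groups <- rlang::syms(keys)
  }
  data |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      n_measurements = dplyr::n(),
      value_logM = bucket_integrate(.data$value_logM),
      .groups = "drop"
    )
}

#' Classify molecules as active or inactive
#'
#' Uses the 1 uM threshold (6 -logM): values at or above the threshold are
#' active.
#'
#' @param value_logM Numeric -logM values.
#' @param threshold Activity threshold in -logM (default 6).
#' @return Character vector, `"active"` or `"inactive"`.
#' @examples
#' classify_active(c(9, 5.33, 6))  # active, inactive, active
#' @export
classify_active <- function(value_logM, threshold = 6) {
  stopifnot(is.numeric(value_logM))
  ifelse(value_logM >= threshold, "active", "inactive")
}

#' Drop targets with insufficient bioactivity endpoints
#'
#' Removes all records of targets whose endpoint count falls below the
#' cutoff (default 300), keeping only targets on which reliable per-target
#' models can be trained. Idempotent.
#'
#' @param data A bioactivity data frame with a `target_id` column.
#' @param min_endpoints Minimum endpoints per retained target.
#' @return Filtered tibble.
#' @export
filter_targets <- function(data, min_endpoints = 300) {
  stopifnot(is.data.frame(data), "target_id" %in% names(data))
  data |>
    dplyr::add_count(.data$target_id, name = ".n_endpoints") |>
    dplyr::filter(.data$.n_endpoints >= min_endpoints) |>
    dplyr::select(-".n_endpoints") |>
    as_tibble()
}

#' Full bioactivity curation pipeline
#'
#' Composes [filter_records()], [integrate_bioactivities()] and
#' [filter_targets()], the table-level curation applied before conformer
#' generation.
#'
#' @inheritParams filter_records
#' @inheritParams filter_targets
#' @return Curated tibble of integrated per-molecule-per-target records.
#' @export
curate_bioactivity <- function(data, activity_types = ACTIVITY_TYPES,
                               match_labels = MATCH_LABELS,
                               min_endpoints = 300) {
  data |>
    filter_records(activity_types = activity_types,
                   match_labels = match_labels) |>
    integrate_bioactivities() |>
    filter_targets(min_endpoints = min_endpoints)
}
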