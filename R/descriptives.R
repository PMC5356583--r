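#' Cohort category percentages with missing-data footnotes
#'
#' Recomputes the percentage of patients in each category of a clinical
#' characteristic (e.g. Gleason-score strata) from raw counts, using the
#' number of patients with the characteristic available as the denominator:
#' `100 * count / (n_total - n_missing)`.
#'
#' @param counts named integer vector of per-category patient counts.
#' @param n_total total cohort size.
#' @param n_missing patients for whom the characteristic is unavailable.
#' @param digits optional rounding (e.g. 1 to match a printed table);
#'   `NULL` returns unrounded percentages.
#' @return named numeric vector of percentages.
#' @export
cohort_percentages <- function(counts, n_total, n_missing = 0, digits = NULL) {
  n_total <- check_count(n_total, "n_total", min = 1L)
  n_missing <- check_count(n_missing, "n_missing", min = 0L)
  denom <- n_total - n_missing
  if (denom <= 0) stop("no patients with data available", call. = FALSE)
  if (sum(counts) > denom) stop("counts exceed available patients", call. = FALSE)
  pct <- 100 * counts / denom
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}
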