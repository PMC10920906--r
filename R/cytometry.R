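#' Derive a positivity gate from a parental control sample
#'
#' The gate is the stated percentile of the control (parental,
#' reporter-negative) intensity distribution, so roughly
#' `1 - percentile/100` of control events fall above it by construction.
#'
#' @param control numeric vector of control-event intensities, or a tibble
#'   with an `intensity` column (e.g. from [simulate_flow_population()]
#'   with `is_control = TRUE`).
#' @param percentile gate percentile of the control distribution
#'   (default 99.5).
#' @param min_events minimum number of control events required.
#' @return Threshold intensity (scalar).
#' @export
derive_gate <- function(control, percentile = 99.5, min_events = 100) {
  x <- if (is.data.frame(control)) control$intensity else control
  x <- x[is.finite(x)]
  if (length(x) < min_events) {
    stop("control sample has ", length(x), " events; need >= ", min_events)
  }
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  unname(stats::quantile(x, percentile / 100, type = 7))
}

#' Median fluorescence intensity of gated events, per sample
#'
#' Computes the median intensity over events above the gate threshold for
#' each sample (or over all events with `gated = FALSE`). Samples with zero
#' gated events are flagged and their median set to `NA` (excluded from any
#' downstream mean). If `reference_sample` is given, a `relative_median`
#' column reports each median as a ratio to that sample's; per-repeat
#' two-condition normalization is left to [two_condition_normalize()].
#'
#' @param samples tibble with `sample_id`, `intensity` and optional
#'   `condition` columns; rows are events.
#' @param threshold gate from [derive_gate()].
#' @param gated compute the median on gated events only (default) or on
#'   all events.
#' @param reference_sample optional `sample_id` used as ratio denominator.
#' @return Tibble with `sample_id` (and `condition` if present),
#'   `n_events`, `n_gated`, `median_intensity`, `flagged` and optionally
#'   `relative_median`.
#' @export
relative_median_mfi <- function(samples, threshold, gated = TRUE,
                                reference_sample = NULL) {
  stopifnot(all(c("sample_id", "intensity") %in% names(samples)))
  grp <- intersect(c("sample_id", "condition"), names(samples))
  out <- dplyr::summarise(
    dplyr::group_by(samples, dplyr::across(dplyr::all_of(grp))),
    n_events = dplyr::n(),
    n_gated = sum(.data$intensity > threshold),
    median_intensity = {
      v <- if (gated) .data$intensity[.data$intensity > threshold]
           else .data$intensity
      if (length(v)) stats::median(v) else NA_real_
    },
    .groups = "drop")
  out$flagged <- gated & out$n_gated == 0
  if (!is.null(reference_sample)) {
    i <- match(reference_sample, out$sample_id)
    if (is.na(i)) stop("reference_sample '", reference_sample, "' not found")
    out$relative_median <- out$median_intensity / out$median_intensity[i]
  }
  out
}
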