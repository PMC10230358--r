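#' Ventilation adjustment of the distance stream
#'
#' During mechanical ventilation the natural variation of vital parameters
#' is iatrogenically diminished, so the Mahalanobis distance is inflated by
#' `multiplier` (default +20%) at ventilated seconds to keep deviations
#' comparable across ventilation states.
#'
#' @param d nonnegative distance(s).
#' @param ventilated logical vector (recycled to `length(d)`).
#' @param multiplier inflation factor (default 1.2).
#' @return adjusted distances.
#' @export
adjust_for_ventilation <- function(d, ventilated, multiplier = 1.2) {
  ifelse(rep_len(ventilated, length(d)), d * multiplier, d)
}

#' Trend and baseline medians of the adjusted distance stream
#'
#' `trend_Z()` is the causal moving median of the ventilation-adjusted
#' distances over the `window` seconds preceding each time point (undefined
#' when fewer than `min_obs` values fall in the window). `baseline_B()` is
#' the patient's unique baseline: the expanding median of all adjusted
#' distances preceding each time point. Both skip seconds with no distance
#' sample (incomplete parameter vectors) and depend only on strictly past
#' values.
#'
#' @param d_adj numeric vector of per-second adjusted distances (`NA` where
#'   no sample).
#' @param window trailing window in seconds (default 300).
#' @param min_obs minimum defined values in the window (default 150).
#' @return numeric vector of the same length; `NA` where undefined.
#' @name baseline_medians
NULL

#' @rdname baseline_medians
#' @export
trend_Z <- function(d_adj, window = 300L, min_obs = 150L) {
  roll_median_prev(as.numeric(d_adj), as.integer(window), as.integer(min_obs))
}

#' @rdname baseline_medians
#' @export
baseline_B <- function(d_adj) {
  expanding_median_prev(as.numeric(d_adj))
}

#' Trimmed noise SD of the baseline-corrected distance stream
#'
#' The instability threshold needs the noise scale of supposedly stable
#' time: the standard deviation of the baseline-corrected distances
#' `c(s) = d'(s) - B(s)` after removal of the upper `trim_percent`% of
#' values (which are presumed to contain the unstable time). Computation is
#' causal: the SD at time t uses only history before t, and is recomputed
#' every `cadence` seconds (held constant in between).
#'
#' @param corrected numeric vector of per-second baseline-corrected
#'   distances (`NA` where undefined).
#' @param trim_percent upper percentage removed (default 20; the largest
#'   `floor(n * trim_percent/100)` values are dropped).
#' @param min_history minimum corrected values before the SD is defined
#'   (default 600).
#' @param cadence recomputation interval in seconds (default 60).
#' @return numeric vector of SD values, `NA` where undefined.
#' @export
trimmed_sd_stream <- function(corrected, trim_percent = 20, min_history = 600L,
                              cadence = 60L) {
  n <- length(corrected)
  out <- rep(NA_real_, n)
  if (n < 2L) return(out)
  recompute <- seq(2L, n, by = as.integer(cadence))
  for (j in seq_along(recompute)) {
    i <- recompute[j]
    h <- corrected[seq_len(i - 1L)]
    h <- h[!is.na(h)]
    if (length(h) >= min_history) {
      upto <- if (j < length(recompute)) recompute[j + 1L] - 1L else n
      out[i:upto] <- trimmed_sd(h, trim_percent)
    }
  }
  out
}

#' @rdname trimmed_sd_stream
#' @param values numeric vector of baseline-corrected distances (no `NA`).
#' @export
trimmed_sd <- function(values, trim_percent = 20) {
  n <- length(values)
  drop_n <- floor(n * trim_percent / 100)
  kept <- sort(values)[seq_len(n - drop_n)]
  if (length(kept) < 2L) return(NA_real_)
  sd(kept)
}

#' Classify baseline deviation
#'
#' Because distances are computed on normalized values, a trend moving
#' toward the stratum centre (`Z - B < 0`) reflects clinical improvement,
#' while a trend drifting at least `k` noise-SDs above the patient's
#' baseline (`Z - B >= k * sd`) reflects instability. Improvement is
#' treated as non-unstable by the fusion stage.
#'
#' @param Z,B,sd_value numeric vectors (trend, baseline, trimmed SD);
#'   elements with any `NA` yield `NA`.
#' @param k threshold in SD multiples (default 2).
#' @return character vector of `"IMPROVEMENT"` / `"STABLE"` / `"UNSTABLE"`.
#' @export
classify_submodel3 <- function(Z, B, sd_value, k = 2) {
  delta <- Z - B
  out <- ifelse(delta < 0, "IMPROVEMENT",
                ifelse(delta >= k * sd_value, "UNSTABLE", "STABLE"))
  out[is.na(Z) | is.na(B) | is.na(sd_value)] <- NA_character_
  out
}

#' Patient-specific baseline-deviation stream of a record
#'
#' Runs the full baseline analysis: Mahalanobis distance of each complete
#' z-scored parameter vector, +20% ventilation adjustment, trend median Z,
#' expanding baseline median B, causal trimmed noise SD, and the
#' improvement / stable / unstable labels.
#'
#' @param record a [vital_record].
#' @param model a fitted `stratum_model` (supplies the stratum moments).
#' @param control a [detect_control()] list.
#' @return data.frame trace with columns
#'   `t, d_adj, Z, B, SD, zb_delta, label3`.
#' @export
baseline_stream <- function(record, model, control = detect_control()) {
  pm <- parameter_matrix(record, control)
  z <- normalize_vectors(pm, model$stats)
  d <- mahalanobis_distance(z, model$stats$covariance)
  vent <- ventilation_status(record$data$etco2)
  d_adj <- adjust_for_ventilation(d, vent, control$vent_multiplier)
  Z <- trend_Z(d_adj, control$trend_window, control$trend_min_obs)
  B <- baseline_B(d_adj)
  corrected <- d_adj - B
  SD <- trimmed_sd_stream(corrected, control$sd_trim_percent,
                          control$sd_min_history, control$sd_cadence)
  label3 <- classify_submodel3(Z, B, SD, control$k)
  data.frame(t = record$data$t, d_adj = d_adj, Z = Z, B = B, SD = SD,
             zb_delta = Z - B, label3 = label3)
}
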