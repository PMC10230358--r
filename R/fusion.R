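#' Fuse per-second submodel outputs into one label
#'
#' Precedence per second: `WARMUP` during the first hour of admission;
#' `SENSOR_DYSFUNCTION` wherever the dysfunction mask is set (no stability
#' classification is attempted on dysfunctional data); `UNKNOWN` when
#' neither stability submodel produced an output; `UNSTABLE` when either
#' the population-level or the baseline-deviation submodel — or both —
#' calls the second unstable; `STABLE` otherwise (improvement counts as
#' non-unstable).
#'
#' @param dysfunction logical vector (dysfunction mask).
#' @param s2 character vector of population-level labels
#'   (`"STABLE"`/`"UNSTABLE"`/`NA`).
#' @param s3 character vector of baseline labels
#'   (`"IMPROVEMENT"`/`"STABLE"`/`"UNSTABLE"`/`NA`).
#' @param t integer seconds since admission start.
#' @param warmup warm-up length in seconds (default 3600).
#' @return character vector of per-second labels.
#' @export
fuse_seconds <- function(dysfunction, s2, s3, t, warmup = 3600L) {
  n <- length(t)
  stopifnot(length(dysfunction) == n, length(s2) == n, length(s3) == n)
  unstable <- (!is.na(s2) & s2 == "UNSTABLE") | (!is.na(s3) & s3 == "UNSTABLE")
  known <- !is.na(s2) | !is.na(s3)
  out <- ifelse(unstable, "UNSTABLE", "STABLE")
  out[!known] <- "UNKNOWN"
  out[dysfunction] <- "SENSOR_DYSFUNCTION"
  out[t < warmup] <- "WARMUP"
  out
}

#' Smooth raw per-second labels with the 5-minute episode rule
#'
#' A second is episode-unstable when at least `min_unstable` of the
#' trailing `window` seconds carry a raw `UNSTABLE` label (nonconsecutive
#' seconds count); with fewer, it is episode-stable. `WARMUP`, `UNKNOWN`
#' and `SENSOR_DYSFUNCTION` seconds pass through unchanged and count as
#' non-unstable inside the window.
#'
#' @param labels character vector of raw fused labels.
#' @param window trailing window in seconds (default 300; includes the
#'   current second).
#' @param min_unstable threshold count (default 240, i.e. >= 80%).
#' @return character vector of smoothed labels.
#' @export
smooth_labels <- function(labels, window = 300L, min_unstable = 240L) {
  n <- length(labels)
  raw_unst <- labels == "UNSTABLE"
  cs0 <- c(0L, cumsum(raw_unst))
  i <- seq_len(n)
  lo <- pmax(i - window + 1L, 1L)
  cnt <- cs0[i + 1L] - cs0[lo]
  out <- labels
  classify <- labels %in% c("STABLE", "UNSTABLE")
  out[classify] <- ifelse(cnt[classify] >= min_unstable, "UNSTABLE", "STABLE")
  out
}

# Relabel UNKNOWN runs of <= gap_max seconds flanked on both sides by the
# same episode label to that label, so short data gaps do not split an
# episode. Longer gaps break runs and stay UNKNOWN.
bridge_unknown <- function(labels, gap_max = 60L) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] != "UNKNOWN" || r$lengths[j] > gap_max) next
    if (j == 1L || j == length(r$values)) next
    if (r$values[j - 1L] == r$values[j + 1L] &&
        r$values[j - 1L] %in% c("STABLE", "UNSTABLE", "SENSOR_DYSFUNCTION"))
      labels[starts[j]:ends[j]] <- r$values[j - 1L]
  }
  labels
}

#' Segment smoothed labels into episodes
#'
#' Maximal constant-label runs of `STABLE`, `UNSTABLE` and
#' `SENSOR_DYSFUNCTION` (warm-up and unknown seconds are excluded) are
#' split left-to-right into chunks of at most `cap` seconds; episodes are
#' counted with a maximum duration of 2 consecutive hours so that results
#' do not shift with episode length.
#'
#' @param labels character vector of smoothed per-second labels.
#' @param t integer seconds since admission start (defaults to 0-based).
#' @param cap maximum episode duration in seconds (default 7200).
#' @param unknown_gap_max bridgeable unknown-gap length (default 60);
#'   see Details.
#' @return data.frame with columns `start`, `end` (inclusive), `label`,
#'   `duration_s`.
#' @export
segment_episodes <- function(labels, t = seq_along(labels) - 1L, cap = 7200L,
                             unknown_gap_max = 60L) {
  labels <- bridge_unknown(labels, unknown_gap_max)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("STABLE", "UNSTABLE", "SENSOR_DYSFUNCTION")
  out <- list()
  for (j in which(keep)) {
    lo <- starts[j]
    while (lo <= ends[j]) {
      hi <- min(lo + cap - 1L, ends[j])
      out[[length(out) + 1L]] <- data.frame(
        start = t[lo], end = t[hi], label = r$values[j],
        duration_s = hi - lo + 1L)
      lo <- hi + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), duration_s = integer(0)))
  do.call(rbind, out)
}
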