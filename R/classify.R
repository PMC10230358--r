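#' Classify a patient record into a deterioration timeline
#'
#' Runs the full detector on one record: builds the per-second 5-parameter
#' vectors, applies the sensor-dysfunction rules, classifies every complete
#' vector with the population-level stratum model, runs the patient-specific
#' baseline-deviation analysis, fuses the three outputs with dysfunction
#' precedence and the first-hour warm-up, smooths with the 5-minute
#' episode-window rule, and segments the result into capped episodes.
#'
#' @param record a [vital_record].
#' @param model a fitted `stratum_model` (see [fit_stratum_model()]) for
#'   the record's stratum.
#' @param control a [detect_control()] list of thresholds.
#' @return An object of class `deterioration_timeline`: list with
#'   `timeline` (data.frame `t, label, sources`), `episodes` (data.frame
#'   `start, end, label, duration_s`), `trace` (baseline-deviation
#'   diagnostics, see [baseline_stream()]), `mask` (dysfunction mask),
#'   `stratum`, `patient_id`, `control`.
#' @export
classify_record <- function(record, model, control = detect_control()) {
  stopifnot(inherits(record, "vital_record"), inherits(model, "stratum_model"))
  pm <- parameter_matrix(record, control)
  mask <- dysfunction_mask(record, control)
  s2 <- predict(model, pm)
  trace <- baseline_stream(record, model, control)
  t <- record$data$t
  raw <- fuse_seconds(mask$mask, s2, trace$label3, t, control$warmup)
  smoothed <- smooth_labels(raw, control$smooth_window,
                            control$smooth_min_unstable)
  smoothed <- bridge_unknown(smoothed, control$unknown_gap_max)
  episodes <- segment_episodes(smoothed, t, control$episode_cap,
                               control$unknown_gap_max)
  sources <- character(length(t))
  fired2 <- !is.na(s2) & s2 == "UNSTABLE"
  fired3 <- !is.na(trace$label3) & trace$label3 == "UNSTABLE"
  sources[fired2] <- "s2"
  sources[fired3] <- ifelse(sources[fired3] == "", "s3",
                            paste(sources[fired3], "s3", sep = ";"))
  sources[mask$mask] <- "s1"
  structure(
    list(timeline = data.frame(t = t, label = smoothed, raw_label = raw,
                               sources = sources),
         episodes = episodes, trace = trace, mask = mask,
         stratum = model$stats$stratum, patient_id = record$patient_id,
         control = control),
    class = "deterioration_timeline")
}

#' @export
print.deterioration_timeline <- function(x, ...) {
  tl <- x$timeline
  cat(sprintf("<deterioration_timeline> patient %s (%s), %d s (%.1f h)\n",
              x$patient_id, x$stratum, nrow(tl), nrow(tl) / 3600))
  tab <- table(factor(tl$label, levels = LABELS))
  for (nm in names(tab))
    if (tab[[nm]] > 0L)
      cat(sprintf("  %-18s %7d s (%5.1f%%)\n", nm, tab[[nm]],
                  100 * tab[[nm]] / nrow(tl)))
  ep <- table(factor(x$episodes$label,
                     levels = c("STABLE", "UNSTABLE", "SENSOR_DYSFUNCTION")))
  cat(sprintf("  episodes: %d stable, %d unstable, %d sensor-dysfunction\n",
              ep[["STABLE"]], ep[["UNSTABLE"]], ep[["SENSOR_DYSFUNCTION"]]))
  invisible(x)
}

#' @export
summary.deterioration_timeline <- function(object, ...) {
  print(object)
  if (nrow(object$episodes)) {
    cat("  episode table:\n")
    print(object$episodes, row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.deterioration_timeline <- function(x, ...) x$timeline

#' Plot a deterioration timeline
#'
#' Draws the ventilation-adjusted distance stream with trend and baseline
#' medians, and a coloured classification band underneath.
#'
#' @param x a `deterioration_timeline`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.deterioration_timeline <- function(x, ...) {
  tr <- x$trace
  h <- tr$t / 3600
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h, tr$d_adj, type = "l", col = "grey70",
                 xlab = "", ylab = "adjusted distance",
                 main = sprintf("patient %s (%s)", x$patient_id, x$stratum), ...)
  graphics::lines(h, tr$Z, col = "steelblue", lwd = 1.5)
  graphics::lines(h, tr$B, col = "darkorange", lwd = 1.5)
  graphics::legend("topright", c("d'", "Z (trend)", "B (baseline)"),
                   col = c("grey70", "steelblue", "darkorange"), lwd = 1.5,
                   bty = "n", cex = 0.8)
  cols <- c(WARMUP = "grey85", UNKNOWN = "white", SENSOR_DYSFUNCTION = "gold",
            STABLE = "palegreen3", UNSTABLE = "firebrick2")
  lab <- x$timeline$label
  graphics::plot(range(h), c(0, 1), type = "n", xlab = "hours since admission",
                 ylab = "", yaxt = "n")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  graphics::rect(h[starts], 0, h[ends], 1, col = cols[r$values], border = NA)
  graphics::legend("top", names(cols), fill = cols, horiz = TRUE, bty = "n",
                   cex = 0.7)
  invisible(x)
}

#' Export a timeline and its episodes to CSV
#'
#' @param x a `deterioration_timeline`.
#' @param timeline_path,episodes_path output CSV paths (`NULL` to skip).
#' @export
write_timeline <- function(x, timeline_path = NULL, episodes_path = NULL) {
  stopifnot(inherits(x, "deterioration_timeline"))
  if (!is.null(timeline_path))
    write.csv(x$timeline[c("t", "label", "sources")], timeline_path,
              row.names = FALSE, quote = FALSE)
  if (!is.null(episodes_path))
    write.csv(x$episodes, episodes_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}
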