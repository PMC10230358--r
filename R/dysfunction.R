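#' Sensor-dysfunction rules
#'
#' Per-second artifact rules for the monitored parameters. Heart rate is
#' deliberately never checked: no reliable distinction can be made between a
#' true cardiac arrest and an HR sensor error.
#'
#' `detect_jump()` flags a second when the absolute difference to the
#' previously measured value (at t-1) exceeds `threshold` points; if the
#' previous second is missing no comparison is made. Applies to invasive
#' blood pressure and SpO2.
#'
#' `detect_rso2_limit()` flags readings at the ends of the rSO2 scale
#' (`<= low` or `>= high`), which arise from escaping sensor-light emission
#' rather than true cerebral saturation.
#'
#' `detect_rr_malfunction()` flags raw (unsmoothed) respiratory rates below
#' `floor` breaths per minute.
#'
#' @param x numeric per-second series (`NA` = missing).
#' @param threshold jump size in scale points (strict `>`, default 25).
#' @param low,high rSO2 scale limits (default 15 and 95, inclusive).
#' @param floor RR malfunction floor in breaths/min (strict `<`, default 5).
#' @return integer vector of triggering second indices (1-based positions in
#'   the series).
#' @name dysfunction_rules
NULL

#' @rdname dysfunction_rules
#' @export
detect_jump <- function(x, threshold = 25) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  d <- abs(diff(x))
  which(c(FALSE, !is.na(d) & d > threshold))
}

#' @rdname dysfunction_rules
#' @export
detect_rso2_limit <- function(x, low = 15, high = 95) {
  which(!is.na(x) & (x <= low | x >= high))
}

#' @rdname dysfunction_rules
#' @export
detect_rr_malfunction <- function(x, floor = 5) {
  which(!is.na(x) & x < floor)
}

#' Expand dysfunction detections into a per-second mask
#'
#' Consecutive triggering seconds of one parameter (gap <= 1 s) form a
#' detection run; each run flags the interval from one minute before its
#' first detection to one minute after its last, clipped to the record. The
#' final mask is the union over parameters, with per-parameter provenance.
#'
#' @param events named list of integer index vectors, one per parameter
#'   (e.g. `list(IBP = ..., SPO2 = ..., RSO2 = ..., RR = ...)`).
#' @param duration record length in seconds.
#' @param pad padding in seconds on each side of a run (default 60).
#' @return An object of class `dysfunction_mask`: list with `mask` (logical,
#'   length `duration`), `by_parameter` (logical matrix), `events`.
#' @export
expand_windows <- function(events, duration, pad = 60L) {
  duration <- as.integer(duration)
  params <- names(events)
  if (is.null(params)) params <- paste0("P", seq_along(events))
  by_param <- matrix(FALSE, nrow = duration, ncol = length(events),
                     dimnames = list(NULL, params))
  for (j in seq_along(events)) {
    ev <- sort(unique(as.integer(events[[j]])))
    ev <- ev[ev >= 1L & ev <= duration]
    if (length(ev) == 0L) next
    run_id <- cumsum(c(1L, diff(ev) > 1L))
    for (r in split(ev, run_id)) {
      lo <- max(1L, r[1L] - pad)
      hi <- min(duration, r[length(r)] + pad)
      by_param[lo:hi, j] <- TRUE
    }
  }
  structure(list(mask = rowSums(by_param) > 0L, by_parameter = by_param,
                 events = events, pad = as.integer(pad)),
            class = "dysfunction_mask")
}

#' @export
print.dysfunction_mask <- function(x, ...) {
  cat(sprintf("<dysfunction_mask> %d of %d seconds flagged (%.1f%%)\n",
              sum(x$mask), length(x$mask), 100 * mean(x$mask)))
  ev <- vapply(x$events, length, integer(1))
  if (length(ev)) cat("  detections:", paste(names(ev), ev, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Sensor-dysfunction mask of a record
#'
#' Applies all dysfunction rules to a record and expands detections with the
#' +/- `pad` second rule: jump rule on IBP and SpO2, scale-limit rule on the
#' fused rSO2 and on each raw probe (a railing probe is an artifact even
#' when the other probe is valid), and the malfunction floor on raw RR.
#'
#' @param record a [vital_record].
#' @param control a [detect_control()] list.
#' @return A `dysfunction_mask` (see [expand_windows()]).
#' @export
dysfunction_mask <- function(record, control = detect_control()) {
  d <- record$data
  fused <- fuse_rso2(d$rso2_left, d$rso2_right)
  rso2_events <- sort(unique(c(
    detect_rso2_limit(fused, control$rso2_low, control$rso2_high),
    detect_rso2_limit(d$rso2_left, control$rso2_low, control$rso2_high),
    detect_rso2_limit(d$rso2_right, control$rso2_low, control$rso2_high))))
  events <- list(
    IBP = detect_jump(d$ibp_mean, control$jump_threshold),
    SPO2 = detect_jump(d$spo2, control$jump_threshold),
    RSO2 = rso2_events,
    RR = detect_rr_malfunction(d$rr, control$rr_floor))
  expand_windows(events, duration = nrow(d), pad = control$pad)
}

#' Export a dysfunction mask as a per-second table
#'
#' @param mask a `dysfunction_mask`.
#' @param t integer timestamps to attach (defaults to 0-based seconds).
#' @return data.frame with columns `t`, `dysfunction`, `parameters`
#'   (semicolon-joined provenance).
#' @export
mask_table <- function(mask, t = seq_len(length(mask$mask)) - 1L) {
  prov <- apply(mask$by_parameter, 1L, function(row)
    paste(colnames(mask$by_parameter)[row], collapse = ";"))
  data.frame(t = t, dysfunction = mask$mask, parameters = prov)
}
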