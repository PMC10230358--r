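#' Detection-pipeline tuning parameters
#'
#' Collects every tunable threshold of the detector in one place. The
#' defaults are the model's operating constants; all are overridable.
#'
#' @param jump_threshold points of change between consecutive seconds above
#'   which an IBP or SpO2 reading is a sensor jump (default 25, strict `>`).
#' @param rso2_low,rso2_high rSO2 scale limits; readings `<= rso2_low` or
#'   `>= rso2_high` are measurement error from escaping sensor light
#'   (defaults 15 and 95).
#' @param rr_floor raw respiratory rate below which the RR sensor is
#'   malfunctioning (default 5, strict `<`).
#' @param pad seconds of padding around each dysfunction detection run
#'   (default 60: the minute before the first and after the last detection).
#' @param rr_window,rr_min_obs trailing window and minimum observations for
#'   the RR trend (defaults 300 and 150).
#' @param trend_window,trend_min_obs trailing window and minimum observations
#'   for the baseline-deviation trend median Z (defaults 300 and 150).
#' @param vent_multiplier multiplicative inflation of the Mahalanobis
#'   distance during mechanical ventilation (default 1.2, i.e. +20%,
#'   compensating iatrogenically diminished variation).
#' @param sd_trim_percent upper percentage of baseline-corrected distances
#'   removed before computing the noise SD (default 20).
#' @param sd_min_history minimum baseline-corrected values before the
#'   trimmed SD is defined (default 600).
#' @param sd_cadence seconds between trimmed-SD recomputations; the value is
#'   held constant in between (default 60).
#' @param k instability threshold in multiples of the trimmed SD applied to
#'   Z - B (default 2).
#' @param smooth_window,smooth_min_unstable the moving episode window: a
#'   second is episode-unstable when at least `smooth_min_unstable` of the
#'   trailing `smooth_window` seconds are raw-unstable (defaults 300 and
#'   240, i.e. at least 4 of any 5 minutes).
#' @param unknown_gap_max longest run of missing-data seconds bridged inside
#'   an episode (default 60).
#' @param episode_cap maximum counted episode duration in seconds
#'   (default 7200: 2 consecutive hours).
#' @param warmup seconds of baseline build-up during which no classification
#'   is emitted (default 3600: the first hour of admission).
#' @return A classed list of parameters.
#' @export
detect_control <- function(jump_threshold = 25, rso2_low = 15, rso2_high = 95,
                           rr_floor = 5, pad = 60L,
                           rr_window = 300L, rr_min_obs = 150L,
                           trend_window = 300L, trend_min_obs = 150L,
                           vent_multiplier = 1.2,
                           sd_trim_percent = 20, sd_min_history = 600L,
                           sd_cadence = 60L, k = 2,
                           smooth_window = 300L, smooth_min_unstable = 240L,
                           unknown_gap_max = 60L, episode_cap = 7200L,
                           warmup = 3600L) {
  ctl <- list(jump_threshold = jump_threshold, rso2_low = rso2_low,
              rso2_high = rso2_high, rr_floor = rr_floor, pad = as.integer(pad),
              rr_window = as.integer(rr_window), rr_min_obs = as.integer(rr_min_obs),
              trend_window = as.integer(trend_window),
              trend_min_obs = as.integer(trend_min_obs),
              vent_multiplier = vent_multiplier,
              sd_trim_percent = sd_trim_percent,
              sd_min_history = as.integer(sd_min_history),
              sd_cadence = as.integer(sd_cadence), k = k,
              smooth_window = as.integer(smooth_window),
              smooth_min_unstable = as.integer(smooth_min_unstable),
              unknown_gap_max = as.integer(unknown_gap_max),
              episode_cap = as.integer(episode_cap),
              warmup = as.integer(warmup))
  stopifnot(ctl$jump_threshold > 0, ctl$rso2_low < ctl$rso2_high,
            ctl$rr_floor > 0, ctl$pad >= 0, ctl$vent_multiplier >= 1,
            ctl$sd_trim_percent >= 0, ctl$sd_trim_percent < 100,
            ctl$k >= 0, ctl$smooth_min_unstable <= ctl$smooth_window,
            ctl$episode_cap >= 1, ctl$warmup >= 0)
  class(ctl) <- "detect_control"
  ctl
}
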