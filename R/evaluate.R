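#' Time-percentual scoring of a label timeline against truth
#'
#' For each class (stable, unstable, sensor dysfunction): occurrence is the
#' truth time carrying that class; correctness is the fraction of those
#' seconds the detector labeled identically. Warm-up seconds and seconds
#' the detector could not classify (`UNKNOWN`) are excluded from both
#' numerator and denominator.
#'
#' @param predicted,truth character vectors of per-second labels, same
#'   length.
#' @return data.frame with one row per class: `class`, `occurrence_s`,
#'   `correct_s`, `occurrence_h`, `correct_pct`.
#' @export
time_score <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  keep <- truth != "WARMUP" & !predicted %in% c("WARMUP", "UNKNOWN")
  p <- predicted[keep]; tr <- truth[keep]
  cls <- c("STABLE", "UNSTABLE", "SENSOR_DYSFUNCTION")
  occ <- vapply(cls, function(k) sum(tr == k), numeric(1))
  cor <- vapply(cls, function(k) sum(tr == k & p == k), numeric(1))
  data.frame(class = cls, occurrence_s = occ, correct_s = cor,
             occurrence_h = occ / 3600,
             correct_pct = ifelse(occ > 0, 100 * cor / occ, NA_real_),
             row.names = NULL)
}

# maximal constant-label runs of the scoreable classes, split at the cap
label_runs <- function(labels, t, cap = 7200L) {
  segment_episodes(labels, t, cap = cap, unknown_gap_max = 0L)
}

#' Episodic scoring of predicted episodes against truth intervals
#'
#' Truth episodes (maximal runs of one truth class, pre-split at the 2-hour
#' cap) count as correctly detected when at least one predicted episode of
#' the same class overlaps them; a correct detection whose total same-class
#' overlap covers less than `match_fraction` of the truth duration is
#' additionally counted as partial (detected, but the labeling did not
#' cover the full episode).
#'
#' @param predicted data.frame of predicted episodes
#'   (`start, end, label, duration_s`), e.g. from [classify_record()].
#' @param truth character vector of per-second truth labels.
#' @param t integer timestamps matching `truth`.
#' @param match_fraction coverage below which a detection is partial
#'   (default 0.5).
#' @param cap episode cap in seconds (default 7200).
#' @return data.frame with one row per class: `class`, `occurrence`,
#'   `correct`, `partial`, `correct_pct`.
#' @export
episodic_score <- function(predicted, truth, t = seq_along(truth) - 1L,
                           match_fraction = 0.5, cap = 7200L) {
  te <- label_runs(truth, t, cap)
  cls <- c("STABLE", "UNSTABLE", "SENSOR_DYSFUNCTION")
  res <- lapply(cls, function(k) {
    tk <- te[te$label == k, , drop = FALSE]
    pk <- predicted[predicted$label == k, , drop = FALSE]
    correct <- 0L; partial <- 0L
    if (nrow(tk)) for (i in seq_len(nrow(tk))) {
      ov <- pmax(0L, pmin(tk$end[i], pk$end) - pmax(tk$start[i], pk$start) + 1L)
      tot <- sum(ov)
      if (tot > 0L) {
        correct <- correct + 1L
        if (tot < match_fraction * tk$duration_s[i]) partial <- partial + 1L
      }
    }
    data.frame(class = k, occurrence = nrow(tk), correct = correct,
               partial = partial,
               correct_pct = if (nrow(tk)) 100 * correct / nrow(tk) else NA_real_)
  })
  do.call(rbind, res)
}

#' Score one classified record against its ground truth
#'
#' @param timeline a `deterioration_timeline` from [classify_record()].
#' @param truth data.frame `t, truth_label` (e.g. from [simulate_record()]).
#' @param match_fraction,cap see [episodic_score()].
#' @return list with elements `stratum`, `time` ([time_score()] fragment)
#'   and `episodic` ([episodic_score()] fragment).
#' @export
evaluate_timeline <- function(timeline, truth, match_fraction = 0.5,
                              cap = 7200L) {
  stopifnot(inherits(timeline, "deterioration_timeline"),
            all(timeline$timeline$t == truth$t))
  list(stratum = timeline$stratum,
       time = time_score(timeline$timeline$label, truth$truth_label),
       episodic = episodic_score(timeline$episodes, truth$truth_label,
                                 truth$t, match_fraction, cap))
}

#' Aggregate per-record scores into a performance report
#'
#' Sums episodic and time scores per stratum and overall, in the layout of
#' a performance-overview table: episodic occurrence and correctness, time
#' occurrence (hours) and correctness, for stable, unstable and
#' sensor-dysfunction classes.
#'
#' @param scores list of [evaluate_timeline()] results.
#' @return An object of class `performance_report` (a data.frame with
#'   columns `stratum, class, episodic_occurrence, episodic_correct,
#'   episodic_partial, episodic_correct_pct, time_occurrence_h,
#'   time_correct_h, time_correct_pct`).
#' @export
performance_report <- function(scores) {
  strata <- unique(vapply(scores, `[[`, character(1), "stratum"))
  one <- function(sel, name) {
    ep <- Reduce(`+`, lapply(scores[sel], function(s)
      as.matrix(s$episodic[c("occurrence", "correct", "partial")])))
    tm <- Reduce(`+`, lapply(scores[sel], function(s)
      as.matrix(s$time[c("occurrence_s", "correct_s")])))
    cls <- scores[[which(sel)[1L]]]$episodic$class
    data.frame(stratum = name, class = cls,
               episodic_occurrence = ep[, "occurrence"],
               episodic_correct = ep[, "correct"],
               episodic_partial = ep[, "partial"],
               episodic_correct_pct = ifelse(ep[, "occurrence"] > 0,
                 100 * ep[, "correct"] / ep[, "occurrence"], NA_real_),
               time_occurrence_h = tm[, "occurrence_s"] / 3600,
               time_correct_h = tm[, "correct_s"] / 3600,
               time_correct_pct = ifelse(tm[, "occurrence_s"] > 0,
                 100 * tm[, "correct_s"] / tm[, "occurrence_s"], NA_real_),
               row.names = NULL)
  }
  parts <- lapply(strata, function(st)
    one(vapply(scores, function(s) s$stratum == st, logical(1)), st))
  parts[[length(parts) + 1L]] <- one(rep(TRUE, length(scores)), "Total")
  out <- do.call(rbind, parts)
  class(out) <- c("performance_report", "data.frame")
  out
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Performance analysis overview (episodic and time occurrence)\n")
  for (st in unique(x$stratum)) {
    cat(sprintf("\n== %s ==\n", st))
    sub <- x[x$stratum == st, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      cat(sprintf("  %-18s episodes %3d correct %3d (%s%%) partial %d | time %6.1f h correct %6.1f h (%s%%)\n",
                  r$class, r$episodic_occurrence, r$episodic_correct,
                  ifelse(is.na(r$episodic_correct_pct), "-",
                         sprintf("%.0f", r$episodic_correct_pct)),
                  r$episodic_partial, r$time_occurrence_h, r$time_correct_h,
                  ifelse(is.na(r$time_correct_pct), "-",
                         sprintf("%.0f", r$time_correct_pct))))
    }
  }
  invisible(x)
}
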