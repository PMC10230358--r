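#' Stratum physiology profiles for the simulator
#'
#' Central values are the published cohort medians for the two saturation
#' strata; dispersions are derived from the printed interquartile ranges via
#' the normal-theory factor IQR/1.349. Because those are cohort-level
#' spreads, the variance is partitioned into a patient-specific baseline
#' offset (fraction `between_fraction`, drawn once per record — each
#' neonate has a unique baseline, the premise of the baseline-deviation
#' analysis) and within-record dynamics on two timescales: a slow
#' multivariate AR(1) wander (coefficient `phi` per second; drifts over
#' tens of minutes) and a fast AR(1) fluctuation (coefficient `phi_fast`;
#' the seconds-scale variability from breathing, movement and behavioural
#' state), both sharing a mild cross-parameter correlation (positive HR-RR
#' and SpO2-rSO2), plus independent second-to-second measurement jitter of
#' typical bedside monitor magnitude on each parameter. The ensemble
#' marginal over many records reproduces the cohort dispersions. Physiologic clip ranges keep clean
#' records inside valid sensor scales — in particular strictly inside the
#' rSO2 (15, 95) artifact band, so an artifact-free record never trips the
#' rail rule.
#'
#' @param stratum `"LOW_SAT"` (admission-mean SpO2 < 90%) or `"HIGH_SAT"`.
#' @param phi slow AR(1) coefficient per second (default 0.999).
#' @param phi_fast fast AR(1) coefficient per second (default 0.9).
#' @param between_fraction fraction of the cohort variance attributed to
#'   between-patient baseline differences (default 0.6, in the range of
#'   published intraclass correlations for repeated vital-sign measurements
#'   in intensive care).
#' @param fast_fraction share of the within-record variance carried by the
#'   fast component (default 0.5).
#' @param correlation 5x5 correlation matrix (canonical parameter order).
#' @param jitter named vector of iid per-second measurement-noise SDs in
#'   clinical units (defaults: HR 3 beats/min, RR 2 breaths/min, SpO2 1%,
#'   rSO2 1.5% per probe, IBP 2 mm Hg).
#' @param probe_sd SD of the slow left/right rSO2 probe offsets (default 2).
#' @return A classed list with `centre`, `sd`, `correlation`, `phi`,
#'   `clip_low`, `clip_high`, `jitter`, `probe_sd`, `stratum`.
#' @export
stratum_profile <- function(stratum = c("LOW_SAT", "HIGH_SAT"), phi = 0.999,
                            phi_fast = 0.9, between_fraction = 0.6,
                            fast_fraction = 0.5, correlation = NULL,
                            jitter = c(hr = 3, rr = 2, spo2 = 1, rso2 = 1.5,
                                       ibp = 2),
                            probe_sd = 2) {
  stopifnot(between_fraction >= 0, between_fraction < 1,
            fast_fraction >= 0, fast_fraction <= 1)
  stratum <- match.arg(stratum)
  iqr_sd <- function(lo, hi) (hi - lo) / 1.349
  if (stratum == "LOW_SAT") {
    centre <- c(hr = 159, rr = 34, spo2 = 77, rso2 = 55.0, ibp = 51)
    disp <- c(hr = iqr_sd(147, 170), rr = iqr_sd(30, 38), spo2 = iqr_sd(70, 81),
              rso2 = iqr_sd(49, 63), ibp = iqr_sd(47, 57))
  } else {
    centre <- c(hr = 146, rr = 35, spo2 = 97, rso2 = 71.5, ibp = 53)
    disp <- c(hr = iqr_sd(132, 158), rr = iqr_sd(30, 40), spo2 = iqr_sd(95, 100),
              rso2 = iqr_sd(63.5, 80), ibp = iqr_sd(47, 60))
  }
  if (is.null(correlation)) {
    correlation <- diag(5)
    correlation[1, 2] <- correlation[2, 1] <- 0.3  # hr-rr
    correlation[3, 4] <- correlation[4, 3] <- 0.5  # spo2-rso2
  }
  stopifnot(all(dim(correlation) == c(5, 5)),
            all(abs(diag(correlation) - 1) < 1e-12),
            min(eigen(correlation, symmetric = TRUE,
                      only.values = TRUE)$values) > 0)
  clip_low <- c(hr = 50, rr = 6, spo2 = 5, rso2 = 16, ibp = 5)
  clip_high <- c(hr = 250, rr = 120, spo2 = 100, rso2 = 94.5, ibp = 150)
  structure(list(stratum = stratum, centre = centre, sd = disp,
                 correlation = correlation, phi = phi, phi_fast = phi_fast,
                 between_fraction = between_fraction,
                 fast_fraction = fast_fraction,
                 clip_low = clip_low, clip_high = clip_high,
                 jitter = jitter, probe_sd = probe_sd),
            class = "stratum_profile")
}

#' Simulator events
#'
#' Constructors for injectable events. `deterioration_event()` shifts two
#' or more parameters smoothly (logistic ramp over `ramp` seconds, sustained
#' to `end`, ramped back) by `magnitude` profile-SD units.
#' `artifact_event()` corrupts the signal the way a failing sensor does;
#' `ventilation_event()` raises EtCO2 above zero for its duration.
#'
#' @param start,end event interval in seconds (inclusive).
#' @param magnitude named vector of per-parameter shifts in profile-SD units
#'   (names among `hr, rr, spo2, rso2, ibp`); a deterioration must move at
#'   least 2 parameters.
#' @param ramp ramp length in seconds (default 300).
#' @param kind artifact kind: `ARTIFACT_JUMP` (step > 25 points with fast
#'   decay, on `parameter`), `ARTIFACT_RSO2_RAIL` (both probes railed to the
#'   scale `side`), `ARTIFACT_RR_LOSS` (raw RR below the malfunction floor),
#'   `DROPOUT` (parameters missing).
#' @param parameter target column for `ARTIFACT_JUMP` (`"ibp_mean"` or
#'   `"spo2"`) or columns for `DROPOUT`.
#' @param jump step size in points for `ARTIFACT_JUMP` (default 30).
#' @param side `"low"` or `"high"` rail for `ARTIFACT_RSO2_RAIL`.
#' @param level EtCO2 value during ventilation (default 4.8 kPa).
#' @return A classed event list.
#' @name sim_events
NULL

#' @rdname sim_events
#' @export
deterioration_event <- function(start, end,
                                magnitude = c(hr = 5, ibp = -5, rso2 = -5),
                                ramp = 300L) {
  if (sum(magnitude != 0) > 0 && sum(magnitude != 0) < 2)
    stop("a deterioration must shift at least 2 parameters")
  structure(list(kind = "DETERIORATION", start = as.integer(start),
                 end = as.integer(end), magnitude = magnitude,
                 ramp = as.integer(ramp)),
            class = "sim_event")
}

#' @rdname sim_events
#' @export
artifact_event <- function(kind = c("ARTIFACT_JUMP", "ARTIFACT_RSO2_RAIL",
                                    "ARTIFACT_RR_LOSS", "DROPOUT"),
                           start, end = start, parameter = "ibp_mean",
                           jump = 30, side = c("high", "low")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, start = as.integer(start), end = as.integer(end),
                 parameter = parameter, jump = jump, side = match.arg(side)),
            class = "sim_event")
}

#' @rdname sim_events
#' @export
ventilation_event <- function(start, end, level = 4.8) {
  structure(list(kind = "VENTILATION", start = as.integer(start),
                 end = as.integer(end), level = level),
            class = "sim_event")
}

# logistic ramp profile: 0 before start, ~1 on [start+ramp, end], back to 0
event_shape <- function(n, start, end, ramp) {
  t <- seq_len(n) - 1L
  if (ramp < 1L) return(as.numeric(t >= start & t <= end))
  up <- 1 / (1 + exp(-(t - (start + ramp / 2)) / (ramp / 8)))
  down <- 1 / (1 + exp(-(t - (end + ramp / 2)) / (ramp / 8)))
  up - down
}

#' Simulate a stratified neonatal vital-sign record with ground truth
#'
#' Generates a 1 Hz record from a clipped multivariate AR(1) around the
#' stratum profile centres, then injects the requested ventilation periods,
#' deterioration events and sensor artifacts, recording per-second ground
#' truth (`WARMUP` / `STABLE` / `UNSTABLE` / `SENSOR_DYSFUNCTION`) and the
#' artifact mask. Identical seeds and configurations produce identical
#' records.
#'
#' @param stratum `"LOW_SAT"` or `"HIGH_SAT"` (ignored when `profile`
#'   given).
#' @param duration record length in seconds (>= 7200).
#' @param seed integer seed.
#' @param events list of [sim_events] objects.
#' @param profile a [stratum_profile()]; default built from `stratum`.
#' @param patient_id,birth_weight_g,age_days record metadata.
#' @param warmup seconds marked `WARMUP` in the truth timeline
#'   (default 3600).
#' @return An object of class `sim_record`: list with `record`
#'   ([vital_record]), `truth` (data.frame `t, truth_label`),
#'   `artifact_seconds` (logical), `events`, `profile`, `seed`.
#' @export
simulate_record <- function(stratum = "LOW_SAT", duration = 21600L, seed = 1L,
                            events = list(), profile = NULL,
                            patient_id = "sim", birth_weight_g = 3400,
                            age_days = 7, warmup = 3600L) {
  if (is.null(profile)) profile <- stratum_profile(stratum)
  duration <- as.integer(duration)
  if (duration < 7200L) stop("duration must be at least 7200 seconds")
  for (ev in events)
    if (ev$start < 0L || ev$end >= duration || ev$start > ev$end)
      stop("event outside record: ", ev$kind)
  det <- Filter(function(e) e$kind == "DETERIORATION", events)
  if (length(det) > 1L) {
    iv <- sapply(det, function(e) c(e$start, e$end))
    o <- order(iv[1L, ])
    if (any(iv[1L, o][-1L] <= iv[2L, o][-ncol(iv)]))
      stop("overlapping deterioration events")
  }
  n <- duration
  x <- local_seed(seed, {
    S <- diag(profile$sd) %*% profile$correlation %*% diag(profile$sd)
    bf <- profile$between_fraction
    ff <- profile$fast_fraction
    # patient-specific baseline offset, then slow + fast AR(1) components
    # (chol of an all-zero matrix arises for zero-dispersion profiles)
    chol0 <- function(M) if (all(M == 0)) M else chol(M)
    offset <- drop(rnorm(5L) %*% chol0(bf * S))
    ar1 <- function(share, phi) {
      L <- chol0(share * S)
      e <- matrix(rnorm(n * 5L), n, 5L) %*% L * sqrt(1 - phi^2)
      e[1L, ] <- rnorm(5L) %*% L  # stationary start
      sapply(1:5, function(j) stats::filter(e[, j], phi, method = "recursive"))
    }
    x <- ar1((1 - bf) * (1 - ff), profile$phi) +
      (if (ff > 0) ar1((1 - bf) * ff, profile$phi_fast) else 0)
    x <- sweep(x, 2L, profile$centre + offset, "+")
    colnames(x) <- names(profile$centre)
    # per-second measurement jitter; slow probe offsets around the rSO2 latent
    jit <- profile$jitter
    x <- cbind(x,
               jit_hr = rnorm(n, 0, jit[["hr"]]),
               jit_rr = rnorm(n, 0, jit[["rr"]]),
               jit_spo2 = rnorm(n, 0, jit[["spo2"]]),
               jit_rso2_l = rnorm(n, 0, jit[["rso2"]]),
               jit_rso2_r = rnorm(n, 0, jit[["rso2"]]),
               jit_ibp = rnorm(n, 0, jit[["ibp"]]),
               off_l = as.numeric(stats::filter(
                 rnorm(n, 0, profile$probe_sd * sqrt(1 - profile$phi^2)),
                 profile$phi, method = "recursive")),
               off_r = as.numeric(stats::filter(
                 rnorm(n, 0, profile$probe_sd * sqrt(1 - profile$phi^2)),
                 profile$phi, method = "recursive")))
    x
  })
  t <- seq_len(n) - 1L
  truth <- rep("STABLE", n)
  # deterioration shifts (profile-sd units, smooth ramps), before clipping
  for (ev in det) {
    shape <- event_shape(n, ev$start, ev$end, ev$ramp)
    for (nm in names(ev$magnitude)) {
      if (!nm %in% colnames(x)[1:5]) stop("unknown parameter: ", nm)
      x[, nm] <- x[, nm] + ev$magnitude[[nm]] * profile$sd[[nm]] * shape
    }
    if (any(ev$magnitude != 0))
      truth[t >= ev$start & t <= ev$end] <- "UNSTABLE"
  }
  clip <- function(v, nm) pmin(pmax(v, profile$clip_low[[nm]]),
                               profile$clip_high[[nm]])
  hr <- clip(x[, "hr"] + x[, "jit_hr"], "hr")
  rr <- clip(x[, "rr"] + x[, "jit_rr"], "rr")
  spo2 <- clip(x[, "spo2"] + x[, "jit_spo2"], "spo2")
  rso2_l <- clip(x[, "rso2"] + x[, "off_l"] + x[, "jit_rso2_l"], "rso2")
  rso2_r <- clip(x[, "rso2"] + x[, "off_r"] + x[, "jit_rso2_r"], "rso2")
  ibp <- clip(x[, "ibp"] + x[, "jit_ibp"], "ibp")
  etco2 <- rep(0, n)
  artifact <- rep(FALSE, n)
  for (ev in events) {
    idx <- which(t >= ev$start & t <= ev$end)
    switch(ev$kind,
      VENTILATION = { etco2[idx] <- ev$level },
      ARTIFACT_JUMP = {
        # sustained step whose return decays below the jump threshold within
        # a few seconds, so exactly one jump event fires at onset
        decay <- ev$jump * c(1, 0.4, 0.15, 0.05)
        span <- ev$start + seq_along(decay) - 1L
        span <- span[span < n]
        target <- if (ev$parameter == "spo2") "spo2" else "ibp_mean"
        if (target == "spo2") spo2[span + 1L] <- pmin(100, spo2[span + 1L] + decay[seq_along(span)])
        else ibp[span + 1L] <- ibp[span + 1L] + decay[seq_along(span)]
        artifact[span + 1L] <- TRUE
        truth[span + 1L] <- "SENSOR_DYSFUNCTION"
      },
      ARTIFACT_RSO2_RAIL = {
        rail <- if (ev$side == "high") 95 else 10
        rso2_l[idx] <- rail; rso2_r[idx] <- rail
        artifact[idx] <- TRUE
        truth[idx] <- "SENSOR_DYSFUNCTION"
      },
      ARTIFACT_RR_LOSS = {
        rr[idx] <- 0
        artifact[idx] <- TRUE
        truth[idx] <- "SENSOR_DYSFUNCTION"
      },
      DROPOUT = {
        for (p in ev$parameter) {
          v <- switch(p, hr = , rr = , spo2 = , ibp_mean = , etco2 = p,
                      rso2 = c("rso2_left", "rso2_right"), p)
          if ("hr" %in% v) hr[idx] <- NA
          if ("rr" %in% v) rr[idx] <- NA
          if ("spo2" %in% v) spo2[idx] <- NA
          if (any(v == "rso2_left")) rso2_l[idx] <- NA
          if (any(v == "rso2_right")) rso2_r[idx] <- NA
          if ("ibp_mean" %in% v) ibp[idx] <- NA
          if ("etco2" %in% v) etco2[idx] <- NA
        }
      },
      DETERIORATION = NULL)
  }
  truth[t < warmup] <- "WARMUP"
  record <- vital_record(
    data.frame(t = t, hr = hr, rr = rr, spo2 = spo2, rso2_left = rso2_l,
               rso2_right = rso2_r, ibp_mean = ibp, etco2 = etco2),
    patient_id = patient_id, birth_weight_g = birth_weight_g,
    age_days = age_days)
  structure(list(record = record,
                 truth = data.frame(t = t, truth_label = truth),
                 artifact_seconds = artifact, events = events,
                 profile = profile, seed = as.integer(seed)),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record> %s, seed %d, %d events\n", x$profile$stratum,
              x$seed, length(x$events)))
  print(x$record)
  invisible(x)
}

#' Draw stable stratum parameter vectors for model training
#'
#' Independent multivariate-normal draws of complete 5-parameter vectors
#' (canonical order, RR already on the trend scale) from a stratum profile,
#' clipped to the profile's physiological ranges. The marginal covariance
#' combines the slow-wander correlation structure with the per-second
#' measurement jitter as it survives preprocessing (full jitter on HR, SpO2
#' and IBP; halved variance on the two-probe rSO2 fusion; none on the
#' 300-second RR trend). Used to fit stratum statistics and the
#' population-level SVM without a patient cohort.
#'
#' @param n number of vectors.
#' @param profile a [stratum_profile()].
#' @param seed integer seed.
#' @return numeric n x 5 matrix.
#' @export
simulate_stable_vectors <- function(n, profile = stratum_profile("LOW_SAT"),
                                    seed = 1L) {
  local_seed(seed, {
    S <- diag(profile$sd) %*% profile$correlation %*% diag(profile$sd)
    jit <- profile$jitter
    S <- S + diag(c(jit[["hr"]]^2, 0, jit[["spo2"]]^2, jit[["rso2"]]^2 / 2,
                    jit[["ibp"]]^2))
    x <- matrix(rnorm(n * 5L), n, 5L) %*% chol(S)
    x <- sweep(x, 2L, profile$centre, "+")
    for (j in 1:5) x[, j] <- pmin(pmax(x[, j], profile$clip_low[[j]]),
                                  profile$clip_high[[j]])
    colnames(x) <- PARAMS
    x
  })
}

#' Simulate a training cohort and pool its parameter vectors
#'
#' Emulates the data a stratum model is fitted on in practice: perioperative
#' admissions that contain deterioration episodes and ventilation periods,
#' not curated stable time. Each simulated record carries a ventilation
#' block and two multi-parameter deterioration episodes (cycling through
#' tachycardic-hypotensive-desaturating phenotypes), so roughly 17% of the
#' pooled time is genuinely unstable — the contaminated upper tail that the
#' Mahalanobis percentile prefilter is designed to discard before SVM
#' training. The default cohort size matches the scale of a realistic
#' stratum cohort (a few dozen admissions), which matters: each patient
#' contributes one baseline-offset "blob" to the pooled cloud, and the SVM
#' needs enough patients to cover the between-patient space.
#'
#' @param n_records number of simulated admissions (default 48, the scale
#'   of the larger published stratum cohort).
#' @param stratum `"LOW_SAT"` or `"HIGH_SAT"` (ignored when `profile`
#'   given).
#' @param duration seconds per record (default 10800).
#' @param seed integer master seed; record i uses `seed * 100 + i`.
#' @param profile a [stratum_profile()].
#' @return numeric matrix of pooled complete parameter vectors (rows).
#' @export
simulate_training_cohort <- function(n_records = 48L, stratum = "LOW_SAT",
                                     duration = 10800L, seed = 1L,
                                     profile = NULL) {
  if (is.null(profile)) profile <- stratum_profile(stratum)
  phenotypes <- list(c(hr = 4, ibp = -4, rso2 = -4),
                     c(hr = -3.5, spo2 = -4, rso2 = -3),
                     c(hr = 5, ibp = 5, rr = 3))
  pooled <- lapply(seq_len(n_records), function(i) {
    ev <- list(
      ventilation_event(900L, 4500L),
      deterioration_event(3600L, 4500L,
                          magnitude = phenotypes[[(i - 1L) %% 3L + 1L]]),
      deterioration_event(7200L, 8100L,
                          magnitude = phenotypes[[i %% 3L + 1L]]))
    ev <- Filter(function(e) e$end < duration, ev)
    sim <- simulate_record(duration = duration, seed = seed * 100L + i,
                           events = ev, profile = profile,
                           patient_id = sprintf("train%02d", i))
    pm <- parameter_matrix(sim$record)
    pm[stats::complete.cases(pm), , drop = FALSE]
  })
  do.call(rbind, pooled)
}

#' Write simulator outputs to CSV
#'
#' Writes the stream CSV, metadata CSV, truth timeline and artifact mask of
#' a simulated record.
#'
#' @param sim a `sim_record`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_record <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vital_record(sim$record, file.path(dir, "stream.csv"))
  write.csv(data.frame(patient_id = sim$record$patient_id,
                       birth_weight_g = sim$record$birth_weight_g,
                       age_days = sim$record$age_days),
            file.path(dir, "metadata.csv"), row.names = FALSE, quote = FALSE)
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(t = sim$truth$t, artifact = sim$artifact_seconds),
            file.path(dir, "artifact_mask.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
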