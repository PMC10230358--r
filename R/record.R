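#' Patient vital-sign records
#'
#' A `vital_record` holds a 1 Hz-aligned series of per-second vital-sign
#' observations together with patient metadata. The canonical grid is integer
#' seconds since admission start; readers align rows to the grid, resolve
#' duplicate timestamps last-wins, and fill gaps with all-missing seconds.
#'
#' @param data data.frame with columns `t, hr, rr, spo2, rso2_left,
#'   rso2_right, ibp_mean, etco2`; `t` integer seconds, other columns numeric
#'   with `NA` for missing.
#' @param patient_id opaque identifier.
#' @param birth_weight_g birth weight in grams (may be `NA`).
#' @param age_days age at admission in days (may be `NA`).
#' @return An object of class `vital_record`.
#' @export
vital_record <- function(data, patient_id = "anon", birth_weight_g = NA_real_,
                         age_days = NA_real_) {
  cols <- c("t", "hr", "rr", "spo2", "rso2_left", "rso2_right", "ibp_mean", "etco2")
  if (!is.data.frame(data) || !all(cols %in% names(data)))
    stop("record data must contain columns: ", paste(cols, collapse = ","))
  data <- data[cols]
  if (nrow(data) == 0L) stop("record must contain at least one second")
  t <- as.integer(data$t)
  if (anyNA(t)) stop("timestamps must be integer seconds")
  if (any(t < 0L)) stop("timestamps must be >= 0")
  if (any(diff(t) < 0L)) stop("timestamps must be non-decreasing")
  # duplicate t: last row wins
  keep <- !duplicated(t, fromLast = TRUE)
  data <- data[keep, , drop = FALSE]
  t <- t[keep]
  # align to contiguous 1 Hz grid from the first timestamp; gaps all-missing
  grid <- seq(t[1L], t[length(t)])
  full <- data.frame(t = grid)
  idx <- match(grid, t)
  for (col in cols[-1L]) {
    v <- as.numeric(data[[col]])
    if (any(!is.finite(v) & !is.na(v))) stop("non-finite value in column ", col)
    full[[col]] <- v[idx]
  }
  for (col in c("spo2", "rso2_left", "rso2_right")) {
    bad <- !is.na(full[[col]]) & (full[[col]] < 0 | full[[col]] > 100)
    if (any(bad)) stop(col, " must lie in [0, 100]")
  }
  structure(
    list(patient_id = as.character(patient_id),
         birth_weight_g = as.numeric(birth_weight_g),
         age_days = as.numeric(age_days),
         data = full),
    class = "vital_record")
}

#' @export
print.vital_record <- function(x, ...) {
  d <- x$data
  cat(sprintf("<vital_record> patient %s: %d s (%.1f h), t = %d..%d\n",
              x$patient_id, nrow(d), nrow(d) / 3600, d$t[1L], d$t[nrow(d)]))
  compl <- complete_seconds(x)
  cat(sprintf("  complete parameter vectors: %d s (%.1f h)\n",
              sum(compl), sum(compl) / 3600))
  invisible(x)
}

#' @export
length.vital_record <- function(x) nrow(x$data)

#' Read a per-second vital-sign stream from CSV
#'
#' Expects header `t,hr,rr,spo2,rso2_left,rso2_right,ibp_mean,etco2`; empty
#' cells are missing values. Rows are aligned to a 1 Hz grid starting at the
#' first timestamp, duplicates resolved last-wins, gaps filled with
#' all-missing seconds.
#'
#' @param path CSV file path.
#' @inheritParams vital_record
#' @return A [vital_record].
#' @export
read_vital_record <- function(path, patient_id = "anon",
                              birth_weight_g = NA_real_, age_days = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, header = TRUE, colClasses = "numeric",
                 na.strings = c("", "NA"))
  cols <- c("t", "hr", "rr", "spo2", "rso2_left", "rso2_right", "ibp_mean", "etco2")
  if (!identical(names(df), cols))
    stop("malformed header: expected ", paste(cols, collapse = ","))
  vital_record(df, patient_id = patient_id, birth_weight_g = birth_weight_g,
               age_days = age_days)
}

#' Write a vital-sign stream to CSV
#'
#' Inverse of [read_vital_record()]: round-trips a record including
#' missingness (missing values written as empty cells).
#'
#' @param record a [vital_record].
#' @param path output CSV path.
#' @export
write_vital_record <- function(record, path) {
  stopifnot(inherits(record, "vital_record"))
  write.csv(record$data, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# logical vector: seconds whose 5-parameter vector is complete
complete_seconds <- function(record, control = detect_control()) {
  stats::complete.cases(parameter_matrix(record, control))
}

#' Per-second 5-parameter matrix
#'
#' Builds the model's parameter vectors for every second of a record:
#' heart rate, smoothed respiratory-rate trend (see [rr_trend()]), SpO2,
#' fused cerebral rSO2 (see [fuse_rso2()]), and invasive mean blood pressure.
#'
#' @param record a [vital_record].
#' @param control a [detect_control()] list (window parameters).
#' @return numeric matrix, one row per second, columns
#'   `hr, rr_trend, spo2, rso2, ibp_mean`; `NA` where a parameter is missing.
#' @export
parameter_matrix <- function(record, control = detect_control()) {
  d <- record$data
  m <- cbind(hr = d$hr,
             rr_trend = rr_trend(record, window = control$rr_window,
                                 min_obs = control$rr_min_obs),
             spo2 = d$spo2,
             rso2 = fuse_rso2(d$rso2_left, d$rso2_right),
             ibp_mean = d$ibp_mean)
  m
}

#' Cohort inclusion filter
#'
#' A record is included when it provides at least `min_hours` of complete
#' 5-parameter data, the birth weight is at least `min_weight` grams, and the
#' patient is younger than `max_age` days at admission.
#'
#' @param record a [vital_record].
#' @param min_hours minimum hours of complete data (default 12).
#' @param min_weight minimum birth weight in grams (default 2000).
#' @param max_age maximum age at admission in days, exclusive (default 365).
#' @param control a [detect_control()] list.
#' @return `TRUE` if the record passes all inclusion criteria.
#' @export
cohort_inclusion_filter <- function(record, min_hours = 12, min_weight = 2000,
                                    max_age = 365, control = detect_control()) {
  stopifnot(inherits(record, "vital_record"))
  complete_h <- sum(complete_seconds(record, control)) / 3600
  isTRUE(complete_h >= min_hours) &&
    isTRUE(record$birth_weight_g >= min_weight) &&
    isTRUE(record$age_days < max_age)
}

#' Respiratory-rate trend
#'
#' Neonatal respiratory rate fluctuates considerably within minutes, so the
#' model examines a trend rather than the raw rate: the mean of the
#' non-missing raw RR values over the `window` seconds preceding each time
#' point. The trend is missing when fewer than `min_obs` raw values fall in
#' the window.
#'
#' @param record a [vital_record].
#' @param window trailing window length in seconds (default 300).
#' @param min_obs minimum non-missing values required (default 150).
#' @return numeric vector, one value per second of the record.
#' @export
rr_trend <- function(record, window = 300L, min_obs = 150L) {
  rr <- record$data$rr
  n <- length(rr)
  ok <- !is.na(rr)
  cs0 <- c(0, cumsum(ifelse(ok, rr, 0)))
  cn0 <- c(0L, cumsum(ok))
  # trailing window [i-window, i-1] in 1-based indices
  i <- seq_len(n)
  lo <- pmax(i - window, 1L)
  wsum <- cs0[i] - cs0[lo]
  wn <- cn0[i] - cn0[lo]
  ifelse(wn >= min_obs, wsum / wn, NA_real_)
}

#' Fuse the two cerebral rSO2 probes
#'
#' Bilateral near-infrared spectroscopy probes are fused to a single cerebral
#' saturation: the mean when both probes record a value, the available value
#' when only one does, missing when neither does.
#'
#' @param left,right numeric vectors of per-second probe readings (%).
#' @return numeric vector of fused rSO2 values.
#' @export
fuse_rso2 <- function(left, right) {
  stopifnot(length(left) == length(right))
  out <- rowMeans(cbind(left, right), na.rm = TRUE)
  out[is.na(left) & is.na(right)] <- NA_real_
  out
}

#' Mechanical-ventilation status from EtCO2
#'
#' End-tidal CO2 is monitored in all mechanically ventilated patients, so a
#' positive EtCO2 reading at time t is taken as "currently ventilated".
#' Missing EtCO2 is treated as not ventilated (conservative: the ventilation
#' adjustment only inflates distances).
#'
#' @param etco2 numeric vector of EtCO2 readings (any nonnegative unit).
#' @return logical vector.
#' @export
ventilation_status <- function(etco2) {
  !is.na(etco2) & etco2 > 0
}

#' Stratify a record by admission-mean SpO2
#'
#' Patients are split into two physiological strata by mean oxygen saturation
#' over the admission: `LOW_SAT` (< 90%, cyanotic physiology) versus
#' `HIGH_SAT` (>= 90%, acyanotic). The mean uses all non-missing SpO2
#' seconds; exactly 90% falls in `HIGH_SAT`.
#'
#' @param record a [vital_record].
#' @return `"LOW_SAT"` or `"HIGH_SAT"`.
#' @export
stratify <- function(record) {
  s <- record$data$spo2
  if (all(is.na(s))) stop("cannot stratify: all SpO2 values missing")
  if (mean(s, na.rm = TRUE) < 90) "LOW_SAT" else "HIGH_SAT"
}
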