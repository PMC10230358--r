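# Fixture builders shared across test files. Everything is generated in
# code; heavyweight fitted objects are cached per test run.

# data.frame with the canonical stream columns; unspecified columns NA
stream_df <- function(t, hr = NA, rr = NA, spo2 = NA, rso2_left = NA,
                      rso2_right = NA, ibp_mean = NA, etco2 = NA) {
  data.frame(t = t, hr = hr, rr = rr, spo2 = spo2, rso2_left = rso2_left,
             rso2_right = rso2_right, ibp_mean = ibp_mean, etco2 = etco2)
}

# a fully-observed, benign record: constant-ish vitals, no artifacts
flat_record <- function(n = 1200L, hr = 150, rr = 34, spo2 = 77, rso2 = 55,
                        ibp = 51, etco2 = 0, birth_weight_g = 3400,
                        age_days = 7) {
  vital_record(stream_df(t = seq_len(n) - 1L, hr = hr, rr = rr, spo2 = spo2,
                         rso2_left = rso2, rso2_right = rso2, ibp_mean = ibp,
                         etco2 = etco2),
               patient_id = "flat", birth_weight_g = birth_weight_g,
               age_days = age_days)
}

# cache of expensive fitted objects, built once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# canonical fitted LOW_SAT model: 48-admission contaminated cohort, seed 1
low_sat_model <- function() {
  fixture("low_sat_model", function() {
    x <- simulate_training_cohort(stratum = "LOW_SAT", seed = 1L)
    fit_stratum_model(x, stratum = "LOW_SAT")
  })
}

# small iid-vector model for cheap SVM-level tests
small_model <- function() {
  fixture("small_model", function() {
    x <- simulate_stable_vectors(5000, stratum_profile("LOW_SAT"), seed = 42L)
    fit_stratum_model(x, stratum = "LOW_SAT")
  })
}

# batch (sort-based) medians used as oracles for the streaming versions
batch_roll_median <- function(x, window, min_obs) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - window):max(1L, i - 1L)]
    if (i == 1L) return(NA_real_)
    w <- w[!is.na(w)]
    if (length(w) < min_obs) NA_real_ else median(w)
  }, numeric(1))
}

batch_expanding_median <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    if (i == 1L) return(NA_real_)
    w <- x[seq_len(i - 1L)]
    w <- w[!is.na(w)]
    if (length(w) == 0L) NA_real_ else median(w)
  }, numeric(1))
}
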