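test_that("CSV reading aligns to a 1 Hz grid with gap-fill and last-wins duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,hr,rr,spo2,rso2_left,rso2_right,ibp_mean,etco2",
               "0,150,34,77,55,56,51,0",
               "1,151,35,78,54,55,52,0",
               "2,152,36,79,53,54,53,0"), path)
  rec <- read_vital_record(path)
  expect_s3_class(rec, "vital_record")
  expect_equal(length(rec), 3L)
  expect_equal(rec$data$hr, c(150, 151, 152))

  # gap at t=1 becomes an all-missing second
  writeLines(c("t,hr,rr,spo2,rso2_left,rso2_right,ibp_mean,etco2",
               "0,150,34,77,55,56,51,0",
               "2,152,36,79,53,54,53,0"), path)
  rec <- read_vital_record(path)
  expect_equal(length(rec), 3L)
  expect_true(all(is.na(rec$data[2, -1])))

  # duplicate timestamp: the later row wins
  writeLines(c("t,hr,rr,spo2,rso2_left,rso2_right,ibp_mean,etco2",
               "4,150,34,77,55,56,51,0",
               "5,151,34,77,55,56,51,0",
               "5,160,34,77,55,56,51,0",
               "6,152,34,77,55,56,51,0"), path)
  rec <- read_vital_record(path)
  expect_equal(length(rec), 3L)
  expect_equal(rec$data$hr[rec$data$t == 5], 160)

  # malformed header and non-monotone timestamps are rejected
  writeLines(c("time,hr,rr,spo2,rso2_left,rso2_right,ibp_mean,etco2",
               "0,150,34,77,55,56,51,0"), path)
  expect_error(read_vital_record(path), "malformed header")
  writeLines(c("t,hr,rr,spo2,rso2_left,rso2_right,ibp_mean,etco2",
               "5,150,34,77,55,56,51,0",
               "3,150,34,77,55,56,51,0"), path)
  expect_error(read_vital_record(path), "non-decreasing")
})

test_that("write then read round-trips a record including missingness", {
  df <- stream_df(t = 0:9, hr = c(150, NA, 152, 150, NA, 150, 151, 149, 150, 150),
                  rr = 34, spo2 = c(NA, NA, 77, 78, 77, 76, 77, 77, 78, 77),
                  rso2_left = 55, rso2_right = NA, ibp_mean = 51,
                  etco2 = c(0, 0, 0, 4.8, 4.8, 4.8, 0, 0, 0, 0))
  rec <- vital_record(df, patient_id = "rt", birth_weight_g = 3000, age_days = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vital_record(rec, path)
  rec2 <- read_vital_record(path, patient_id = "rt", birth_weight_g = 3000,
                            age_days = 3)
  expect_identical(rec2$data, rec$data)
})

test_that("cohort inclusion enforces complete-data hours, birth weight and age", {
  # 1200 s of complete data at min_hours scaled to the fixture size
  rec <- flat_record(n = 4000L, birth_weight_g = 3400, age_days = 7)
  hrs <- sum(complete.cases(parameter_matrix(rec))) / 3600
  expect_true(cohort_inclusion_filter(rec, min_hours = hrs))
  expect_false(cohort_inclusion_filter(rec, min_hours = hrs + 0.01))
  # low birth weight excluded at the 2000 g floor
  rec_lw <- flat_record(n = 4000L, birth_weight_g = 1900)
  expect_false(cohort_inclusion_filter(rec_lw, min_hours = 0.5))
  rec_ok <- flat_record(n = 4000L, birth_weight_g = 2000)
  expect_true(cohort_inclusion_filter(rec_ok, min_hours = 0.5))
  # age at admission must be under the cap
  rec_old <- flat_record(n = 4000L, age_days = 365)
  expect_false(cohort_inclusion_filter(rec_old, min_hours = 0.5))
})

test_that("rr_trend is the causal moving mean with a minimum-observation rule", {
  # constant rate passes through
  rec <- flat_record(n = 900L, rr = 34)
  rt <- rr_trend(rec)
  expect_equal(rt[400], 34)
  # linear ramp: compare against direct summation
  rr <- rep(NA_real_, 900)
  rr[1:900] <- 20 + (0:899) %% 40
  rec <- vital_record(stream_df(t = 0:899, rr = rr))
  rt <- rr_trend(rec)
  i <- 700L
  expect_equal(rt[i], mean(rr[(i - 300):(i - 1)]))
  # fewer than min_obs values in the window yields missing
  rr2 <- rep(NA_real_, 900)
  rr2[sample(301:400, 100)] <- 30  # only 100 observations ever
  rec2 <- vital_record(stream_df(t = 0:899, rr = rr2))
  expect_true(is.na(rr_trend(rec2)[500]))
  # shift-equivariance: shifting the record start leaves the trend sequence unchanged
  rec3 <- vital_record(stream_df(t = 1000:1899, rr = rr))
  expect_equal(rr_trend(rec3), rt)
})

test_that("rSO2 fusion averages both probes, falls back to one, is symmetric", {
  expect_equal(fuse_rso2(50, 60), 55)
  expect_equal(fuse_rso2(50, NA), 50)
  expect_equal(fuse_rso2(NA, 60), 60)
  expect_true(is.na(fuse_rso2(NA_real_, NA_real_)))
  l <- c(50, NA, 70, NA); r <- c(60, 65, NA, NA)
  expect_equal(fuse_rso2(l, r), fuse_rso2(r, l))
})

test_that("ventilation status is EtCO2 strictly positive, missing = not ventilated", {
  expect_identical(ventilation_status(c(5.2, 0, NA, 0.01, -1)),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("stratification splits at mean SpO2 of 90% with 90 itself high", {
  rec_low <- flat_record(spo2 = 77)
  expect_equal(stratify(rec_low), "LOW_SAT")
  rec_high <- flat_record(spo2 = 97)
  expect_equal(stratify(rec_high), "HIGH_SAT")
  rec_edge <- flat_record(spo2 = 90)
  expect_equal(stratify(rec_edge), "HIGH_SAT")
  # order-invariance: stratification depends only on the multiset of values
  set.seed(7)
  v <- runif(600, 80, 100)
  r1 <- vital_record(stream_df(t = 0:599, spo2 = v))
  r2 <- vital_record(stream_df(t = 0:599, spo2 = sample(v)))
  expect_equal(stratify(r1), stratify(r2))
  # all-missing SpO2 cannot be stratified
  expect_error(stratify(vital_record(stream_df(t = 0:9))), "missing")
})
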