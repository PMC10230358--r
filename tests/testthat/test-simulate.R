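test_that("identical seeds and configurations reproduce records byte-identically", {
  s1 <- simulate_record("LOW_SAT", duration = 7200L, seed = 5L)
  s2 <- simulate_record("LOW_SAT", duration = 7200L, seed = 5L)
  expect_identical(s1$record$data, s2$record$data)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_record(s1, d1); write_sim_record(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  s3 <- simulate_record("LOW_SAT", duration = 7200L, seed = 6L)
  expect_false(identical(s1$record$data, s3$record$data))
})

test_that("a zero-dispersion profile yields constant series at the centres", {
  p <- stratum_profile("LOW_SAT")
  p$sd[] <- 0
  p$jitter[] <- 0
  p$probe_sd <- 0
  s <- simulate_record(duration = 7200L, seed = 1L, profile = p)
  expect_true(all(s$record$data$hr == p$centre[["hr"]]))
  expect_true(all(s$record$data$spo2 == p$centre[["spo2"]]))
  expect_true(all(s$record$data$ibp_mean == p$centre[["ibp"]]))
})

test_that("generated records match the stratum medians and dispersions", {
  # pool several records so the patient-offset mixture averages out
  pooled <- do.call(rbind, lapply(1:6, function(s)
    simulate_record("LOW_SAT", duration = 7200L, seed = 100L + s)$record$data))
  p <- stratum_profile("LOW_SAT")
  expect_lt(abs(median(pooled$hr) - 159), p$sd[["hr"]])
  expect_lt(abs(median(pooled$spo2) - 77), p$sd[["spo2"]])
  expect_lt(abs(median(pooled$ibp_mean) - 51), p$sd[["ibp"]])
  expect_lt(abs(median(fuse_rso2(pooled$rso2_left, pooled$rso2_right)) - 55),
            p$sd[["rso2"]])
  ph <- stratum_profile("HIGH_SAT")
  pooled_h <- do.call(rbind, lapply(1:6, function(s)
    simulate_record("HIGH_SAT", duration = 7200L, seed = 200L + s)$record$data))
  expect_lt(abs(median(pooled_h$spo2) - 97), ph$sd[["spo2"]])
  expect_lt(abs(median(pooled_h$hr) - 146), ph$sd[["hr"]])
})

test_that("clean records never trip an artifact rule and EtCO2 tracks ventilation events", {
  s <- simulate_record("LOW_SAT", duration = 14400L, seed = 3L,
                       events = list(ventilation_event(2000L, 6000L)))
  m <- dysfunction_mask(s$record)
  expect_equal(sum(m$mask), 0L)
  vent <- ventilation_status(s$record$data$etco2)
  expect_true(all(vent[2001:6001]))
  expect_false(any(vent[-(2001:6001)]))
})

test_that("a zero-magnitude deterioration leaves the record unchanged", {
  ev <- deterioration_event(8000L, 10000L, magnitude = c(hr = 0, ibp = 0))
  s0 <- simulate_record(duration = 12000L, seed = 9L)
  s1 <- simulate_record(duration = 12000L, seed = 9L, events = list(ev))
  expect_identical(s0$record$data, s1$record$data)
  expect_true(all(s1$truth$truth_label[s1$truth$t >= 3600] == "STABLE"))
})

test_that("deterioration magnitudes must move at least two parameters and not overlap", {
  expect_error(deterioration_event(0, 100, magnitude = c(hr = 5)),
               "at least 2")
  expect_error(simulate_record(duration = 9000L, seed = 1L, events = list(
    deterioration_event(1000L, 4000L), deterioration_event(3000L, 6000L))),
    "overlapping")
})

test_that("injected artifacts are flagged by the dysfunction rules at the prescribed windows", {
  # a single jump artifact flags exactly the minute either side of onset
  s <- simulate_record(duration = 9000L, seed = 15L,
                       events = list(artifact_event("ARTIFACT_JUMP", 5000L)))
  m <- dysfunction_mask(s$record)
  expect_equal(which(m$mask) - 1L, 4940:5060)
  # a 120 s RR loss is covered within +/- 60 s
  s2 <- simulate_record(duration = 9000L, seed = 16L,
                        events = list(artifact_event("ARTIFACT_RR_LOSS", 5000L, 5119L)))
  m2 <- dysfunction_mask(s2$record)
  expect_equal(which(m2$mask) - 1L, 4940:5179)
  # railed probes flag the rSO2 rule
  s3 <- simulate_record(duration = 9000L, seed = 17L,
                        events = list(artifact_event("ARTIFACT_RSO2_RAIL", 4000L, 4050L,
                                                     side = "low")))
  m3 <- dysfunction_mask(s3$record)
  expect_true(all(m3$mask[(3940:4110) + 1L]))
  expect_true(all(s3$artifact_seconds[4001:4051]))
  # every injected artifact second lies inside the detected mask
  expect_true(all(m3$mask[s3$artifact_seconds]))
  # no events: empty artifact truth
  expect_equal(sum(simulate_record(duration = 7200L, seed = 18L)$artifact_seconds), 0L)
})

test_that("dropout events produce missing data and unknown classifications downstream", {
  s <- simulate_record(duration = 9000L, seed = 19L,
                       events = list(artifact_event("DROPOUT", 5000L, 5300L,
                                                    parameter = c("hr", "spo2"))))
  d <- s$record$data
  expect_true(all(is.na(d$hr[5001:5301])))
  expect_true(all(is.na(d$spo2[5001:5301])))
  expect_false(anyNA(d$ibp_mean))
})
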