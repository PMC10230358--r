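test_that("time scoring counts matching truth seconds and excludes warm-up and unknown", {
  truth <- c(rep("WARMUP", 100), rep("STABLE", 500), rep("UNSTABLE", 200),
             rep("SENSOR_DYSFUNCTION", 100))
  # identical streams: 100% for every occurring class
  ts <- time_score(truth, truth)
  expect_equal(ts$correct_pct, c(100, 100, 100))
  expect_equal(ts$occurrence_s, c(500, 200, 100))
  # all-stable prediction against 1 h unstable in 10 h
  truth2 <- c(rep("STABLE", 9 * 3600), rep("UNSTABLE", 3600))
  pred2 <- rep("STABLE", 10 * 3600)
  ts2 <- time_score(pred2, truth2)
  expect_equal(ts2$correct_pct[ts2$class == "STABLE"], 100)
  expect_equal(ts2$correct_pct[ts2$class == "UNSTABLE"], 0)
  expect_equal(ts2$occurrence_h[ts2$class == "UNSTABLE"], 1)
  # warm-up and unknown seconds appear in no denominator
  pred3 <- truth
  pred3[101:200] <- "UNKNOWN"
  ts3 <- time_score(pred3, truth)
  expect_equal(ts3$occurrence_s[ts3$class == "STABLE"], 400)
  # symmetry in time: reversing both streams changes nothing
  ts4 <- time_score(rev(pred3), rev(truth))
  expect_equal(ts4, ts3)
})

test_that("episodic scoring matches overlap, flags partial coverage, splits at the cap", {
  truth <- c(rep("STABLE", 3600), rep("UNSTABLE", 3600), rep("STABLE", 3600))
  t <- seq_along(truth) - 1L
  # prediction equal to truth: all episodes correct, none partial
  pred_ep <- segment_episodes(truth, t)
  es <- episodic_score(pred_ep, truth, t)
  expect_equal(es$correct, es$occurrence)
  expect_equal(sum(es$partial), 0L)
  expect_equal(es$correct_pct[es$class == "UNSTABLE"], 100)
  # 20 minutes detected of a 60-minute unstable episode: correct but partial
  pred <- rep("STABLE", length(truth))
  pred[3601 + 0:1199] <- "UNSTABLE"
  es2 <- episodic_score(segment_episodes(pred, t), truth, t)
  expect_equal(es2$correct[es2$class == "UNSTABLE"], 1L)
  expect_equal(es2$partial[es2$class == "UNSTABLE"], 1L)
  # no predicted unstable episodes: 0 of 3 detected
  truth3 <- rep("STABLE", 20000)
  truth3[c(3000:3600, 8000:8600, 15000:15600)] <- "UNSTABLE"
  es3 <- episodic_score(segment_episodes(rep("STABLE", 20000), 0:19999),
                        truth3, 0:19999)
  expect_equal(es3$occurrence[es3$class == "UNSTABLE"], 3L)
  expect_equal(es3$correct[es3$class == "UNSTABLE"], 0L)
  # truth episodes longer than 2 h are pre-split by the cap
  truth4 <- rep("UNSTABLE", 5 * 3600)
  es4 <- episodic_score(segment_episodes(truth4, seq_along(truth4) - 1L),
                        truth4, seq_along(truth4) - 1L)
  expect_equal(es4$occurrence[es4$class == "UNSTABLE"], 3L)
})

test_that("the performance report aggregates strata and mirrors the total column", {
  mk_score <- function(stratum, occ, corr, occ_s, corr_s) {
    cls <- c("STABLE", "UNSTABLE", "SENSOR_DYSFUNCTION")
    list(stratum = stratum,
         time = data.frame(class = cls, occurrence_s = occ_s, correct_s = corr_s,
                           occurrence_h = occ_s / 3600,
                           correct_pct = 100 * corr_s / pmax(occ_s, 1)),
         episodic = data.frame(class = cls, occurrence = occ, correct = corr,
                               partial = c(0L, 1L, 0L),
                               correct_pct = 100 * corr / pmax(occ, 1)))
  }
  rep1 <- mk_score("LOW_SAT", c(77L, 21L, 57L), c(66L, 17L, 56L),
                   c(324000, 28800, 7200), c(298080, 14400, 7000))
  rep2 <- mk_score("HIGH_SAT", c(76L, 36L, 81L), c(68L, 29L, 74L),
                   c(324000, 72000, 10800), c(302400, 61200, 9800))
  pr <- performance_report(list(rep1, rep2))
  tot <- pr[pr$stratum == "Total", ]
  low <- pr[pr$stratum == "LOW_SAT", ]
  high <- pr[pr$stratum == "HIGH_SAT", ]
  expect_equal(tot$episodic_occurrence, low$episodic_occurrence + high$episodic_occurrence)
  expect_equal(tot$episodic_correct, low$episodic_correct + high$episodic_correct)
  expect_equal(tot$time_occurrence_h, low$time_occurrence_h + high$time_occurrence_h)
  expect_equal(tot$episodic_occurrence[tot$class == "STABLE"], 153L)
  expect_true(all(pr$episodic_correct <= pr$episodic_occurrence))
  expect_true(all(pr$episodic_correct_pct >= 0 & pr$episodic_correct_pct <= 100,
                  na.rm = TRUE))
})
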