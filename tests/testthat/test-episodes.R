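test_that("per-second fusion follows the precedence truth table", {
  t <- 4000L  # past warm-up
  expect_equal(fuse_seconds(TRUE, "UNSTABLE", "STABLE", t), "SENSOR_DYSFUNCTION")
  expect_equal(fuse_seconds(FALSE, "STABLE", "UNSTABLE", t), "UNSTABLE")
  expect_equal(fuse_seconds(FALSE, "UNSTABLE", "STABLE", t), "UNSTABLE")
  expect_equal(fuse_seconds(FALSE, "STABLE", "IMPROVEMENT", t), "STABLE")
  expect_equal(fuse_seconds(FALSE, "STABLE", "STABLE", t), "STABLE")
  expect_equal(fuse_seconds(FALSE, NA, NA, t), "UNKNOWN")
  expect_equal(fuse_seconds(FALSE, NA, "UNSTABLE", t), "UNSTABLE")
  expect_equal(fuse_seconds(FALSE, "UNSTABLE", "UNSTABLE", 100L), "WARMUP")
})

test_that("the 5-minute window rule needs at least 4 nonconsecutive unstable minutes", {
  base <- rep("STABLE", 4000L)
  mk <- function(n_unstable) {
    l <- base
    # scatter the unstable seconds over the trailing window of second 3999
    l[seq(3700, by = 1, length.out = n_unstable)] <- "UNSTABLE"
    smooth_labels(l)[3999]
  }
  expect_equal(mk(240), "UNSTABLE")
  expect_equal(mk(239), "STABLE")
  expect_equal(mk(300), "UNSTABLE")
  # nonconsecutive blocks count toward the 4 minutes
  l <- base
  for (s in c(3700, 3770, 3840, 3910)) l[s:(s + 59)] <- "UNSTABLE"
  expect_equal(smooth_labels(l)[3999], "UNSTABLE")
})

test_that("window smoothing equals a brute-force trailing count on random label streams", {
  set.seed(17)
  labs <- c("STABLE", "UNSTABLE", "UNKNOWN", "SENSOR_DYSFUNCTION", "WARMUP")
  for (rep in 1:5) {
    l <- sample(labs, 3000, replace = TRUE, prob = c(.5, .3, .1, .05, .05))
    sm <- smooth_labels(l, window = 300L, min_unstable = 240L)
    oracle <- vapply(seq_along(l), function(i) {
      if (!l[i] %in% c("STABLE", "UNSTABLE")) return(l[i])
      w <- l[max(1L, i - 299L):i]
      if (sum(w == "UNSTABLE") >= 240L) "UNSTABLE" else "STABLE"
    }, character(1))
    expect_identical(sm, oracle)
  }
})

test_that("episode segmentation caps runs at two hours, left to right", {
  l <- rep("UNSTABLE", 5 * 3600L)
  ep <- segment_episodes(l)
  expect_equal(ep$duration_s, c(7200L, 7200L, 3600L))
  expect_equal(ep$label, rep("UNSTABLE", 3))
  expect_equal(ep$start, c(0L, 7200L, 14400L))
  expect_equal(ep$end, c(7199L, 14399L, 17999L))
  # a short stable run is one episode
  ep2 <- segment_episodes(rep("STABLE", 1800L))
  expect_equal(nrow(ep2), 1L)
  expect_equal(ep2$duration_s, 1800L)
  # alternating labels produce one episode per maximal run
  l3 <- rep(c("STABLE", "UNSTABLE"), 50)
  ep3 <- segment_episodes(l3, unknown_gap_max = 0L)
  expect_equal(nrow(ep3), 100L)
  expect_true(all(ep3$duration_s == 1L))
})

test_that("segmentation conserves time and respects the cap on random streams", {
  set.seed(23)
  for (rep in 1:5) {
    l <- sample(c("STABLE", "UNSTABLE", "SENSOR_DYSFUNCTION", "UNKNOWN", "WARMUP"),
                9000, replace = TRUE, prob = c(.6, .2, .1, .05, .05))
    l[1:300] <- "WARMUP"
    ep <- segment_episodes(l, cap = 1800L, unknown_gap_max = 0L)
    expect_true(all(ep$duration_s <= 1800L))
    expect_true(all(ep$duration_s == ep$end - ep$start + 1L))
    # episode seconds + warm-up + unknown = record duration
    expect_equal(sum(ep$duration_s) + sum(l == "WARMUP") + sum(l == "UNKNOWN"),
                 length(l))
    # episodes are non-overlapping and ordered
    expect_true(all(diff(ep$start) > 0))
    expect_true(all(ep$start[-1L] > ep$end[-nrow(ep)]))
  }
})

test_that("short unknown gaps are bridged inside an episode, long gaps break it", {
  l <- c(rep("STABLE", 500), rep("UNKNOWN", 30), rep("STABLE", 500))
  ep <- segment_episodes(l, unknown_gap_max = 60L)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_s, 1030L)
  l2 <- c(rep("STABLE", 500), rep("UNKNOWN", 120), rep("STABLE", 500))
  ep2 <- segment_episodes(l2, unknown_gap_max = 60L)
  expect_equal(nrow(ep2), 2L)
  # gaps between different labels are never bridged
  l3 <- c(rep("STABLE", 500), rep("UNKNOWN", 30), rep("UNSTABLE", 500))
  ep3 <- segment_episodes(l3, unknown_gap_max = 60L)
  expect_equal(nrow(ep3), 2L)
})
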