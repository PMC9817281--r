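tagging_tl <- function() tagging_protocol(electrode_grid())

norm_series <- function(values, times = seq(3, 329, by = 4)) {
  tibble::tibble(time_min = times, channel = 1L,
                 normalized = rep_len(values, length(times)))
}

test_that("classify_ltp separates non-LTP, E-LTP and L-LTP trajectories", {
  tl <- tagging_tl()
  flat <- norm_series(100)
  expect_equal(classify_ltp(flat, tl, event_time = 60), "non_LTP")

  sustained <- norm_series(100)
  sustained$normalized[sustained$time_min > 60] <- 150
  expect_equal(classify_ltp(sustained, tl, event_time = 60), "L_LTP")

  # 150% at 30-60 min decaying back to 100% by 2.5 h
  decay <- norm_series(100)
  post <- decay$time_min > 60
  u <- decay$time_min[post] - 60
  decay$normalized[post] <- 100 + 50 * exp(-pmax(0, u - 45) / 40)
  expect_equal(classify_ltp(decay, tl, event_time = 60), "E_LTP")
})

test_that("classify_ltp refuses recordings too short for the late phase", {
  tl <- experiment_timeline(
    baseline_end = 60,
    events = tibble::tibble(time_min = 60, kind = "strong_TBS", site = 26L),
    recording_end = 120)
  expect_error(
    classify_ltp(norm_series(100, seq(3, 119, 4)), tl, event_time = 60),
    class = "med64_classification_error", regexp = "180")
})

test_that("tagging-like flag requires S2 late LTP inside the capture window", {
  tl <- tagging_tl() # strong at 60, tagging at 90: interval 30
  expect_true(tag_tagging_like("L_LTP", tl))
  expect_false(tag_tagging_like("E_LTP", tl))
  long <- experiment_timeline(
    baseline_end = 60,
    events = tibble::tibble(time_min = c(60, 180),
                            kind = c("strong_TBS", "tagging_TBS"),
                            site = c(26L, 46L)),
    recording_end = 420)
  expect_false(tag_tagging_like("L_LTP", long)) # 120-min interval
  no_events <- experiment_timeline(baseline_end = 60,
                                   recording_end = 330)
  expect_error(tag_tagging_like("L_LTP", no_events),
               class = "med64_classification_error")
})

test_that("l_ltp_ratio reproduces worked ratios and guards empty input", {
  expect_equal(round(l_ltp_ratio(c(E_LTP = 21, L_LTP = 54,
                                   non_LTP = 24)), 2), 54.55)
  expect_equal(l_ltp_ratio(c(non_LTP = 10, E_LTP = 5)), 0)
  expect_equal(l_ltp_ratio(c(L_LTP = 12, non_LTP = 36)), 25.00)
  expect_error(l_ltp_ratio(c(L_LTP = 0, non_LTP = 0)),
               class = "med64_ratio_error")
  expect_error(l_ltp_ratio(c(bogus = 3)), class = "med64_input_error")
})

test_that("detect_activated applies the amplitude threshold and is monotone in it", {
  tl <- tagging_tl()
  times <- seq(2, 330, by = 2)
  sim <- simulate_slice(sim_preset("adult"), seed = 3L)
  b <- bin_slopes(sim$slopes)
  act0 <- detect_activated(b, tl, amp_threshold = 10)
  expect_false(any(act0$activated[act0$baseline_amp_uV == 0]))
  expect_true(any(act0$activated[act0$baseline_amp_uV >= 14]))
  counts <- vapply(seq(0, 50, by = 5), function(thr) {
    sum(detect_activated(b, tl, amp_threshold = thr)$activated)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("recruitment counts are cumulative and recruited channels were silent at baseline", {
  grid <- electrode_grid()
  tl <- tagging_tl()
  times <- seq(3, 329, by = 4)
  amp <- matrix(0, 64, length(times))
  act_ch <- c(25, 27, 45, 47)
  amp[act_ch, ] <- 20
  # channel 33 crosses threshold 90 min after the strong train (t = 150)
  amp[33, times > 150] <- 24
  tb <- slope_table_from_amp(amp, times)
  rt <- recruitment_timecourse(tb, tl, grid)
  s1 <- rt[rt$site == "S1", ]
  expect_equal(s1$recruited_count[s1$hour == 1], 0)
  expect_equal(s1$recruited_count[s1$hour %in% 2:5], rep(1, 4))
  # no crossings anywhere -> all zeros
  rt0 <- recruitment_timecourse(slope_table_from_amp(
    amp * (amp >= 20) * 0 + ifelse(row(amp) %in% act_ch, 20, 0), times),
    tl, grid)
  expect_true(all(rt0$recruited_count == 0))
  # simulated slice: counts non-decreasing within each site
  sim <- simulate_slice(sim_preset("adult"), seed = 7L)
  b <- slope_pipeline(sim$slopes, timeline = tl)
  rts <- recruitment_timecourse(b, tl, grid)
  for (s in unique(rts$site)) {
    expect_true(all(diff(rts$recruited_count[rts$site == s]) >= 0))
  }
  # recruited channels are disjoint from baseline-activated channels
  cls <- classify_channels(b, tl, grid)
  expect_length(
    intersect(cls$channel[cls$activated],
              cls$channel[!is.na(cls$recruited_time_min)]), 0)
})

test_that("last30_summary aggregates per-slice means with SEM", {
  tl <- tagging_tl()
  flat <- function(level) {
    tibble::tibble(time_min = rep(seq(3, 329, 4), 2),
                   channel = rep(1:2, each = 82),
                   normalized = level)
  }
  s <- last30_summary(list(flat(100), flat(100)), tl)
  expect_equal(s$mean_pct, 100)
  expect_equal(s$sem_pct, 0)
  s3 <- last30_summary(list(flat(140), flat(150), flat(160)), tl)
  expect_equal(s3$mean_pct, 150)
  expect_equal(s3$sem_pct, sd(c(140, 150, 160)) / sqrt(3))
  expect_equal(round(s3$sem_pct, 2), 5.77)
})

test_that("group_compare matches the pooled-variance formula and a permutation null", {
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # hand-computed pooled t for {1,2,3} vs {4,5,6}
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  got <- group_compare(a, b)
  expect_equal(got$statistic, t_hand)
  expect_equal(round(got$statistic, 3), -3.674)
  expect_equal(got$df, 4)
  # degenerate equal-constant groups
  deg <- group_compare(c(2, 2), c(2, 2))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  # t-distribution p within Monte-Carlo error of a permutation null
  withr::with_seed(9L, {
    x <- rnorm(8, 0.8); y <- rnorm(8)
    obs <- abs(group_compare(x, y)$statistic)
    pool <- c(x, y)
    perm <- replicate(1e4, {
      idx <- sample(16L, 8L)
      abs(group_compare(pool[idx], pool[-idx])$statistic)
    })
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(group_compare(x, y)$p_value - p_perm), 0.05)
})

test_that("activated channels partition into exactly one LTP class", {
  grid <- electrode_grid()
  tl <- tagging_tl()
  for (seed in c(2L, 9L)) {
    sim <- simulate_slice(sim_preset("middle_aged"), seed = seed)
    ns <- slope_pipeline(sim$slopes, timeline = tl)
    cls <- classify_channels(ns, tl, grid)
    act <- cls[cls$activated, ]
    expect_true(all(act$ltp_class %in% c("non_LTP", "E_LTP", "L_LTP")))
    expect_equal(sum(table(act$ltp_class)), nrow(act))
    expect_true(all(is.na(cls$ltp_class[!cls$activated])))
    # tagging-like implies late LTP at S2
    expect_true(all(act$ltp_class[act$tagging_like] == "L_LTP"))
    expect_true(all(act$site[act$tagging_like] == "S2"))
  }
})

test_that("tagging induction ratio counts activated S2 channels only", {
  cls <- tibble::tibble(
    channel = 1:6,
    site = c("S1", "S1", "S2", "S2", "S2", "S2"),
    activated = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    recruited_time_min = NA_real_,
    ltp_class = c("L_LTP", "L_LTP", "L_LTP", "E_LTP", "L_LTP", NA),
    tagging_like = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    last30_pct = 150)
  expect_equal(tagging_induction_ratio(cls), 100 * 2 / 3)
  # invariant to channel relabeling
  perm <- cls[sample(6), ]
  perm$channel <- sample(100:105)
  expect_equal(tagging_induction_ratio(perm), 100 * 2 / 3)
  expect_error(tagging_induction_ratio(cls[1:2, ]),
               class = "med64_ratio_error")
})

test_that("vectorised slice classification agrees with per-channel classify_ltp", {
  grid <- electrode_grid()
  tl <- tagging_tl()
  sim <- simulate_slice(sim_preset("adult"), seed = 21L)
  ns <- slope_pipeline(sim$slopes, timeline = tl)
  cls <- classify_channels(ns, tl, grid)
  events <- c(S1 = 60, S2 = 90)
  for (ch in cls$channel[cls$activated]) {
    ser <- ns[ns$channel == ch, ]
    expect_equal(
      cls$ltp_class[cls$channel == ch],
      classify_ltp(ser, tl, events[[cls$site[cls$channel == ch]]]))
  }
})
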