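test_that("fepsp_slope recovers the slope of a pure linear ramp", {
  ramp <- seq(0, -10, length.out = 21) # falls 10 uV over 2 ms at 10 kHz
  res <- fepsp_slope(ramp, sample_rate_khz = 10)
  expect_equal(res$slope_uV_per_ms, -5, tolerance = 1e-10)
  expect_false(res$no_response)
  expect_equal(res$amplitude_uV, 10)
})

test_that("a flat trace yields slope 0 with the no-response flag", {
  res <- fepsp_slope(rep(3.2, 50), sample_rate_khz = 10)
  expect_equal(res$slope_uV_per_ms, 0)
  expect_true(res$no_response)
})

test_that("sub-noise-floor deflections are flagged as no response", {
  # noisy pre-stimulus segment sets a high floor; the small post-stimulus
  # deflection stays well inside it
  withr::with_seed(4L, {
    trace <- c(rnorm(50, sd = 5), rnorm(50, sd = 0.5) - 1)
  })
  res <- fepsp_slope(trace, sample_rate_khz = 10, stim_onset_ms = 5,
                     artifact_ms = 0)
  expect_true(res$no_response)
  expect_equal(res$slope_uV_per_ms, 0)
})

test_that("double-exponential fEPSP slope matches a brute-force fit of the same segment", {
  trace <- fepsp_trace(peak_uv = 20)
  res <- fepsp_slope(trace, sample_rate_khz = 10, stim_onset_ms = 5,
                     artifact_ms = 2, smooth_ms = 0)
  # independent segment extraction: locate the peak, interpolate the
  # 20%/80% crossing times on the rise, least-squares over raw samples
  t_ms <- (seq_along(trace) - 1) / 10
  post <- which(t_ms >= 7)
  v <- trace[post] - mean(trace[t_ms < 5])
  tt <- t_ms[post]
  ipk <- which.min(v)
  f <- v[seq_len(ipk)] / v[ipk]
  crossing <- function(level) {
    idx <- max(which(f < level))
    tt[idx] + (level - f[idx]) / (f[idx + 1] - f[idx]) * (tt[idx + 1] - tt[idx])
  }
  sel <- which(tt >= crossing(0.2) & tt <= crossing(0.8) &
                 seq_along(tt) <= ipk)
  fit <- lm(v[sel] ~ tt[sel])
  expect_equal(res$slope_uV_per_ms, unname(coef(fit)[2]),
               tolerance = 1e-10)
  expect_true(res$slope_uV_per_ms < 0)
  expect_equal(res$amplitude_uV, 20, tolerance = 0.05)
})

test_that("fepsp_slope is DC-invariant and scales linearly with amplitude (property)", {
  base <- fepsp_trace(peak_uv = 15)
  r0 <- fepsp_slope(base, 10, stim_onset_ms = 5, artifact_ms = 2)
  for (offset in c(-40, 13.7)) {
    r <- fepsp_slope(base + offset, 10, stim_onset_ms = 5, artifact_ms = 2)
    expect_equal(r$slope_uV_per_ms, r0$slope_uV_per_ms, tolerance = 1e-9)
  }
  for (gain in c(0.5, 2, 3.5)) {
    r <- fepsp_slope(base * gain, 10, stim_onset_ms = 5, artifact_ms = 2)
    expect_equal(r$slope_uV_per_ms, gain * r0$slope_uV_per_ms,
                 tolerance = 1e-9)
  }
})

test_that("bin_slopes averages 2-min pairs into 4-min bins", {
  tb <- tibble::tibble(time_min = c(0, 2), channel = c(1L, 1L),
                       slope_uV_per_ms = c(1, 3), amplitude_uV = c(2, 6))
  b <- bin_slopes(tb)
  expect_equal(nrow(b), 1L)
  expect_equal(b$slope_uV_per_ms, 2)
  expect_equal(b$time_min, 1)
  # 2n samples -> n bins; mean conserved
  withr::with_seed(2L, {
    tb <- tibble::tibble(time_min = rep(seq(2, 40, by = 2), each = 1),
                         channel = 1L,
                         slope_uV_per_ms = rnorm(20),
                         amplitude_uV = abs(rnorm(20)))
  })
  b <- bin_slopes(tb)
  expect_equal(nrow(b), 10L)
  expect_equal(mean(b$slope_uV_per_ms), mean(tb$slope_uV_per_ms))
  expect_false(any(b$singleton))
})

test_that("an odd trailing sample is kept as a flagged singleton bin", {
  tb <- tibble::tibble(time_min = c(2, 4, 6), channel = 1L,
                       slope_uV_per_ms = c(1, 3, 9),
                       amplitude_uV = c(1, 1, 1))
  b <- bin_slopes(tb)
  expect_equal(nrow(b), 2L)
  expect_equal(b$singleton, c(FALSE, TRUE))
  expect_equal(b$slope_uV_per_ms, c(2, 9))
})

test_that("simulator cadence yields 15 baseline bins over the 60-min hour", {
  sim <- simulate_slice(sim_preset("adult"), seed = 1L)
  b <- bin_slopes(sim$slopes)
  base <- unique(b$time_min[b$time_min <= 60])
  expect_equal(length(base), 15L)
})

test_that("baseline normalisation is exact and idempotent up to scale", {
  withr::with_seed(3L, {
    tb <- tibble::tibble(
      time_min = rep(seq(2, 120, by = 4), each = 2),
      channel = rep(1:2, times = 30),
      slope_uV_per_ms = -abs(rnorm(60, 10, 2)),
      amplitude_uV = abs(rnorm(60, 20, 2)))
  })
  tl <- experiment_timeline(baseline_end = 60, recording_end = 120,
                            events = tibble::tibble(
                              time_min = 60, kind = "strong_TBS",
                              site = 1L))
  ns <- normalize_to_baseline(tb, tl)
  base <- ns[ns$time_min <= 60, ]
  for (ch in 1:2) {
    expect_equal(mean(base$normalized[base$channel == ch]), 100)
  }
  # feeding the normalised series back reproduces it (idempotence)
  tb2 <- dplyr::mutate(tb, slope_uV_per_ms = -ns$normalized)
  ns2 <- normalize_to_baseline(tb2, tl)
  expect_equal(ns2$normalized, ns$normalized)
  # a bin at 1.48x the baseline mean normalises to 148.0
  flat <- tibble::tibble(time_min = seq(2, 62, by = 4), channel = 1L,
                         slope_uV_per_ms = -10, amplitude_uV = 20)
  flat$slope_uV_per_ms[nrow(flat)] <- -14.8
  nf <- normalize_to_baseline(flat, tl)
  expect_equal(nf$normalized[nrow(nf)], 148.0)
})

test_that("normalisation guards degenerate baselines", {
  tl <- experiment_timeline(baseline_end = 60, recording_end = 120,
                            events = tibble::tibble(
                              time_min = 60, kind = "strong_TBS",
                              site = 1L))
  zero <- tibble::tibble(time_min = seq(2, 62, by = 4), channel = 1L,
                         slope_uV_per_ms = 0, amplitude_uV = 0)
  expect_error(normalize_to_baseline(zero, tl, on_zero = "error"),
               class = "med64_normalization_error")
  expect_error(normalize_to_baseline(zero, tl),
               class = "med64_normalization_error")
  short <- tibble::tibble(time_min = c(2, 6), channel = 1L,
                          slope_uV_per_ms = -1, amplitude_uV = 2)
  expect_error(normalize_to_baseline(short, tl),
               class = "med64_input_error")
})

test_that("stability gate applies the strict 5% CV and inclusive 10% fraction rules", {
  tl <- experiment_timeline(baseline_end = 60, recording_end = 120,
                            events = tibble::tibble(
                              time_min = 60, kind = "strong_TBS",
                              site = 1L))
  times <- seq(2, 58, by = 4)
  mk <- function(n_unstable, n_active = 20L) {
    stable <- rep(10, length(times))
    wobble <- 10 * (1 + 0.2 * rep_len(c(1, -1), length(times)))
    amp <- matrix(rep(stable, n_active), nrow = n_active, byrow = TRUE)
    if (n_unstable > 0) {
      amp[seq_len(n_unstable), ] <-
        matrix(rep(wobble, n_unstable), nrow = n_unstable, byrow = TRUE)
    }
    slope_table_from_amp(amp, times, slope_per_uv = 1)
  }
  # all-constant baselines: nothing unstable
  r0 <- stability_gate(mk(0), tl)
  expect_equal(length(r0$unstable_channels), 0L)
  expect_true(r0$passed)
  # 2 of 20 -> fraction 0.10, inclusive boundary passes
  r2 <- stability_gate(mk(2), tl)
  expect_equal(r2$fraction_unstable, 0.10)
  expect_true(r2$passed)
  # 3 of 20 -> 0.15, fails
  r3 <- stability_gate(mk(3), tl)
  expect_equal(r3$fraction_unstable, 0.15)
  expect_false(r3$passed)
  # no active channels -> gate error
  empty <- mk(0)
  empty$amplitude_uV <- 0
  empty$slope_uV_per_ms <- 0
  expect_error(stability_gate(empty, tl), class = "med64_gate_error")
})

test_that("slope extraction from synthesised waveforms tracks the noise-free trajectory", {
  sim <- simulate_slice(
    sim_preset("adult", channel_sigma = 0, slice_sigma = 0,
               p_capture = 1),
    seed = 2L, output = "recording", waveform_noise_uV = 0)
  ns <- slope_pipeline(sim$recording)
  truth <- sim$truth
  for (ch in truth$channel[truth$activated]) {
    got <- mean(ns$normalized[ns$channel == ch & ns$time_min >= 300])
    expect_equal(got, truth$plateau_pct[truth$channel == ch],
                 tolerance = 1e-6)
  }
})
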