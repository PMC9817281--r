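# Small in-code fixtures shared across test files.

tiny_recording <- function(seed = 7L, n_chan_grid = c(2L, 2L),
                           n_sweeps = 6L, n_samp = 40L) {
  grid <- electrode_grid(rows = n_chan_grid[1], cols = n_chan_grid[2],
                         stim_channels = c(S1 = 1L))
  timeline <- experiment_timeline(
    baseline_start = 0, baseline_end = 8,
    events = tibble::tibble(time_min = 8, kind = "strong_TBS", site = 1L),
    recording_end = n_sweeps * 2)
  withr::with_seed(seed, {
    arr <- array(rnorm(prod(n_chan_grid) * n_sweeps * n_samp),
                 dim = c(prod(n_chan_grid), n_sweeps, n_samp))
    med64_recording(grid, timeline, arr,
                    sweep_times = seq(2, by = 2, length.out = n_sweeps),
                    sample_rate_khz = 4, sweep_interval_min = 2,
                    stim_onset_ms = 2, artifact_ms = 1,
                    meta = list(note = "tiny"))
  })
}

# double-exponential fEPSP trace with a flat pre-stimulus segment
fepsp_trace <- function(peak_uv = 20, tau_rise = 1, tau_decay = 5,
                        onset_ms = 8, rate = 10, dur_ms = 40) {
  t_ms <- seq(0, dur_ms - 1 / rate, by = 1 / rate)
  u <- pmax(0, t_ms - onset_ms)
  shape <- exp(-u / tau_decay) - exp(-u / tau_rise)
  shape[t_ms < onset_ms] <- 0
  -peak_uv * shape / max(shape)
}

# slope-dialect tibble built directly from per-channel trajectories:
# traj is a matrix channels x times of amplitudes in uV
slope_table_from_amp <- function(amp, times, slope_per_uv = 0.5) {
  n_ch <- nrow(amp)
  tibble::tibble(
    time_min = rep(times, each = n_ch),
    channel = rep(seq_len(n_ch), times = length(times)),
    slope_uV_per_ms = -slope_per_uv * as.vector(amp),
    amplitude_uV = as.vector(amp),
    no_response = as.vector(amp) <= 0)
}

expect_recording_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(a$grid[c("rows", "cols", "pitch_um", "electrode_um")],
               b$grid[c("rows", "cols", "pitch_um", "electrode_um")])
  expect_equal(sort(a$grid$stim_channels), sort(b$grid$stim_channels))
  expect_equal(a$timeline$baseline_start, b$timeline$baseline_start)
  expect_equal(a$timeline$baseline_end, b$timeline$baseline_end)
  expect_equal(a$timeline$recording_end, b$timeline$recording_end)
  expect_equal(as.data.frame(a$timeline$events),
               as.data.frame(b$timeline$events))
  expect_equal(a$sweep_times, b$sweep_times, tolerance = tolerance)
  expect_equal(a$sample_rate_khz, b$sample_rate_khz)
  expect_equal(a$sweep_interval_min, b$sweep_interval_min)
  expect_equal(a$stim_onset_ms, b$stim_onset_ms)
  expect_equal(a$artifact_ms, b$artifact_ms)
  expect_equal(a$sweeps, b$sweeps, tolerance = tolerance)
}
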