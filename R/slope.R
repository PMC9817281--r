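#' fEPSP slope and amplitude of a single sweep
#'
#' The initial slope of the negative-going field potential is the standard
#' index of synaptic strength. It is measured here as the least-squares
#' linear slope of the trace segment between `window[1]` and `window[2]` of
#' the peak negativity (default the 20-80% rising phase of the deflection),
#' after masking `artifact_ms` of stimulus artifact. The pre-stimulus
#' segment provides the DC baseline and the noise floor: a sweep with no
#' negative deflection exceeding `noise_mult` pre-stimulus standard
#' deviations is flagged as having no response and given slope 0.
#'
#' To keep the measurement unbiased in noise, the peak and the fractional
#' crossing times are located on a lightly smoothed copy of the trace
#' (moving average of width `smooth_ms`), with the crossing times
#' interpolated linearly; the least-squares fit itself runs on the raw
#' samples inside the crossing window. Selecting raw samples by their own
#' noisy value would systematically flatten the fitted slope.
#'
#' @param trace Numeric voltage trace in uV.
#' @param sample_rate_khz Samples per ms.
#' @param window Fractional bounds of the rising segment, `0 <= lo < hi <= 1`.
#' @param stim_onset_ms Stimulus time within the sweep (ms); samples before
#'   it form the pre-stimulus segment (may be 0 for bare traces).
#' @param artifact_ms Duration masked after stimulus onset (ms).
#' @param noise_mult Noise-floor multiplier for response detection.
#' @param smooth_ms Width (ms) of the moving average used for peak and
#'   crossing detection; 0 disables smoothing.
#' @return A one-row tibble: `slope_uV_per_ms` (negative for a
#'   negative-going fEPSP), `amplitude_uV` (peak negativity magnitude) and
#'   `no_response`.
#' @examples
#' ramp <- seq(0, -10, length.out = 21) # 10 uV fall over 2 ms at 10 kHz
#' fepsp_slope(ramp, sample_rate_khz = 10)
#' @export
fepsp_slope <- function(trace, sample_rate_khz, window = c(0.2, 0.8),
                        stim_onset_ms = 0, artifact_ms = 0, noise_mult = 3,
                        smooth_ms = 0.5) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[1] < window[2],
            window[2] <= 1, sample_rate_khz > 0)
  n <- length(trace)
  t_ms <- (seq_len(n) - 1L) / sample_rate_khz
  pre <- which(t_ms < stim_onset_ms)
  post <- which(t_ms >= stim_onset_ms + artifact_ms)
  if (length(post) < 2L) {
    abort("trace shorter than the artifact mask", class = "med64_input_error")
  }
  baseline <- if (length(pre)) mean(trace[pre]) else trace[[1L]]
  v <- trace[post] - baseline
  vs <- smooth_trace(v, sample_rate_khz, smooth_ms)
  noise_sd <- if (length(pre) > 1L) {
    sd(smooth_trace(trace[pre], sample_rate_khz, smooth_ms))
  } else 0
  res <- slope_core(v, vs, t_ms[post], window, noise_mult * noise_sd)
  tibble::tibble(slope_uV_per_ms = res[[1L]], amplitude_uV = res[[2L]],
                 no_response = res[[3L]] > 0.5)
}

# centred moving average; edges fall back to the raw samples
smooth_trace <- function(v, sample_rate_khz, smooth_ms) {
  k <- round(smooth_ms * sample_rate_khz)
  k <- k + (k + 1L) %% 2L # force odd
  if (k <= 1L || length(v) < k) return(v)
  vs <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  bad <- is.na(vs)
  vs[bad] <- v[bad]
  vs
}

# returns c(slope, amplitude, no_response) for one baseline-subtracted
# post-stimulus segment; vs is the smoothed copy used for detection
slope_core <- function(v, vs, tt, window, floor_uv) {
  ipk <- which.min(vs)
  peak <- vs[[ipk]]
  floor_uv <- max(floor_uv, 1e-9)
  if (peak >= 0 || -peak <= floor_uv) {
    return(c(0, 0, 1))
  }
  f <- vs[seq_len(ipk)] / peak # fraction of peak, rising 0..1
  cross_time <- function(level) {
    below <- which(f < level)
    if (!length(below)) return(tt[[1L]])
    idx <- max(below) # last crossing before the peak
    if (idx >= ipk) return(tt[[ipk]])
    f0 <- f[[idx]]; f1 <- f[[idx + 1L]]
    if (f1 == f0) return(tt[[idx + 1L]])
    tt[[idx]] + (level - f0) / (f1 - f0) * (tt[[idx + 1L]] - tt[[idx]])
  }
  t_lo <- cross_time(window[1])
  t_hi <- cross_time(window[2])
  if (t_hi < t_lo) t_hi <- tt[[ipk]]
  sel <- which(tt >= t_lo & tt <= t_hi & seq_along(tt) <= ipk)
  if (length(sel) < 2L) sel <- unique(c(max(1L, ipk - 1L), ipk))
  xs <- tt[sel]
  ys <- v[sel]
  slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  c(slope, -peak, 0)
}

#' Per-sweep slopes and amplitudes of a whole recording
#'
#' Applies [fepsp_slope()] to every (channel, sweep) trace. Detection of
#' unresponsive sweeps is vectorised; the least-squares segment fit runs
#' only on sweeps with a detectable deflection.
#'
#' @param rec A [med64_recording()].
#' @inheritParams fepsp_slope
#' @inheritParams fepsp_slope
#' @return A tibble with one row per (sweep, channel): `time_min`,
#'   `channel`, `slope_uV_per_ms`, `amplitude_uV`, `no_response`.
#' @export
extract_slopes <- function(rec, window = c(0.2, 0.8), noise_mult = 3,
                           smooth_ms = 0.5) {
  d <- dim(rec$sweeps)
  n_tr <- d[[1L]] * d[[2L]]
  m <- matrix(rec$sweeps, nrow = n_tr, ncol = d[[3L]])
  t_ms <- (seq_len(d[[3L]]) - 1L) / rec$sample_rate_khz
  pre <- which(t_ms < rec$stim_onset_ms)
  post <- which(t_ms >= rec$stim_onset_ms + rec$artifact_ms)
  if (length(post) < 2L) {
    abort("sweeps shorter than the artifact mask", class = "med64_input_error")
  }
  # smoothed copy (moving average along the sample axis) for detection
  k <- round(smooth_ms * rec$sample_rate_khz)
  k <- k + (k + 1L) %% 2L
  ms <- if (k > 1L && d[[3L]] >= k) {
    sm <- t(stats::filter(t(m), rep(1 / k, k), sides = 2))
    bad <- is.na(sm)
    sm[bad] <- m[bad]
    sm
  } else m
  if (length(pre)) {
    baseline <- rowMeans(m[, pre, drop = FALSE])
    pres <- ms[, pre, drop = FALSE]
    noise_sd <- if (length(pre) > 1L) {
      mu <- rowMeans(pres)
      sqrt(pmax(0, rowMeans(pres^2) - mu^2) *
             length(pre) / (length(pre) - 1L))
    } else rep(0, n_tr)
  } else {
    baseline <- m[, 1L]
    noise_sd <- rep(0, n_tr)
  }
  v <- m[, post, drop = FALSE] - baseline
  vs <- ms[, post, drop = FALSE] - baseline
  peak_s <- apply(vs, 1L, min)
  floor_uv <- pmax(noise_mult * noise_sd, 1e-9)
  responds <- peak_s < 0 & -peak_s > floor_uv
  slope <- numeric(n_tr)
  amp <- numeric(n_tr)
  tt <- t_ms[post]
  for (i in which(responds)) {
    res <- slope_core(v[i, ], vs[i, ], tt, window, floor_uv[[i]])
    slope[[i]] <- res[[1L]]
    amp[[i]] <- res[[2L]]
  }
  tibble::tibble(
    time_min = rep(rec$sweep_times, each = d[[1L]]),
    channel = rep(seq_len(d[[1L]]), times = d[[2L]]),
    slope_uV_per_ms = slope, amplitude_uV = amp,
    no_response = !responds)
}

#' Average consecutive sweeps into bins
#'
#' Test responses are sampled every 2 min and reported as 4-min averages:
#' consecutive pairs of sweeps are averaged per channel, the bin centre
#' being the mean of the member sweep times. An odd trailing sweep is kept
#' as a flagged singleton bin.
#'
#' @param slopes Per-sweep slope tibble (from [extract_slopes()] or the
#'   slope dialect).
#' @param per_bin Number of consecutive sweeps per bin (default 2).
#' @return A tibble with one row per (bin, channel): `time_min` (bin
#'   centre), `channel`, `slope_uV_per_ms`, `amplitude_uV`, `n_sweeps`,
#'   `singleton`, and `no_response` (all member sweeps unresponsive) when
#'   present in the input.
#' @export
bin_slopes <- function(slopes, per_bin = 2L) {
  stopifnot(per_bin >= 1L)
  times <- sort(unique(slopes$time_min))
  n_bins <- ceiling(length(times) / per_bin)
  bin <- ((match(slopes$time_min, times) - 1L) %/% per_bin) + 1L
  chans <- sort(unique(slopes$channel))
  gid <- (match(slopes$channel, chans) - 1L) * n_bins + bin
  has_flag <- "no_response" %in% names(slopes)
  cols <- cbind(one = 1, time_min = slopes$time_min,
                slope = slopes$slope_uV_per_ms,
                amp = slopes$amplitude_uV,
                nr = if (has_flag) as.numeric(slopes$no_response) else 0)
  sums <- rowsum(cols, gid)
  g <- as.integer(rownames(sums))
  n <- sums[, "one"]
  out <- tibble::tibble(
    channel = chans[(g - 1L) %/% n_bins + 1L],
    time_min = unname(sums[, "time_min"] / n),
    slope_uV_per_ms = unname(sums[, "slope"] / n),
    amplitude_uV = unname(sums[, "amp"] / n),
    n_sweeps = as.integer(unname(n)),
    no_response = if (has_flag) unname(sums[, "nr"] == n) else NA,
    singleton = unname(n < per_bin))
  if (!has_flag) out$no_response <- NULL
  dplyr::arrange(out, .data$time_min, .data$channel)
}

baseline_bin_filter <- function(slopes, timeline) {
  dplyr::filter(slopes, .data$time_min >= timeline$baseline_start,
                .data$time_min <= timeline$baseline_end)
}

#' Normalise binned slopes to the baseline mean
#'
#' Adds, per channel, the baseline mean slope magnitude
#' (`baseline_mean_slope`, uV/ms over the baseline bins) and the
#' baseline-normalised slope `normalized = 100 * |slope| /
#' baseline_mean_slope` (% of baseline). By construction the mean of
#' `normalized` over the baseline bins is exactly 100.
#'
#' @param slopes Binned slope tibble (see [bin_slopes()]).
#' @param timeline An [experiment_timeline()] providing the baseline window.
#' @param min_baseline_bins Minimum number of baseline bins required.
#' @param on_zero What to do for channels whose baseline mean slope is 0:
#'   `"na"` (default) leaves `normalized` as `NA`, `"error"` raises.
#' @return The input with `baseline_mean_slope` and `normalized` columns.
#' @export
normalize_to_baseline <- function(slopes, timeline, min_baseline_bins = 3L,
                                  on_zero = c("na", "error")) {
  on_zero <- match.arg(on_zero)
  base <- baseline_bin_filter(slopes, timeline) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(baseline_mean_slope = mean(abs(.data$slope_uV_per_ms)),
                     n_baseline_bins = dplyr::n(), .groups = "drop")
  if (nrow(base) == 0L || any(base$n_baseline_bins < min_baseline_bins)) {
    abort(sprintf("need at least %d baseline bins per channel",
                  min_baseline_bins), class = "med64_input_error")
  }
  if (on_zero == "error" && any(base$baseline_mean_slope == 0)) {
    abort("baseline mean slope is zero; normalization undefined",
          class = "med64_normalization_error")
  }
  if (all(base$baseline_mean_slope == 0)) {
    abort("all channels have zero baseline mean slope",
          class = "med64_normalization_error")
  }
  slopes |>
    dplyr::left_join(dplyr::select(base, "channel", "baseline_mean_slope"),
                     by = "channel") |>
    dplyr::mutate(normalized = dplyr::if_else(
      .data$baseline_mean_slope > 0,
      100 * abs(.data$slope_uV_per_ms) / .data$baseline_mean_slope,
      NA_real_))
}

#' Baseline stability gate
#'
#' A slice is admitted when single-channel baseline variation (coefficient
#' of variation of the baseline bin slopes) is below `cv_limit` (< 5%) for
#' all but at most a `fraction_limit` (<= 10%) share of the active
#' channels. The CV rule is strict, the fraction rule inclusive.
#'
#' @param slopes Binned slope tibble.
#' @param timeline An [experiment_timeline()].
#' @param cv_limit Channel-instability threshold on the baseline CV.
#' @param fraction_limit Maximum tolerated fraction of unstable channels.
#' @param amp_threshold Baseline amplitude (uV) defining an active channel.
#' @return An object of class `stability_report`: tibble `per_channel`
#'   (`channel`, `baseline_cv`, `active`, `unstable`), the set
#'   `unstable_channels`, `fraction_unstable` and `passed`.
#' @export
stability_gate <- function(slopes, timeline, cv_limit = 0.05,
                           fraction_limit = 0.10, amp_threshold = 10) {
  per <- baseline_bin_filter(slopes, timeline) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      baseline_mean = mean(abs(.data$slope_uV_per_ms)),
      baseline_cv = dplyr::if_else(
        mean(abs(.data$slope_uV_per_ms)) > 0,
        sd(abs(.data$slope_uV_per_ms)) / mean(abs(.data$slope_uV_per_ms)),
        0),
      mean_amp = mean(.data$amplitude_uV),
      .groups = "drop") |>
    dplyr::mutate(active = .data$mean_amp >= amp_threshold,
                  unstable = .data$active & .data$baseline_cv >= cv_limit)
  n_active <- sum(per$active)
  if (n_active == 0L) {
    abort("no active channels at baseline; stability gate undefined",
          class = "med64_gate_error")
  }
  unstable <- per$channel[per$unstable]
  fraction <- length(unstable) / n_active
  structure(list(per_channel = per, unstable_channels = unstable,
                 fraction_unstable = fraction,
                 n_active = n_active,
                 cv_limit = cv_limit, fraction_limit = fraction_limit,
                 passed = fraction <= fraction_limit),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %d active channels, %d unstable (%.1f%%): %s\n",
    x$n_active, length(x$unstable_channels), 100 * x$fraction_unstable,
    if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Serialise a stability report to JSON
#' @param x A `stability_report`.
#' @param path Output file path.
#' @export
write_stability_report <- function(x, path) {
  jsonlite::write_json(
    list(n_active = x$n_active,
         unstable_channels = as.integer(x$unstable_channels),
         fraction_unstable = x$fraction_unstable,
         cv_limit = x$cv_limit, fraction_limit = x$fraction_limit,
         passed = x$passed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full slope pipeline on a recording or slope table
#'
#' Convenience wrapper: per-sweep extraction (recordings only), 4-min
#' binning, baseline normalisation.
#'
#' @param x A [med64_recording()] or a per-sweep slope tibble.
#' @param timeline Required when `x` is a slope tibble; taken from the
#'   recording otherwise.
#' @param per_bin Sweeps per bin.
#' @return A normalised binned slope tibble.
#' @export
slope_pipeline <- function(x, timeline = NULL, per_bin = 2L) {
  if (inherits(x, "med64_recording")) {
    timeline <- x$timeline
    x <- extract_slopes(x)
  }
  if (is.null(timeline)) {
    abort("timeline required when input is a slope table",
          class = "med64_input_error")
  }
  x |>
    bin_slopes(per_bin = per_bin) |>
    normalize_to_baseline(timeline)
}
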