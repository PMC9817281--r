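#' Simulation presets
#'
#' Bundled parameter sets emulating the study conditions of the four
#' experimental groups. The group-level targets (`s1_plateau`,
#' `s2_tagging_plateau`, `p_capture`) are calibrated to the printed group
#' statistics, so simulations reproduce those numbers in expectation by
#' construction; the trajectory shapes (smoothstep rise to plateau over
#' ~40 min, exponential early-LTP decay) are minimal forms matching the
#' published time courses qualitatively.
#'
#' @param name One of `"adult"`, `"middle_aged"`, `"middle_aged_BDNF"`,
#'   `"middle_aged_R13"` (the rescued presets use the adult plateau and a
#'   slice-level capture probability of 1).
#' @param ... Named overrides of any preset field.
#' @return A list of class `sim_preset` with fields:
#' \describe{
#'   \item{s1_plateau}{final-30-min normalised slope target at S1, %.}
#'   \item{s2_tagging_plateau}{final-30-min mixture target over activated
#'     S2 channels, %.}
#'   \item{p_capture}{probability an activated S2 channel converts to a
#'     tagging-like late LTP.}
#'   \item{e_ltp_decay_tau}{early-LTP decay constant, min (75, so the
#'     early LTP returns near baseline by ~2.5 h).}
#'   \item{e_ltp_jump}{early-LTP initial increment, % of baseline.}
#'   \item{recruit_rate}{expected newly recruited channels per hour per
#'     site.}
#'   \item{slice_sigma}{between-slice SD of plateau draws, %.}
#'   \item{channel_sigma}{within-slice per-sweep noise SD, % (4-min bins
#'     then have ~sigma/sqrt(2) SD, keeping the <5% baseline CV gate
#'     satisfied).}
#'   \item{amp_at_site}{fEPSP amplitude at zero distance from the
#'     stimulation site, uV.}
#'   \item{decay_length_um}{spatial length constant of the amplitude
#'     decay (300 um puts ~8 channels per site above the 10 uV activation
#'     threshold).}
#'   \item{ltp_rise_min}{duration of the rise to plateau, min.}
#'   \item{recruit_amp_mean, recruit_amp_sd}{plateau amplitude of
#'     recruited channels, uV.}
#' }
#' @export
sim_preset <- function(name = c("adult", "middle_aged", "middle_aged_BDNF",
                                "middle_aged_R13"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    s1_plateau = 148.0, s2_tagging_plateau = 175.2, p_capture = 0.7333,
    e_ltp_decay_tau = 75, e_ltp_jump = 36.5, recruit_rate = 1.2,
    slice_sigma = 8, channel_sigma = 5,
    amp_at_site = 25, decay_length_um = 300, ltp_rise_min = 40,
    recruit_amp_mean = 24, recruit_amp_sd = 1)
  if (name == "middle_aged") {
    base$s1_plateau <- 128.0
    base$s2_tagging_plateau <- 114.4
    base$p_capture <- 0.3333
    base$recruit_rate <- 0.3
  } else if (name %in% c("middle_aged_BDNF", "middle_aged_R13")) {
    base$p_capture <- 1.0
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) {
    abort(paste0("unknown preset fields: ", paste(bad, collapse = ", ")),
          class = "med64_input_error")
  }
  p <- modifyList(base, over)
  stopifnot(p$p_capture >= 0, p$p_capture <= 1, p$e_ltp_decay_tau > 0,
            p$slice_sigma >= 0, p$channel_sigma >= 0, p$ltp_rise_min > 0)
  structure(p, class = "sim_preset")
}

#' @export
print.sim_preset <- function(x, ...) {
  cat(sprintf(
    "<sim_preset %s> S1 plateau %g%%, S2 target %g%%, p_capture %g\n",
    x$name, x$s1_plateau, x$s2_tagging_plateau, x$p_capture))
  invisible(x)
}

# smooth sigmoidal ramp, exactly 0 at u <= 0 and exactly 1 at u >= 1
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# replicate the pipeline's pairwise binning of a per-sweep vector and
# return the mean over bins whose centre lies in [lo, hi]
binned_window_mean <- function(values, sweep_times, lo, hi) {
  n <- length(sweep_times)
  bin <- ((seq_len(n) - 1L) %/% 2L) + 1L
  centers <- tapply(sweep_times, bin, mean)
  means <- tapply(values, bin, mean)
  sel <- centers >= lo & centers <= hi
  mean(means[sel])
}

# per-channel multiplicative trajectory (baseline = 1) on the sweep grid
slice_trajectories <- function(preset, timeline, assign, sweep_times,
                               capture, p1_plateau, tag_plateau) {
  n_chan <- nrow(assign)
  g <- matrix(1, n_chan, length(sweep_times))
  for (i in seq_len(n_chan)) {
    if (!assign$activated[i]) next
    ev <- assign$event_time[i]
    u <- sweep_times - ev
    if (assign$site[i] == "S1") {
      g[i, ] <- 1 + (p1_plateau / 100 - 1) *
        smoothstep(u / preset$ltp_rise_min)
    } else if (isTRUE(capture[i])) {
      g[i, ] <- 1 + (tag_plateau / 100 - 1) *
        smoothstep(u / preset$ltp_rise_min)
    } else {
      dec <- ifelse(u > 0,
                    (preset$e_ltp_jump / 100) *
                      exp(-pmax(0, u) / preset$e_ltp_decay_tau),
                    0)
      g[i, ] <- 1 + dec
    }
  }
  g
}

#' Simulate one slice experiment
#'
#' Generates a full synthetic slice: baseline fEPSP amplitudes decaying
#' exponentially with distance from the stimulated sites, a strong-train
#' late LTP at S1 with a slice-level plateau draw, Bernoulli tagging
#' capture at S2 (sustained plateau for captured channels, decaying early
#' LTP otherwise, with the capture-mixture plateau solved so the expected
#' S2 group mean equals the preset target), Poisson recruitment of
#' initially silent channels, and multiplicative per-sweep noise. Output
#' is either a raw-waveform [med64_recording()] (double-exponential fEPSP
#' template scaled per sweep) or a per-sweep slope table ready for
#' [slope_pipeline()].
#'
#' Ground-truth labels are the classes implied by the noise-free
#' trajectories (so a slice whose plateau draw falls below the 120%
#' criterion is truthfully non-LTP); the Bernoulli capture branch is
#' recorded separately in `capture`.
#'
#' @param preset A [sim_preset()].
#' @param grid An [electrode_grid()].
#' @param timeline An [experiment_timeline()]; defaults to the tagging
#'   protocol.
#' @param seed Integer seed; identical seeds give identical output.
#' @param output `"slopes"` (per-sweep slope table) or `"recording"`
#'   (raw waveforms).
#' @param sample_rate_khz,sweep_ms,waveform_noise_uV Waveform synthesis
#'   parameters (recording output only).
#' @param amp_threshold Activation threshold used for the ground-truth
#'   labels (uV).
#' @return A list of class `med64_sim`: `slopes` or `recording`, `truth`
#'   (tibble with `channel`, `site`, `is_stim`, `activated`, `capture`,
#'   `ltp_class`, `tagging_like`, `recruited_time_min`, `plateau_pct`),
#'   `timeline`, `grid`, `preset`, `seed`.
#' @export
simulate_slice <- function(preset, grid = electrode_grid(),
                           timeline = tagging_protocol(grid), seed = 1L,
                           output = c("slopes", "recording"),
                           sample_rate_khz = 10, sweep_ms = 40,
                           waveform_noise_uV = 1, amp_threshold = 10) {
  output <- match.arg(output)
  stopifnot(inherits(preset, "sim_preset"))
  if (!any(timeline$events$kind %in% tbs_kinds)) {
    abort("timeline lacks TBS events; nothing to simulate",
          class = "med64_simulation_error")
  }
  site_events <- site_event_table(timeline, grid)
  withr::with_seed(as.integer(seed), {
    sweep_times <- seq(timeline$baseline_start + 2, timeline$recording_end,
                       by = 2)
    n_chan <- grid$rows * grid$cols
    stim <- as.integer(grid$stim_channels)
    assign <- assign_sites(grid, site_events)
    dists <- vapply(seq_len(nrow(site_events)), function(i) {
      channel_distances(grid, site_events$stim_channel[i])
    }, numeric(n_chan))
    nearest <- max.col(-dists, ties.method = "first")
    own_dist <- dists[cbind(seq_len(n_chan), nearest)]
    a0 <- preset$amp_at_site * exp(-own_dist / preset$decay_length_um)
    is_stim <- seq_len(n_chan) %in% stim
    a0[is_stim] <- 0
    assign$activated <- a0 >= amp_threshold & !is_stim

    # capture-mixture solve: the sustained plateau of captured channels
    # is set so that the expected S2 mixture mean equals the preset
    # target; the slice-level variability then applies to the plateau
    # itself (as for S1), keeping the mixture unbiased at the target
    p1_plateau <- rnorm(1, preset$s1_plateau, preset$slice_sigma)
    end <- timeline$recording_end
    s2_ev <- assign$event_time[match("S2", assign$site)]
    e_shape <- 1 + (preset$e_ltp_jump / 100) *
      exp(-pmax(0, sweep_times - s2_ev) / preset$e_ltp_decay_tau)
    e_shape[sweep_times <= s2_ev] <- 1
    e_last30_pct <- 100 * binned_window_mean(e_shape, sweep_times,
                                             end - 30, end)
    tag_plateau <- if (preset$p_capture > 0) {
      rnorm(1,
            (preset$s2_tagging_plateau -
               (1 - preset$p_capture) * e_last30_pct) / preset$p_capture,
            preset$slice_sigma)
    } else NA_real_

    capture <- rep(NA, n_chan)
    s2_act <- which(assign$activated & assign$site == "S2")
    capture[s2_act] <- rbinom(length(s2_act), 1L, preset$p_capture) == 1L

    g <- slice_trajectories(preset, timeline, assign, sweep_times,
                            capture, p1_plateau, tag_plateau)

    # Poisson recruitment of initially silent channels, nearest first
    amp <- a0 * g
    recruited_time <- rep(NA_real_, n_chan)
    rec_plateau <- rep(NA_real_, n_chan)
    for (i in seq_len(nrow(site_events))) {
      ev <- site_events$time_min[i]
      horizon <- (end - ev) / 60
      pool <- which(!assign$activated & !is_stim &
                    assign$site == site_events$site[i] &
                    is.na(recruited_time))
      pool <- pool[order(own_dist[pool])]
      for (h in seq_len(ceiling(horizon))) {
        frac <- min(1, horizon - (h - 1))
        n_new <- rpois(1L, preset$recruit_rate * frac)
        n_new <- min(n_new, length(pool))
        if (n_new == 0L) next
        ch_new <- pool[seq_len(n_new)]
        pool <- pool[-seq_len(n_new)]
        t_rec <- ev + 60 * (h - 1) + runif(n_new, 0, 60 * frac)
        t_rec <- pmin(t_rec, end - 10)
        plat <- rnorm(n_new, preset$recruit_amp_mean, preset$recruit_amp_sd)
        recruited_time[ch_new] <- t_rec
        rec_plateau[ch_new] <- plat
        for (k in seq_along(ch_new)) {
          # onset placed so the ramp crosses the activation threshold
          # close to the drawn recruitment time
          cross <- amp_threshold / plat[k]
          u0 <- stats::uniroot(function(u) smoothstep(u) - cross,
                               c(0, 1))$root
          onset <- max(ev, t_rec[k] - u0 * preset$ltp_rise_min)
          amp[ch_new[k], ] <- plat[k] *
            smoothstep((sweep_times - onset) / preset$ltp_rise_min)
        }
      }
    }

    noise <- matrix(1 + rnorm(n_chan * length(sweep_times),
                              sd = preset$channel_sigma / 100),
                    n_chan, length(sweep_times))
    amp_noisy <- pmax(amp * noise, 0)

    truth <- truth_labels(assign, is_stim, capture, g, amp, sweep_times,
                          timeline, recruited_time, p1_plateau,
                          tag_plateau, amp_threshold)

    out <- list(truth = truth, timeline = timeline, grid = grid,
                preset = preset, seed = as.integer(seed),
                sweep_times = sweep_times)
    if (output == "slopes") {
      slope_per_uv <- 0.65 # uV/ms of fEPSP slope per uV of amplitude
      out$slopes <- tibble::tibble(
        time_min = rep(sweep_times, each = n_chan),
        channel = rep(seq_len(n_chan), times = length(sweep_times)),
        slope_uV_per_ms = -slope_per_uv * as.vector(amp_noisy),
        amplitude_uV = as.vector(amp_noisy),
        no_response = as.vector(amp_noisy) < 1e-9)
    } else {
      out$recording <- synth_waveforms(amp_noisy, grid, timeline,
                                       sweep_times, sample_rate_khz,
                                       sweep_ms, waveform_noise_uV,
                                       is_stim)
    }
    structure(out, class = "med64_sim")
  })
}

truth_labels <- function(assign, is_stim, capture, g, amp, sweep_times,
                         timeline, recruited_time, p1_plateau,
                         tag_plateau, amp_threshold) {
  end <- timeline$recording_end
  has_tagging <- !is.na(event_time(timeline, "strong_TBS")) &&
    !is.na(event_time(timeline, "tagging_TBS"))
  n_chan <- nrow(assign)
  cls <- rep(NA_character_, n_chan)
  tagging <- rep(FALSE, n_chan)
  plateau <- rep(NA_real_, n_chan)
  for (i in seq_len(n_chan)) {
    if (!assign$activated[i]) next
    ev <- assign$event_time[i]
    norm <- 100 * g[i, ]
    late <- binned_window_mean(norm, sweep_times, end - 30, end)
    early <- binned_window_mean(norm, sweep_times, ev + 30, ev + 60)
    cls[i] <- if (late >= 120) "L_LTP" else if (early >= 120) "E_LTP" else
      "non_LTP"
    plateau[i] <- late
    if (has_tagging && assign$site[i] == "S2" && cls[i] == "L_LTP") {
      tagging[i] <- tag_tagging_like(cls[i], timeline)
    }
  }
  tibble::tibble(channel = assign$channel, site = assign$site,
                 is_stim = is_stim, activated = assign$activated,
                 capture = capture, ltp_class = cls,
                 tagging_like = tagging,
                 recruited_time_min = recruited_time,
                 plateau_pct = plateau)
}

synth_waveforms <- function(amp_noisy, grid, timeline, sweep_times,
                            sample_rate_khz, sweep_ms, waveform_noise_uV,
                            is_stim, stim_onset_ms = 5, artifact_ms = 2,
                            fepsp_onset_ms = 8, tau_rise = 1,
                            tau_decay = 5) {
  n_samp <- round(sweep_ms * sample_rate_khz)
  t_ms <- (seq_len(n_samp) - 1L) / sample_rate_khz
  u <- pmax(0, t_ms - fepsp_onset_ms)
  shape <- exp(-u / tau_decay) - exp(-u / tau_rise)
  shape[t_ms < fepsp_onset_ms] <- 0
  template <- -shape / max(shape) # peak normalised to -1
  artifact <- numeric(n_samp)
  in_art <- t_ms >= stim_onset_ms & t_ms < stim_onset_ms + artifact_ms
  artifact[in_art] <- 30 * rep_len(c(1, -1), sum(in_art))
  n_chan <- nrow(amp_noisy)
  n_sweep <- ncol(amp_noisy)
  amp_flat <- amp_noisy
  amp_flat[is_stim, ] <- 0
  arr <- array(0, dim = c(n_chan, n_sweep, n_samp))
  for (s in seq_len(n_samp)) {
    arr[, , s] <- amp_flat * template[s] + artifact[s]
  }
  arr <- arr + array(rnorm(length(arr), sd = waveform_noise_uV), dim(arr))
  med64_recording(grid = grid, timeline = timeline, sweeps = arr,
                  sweep_times = sweep_times,
                  sample_rate_khz = sample_rate_khz,
                  sweep_interval_min = 2, stim_onset_ms = stim_onset_ms,
                  artifact_ms = artifact_ms)
}

#' Simulate a group of slices and summarise it
#'
#' Independent slices with slice-level plateau draws, each pushed through
#' the analysis pipeline ([slope_pipeline()] then [classify_channels()]),
#' with the group summary holding the mean and SEM of the final-30-min
#' normalised slope at each site and of the per-slice tagging induction
#' ratio.
#'
#' @inheritParams simulate_slice
#' @param n_slices Number of slices (>= 1).
#' @param ... Passed on to [simulate_slice()].
#' @return A list of class `med64_sim_group`: `slices` (list of
#'   `med64_sim`), `classifications` (list of tibbles), `summary`
#'   (one-row tibble with `s1_last30_mean/sem`, `s2_last30_mean/sem`,
#'   `tagging_ratio_mean/sem`, `n_slices`), and `per_slice` (tibble).
#' @export
simulate_group <- function(preset, n_slices = 5L, seed = 1L,
                           grid = electrode_grid(),
                           timeline = tagging_protocol(grid),
                           output = c("slopes", "recording"),
                           amp_threshold = 10, ...) {
  output <- match.arg(output)
  stopifnot(n_slices >= 1L)
  slice_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(.Machine$integer.max,
                                             n_slices))
  slices <- lapply(slice_seeds, function(s) {
    simulate_slice(preset, grid = grid, timeline = timeline, seed = s,
                   output = output, amp_threshold = amp_threshold, ...)
  })
  normed <- lapply(slices, function(sl) {
    x <- if (output == "recording") sl$recording else sl$slopes
    slope_pipeline(x, timeline = timeline)
  })
  cls <- lapply(normed, function(ns) {
    classify_channels(ns, timeline, grid, amp_threshold = amp_threshold)
  })
  per_slice <- dplyr::bind_rows(lapply(seq_len(n_slices), function(i) {
    cc <- cls[[i]]
    s1_ch <- cc$channel[cc$site == "S1" & cc$activated]
    s2_ch <- cc$channel[cc$site == "S2" & cc$activated]
    ns <- normed[[i]]
    w <- function(ch) {
      x <- ns$normalized[ns$channel %in% ch &
                           ns$time_min >= timeline$recording_end - 30]
      mean(x[is.finite(x)])
    }
    tibble::tibble(
      slice = i, seed = slice_seeds[i],
      s1_last30 = if (length(s1_ch)) w(s1_ch) else NA_real_,
      s2_last30 = if (length(s2_ch)) w(s2_ch) else NA_real_,
      tagging_ratio = tryCatch(tagging_induction_ratio(cc),
                               med64_ratio_error = function(e) NA_real_),
      n_activated = sum(cc$activated))
  }))
  msem <- function(x) {
    x <- x[is.finite(x)]
    c(mean(x), if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0)
  }
  s1 <- msem(per_slice$s1_last30)
  s2 <- msem(per_slice$s2_last30)
  tr <- msem(per_slice$tagging_ratio)
  structure(list(
    slices = slices, classifications = cls, normalized = normed,
    per_slice = per_slice,
    summary = tibble::tibble(
      s1_last30_mean = s1[1], s1_last30_sem = s1[2],
      s2_last30_mean = s2[1], s2_last30_sem = s2[2],
      tagging_ratio_mean = tr[1], tagging_ratio_sem = tr[2],
      n_slices = n_slices)),
    class = "med64_sim_group")
}

#' @export
print.med64_sim_group <- function(x, ...) {
  cat(sprintf("<med64_sim_group> %d slices\n", x$summary$n_slices))
  print(x$summary)
  invisible(x)
}

#' Write the canonical fixture suite
#'
#' Writes, under `out_dir`: per-preset slope-table fixtures
#' (`slices/<preset>_slice<i>.csv`, `n_slices` per preset), noise-free
#' editions (`noisefree/<preset>.csv`), one example raw recording in both
#' dialects (`recording/` container and `recording.csv`, at a reduced
#' waveform resolution to keep fixtures small), tiny 4x4-grid MAP
#' instances with their archived solutions (`mrf/instance<k>.json`), and
#' a `manifest.json` with ground-truth labels, seeds and MD5 hashes.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_slices Slices per preset.
#' @param presets Character vector of preset names.
#' @return The manifest, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, n_slices = 5L,
                               presets = c("adult", "middle_aged",
                                           "middle_aged_BDNF",
                                           "middle_aged_R13")) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create '%s'", out_dir),
                   class = "med64_io_error")
  }
  for (d in c("slices", "noisefree", "mrf")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  grid <- electrode_grid()
  timeline <- tagging_protocol(grid)
  manifest <- list(seed = as.integer(seed), slices = list(),
                   noisefree = list(), mrf = list())
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max,
                                       length(presets) * n_slices + 10))
  k <- 0L
  for (p in presets) {
    for (i in seq_len(n_slices)) {
      k <- k + 1L
      sl <- simulate_slice(sim_preset(p), grid, timeline, seed = seeds[k])
      f <- file.path("slices", sprintf("%s_slice%d.csv", p, i))
      write_slope_table(dplyr::select(sl$slopes, -"no_response"),
                        file.path(out_dir, f))
      manifest$slices[[length(manifest$slices) + 1L]] <- list(
        file = f, preset = p, slice = i, seed = seeds[k],
        truth = sl$truth)
    }
  }
  for (p in presets) {
    k <- k + 1L
    sl <- simulate_slice(sim_preset(p, channel_sigma = 0, slice_sigma = 0),
                         grid, timeline, seed = seeds[k])
    f <- file.path("noisefree", paste0(p, ".csv"))
    write_slope_table(dplyr::select(sl$slopes, -"no_response"),
                      file.path(out_dir, f))
    manifest$noisefree[[length(manifest$noisefree) + 1L]] <- list(
      file = f, preset = p, seed = seeds[k], truth = sl$truth)
  }
  # example raw recording, both dialects, reduced resolution
  k <- k + 1L
  rec_sim <- simulate_slice(sim_preset("adult"), grid, timeline,
                            seed = seeds[k], output = "recording",
                            sample_rate_khz = 2, sweep_ms = 25)
  write_recording(rec_sim$recording, file.path(out_dir, "recording"),
                  format = "container")
  write_recording(rec_sim$recording, file.path(out_dir, "recording.csv"),
                  format = "csv")
  manifest$recording <- list(container = "recording",
                             csv = "recording.csv", seed = seeds[k])
  # tiny MAP instances with archived solutions
  for (j in 1:3) {
    k <- k + 1L
    obs <- withr::with_seed(seeds[k],
                            matrix(rnorm(16, 100, 20), 4, 4))
    pr <- mrf_problem(obs, N = 12)
    sol <- solve_map_spatial(pr)
    f <- file.path("mrf", sprintf("instance%d.json", j))
    jsonlite::write_json(
      list(obs = obs, N = 12, alpha = pr$alpha, beta = pr$beta,
           kernel_scale = pr$kernel_scale, ridge = pr$ridge,
           seed = seeds[k], solution = sol$values,
           objective = sol$objective),
      file.path(out_dir, f), digits = NA, auto_unbox = TRUE,
      matrix = "rowmajor")
    manifest$mrf[[length(manifest$mrf) + 1L]] <- list(file = f,
                                                      seed = seeds[k])
  }
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest$hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
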