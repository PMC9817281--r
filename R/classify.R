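#' Detect channels activated at baseline
#'
#' A channel counts as activated when it shows a detectable fEPSP during
#' the baseline period: mean baseline amplitude at or above
#' `amp_threshold` (default 10 uV) and at least one responsive baseline
#' sweep. Stimulation channels are excluded (their trace is stimulus
#' artifact, not a field response).
#'
#' @param slopes Binned slope tibble (see [bin_slopes()]).
#' @param timeline An [experiment_timeline()].
#' @param amp_threshold Minimum mean baseline amplitude in uV.
#' @param exclude Channel indices to exclude (typically the stimulation
#'   channels).
#' @return A tibble with `channel`, `baseline_amp_uV` and `activated`.
#' @export
detect_activated <- function(slopes, timeline, amp_threshold = 10,
                             exclude = integer(0)) {
  has_flag <- "no_response" %in% names(slopes)
  out <- baseline_bin_filter(slopes, timeline) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      baseline_amp_uV = mean(.data$amplitude_uV),
      any_response = if (has_flag) any(!.data$no_response) else TRUE,
      .groups = "drop") |>
    dplyr::mutate(activated = .data$baseline_amp_uV >= amp_threshold &
                    .data$any_response &
                    !(.data$channel %in% exclude)) |>
    dplyr::select("channel", "baseline_amp_uV", "activated")
  out
}

#' Classify the LTP phase of one channel
#'
#' A window is "potentiated" when the mean normalised slope over it
#' reaches `pot_threshold` (default 120% of baseline, the conventional
#' field-potential cut-off). The channel is `L_LTP` when potentiation
#' persists through the final `late_window` minutes of the recording
#' (which must extend at least `min_post_min` past the conditioning
#' train, i.e. into the protein-synthesis-dependent late phase);
#' `E_LTP` when the 30-60 min post-train window is potentiated but the
#' final window is not; otherwise `non_LTP`.
#'
#' @param series Normalised binned slope tibble for a single channel
#'   (columns `time_min`, `normalized`).
#' @param timeline An [experiment_timeline()].
#' @param event_time Time (min) of the conditioning train the channel is
#'   referred to.
#' @param pot_threshold Potentiation threshold in % of baseline.
#' @param early_window Offsets (min) after the train bounding the early
#'   window, default `c(30, 60)`.
#' @param late_window Length (min) of the final window, default 30.
#' @param min_post_min Minimum recording extent past the train (default
#'   180 min) for the late phase to be assessable.
#' @return One of `"non_LTP"`, `"E_LTP"`, `"L_LTP"`.
#' @export
classify_ltp <- function(series, timeline, event_time,
                         pot_threshold = 120, early_window = c(30, 60),
                         late_window = 30, min_post_min = 180) {
  end <- timeline$recording_end
  if (end - event_time < min_post_min) {
    abort(sprintf(
      "recording extends only %g min past the train; %g min required to assess the late phase",
      end - event_time, min_post_min),
      class = "med64_classification_error")
  }
  win_mean <- function(lo, hi) {
    x <- series$normalized[series$time_min >= lo & series$time_min <= hi]
    if (!length(x)) NA_real_ else mean(x)
  }
  late <- win_mean(end - late_window, end)
  early <- win_mean(event_time + early_window[1], event_time + early_window[2])
  if (!is.na(late) && late >= pot_threshold) return("L_LTP")
  if (!is.na(early) && early >= pot_threshold) return("E_LTP")
  "non_LTP"
}

#' Tagging-like response flag
#'
#' A deep-layer (S2) channel is tagging-like when its weak train converts
#' to late-phase LTP inside the capture window: the channel class is
#' `L_LTP` and the tagging train followed the strong train by no more
#' than `max_interval` minutes (default 30 min, the protocol's design).
#'
#' @param s2_class LTP class of the channel (`"non_LTP"`, `"E_LTP"`,
#'   `"L_LTP"`).
#' @param timeline An [experiment_timeline()] containing both a
#'   `strong_TBS` and a `tagging_TBS` event.
#' @param max_interval Maximum strong-to-tagging interval in minutes.
#' @return Logical flag.
#' @export
tag_tagging_like <- function(s2_class, timeline, max_interval = 30) {
  t_strong <- event_time(timeline, "strong_TBS")
  t_tag <- event_time(timeline, "tagging_TBS")
  if (is.na(t_strong) || is.na(t_tag)) {
    abort("timeline lacks strong_TBS and/or tagging_TBS events; tagging flag undefined",
          class = "med64_classification_error")
  }
  interval <- t_tag - t_strong
  identical(s2_class, "L_LTP") && interval > 0 && interval <= max_interval
}

site_event_table <- function(timeline, grid) {
  ev <- dplyr::filter(timeline$events, .data$kind %in% tbs_kinds)
  if (!nrow(ev)) {
    abort("timeline contains no TBS events; channels cannot be classified",
          class = "med64_classification_error")
  }
  roles <- tibble::tibble(site = names(grid$stim_channels),
                          stim_channel = as.integer(grid$stim_channels))
  dplyr::inner_join(roles, ev, by = c(stim_channel = "site")) |>
    dplyr::group_by(.data$site) |>
    dplyr::slice_min(.data$time_min, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
}

assign_sites <- function(grid, site_events) {
  cc <- channel_coords(grid)
  stim <- dplyr::inner_join(
    site_events,
    dplyr::select(cc, "channel", "x_um", "y_um"),
    by = c(stim_channel = "channel"))
  d2 <- outer(cc$x_um, stim$x_um, `-`)^2 + outer(cc$y_um, stim$y_um, `-`)^2
  nearest <- apply(d2, 1L, which.min)
  tibble::tibble(channel = cc$channel,
                 site = stim$site[nearest],
                 event_time = stim$time_min[nearest],
                 event_kind = stim$kind[nearest])
}

#' Classify every channel of a slice
#'
#' Orchestrates the per-channel analysis: baseline activation, site
#' assignment (each channel is referred to the nearest stimulation site
#' that received a train), LTP phase relative to that site's train,
#' tagging-like flag for S2 channels when the timeline holds a tagging
#' protocol, recruitment time for channels silent at baseline, and the
#' final-30-min mean.
#'
#' @param slopes Normalised binned slope tibble for the slice.
#' @param timeline An [experiment_timeline()].
#' @param grid An [electrode_grid()].
#' @param amp_threshold Activation/recruitment amplitude threshold (uV).
#' @param pot_threshold Potentiation threshold (% of baseline).
#' @param max_interval Tagging capture window (min).
#' @param early_window,late_window,min_post_min See [classify_ltp()].
#' @return A tibble with one row per non-stimulation channel: `channel`,
#'   `site`, `activated`, `recruited_time_min`, `ltp_class`,
#'   `tagging_like`, `last30_pct`.
#' @export
classify_channels <- function(slopes, timeline, grid, amp_threshold = 10,
                              pot_threshold = 120, max_interval = 30,
                              early_window = c(30, 60), late_window = 30,
                              min_post_min = 180) {
  stim <- as.integer(grid$stim_channels)
  site_events <- site_event_table(timeline, grid)
  sites <- assign_sites(grid, site_events)
  act <- detect_activated(slopes, timeline, amp_threshold, exclude = stim)
  end <- timeline$recording_end
  too_short <- end - site_events$time_min < min_post_min
  if (any(too_short)) {
    abort(sprintf(
      "recording extends only %g min past the %s train; %g min required to assess the late phase",
      min(end - site_events$time_min[too_short]),
      site_events$site[too_short][1L], min_post_min),
      class = "med64_classification_error")
  }
  has_tagging <- !is.na(event_time(timeline, "strong_TBS")) &&
    !is.na(event_time(timeline, "tagging_TBS"))
  chans <- setdiff(sort(unique(slopes$channel)), stim)
  info <- sites[match(chans, sites$channel), ]
  a <- act$activated[match(chans, act$channel)]
  # windowed means of the normalised slope, vectorised over channels
  win_mean <- function(lo_by_ch, hi_by_ch) {
    idx <- match(slopes$channel, chans)
    lo <- lo_by_ch[idx]
    hi <- hi_by_ch[idx]
    inw <- !is.na(idx) & !is.na(lo) & slopes$time_min >= lo &
      slopes$time_min <= hi & is.finite(slopes$normalized)
    sums <- rowsum(cbind(1, slopes$normalized[inw]),
                   slopes$channel[inw])
    out <- rep(NA_real_, length(chans))
    hit <- match(as.integer(rownames(sums)), chans)
    out[hit[!is.na(hit)]] <- (sums[, 2] / sums[, 1])[!is.na(hit)]
    out
  }
  late_mean <- win_mean(rep(end - late_window, length(chans)),
                        rep(end, length(chans)))
  early_mean <- win_mean(info$event_time + early_window[1],
                         info$event_time + early_window[2])
  cls <- dplyr::case_when(
    !a ~ NA_character_,
    !is.na(late_mean) & late_mean >= pot_threshold ~ "L_LTP",
    !is.na(early_mean) & early_mean >= pot_threshold ~ "E_LTP",
    TRUE ~ "non_LTP")
  tagging <- rep(FALSE, length(chans))
  if (has_tagging) {
    t_strong <- event_time(timeline, "strong_TBS")
    t_tag <- event_time(timeline, "tagging_TBS")
    interval_ok <- (t_tag - t_strong) > 0 &&
      (t_tag - t_strong) <= max_interval
    tagging <- !is.na(cls) & cls == "L_LTP" & info$site == "S2" &
      interval_ok
  }
  # recruitment time of channels silent at baseline
  recruited <- rep(NA_real_, length(chans))
  ev_by_row <- info$event_time[match(slopes$channel, chans)]
  cand <- !is.na(ev_by_row) & slopes$time_min > ev_by_row &
    slopes$amplitude_uV >= amp_threshold &
    slopes$channel %in% chans[!a]
  if (any(cand)) {
    first_hit <- tapply(slopes$time_min[cand], slopes$channel[cand], min)
    hit <- match(as.integer(names(first_hit)), chans)
    recruited[hit] <- as.numeric(first_hit)
  }
  tibble::tibble(channel = chans, site = info$site, activated = a,
                 recruited_time_min = recruited, ltp_class = cls,
                 tagging_like = tagging,
                 last30_pct = ifelse(a, late_mean, NA_real_))
}

#' Late-LTP channel ratio
#'
#' Percentage of activated channels whose class is `L_LTP`.
#'
#' @param counts Named numeric vector of per-class channel counts with
#'   names among `non_LTP`, `E_LTP`, `L_LTP`; the activated total is
#'   their sum.
#' @return Percentage in `[0, 100]`.
#' @examples
#' l_ltp_ratio(c(E_LTP = 21, L_LTP = 54, non_LTP = 24)) # 54.55
#' @export
l_ltp_ratio <- function(counts) {
  bad <- setdiff(names(counts), c("non_LTP", "E_LTP", "L_LTP"))
  if (length(bad)) {
    abort(paste0("unknown class names: ", paste(bad, collapse = ", ")),
          class = "med64_input_error")
  }
  total <- sum(counts)
  if (total <= 0) {
    abort("no activated channels; ratio undefined",
          class = "med64_ratio_error")
  }
  l <- if ("L_LTP" %in% names(counts)) counts[["L_LTP"]] else 0
  100 * l / total
}

#' Tagging induction ratio of one slice
#'
#' Percentage of baseline-activated S2 channels showing a tagging-like
#' late LTP.
#'
#' @param classification Output of [classify_channels()].
#' @return Percentage in `[0, 100]`.
#' @export
tagging_induction_ratio <- function(classification) {
  s2 <- dplyr::filter(classification, .data$site == "S2", .data$activated)
  if (nrow(s2) == 0L) {
    abort("no activated S2 channels; tagging induction ratio undefined",
          class = "med64_ratio_error")
  }
  100 * sum(s2$tagging_like) / nrow(s2)
}

#' Cumulative recruitment time course
#'
#' A channel silent at baseline is recruited at hour `h` when its
#' amplitude reaches `amp_threshold` in any bin up to `h` hours after its
#' site's train, so counts are cumulative and non-decreasing in `h`. Also
#' reports the mean amplitude of the recruited channels over the bins of
#' each hour.
#'
#' @param slopes Binned slope tibble for the slice.
#' @param timeline An [experiment_timeline()].
#' @param grid An [electrode_grid()].
#' @param amp_threshold Recruitment amplitude threshold (uV).
#' @param hours Hours after the train at which to report counts.
#' @return A tibble with one row per (site, hour): `site`, `hour`,
#'   `recruited_count`, `mean_amp_uV`.
#' @export
recruitment_timecourse <- function(slopes, timeline, grid,
                                   amp_threshold = 10, hours = 1:5) {
  stim <- as.integer(grid$stim_channels)
  site_events <- site_event_table(timeline, grid)
  sites <- assign_sites(grid, site_events)
  act <- detect_activated(slopes, timeline, amp_threshold, exclude = stim)
  silent <- act$channel[!act$activated]
  silent <- setdiff(silent, stim)
  out <- lapply(seq_len(nrow(site_events)), function(i) {
    se <- site_events[i, ]
    ch_here <- sites$channel[sites$site == se$site]
    cand <- intersect(silent, ch_here)
    sub <- dplyr::filter(slopes, .data$channel %in% cand,
                         .data$time_min > se$time_min)
    dplyr::bind_rows(lapply(hours, function(h) {
      upto <- dplyr::filter(sub, .data$time_min <= se$time_min + 60 * h)
      rec_ch <- unique(upto$channel[upto$amplitude_uV >= amp_threshold])
      in_hour <- dplyr::filter(
        sub, .data$channel %in% rec_ch,
        .data$time_min > se$time_min + 60 * (h - 1),
        .data$time_min <= se$time_min + 60 * h)
      tibble::tibble(site = se$site, hour = h,
                     recruited_count = length(rec_ch),
                     mean_amp_uV = if (nrow(in_hour))
                       mean(in_hour$amplitude_uV) else NA_real_)
    }))
  })
  dplyr::bind_rows(out)
}

#' Group summary of final-30-min normalised slopes
#'
#' For each slice, the mean normalised slope over the final 30 minutes of
#' the recording across the selected channels; then the group mean and
#' standard error across slices.
#'
#' @param slices List of normalised binned slope tibbles, one per slice.
#' @param timeline An [experiment_timeline()] shared by the slices.
#' @param channels Optional list (same length) of channel indices to
#'   average within each slice; `NULL` uses all channels with defined
#'   `normalized`.
#' @param window_min Length of the final window (min).
#' @return A one-row tibble: `mean_pct`, `sem_pct`, `n_slices`, with the
#'   per-slice means in attribute `"per_slice"`.
#' @export
last30_summary <- function(slices, timeline, channels = NULL,
                           window_min = 30) {
  end <- timeline$recording_end
  per_slice <- vapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    if (!is.null(channels)) {
      s <- dplyr::filter(s, .data$channel %in% channels[[i]])
    }
    x <- s$normalized[s$time_min >= end - window_min & s$time_min <= end]
    x <- x[is.finite(x)]
    if (!length(x)) {
      abort(sprintf("slice %d has no bins in the final %g min", i,
                    window_min), class = "med64_input_error")
    }
    mean(x)
  }, numeric(1))
  n <- length(per_slice)
  out <- tibble::tibble(
    mean_pct = mean(per_slice),
    sem_pct = if (n > 1L) sd(per_slice) / sqrt(n) else 0,
    n_slices = n)
  attr(out, "per_slice") <- per_slice
  out
}

#' Two-group comparison (Student's t-test)
#'
#' Two-sample t-test with pooled variance by default (Welch via
#' `var_equal = FALSE`), two-sided. When both groups are constant and
#' equal, the comparison is degenerate: `t = 0`, `p = 1`, flagged.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (Student's test) or not (Welch).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `method`, `degenerate`.
#' @export
group_compare <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs at least 2 values",
          class = "med64_input_error")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    equal <- mean(group_a) == mean(group_b)
    return(tibble::tibble(
      statistic = if (equal) 0 else Inf * sign(mean(group_a) - mean(group_b)),
      df = length(group_a) + length(group_b) - 2,
      p_value = if (equal) 1 else 0,
      mean_a = mean(group_a), mean_b = mean(group_b),
      method = if (var_equal) "student" else "welch",
      degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 method = if (var_equal) "student" else "welch",
                 degenerate = FALSE)
}

#' Per-slice summary
#'
#' Aggregates a slice's classification into the quantities reported per
#' group: class counts by site, tagging induction ratio, late-LTP ratio,
#' cumulative recruitment counts, and pre/post activation hull areas.
#'
#' @param classification Output of [classify_channels()].
#' @param slopes Normalised binned slope tibble of the slice.
#' @param timeline An [experiment_timeline()].
#' @param grid An [electrode_grid()].
#' @param amp_threshold Activation amplitude threshold (uV).
#' @param hours Hours at which recruitment is counted.
#' @return A list of class `slice_summary`: `class_counts` (tibble),
#'   `tagging_induction_ratio`, `l_ltp_ratio`, `recruitment` (tibble),
#'   `hull_pre`, `hull_post` (see [activation_hull()]).
#' @export
slice_summary <- function(classification, slopes, timeline, grid,
                          amp_threshold = 10, hours = 1:5) {
  act <- dplyr::filter(classification, .data$activated)
  counts <- act |>
    dplyr::count(.data$site, .data$ltp_class, name = "n")
  cls_counts <- act |> dplyr::count(.data$ltp_class, name = "n")
  cvec <- setNames(cls_counts$n, cls_counts$ltp_class)
  tir <- tryCatch(tagging_induction_ratio(classification),
                  med64_ratio_error = function(e) NA_real_)
  llr <- tryCatch(l_ltp_ratio(cvec),
                  med64_ratio_error = function(e) NA_real_)
  recruit <- tryCatch(
    recruitment_timecourse(slopes, timeline, grid, amp_threshold, hours),
    med64_classification_error = function(e) NULL)
  pre_ch <- act$channel
  recruited_ch <- classification$channel[
    !is.na(classification$recruited_time_min)]
  hull_pre <- if (length(pre_ch))
    activation_hull(pre_ch, grid) else NULL
  hull_post <- if (length(c(pre_ch, recruited_ch)))
    activation_hull(unique(c(pre_ch, recruited_ch)), grid) else NULL
  structure(list(class_counts = counts,
                 tagging_induction_ratio = tir, l_ltp_ratio = llr,
                 recruitment = recruit,
                 hull_pre = hull_pre, hull_post = hull_post),
            class = "slice_summary")
}

#' @export
print.slice_summary <- function(x, ...) {
  cat("<slice_summary>\n")
  cat(sprintf("  tagging induction ratio: %s\n",
              format(x$tagging_induction_ratio)))
  cat(sprintf("  L-LTP ratio: %s\n", format(x$l_ltp_ratio)))
  if (!is.null(x$hull_pre) && !is.null(x$hull_post)) {
    cat(sprintf("  hull area pre %g um^2, post %g um^2\n",
                x$hull_pre$area_um2, x$hull_post$area_um2))
  }
  invisible(x)
}
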