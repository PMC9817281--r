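#' Experiment timeline
#'
#' Records the temporal design of a slice experiment on a common clock in
#' minutes from the start of the baseline period: the baseline window used
#' for normalisation and stability gating, the stimulation events, and the
#' end of the recording.
#'
#' @param baseline_start,baseline_end Baseline window in minutes (default
#'   0-60: a stable hour of baseline before any conditioning train).
#' @param events A tibble with columns `time_min`, `kind` (one of
#'   `strong_TBS`, `tagging_TBS`, `weak_TBS`, `drug_on`, `drug_off`) and
#'   `site` (stimulated channel index, `NA` for drug events).
#' @param recording_end End of the recording in minutes.
#' @return An object of class `experiment_timeline`.
#' @seealso [tagging_protocol()], [weak_tbs_protocol()]
#' @export
experiment_timeline <- function(baseline_start = 0, baseline_end = 60,
                                events = tibble::tibble(
                                  time_min = numeric(), kind = character(),
                                  site = integer()),
                                recording_end = 330) {
  tl <- structure(
    list(baseline_start = as.numeric(baseline_start),
         baseline_end = as.numeric(baseline_end),
         events = tibble::as_tibble(events),
         recording_end = as.numeric(recording_end)),
    class = "experiment_timeline"
  )
  viol <- validate_timeline(tl)
  if (nrow(viol) > 0L) {
    abort(paste0("invalid experiment_timeline: ",
                 paste(viol$rule, collapse = "; ")),
          class = "med64_validation_error")
  }
  tl
}

tbs_kinds <- c("strong_TBS", "tagging_TBS", "weak_TBS")
event_kinds <- c(tbs_kinds, "drug_on", "drug_off")

validate_timeline <- function(tl) {
  v <- list()
  note <- function(field, rule) tibble::tibble(field = field, rule = rule)
  if (tl$baseline_end < tl$baseline_start) {
    v[[length(v) + 1L]] <- note("baseline_end",
                                "baseline_end must be >= baseline_start")
  }
  ev <- tl$events
  if (nrow(ev)) {
    if (is.unsorted(ev$time_min, strictly = TRUE)) {
      v[[length(v) + 1L]] <- note("events",
                                  "event times must be strictly increasing")
    }
    if (!all(ev$kind %in% event_kinds)) {
      v[[length(v) + 1L]] <- note(
        "events", paste0("event kind must be one of ",
                         paste(event_kinds, collapse = ", ")))
    }
    if (any(ev$time_min < tl$baseline_start | ev$time_min > tl$recording_end)) {
      v[[length(v) + 1L]] <- note(
        "events", "event times must lie within [baseline_start, recording_end]")
    }
  }
  if (tl$recording_end < tl$baseline_end) {
    v[[length(v) + 1L]] <- note("recording_end",
                                "recording_end must be >= baseline_end")
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(field = character(), rule = character())
}

#' @export
print.experiment_timeline <- function(x, ...) {
  cat(sprintf("<experiment_timeline> baseline %g-%g min, end %g min\n",
              x$baseline_start, x$baseline_end, x$recording_end))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Standard synaptic-tagging protocol timeline
#'
#' One hour of stable baseline, a strong theta-burst train (4 pulses x 5
#' bursts x 5 trains) at the superficial-layer site S1 at 60 min, a weak
#' tagging train (4 x 5 x 1) at the deep-layer site S2 thirty minutes later,
#' and 4 h of follow-up after the tagging train (4.5 h after the strong
#' train).
#'
#' @param grid An [electrode_grid()] whose `stim_channels` carry the `S1`
#'   and `S2` roles.
#' @param strong_at,tagging_at Event times in minutes.
#' @param recording_end End of recording in minutes.
#' @export
tagging_protocol <- function(grid = electrode_grid(), strong_at = 60,
                             tagging_at = 90, recording_end = 330) {
  experiment_timeline(
    baseline_start = 0, baseline_end = strong_at,
    events = tibble::tibble(
      time_min = c(strong_at, tagging_at),
      kind = c("strong_TBS", "tagging_TBS"),
      site = as.integer(c(grid$stim_channels[["S1"]],
                          grid$stim_channels[["S2"]]))),
    recording_end = recording_end)
}

#' Weak-TBS-only protocol timeline
#'
#' One hour of baseline followed by a single weak theta-burst train
#' (4 x 5 x 1) at the deep-layer site, with no preceding strong train.
#'
#' @inheritParams tagging_protocol
#' @param weak_at Time of the weak train in minutes.
#' @export
weak_tbs_protocol <- function(grid = electrode_grid(), weak_at = 60,
                              recording_end = 330) {
  experiment_timeline(
    baseline_start = 0, baseline_end = weak_at,
    events = tibble::tibble(
      time_min = weak_at, kind = "weak_TBS",
      site = as.integer(grid$stim_channels[["S2"]])),
    recording_end = recording_end)
}

#' Time of the first event of a given kind, NA if absent
#' @noRd
event_time <- function(timeline, kind) {
  ev <- timeline$events
  t <- ev$time_min[ev$kind == kind]
  if (length(t)) t[[1L]] else NA_real_
}

#' Theta-burst stimulation protocol descriptor
#'
#' Purely descriptive record of a TBS train: bursts of 100 Hz pulses
#' delivered at 5 bursts per train (200 ms inter-burst interval), with the
#' strong protocol repeating the train five times at 10 s intervals
#' (4 x 5 x 5) and the weak/tagging protocol delivering a single train
#' (4 x 5 x 1).
#'
#' @param pulses_per_burst,bursts_per_train,trains Train structure counts.
#' @param intra_burst_hz Within-burst pulse rate in Hz.
#' @param burst_interval_ms Between-burst interval in ms.
#' @param train_interval_s Between-train interval in s.
#' @export
tbs_protocol <- function(pulses_per_burst = 4L, bursts_per_train = 5L,
                         trains = 5L, intra_burst_hz = 100,
                         burst_interval_ms = 200, train_interval_s = 10) {
  stopifnot(pulses_per_burst >= 1, bursts_per_train >= 1, trains >= 1)
  structure(list(pulses_per_burst = as.integer(pulses_per_burst),
                 bursts_per_train = as.integer(bursts_per_train),
                 trains = as.integer(trains),
                 intra_burst_hz = intra_burst_hz,
                 burst_interval_ms = burst_interval_ms,
                 train_interval_s = train_interval_s),
            class = "tbs_protocol")
}

#' @rdname tbs_protocol
#' @export
strong_tbs <- function() tbs_protocol(trains = 5L)

#' @rdname tbs_protocol
#' @export
weak_tbs <- function() tbs_protocol(trains = 1L)
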