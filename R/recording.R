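#' Raw multi-channel field-potential recording
#'
#' Container for per-channel raw sweeps: a 3-D voltage array indexed by
#' (channel, sweep, sample) in microvolts, with the electrode geometry, the
#' experiment timeline, the sweep clock in minutes and the waveform sample
#' clock in samples per millisecond. Each sweep is one evoked response to a
#' test pulse; the stimulus is delivered `stim_onset_ms` into the sweep and
#' the first `artifact_ms` after it are masked as stimulus artifact when
#' extracting slopes.
#'
#' @param grid An [electrode_grid()].
#' @param timeline An [experiment_timeline()].
#' @param sweeps Numeric array `channel x sweep x sample`, in uV.
#' @param sweep_times Numeric vector of sweep times in minutes (ascending,
#'   one per sweep; the usual cadence is one test response every 2 min).
#' @param sample_rate_khz Samples per millisecond of the waveform clock.
#' @param sweep_interval_min Declared cadence between sweeps in minutes.
#' @param stim_onset_ms Time of the test stimulus within a sweep, in ms.
#' @param artifact_ms Duration masked after stimulus onset, in ms.
#' @param meta Optional named list of free-form metadata.
#' @return An object of class `med64_recording`.
#' @export
med64_recording <- function(grid, timeline, sweeps, sweep_times,
                            sample_rate_khz = 10, sweep_interval_min = 2,
                            stim_onset_ms = 5, artifact_ms = 2,
                            meta = list()) {
  rec <- structure(
    list(grid = grid, timeline = timeline, sweeps = sweeps,
         sweep_times = as.numeric(sweep_times),
         sample_rate_khz = as.numeric(sample_rate_khz),
         sweep_interval_min = as.numeric(sweep_interval_min),
         stim_onset_ms = as.numeric(stim_onset_ms),
         artifact_ms = as.numeric(artifact_ms),
         meta = meta),
    class = "med64_recording"
  )
  rec
}

#' Validate a recording against the container invariants
#'
#' Checks every structural invariant of the data model (grid geometry,
#' timeline ordering, sweep array shape, sweep clock monotonicity and
#' cadence, positive sample rate) and reports violations instead of
#' raising, one row per violated rule.
#'
#' @param rec A [med64_recording()].
#' @return A tibble with columns `field` and `rule`; zero rows iff the
#'   recording is valid.
#' @export
validate_recording <- function(rec) {
  v <- list(validate_grid(rec$grid), validate_timeline(rec$timeline))
  note <- function(field, rule) tibble::tibble(field = field, rule = rule)
  n_chan <- rec$grid$rows * rec$grid$cols
  dims <- dim(rec$sweeps)
  if (is.null(dims) || length(dims) != 3L) {
    v[[length(v) + 1L]] <- note("sweeps",
                                "sweeps must be a 3-D array (channel, sweep, sample)")
  } else {
    if (dims[[1L]] != n_chan) {
      v[[length(v) + 1L]] <- note(
        "sweeps", sprintf("sweeps has %d channels but grid declares %d",
                          dims[[1L]], n_chan))
    }
    if (dims[[2L]] != length(rec$sweep_times)) {
      v[[length(v) + 1L]] <- note(
        "sweep_times", "length of sweep_times must equal the sweep count")
    }
  }
  if (length(rec$sweep_times) > 1L) {
    if (is.unsorted(rec$sweep_times, strictly = TRUE)) {
      v[[length(v) + 1L]] <- note("sweep_times",
                                  "sweep_times must be strictly increasing")
    } else {
      gaps <- diff(rec$sweep_times)
      if (any(abs(gaps - rec$sweep_interval_min) > 1e-8)) {
        v[[length(v) + 1L]] <- note(
          "sweep_times",
          sprintf("sweep spacing must equal the declared cadence (%g min)",
                  rec$sweep_interval_min))
      }
    }
  }
  if (!is.numeric(rec$sample_rate_khz) || rec$sample_rate_khz <= 0) {
    v[[length(v) + 1L]] <- note("sample_rate_khz", "sample_rate must be > 0")
  }
  if (rec$artifact_ms < 0) {
    v[[length(v) + 1L]] <- note("artifact_ms", "artifact mask must be >= 0")
  }
  out <- dplyr::bind_rows(v)
  if (nrow(out)) out else tibble::tibble(field = character(),
                                         rule = character())
}

#' @export
print.med64_recording <- function(x, ...) {
  dims <- dim(x$sweeps)
  cat(sprintf(
    "<med64_recording> %d channels, %d sweeps x %d samples @ %g kHz\n",
    dims[[1L]], dims[[2L]], dims[[3L]], x$sample_rate_khz))
  cat(sprintf("  sweeps every %g min, %g-%g min\n", x$sweep_interval_min,
              min(x$sweep_times), max(x$sweep_times)))
  invisible(x)
}

stop_if_invalid <- function(rec) {
  viol <- validate_recording(rec)
  if (nrow(viol) > 0L) {
    abort(paste0("invalid recording: ",
                 paste(unique(viol$rule), collapse = "; ")),
          class = "med64_validation_error")
  }
  invisible(rec)
}
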