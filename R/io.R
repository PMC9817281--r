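#' Read and write recordings
#'
#' Two open on-disk dialects are supported, both plain text and both
#' lossless for the numeric fields at double precision:
#'
#' * `"container"` — a directory bundle with `geometry.json`,
#'   `timeline.json`, `meta.json`, `sweep_times.csv` and a wide
#'   `waveforms.csv` (one row per channel x sweep, one column per sample).
#' * `"csv"` — a single long-format CSV
#'   (`channel,sweep,time_min,sample,value_uV`) whose geometry, timeline and
#'   acquisition metadata are carried in `#`-comment JSON header lines.
#'
#' Channel labels in both dialects are the package's 1-based row-major
#' channel numbers.
#'
#' @param rec A [med64_recording()].
#' @param path Directory path (`container`) or file path (`csv`).
#' @param format One of `"container"`, `"csv"`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a validated [med64_recording()].
#' @name recording_io
NULL

grid_to_list <- function(grid) {
  list(rows = grid$rows, cols = grid$cols, pitch_um = grid$pitch_um,
       electrode_um = grid$electrode_um,
       stim_roles = as.list(setNames(as.integer(grid$stim_channels),
                                     names(grid$stim_channels))))
}

grid_from_list <- function(x) {
  electrode_grid(rows = x$rows, cols = x$cols, pitch_um = x$pitch_um,
                 electrode_um = x$electrode_um,
                 stim_channels = unlist(x$stim_roles))
}

timeline_to_list <- function(tl) {
  list(baseline_start = tl$baseline_start, baseline_end = tl$baseline_end,
       recording_end = tl$recording_end,
       events = lapply(seq_len(nrow(tl$events)), function(i) {
         as.list(tl$events[i, ])
       }))
}

timeline_from_list <- function(x) {
  ev <- if (length(x$events)) {
    dplyr::bind_rows(lapply(x$events, function(e) {
      tibble::tibble(time_min = as.numeric(e$time_min),
                     kind = as.character(e$kind),
                     site = as.integer(e$site %||% NA_integer_))
    }))
  } else {
    tibble::tibble(time_min = numeric(), kind = character(), site = integer())
  }
  experiment_timeline(baseline_start = x$baseline_start,
                      baseline_end = x$baseline_end, events = ev,
                      recording_end = x$recording_end)
}

rec_meta_list <- function(rec) {
  list(sample_rate_khz = rec$sample_rate_khz,
       sweep_interval_min = rec$sweep_interval_min,
       stim_onset_ms = rec$stim_onset_ms,
       artifact_mask_ms = rec$artifact_ms,
       extra = rec$meta)
}

#' @rdname recording_io
#' @export
write_recording <- function(rec, path, format = c("container", "csv")) {
  format <- match.arg(format)
  stop_if_invalid(rec)
  if (format == "container") {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) abort(sprintf("cannot create container directory '%s'", path),
                     class = "med64_io_error")
    }
    jsonlite::write_json(grid_to_list(rec$grid),
                         file.path(path, "geometry.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(timeline_to_list(rec$timeline),
                         file.path(path, "timeline.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(rec_meta_list(rec), file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(tibble::tibble(sweep = seq_along(rec$sweep_times),
                                    time_min = rec$sweep_times),
                     file.path(path, "sweep_times.csv"), progress = FALSE)
    d <- dim(rec$sweeps)
    flat <- matrix(rec$sweeps, nrow = d[[1L]] * d[[2L]], ncol = d[[3L]])
    wide <- tibble::as_tibble(as.data.frame(flat),
                              .name_repair = ~ sprintf("s%04d",
                                                       seq_len(d[[3L]])))
    wide <- dplyr::bind_cols(
      tibble::tibble(channel = rep(seq_len(d[[1L]]), times = d[[2L]]),
                     sweep = rep(seq_len(d[[2L]]), each = d[[1L]])),
      wide)
    readr::write_csv(wide, file.path(path, "waveforms.csv"),
                     progress = FALSE)
  } else {
    dir_ok <- dir.exists(dirname(path)) || dirname(path) == "."
    if (!dir_ok) abort(sprintf("directory of '%s' does not exist", path),
                       class = "med64_io_error")
    hdr <- c(
      "# med64_recording v1",
      paste0("# geometry: ", jsonlite::toJSON(grid_to_list(rec$grid),
                                              auto_unbox = TRUE, digits = NA)),
      paste0("# timeline: ", jsonlite::toJSON(timeline_to_list(rec$timeline),
                                              auto_unbox = TRUE, digits = NA)),
      paste0("# meta: ", jsonlite::toJSON(rec_meta_list(rec),
                                          auto_unbox = TRUE, digits = NA)))
    d <- dim(rec$sweeps)
    long <- tibble::tibble(
      channel = rep(seq_len(d[[1L]]), times = d[[2L]] * d[[3L]]),
      sweep = rep(rep(seq_len(d[[2L]]), each = d[[1L]]), times = d[[3L]]),
      time_min = rep(rep(rec$sweep_times, each = d[[1L]]), times = d[[3L]]),
      sample = rep(seq_len(d[[3L]]), each = d[[1L]] * d[[2L]]),
      value_uV = as.vector(rec$sweeps))
    con <- tryCatch(file(path, open = "wb"),
                    error = function(e) abort(
                      sprintf("cannot open '%s' for writing", path),
                      class = "med64_io_error"))
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    writeLines(hdr, con)
    readr::write_csv(long, con, progress = FALSE)
  }
  invisible(path)
}

parse_header_json <- function(lines, key) {
  pat <- paste0("^# ", key, ": ")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) {
    abort(sprintf("malformed recording file: missing '%s' header", key),
          class = "med64_format_error")
  }
  jsonlite::fromJSON(sub(pat, "", hit[[1L]]), simplifyVector = FALSE)
}

#' @rdname recording_io
#' @export
read_recording <- function(path, format = c("container", "csv")) {
  format <- match.arg(format)
  if (format == "container") {
    if (!dir.exists(path)) {
      abort(sprintf("container directory '%s' not found", path),
            class = "med64_io_error")
    }
    need <- c("geometry.json", "timeline.json", "meta.json",
              "sweep_times.csv", "waveforms.csv")
    missing <- need[!file.exists(file.path(path, need))]
    if (length(missing)) {
      abort(paste0("malformed container: missing ",
                   paste(missing, collapse = ", ")),
            class = "med64_format_error")
    }
    geom <- jsonlite::fromJSON(file.path(path, "geometry.json"),
                               simplifyVector = FALSE)
    tl <- jsonlite::fromJSON(file.path(path, "timeline.json"),
                             simplifyVector = FALSE)
    meta <- jsonlite::fromJSON(file.path(path, "meta.json"),
                               simplifyVector = FALSE)
    st <- readr::read_csv(file.path(path, "sweep_times.csv"),
                          col_types = readr::cols(
                            sweep = readr::col_integer(),
                            time_min = readr::col_double()),
                          progress = FALSE)
    wide <- readr::read_csv(file.path(path, "waveforms.csv"),
                            col_types = readr::cols(.default = "d"),
                            progress = FALSE)
    n_chan <- geom$rows * geom$cols
    n_sweep <- nrow(st)
    samp_cols <- grep("^s\\d+$", names(wide), value = TRUE)
    arr <- array(0, dim = c(n_chan, n_sweep, length(samp_cols)))
    flat <- as.matrix(wide[, samp_cols])
    idx <- cbind(rep(wide$channel, times = length(samp_cols)),
                 rep(wide$sweep, times = length(samp_cols)),
                 rep(seq_along(samp_cols), each = nrow(wide)))
    arr[idx] <- as.vector(flat)
    rec <- med64_recording(
      grid = grid_from_list(geom), timeline = timeline_from_list(tl),
      sweeps = arr, sweep_times = st$time_min,
      sample_rate_khz = meta$sample_rate_khz,
      sweep_interval_min = meta$sweep_interval_min,
      stim_onset_ms = meta$stim_onset_ms,
      artifact_ms = meta$artifact_mask_ms,
      meta = meta$extra %||% list())
  } else {
    if (!file.exists(path)) {
      abort(sprintf("file '%s' not found", path), class = "med64_io_error")
    }
    hdr <- readLines(path, n = 10L)
    geom <- parse_header_json(hdr, "geometry")
    tl <- parse_header_json(hdr, "timeline")
    meta <- parse_header_json(hdr, "meta")
    long <- readr::read_csv(path, comment = "#",
                            col_types = readr::cols(
                              channel = readr::col_integer(),
                              sweep = readr::col_integer(),
                              time_min = readr::col_double(),
                              sample = readr::col_integer(),
                              value_uV = readr::col_double()),
                            progress = FALSE)
    n_chan <- geom$rows * geom$cols
    n_sweep <- max(long$sweep)
    n_samp <- max(long$sample)
    arr <- array(0, dim = c(n_chan, n_sweep, n_samp))
    arr[cbind(long$channel, long$sweep, long$sample)] <- long$value_uV
    st <- dplyr::distinct(long, .data$sweep, .data$time_min)
    st <- dplyr::arrange(st, .data$sweep)
    rec <- med64_recording(
      grid = grid_from_list(geom), timeline = timeline_from_list(tl),
      sweeps = arr, sweep_times = st$time_min,
      sample_rate_khz = meta$sample_rate_khz,
      sweep_interval_min = meta$sweep_interval_min,
      stim_onset_ms = meta$stim_onset_ms,
      artifact_ms = meta$artifact_mask_ms,
      meta = meta$extra %||% list())
  }
  viol <- validate_recording(rec)
  if (nrow(viol) > 0L) {
    abort(paste0("recording fails validation: ",
                 paste(unique(viol$rule), collapse = "; ")),
          class = "med64_validation_error")
  }
  rec
}

#' Read and write slope tables
#'
#' The flat slope dialect shared by all downstream modules: one row per
#' (time bin, channel) with header `time_min,channel,slope_uV_per_ms,
#' amplitude_uV`, UTF-8, `.` decimal separator. Extra columns (e.g.
#' `normalized`) are preserved when present.
#'
#' @param slopes A tibble with at least the dialect columns.
#' @param path File path.
#' @return `read_slope_table()` returns a tibble sorted by time then
#'   channel.
#' @export
write_slope_table <- function(slopes, path) {
  need <- c("time_min", "channel", "slope_uV_per_ms", "amplitude_uV")
  missing <- setdiff(need, names(slopes))
  if (length(missing)) {
    abort(paste0("slope table lacks columns: ",
                 paste(missing, collapse = ", ")),
          class = "med64_format_error")
  }
  out <- dplyr::relocate(slopes, dplyr::all_of(need))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_slope_table
#' @export
read_slope_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' not found", path), class = "med64_io_error")
  }
  tb <- readr::read_csv(path, col_types = readr::cols(
    time_min = readr::col_double(), channel = readr::col_integer(),
    slope_uV_per_ms = readr::col_double(),
    amplitude_uV = readr::col_double(), .default = "d"), progress = FALSE)
  need <- c("time_min", "channel", "slope_uV_per_ms", "amplitude_uV")
  missing <- setdiff(need, names(tb))
  if (length(missing)) {
    abort(paste0("malformed slope table: missing ",
                 paste(missing, collapse = ", ")),
          class = "med64_format_error")
  }
  dplyr::arrange(tb, .data$time_min, .data$channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
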