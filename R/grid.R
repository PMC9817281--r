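#' Electrode grid geometry
#'
#' Describes the planar multi-electrode probe: an `rows` x `cols` lattice of
#' square electrodes (50 x 50 um on the MED64 probe) with centre-to-centre
#' pitch `pitch_um` (150 um on the MED64 probe). Channels are numbered 1 to
#' `rows * cols` in row-major order from the top-left corner of the probe, so
#' channel `k` sits at row `(k - 1) %/% cols + 1` and column
#' `(k - 1) %% cols + 1`; physical coordinates in um are
#' `(col - 1) * pitch_um` and `(row - 1) * pitch_um`.
#'
#' Stimulation channels are marked with a role: by convention `S1` is the
#' superficial-layer site that receives the strong theta-burst train and `S2`
#' the deep-layer site that receives the weak (tagging) train.
#'
#' @param rows,cols Lattice dimensions (default 8 x 8, i.e. 64 channels).
#' @param pitch_um Centre-to-centre electrode spacing in micrometres.
#' @param electrode_um Electrode side length in micrometres.
#' @param stim_channels Named integer vector of stimulation channels; names
#'   are the site roles (e.g. `c(S1 = 26, S2 = 46)`).
#' @return An object of class `electrode_grid`.
#' @examples
#' grid <- electrode_grid()
#' channel_coords(grid)
#' @export
electrode_grid <- function(rows = 8L, cols = 8L, pitch_um = 150,
                           electrode_um = 50,
                           stim_channels = c(S1 = 26L, S2 = 46L)) {
  g <- structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pitch_um = as.numeric(pitch_um),
         electrode_um = as.numeric(electrode_um),
         stim_channels = stim_channels),
    class = "electrode_grid"
  )
  viol <- validate_grid(g)
  if (nrow(viol) > 0L) {
    abort(paste0("invalid electrode_grid: ",
                 paste(viol$rule, collapse = "; ")),
          class = "med64_validation_error")
  }
  g
}

validate_grid <- function(grid) {
  v <- list()
  note <- function(field, rule) tibble::tibble(field = field, rule = rule)
  if (!is.numeric(grid$rows) || grid$rows < 1 || !is.numeric(grid$cols) ||
      grid$cols < 1) {
    v[[length(v) + 1L]] <- note("rows/cols", "rows and cols must be >= 1")
  }
  if (!is.numeric(grid$pitch_um) || grid$pitch_um <= 0) {
    v[[length(v) + 1L]] <- note("pitch_um", "pitch must be > 0")
  }
  n <- grid$rows * grid$cols
  sc <- grid$stim_channels
  if (length(sc)) {
    if (any(sc < 1 | sc > n)) {
      v[[length(v) + 1L]] <- note(
        "stim_channels",
        sprintf("stim channel indices must lie in 1..%d", n))
    }
    if (anyDuplicated(sc)) {
      v[[length(v) + 1L]] <- note("stim_channels",
                                  "stim channels must be distinct")
    }
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(field = character(), rule = character())
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d, pitch %g um, electrode %g um\n",
              x$rows, x$cols, x$pitch_um, x$electrode_um))
  if (length(x$stim_channels)) {
    cat("  stim:", paste(sprintf("%s=%d", names(x$stim_channels),
                                 x$stim_channels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Channel-to-coordinate table for a grid
#'
#' @param grid An [electrode_grid()].
#' @return A tibble with one row per channel: `channel`, `row`, `col`,
#'   `x_um`, `y_um`, `site` (stimulation role or `NA`).
#' @export
channel_coords <- function(grid) {
  n <- grid$rows * grid$cols
  k <- seq_len(n)
  row <- (k - 1L) %/% grid$cols + 1L
  col <- (k - 1L) %% grid$cols + 1L
  site <- rep(NA_character_, n)
  if (length(grid$stim_channels)) {
    site[grid$stim_channels] <- names(grid$stim_channels)
  }
  tibble::tibble(channel = k, row = row, col = col,
                 x_um = (col - 1L) * grid$pitch_um,
                 y_um = (row - 1L) * grid$pitch_um,
                 site = site)
}

#' Euclidean distance (um) from every channel to a reference channel
#' @noRd
channel_distances <- function(grid, ref_channel) {
  cc <- channel_coords(grid)
  ref <- cc[cc$channel == ref_channel, ]
  sqrt((cc$x_um - ref$x_um)^2 + (cc$y_um - ref$y_um)^2)
}
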