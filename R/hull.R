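#' Convex hull of an activated channel set
#'
#' The activation area of a slice is summarised by the convex hull of the
#' activated electrodes' physical coordinates. Vertices are returned in
#' counter-clockwise order; degenerate sets (a single channel or collinear
#' channels) have area 0.
#'
#' @param channels Integer vector of activated channel indices (>= 1
#'   channel).
#' @param grid An [electrode_grid()].
#' @return A list of class `activation_hull`: `vertices` (tibble with
#'   `channel`, `x_um`, `y_um` in counter-clockwise order), `area_um2`,
#'   and `channels` (the input set).
#' @examples
#' g <- electrode_grid()
#' activation_hull(c(1, 4, 25, 28), g)$area_um2 # 450 um square = 202500
#' @export
activation_hull <- function(channels, grid) {
  channels <- unique(as.integer(channels))
  if (length(channels) == 0L) {
    abort("empty channel set; hull undefined", class = "med64_hull_error")
  }
  cc <- channel_coords(grid)
  pts <- cc[match(channels, cc$channel), ]
  if (anyNA(pts$channel)) {
    abort("channel index outside the grid", class = "med64_hull_error")
  }
  if (nrow(pts) == 1L) {
    return(structure(list(
      vertices = tibble::tibble(channel = pts$channel, x_um = pts$x_um,
                                y_um = pts$y_um),
      area_um2 = 0, channels = channels), class = "activation_hull"))
  }
  idx <- grDevices::chull(pts$x_um, pts$y_um)
  verts <- pts[idx, ]
  area2 <- shoelace_2area(verts$x_um, verts$y_um)
  if (area2 < 0) { # enforce counter-clockwise orientation
    verts <- verts[rev(seq_len(nrow(verts))), ]
    area2 <- -area2
  }
  structure(list(
    vertices = tibble::tibble(channel = verts$channel, x_um = verts$x_um,
                              y_um = verts$y_um),
    area_um2 = area2 / 2, channels = channels),
    class = "activation_hull")
}

# signed doubled polygon area (positive when counter-clockwise)
shoelace_2area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y)
}

#' @export
print.activation_hull <- function(x, ...) {
  cat(sprintf("<activation_hull> %d channels, %d vertices, area %g um^2\n",
              length(x$channels), nrow(x$vertices), x$area_um2))
  invisible(x)
}
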