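#' Group slope time course figure
#'
#' Mean and SEM band of the baseline-normalised slope across the selected
#' channels, with the conditioning trains marked.
#'
#' @param slopes Normalised binned slope tibble.
#' @param timeline An [experiment_timeline()].
#' @param channels Optional channel subset.
#' @return A ggplot object.
#' @export
plot_slope_timecourse <- function(slopes, timeline, channels = NULL) {
  if (!is.null(channels)) {
    slopes <- dplyr::filter(slopes, .data$channel %in% channels)
  }
  agg <- slopes |>
    dplyr::filter(is.finite(.data$normalized)) |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(mean = mean(.data$normalized),
                     sem = dplyr::if_else(
                       dplyr::n() > 1L,
                       sd(.data$normalized) / sqrt(dplyr::n()), 0),
                     .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$time_min,
                                         y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 100, linetype = "dotted") +
    ggplot2::labs(x = "Time (min)", y = "fEPSP slope (% of baseline)")
  if (nrow(timeline$events)) {
    p <- p + ggplot2::geom_vline(xintercept = timeline$events$time_min,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Polygonal activation diagram
#'
#' Dots for all electrodes, the baseline (pre) and post-train activation
#' hulls overlaid in distinct colours, hull areas in the subtitle, and the
#' slice layer boundaries as vertical dashed lines.
#'
#' @param pre,post Channel index sets (pre may be empty, with a warning).
#' @param grid An [electrode_grid()].
#' @param layer_x_um Optional x positions (um) of layer boundaries.
#' @return A ggplot object.
#' @export
plot_polygon_diagram <- function(pre, post, grid, layer_x_um = NULL) {
  cc <- channel_coords(grid)
  hulls <- list()
  if (length(pre) == 0L) {
    warn("empty pre set; drawing post hull only")
  } else {
    hulls$pre <- activation_hull(pre, grid)
  }
  hulls$post <- activation_hull(post, grid)
  hull_df <- dplyr::bind_rows(lapply(names(hulls), function(nm) {
    v <- hulls[[nm]]$vertices
    tibble::tibble(x_um = v$x_um, y_um = v$y_um, phase = nm)
  }))
  areas <- vapply(hulls, function(h) h$area_um2, numeric(1))
  subtitle <- paste(sprintf("%s area %.0f um^2", names(areas), areas),
                    collapse = ", ")
  p <- ggplot2::ggplot(cc, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_point(colour = "black", size = 1) +
    ggplot2::geom_polygon(
      data = hull_df,
      ggplot2::aes(fill = .data$phase, colour = .data$phase),
      alpha = 0.25) +
    ggplot2::scale_fill_manual(values = c(pre = "blue", post = "red")) +
    ggplot2::scale_colour_manual(values = c(pre = "blue", post = "red")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", subtitle = subtitle)
  if (!is.null(layer_x_um)) {
    p <- p + ggplot2::geom_vline(xintercept = layer_x_um,
                                 linetype = "dashed")
  }
  p
}

#' @rdname plot_polygon_diagram
#' @param path Output image file (PNG).
#' @param width,height,dpi Device geometry.
#' @export
render_polygon_diagram <- function(pre, post, grid, path,
                                   layer_x_um = NULL, width = 5,
                                   height = 5, dpi = 100) {
  p <- plot_polygon_diagram(pre, post, grid, layer_x_um)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' Heat-map view of a latent field frame
#'
#' @param object A `latent_field`.
#' @param frame Frame index (spatio-temporal fields).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.latent_field <- function(object, frame = 1L, ...) {
  vals <- if (object$n_frames == 1L) object$values else
    object$values[, , frame]
  df <- tibble::tibble(row = rep(seq_len(object$N), times = object$N),
                       col = rep(seq_len(object$N), each = object$N),
                       value = as.vector(vals))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "field") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "latent column", y = "latent row")
}

#' Render 3-D surface images of a latent field
#'
#' One perspective surface per requested frame, with a fixed camera
#' (theta 35, phi 30) and a fixed colour ramp over the display range, so
#' identical inputs give identical images.
#'
#' @param field A `latent_field`.
#' @param frames Frame indices to render (empty: warning, no output).
#' @param out_dir Output directory.
#' @param labels Optional per-frame labels used in file names and titles.
#' @param state_range Display range `c(m_min, m_max)`; defaults to the
#'   field's full value range.
#' @param width,height Image size in pixels.
#' @return Paths of the written PNG files, invisibly.
#' @export
render_surface <- function(field, frames = seq_len(field$n_frames),
                           out_dir = ".", labels = NULL,
                           state_range = NULL, width = 600, height = 500) {
  if (!length(frames)) {
    warn("no frames requested; nothing rendered")
    return(invisible(character()))
  }
  if (!all(is.finite(unlist(field$values)))) {
    abort("latent field contains non-finite values",
          class = "med64_validation_error")
  }
  if (is.null(state_range)) {
    state_range <- field$state_range %||% range(field$values)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ramp <- grDevices::hcl.colors(100, "viridis")
  paths <- character(length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    vals <- if (field$n_frames == 1L) field$values else field$values[, , fr]
    lab <- if (!is.null(labels)) labels[[k]] else sprintf("frame%03d", fr)
    path <- file.path(out_dir, paste0("surface_", lab, ".png"))
    facet <- (vals[-1, -1] + vals[-1, -ncol(vals)] +
                vals[-nrow(vals), -1] + vals[-nrow(vals), -ncol(vals)]) / 4
    if (state_range[2] > state_range[1]) {
      ci <- pmin(100, pmax(1, ceiling(
        99 * (facet - state_range[1]) /
          (state_range[2] - state_range[1]) + 1e-9)))
    } else {
      ci <- matrix(1L, nrow(facet), ncol(facet))
    }
    grDevices::png(path, width = width, height = height)
    graphics::par(mar = c(1, 1, 2, 1))
    zlim <- if (state_range[2] > state_range[1]) state_range else
      state_range + c(-1, 1)
    graphics::persp(x = seq_len(nrow(vals)), y = seq_len(ncol(vals)),
                    z = vals, zlim = zlim, theta = 35, phi = 30,
                    expand = 0.6, col = ramp[ci], border = NA,
                    shade = NA, box = TRUE, axes = FALSE, main = lab)
    grDevices::dev.off()
    paths[[k]] <- path
  }
  invisible(paths)
}
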