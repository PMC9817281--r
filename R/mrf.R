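#' Lanczos kernel weight
#'
#' Windowed-sinc smoothness weight
#' `L(d) = alpha * sin(pi d) * sin(pi d / alpha) / (pi^2 d^2)` for
#' `0 < |d| < alpha`, with `L(0) = 1` (the sinc limit) and `L(d) = 0` for
#' `|d| >= alpha`. Used as the pairwise weight between latent sites, with
#' the lattice offset divided by `kernel_scale` so that integer offsets do
#' not fall exactly on the kernel's zeros.
#'
#' @param d Numeric distance(s), unitless.
#' @param alpha Kernel order (window half-width); default 3.
#' @return Weight(s) in `[-0.09, 1]`.
#' @examples
#' lanczos_weight(0)       # 1
#' lanczos_weight(1:2)     # exactly 0 at integer arguments
#' lanczos_weight(0.5)     # 0.6079 within rounding
#' @export
lanczos_weight <- function(d, alpha = 3) {
  stopifnot(alpha > 0)
  d <- abs(d)
  w <- numeric(length(d))
  w[d == 0] <- 1
  inside <- d > 0 & d < alpha
  di <- d[inside]
  w[inside] <- alpha * sin(pi * di) * sin(pi * di / alpha) / (pi^2 * di^2)
  w
}

# temporal taper (beta - |dt|) / beta, zero at |dt| >= beta
temporal_weight <- function(dt, beta = 3) {
  pmax(0, (beta - abs(dt)) / beta)
}

spatial_offsets <- function(alpha, kernel_scale, clip_negative = TRUE,
                            include_self = FALSE, drop_zero = TRUE) {
  w <- ceiling(alpha) - 1L
  g <- expand.grid(dr = -w:w, dc = -w:w)
  if (!include_self) g <- g[!(g$dr == 0 & g$dc == 0), ]
  g$weight <- lanczos_weight(sqrt(g$dr^2 + g$dc^2) / kernel_scale, alpha)
  if (clip_negative) g$weight <- pmax(0, g$weight)
  if (drop_zero) g <- g[g$weight != 0, , drop = FALSE]
  g
}

#' Weighted neighbourhood of a latent site
#'
#' The neighbourhood of site `i` spans a `(2 ceil(alpha) - 1)^2` window
#' (5 x 5 at `alpha = 3`), truncated at the grid borders, with weight
#' `lanczos_weight(||offset|| / kernel_scale, alpha)`. In spatio-temporal
#' mode the neighbourhood additionally extends `beta - 1` frames either
#' way along the site's own time line, the temporal taper
#' `(beta - |dt|) / beta` applied to the spatial self-factor `L(0) = 1`:
#' in-frame neighbours provide spatial smoothness, cross-frame same-site
#' neighbours temporal smoothness. (Coupling distinct sites across
#' distinct frames would over-smooth: constant-in-time observations would
#' no longer reproduce the per-frame spatial estimate.) Negative Lanczos
#' lobes are clipped to zero by default so the MAP objective stays
#' convex.
#'
#' @param site Integer pair `c(row, col)` of the centre site (1-based).
#' @param N Latent grid side.
#' @param alpha Lanczos order.
#' @param kernel_scale Distance divisor applied to lattice offsets.
#' @param mode `"spatial"` or `"spatiotemporal"`.
#' @param beta Temporal window parameter.
#' @param frame,n_frames Centre frame and frame count (spatio-temporal).
#' @param clip_negative Clip negative kernel lobes to zero.
#' @return A tibble of neighbours: `row`, `col`, (`frame`,) `weight`.
#' @export
build_neighborhood <- function(site, N, alpha = 3, kernel_scale = 2.5,
                               mode = c("spatial", "spatiotemporal"),
                               beta = 3, frame = 1L, n_frames = 1L,
                               clip_negative = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(site) == 2L, site[1] >= 1, site[1] <= N,
            site[2] >= 1, site[2] <= N)
  if (mode == "spatial") {
    off <- spatial_offsets(alpha, kernel_scale, clip_negative,
                           drop_zero = FALSE)
    out <- tibble::tibble(row = site[1] + off$dr, col = site[2] + off$dc,
                          weight = off$weight)
    return(dplyr::filter(out, .data$row >= 1, .data$row <= N,
                         .data$col >= 1, .data$col <= N))
  }
  offs <- spatial_offsets(alpha, kernel_scale, clip_negative,
                          drop_zero = FALSE)
  spatial <- tibble::tibble(row = site[1] + offs$dr,
                            col = site[2] + offs$dc,
                            frame = frame, weight = offs$weight)
  dts <- setdiff((-(beta - 1)):(beta - 1), 0L)
  temporal <- tibble::tibble(row = site[1], col = site[2],
                             frame = frame + dts,
                             weight = temporal_weight(dts, beta))
  out <- dplyr::bind_rows(spatial, temporal)
  dplyr::filter(out, .data$row >= 1, .data$row <= N, .data$col >= 1,
                .data$col <= N, .data$frame >= 1, .data$frame <= n_frames)
}

#' Specify a super-resolution MAP problem
#'
#' Bundles one frame of electrode observations with the latent-field
#' geometry and regularisation parameters. The `obs_rows x obs_cols`
#' observations (values in % of baseline or uV; units are carried
#' through) are embedded at the centres of their latent cells: electrode
#' `(r, c)` observes latent site
#' `(floor((r - 0.5) N / obs_rows) + 1, floor((c - 0.5) N / obs_cols) + 1)`.
#'
#' The MAP objective is
#' `Phi(X) = sum_obs (o_i - x_i)^2
#'   + lambda * sum_i sum_{j in N(i)} a_ij (x_i - x_j)^2
#'   + ridge * ||X - mean(O)||^2`,
#' a strictly convex quadratic once negative kernel lobes are clipped and
#' `ridge > 0`. `lambda` defaults to the term-count balance
#' (number of unary terms / number of pairwise terms) so the
#' reconstruction stays anchored to the observations at any `N`.
#'
#' @param observations Numeric matrix of electrode readings (e.g. 8 x 8),
#'   or a vector reshaped row-major onto `obs_rows x obs_cols`.
#' @param N Latent grid side (default 256).
#' @param obs_rows,obs_cols Observation lattice dimensions (defaults taken
#'   from the matrix).
#' @param alpha,beta Lanczos order and temporal window parameter.
#' @param kernel_scale Distance divisor for the kernel argument.
#' @param lambda Unary/pairwise balance; `NULL` for the term-count
#'   default.
#' @param ridge Small positive Tikhonov weight centred on the observation
#'   mean.
#' @param clip_negative Clip negative kernel lobes (keeps the system
#'   positive definite).
#' @param mask_channels Row-major observation indices excluded from the
#'   unary term (typically the stimulation channel, whose value is
#'   artifact).
#' @param state_range Optional `c(m_min, m_max)` display range.
#' @return An object of class `mrf_problem`.
#' @export
mrf_problem <- function(observations, N = 256, obs_rows = NULL,
                        obs_cols = NULL, alpha = 3, beta = 3,
                        kernel_scale = 2.5, lambda = NULL, ridge = 1e-6,
                        clip_negative = TRUE, mask_channels = integer(0),
                        state_range = NULL) {
  if (is.matrix(observations)) {
    obs_rows <- nrow(observations)
    obs_cols <- ncol(observations)
    obs <- as.vector(t(observations)) # row-major channel order
  } else {
    if (is.null(obs_rows) || is.null(obs_cols)) {
      abort("obs_rows and obs_cols required for vector observations",
            class = "med64_validation_error")
    }
    obs <- as.numeric(observations)
  }
  if (length(obs) != obs_rows * obs_cols) {
    abort("observation length does not match obs_rows * obs_cols",
          class = "med64_validation_error")
  }
  keep <- setdiff(seq_along(obs), mask_channels)
  if (!length(keep)) {
    abort("no observations left after masking; problem unsolvable",
          class = "med64_unsolvable_error")
  }
  if (any(!is.finite(obs[keep]))) {
    abort("non-finite observation value", class = "med64_validation_error")
  }
  stopifnot(N >= obs_rows, N >= obs_cols, alpha > 0, beta >= 1,
            ridge > 0, is.null(lambda) || lambda >= 0)
  k <- seq_len(obs_rows * obs_cols)
  er <- (k - 1L) %/% obs_cols + 1L
  ec <- (k - 1L) %% obs_cols + 1L
  lat_r <- floor((er - 0.5) * N / obs_rows) + 1L
  lat_c <- floor((ec - 0.5) * N / obs_cols) + 1L
  sites <- (lat_c - 1L) * N + lat_r # column-major linear index
  if (anyDuplicated(sites[keep])) {
    abort("latent grid too coarse: observed sites collide",
          class = "med64_validation_error")
  }
  structure(list(obs = obs, obs_rows = obs_rows, obs_cols = obs_cols,
                 N = as.integer(N), sites = sites, keep = keep,
                 alpha = alpha, beta = beta, kernel_scale = kernel_scale,
                 lambda = lambda, ridge = ridge,
                 clip_negative = clip_negative,
                 mask_channels = as.integer(mask_channels),
                 state_range = state_range),
            class = "mrf_problem")
}

# Sparse pairwise weight matrix over the N x N (x T) lattice. Within a
# frame, sites couple across the Lanczos 5 x 5 window; across frames a
# site couples to itself (spatial factor L(0) = 1) with the temporal
# taper a_t, so that replicated observations reproduce the per-frame
# spatial solution exactly. Returns the number of directed *spatial*
# terms, which sets the default unary/pairwise balance independent of T.
pairwise_matrix <- function(N, alpha, kernel_scale, clip_negative,
                            beta = 3, n_frames = 1L) {
  offs <- spatial_offsets(alpha, kernel_scale, clip_negative)
  trip_i <- list(); trip_j <- list(); trip_w <- list()
  r <- rep(seq_len(N), times = N)
  c_ <- rep(seq_len(N), each = N)
  n2 <- N * N
  n_spatial <- 0L
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]; w <- offs$weight[k]
    ok <- r + dr >= 1 & r + dr <= N & c_ + dc >= 1 & c_ + dc <= N
    i0 <- which(ok)
    j0 <- i0 + dr + dc * N
    for (tf in seq_len(n_frames)) {
      trip_i[[length(trip_i) + 1L]] <- i0 + (tf - 1L) * n2
      trip_j[[length(trip_j) + 1L]] <- j0 + (tf - 1L) * n2
      trip_w[[length(trip_w) + 1L]] <- rep(w, length(i0))
    }
    n_spatial <- n_spatial + length(i0) * n_frames
  }
  if (n_frames > 1L) {
    for (dt in seq_len(min(beta - 1L, n_frames - 1L))) {
      tw <- temporal_weight(dt, beta)
      if (tw <= 0) next
      for (tf in seq_len(n_frames - dt)) {
        i0 <- seq_len(n2) + (tf - 1L) * n2
        j0 <- seq_len(n2) + (tf + dt - 1L) * n2
        trip_i[[length(trip_i) + 1L]] <- c(i0, j0)
        trip_j[[length(trip_j) + 1L]] <- c(j0, i0)
        trip_w[[length(trip_w) + 1L]] <- rep(tw, 2L * n2)
      }
    }
  }
  i <- unlist(trip_i); j <- unlist(trip_j); w <- unlist(trip_w)
  W <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(n2 * n_frames, n2 * n_frames))
  list(W = W, n_terms = n_spatial / n_frames)
}

solve_map_system <- function(obs_vec, site_idx, N, n_frames, alpha, beta,
                             kernel_scale, lambda, ridge, clip_negative) {
  pm <- pairwise_matrix(N, alpha, kernel_scale, clip_negative, beta,
                        n_frames)
  n_all <- N * N * n_frames
  # unary terms per frame balanced against spatial pairwise terms per
  # frame, so the balance does not depend on the number of frames
  if (is.null(lambda)) {
    lambda <- (length(site_idx) / n_frames) / pm$n_terms
  }
  u <- numeric(n_all)
  u[site_idx] <- 1
  b <- numeric(n_all)
  b[site_idx] <- obs_vec
  centre <- mean(obs_vec)
  D <- Matrix::Diagonal(n_all, x = Matrix::rowSums(pm$W))
  A <- Matrix::Diagonal(n_all, x = u + ridge) +
    2 * lambda * (D - pm$W)
  A <- Matrix::forceSymmetric(A)
  x <- as.numeric(Matrix::solve(A, b + ridge * centre))
  resid <- sqrt(sum((as.numeric(A %*% x) - (b + ridge * centre))^2))
  quad_pair <- as.numeric(Matrix::crossprod(x, (D - pm$W) %*% x))
  objective <- sum((obs_vec - x[site_idx])^2) +
    lambda * 2 * quad_pair + ridge * sum((x - centre)^2)
  list(x = x, lambda = lambda, residual_norm = resid,
       objective = objective, centre = centre)
}

#' Spatial MAP estimate of the latent field
#'
#' Solves the sparse symmetric positive-definite normal equations of the
#' MAP objective (see [mrf_problem()]) by direct sparse factorisation;
#' the solver certifies the solution by the residual norm of the normal
#' equations (gradient norm at the solution = 2 x residual norm).
#'
#' @param problem An [mrf_problem()].
#' @return An object of class `latent_field` with `values` (`N x N`
#'   matrix), `objective`, `residual_norm`, and the solved parameters.
#' @export
solve_map_spatial <- function(problem) {
  stopifnot(inherits(problem, "mrf_problem"))
  sol <- solve_map_system(
    obs_vec = problem$obs[problem$keep],
    site_idx = problem$sites[problem$keep],
    N = problem$N, n_frames = 1L, alpha = problem$alpha,
    beta = problem$beta, kernel_scale = problem$kernel_scale,
    lambda = problem$lambda, ridge = problem$ridge,
    clip_negative = problem$clip_negative)
  structure(list(values = matrix(sol$x, nrow = problem$N),
                 n_frames = 1L, N = problem$N,
                 objective = sol$objective,
                 residual_norm = sol$residual_norm,
                 lambda = sol$lambda, ridge = problem$ridge,
                 alpha = problem$alpha, beta = problem$beta,
                 kernel_scale = problem$kernel_scale,
                 sites = problem$sites, keep = problem$keep,
                 state_range = problem$state_range),
            class = "latent_field")
}

#' Spatio-temporal MAP estimate across frames
#'
#' Joint MAP over `T` frames: per-frame unary and Lanczos spatial
#' pairwise terms, plus temporal pairwise terms coupling each site to
#' itself across up to `beta - 1` neighbouring frames with weight
#' `(beta - |dt|) / beta` (see [build_neighborhood()] for why cross-frame
#' coupling stays on the site's own time line). With `T = 1` the temporal
#' terms vanish and the solution equals [solve_map_spatial()] exactly;
#' observations constant in time reproduce the per-frame spatial
#' solution.
#'
#' @param problems A list of [mrf_problem()]s, one per frame, sharing
#'   geometry, embedding and parameters (only the observations may
#'   differ).
#' @return A `latent_field` whose `values` is an `N x N x T` array.
#' @export
solve_map_spatiotemporal <- function(problems) {
  stopifnot(length(problems) >= 1L,
            all(vapply(problems, inherits, logical(1), "mrf_problem")))
  p1 <- problems[[1L]]
  for (p in problems[-1L]) {
    same <- identical(p$sites, p1$sites) && identical(p$keep, p1$keep) &&
      p$N == p1$N && p$alpha == p1$alpha && p$beta == p1$beta &&
      p$kernel_scale == p1$kernel_scale && p$ridge == p1$ridge &&
      p$clip_negative == p1$clip_negative
    if (!same) {
      abort("frames disagree on grid, embedding or parameters",
            class = "med64_validation_error")
    }
  }
  n_frames <- length(problems)
  n2 <- p1$N^2
  site_idx <- unlist(lapply(seq_len(n_frames), function(t) {
    p1$sites[p1$keep] + (t - 1L) * n2
  }))
  obs_vec <- unlist(lapply(problems, function(p) p$obs[p$keep]))
  sol <- solve_map_system(
    obs_vec = obs_vec, site_idx = site_idx, N = p1$N,
    n_frames = n_frames, alpha = p1$alpha, beta = p1$beta,
    kernel_scale = p1$kernel_scale, lambda = p1$lambda, ridge = p1$ridge,
    clip_negative = p1$clip_negative)
  structure(list(values = array(sol$x, dim = c(p1$N, p1$N, n_frames)),
                 n_frames = n_frames, N = p1$N,
                 objective = sol$objective,
                 residual_norm = sol$residual_norm,
                 lambda = sol$lambda, ridge = p1$ridge,
                 alpha = p1$alpha, beta = p1$beta,
                 kernel_scale = p1$kernel_scale,
                 sites = p1$sites, keep = p1$keep,
                 state_range = p1$state_range),
            class = "latent_field")
}

#' @export
print.latent_field <- function(x, ...) {
  cat(sprintf(
    "<latent_field> %d x %d x %d, objective %.6g, residual %.3g, lambda %.3g\n",
    x$N, x$N, x$n_frames, x$objective, x$residual_norm, x$lambda))
  invisible(x)
}

#' Stretch a latent field to the 8-bit display range
#'
#' Affine map of `[m_min, m_max]` onto `[0, 255]`, clipped at the ends
#' and rounded half-to-even; invertible up to quantisation for in-range
#' values.
#'
#' @param field A `latent_field` or numeric array.
#' @param state_range `c(m_min, m_max)`; defaults to the field's declared
#'   `state_range` or, failing that, its value range.
#' @return An integer array of the same shape with values in 0..255.
#' @export
stretch_for_display <- function(field, state_range = NULL) {
  vals <- if (inherits(field, "latent_field")) field$values else field
  if (is.null(state_range) && inherits(field, "latent_field")) {
    state_range <- field$state_range
  }
  if (is.null(state_range)) state_range <- range(vals)
  if (!(state_range[2] > state_range[1])) {
    abort("degenerate state range: m_max must exceed m_min",
          class = "med64_validation_error")
  }
  y <- (vals - state_range[1]) / (state_range[2] - state_range[1]) * 255
  y <- pmin(255, pmax(0, y))
  out <- round(y) # round() is IEC half-to-even
  storage.mode(out) <- "integer"
  dim(out) <- dim(vals)
  out
}

#' @export
tidy.latent_field <- function(x, ...) {
  if (x$n_frames == 1L) {
    tibble::tibble(row = rep(seq_len(x$N), times = x$N),
                   col = rep(seq_len(x$N), each = x$N),
                   value = as.vector(x$values))
  } else {
    tibble::tibble(
      row = rep(seq_len(x$N), times = x$N * x$n_frames),
      col = rep(rep(seq_len(x$N), each = x$N), times = x$n_frames),
      frame = rep(seq_len(x$n_frames), each = x$N * x$N),
      value = as.vector(x$values))
  }
}

#' @export
glance.latent_field <- function(x, ...) {
  tibble::tibble(N = x$N, n_frames = x$n_frames, objective = x$objective,
                 residual_norm = x$residual_norm, lambda = x$lambda,
                 ridge = x$ridge, alpha = x$alpha, beta = x$beta,
                 kernel_scale = x$kernel_scale)
}

#' Write/read a latent field as a portable text array
#'
#' One CSV with a `#`-comment JSON header carrying the solve metadata and
#' one row per (frame, row, col).
#'
#' @param field A `latent_field`.
#' @param path File path.
#' @export
write_latent_field <- function(field, path) {
  hdr <- paste0("# latent_field: ", jsonlite::toJSON(
    glance(field), auto_unbox = TRUE, digits = NA))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  readr::write_csv(tidy(field), con, progress = FALSE)
  invisible(path)
}

#' @rdname write_latent_field
#' @export
read_latent_field <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- jsonlite::fromJSON(sub("^# latent_field: ", "", hdr))
  tb <- readr::read_csv(path, comment = "#",
                        col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  n_frames <- if ("frame" %in% names(tb)) max(tb$frame) else 1L
  N <- as.integer(meta$N)
  vals <- if (n_frames == 1L) {
    m <- matrix(NA_real_, N, N)
    m[cbind(tb$row, tb$col)] <- tb$value
    m
  } else {
    a <- array(NA_real_, dim = c(N, N, n_frames))
    a[cbind(tb$row, tb$col, tb$frame)] <- tb$value
    a
  }
  structure(list(values = vals, n_frames = as.integer(n_frames), N = N,
                 objective = meta$objective,
                 residual_norm = meta$residual_norm, lambda = meta$lambda,
                 ridge = meta$ridge, alpha = meta$alpha, beta = meta$beta,
                 kernel_scale = meta$kernel_scale, sites = NULL,
                 keep = NULL, state_range = NULL),
            class = "latent_field")
}
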