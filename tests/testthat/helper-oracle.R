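# Independent brute-force minimiser of the MAP objective, used to verify
# the sparse solver. Builds the neighbour weights from the kernel formula
# directly (its own code path, no package internals) and minimises the
# quadratic by nonlinear conjugate gradients with exact line search,
# which for a quadratic is plain linear CG on function/gradient
# evaluations only.

oracle_lanczos <- function(d, alpha = 3) {
  d <- abs(d)
  if (d == 0) return(1)
  if (d >= alpha) return(0)
  alpha * sin(pi * d) * sin(pi * d / alpha) / (pi^2 * d^2)
}

# neighbour list over an N x N x T lattice (column-major site index within
# a frame, frames stacked); clip_negative always on, matching the default
oracle_neighbors <- function(N, n_frames = 1L, alpha = 3,
                             kernel_scale = 2.5, beta = 3) {
  w <- ceiling(alpha) - 1L
  nb <- vector("list", N * N * n_frames)
  for (tt in seq_len(n_frames)) {
    for (cc in seq_len(N)) {
      for (rr in seq_len(N)) {
        i <- (tt - 1L) * N * N + (cc - 1L) * N + rr
        js <- integer(0); ws <- numeric(0)
        # spatial window within the frame
        for (dc in -w:w) {
          for (dr in -w:w) {
            if (dr == 0 && dc == 0) next
            r2 <- rr + dr; c2 <- cc + dc
            if (r2 < 1L || r2 > N || c2 < 1L || c2 > N) next
            aw <- max(0, oracle_lanczos(sqrt(dr^2 + dc^2) / kernel_scale,
                                        alpha))
            if (aw <= 0) next
            js <- c(js, (tt - 1L) * N * N + (c2 - 1L) * N + r2)
            ws <- c(ws, aw)
          }
        }
        # same-site temporal line across frames
        if (n_frames > 1L) {
          for (dt in setdiff((-(beta - 1)):(beta - 1), 0L)) {
            t2 <- tt + dt
            if (t2 < 1L || t2 > n_frames) next
            js <- c(js, (t2 - 1L) * N * N + (cc - 1L) * N + rr)
            ws <- c(ws, (beta - abs(dt)) / beta)
          }
        }
        nb[[i]] <- list(j = js, w = ws)
      }
    }
  }
  nb
}

# gradient of Phi at x (factor 4 on the pairwise part: each ordered pair
# appears twice in the double sum and the square differentiates to 2)
oracle_gradient <- function(x, nb, sites, obs, lambda, ridge, centre) {
  g <- 2 * ridge * (x - centre)
  g[sites] <- g[sites] + 2 * (x[sites] - obs)
  for (i in seq_along(nb)) {
    if (length(nb[[i]]$j)) {
      g[i] <- g[i] + 4 * lambda * sum(nb[[i]]$w * (x[i] - x[nb[[i]]$j]))
    }
  }
  g
}

oracle_map <- function(obs_frames, N, alpha = 3, kernel_scale = 2.5,
                       beta = 3, lambda, ridge, mask = integer(0),
                       tol = 1e-10, max_iter = 5000L) {
  if (!is.list(obs_frames)) obs_frames <- list(obs_frames)
  n_frames <- length(obs_frames)
  obs_r <- nrow(obs_frames[[1]])
  obs_c <- ncol(obs_frames[[1]])
  k <- seq_len(obs_r * obs_c)
  er <- (k - 1L) %/% obs_c + 1L
  ec <- (k - 1L) %% obs_c + 1L
  lat_r <- floor((er - 0.5) * N / obs_r) + 1L
  lat_c <- floor((ec - 0.5) * N / obs_c) + 1L
  site0 <- (lat_c - 1L) * N + lat_r
  keep <- setdiff(k, mask)
  sites <- unlist(lapply(seq_len(n_frames), function(t) {
    site0[keep] + (t - 1L) * N * N
  }))
  obs <- unlist(lapply(obs_frames, function(m) as.vector(t(m))[keep]))
  nb <- oracle_neighbors(N, n_frames, alpha, kernel_scale, beta)
  centre <- mean(obs)
  x <- rep(centre, N * N * n_frames)
  g <- oracle_gradient(x, nb, sites, obs, lambda, ridge, centre)
  d <- -g
  scale <- max(1, sqrt(sum(obs^2)))
  for (it in seq_len(max_iter)) {
    gd <- oracle_gradient(x + 1e-4 * d, nb, sites, obs, lambda, ridge,
                          centre)
    dAd <- sum(d * (gd - g)) / 1e-4
    if (dAd <= 0) break
    step <- -sum(g * d) / dAd
    x <- x + step * d
    gn <- oracle_gradient(x, nb, sites, obs, lambda, ridge, centre)
    if (sqrt(sum(gn^2)) < tol * scale) break
    d <- -gn + (sum(gn^2) / sum(g^2)) * d
    g <- gn
  }
  x
}
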