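test_that("Lanczos kernel has the sinc limit, integer zeros and known values", {
  expect_equal(lanczos_weight(0), 1)
  expect_equal(lanczos_weight(1), 0, tolerance = 1e-12)
  expect_equal(lanczos_weight(2), 0, tolerance = 1e-12)
  expect_equal(lanczos_weight(-1.5), lanczos_weight(1.5)) # even
  expect_equal(lanczos_weight(3), 0)
  expect_equal(lanczos_weight(4.7), 0) # outside support
  # alpha sin(pi/2) sin(pi/6) / (pi^2 / 4) at d = 0.5, alpha = 3
  expect_equal(lanczos_weight(0.5), 3 * sin(pi / 2) * sin(pi / 6) /
                 (pi^2 * 0.25))
  expect_equal(round(lanczos_weight(0.5), 4), 0.6079)
})

test_that("spatial neighbourhoods span the 5x5 window truncated at borders", {
  nb <- build_neighborhood(c(5, 5), N = 12)
  expect_equal(nrow(nb), 24L) # 5x5 window minus the centre
  expect_true(all(abs(nb$row - 5) <= 2 & abs(nb$col - 5) <= 2))
  corner <- build_neighborhood(c(1, 1), N = 12)
  expect_equal(nrow(corner), 8L) # 3x3 quadrant minus centre
  # weights follow the scaled kernel
  d <- sqrt((nb$row - 5)^2 + (nb$col - 5)^2) / 2.5
  expect_equal(nb$weight, pmax(0, lanczos_weight(d)))
})

test_that("spatio-temporal neighbourhoods add a tapered same-site time line", {
  nb <- build_neighborhood(c(6, 6), N = 12, mode = "spatiotemporal",
                           frame = 3, n_frames = 7)
  # 24 in-frame spatial neighbours + 4 same-site temporal neighbours
  expect_equal(nrow(nb), 28L)
  expect_true(all(abs(nb$frame - 3) <= 2))
  # temporal taper (beta - |dt|)/beta on the site's own time line
  self_sp <- nb[nb$row == 6 & nb$col == 6, ]
  expect_equal(self_sp$weight[self_sp$frame == 2], (3 - 1) / 3)
  expect_equal(self_sp$weight[self_sp$frame == 1], (3 - 2) / 3)
  expect_equal(self_sp$weight[self_sp$frame == 4], (3 - 1) / 3)
  # zero taper at |dt| = beta: frame offsets +-3 are outside the window
  expect_false(any(abs(nb$frame - 3) == 3))
  # truncation at the start of the recording
  nb1 <- build_neighborhood(c(6, 6), N = 12, mode = "spatiotemporal",
                            frame = 1, n_frames = 7)
  expect_true(all(nb1$frame >= 1))
})

test_that("constant observations reproduce a constant field exactly", {
  pr <- mrf_problem(matrix(7.5, 4, 4), N = 12)
  f <- solve_map_spatial(pr)
  expect_equal(as.vector(f$values), rep(7.5, 144), tolerance = 1e-10)
  expect_lt(f$residual_norm, 1e-8 * sqrt(sum(pr$obs^2)))
})

test_that("a symmetric two-point problem interpolates to the midpoint at the centre", {
  # 1 x 3 observation row embedded in a 3 x 3 latent grid; the middle
  # electrode is masked so only the two ends are observed
  pr <- mrf_problem(c(0, 0, 1), obs_rows = 1, obs_cols = 3, N = 3,
                    mask_channels = 2L)
  f <- solve_map_spatial(pr)
  expect_equal(f$values[2, 2], 0.5, tolerance = 1e-10)
})

test_that("as lambda -> 0 the field honours the observations", {
  obs <- withr::with_seed(5L, matrix(rnorm(16, 100, 15), 4, 4))
  pr <- mrf_problem(obs, N = 12, lambda = 1e-8, ridge = 1e-8)
  f <- solve_map_spatial(pr)
  fitted <- as.vector(f$values)[pr$sites]
  expect_equal(fitted, pr$obs, tolerance = 1e-4)
})

test_that("as lambda grows the field collapses towards a constant", {
  obs <- withr::with_seed(6L, matrix(rnorm(16, 100, 15), 4, 4))
  vars <- vapply(c(0.1, 1, 10, 100), function(l) {
    f <- solve_map_spatial(mrf_problem(obs, N = 12, lambda = l))
    var(as.vector(f$values))
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
  expect_lt(vars[4], vars[1] / 10)
})

test_that("the MAP estimate is shift- and scale-equivariant", {
  obs <- withr::with_seed(7L, matrix(rnorm(16, 100, 15), 4, 4))
  f0 <- solve_map_spatial(mrf_problem(obs, N = 12))
  f1 <- solve_map_spatial(mrf_problem(2.5 * obs - 40, N = 12))
  expect_equal(f1$values, 2.5 * f0$values - 40, tolerance = 1e-8)
})

test_that("the sparse solve matches the brute-force minimiser (spatial)", {
  for (seed in 1:3) {
    obs <- withr::with_seed(seed, matrix(rnorm(16, 100, 20), 4, 4))
    pr <- mrf_problem(obs, N = 12)
    f <- solve_map_spatial(pr)
    x_star <- oracle_map(obs, N = 12, lambda = f$lambda, ridge = pr$ridge)
    rel <- sqrt(sum((as.vector(f$values) - x_star)^2)) /
      sqrt(sum(x_star^2))
    expect_lt(rel, 1e-6)
  }
})

test_that("the joint spatio-temporal solve matches the brute-force minimiser", {
  frames <- withr::with_seed(11L, list(matrix(rnorm(16, 100, 20), 4, 4),
                                       matrix(rnorm(16, 100, 20), 4, 4)))
  probs <- lapply(frames, mrf_problem, N = 8)
  f <- solve_map_spatiotemporal(probs)
  x_star <- oracle_map(frames, N = 8, lambda = f$lambda,
                       ridge = probs[[1]]$ridge)
  rel <- sqrt(sum((as.vector(f$values) - x_star)^2)) / sqrt(sum(x_star^2))
  expect_lt(rel, 1e-6)
})

test_that("T = 1 spatio-temporal estimation reduces exactly to the spatial solve", {
  obs <- withr::with_seed(12L, matrix(rnorm(16, 100, 20), 4, 4))
  pr <- mrf_problem(obs, N = 12)
  fs <- solve_map_spatial(pr)
  ft <- solve_map_spatiotemporal(list(pr))
  expect_equal(ft$values[, , 1], fs$values, tolerance = 1e-12)
  expect_equal(ft$lambda, fs$lambda)
})

test_that("identical frames replicate the spatial solution across time", {
  obs <- withr::with_seed(13L, matrix(rnorm(16, 100, 20), 4, 4))
  pr <- mrf_problem(obs, N = 10)
  fs <- solve_map_spatial(pr)
  ft <- solve_map_spatiotemporal(replicate(5, pr, simplify = FALSE))
  for (t in 1:5) {
    expect_equal(ft$values[, , t], fs$values, tolerance = 1e-7)
  }
})

test_that("frames with inconsistent geometry are rejected", {
  obs <- matrix(1:16, 4, 4)
  a <- mrf_problem(obs, N = 12)
  b <- mrf_problem(obs, N = 12, kernel_scale = 3)
  expect_error(solve_map_spatiotemporal(list(a, b)),
               class = "med64_validation_error")
  expect_error(mrf_problem(matrix(c(NA, rep(1, 15)), 4, 4), N = 12),
               class = "med64_validation_error")
  expect_error(mrf_problem(obs, N = 12,
                           mask_channels = 1:16),
               class = "med64_unsolvable_error")
})

test_that("coarse and refined reconstructions agree at the electrode sites", {
  # a smooth bump observed on the 4x4 grid, solved at two latent scales
  cc <- expand.grid(r = 1:4, c = 1:4)
  obs <- matrix(100 + 40 * exp(-((cc$r - 2.5)^2 + (cc$c - 2.5)^2) / 2),
                4, 4)
  f8 <- solve_map_spatial(mrf_problem(obs, N = 8))
  f16 <- solve_map_spatial(mrf_problem(obs, N = 16))
  p8 <- mrf_problem(obs, N = 8)
  p16 <- mrf_problem(obs, N = 16)
  at8 <- as.vector(f8$values)[p8$sites]
  at16 <- as.vector(f16$values)[p16$sites]
  expect_gt(cor(at8, at16), 0.99)
})

test_that("display stretch maps the state range onto 0..255 with half-to-even rounding", {
  vals <- matrix(c(0, 5, 10, 12, -3, 2.5), 2, 3)
  s <- stretch_for_display(vals, state_range = c(0, 10))
  expect_equal(s[1, 1], 0L)
  expect_equal(s[1, 2], 255L)   # 10 -> 255
  expect_equal(s[2, 2], 255L)   # 12 clipped
  expect_equal(s[1, 3], 0L)     # -3 clipped
  # midpoint: 127.5 rounds half-to-even to 128
  expect_equal(stretch_for_display(matrix(5), c(0, 10))[1, 1], 128L)
  expect_error(stretch_for_display(vals, state_range = c(1, 1)),
               class = "med64_validation_error")
  # invertible up to quantisation on in-range values
  x <- matrix(seq(0, 10, length.out = 11))
  s2 <- stretch_for_display(x, c(0, 10))
  back <- s2 / 255 * 10
  expect_true(all(abs(back - x) <= 10 / 255 / 2 + 1e-9))
})

test_that("tidy and glance expose the fitted field and its diagnostics", {
  obs <- matrix(1:16, 4, 4)
  f <- solve_map_spatial(mrf_problem(obs, N = 8))
  td <- tidy(f)
  expect_equal(nrow(td), 64L)
  expect_equal(td$value[td$row == 3 & td$col == 5], f$values[3, 5])
  gl <- glance(f)
  expect_equal(gl$N, 8L)
  expect_true(gl$residual_norm < 1e-8)
  # round-trip through the portable text format
  p <- file.path(withr::local_tempdir(), "field.csv")
  write_latent_field(f, p)
  back <- read_latent_field(p)
  expect_equal(back$values, f$values, tolerance = 1e-12)
  expect_equal(back$lambda, f$lambda)
})
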