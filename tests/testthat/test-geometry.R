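test_that("resampling preserves straight lines, recovers circles, handles duplicates", {
  ## identity on an already-canonical straight polyline
  pts <- cbind(seq(0, 120, length.out = 13), 0)
  rs <- resample_centerline(centerline(pts), 13)
  expect_equal(rs$points, pts, ignore_attr = TRUE, tolerance = 1e-12)

  ## 4 points on a quarter circle resample back onto the circle
  R <- 50
  th <- seq(0, pi / 2, length.out = 4)
  rs <- resample_centerline(centerline(cbind(R * cos(th), R * sin(th))), 13)
  expect_lt(max(abs(sqrt(rowSums(rs$points^2)) - R)), 0.1)

  ## arc length preserved within 0.5% on a reasonably sampled curve
  th2 <- seq(0, pi, length.out = 40)
  c2 <- centerline(cbind(40 * cos(th2), 40 * sin(th2)))
  expect_lt(abs(body_length(resample_centerline(c2, 13)) /
                body_length(c2) - 1), 0.005)

  ## duplicated vertex collapsed before resampling
  c3 <- centerline(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0), c(3, 0)))
  r3 <- resample_centerline(c3, 5)
  expect_equal(body_length(r3), 3, tolerance = 1e-9)
  expect_equal(nrow(r3$points), 5L)

  ## degenerate input errors
  expect_error(resample_centerline(
    centerline(matrix(1, 4, 2) + 1e-12 * matrix(rnorm(8), 4, 2))),
    "degenerate|zero")
})

test_that("body_length sums segment lengths and rejects degenerate input", {
  expect_equal(body_length(centerline(cbind(seq(0, 120, 10), 0))), 120)
  th <- seq(0, 2 * pi, length.out = 2000)
  expect_equal(body_length(centerline(cbind(cos(th), sin(th)))), 2 * pi,
               tolerance = 1e-5)
  expect_error(body_length(centerline(matrix(c(1, 1, 1, 1), 2, 2))),
               "zero arc length")
})

test_that("body_center is the arc-length-weighted centroid", {
  expect_equal(body_center(centerline(cbind(seq(0, 12, 1), 0))), c(6, 0),
               ignore_attr = TRUE)
  ## symmetric C about the x axis: center on the axis
  th <- seq(-1, 1, length.out = 101)
  cs <- centerline(cbind(30 * cos(th), 30 * sin(th)))
  expect_lt(abs(body_center(cs)[2]), 1e-9)
  ## quarter circle: analytic arc centroid at 2R/pi * (sin etc.)
  R <- 40
  th <- seq(0, pi / 2, length.out = 400)
  cq <- centerline(cbind(R * cos(th), R * sin(th)))
  expect_equal(body_center(cq), c(2 * R / pi, 2 * R / pi),
               ignore_attr = TRUE, tolerance = 1e-3)
})

test_that("curvature matches analytic circle and sinusoid forms", {
  ## straight worm: twelve zeros
  expect_equal(compute_curvature(centerline(cbind(seq(0, 60, 5), 0))),
               rep(0, 12))

  ## worm on a circle of radius L/2: |khat| = 2, constant sign
  L <- 60; R <- L / 2
  th <- seq(0, L / R, length.out = 200)
  k <- compute_curvature(centerline(cbind(R * cos(th), R * sin(th))))
  expect_equal(abs(k), rep(2, 12), tolerance = 0.02)
  expect_length(unique(sign(k)), 1L)

  ## circle oracle across radii R in [0.2L, 5L]: |khat| = L/R within 2%
  for (Rf in c(0.2, 0.5, 1, 2, 5)) {
    Rr <- Rf * L
    th <- seq(0, L / Rr, length.out = 200)
    cc <- centerline(cbind(Rr * cos(th), Rr * sin(th)))
    k <- compute_curvature(cc)
    expect_lt(max(abs(abs(k) * Rr / body_length(cc) - 1)), 0.02)
  }

  ## tangent angle theta(s) = alpha*sin(2*pi*s): khat = 2*pi*alpha*cos(2*pi*s)
  alpha <- 0.6
  s_f <- seq(0, 1, length.out = 2001); ds <- diff(s_f)[1]
  theta <- alpha * sin(2 * pi * s_f)
  x <- c(0, cumsum(ds * cos(theta[-1]))); y <- c(0, cumsum(ds * sin(theta[-1])))
  cl <- centerline(cbind(x, y) * 80)
  k <- compute_curvature(cl)
  mids <- (1:12 - 0.5) / 12
  expect_equal(k, 2 * pi * alpha * cos(2 * pi * mids), tolerance = 0.03)

  ## collinear window inside an otherwise bent body gives 0, not an error
  bentp <- rbind(cbind(seq(0, 30, length.out = 40), 0),
                 cbind(30 + 10 * sin(seq(0.05, pi / 2, length.out = 40)),
                       10 * (1 - cos(seq(0.05, pi / 2, length.out = 40)))))
  k <- compute_curvature(centerline(bentp))
  expect_equal(k[2], 0, tolerance = 0.05)
})

test_that("dimensionless curvature is scale invariant and flips under reversal", {
  scn <- swim_scenario(seed = 2)
  g <- generate_curvature(scn)
  base <- integrate_posture(g$map$values[, 5], 60)
  k0 <- compute_curvature(base)
  for (lam in c(0.5, 3, 10)) {
    scl <- centerline(base$points * lam, base$half_widths * lam)
    expect_equal(compute_curvature(scl), k0, tolerance = 1e-6)
  }
  rev_cl <- centerline(base$points[nrow(base$points):1, ],
                       rev(base$half_widths))
  expect_equal(compute_curvature(rev_cl), rev(-k0), tolerance = 1e-6)
})

test_that("curvature map columns reproduce the generating wave and mask invalid frames", {
  ## zero map for straight frames
  frames <- lapply(1:50, function(t)
    centerline(cbind(seq(0, 60, length.out = 25), 0), 2, t))
  m0 <- build_curvature_map(frames, 18)
  expect_equal(dim(m0$values), c(12L, 50L))
  expect_true(all(abs(m0$values) < 1e-9))
  expect_true(all(m0$valid_frames))

  ## khat(s,t) = 3*sin(2*pi*(1.5 s - 2 t/18)) within 5% RMS of closed form
  T_ <- 72; fps <- 18
  mids <- (1:12 - 0.5) / 12
  frames <- lapply(seq_len(T_), function(t) {
    kcol <- 3 * sin(2 * pi * (1.5 * mids - 2 * (t - 1) / fps))
    integrate_posture(kcol, 60, frame_index = t)
  })
  m <- build_curvature_map(frames, fps)
  truth <- sapply(seq_len(T_), function(t)
    3 * sin(2 * pi * (1.5 * mids - 2 * (t - 1) / fps)))
  expect_lt(sqrt(mean((m$values - truth)^2)) / sqrt(mean(truth^2)), 0.05)

  ## invalid frames masked exactly where flagged
  frames2 <- frames
  for (t in 10:19) frames2[[t]]$valid <- FALSE
  m2 <- build_curvature_map(frames2, fps)
  expect_equal(which(!m2$valid_frames), 10:19)
  expect_true(all(is.na(m2$values[, 10:19])))

  expect_error(build_curvature_map(list(), 18), "empty")
})

test_that("posture reconstruction is the inverse of curvature estimation", {
  ## zero curvature: straight line of the requested length
  cl <- integrate_posture(rep(0, 12), 60)
  expect_equal(body_length(cl), 60, tolerance = 1e-9)
  expect_lt(max(abs(cl$points[, 2])), 1e-9)

  ## constant khat = 2*pi closes into a circle (total turning 2*pi)
  cl <- integrate_posture(rep(2 * pi, 12), 60)
  expect_lt(sqrt(sum((cl$points[1, ] - cl$points[nrow(cl$points), ])^2)),
            0.02 * 60)

  ## integrate then re-estimate: original values within 5% RMS
  scn <- swim_scenario(seed = 4)
  g <- generate_curvature(scn)
  for (t in c(1, 100, 300)) {
    cl <- integrate_posture(g$map$values[, t], 60)
    k <- compute_curvature(cl)
    expect_lt(sqrt(mean((k - g$map$values[, t])^2)) /
              sqrt(mean(g$map$values[, t]^2)), 0.05)
  }
})

test_that("centerline tables round-trip through CSV", {
  sim <- simulate(swim_scenario(duration_s = 1, seed = 9))
  tr <- sim$track
  tr$frames[[3]]$valid <- FALSE
  path <- tempfile(fileext = ".csv")
  write_centerlines(tr, path)
  back <- read_centerlines(path, frame_rate = 18)
  expect_length(back, 1L)
  b <- back[[1]]
  expect_length(b$frames, length(tr$frames))
  expect_false(b$frames[[3]]$valid)
  expect_equal(b$frames[[5]]$points, tr$frames[[5]]$points,
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(b$frames[[5]]$half_widths, tr$frames[[5]]$half_widths,
               tolerance = 1e-6)
})
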