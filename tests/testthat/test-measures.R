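mids <- (1:12 - 0.5) / 12

test_that("wave initiation rate is 60 |f_t| and ignores direction", {
  scn <- swim_scenario(f = 2, duration_s = 10)
  modes <- spectral_modes(generate_curvature(scn)$map)
  wir <- wave_initiation_rate(modes)
  expect_equal(wir$median, 120, tolerance = 0.01)

  ## tail-initiated wave at 1 Hz still counts 60 waves/min
  mapr <- raw_map(sapply(1:200, function(t)
    3 * sin(2 * pi * (1.5 * mids - 1 * (t - 1) / 18))))
  wir_r <- wave_initiation_rate(spectral_modes(mapr))
  expect_equal(wir_r$median, 60, tolerance = 1)

  ## quiescent trial: empty series, no median
  quiet <- wave_initiation_rate(spectral_modes(raw_map(matrix(0, 12, 100))))
  expect_equal(quiet$n, 0L)
  expect_true(is.na(quiet$median))
})

test_that("body wave number recovers the spatial frequency, including sub-unity waves", {
  for (n_true in c(0.7, 1.5)) {
    scn <- swim_scenario(n = n_true, duration_s = 10)
    bwn <- body_wave_number(spectral_modes(generate_curvature(scn)$map))
    expect_equal(bwn$median, n_true, tolerance = 0.1)
  }
  b <- body_wave_number(spectral_modes(generate_curvature(
    swim_scenario(n = 0.7, duration_s = 10))$map))
  expect_gt(b$median, 0); expect_lt(b$median, 1)
})

test_that("asymmetry averages curvature over two strokes; bias survives, waves cancel", {
  T_ <- 360
  wave <- sapply(1:T_, function(t)
    3 * sin(2 * pi * (1.5 * mids + 1.5 * (t - 1) / 18)))
  ck <- const_clock(12, T_)
  a0 <- asymmetry(raw_map(wave), ck)
  expect_lt(abs(a0$median), 0.05)

  a_b <- asymmetry(raw_map(wave + 0.7), ck)
  expect_equal(a_b$median, 0.7, tolerance = 0.05)

  ## frozen clockwise arc khat = +2
  a_c <- asymmetry(raw_map(matrix(2, 12, T_)), ck)
  expect_equal(a_c$median, 2, tolerance = 1e-9)
})

test_that("stretch is the largest per-segment curvature range over two strokes", {
  T_ <- 360
  ck <- const_clock(12, T_)
  wave <- sapply(1:T_, function(t)
    3 * sin(2 * pi * (1.5 * mids + 1.5 * (t - 1) / 18)))
  expect_equal(stretch(raw_map(wave), ck)$median, 6, tolerance = 0.1)

  expect_equal(stretch(raw_map(matrix(1.3, 12, T_)), ck)$median, 0)

  ## envelope peaking mid-body at 4, elsewhere 2: stretch = 8
  env <- ifelse(abs(mids - 0.5) < 0.15, 4, 2)
  wave2 <- sapply(1:T_, function(t)
    env * sin(2 * pi * (1.5 * mids + 1.5 * (t - 1) / 18)))
  expect_equal(stretch(raw_map(wave2), ck)$median, 8, tolerance = 0.2)
})

test_that("attenuation compares tail-quarter to head-quarter ranges", {
  T_ <- 360
  ck <- const_clock(12, T_)
  wave <- function(env) sapply(1:T_, function(t)
    env * sin(2 * pi * (1.5 * mids + 1.5 * (t - 1) / 18)))

  expect_equal(attenuation(raw_map(wave(rep(3, 12))), ck)$median, 0,
               tolerance = 1)

  ## active head, motionless tail
  env1 <- 3 * nemaswim:::.envelope(mids, 1)
  expect_equal(attenuation(raw_map(wave(env1)), ck)$median, 100,
               tolerance = 1)

  ## tail range twice the head range: amplification, -100%
  env2 <- ifelse(mids <= 0.25, 2, 1) * 2
  expect_equal(attenuation(raw_map(wave(env2)), ck)$median, -100,
               tolerance = 2)

  ## motionless head: undefined rather than division blowup
  att <- attenuation(raw_map(wave(rep(0.001, 12))), ck)
  expect_equal(att$n, 0L)
})

test_that("reverse swimming counts frames with negative temporal frequency", {
  scn <- swim_scenario(duration_s = 10)
  modes <- spectral_modes(generate_curvature(scn)$map)
  expect_equal(reverse_swimming(modes)$percentage, 0)

  scn2 <- swim_scenario(reverse_episodes = list(c(200, 289)))
  modes2 <- spectral_modes(generate_curvature(scn2)$map)
  expect_equal(reverse_swimming(modes2)$percentage, 100 * 90 / 540,
               tolerance = 0.2)

  mapr <- raw_map(sapply(1:200, function(t)
    3 * sin(2 * pi * (1.5 * mids - 1.5 * (t - 1) / 18))))
  expect_equal(reverse_swimming(spectral_modes(mapr))$percentage, 100)
})

test_that("curling fires on O and 6 postures, inclusive at the L/3 boundary", {
  straight <- swim_track(lapply(1:3, function(t)
    centerline(cbind(seq(0, 60, length.out = 49), 0), 2, t)))
  ## nearest far-body point of a straight worm sits at arc separation
  ## exactly L/2, so the score is 0.5 body lengths: well clear of L/3
  cu <- curling(straight)
  expect_equal(cu$percentage, 0)
  expect_equal(min(cu$score), 0.5, tolerance = 0.01)

  ## closed O: constant khat = 2*pi
  o_track <- swim_track(lapply(1:3, function(t)
    integrate_posture(rep(2 * pi, 12), 60, frame_index = t)))
  cuo <- curling(o_track)
  expect_equal(cuo$percentage, 100)
  expect_lt(max(cuo$score), 0.1)

  ## V posture (arms of length L/2) with apex angle chosen so the tip
  ## separation is exactly L/3: curled (boundary inclusive; the nearest
  ## far-body point is at most the other tip)
  L <- 60
  v_track <- function(costh) {
    th <- acos(costh)
    arm1 <- cbind(seq(0, L / 2, length.out = 25), 0)
    s2 <- seq(0, L / 2, length.out = 25)[-1]
    arm2 <- cbind(L / 2 + s2 * cos(th), s2 * sin(th))
    swim_track(list(centerline(rbind(arm1, arm2), 2, 1)))
  }
  cv <- curling(v_track(-7 / 9))          # tip separation = L/3
  expect_equal(cv$values[1], 1)

  ## a wider V (tip separation 0.48 L) is not curled
  cw <- curling(v_track(2 * 0.48^2 - 1))
  expect_equal(cw$values[1], 0)
})

test_that("travel speed scores directed drift and cancels lateral wobble", {
  ## rigid drift of a straight worm: v * fps / L body lengths per second
  L <- 60; fps <- 18; v <- 2
  frames <- lapply(1:120, function(t)
    centerline(cbind(seq(0, L, length.out = 25) + v * t, 40), 2, t))
  ck <- const_clock(12, 120, fps)
  ts <- travel_speed(swim_track(frames), ck, fps)
  expect_equal(ts$median, v * fps / L, tolerance = 0.02)

  ## undulation in place: ~0
  sim0 <- simulate(swim_scenario(duration_s = 10, seed = 2))
  tr0 <- swim_trial(sim0$track)
  expect_lt(tr0$measures$travel_speed$median, 0.03)

  ## undulation + drift: same as pure drift within 5%
  simd <- simulate(swim_scenario(duration_s = 15, drift_v = 0.25, seed = 2),
                   base = c(30, 80))
  trd <- swim_trial(simd$track)
  expect_lt(abs(trd$measures$travel_speed$median - 0.25), 0.05 * 0.25)
})

test_that("brush stroke measures painted area in body areas and is scale invariant", {
  ## frozen, non-translating worm paints only itself
  frames <- lapply(1:60, function(t)
    centerline(cbind(seq(0, 60, length.out = 49), 30), 3, t))
  ck <- const_clock(12, 60)
  expect_equal(brush_stroke(swim_track(frames), ck)$median, 0,
               tolerance = 0.02)

  ## straight worm rotating about its center sweeps a disc of radius L/2
  ## over two strokes: union/body - 1, vs analytic areas
  L <- 60; r <- 2; T_ <- 180
  rot <- lapply(1:T_, function(t) {
    ang <- pi * (t - 1) / 90          # half-turn per 90 frames
    d <- c(cos(ang), sin(ang))
    s <- seq(-L / 2, L / 2, length.out = 49)
    centerline(cbind(100 + s * d[1], 100 + s * d[2]), r, t)
  })
  ck2 <- const_clock(90, T_)          # two strokes = 180 frames = full turn
  bs <- brush_stroke(swim_track(rot), ck2)
  expected <- (pi * (L / 2)^2) / (2 * r * L) - 1
  expect_equal(bs$values[90], expected, tolerance = 0.05 * expected)

  ## 2x spatial scale: identical within 2%
  rot2 <- lapply(rot, function(f) centerline(f$points * 2,
                                             f$half_widths * 2,
                                             f$frame_index))
  bs2 <- brush_stroke(swim_track(rot2), ck2)
  expect_equal(bs2$values[90], bs$values[90],
               tolerance = 0.02 * abs(bs$values[90]))
})

test_that("activity index is brush stroke per two-stroke time", {
  b <- measure_series("brush_stroke", rep(1, 50), "body areas")
  ck <- const_clock(9, 50, 18)
  ai <- activity_index(b, ck, 18)
  expect_equal(ai$median, 1.0)
  b0 <- measure_series("brush_stroke", rep(0, 50), "body areas")
  expect_equal(activity_index(b0, ck, 18)$median, 0)
  ## doubling stroke frequency (halving D) doubles the index
  expect_equal(activity_index(b, const_clock(4.5, 50, 18), 18)$median, 2.0)
})

test_that("trial summaries are robust medians with 10-90 percentile ranges", {
  s_const <- measure_series("x", rep(4.2, 100), "u")
  expect_equal(c(s_const$p10, s_const$median, s_const$p90), rep(4.2, 3))

  ## alternating 60/120: median and percentiles between the two values
  v <- rep(c(60, 120), 50)
  s_alt <- measure_series("x", v, "u")
  expect_gte(s_alt$median, 60); expect_lte(s_alt$median, 120)
  cnt <- tabulate(factor(round(v), levels = 50:130))
  expect_equal(sum(cnt > 0), 2L)

  ## 10% outliers at 10x: median unmoved, mean would shift
  set.seed(1)
  v2 <- c(rep(10, 90), rep(100, 10))
  s_out <- measure_series("x", v2, "u")
  expect_equal(s_out$median, 10)
  expect_gt(mean(v2), 15)

  ## invalid frames never contribute to summaries
  v3 <- c(rep(5, 50), rep(1e6, 50))
  s_mask <- measure_series("x", v3, "u",
                           valid = c(rep(TRUE, 50), rep(FALSE, 50)))
  expect_equal(s_mask$median, 5)
  expect_equal(s_mask$n, 50L)
})

test_that("summarize_trial errors name the cause of emptiness", {
  map_bad <- raw_map(matrix(1, 12, 10), valid = rep(FALSE, 10))
  modes <- spectral_modes(raw_map(matrix(0, 12, 10)))
  clock <- stroke_clock(modes)
  expect_error(summarize_trial(NULL, map_bad, modes, clock), "invalid")
  map_ok <- raw_map(matrix(0, 12, 10))
  expect_error(summarize_trial(NULL, map_ok, modes, clock),
               "no dominant wave mode")
})

test_that("head-tail relabeling flips reverse %, asymmetry sign and f_t sign", {
  scn <- swim_scenario(bias_c = 0.5, reverse_episodes = list(c(100, 189)),
                       duration_s = 15, seed = 6)
  sim <- simulate(scn)
  fwd <- swim_trial(sim$track, auto_orient = FALSE)
  back <- swim_trial(flip_head_tail(sim$track), auto_orient = FALSE)
  p <- fwd$reverse_fraction
  expect_equal(back$reverse_fraction, 100 - p, tolerance = 1.5)
  expect_equal(back$measures$asymmetry$median,
               -fwd$measures$asymmetry$median, tolerance = 0.05)
  ## tail and head quarters swap in the attenuation ratio
  a_fwd <- fwd$summary$score[fwd$summary$measure == "attenuation"]
  a_back <- back$summary$score[back$summary$measure == "attenuation"]
  expect_equal(a_back, 0, tolerance = 2)  # symmetric envelope: both ~0
  expect_equal(a_fwd, 0, tolerance = 2)
  ## a trial dominated by reverse swimming is auto-swapped
  scn_r <- swim_scenario(reverse_episodes = list(c(1, 400)),
                         duration_s = 30, seed = 6)
  sim_r <- simulate(scn_r)
  tri <- swim_trial(sim_r$track)
  expect_true(tri$head_tail_swapped)
  expect_lt(tri$reverse_fraction, 50)
})

test_that("measures recover a composite scenario's ground truth end to end", {
  scn <- swim_scenario(f = 1.5, n = 1.5, A = 3, bias_c = 0.5,
                       attenuation_alpha = 0.5,
                       reverse_episodes = list(c(200, 289)),
                       curl_episodes = list(list(frames = c(400, 453),
                                                 shape = "O")),
                       drift_v = 0.2, seed = 3)
  sim <- simulate(scn, base = c(50, 50), heading = 0.3)
  sc <- coef(swim_trial(sim$track))
  tru <- sim$truth
  expect_lt(abs(sc[["wave_initiation_rate"]] - tru$wave_initiation_rate),
            0.05 * tru$wave_initiation_rate)
  expect_lt(abs(sc[["body_wave_number"]] - tru$body_wave_number), 0.1)
  expect_lt(abs(sc[["asymmetry"]] - tru$asymmetry),
            0.1 * abs(tru$asymmetry))
  expect_lt(abs(sc[["stretch"]] - tru$stretch), 0.1 * tru$stretch)
  expect_lt(abs(sc[["attenuation"]] - tru$attenuation), 7)
  expect_lt(abs(sc[["reverse_swimming"]] - tru$reverse_swimming), 3)
  expect_lt(abs(sc[["curling"]] - tru$curling), 3)
  expect_lt(abs(sc[["travel_speed"]] - tru$travel_speed),
            0.05 * tru$travel_speed)
})
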