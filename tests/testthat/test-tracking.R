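test_that("segmentation finds nothing in noise and every animal in a clean scene", {
  set.seed(3)
  blank <- matrix(0.9 + 0.05 * rnorm(160 * 120), 160, 120)
  seg <- segment_frame(blank, track_params(expected_count = 2), 1L)
  expect_length(seg$centerlines, 0L)

  scene <- five_worm_scene(duration_s = 0.2)
  seg5 <- segment_frame(scene$video[, , 1], track_params(expected_count = 5),
                        1L)
  expect_length(seg5$centerlines, 5L)
  ## each matched to its generating animal by centroid, within 1 px mean
  for (cl in seg5$centerlines) {
    j <- which.min(vapply(scene$sims, function(s)
      sum((body_center(s$track$frames[[1]]) - body_center(cl))^2),
      numeric(1)))
    expect_lt(dev_pp(cl, scene$sims[[j]]$track$frames[[1]]), 1)
  }
})

test_that("track_step is the identity on a static animal and follows a moving one", {
  sim <- simulate(swim_scenario(duration_s = 0.5, noise_sigma = 0, seed = 4),
                  base = c(60, 80), heading = 0.3)
  vid <- render_video(sim, width = 220, height = 200, noise_sigma = 0)
  prev <- resample_centerline(sim$track$frames[[1]], 25L)
  prev$frame_index <- 1L
  ## identical frames: output equals input to sub-pixel
  same <- track_step(prev, vid[, , 1], vid[, , 1])
  expect_lt(dev_pp(same, prev), 0.5)
  ## one wave phase ahead at 18 fps: within 1 px of truth
  stepped <- track_step(prev, vid[, , 1], vid[, , 2])
  expect_lt(dev_pp(stepped, sim$track$frames[[2]]), 1)
})

test_that("keyframe merge corrects accumulated tracking drift", {
  sim <- simulate(swim_scenario(duration_s = 0.2, noise_sigma = 0, seed = 5),
                  base = c(60, 80), heading = 0.3)
  vid <- render_video(sim, width = 220, height = 200, noise_sigma = 0)
  img <- vid[, , 1]
  truth <- resample_centerline(sim$track$frames[[1]], 25L)
  seg <- segment_frame(img, track_params(expected_count = 1), 1L)

  ## perfect tracking: merge is a near no-op
  merged0 <- keyframe_merge(truth, seg$centerlines[[1]], img)
  expect_lt(dev_pp(merged0, truth), 0.7)

  ## tracked centerline drifted 3 px: post-merge error < 1 px
  drifted <- centerline(truth$points + 3, truth$half_widths,
                        truth$frame_index)
  merged <- keyframe_merge(drifted, seg$centerlines[[1]], img)
  expect_lt(dev_pp(merged, truth), 1)
})

test_that("five clean swimmers track within a pixel and are never rejected", {
  scene <- five_worm_scene(duration_s = 5)
  tracks <- track_swimmers(scene$video, 18, track_params(expected_count = 5))
  expect_length(tracks, 5L)
  n_f <- length(tracks[[1]]$frames)
  all_devs <- c()
  for (tr in tracks) {
    j <- match_track_to_sim(tr, scene$sims)
    devs <- vapply(seq_len(n_f), function(t)
      dev_pp(tr$frames[[t]], scene$sims[[j]]$track$frames[[t]]), numeric(1))
    all_devs <- c(all_devs, devs)
    expect_false(tr$rejected)
  }
  expect_gte(mean(all_devs <= 1), 0.95)

  ## determinism: identical video and config give identical output
  tracks2 <- track_swimmers(scene$video, 18, track_params(expected_count = 5))
  expect_identical(lapply(tracks, function(t) t$frames),
                   lapply(tracks2, function(t) t$frames))
})

test_that("quality checker applies the 2-SD length rule and the 20% rejection rule", {
  mk_track <- function(short_frac) {
    T_ <- 100L
    n_short <- round(short_frac * T_)
    lens <- c(rep(60, T_ - n_short), rep(30, n_short))
    swim_track(lapply(seq_len(T_), function(t)
      centerline(cbind(seq(0, lens[t], length.out = 25), 50), 2, t)))
  }
  ok <- quality_check(mk_track(0))
  expect_equal(nrow(ok$flags), 0L)
  expect_false(ok$rejected)

  rej <- quality_check(mk_track(0.30))
  expect_equal(nrow(rej$flags), 30L)
  expect_true(all(rej$flags$flag_type == "length"))
  expect_true(rej$rejected)

  acc <- quality_check(mk_track(0.10))
  expect_equal(nrow(acc$flags), 10L)
  expect_false(acc$rejected)           # 0.10 <= 0.20: kept

  ## manual overrides flip frames and the whole-animal verdict
  manual <- quality_check(mk_track(0.30),
                          overrides = data.frame(frame = 0,
                                                 new_validity = TRUE))
  expect_false(manual$rejected)
  one <- quality_check(mk_track(0),
                       overrides = data.frame(frame = 7,
                                              new_validity = FALSE))
  expect_false(one$frames[[7]]$valid)
  expect_equal(one$flags$source, "manual")
})

test_that("head-tail orientation flips only above 50% reverse", {
  sim <- simulate(swim_scenario(duration_s = 1, seed = 6))
  t10 <- orient_head_tail(sim$track, 10)
  expect_false(t10$head_tail_swapped)
  t90 <- orient_head_tail(sim$track, 90)
  expect_true(t90$head_tail_swapped)
  expect_equal(t90$frames[[1]]$points,
               sim$track$frames[[1]]$points[
                 nrow(sim$track$frames[[1]]$points):1, ],
               ignore_attr = TRUE)
  t50 <- orient_head_tail(sim$track, 50)
  expect_false(t50$head_tail_swapped)  # strict inequality at the boundary
})

test_that("contact handling flags crossings and self-overlap, sparing distant animals", {
  ## two far-apart straight worms: no flags
  mk <- function(y, x0 = 0) swim_track(lapply(1:10, function(t)
    centerline(cbind(seq(x0, x0 + 60, length.out = 25), y), 3, t)))
  none <- handle_contacts(list(mk(20), mk(120)), track_params(), 18)
  expect_false(any(none))

  ## two worms crossing during frames 4-7: both flagged there
  worm_a <- swim_track(lapply(1:10, function(t)
    centerline(cbind(seq(0, 60, length.out = 25), 60), 3, t)))
  y_b <- c(200, 160, 120, 70, 60, 60, 70, 120, 160, 200)
  worm_b <- swim_track(lapply(1:10, function(t)
    centerline(cbind(30, seq(y_b[t] - 30, y_b[t] + 30, length.out = 25)),
               3, t)))
  flags <- handle_contacts(list(worm_a, worm_b), track_params(), 18)
  expect_true(all(flags[4:7, 1]))
  expect_true(all(flags[4:7, 2]))
  expect_false(any(flags[c(1, 10), ]))

  ## a tightly curled O overlaps itself
  curl <- swim_track(list(integrate_posture(rep(2 * pi, 12), 60,
                                            half_widths = 3,
                                            frame_index = 1)))
  expect_true(handle_contacts(list(curl), track_params(), 18)[1, 1])
})

test_that("measures agree between ground-truth and tracked centerlines", {
  ## 20 s trial: the agreement under test is the systematic one, and the
  ## per-trial sampling noise of a 10 s median (~0.02 on the wave number)
  ## is a visible fraction of the agreement tolerances
  scn <- swim_scenario(f = 1.5, n = 1.5, A = 3, bias_c = 0.4,
                       noise_sigma = 0.05, duration_s = 20, seed = 12)
  sim <- simulate(scn, base = c(80, 90), heading = 0.5)
  vid <- render_video(sim, width = 300, height = 260, noise_sigma = 0.05,
                      seed = 12)
  tracks <- track_swimmers(vid, 18, track_params(expected_count = 1))
  expect_length(tracks, 1L)
  tr_true <- coef(swim_trial(sim$track))
  tr_est <- coef(swim_trial(tracks[[1]]))
  expect_lt(abs(tr_est[["wave_initiation_rate"]] -
                tr_true[["wave_initiation_rate"]]),
            0.05 * tr_true[["wave_initiation_rate"]])
  expect_lt(abs(tr_est[["body_wave_number"]] -
                tr_true[["body_wave_number"]]), 0.1)
  expect_lt(abs(tr_est[["asymmetry"]] - tr_true[["asymmetry"]]),
            0.1 * abs(tr_true[["asymmetry"]]))
  expect_lt(abs(tr_est[["stretch"]] - tr_true[["stretch"]]),
            0.1 * tr_true[["stretch"]])
  expect_lt(abs(tr_est[["reverse_swimming"]] -
                tr_true[["reverse_swimming"]]), 3)
})
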