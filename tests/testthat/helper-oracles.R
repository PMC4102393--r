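# Shared fixtures and independent oracles, built in code.

# mean point-to-point deviation between two centerlines after arc-length
# resampling, minimized over head/tail orientation
dev_pp <- function(est, tru, n = 49L) {
  est <- resample_centerline(est, n)
  tru <- resample_centerline(tru, n)
  min(mean(sqrt(rowSums((est$points - tru$points)^2))),
      mean(sqrt(rowSums((est$points[n:1, ] - tru$points)^2))))
}

# brute-force 2D DFT magnitude of a (already tapered/demeaned) patch on
# the same frequency raster as stft2d: direct summation, no FFT
bf_dft_mag <- function(patch, fs, ft, frame_rate, n_segments = 12L) {
  s <- (seq_len(nrow(patch)) - 1L) / n_segments      # body lengths
  tt <- (seq_len(ncol(patch)) - 1L) / frame_rate     # seconds
  mag <- matrix(NA_real_, length(fs), length(ft))
  for (i in seq_along(fs)) for (j in seq_along(ft)) {
    ph <- outer(s * fs[i], tt * ft[j], `+`)
    mag[i, j] <- Mod(sum(patch * exp(-2i * pi * ph)))
  }
  mag
}

# the tapering stft2d applies (patch demean + temporal Hann), reproduced
# independently for the oracle
taper_patch <- function(patch) {
  patch <- patch - mean(patch)
  w <- ncol(patch)
  han <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1L)) / (w - 1L))
  sweep(patch, 2L, han, `*`)
}

# curvature map object from raw values (bypasses geometry)
raw_map <- function(values, frame_rate = 18, valid = rep(TRUE, ncol(values)),
                    L = 60) {
  structure(list(values = values, frame_rate = frame_rate,
                 valid_frames = valid,
                 body_length_px = rep(L, ncol(values)),
                 n_segments = nrow(values)),
            class = "curvature_map")
}

# a stroke clock with constant duration D over T frames (for unit tests
# of window-based measures on constructed maps)
const_clock <- function(D, T_, frame_rate = 18) {
  structure(list(duration = rep(D, T_),
                 lo = pmax(1L, as.integer(ceiling(seq_len(T_) - D))),
                 hi = pmin(T_, as.integer(ceiling(seq_len(T_) + D)) - 1L),
                 defined = rep(TRUE, T_), frame_rate = frame_rate,
                 any_defined = TRUE),
            class = "stroke_clock")
}

# standard five-worm scene used by tracking tests
five_worm_scene <- function(duration_s = 10, noise_sigma = 0.05,
                            seed = 11L) {
  fs <- c(1.0, 1.5, 2.0, 0.8, 1.2)
  ns <- c(1.2, 1.5, 1.8, 1.5, 1.0)
  bases <- list(c(50, 60), c(230, 60), c(50, 230), c(230, 230), c(140, 145))
  heads <- c(0.3, 2.2, -0.8, 1.2, 2.9)
  sims <- lapply(1:5, function(i)
    simulate(swim_scenario(f = fs[i], n = ns[i], noise_sigma = noise_sigma,
                           seed = i, duration_s = duration_s),
             base = bases[[i]], heading = heads[i]))
  vid <- render_video(lapply(sims, function(s) s$track),
                      width = 360, height = 330,
                      noise_sigma = noise_sigma, seed = seed)
  list(sims = sims, video = vid)
}

match_track_to_sim <- function(track, sims) {
  c0 <- body_center(track$frames[[1]])
  which.min(vapply(sims, function(s)
    sum((body_center(s$track$frames[[1]]) - c0)^2), numeric(1)))
}
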