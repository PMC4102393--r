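#' Synthetic swim scenario
#'
#' Describes a synthetic swimmer in curvature space: a traveling sinusoidal
#' curvature wave with configurable temporal frequency, body wavenumber,
#' amplitude, amplitude envelope (attenuation), constant curvature bias
#' (asymmetry), reversal and curling episodes, and translational drift.
#' Because all behavioral measures are defined on the curvature kymograph,
#' synthesising in curvature space makes the ground-truth measure values
#' exact by construction; no hydrodynamics is modelled.
#'
#' The amplitude envelope is \code{1 - attenuation_alpha} over the tail
#' quarter (s <= 0.25), 1 over the head quarter (s >= 0.75), and a linear
#' ramp in between, so that the attenuation measure (tail-quarter vs
#' head-quarter curvature range) equals \code{100 * attenuation_alpha}
#' exactly.
#'
#' @param f wave temporal frequency, Hz.
#' @param n body wave number, cycles per body length.
#' @param A curvature amplitude, dimensionless (per body length).
#' @param bias_c constant curvature offset (asymmetry), dimensionless.
#' @param attenuation_alpha tail amplitude deficit fraction in [0, 1].
#' @param reverse_episodes list of length-2 integer vectors
#'   \code{c(first_frame, last_frame)} (1-based, inclusive) during which the
#'   wave travels tail-to-head.
#' @param curl_episodes list of \code{list(frames = c(first, last),
#'   shape = "O" | "six")} postural overrides.
#' @param drift_v translation speed, body lengths per second.
#' @param drift_dir drift direction, radians in image coordinates.
#' @param L_px body length in pixels.
#' @param half_width_max maximal body half-width in pixels (the half-width
#'   profile is \code{half_width_max * sin(pi*s)^0.5}, tapering to 0 at the
#'   tips).
#' @param fps frames per second.
#' @param duration_s trial duration, seconds.
#' @param noise_sigma additive Gaussian pixel noise s.d. for rendering.
#' @param contrast worm darkness below background for rendering (in [0,1]).
#' @param seed integer seed (mandatory; reproducibility contract).
#' @return An object of class \code{"swim_scenario"}.
#' @export
swim_scenario <- function(f = 1.5, n = 1.5, A = 3, bias_c = 0,
                          attenuation_alpha = 0,
                          reverse_episodes = list(),
                          curl_episodes = list(),
                          drift_v = 0, drift_dir = 0,
                          L_px = 60, half_width_max = 3,
                          fps = 18, duration_s = 30,
                          noise_sigma = 0.05, contrast = 0.5,
                          seed = 1L) {
  stopifnot(is.finite(f), is.finite(n), is.finite(A), is.finite(bias_c),
            attenuation_alpha >= 0, attenuation_alpha <= 1,
            fps > 0, duration_s > 0, L_px > 0, !is.null(seed))
  n_frames <- round(fps * duration_s)
  all_eps <- c(lapply(reverse_episodes, identity),
               lapply(curl_episodes, function(e) e$frames))
  for (e in all_eps) {
    if (length(e) != 2L || e[1] > e[2] || e[1] < 1L || e[2] > n_frames)
      stop("episode out of trial bounds: [", e[1], ", ", e[2], "]")
  }
  if (length(all_eps) > 1L) {
    m <- do.call(rbind, all_eps)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("episodes overlap")
  }
  structure(list(f = f, n = n, A = A, bias_c = bias_c,
                 attenuation_alpha = attenuation_alpha,
                 reverse_episodes = reverse_episodes,
                 curl_episodes = curl_episodes,
                 drift_v = drift_v, drift_dir = drift_dir,
                 L_px = L_px, half_width_max = half_width_max,
                 fps = fps, duration_s = duration_s, n_frames = n_frames,
                 noise_sigma = noise_sigma, contrast = contrast,
                 seed = as.integer(seed)),
            class = "swim_scenario")
}

#' @export
print.swim_scenario <- function(x, ...) {
  cat(sprintf(
    "<swim_scenario> f=%g Hz, n=%g, A=%g, bias=%g, alpha=%g, drift=%g BL/s\n",
    x$f, x$n, x$A, x$bias_c, x$attenuation_alpha, x$drift_v))
  cat(sprintf("  %g s @ %g fps (%d frames), L=%g px, seed=%d\n",
              x$duration_s, x$fps, x$n_frames, x$L_px, x$seed))
  invisible(x)
}

.in_episodes <- function(frames, episodes) {
  out <- logical(frames)
  for (e in episodes) out[e[1]:e[2]] <- TRUE
  out
}

.envelope <- function(s, alpha) {
  e <- rep(1, length(s))
  lo <- s <= 0.25
  mid <- s > 0.25 & s < 0.75
  e[lo] <- 1 - alpha
  e[mid] <- 1 - alpha * (0.75 - s[mid]) / 0.5
  e
}

.half_width_profile <- function(s, half_width_max) {
  half_width_max * sqrt(pmax(sin(pi * s), 0))
}

#' Ground-truth curvature kymograph for a scenario
#'
#' Evaluates the scenario's curvature wave at the 12 body-segment
#' midpoints for every frame. The wave phase advances as
#' \code{2*pi*f*sigma(t)*dt} with \code{sigma = -1} inside reversal
#' episodes, so phase is continuous across direction switches. Curl
#' episodes override the wave with a constant "O" posture
#' (\code{kappa_hat = 2*pi}) or a "6" posture (straight tail half, tightly
#' bent head half).
#'
#' @param scn a \code{\link{swim_scenario}}.
#' @param n_segments number of body segments (12).
#' @return List with \code{map} (a \code{curvature_map}), \code{truth}
#'   (named list of ground-truth measure values) and \code{curled},
#'   \code{reversed} per-frame logical vectors.
#' @export
generate_curvature <- function(scn, n_segments = 12L) {
  stopifnot(inherits(scn, "swim_scenario"))
  T_ <- scn$n_frames
  s_mid <- (seq_len(n_segments) - 0.5) / n_segments
  reversed <- .in_episodes(T_, scn$reverse_episodes)
  curled <- .in_episodes(T_, lapply(scn$curl_episodes, `[[`, "frames"))
  dt <- 1 / scn$fps
  sigma <- ifelse(reversed, -1, 1)
  ## phase at frame i corresponds to time (i-1)*dt; continuous across switches
  phase <- 2 * pi * scn$f * c(0, cumsum(sigma[-T_] * dt))
  env <- .envelope(s_mid, scn$attenuation_alpha)
  values <- matrix(NA_real_, n_segments, T_)
  for (t in seq_len(T_)) {
    values[, t] <- scn$A * env * sin(2 * pi * scn$n * s_mid + phase[t]) +
      scn$bias_c
  }
  for (e in scn$curl_episodes) {
    idx <- e$frames[1]:e$frames[2]
    prof <- if (identical(e$shape, "O")) rep(2 * pi, n_segments)
            else ifelse(s_mid < 0.5, 0, 4 * pi)
    values[, idx] <- prof
  }
  truth <- list(
    wave_initiation_rate = 60 * scn$f,
    body_wave_number = scn$n,
    asymmetry = scn$bias_c,
    stretch = 2 * scn$A,
    attenuation = 100 * scn$attenuation_alpha,
    reverse_swimming = 100 * mean(reversed),
    curling = 100 * mean(curled),
    travel_speed = abs(scn$drift_v))
  map <- structure(list(values = values, frame_rate = scn$fps,
                        valid_frames = rep(TRUE, T_),
                        body_length_px = rep(scn$L_px, T_),
                        n_segments = n_segments),
                   class = "curvature_map")
  list(map = map, truth = truth, curled = curled, reversed = reversed)
}

#' Reconstruct a posture from one kymograph column
#'
#' Integrates the tangent angle (d theta / d s = kappa_hat / L) over arc
#' length, treating each of the 12 segment curvatures as constant over its
#' segment, then integrates the tangent to obtain positions. The tail point
#' is placed at \code{base} and the initial tangent at angle
#' \code{heading}.
#'
#' @param kappa numeric vector of segment curvatures (dimensionless).
#' @param L_px body length in pixels.
#' @param base length-2 tail position (pixels).
#' @param heading initial tangent angle, radians.
#' @param half_widths per-point half-widths, or a single maximal value fed
#'   to the default tapered profile.
#' @param n_sub substeps per segment (output has
#'   \code{length(kappa)*n_sub + 1} points).
#' @param frame_index,valid stored in the returned centerline.
#' @return A \code{\link{centerline}}.
#' @export
integrate_posture <- function(kappa, L_px, base = c(0, 0), heading = 0,
                              half_widths = 3, n_sub = 8L,
                              frame_index = NA_integer_, valid = TRUE) {
  n_seg <- length(kappa)
  n_pts <- n_seg * n_sub + 1L
  ds <- 1 / (n_seg * n_sub)                 # in body lengths
  k_fine <- rep(kappa, each = n_sub)        # constant within each segment
  ## theta at substep midpoints (midpoint rule keeps arcs exact)
  theta_mid <- heading + (cumsum(k_fine) - k_fine / 2) * ds
  step <- L_px * ds
  x <- base[1] + c(0, cumsum(step * cos(theta_mid)))
  y <- base[2] + c(0, cumsum(step * sin(theta_mid)))
  s <- seq(0, 1, length.out = n_pts)
  hw <- if (length(half_widths) == n_pts) half_widths
        else .half_width_profile(s, half_widths[1])
  centerline(cbind(x, y), hw, frame_index, valid)
}

#' Simulate a ground-truth swimmer track from a scenario
#'
#' @param object a \code{\link{swim_scenario}}.
#' @param nsim number of replicates (tracks are deterministic given the
#'   scenario; replicates differ only when rendered with noise).
#' @param seed optional override of the scenario seed.
#' @param base starting tail position in pixels.
#' @param heading initial heading, radians.
#' @param ... unused.
#' @return For \code{nsim = 1} a \code{"swim_sim"} list with \code{track}
#'   (a \code{\link{swim_track}}), \code{map}, \code{truth} and the
#'   \code{scenario}; otherwise a list of such objects.
#' @export
simulate.swim_scenario <- function(object, nsim = 1, seed = NULL,
                                   base = c(0, 0), heading = 0, ...) {
  scn <- object
  if (!is.null(seed)) scn$seed <- as.integer(seed)
  one <- function(k) {
    gc_ <- generate_curvature(scn)
    dir <- c(cos(scn$drift_dir), sin(scn$drift_dir))
    frames <- vector("list", scn$n_frames)
    for (t in seq_len(scn$n_frames)) {
      b <- base + dir * scn$drift_v * scn$L_px * (t - 1) / scn$fps
      frames[[t]] <- integrate_posture(gc_$map$values[, t], scn$L_px,
                                       base = b, heading = heading,
                                       half_widths = scn$half_width_max,
                                       frame_index = t)
    }
    structure(list(track = swim_track(frames, scn$fps,
                                      sprintf("sim%d", k)),
                   map = gc_$map, truth = gc_$truth,
                   curled = gc_$curled, reversed = gc_$reversed,
                   scenario = scn),
              class = "swim_sim")
  }
  if (nsim == 1L) one(1L) else lapply(seq_len(nsim), one)
}

#' @export
print.swim_sim <- function(x, ...) {
  cat("<swim_sim> ground-truth synthetic swimmer\n")
  print(x$scenario)
  invisible(x)
}

## run code with a private RNG stream, restoring the global state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render swimmer tracks as a noisy grayscale video
#'
#' Draws each animal as a dark anti-aliased tube (centerline plus local
#' half-width) on a light background, applies a ~1 px Gaussian blur and
#' adds seeded Gaussian noise. Geometry is deterministic; only the noise
#' depends on the seed.
#'
#' @param tracks a \code{\link{swim_track}}, a \code{"swim_sim"}, or a list
#'   of either.
#' @param width,height image size in pixels.
#' @param noise_sigma additive Gaussian noise s.d.
#' @param contrast worm darkness below background.
#' @param background background intensity in [0, 1].
#' @param seed noise seed.
#' @param blur_sigma Gaussian blur s.d. in pixels.
#' @return A numeric array \code{width x height x n_frames} with values in
#'   [0, 1] (EBImage convention: first index x, second y).
#' @export
render_video <- function(tracks, width = 320, height = 240,
                         noise_sigma = 0.05, contrast = 0.5,
                         background = 0.9, seed = 1L, blur_sigma = 1) {
  if (inherits(tracks, "swim_sim")) tracks <- list(tracks$track)
  if (inherits(tracks, "swim_track")) tracks <- list(tracks)
  tracks <- lapply(tracks, function(x)
    if (inherits(x, "swim_sim")) x$track else x)
  n_frames <- length(tracks[[1]]$frames)
  frames <- array(background, dim = c(width, height, n_frames))
  for (t in seq_len(n_frames)) {
    img <- matrix(background, width, height)
    for (tr in tracks) {
      f <- tr$frames[[t]]
      pts <- f$points; hw <- f$half_widths
      if (any(pts[, 1] < 2 | pts[, 1] > width - 1 |
              pts[, 2] < 2 | pts[, 2] > height - 1))
        stop("worm out of bounds at frame ", t)
      x0 <- max(1L, floor(min(pts[, 1] - hw)) - 2L)
      x1 <- min(width, ceiling(max(pts[, 1] + hw)) + 2L)
      y0 <- max(1L, floor(min(pts[, 2] - hw)) - 2L)
      y1 <- min(height, ceiling(max(pts[, 2] + hw)) + 2L)
      gx <- x0:x1; gy <- y0:y1
      X <- matrix(gx, length(gx), length(gy))
      Y <- matrix(gy, length(gx), length(gy), byrow = TRUE)
      field <- matrix(Inf, length(gx), length(gy))
      for (i in seq_len(nrow(pts))) {
        d <- sqrt((X - pts[i, 1])^2 + (Y - pts[i, 2])^2) - hw[i]
        field <- pmin(field, d)
      }
      alpha <- pmin(pmax(0.5 - field, 0), 1)
      img[gx, gy] <- pmin(img[gx, gy], background - contrast * alpha)
    }
    if (blur_sigma > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
    frames[, , t] <- img
  }
  if (noise_sigma > 0) {
    frames <- .with_seed(seed, {
      frames + array(stats::rnorm(length(frames), 0, noise_sigma), dim(frames))
    })
  }
  frames[frames < 0] <- 0; frames[frames > 1] <- 1
  frames
}

#' Write rendered frames as a multi-page TIFF
#'
#' @param frames array from \code{\link{render_video}}.
#' @param path output file path.
#' @export
write_video_tiff <- function(frames, path) {
  img <- EBImage::Image(frames, colormode = "Grayscale")
  EBImage::writeImage(img, path, type = "tiff")
  invisible(path)
}

#' Read a multi-page TIFF video into a frame array
#'
#' @param path TIFF file path.
#' @return Numeric array width x height x n_frames.
#' @export
read_video_tiff <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a
}
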