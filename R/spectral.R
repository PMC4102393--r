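#' @name spectral
#' @title Short-time 2D Fourier analysis of the curvature kymograph
#'
#' @description
#' Swimming C. elegans carry a single traveling curvature wave whose
#' temporal frequency and body wavenumber drift over a trial, so a static
#' whole-trial Fourier transform is unsuitable. Instead, a short-time 2D
#' Fourier transform of the 12 x window curvature patch is computed at
#' every frame for five window lengths (32, 40, 48, 56, 64 frames),
#' resampled onto one fixed frequency raster by zero-padding (64 spatial x
#' 256 temporal bins), and averaged. The dominant mode of the averaged
#' magnitude spectrum gives the instantaneous spatial frequency f_s
#' (cycles per body length) and signed temporal frequency f_t (Hz):
#' f_t > 0 is forward (head-to-tail) wave travel, f_t < 0 reverse.
#' Because curvature is real the full-plane spectrum is centro-symmetric
#' and only the f_s >= 0 half-plane is retained.
NULL

.default_windows <- c(32L, 40L, 48L, 56L, 64L)

## frequency rasters for the fixed padded grid
.fs_axis <- function(n_segments = 12L, n_fs = 64L) {
  (0:(n_fs %/% 2)) * n_segments / n_fs        # cycles per body length, >= 0
}
.ft_axis <- function(frame_rate, n_ft = 256L) {
  idx <- 0:(n_ft - 1L)
  ifelse(idx <= n_ft %/% 2 - 1L, idx, idx - n_ft) * frame_rate / n_ft  # Hz
}

#' Short-time 2D Fourier magnitude spectrum at one frame
#'
#' Extracts the curvature patch of \code{window} frames centered on
#' \code{t} (clipped at trial edges), subtracts the patch mean, applies a
#' Hann taper along time (none along the 12-sample body axis), zero-pads
#' to the fixed 64 x 256 grid and returns the magnitude of the 2D DFT on
#' the f_s >= 0 half-plane. Invalid frames are zero-filled; the spectrum
#' is undefined when fewer than 8 or fewer than 25% of the window's frames
#' are valid.
#'
#' @param map a \code{curvature_map}.
#' @param t frame index (window center).
#' @param window window length in frames.
#' @param n_fs,n_ft padded grid sizes (spatial, temporal).
#' @return List with \code{mag} (33 x 256 magnitude matrix or NULL),
#'   \code{fs}, \code{ft} frequency axes, and \code{defined}.
#' @export
stft2d <- function(map, t, window, n_fs = 64L, n_ft = 256L) {
  stopifnot(inherits(map, "curvature_map"))
  T_ <- ncol(map$values)
  lo <- max(1L, t - window %/% 2L)
  hi <- min(T_, lo + window - 1L)
  lo <- max(1L, hi - window + 1L)
  idx <- lo:hi
  valid <- map$valid_frames[idx]
  fs <- .fs_axis(nrow(map$values), n_fs)
  ft <- .ft_axis(map$frame_rate, n_ft)
  if (sum(valid) < 8L || mean(valid) < 0.25)
    return(list(mag = NULL, fs = fs, ft = ft, defined = FALSE,
                window = window, t = t))
  patch <- map$values[, idx, drop = FALSE]
  patch[, !valid] <- 0
  patch <- patch - mean(patch[, valid])
  patch[, !valid] <- 0
  w <- length(idx)
  taper <- if (w > 1L) 0.5 - 0.5 * cos(2 * pi * (0:(w - 1L)) / (w - 1L)) else 1
  patch <- sweep(patch, 2L, taper, `*`)
  ## 2D DFT via FFT along time of the 12 rows, then along the padded body axis
  Pt <- matrix(0, n_ft, nrow(patch))
  Pt[seq_len(w), ] <- t(patch)
  Ft <- stats::mvfft(Pt)                       # n_ft x 12, FFT along time
  G <- matrix(0+0i, n_fs, n_ft)
  G[seq_len(nrow(patch)), ] <- t(Ft)
  F2 <- stats::mvfft(G)                        # FFT along body axis
  mag <- Mod(F2[seq_len(n_fs %/% 2 + 1L), , drop = FALSE])
  list(mag = mag, fs = fs, ft = ft, defined = TRUE, window = window, t = t)
}

#' Multi-window averaged short-time spectrum at one frame
#'
#' Pointwise arithmetic mean of the five single-window magnitude spectra
#' on the shared padded raster; windows falling off the trial edge use
#' their valid truncation. Undefined when all windows are undefined.
#'
#' @param map a \code{curvature_map}.
#' @param t frame index.
#' @param windows window lengths in frames.
#' @inheritParams stft2d
#' @return Same structure as \code{\link{stft2d}}.
#' @export
averaged_stft <- function(map, t, windows = .default_windows,
                          n_fs = 64L, n_ft = 256L) {
  acc <- NULL; n_ok <- 0L; fs <- NULL; ft <- NULL
  for (w in windows) {
    sp <- stft2d(map, t, w, n_fs, n_ft)
    fs <- sp$fs; ft <- sp$ft
    if (sp$defined) {
      acc <- if (is.null(acc)) sp$mag else acc + sp$mag
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L)
    return(list(mag = NULL, fs = fs, ft = ft, defined = FALSE, t = t))
  list(mag = acc / n_ok, fs = fs, ft = ft, defined = TRUE, t = t)
}

## parabolic sub-bin refinement around a discrete peak; returns offset in bins
.parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, off))
}

#' Dominant spectral mode of a magnitude spectrum
#'
#' Locates the argmax of the magnitude over f_s > 0 (the f_s = 0 line
#' carries the asymmetry/DC component, not the traveling wave) and refines
#' it by 2D parabolic interpolation. The mode is undefined when the mode
#' energy (squared magnitude summed over the 3 x 3 bin neighborhood of the
#' discrete peak, i.e. the parabolic stencil) is below \code{eps_mode}
#' times the total spectral energy of the half-plane; this marks quiescent
#' or curled frames as undefined instead of emitting junk frequencies.
#'
#' @param spectrum output of \code{\link{stft2d}} or
#'   \code{\link{averaged_stft}}.
#' @param eps_mode dominance threshold (fraction of total magnitude).
#' @return List with \code{f_s_star} (>= 0, cycles/body), \code{f_t_star}
#'   (signed, Hz), \code{magnitude}, \code{defined}.
#' @export
find_mode <- function(spectrum, eps_mode = 0.02) {
  undef <- list(f_s_star = NA_real_, f_t_star = NA_real_,
                magnitude = NA_real_, defined = FALSE)
  if (is.null(spectrum$mag) || !isTRUE(spectrum$defined)) return(undef)
  mag <- spectrum$mag
  total <- sum(mag)
  if (!is.finite(total) || total <= 0) return(undef)
  ## candidate bins: f_s > 0 and a strict local maximum along f_s
  ## (including against the f_s = 0 line). Leakage ridges shed by static
  ## posture content on the f_s = 0 line decay monotonically in f_s and
  ## so can never qualify; a traveling wave's lobe always does.
  n_fs <- nrow(mag); n_ft <- ncol(mag)
  inner <- 2:(n_fs - 1L)
  cand <- mag[inner, , drop = FALSE] > mag[inner - 1L, , drop = FALSE] &
          mag[inner, , drop = FALSE] >= mag[inner + 1L, , drop = FALSE]
  if (!any(cand)) return(undef)
  sub <- mag[inner, , drop = FALSE]
  sub[!cand] <- -Inf
  pk <- arrayInd(which.max(sub), dim(sub))
  i <- pk[1] + 1L; j <- pk[2]
  peak <- mag[i, j]
  ii <- max(1L, i - 1L):min(nrow(mag), i + 1L)
  jj <- ((j - 1L + (-1:1)) %% n_ft) + 1L
  if (sum(mag[ii, jj]^2) < eps_mode * sum(mag^2)) return(undef)
  dfs <- spectrum$fs[2] - spectrum$fs[1]
  dft <- abs(spectrum$ft[2] - spectrum$ft[1])
  ## spatial refinement (no wrap; skip at half-plane edges)
  off_s <- if (i > 2L && i < nrow(mag))
    .parabolic_offset(mag[i - 1L, j], peak, mag[i + 1L, j]) else 0
  ## temporal refinement with circular indexing across the Nyquist wrap
  jm <- if (j == 1L) n_ft else j - 1L
  jp <- if (j == n_ft) 1L else j + 1L
  off_t <- .parabolic_offset(mag[i, jm], peak, mag[i, jp])
  f_s <- spectrum$fs[i] + off_s * dfs
  f_t <- spectrum$ft[j] + off_t * dft
  list(f_s_star = f_s, f_t_star = f_t, magnitude = peak, defined = TRUE)
}

#' Per-frame dominant modes of a whole trial
#'
#' Runs the averaged multi-window short-time transform and mode extraction
#' at every frame of the kymograph.
#'
#' @param map a \code{curvature_map}.
#' @param windows window lengths in frames.
#' @param eps_mode mode dominance threshold.
#' @inheritParams stft2d
#' @return An object of class \code{"spectral_modes"}: data.frame with
#'   columns \code{frame, f_s, f_t, magnitude, defined}, with
#'   \code{frame_rate} attribute.
#' @export
spectral_modes <- function(map, windows = .default_windows, eps_mode = 0.02,
                           n_fs = 64L, n_ft = 256L) {
  stopifnot(inherits(map, "curvature_map"))
  T_ <- ncol(map$values)
  f_s <- f_t <- mg <- rep(NA_real_, T_)
  def <- logical(T_)
  for (t in seq_len(T_)) {
    sp <- averaged_stft(map, t, windows, n_fs, n_ft)
    m <- find_mode(sp, eps_mode)
    f_s[t] <- m$f_s_star; f_t[t] <- m$f_t_star
    mg[t] <- m$magnitude; def[t] <- m$defined
  }
  out <- data.frame(frame = seq_len(T_), f_s = f_s, f_t = f_t,
                    magnitude = mg, defined = def)
  attr(out, "frame_rate") <- map$frame_rate
  class(out) <- c("spectral_modes", "data.frame")
  out
}

#' Per-frame stroke duration and two-stroke windows
#'
#' One stroke is one full undulation cycle; its duration is the inverse of
#' the dominant temporal frequency, D(t) = frame_rate / |f_t*(t)| frames.
#' Frames without a defined mode inherit the nearest defined duration
#' (gap-fill), so window-based measures remain computable across brief
#' undefined runs; the frames themselves stay excluded from summaries.
#' The two-stroke window is the half-open frame interval [t - D, t + D)
#' clipped to the trial.
#'
#' @param modes a \code{\link{spectral_modes}} data.frame.
#' @param frame_rate frames per second (defaults to the modes attribute).
#' @return An object of class \code{"stroke_clock"}: list with
#'   \code{duration} (frames, NA when nothing is defined anywhere),
#'   \code{lo}, \code{hi} (inclusive integer window bounds), and
#'   \code{defined} (which frames had their own mode).
#' @export
stroke_clock <- function(modes, frame_rate = attr(modes, "frame_rate")) {
  stopifnot(inherits(modes, "spectral_modes"))
  T_ <- nrow(modes)
  dur <- rep(NA_real_, T_)
  def <- modes$defined & is.finite(modes$f_t) & abs(modes$f_t) > 0
  dur[def] <- frame_rate / abs(modes$f_t[def])
  if (any(def)) {
    idx <- which(def)
    near <- idx[pmax(1L, pmin(length(idx),
      findInterval(seq_len(T_), (idx[-length(idx)] + idx[-1]) / 2,
                   left.open = FALSE) + 1L))]
    dur <- dur[near]
  }
  lo <- pmax(1L, as.integer(ceiling(seq_len(T_) - dur)))
  hi <- pmin(T_, as.integer(ceiling(seq_len(T_) + dur)) - 1L)
  structure(list(duration = dur, lo = lo, hi = hi, defined = def,
                 frame_rate = frame_rate, any_defined = any(def)),
            class = "stroke_clock")
}
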