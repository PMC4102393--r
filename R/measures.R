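#' @name measures
#' @title The ten swim measures
#'
#' @description
#' Each measure is computed per frame, yielding a time series that tracks
#' the behavior as it happens; a trial is summarized by the temporal
#' median and the 10-90 percentile range over valid, defined frames
#' (medians because dynamic changes within a trial skew means away from
#' the most common behavior). Reverse swimming and curling are binary
#' categorical series summarized as percentage of time instead.
NULL

measure_names <- c("wave_initiation_rate", "body_wave_number", "asymmetry",
                   "stretch", "attenuation", "reverse_swimming", "curling",
                   "travel_speed", "brush_stroke", "activity_index")

#' Per-frame series of one measure with robust trial summary
#'
#' @param name measure identifier.
#' @param values per-frame numeric values, NA where undefined.
#' @param units unit string.
#' @param valid logical mask of frames allowed into the summary.
#' @return An object of class \code{"measure_series"} with \code{median},
#'   \code{p10}, \code{p90} computed over valid, defined frames by linear
#'   interpolation between order statistics.
#' @export
measure_series <- function(name, values, units, valid = !is.na(values)) {
  ok <- valid & !is.na(values)
  q <- if (any(ok)) stats::quantile(values[ok], c(0.1, 0.5, 0.9),
                                    names = FALSE, type = 7)
       else rep(NA_real_, 3)
  structure(list(name = name, values = values, units = units,
                 n = sum(ok), p10 = q[1], median = q[2], p90 = q[3]),
            class = "measure_series")
}

#' @export
print.measure_series <- function(x, ...) {
  cat(sprintf("<measure_series> %s [%s]: median %.3g (10-90%%: %.3g..%.3g, n=%d)\n",
              x$name, x$units, x$median, x$p10, x$p90, x$n))
  invisible(x)
}

## robust per-segment curvature range over a window: 5-95% quantile band.
## On a pure sinusoid this is 1.3% below the true peak-to-peak range, but
## unlike max - min it is immune to single-frame tracking glitches, which
## would otherwise inflate every window containing them.
.curv_range <- function(m) {
  apply(m, 1L, function(x)
    diff(stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 7)))
}

## frames of the two-stroke window [lo, hi] that are usable; a window is
## usable only if >= 50% of its frames are valid
.window_cols <- function(clock, t, valid) {
  cols <- clock$lo[t]:clock$hi[t]
  cols <- cols[valid[cols]]
  if (length(cols) < 0.5 * (clock$hi[t] - clock$lo[t] + 1L)) return(integer())
  cols
}

#' Wave initiation rate: body waves initiated per minute
#'
#' 60 times the magnitude of the dominant temporal frequency; counts
#' strokes initiated from either extremity (the sign, i.e. the direction
#' of travel, is ignored).
#'
#' @param modes a \code{\link{spectral_modes}} data.frame.
#' @return A \code{\link{measure_series}} in waves/minute.
#' @export
wave_initiation_rate <- function(modes) {
  v <- ifelse(modes$defined, 60 * abs(modes$f_t), NA_real_)
  measure_series("wave_initiation_rate", v, "waves/min")
}

#' Body wave number: wave cycles present on the body
#'
#' The dominant spatial frequency magnitude; below 1 a single wave
#' traverses the whole body before the next starts.
#'
#' @param modes a \code{\link{spectral_modes}} data.frame.
#' @return A \code{\link{measure_series}} in cycles per body length.
#' @export
body_wave_number <- function(modes) {
  v <- ifelse(modes$defined, abs(modes$f_s), NA_real_)
  measure_series("body_wave_number", v, "cycles/body")
}

#' Asymmetry: mean curvature over a two-stroke window
#'
#' Average signed curvature over all 12 segments and all valid frames of
#' the two-stroke window; positive when the body bends clockwise (seen on
#' screen) from tail to head. A perfectly symmetric swimmer scores 0. The
#' per-animal group statistic uses the absolute value of the median so
#' left- and right-biased animals do not cancel.
#'
#' @param map a \code{curvature_map}.
#' @param clock a \code{\link{stroke_clock}}.
#' @return A \code{\link{measure_series}}, dimensionless curvature.
#' @export
asymmetry <- function(map, clock) {
  T_ <- ncol(map$values)
  v <- rep(NA_real_, T_)
  if (clock$any_defined) {
    for (t in seq_len(T_)) {
      if (is.na(clock$duration[t])) next
      cols <- .window_cols(clock, t, map$valid_frames)
      if (length(cols)) v[t] <- mean(map$values[, cols])
    }
  }
  measure_series("asymmetry", v, "curvature",
                 valid = map$valid_frames & !is.na(v))
}

#' Stretch: largest curvature range of any body part over two strokes
#'
#' @inheritParams asymmetry
#' @return A \code{\link{measure_series}}, dimensionless curvature range.
#' @export
stretch <- function(map, clock) {
  T_ <- ncol(map$values)
  v <- rep(NA_real_, T_)
  if (clock$any_defined) {
    for (t in seq_len(T_)) {
      if (is.na(clock$duration[t])) next
      cols <- .window_cols(clock, t, map$valid_frames)
      if (!length(cols)) next
      v[t] <- max(.curv_range(map$values[, cols, drop = FALSE]))
    }
  }
  measure_series("stretch", v, "curvature",
                 valid = map$valid_frames & !is.na(v))
}

#' Attenuation: tail-quarter vs head-quarter curvature range deficit
#'
#' 100 * (1 - R_tail / R_head) where R_tail (R_head) is the maximum
#' curvature range among the tail-quarter (head-quarter) body segments
#' over the two-stroke window. 0% means the wave depth is fully maintained
#' tail-ward; 100% an active head with a motionless tail; negative values
#' (amplification) occur during reverse swimming. Undefined when the head
#' quarter itself is motionless (R_head below \code{eps_range}).
#'
#' @inheritParams asymmetry
#' @param eps_range guard against a motionless head (dimensionless
#'   curvature).
#' @return A \code{\link{measure_series}} in percent.
#' @export
attenuation <- function(map, clock, eps_range = 0.1) {
  T_ <- ncol(map$values)
  ns <- nrow(map$values)
  tail_rows <- seq_len(ns %/% 4)                 # lower quarter of the body
  head_rows <- (ns - ns %/% 4 + 1L):ns           # upper quarter
  ## light temporal smoothing before taking ranges: any uniform
  ## attenuation of the wave cancels in the tail/head ratio, but the
  ## inflation that frame noise adds to a quantile band does not -- it
  ## hits the small tail range harder than the large head range and
  ## biases the ratio upward
  vals <- t(apply(map$values, 1L, function(x) {
    z <- as.numeric(stats::filter(x, c(0.25, 0.5, 0.25)))
    z[is.na(z)] <- x[is.na(z)]
    z
  }))
  v <- rep(NA_real_, T_)
  if (clock$any_defined) {
    for (t in seq_len(T_)) {
      if (is.na(clock$duration[t])) next
      cols <- .window_cols(clock, t, map$valid_frames)
      if (!length(cols)) next
      rng <- .curv_range(vals[, cols, drop = FALSE])
      r_head <- max(rng[head_rows])
      if (r_head < eps_range) next
      v[t] <- 100 * (1 - max(rng[tail_rows]) / r_head)
    }
  }
  measure_series("attenuation", v, "%",
                 valid = map$valid_frames & !is.na(v))
}

#' Reverse swimming: tail-to-head wave travel
#'
#' A frame is in reverse when the dominant temporal frequency is negative
#' (the transform is restricted to f_s >= 0, so direction lives in the
#' sign of f_t). Summarized as the percentage of defined frames.
#'
#' @param modes a \code{\link{spectral_modes}} data.frame.
#' @return A \code{\link{measure_series}} of 0/1 values with an extra
#'   \code{percentage} field (NA when no frame has a defined mode).
#' @export
reverse_swimming <- function(modes) {
  v <- ifelse(modes$defined, as.numeric(modes$f_t < 0), NA_real_)
  out <- measure_series("reverse_swimming", v, "binary")
  out$percentage <- if (any(modes$defined)) 100 * mean(v[modes$defined])
                    else NA_real_
  out
}

#' Curling: self-overlapping "O"/"6" postures
#'
#' The curl score of a frame is the smaller, over the two extremities, of
#' the distance from the extremity tip to the nearest centerline point at
#' arc-length separation of at least half the body length. A frame is
#' curled when the score is at most L/3 (inclusive), which fires for an
#' "O" (tip near tip), a "6" (tip near mid-body) and shapes in between.
#'
#' @param track a \code{\link{swim_track}} or list of centerlines.
#' @return A \code{\link{measure_series}} of 0/1 values with
#'   \code{percentage} (share of valid frames curled) and \code{score}
#'   (per-frame distances in body lengths) fields.
#' @export
curling <- function(track) {
  frames <- if (inherits(track, "swim_track")) track$frames else track
  T_ <- length(frames)
  v <- score <- rep(NA_real_, T_)
  for (t in seq_len(T_)) {
    f <- frames[[t]]
    if (!f$valid) next
    fine <- if (nrow(f$points) >= 49L) f else resample_centerline(f, 49L)
    p <- fine$points
    n <- nrow(p)
    s <- seq(0, 1, length.out = n)
    d_tip <- function(tip_idx) {
      far <- abs(s - s[tip_idx]) >= 0.5
      if (!any(far)) return(Inf)
      min(sqrt((p[far, 1] - p[tip_idx, 1])^2 +
               (p[far, 2] - p[tip_idx, 2])^2))
    }
    L <- body_length(fine)
    score[t] <- min(d_tip(1L), d_tip(n)) / L
    v[t] <- as.numeric(score[t] <= 1 / 3)
  }
  out <- measure_series("curling", v, "binary")
  out$percentage <- if (any(!is.na(v))) 100 * mean(v[!is.na(v)]) else NA_real_
  out$score <- score
  out
}

## per-frame body centers (2 x T), NA columns on invalid/degenerate frames
.body_centers <- function(frames) {
  T_ <- length(frames)
  ctr <- matrix(NA_real_, 2L, T_)
  for (t in seq_len(T_)) {
    f <- frames[[t]]
    if (!f$valid) next
    c_ <- tryCatch(body_center(f), error = function(e) NULL)
    if (!is.null(c_)) ctr[, t] <- c_
  }
  ctr
}

## mean of centers over frames [max(1,a), min(T,b)] ignoring NA columns
.window_center <- function(ctr, a, b) {
  cols <- max(1L, a):min(ncol(ctr), b)
  m <- ctr[, cols, drop = FALSE]
  ok <- !is.na(m[1, ])
  if (!any(ok)) return(c(NA_real_, NA_real_))
  rowMeans(m[, ok, drop = FALSE])
}

#' Travel speed: directed displacement of the body center
#'
#' The body center (arc-length centroid) is averaged over one stroke
#' centered at t - D/2 and at t + D/2; the speed is the distance between
#' these two stroke-averaged centers per elapsed time, in body lengths per
#' second. Stroke-averaging cancels the lateral back-and-forth wobble of
#' the center so only directed travel is scored.
#'
#' @param track a \code{\link{swim_track}} or list of centerlines.
#' @param clock a \code{\link{stroke_clock}}.
#' @param frame_rate frames per second.
#' @return A \code{\link{measure_series}} in body lengths per second.
#' @export
travel_speed <- function(track, clock, frame_rate = clock$frame_rate) {
  frames <- if (inherits(track, "swim_track")) track$frames else track
  T_ <- length(frames)
  ctr <- .body_centers(frames)
  valid <- !is.na(ctr[1, ])
  L <- mean(vapply(frames[valid], body_length, numeric(1)))
  v <- rep(NA_real_, T_)
  if (clock$any_defined && is.finite(L) && L > 0) {
    for (t in seq_len(T_)) {
      D <- clock$duration[t]
      if (is.na(D)) next
      ## equal integer-length stroke windows: a fractional duration must
      ## not make one window a frame shorter than the other, or the
      ## periodic wobble of the center stops cancelling
      m <- max(1L, as.integer(round(D)))
      c1 <- .window_center(ctr, t - m, t - 1L)      # stroke at t - D/2
      c2 <- .window_center(ctr, t, t + m - 1L)      # stroke at t + D/2
      if (anyNA(c1) || anyNA(c2)) next
      v[t] <- sqrt(sum((c2 - c1)^2)) * frame_rate / (m * L)
    }
  }
  measure_series("travel_speed", v, "body lengths/s",
                 valid = valid & !is.na(v))
}

## rasterize a body tube (points + half-widths, already in raster units)
## into integer cell keys
.rasterize_tube <- function(p, r, nx) {
  rmax <- max(1L, ceiling(max(r)))
  dx <- rep(-rmax:rmax, times = 2L * rmax + 1L)
  dy <- rep(-rmax:rmax, each = 2L * rmax + 1L)
  d2 <- dx^2 + dy^2
  ## point i covers offset j when d2[j] <= r[i]^2 (tip cells always covered)
  hit <- which(outer(d2, pmax(r^2, 0.5), `<=`))
  n_off <- length(d2)
  j <- (hit - 1L) %% n_off + 1L
  i <- (hit - 1L) %/% n_off + 1L
  unique((round(p[i, 1]) + dx[j]) + nx * (round(p[i, 2]) + dy[j]))
}

## incremental sliding-window union counter over rasterized frame sets
.window_union_counts <- function(sets, lo, hi, ncell) {
  T_ <- length(sets)
  cnt <- integer(ncell)
  nz <- 0L
  cur_lo <- 1L; cur_hi <- 0L
  out <- rep(NA_real_, T_)
  add <- function(k) {
    if (is.null(sets[[k]])) return(invisible())
    tb <- cnt[sets[[k]]]
    nz <<- nz + sum(tb == 0L)
    cnt[sets[[k]]] <<- tb + 1L
  }
  rem <- function(k) {
    if (is.null(sets[[k]])) return(invisible())
    tb <- cnt[sets[[k]]]
    cnt[sets[[k]]] <<- tb - 1L
    nz <<- nz - sum(tb == 1L)
  }
  for (t in seq_len(T_)) {
    while (cur_hi < hi[t]) { cur_hi <- cur_hi + 1L; add(cur_hi) }
    while (cur_hi > hi[t]) { rem(cur_hi); cur_hi <- cur_hi - 1L }
    while (cur_lo < lo[t]) { rem(cur_lo); cur_lo <- cur_lo + 1L }
    while (cur_lo > lo[t]) { cur_lo <- cur_lo - 1L; add(cur_lo) }
    out[t] <- nz
  }
  out
}

#' Brush stroke: area painted by the body over two strokes
#'
#' The body tube (centerline plus local half-width) is rasterized on a
#' normalized grid with the body length mapped to 128 raster units, so the
#' value is independent of image resolution and animal size. The value is
#' the ratio of the number of cells covered over the two-stroke window to
#' the number of cells of the single-frame body, minus one: a frozen,
#' non-translating worm paints only itself and scores 0. The series is
#' smoothed by a two-stroke moving average (averages of successive pairs
#' of strokes).
#'
#' @inheritParams travel_speed
#' @param units_per_L raster units per body length.
#' @return A \code{\link{measure_series}} in body areas.
#' @export
brush_stroke <- function(track, clock, units_per_L = 128) {
  frames <- if (inherits(track, "swim_track")) track$frames else track
  T_ <- length(frames)
  valid <- vapply(frames, function(f) f$valid, logical(1))
  v <- rep(NA_real_, T_)
  if (clock$any_defined && any(valid)) {
    L <- mean(vapply(frames[valid], body_length, numeric(1)))
    scale <- units_per_L / L
    allpts <- do.call(rbind, lapply(frames[valid], function(f) f$points))
    origin <- c(min(allpts[, 1]), min(allpts[, 2])) - L
    nx <- as.integer(ceiling((max(allpts[, 1]) - origin[1] + L) * scale)) + 1L
    ny <- as.integer(ceiling((max(allpts[, 2]) - origin[2] + L) * scale)) + 1L
    ## fine tube geometry per frame, in raster units
    geom <- vector("list", T_)
    for (t in which(valid)) {
      fine <- resample_centerline(frames[[t]], as.integer(units_per_L) + 1L)
      geom[[t]] <- list(
        p = (fine$points - rep(origin, each = nrow(fine$points))) * scale,
        r = fine$half_widths * scale)
    }
    sets <- vector("list", T_)
    own_n <- rep(NA_real_, T_)
    for (t in which(valid)) {
      keys <- .rasterize_tube(geom[[t]]$p, geom[[t]]$r, nx)
      own_n[t] <- length(keys)
      ## the body moves between discrete frames: bridge the gap from the
      ## previous frame with interpolated postures so the painted union
      ## does not depend on the frame rate
      if (t > 1L && !is.null(geom[[t - 1L]])) {
        disp <- max(abs(geom[[t]]$p - geom[[t - 1L]]$p))
        n_sub <- floor(disp / 2)
        if (n_sub >= 1L) for (j in seq_len(n_sub)) {
          w <- j / (n_sub + 1L)
          keys <- c(keys, .rasterize_tube(
            (1 - w) * geom[[t]]$p + w * geom[[t - 1L]]$p,
            (1 - w) * geom[[t]]$r + w * geom[[t - 1L]]$r, nx))
        }
      }
      sets[[t]] <- unique(keys)
    }
    union_n <- .window_union_counts(sets, clock$lo, clock$hi,
                                    as.integer(nx) * (ny + 1L))
    raw <- rep(NA_real_, T_)
    for (t in seq_len(T_)) {
      if (is.na(clock$duration[t]) || !valid[t]) next
      cols <- .window_cols(clock, t, valid)
      if (!length(cols)) next
      raw[t] <- union_n[t] / own_n[t] - 1
    }
    ## two-stroke moving average
    for (t in seq_len(T_)) {
      if (is.na(raw[t])) next
      cols <- clock$lo[t]:clock$hi[t]
      v[t] <- mean(raw[cols], na.rm = TRUE)
    }
  }
  measure_series("brush_stroke", v, "body areas", valid = valid & !is.na(v))
}

#' Activity index: brush stroke per unit time
#'
#' The brush stroke normalized by the duration of the two strokes over
#' which it was painted, in body areas per second.
#'
#' @param brush a \code{\link{measure_series}} from
#'   \code{\link{brush_stroke}}.
#' @param clock a \code{\link{stroke_clock}}.
#' @param frame_rate frames per second.
#' @return A \code{\link{measure_series}} in body areas per second.
#' @export
activity_index <- function(brush, clock, frame_rate = clock$frame_rate) {
  v <- brush$values / (2 * clock$duration / frame_rate)
  measure_series("activity_index", v, "body areas/s")
}
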