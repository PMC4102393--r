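#' Centerline of a swimming animal at one video frame
#'
#' A centerline is the mid-body line of lateral symmetry of a nematode,
#' stored as an ordered polyline in pixel image coordinates (x right, y
#' down), tail first and head last, together with the body half-width at
#' each point. The curvilinear coordinate s runs from 0 (tail) to 1 (head).
#'
#' @param points numeric matrix with n rows and 2 columns (x, y), n >= 2.
#' @param half_widths per-point body half-width in pixels (recycled if
#'   length 1); defaults to 0.
#' @param frame_index integer time stamp of the video frame.
#' @param valid logical frame-quality flag; invalid frames are excluded
#'   from all downstream statistics.
#' @return An object of class \code{"centerline"}.
#' @export
centerline <- function(points, half_widths = 0, frame_index = NA_integer_,
                       valid = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop("'points' must be an n x 2 matrix with n >= 2")
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("centerline points contain NA")
  half_widths <- rep_len(as.numeric(half_widths), nrow(points))
  if (any(half_widths < 0)) stop("half_widths must be >= 0")
  structure(
    list(points = points, half_widths = half_widths,
         frame_index = as.integer(frame_index), valid = isTRUE(valid)),
    class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.1f px, frame %s%s\n",
              nrow(x$points), body_length(x),
              ifelse(is.na(x$frame_index), "?", x$frame_index),
              if (x$valid) "" else " [invalid]"))
  invisible(x)
}

## collapse consecutive points closer than `tol` (degenerate vertices)
.dedupe_points <- function(points, half_widths, tol = 1e-9) {
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                     points[-nrow(points), , drop = FALSE])^2))
  keep <- c(TRUE, d > tol)
  list(points = points[keep, , drop = FALSE], half_widths = half_widths[keep])
}

.cumulative_arclen <- function(points) {
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                     points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(d))
}

## unit tangents at every vertex of a polyline, from the circle through
## each point and its neighbors (exact for circular arcs); chord
## direction on collinear input
.vertex_tangents <- function(pts) {
  n <- nrow(pts)
  x1 <- pts[1:(n - 2L), 1]; y1 <- pts[1:(n - 2L), 2]
  x2 <- pts[2:(n - 1L), 1]; y2 <- pts[2:(n - 1L), 2]
  x3 <- pts[3:n, 1];        y3 <- pts[3:n, 2]
  d <- 2 * (x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))
  q1 <- x1^2 + y1^2; q2 <- x2^2 + y2^2; q3 <- x3^2 + y3^2
  ux <- (q1 * (y2 - y3) + q2 * (y3 - y1) + q3 * (y1 - y2)) / d
  uy <- (q1 * (x3 - x2) + q2 * (x1 - x3) + q3 * (x2 - x1)) / d
  ## tangent at a vertex on triple k = perpendicular of (vertex - center_k)
  tang_at <- function(i, k) {
    if (abs(d[k]) < 1e-12) return(pts[min(i + 1L, n), ] - pts[max(i - 1L, 1L), ])
    r <- pts[i, ] - c(ux[k], uy[k])
    tg <- c(-r[2], r[1])
    chord <- pts[k + 2L, ] - pts[k, ]
    if (sum(tg * chord) < 0) -tg else tg
  }
  tg <- matrix(0, n, 2L)
  ok <- abs(d) >= 1e-12
  rx <- x2 - ifelse(ok, ux, 0); ry <- y2 - ifelse(ok, uy, 0)
  tgx <- ifelse(ok, -ry, x3 - x1); tgy <- ifelse(ok, rx, y3 - y1)
  flip <- tgx * (x3 - x1) + tgy * (y3 - y1) < 0
  tgx[flip] <- -tgx[flip]; tgy[flip] <- -tgy[flip]
  tg[2:(n - 1L), ] <- cbind(tgx, tgy)
  tg[1L, ] <- tang_at(1L, 1L)
  tg[n, ] <- tang_at(n, n - 2L)
  tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
}

## densify a polyline with cubic Hermite segments (per_seg points each)
.hermite_densify <- function(pts, per_seg = 10L) {
  n <- nrow(pts)
  tg <- .vertex_tangents(pts)
  u <- seq(0, 1, length.out = per_seg + 1L)[-(per_seg + 1L)]
  h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2;    h11 <- u^3 - u^2
  dseg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                        pts[-n, , drop = FALSE])^2))
  P0 <- pts[-n, , drop = FALSE]; P1 <- pts[-1L, , drop = FALSE]
  T0 <- tg[-n, , drop = FALSE] * dseg; T1 <- tg[-1L, , drop = FALSE] * dseg
  xs <- P0[, 1] %o% h00 + T0[, 1] %o% h10 + P1[, 1] %o% h01 + T1[, 1] %o% h11
  ys <- P0[, 2] %o% h00 + T0[, 2] %o% h10 + P1[, 2] %o% h01 + T1[, 2] %o% h11
  rbind(cbind(as.vector(t(xs)), as.vector(t(ys))), pts[n, , drop = FALSE])
}

#' Total arc length of a centerline
#'
#' @param c a \code{\link{centerline}}.
#' @return Arc length in pixels (sum of segment Euclidean lengths).
#' @export
body_length <- function(c) {
  stopifnot(inherits(c, "centerline"))
  L <- sum(sqrt(rowSums((c$points[-1, , drop = FALSE] -
                         c$points[-nrow(c$points), , drop = FALSE])^2)))
  if (L <= 0) stop("degenerate centerline: zero arc length")
  L
}

#' Resample a centerline to equally spaced points along its arc
#'
#' Near-duplicate vertices (closer than 1e-9 px) are collapsed first. The
#' canonical representation downstream is 13 points delimiting 12 equally
#' long body segments.
#'
#' @param raw a \code{\link{centerline}} with at least 4 points.
#' @param n_points number of output points (default 13).
#' @return A \code{\link{centerline}} with \code{n_points} points equally
#'   spaced in arc length; half-widths linearly interpolated.
#' @export
resample_centerline <- function(raw, n_points = 13L) {
  stopifnot(inherits(raw, "centerline"))
  dd <- .dedupe_points(raw$points, raw$half_widths)
  pts <- dd$points; hw <- dd$half_widths
  if (nrow(pts) < 2L) stop("degenerate centerline: all points coincide")
  al <- .cumulative_arclen(pts)
  L <- al[length(al)]
  if (L <= 0) stop("degenerate centerline: zero arc length")
  ## piecewise cubic Hermite with tangents from local 3-point circle
  ## fits: exact on circular arcs, so a polyline as sparse as 4 points on
  ## a quarter circle resamples back onto the circle to ~0.01 px. The
  ## dense curve is then re-parameterized by its own (longer) arc length,
  ## correcting the chord-length bias of the sparse input.
  if (nrow(pts) >= 3L) {
    dense <- .hermite_densify(pts, per_seg = max(
      8L, ceiling(10 * n_points / (nrow(pts) - 1L))))
    al2 <- .cumulative_arclen(dense)
    wd <- stats::approx(al / L, hw,
                        xout = al2 / al2[nrow(dense)],
                        ties = "ordered")$y
    s_out <- seq(0, al2[nrow(dense)], length.out = n_points)
    x <- stats::approx(al2, dense[, 1], xout = s_out, ties = "ordered")$y
    y <- stats::approx(al2, dense[, 2], xout = s_out, ties = "ordered")$y
    w <- stats::approx(al2, wd, xout = s_out, ties = "ordered")$y
  } else {
    s_out <- seq(0, L, length.out = n_points)
    x <- stats::approx(al, pts[, 1], xout = s_out, ties = "ordered")$y
    y <- stats::approx(al, pts[, 2], xout = s_out, ties = "ordered")$y
    w <- stats::approx(al, hw, xout = s_out, ties = "ordered")$y
  }
  centerline(cbind(x, y), w, raw$frame_index, raw$valid)
}

#' Arc-length-weighted centroid of a centerline
#'
#' The body center used by the travel-speed measure: each segment's
#' midpoint weighted by its length.
#'
#' @param c a \code{\link{centerline}}.
#' @return Numeric length-2 vector (x, y).
#' @export
body_center <- function(c) {
  stopifnot(inherits(c, "centerline"))
  p <- c$points
  seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
  L <- sum(len)
  if (L <= 0) stop("degenerate centerline: zero arc length")
  colSums(mid * len) / L
}

## Kasa algebraic circle fit: returns signed curvature (1/R) of a point run,
## sign positive for clockwise turning on screen (theta increasing with y
## down). Collinear input gives 0.
.circle_curvature <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1] - mean(pts[, 1]); y <- pts[, 2] - mean(pts[, 2])
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  fit <- qr(A)
  if (fit$rank < 3L) return(0)
  sol <- qr.coef(fit, b)
  R2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(R2) || R2 <= 0) return(0)
  kappa <- 1 / sqrt(R2)
  ## sign from net turning of the tangent along the run
  v <- cbind(diff(pts[, 1]), diff(pts[, 2]))
  cr <- v[-nrow(v), 1] * v[-1, 2] - v[-nrow(v), 2] * v[-1, 1]
  s <- sum(cr)
  if (s == 0) return(0)
  sign(s) * kappa
}

#' Signed dimensionless curvature at the 12 body-segment midpoints
#'
#' Curvature is the derivative of the tangent vector with respect to the
#' curvilinear coordinate, estimated as the inverse radius of the
#' least-squares circle fitted over a short arc around each segment
#' midpoint, then multiplied by body length L so the result is
#' dimensionless (per body length) and independent of animal size and
#' image resolution. Sign is positive where the body bends clockwise as
#' seen on screen (image y-axis pointing down) following the tail-to-head
#' direction.
#'
#' @param c a \code{\link{centerline}}.
#' @param window_fraction arc length of the fitting window as a fraction
#'   of body length, in (0, 0.5]. Default 1/12 (one body segment).
#' @param n_segments number of body segments (12).
#' @param n_fine number of points of the internal fine arc-length
#'   resampling used for the circle fits.
#' @return Numeric vector of \code{n_segments} signed curvatures
#'   (kappa * L).
#' @export
compute_curvature <- function(c, window_fraction = 1 / 12, n_segments = 12L,
                              n_fine = 8L * n_segments + 1L) {
  stopifnot(inherits(c, "centerline"))
  if (window_fraction <= 0 || window_fraction > 0.5)
    stop("window_fraction must be in (0, 0.5]")
  fine <- resample_centerline(c, n_fine)
  L <- body_length(fine)
  s <- seq(0, 1, length.out = n_fine)
  mids <- (seq_len(n_segments) - 0.5) / n_segments
  half <- window_fraction / 2
  vapply(mids, function(m) {
    lo <- max(0, m - half); hi <- min(1, m + half)
    idx <- which(s >= lo - 1e-12 & s <= hi + 1e-12)
    if (length(idx) < 3L) idx <- seq(max(1, min(idx) - 1), min(n_fine, max(idx) + 1))
    .circle_curvature(fine$points[idx, , drop = FALSE]) * L
  }, numeric(1))
}

#' Curvature kymograph of a swim trial
#'
#' Builds the segments-by-frames matrix of signed dimensionless curvature
#' that every curvature-based measure reads. Row 1 is the tail-most
#' segment, row 12 the head-most; one column per frame.
#'
#' @param track a list of \code{\link{centerline}} objects (one animal,
#'   chronological) or a \code{\link{swim_track}}.
#' @param frame_rate frames per second.
#' @param window_fraction passed to \code{\link{compute_curvature}}.
#' @param n_segments number of body segments (12).
#' @return An object of class \code{"curvature_map"}: list with
#'   \code{values} (n_segments x T matrix, NA on invalid frames),
#'   \code{frame_rate}, \code{valid_frames} (logical T),
#'   \code{body_length_px} (per-frame arc length).
#' @export
build_curvature_map <- function(track, frame_rate,
                                window_fraction = 1 / 12, n_segments = 12L) {
  frames <- if (inherits(track, "swim_track")) track$frames else track
  if (inherits(track, "swim_track") && missing(frame_rate))
    frame_rate <- track$frame_rate
  if (length(frames) == 0L) stop("empty track")
  T_ <- length(frames)
  values <- matrix(NA_real_, n_segments, T_)
  valid <- logical(T_)
  blen <- rep(NA_real_, T_)
  for (t in seq_len(T_)) {
    f <- frames[[t]]
    stopifnot(inherits(f, "centerline"))
    if (!f$valid) next
    k <- tryCatch(compute_curvature(f, window_fraction, n_segments),
                  error = function(e) NULL)
    if (is.null(k) || !all(is.finite(k))) next
    values[, t] <- k
    valid[t] <- TRUE
    blen[t] <- body_length(f)
  }
  structure(list(values = values, frame_rate = frame_rate,
                 valid_frames = valid, body_length_px = blen,
                 n_segments = n_segments),
            class = "curvature_map")
}

#' @export
print.curvature_map <- function(x, ...) {
  cat(sprintf("<curvature_map> %d segments x %d frames @ %g fps (%d valid)\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              sum(x$valid_frames)))
  invisible(x)
}

#' A tracked animal: chronological centerlines plus flags
#'
#' @param frames list of \code{\link{centerline}} objects, chronological.
#' @param frame_rate frames per second.
#' @param animal_id identifier string.
#' @param flags optional data.frame (frame, flag_type, source).
#' @return An object of class \code{"swim_track"}.
#' @export
swim_track <- function(frames, frame_rate = 18, animal_id = "animal1",
                       flags = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "centerline")))
  if (is.null(flags))
    flags <- data.frame(frame = integer(), flag_type = character(),
                        source = character())
  structure(list(frames = frames, frame_rate = frame_rate,
                 animal_id = animal_id, flags = flags,
                 rejected = FALSE, head_tail_swapped = FALSE),
            class = "swim_track")
}

#' @export
print.swim_track <- function(x, ...) {
  cat(sprintf("<swim_track> '%s': %d frames @ %g fps, %d invalid%s%s\n",
              x$animal_id, length(x$frames), x$frame_rate,
              sum(!vapply(x$frames, function(f) f$valid, logical(1))),
              if (x$rejected) ", REJECTED" else "",
              if (x$head_tail_swapped) ", head/tail swapped" else ""))
  invisible(x)
}

#' Reverse the tail-to-head orientation of every frame of a track
#'
#' @param track a \code{\link{swim_track}}.
#' @return The track with point order reversed on every frame and the
#'   \code{head_tail_swapped} flag toggled.
#' @export
flip_head_tail <- function(track) {
  stopifnot(inherits(track, "swim_track"))
  track$frames <- lapply(track$frames, function(f) {
    n <- nrow(f$points)
    centerline(f$points[n:1, , drop = FALSE], rev(f$half_widths),
               f$frame_index, f$valid)
  })
  track$head_tail_swapped <- !track$head_tail_swapped
  track
}
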