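#' @name tracking
#' @title Multi-animal centerline tracking
#'
#' @description
#' Animals are located in a frame by segmentation: a local
#' standard-deviation filter enhances the animals' edges, a gradient is
#' taken on the filtered image, closed contours are grown greedily along
#' maximal gradient flow, and the inner distance transform of each outline
#' yields the centerline (its inner ridge) and the body half-widths (the
#' transform values). Between segmentations, centerlines are propagated
#' frame to frame by a two-step greedy fit anchored on stationary body
#' points, with a fresh segmentation merged in every 20 frames to bound
#' drift. Frames where animals touch (or a body overlaps itself) are
#' flagged and excluded from measures; a quality checker flags frames
#' whose body length drops two standard deviations below the animal's own
#' mean and rejects animals with more than 20% flagged frames.
NULL

#' Tracking parameters
#'
#' @param std_kernel standard-deviation filter kernel size in pixels
#'   (about the body width of an animal).
#' @param expected_count expected number of animals in the scene.
#' @param expected_width expected body width in pixels.
#' @param closure_tol contour closure tolerance, pixels.
#' @param min_perimeter minimal accepted contour perimeter, pixels
#'   (default 4 x expected body width).
#' @param n_points centerline points carried through tracking.
#' @param displacement_frac per-frame displacement bound for contact
#'   envelopes, fraction of body length at 18 fps (scaled by frame rate).
#' @param keyframe_every frames between fresh segmentations.
#' @param min_contrast minimal intensity separation between an animal and
#'   its surroundings (rejects threshold clusters cut from pure noise).
#' @return List of parameters.
#' @export
track_params <- function(std_kernel = 5, expected_count = 5,
                         expected_width = 6, closure_tol = 2,
                         min_perimeter = 4 * expected_width,
                         n_points = 25L, displacement_frac = 0.25,
                         keyframe_every = 20L, min_contrast = 0.15) {
  list(std_kernel = std_kernel, expected_count = expected_count,
       expected_width = expected_width, closure_tol = closure_tol,
       min_perimeter = min_perimeter, n_points = as.integer(n_points),
       displacement_frac = displacement_frac,
       keyframe_every = as.integer(keyframe_every),
       min_contrast = min_contrast)
}

## local standard deviation filter with a k x k box
.sd_filter <- function(img, k) {
  k <- max(3L, as.integer(k)); if (k %% 2L == 0L) k <- k + 1L
  box <- matrix(1 / (k * k), k, k)
  m1 <- as.matrix(EBImage::filter2(EBImage::Image(img), box))
  m2 <- as.matrix(EBImage::filter2(EBImage::Image(img^2), box))
  sqrt(pmax(m2 - m1^2, 0))
}

## central-difference gradient magnitude
.grad_mag <- function(img) {
  nx <- nrow(img); ny <- ncol(img)
  gx <- img; gy <- img
  gx[2:(nx - 1), ] <- (img[3:nx, ] - img[1:(nx - 2), ]) / 2
  gx[c(1, nx), ] <- 0
  gy[, 2:(ny - 1)] <- (img[, 3:ny] - img[, 1:(ny - 2)]) / 2
  gy[, c(1, ny)] <- 0
  sqrt(gx^2 + gy^2)
}

## bilinear image sampling at arbitrary (x, y)
.bilin <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pmin(pmax(x, 1), nx - 1e-6); y <- pmin(pmax(y, 1), ny - 1e-6)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0, y0); i10 <- cbind(pmin(x0 + 1, nx), y0)
  i01 <- cbind(x0, pmin(y0 + 1, ny)); i11 <- cbind(pmin(x0 + 1, nx), pmin(y0 + 1, ny))
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
}

## greedy contour walk along maximal gradient from one seed
.grow_contour <- function(grad, seed, closure_tol, min_perimeter, max_steps) {
  nx <- nrow(grad); ny <- ncol(grad)
  dxs <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dys <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  path <- matrix(NA_integer_, max_steps + 1L, 2L)
  path[1, ] <- seed
  visited <- integer(max_steps + 1L)      # linear indices along the path
  visited[1] <- seed[1] + nx * (seed[2] - 1L)
  vis <- logical(nx * ny)
  vis[visited[1]] <- TRUE
  cur <- as.integer(seed); prev_dir <- c(0L, 0L)
  n_found <- NULL
  for (step in seq_len(max_steps)) {
    cx <- cur[1] + dxs; cy <- cur[2] + dys
    ok <- cx >= 2L & cx <= nx - 1L & cy >= 2L & cy <= ny - 1L
    if (step > 1L) ok <- ok & (dxs * prev_dir[1] + dys * prev_dir[2]) >= 0L
    lin <- cx + nx * (cy - 1L)
    ok[ok] <- !vis[lin[ok]]
    if (!any(ok)) break
    g <- rep(-Inf, 8L)
    g[ok] <- grad[lin[ok]]
    j <- which.max(g)
    cur <- c(cx[j], cy[j]); prev_dir <- c(dxs[j], dys[j])
    vis[lin[j]] <- TRUE
    visited[step + 1L] <- lin[j]
    path[step + 1L, ] <- cur
    if (step >= min_perimeter &&
        sum((cur - seed)^2) <= closure_tol^2) { n_found <- step + 1L; break }
  }
  if (is.null(n_found)) return(NULL)
  path[seq_len(n_found), , drop = FALSE]
}

## refine a coarse greedy contour into a precise outline: local threshold
## of the region of interest, connected component under the contour,
## filled; returns the ordered outline, the mask's inner distance
## transform and the ROI origin
.refine_outline <- function(image, ct, params) {
  m <- 3L * params$expected_width
  ## the greedy contour may have enclosed only part of the animal: grow
  ## the region of interest until the selected component no longer
  ## touches its border, so the animal is never cropped mid-body
  for (attempt in 1:4) {
    x0 <- max(1L, floor(min(ct[, 1])) - m)
    x1 <- min(nrow(image), ceiling(max(ct[, 1])) + m)
    y0 <- max(1L, floor(min(ct[, 2])) - m)
    y1 <- min(ncol(image), ceiling(max(ct[, 2])) + m)
    roi <- as.matrix(EBImage::gblur(EBImage::Image(
      image[x0:x1, y0:y1, drop = FALSE]),
      max(0.5, params$expected_width / 6)))
    thr <- tryCatch(EBImage::otsu(EBImage::Image(roi)),
                    error = function(e)
                      stats::median(roi) - 2 * stats::sd(roi))
    mask <- EBImage::Image((roi < thr) * 1)
    lab <- EBImage::bwlabel(mask)
    labm <- EBImage::imageData(lab)
    ## component most often under the greedy contour's footprint
    cx <- pmin(pmax(round(ct[, 1]) - x0 + 1L, 1L), nrow(labm))
    cy <- pmin(pmax(round(ct[, 2]) - y0 + 1L, 1L), ncol(labm))
    hits <- labm[cbind(cx, cy)]
    hits <- hits[hits > 0]
    if (!length(hits)) hits <- labm[labm > 0]
    if (!length(hits)) return(NULL)
    keep <- as.integer(names(sort(table(hits), decreasing = TRUE))[1])
    inside <- labm == keep
    at_border <-
      any(inside[1, ]) && x0 > 1L || any(inside[nrow(inside), ]) &&
        x1 < nrow(image) || any(inside[, 1]) && y0 > 1L ||
        any(inside[, ncol(inside)]) && y1 < ncol(image)
    if (!at_border) break
    w_idx <- which(inside, arr.ind = TRUE)
    ct <- cbind(w_idx[, 1] + x0 - 1L, w_idx[, 2] + y0 - 1L)
  }
  ## a real animal is much darker than the background; threshold clusters
  ## cut from pure noise are not
  if (mean(roi[!inside]) - mean(roi[inside]) < params$min_contrast)
    return(NULL)
  comp <- EBImage::fillHull(EBImage::Image(inside * 1))
  oc <- EBImage::ocontour(comp)
  if (!length(oc)) return(NULL)
  outline <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1L
  dt <- as.matrix(EBImage::distmap(comp))
  list(outline = cbind(outline[, 1] + x0 - 1L, outline[, 2] + y0 - 1L),
       dt = dt, origin = c(x0, y0))
}

## ordered outline -> centerline by side pairing: find the two tips
## (sharpest turning, roughly opposite along the boundary), split the
## outline into two sides, average paired points; half-widths are the
## inner distance transform sampled along the ridge
.contour_to_centerline <- function(outline, dt, origin, n_points,
                                   frame_index) {
  n <- nrow(outline)
  if (n < 12L) return(NULL)
  k <- max(3L, round(n / 40))
  sm <- function(v) {
    pad <- c(v[(n - k + 1L):n], v, v[1:k])
    as.numeric(stats::filter(pad, rep(1 / (2 * k + 1), 2 * k + 1))[
      (k + 1L):(k + n)])
  }
  cx <- sm(outline[, 1]); cy <- sm(outline[, 2])
  lag <- max(3L, round(n / 15))
  idx <- seq_len(n)
  ip <- ((idx - 1L + lag) %% n) + 1L
  im <- ((idx - 1L - lag) %% n) + 1L
  v1x <- cx - cx[im]; v1y <- cy - cy[im]
  v2x <- cx[ip] - cx; v2y <- cy[ip] - cy
  dot <- v1x * v2x + v1y * v2y
  nrm <- sqrt((v1x^2 + v1y^2) * (v2x^2 + v2y^2))
  turn <- acos(pmin(pmax(dot / pmax(nrm, 1e-12), -1), 1))
  t1 <- which.max(turn)
  sep <- pmin(abs(idx - t1), n - abs(idx - t1))
  cand <- which(sep >= 0.3 * n)
  if (!length(cand)) return(NULL)
  t2 <- cand[which.max(turn[cand])]
  a <- min(t1, t2); b <- max(t1, t2)
  sideA <- cbind(cx, cy)[a:b, , drop = FALSE]
  sideB <- cbind(cx, cy)[c(b:n, 1:a), , drop = FALSE]
  rs <- function(p, m_) {
    al <- .cumulative_arclen(p)
    if (al[length(al)] <= 0) return(NULL)
    s <- seq(0, al[length(al)], length.out = m_)
    cbind(stats::approx(al, p[, 1], s, ties = "ordered")$y,
          stats::approx(al, p[, 2], s, ties = "ordered")$y)
  }
  A <- rs(sideA, n_points)
  B <- rs(sideB[nrow(sideB):1, , drop = FALSE], n_points)
  if (is.null(A) || is.null(B)) return(NULL)
  mid <- (A + B) / 2
  hw <- .bilin(dt, mid[, 1] - origin[1] + 1, mid[, 2] - origin[2] + 1)
  centerline(mid, pmax(hw, 0), frame_index, TRUE)
}

## outward continuation of a polyline beyond its first point: a constant-
## curvature arc with the tip's tangent and the curvature of the circle
## through the tip and its neighbors, capped (|curvature| <= 1/min_R and
## total turning <= 60 degrees) so extrapolation errors cannot compound
## into hooks; returns points at arc distances `s` beyond the tip
.tip_continuation <- function(p, s, min_R = NULL) {
  k <- min(6L, nrow(p))
  ## curvature signed for outward traversal (body -> tip -> beyond)
  kap <- .circle_curvature(p[k:1, , drop = FALSE])
  if (!is.null(min_R) && min_R > 0)
    kap <- sign(kap) * min(abs(kap), 1 / min_R)
  tang <- p[1, ] - p[2, ]
  tang <- tang / max(sqrt(sum(tang^2)), 1e-9)
  th0 <- atan2(tang[2], tang[1])
  if (abs(kap) < 1e-9)
    return(cbind(p[1, 1] + s * tang[1], p[1, 2] + s * tang[2]))
  s_cap <- (pi / 3) / abs(kap)
  s_arc <- pmin(s, s_cap)
  out <- cbind(p[1, 1] + (sin(th0 + kap * s_arc) - sin(th0)) / kap,
               p[1, 2] - (cos(th0 + kap * s_arc) - cos(th0)) / kap)
  over <- s > s_cap
  if (any(over)) {
    th_c <- th0 + kap * s_cap
    out[over, 1] <- out[which(s_arc == s_cap)[1], 1] +
      (s[over] - s_cap) * cos(th_c)
    out[over, 2] <- out[which(s_arc == s_cap)[1], 2] +
      (s[over] - s_cap) * sin(th_c)
  }
  out
}

## snap the tip (row 1) to the dark extent of the body: darkness is
## sampled along the body curve from 2w inside the tip, continued
## outward along the tip's own fitted arc, and the tip moves to where
## darkness ends. Following the arc (not the tangent) preserves the
## tip's curvature, which the mean-curvature and range measures read.
.fit_tip <- function(p, img, thr, w, su) {
  n <- nrow(p)
  al <- .cumulative_arclen(p)
  L <- al[n]
  if (L <= 0) return(p)
  inset <- min(2 * w, 0.4 * L)
  s_in <- rev(seq(0, inset, by = su))        # distance from tip, base first
  xin <- stats::approx(al, p[, 1], xout = s_in, ties = "ordered")$y
  yin <- stats::approx(al, p[, 2], xout = s_in, ties = "ordered")$y
  s_out <- seq(su, 3 * w, by = su)
  outp <- .tip_continuation(p, s_out, min_R = L / 5)
  path <- rbind(cbind(xin, yin), outp)
  d_tip <- c(-s_in, s_out)                   # signed distance beyond tip
  ok <- path[, 1] >= 1 & path[, 1] <= nrow(img) &
        path[, 2] >= 1 & path[, 2] <= ncol(img)
  if (sum(ok) < 3L || !ok[1]) return(p)
  dark <- .bilin(img, path[ok, 1], path[ok, 2]) < thr
  if (!dark[1]) return(p)
  stop_at <- which(!dark)
  idx <- if (length(stop_at)) max(1L, stop_at[1] - 1L) else sum(ok)
  shift <- d_tip[ok][idx]                    # >0 extend, <0 trim
  if (shift > 0) {
    keep_out <- outp[s_out <= shift, , drop = FALSE]
    if (!nrow(keep_out)) return(p)
    q <- rbind(keep_out[rev(seq_len(nrow(keep_out))), , drop = FALSE], p)
  } else if (shift < 0) {
    keep <- which(al >= -shift)
    if (length(keep) < 3L) return(p)
    tip_new <- c(stats::approx(al, p[, 1], xout = -shift, ties = "ordered")$y,
                 stats::approx(al, p[, 2], xout = -shift, ties = "ordered")$y)
    q <- rbind(tip_new, p[keep, , drop = FALSE])
  } else return(p)
  al2 <- .cumulative_arclen(q)
  s2 <- seq(0, al2[nrow(q)], length.out = n)
  cbind(stats::approx(al2, q[, 1], xout = s2, ties = "ordered")$y,
        stats::approx(al2, q[, 2], xout = s2, ties = "ordered")$y)
}

## thresholding loses the thin, tapered tips: fit both tips to the dark
## extent of the body along their own arcs
.extend_tips <- function(cl, image, params) {
  p <- cl$points; n <- nrow(p)
  bg <- stats::quantile(image, 0.9, names = FALSE)
  body <- stats::median(.bilin(image, p[, 1], p[, 2]))
  thr <- bg - 0.25 * (bg - body)
  su <- params$expected_width / 12
  p <- .fit_tip(p, image, thr, params$expected_width, su)
  p <- .fit_tip(p[nrow(p):1, , drop = FALSE], image, thr,
                params$expected_width, su)
  p <- p[nrow(p):1, , drop = FALSE]
  ## half-widths mapped by relative arc position (tips taper to ~0)
  al_old <- .cumulative_arclen(cl$points); al_old <- al_old / max(al_old)
  al_new <- .cumulative_arclen(p); al_new <- al_new / max(al_new)
  hw <- stats::approx(al_old, cl$half_widths, xout = al_new,
                      ties = "ordered", rule = 2)$y
  resample_centerline(centerline(p, hw, cl$frame_index, cl$valid), n)
}

#' Segment one frame: locate animals and extract centerlines
#'
#' @param image grayscale matrix (x by y, values in [0, 1], animals dark).
#' @param params a \code{\link{track_params}} list.
#' @param frame_index stored in the returned centerlines.
#' @return An object of class \code{"frame_segmentation"}: list with
#'   \code{outlines} (list of contour point matrices) and
#'   \code{centerlines} (list of \code{\link{centerline}}).
#' @export
segment_frame <- function(image, params = track_params(),
                          frame_index = NA_integer_) {
  image <- as.matrix(image)
  u <- params$expected_width / 6           # pixel-scale unit
  sdimg <- .sd_filter(image, params$std_kernel)
  grad <- .grad_mag(as.matrix(EBImage::gblur(EBImage::Image(sdimg),
                                             max(0.5, u))))
  ## seeds: strongest gradient maxima, spaced out
  K <- 4L * params$expected_count
  ord <- order(grad, decreasing = TRUE)[seq_len(min(5000L, length(grad)))]
  seeds <- matrix(NA_real_, K, 2L); ns <- 0L
  min_sep <- params$min_perimeter
  for (o in ord) {
    p <- c((o - 1L) %% nrow(grad) + 1L, (o - 1L) %/% nrow(grad) + 1L)
    if (ns > 0L &&
        min(sqrt((seeds[seq_len(ns), 1] - p[1])^2 +
                 (seeds[seq_len(ns), 2] - p[2])^2)) < min_sep) next
    ns <- ns + 1L; seeds[ns, ] <- p
    if (ns == K) break
  }
  max_steps <- as.integer(50L * params$min_perimeter)
  outlines <- list(); centerlines <- list(); centroids <- NULL
  for (i in seq_len(ns)) {
    ct <- .grow_contour(grad, seeds[i, ], params$closure_tol,
                        params$min_perimeter, max_steps)
    if (is.null(ct)) next
    ref <- .refine_outline(image, ct, params)
    if (is.null(ref)) next
    cl <- .contour_to_centerline(ref$outline, ref$dt, ref$origin,
                                 params$n_points, frame_index)
    if (is.null(cl)) next
    cl <- .extend_tips(cl, image, params)
    if (body_length(cl) < params$min_perimeter) next
    ## a worm is an elongated tube; roundish blobs (noise, debris) are not
    if (body_length(cl) < 8 * mean(cl$half_widths) ||
        mean(cl$half_widths) > params$expected_width) next
    ## duplicate suppression by body overlap: a second walk around the
    ## same animal -- or a mis-split fragment of it -- lies on an
    ## already-accepted centerline even when its centroid does not
    dup <- 0L
    for (k in seq_along(centerlines)) {
      prev_cl <- centerlines[[k]]
      dmin <- vapply(seq_len(nrow(cl$points)), function(q)
        min(sqrt((prev_cl$points[, 1] - cl$points[q, 1])^2 +
                 (prev_cl$points[, 2] - cl$points[q, 2])^2)), numeric(1))
      if (mean(dmin < params$expected_width) > 0.3) { dup <- k; break }
    }
    if (dup > 0L) {
      ## keep the longer interpretation of the animal
      if (body_length(cl) > body_length(centerlines[[dup]])) {
        outlines[[dup]] <- ref$outline
        centerlines[[dup]] <- cl
      }
      next
    }
    outlines[[length(outlines) + 1L]] <- ref$outline
    centerlines[[length(centerlines) + 1L]] <- cl
  }
  structure(list(outlines = outlines, centerlines = centerlines,
                 frame_index = frame_index),
            class = "frame_segmentation")
}

#' @export
print.frame_segmentation <- function(x, ...) {
  cat(sprintf("<frame_segmentation> %d animal(s) at frame %s\n",
              length(x$centerlines),
              ifelse(is.na(x$frame_index), "?", x$frame_index)))
  invisible(x)
}

## refine half-widths of a centerline from the local distance transform
.refine_half_widths <- function(cl, image, expected_width) {
  p <- cl$points
  x0 <- max(1L, floor(min(p[, 1])) - 2L * expected_width)
  x1 <- min(nrow(image), ceiling(max(p[, 1])) + 2L * expected_width)
  y0 <- max(1L, floor(min(p[, 2])) - 2L * expected_width)
  y1 <- min(ncol(image), ceiling(max(p[, 2])) + 2L * expected_width)
  roi <- image[x0:x1, y0:y1, drop = FALSE]
  on_body <- .bilin(image, p[, 1], p[, 2])
  thr <- (stats::median(on_body) + stats::quantile(roi, 0.9, names = FALSE)) / 2
  mask <- roi < thr
  if (!any(mask)) return(cl)
  dt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  hw <- .bilin(dt, p[, 1] - x0 + 1, p[, 2] - y0 + 1)
  centerline(p, pmax(hw, 0), cl$frame_index, cl$valid)
}

#' Propagate a centerline from one frame to the next
#'
#' Identifies stationary body points (lowest local intensity change
#' between the two consecutive images) as anchors, then greedily refits
#' the remaining points to the new image: each point is pulled toward the
#' local center of mass of darkness along its normal (image term), the
#' polyline is smoothed (curvature term) and re-spaced to preserve arc
#' length (length term). Half-widths are refined from the local distance
#' transform.
#'
#' @param prev the animal's \code{\link{centerline}} at the previous
#'   frame.
#' @param image_t1 previous frame image.
#' @param image_t2 current frame image.
#' @param params a \code{\link{track_params}} list.
#' @param n_iter fitting iterations.
#' @param dpatch,blurred optional precomputed frame-change map and blurred
#'   current image (shared across animals of one frame).
#' @return A \code{\link{centerline}} for the current frame; its
#'   \code{valid} flag is FALSE when fewer than two anchors were found
#'   (caller should fall back to fresh segmentation).
#' @export
track_step <- function(prev, image_t1, image_t2, params = track_params(),
                       n_iter = 2L, dpatch = NULL, blurred = NULL) {
  p0 <- resample_centerline(prev, params$n_points)
  p <- p0$points
  n <- nrow(p)
  L0 <- body_length(p0)
  ds <- L0 / (n - 1)
  ## stationary anchors: smallest local intensity change between frames,
  ## at least a quarter body apart
  u <- params$expected_width / 6           # pixel-scale unit
  if (is.null(dpatch)) {
    bk <- 2L * max(2L, round(params$expected_width / 3)) + 1L
    dpatch <- as.matrix(EBImage::filter2(
      EBImage::Image(abs(image_t2 - image_t1)),
      matrix(1 / bk^2, bk, bk)))
  }
  change <- .bilin(dpatch, p[, 1], p[, 2])
  img <- if (is.null(blurred))
    as.matrix(EBImage::gblur(EBImage::Image(image_t2), max(0.5, u)))
    else blurred
  bg <- stats::quantile(img, 0.9, names = FALSE)
  ## a usable anchor must still be on a dark body part in the new frame
  i1 <- .bilin(image_t1, p[, 1], p[, 2])
  i2 <- .bilin(img, p[, 1], p[, 2])
  body_thr <- bg - 0.5 * (bg - stats::median(i1))
  usable <- which(i2 < body_thr)
  if (length(usable) < 2L) usable <- seq_len(n)
  a1 <- usable[which.min(change[usable])]
  far <- usable[abs(usable - a1) >= 0.25 * n]
  if (!length(far)) far <- usable[usable != a1]
  a2 <- far[which.min(change[far])]
  anchors <- c(a1, a2)
  anchored <- i2[anchors] < body_thr &
    change[anchors] <= stats::quantile(change, 0.5)
  dark <- function(x, y) pmax(bg - .bilin(img, x, y), 0)
  dphi <- pi / 36
  phis <- seq(-pi / 3, pi / 3, by = dphi)
  ## march a chain from an anchored point outward: each next point sits at
  ## spacing ds, in the direction (around the previous frame's local
  ## tangent) that maximizes darkness, with a turn penalty (smoothness)
  march <- function(start) {
    q <- p
    for (dir in c(1L, -1L)) {
      rng <- if (dir == 1L) seq(start + 1L, n) else seq(start - 1L, 1L)
      if (dir == 1L && start >= n) next
      if (dir == -1L && start <= 1L) next
      phi_prev <- NULL
      for (i in rng) {
        ref <- p[i, ] - p[i - dir, ]           # prev frame local tangent
        phi0 <- atan2(ref[2], ref[1])
        cand <- phi0 + phis
        cx <- q[i - dir, 1] + ds * cos(cand)
        cy <- q[i - dir, 2] + ds * sin(cand)
        sc <- dark(cx, cy) + 0.5 * dark((q[i - dir, 1] + cx) / 2,
                                        (q[i - dir, 2] + cy) / 2)
        if (!is.null(phi_prev)) {
          dphi_ <- abs(((cand - phi_prev + pi) %% (2 * pi)) - pi)
          sc <- sc - 0.1 * dphi_
        }
        j <- which.max(sc)
        q[i, ] <- c(cx[j], cy[j])
        phi_prev <- cand[j]
      }
    }
    q
  }
  qa <- march(anchors[1]); qb <- march(anchors[2])
  wa <- 1 / (1 + abs(seq_len(n) - anchors[1]))
  wb <- 1 / (1 + abs(seq_len(n) - anchors[2]))
  p <- (qa * wa + qb * wb) / (wa + wb)
  ## refine: recentre on the tube along normals, smooth, restore length.
  ## The sampling reach adapts to the local half-width: at the thin
  ## tapered ends a full-width window would mostly sample background
  ## noise and jitter the fit.
  hw0 <- p0$half_widths
  reach <- pmax(3 * u, pmin(params$expected_width, 2 * hw0 + 2 * u))
  for (it in seq_len(n_iter)) {
    tang <- rbind(p[2, ] - p[1, ],
                  p[3:n, ] - p[1:(n - 2), ],
                  p[n, ] - p[n - 1, ])
    tl <- sqrt(rowSums(tang^2)); tl[tl == 0] <- 1
    nxv <- -tang[, 2] / tl; nyv <- tang[, 1] / tl
    shift <- numeric(n)
    for (i in seq_len(n)) {
      offs <- seq(-reach[i], reach[i], by = u / 2)
      w <- dark(p[i, 1] + offs * nxv[i], p[i, 2] + offs * nyv[i])^2
      if (sum(w) > 0) shift[i] <- sum(w * offs) / sum(w)
    }
    p[, 1] <- p[, 1] + 0.8 * shift * nxv
    p[, 2] <- p[, 2] + 0.8 * shift * nyv
    ps <- p
    ps[2:(n - 1), ] <- 0.2 * p[1:(n - 2), ] + 0.6 * p[2:(n - 1), ] +
      0.2 * p[3:n, ]
    p <- ps
    ## arc-length preservation: extend/trim the ends, re-space equally
    al <- .cumulative_arclen(p)
    Lc <- al[length(al)]
    if (Lc <= 0) break
    if (Lc < L0) {
      ext <- (L0 - Lc) / 2
      p <- rbind(.tip_continuation(p, ext, min_R = L0 / 5),
                 p,
                 .tip_continuation(p[n:1, , drop = FALSE], ext,
                                   min_R = L0 / 5))
      al <- .cumulative_arclen(p)
      Lc <- al[length(al)]
    }
    s <- seq(0, 1, length.out = n) * L0 + (Lc - L0) / 2
    s <- pmin(pmax(s, 0), Lc)
    p <- cbind(stats::approx(al, p[, 1], s, ties = "ordered")$y,
               stats::approx(al, p[, 2], s, ties = "ordered")$y)
  }
  ## the tube is featureless along its axis, so the fit can slide
  ## longitudinally; snap both tips to the dark extent of the body
  ## (lighter threshold: the tapered tips are faint)
  p <- .snap_tips(p, img, bg - 0.25 * (bg - stats::median(i1)), params)
  ## orientation continuity by construction: when a crossing body part
  ## captures an anchor, the fit can come out reversed -- restore the
  ## previous frame's point order (head/tail identity is resolved later
  ## from the wave direction, never frame-locally)
  d_same <- sum((p - p0$points)^2)
  d_flip <- sum((p[n:1, ] - p0$points)^2)
  if (d_flip < d_same) p <- p[n:1, , drop = FALSE]
  out <- centerline(p, p0$half_widths, prev$frame_index + 1L,
                    valid = all(anchored))
  tryCatch(.refine_half_widths(out, image_t2, params$expected_width),
           error = function(e) out)
}

## move each end of the polyline to where the body's darkness ends along
## its own arc; resolves longitudinal sliding of a tube fit
.snap_tips <- function(p, img, thr, params) {
  n <- nrow(p)
  w <- params$expected_width
  p <- .fit_tip(p, img, thr, w, w / 12)
  p <- .fit_tip(p[n:1, , drop = FALSE], img, thr, w, w / 12)
  p[n:1, , drop = FALSE]
}

## orient candidate centerline so that its point order matches `ref`.
## Whole-body comparison with hysteresis: a symmetric C posture is nearly
## congruent to its own reverse, so without a decisive margin the tracked
## orientation is kept -- orientation must stay continuous through
## ambiguous postures (head/tail identity is resolved later from the
## wave direction, not here).
.orient_like <- function(cand, ref) {
  rs_c <- resample_centerline(cand, 25L)$points
  rs_r <- resample_centerline(ref, 25L)$points
  d_same <- sum((rs_c - rs_r)^2)
  d_flip <- sum((rs_c[25:1, ] - rs_r)^2)
  if (d_flip < 0.5 * d_same) {
    n <- nrow(cand$points)
    centerline(cand$points[n:1, , drop = FALSE], rev(cand$half_widths),
               cand$frame_index, cand$valid)
  } else cand
}

#' Merge a tracked centerline with a fresh segmentation at a key frame
#'
#' Pointwise, the candidate with better local image support (darker local
#' intensity on the animal) wins; the merged polyline is then smoothed and
#' re-spaced. Bounded drift: whatever error tracking accumulated since the
#' last key frame is reset by the segmentation where the segmentation is
#' better supported.
#'
#' @param tracked centerline propagated by tracking.
#' @param segmented centerline from \code{\link{segment_frame}} matched to
#'   the same animal (oriented automatically).
#' @param image the key-frame image.
#' @param params a \code{\link{track_params}} list.
#' @return Merged \code{\link{centerline}}.
#' @export
keyframe_merge <- function(tracked, segmented, image,
                           params = track_params()) {
  n <- params$n_points
  a <- resample_centerline(tracked, n)
  b <- .orient_like(resample_centerline(segmented, n), a)
  ## gate: when the two candidates disagree beyond any plausible drift,
  ## pointwise blending would splice two different interpretations of
  ## the scene. Adopt whichever lies on darker (better-supported)
  ## pixels wholesale: a lost track is recovered by the segmentation,
  ## and a garbage segmentation (e.g. on a tangled posture) cannot
  ## destroy a good track -- the frame is flagged instead.
  md <- mean(sqrt(rowSums((a$points - b$points)^2)))
  if (md > params$expected_width) {
    ia_m <- mean(.bilin(image, a$points[, 1], a$points[, 2]))
    ib_m <- mean(.bilin(image, b$points[, 1], b$points[, 2]))
    if (ib_m < ia_m - 0.05) {
      out <- centerline(b$points, b$half_widths, tracked$frame_index, TRUE)
    } else {
      out <- centerline(a$points, a$half_widths, tracked$frame_index,
                        FALSE)
    }
    return(out)
  }
  ia <- .bilin(image, a$points[, 1], a$points[, 2])
  ib <- .bilin(image, b$points[, 1], b$points[, 2])
  ## the fresh segmentation wins ties: a slid-but-still-dark tracked point
  ## has the same darkness but the wrong arc position
  use_b <- ib < ia + 0.05
  p <- a$points; p[use_b, ] <- b$points[use_b, ]
  hw <- a$half_widths; hw[use_b] <- b$half_widths[use_b]
  ps <- p
  ps[2:(n - 1), ] <- 0.25 * p[1:(n - 2), ] + 0.5 * p[2:(n - 1), ] +
    0.25 * p[3:n, ]
  out <- centerline(ps, hw, tracked$frame_index, TRUE)
  resample_centerline(out, n)
}

#' Flag frames where animals are in contact (or self-overlapping)
#'
#' For every frame, each animal's envelope of possible body locations is
#' the union of discs around its body points (radius = local half-width
#' plus the per-frame displacement bound). Animal pairs whose envelopes
#' intersect are examined: if their fitted bodies remain closer than the
#' sum of their half-widths (plus 1 px), both are flagged as in contact.
#' A body whose two ends (arc separation >= 0.3 L) come closer than twice
#' the local half-width is flagged as self-overlapping through the same
#' path.
#'
#' @param tracks list of \code{\link{swim_track}} objects (same frames).
#' @param params a \code{\link{track_params}} list.
#' @param frame_rate frames/s; the displacement bound scales with it.
#' @return Logical matrix (frames x animals) of contact flags.
#' @export
handle_contacts <- function(tracks, params = track_params(),
                            frame_rate = 18) {
  T_ <- length(tracks[[1]]$frames)
  A <- length(tracks)
  flags <- matrix(FALSE, T_, A)
  for (t in seq_len(T_)) {
    cls <- lapply(tracks, function(tr) tr$frames[[t]])
    Ls <- vapply(cls, function(cl)
      tryCatch(body_length(cl), error = function(e) NA_real_), numeric(1))
    bound <- params$displacement_frac * Ls * (18 / frame_rate)
    if (A > 1L) {
      for (i in seq_len(A - 1L)) for (j in (i + 1L):A) {
        pi_ <- cls[[i]]$points; pj <- cls[[j]]$points
        if (anyNA(Ls[c(i, j)])) next
        ri <- cls[[i]]$half_widths; rj <- cls[[j]]$half_widths
        gap <- sqrt(outer(pi_[, 1], pj[, 1], `-`)^2 +
                    outer(pi_[, 2], pj[, 2], `-`)^2)
        ## cheap envelope test first: discs of (local half-width +
        ## displacement bound) around the body points
        env <- outer(ri + bound[i], rj + bound[j], `+`)
        if (all(gap > env)) next
        ## envelopes in contact: re-test the fitted bodies themselves,
        ## pointwise local radii
        if (any(gap <= outer(ri, rj, `+`) + 1)) {
          flags[t, i] <- TRUE; flags[t, j] <- TRUE
        }
      }
    }
    ## self-overlap through the same path (pointwise local radii)
    for (i in seq_len(A)) {
      if (is.na(Ls[i])) next
      p <- cls[[i]]$points; nq <- nrow(p)
      s <- seq(0, 1, length.out = nq)
      hw <- cls[[i]]$half_widths
      dmat <- sqrt(outer(p[, 1], p[, 1], `-`)^2 +
                   outer(p[, 2], p[, 2], `-`)^2)
      sep <- abs(outer(s, s, `-`)) >= 0.3
      if (any(dmat[sep] <= outer(hw, hw, `+`)[sep])) flags[t, i] <- TRUE
    }
  }
  flags
}

#' Quality-check a track: length flags and the 20% rejection rule
#'
#' Flags every frame whose body length is more than two standard
#' deviations below the animal's mean length over the whole video, adds
#' any pre-existing flags, and rejects the animal when the flagged
#' fraction exceeds 20% (strict). Manual overrides (from a review file)
#' switch the validity of specific frames or of the whole animal.
#'
#' @param track a \code{\link{swim_track}}.
#' @param extra_flags optional logical vector of per-frame flags to merge
#'   (e.g. contact flags).
#' @param overrides optional data.frame (frame, new_validity) of manual
#'   decisions; frame = 0 with new_validity TRUE/FALSE force-accepts or
#'   force-rejects the whole animal.
#' @return The track with invalid frames marked, a \code{flags} table, and
#'   \code{rejected} set.
#' @export
quality_check <- function(track, extra_flags = NULL, overrides = NULL) {
  stopifnot(inherits(track, "swim_track"))
  T_ <- length(track$frames)
  len <- vapply(track$frames, function(f)
    tryCatch(body_length(f), error = function(e) NA_real_), numeric(1))
  ## robust moments: with a contaminated minority of bad frames (the very
  ## thing the rule must catch) plain mean/SD would inflate and mask them
  mu <- stats::median(len, na.rm = TRUE)
  sdv <- max(stats::mad(len, na.rm = TRUE), 0.01 * mu)
  flag_len <- is.na(len) | (len < mu - 2 * sdv)
  flag_track <- !vapply(track$frames, function(f) f$valid, logical(1))
  flag_extra <- if (is.null(extra_flags)) rep(FALSE, T_) else extra_flags
  flagged <- flag_len | flag_track | flag_extra
  src <- rep("auto", T_)
  whole_override <- NA
  if (!is.null(overrides) && nrow(overrides)) {
    for (r in seq_len(nrow(overrides))) {
      fr <- overrides$frame[r]
      if (fr == 0) { whole_override <- isTRUE(overrides$new_validity[r]); next }
      if (fr >= 1 && fr <= T_) {
        flagged[fr] <- !isTRUE(overrides$new_validity[r])
        src[fr] <- "manual"
      }
    }
  }
  for (t in seq_len(T_)) track$frames[[t]]$valid <- !flagged[t]
  track$flags <- data.frame(
    frame = which(flagged),
    flag_type = ifelse(flag_len[flagged], "length",
                       ifelse(flag_extra[flagged], "contact", "tracking")),
    source = src[flagged])
  track$rejected <- mean(flagged) > 0.20
  if (!is.na(whole_override)) track$rejected <- !whole_override
  track
}

#' Swap head and tail when reverse swimming dominates
#'
#' The tracker cannot tell head from tail; orientation is fixed after a
#' first measures pass. If the animal appears to swim in reverse more than
#' 50% of the time (strict), the labels are swapped and all measures must
#' be recomputed.
#'
#' @param track a \code{\link{swim_track}}.
#' @param reverse_fraction_first_pass percent of time in reverse under the
#'   initial arbitrary orientation.
#' @return The (possibly flipped) track.
#' @export
orient_head_tail <- function(track, reverse_fraction_first_pass) {
  if (!is.na(reverse_fraction_first_pass) &&
      reverse_fraction_first_pass > 50) flip_head_tail(track) else track
}

#' Track all swimmers through a video
#'
#' Segmentation on the first frame initializes one track per detected
#' animal; subsequent frames are tracked with \code{\link{track_step}},
#' with a fresh segmentation merged in every \code{keyframe_every} frames
#' (\code{\link{keyframe_merge}}); contact flags and the quality checker
#' are applied at the end.
#'
#' @param frames numeric array (width x height x n_frames) or list of
#'   matrices, animals dark on light background.
#' @param frame_rate frames per second.
#' @param params a \code{\link{track_params}} list.
#' @return List of \code{\link{swim_track}} objects.
#' @export
track_swimmers <- function(frames, frame_rate = 18,
                           params = track_params()) {
  get_frame <- if (is.list(frames)) function(t) frames[[t]]
               else function(t) frames[, , t]
  T_ <- if (is.list(frames)) length(frames) else dim(frames)[3]
  seg0 <- segment_frame(get_frame(1), params, 1L)
  A <- length(seg0$centerlines)
  if (A == 0L) return(list())
  cur <- lapply(seg0$centerlines, function(cl)
    resample_centerline(cl, params$n_points))
  hist <- lapply(seq_len(A), function(i) {
    v <- vector("list", T_); v[[1]] <- cur[[i]]; v
  })
  bk <- 2L * max(2L, round(params$expected_width / 3)) + 1L
  boxk <- matrix(1 / bk^2, bk, bk)
  blur_sigma <- max(0.5, params$expected_width / 6)
  for (t in 2:T_) {
    img1 <- get_frame(t - 1); img2 <- get_frame(t)
    dpatch <- as.matrix(EBImage::filter2(
      EBImage::Image(abs(img2 - img1)), boxk))
    blurred <- as.matrix(EBImage::gblur(EBImage::Image(img2), blur_sigma))
    seg <- if (t %% params$keyframe_every == 0L)
      segment_frame(img2, params, t) else NULL
    for (i in seq_len(A)) {
      stepped <- track_step(cur[[i]], img1, img2, params,
                            dpatch = dpatch, blurred = blurred)
      if (!is.null(seg)) {
        if (length(seg$centerlines)) {
          cen <- body_center(stepped)
          d <- vapply(seg$centerlines, function(cl)
            sum((body_center(cl) - cen)^2), numeric(1))
          j <- which.min(d)
          if (sqrt(d[j]) < 0.5 * body_length(stepped))
            stepped <- keyframe_merge(stepped, seg$centerlines[[j]], img2,
                                      params)
          else stepped$valid <- FALSE
        } else stepped$valid <- FALSE
      }
      hist[[i]][[t]] <- stepped
      cur[[i]] <- stepped
    }
  }
  tracks <- lapply(seq_len(A), function(i)
    swim_track(hist[[i]], frame_rate, sprintf("animal%d", i)))
  contact <- handle_contacts(tracks, params, frame_rate)
  lapply(seq_len(A), function(i)
    quality_check(tracks[[i]], extra_flags = contact[, i]))
}
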