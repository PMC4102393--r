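#' Analyze one swim trial
#'
#' The central entry point: takes one animal's track (or a precomputed
#' curvature kymograph), runs the curvature map, the averaged multi-window
#' short-time 2D Fourier analysis, and the ten behavioral measures, and
#' summarizes the trial with temporal medians and 10-90 percentile ranges.
#' If a first pass finds the animal in reverse more than 50% of the time,
#' the head and tail labels are swapped and everything is recomputed
#' (the tracker cannot tell head from tail; the wave direction can).
#'
#' @param track a \code{\link{swim_track}}, a list of
#'   \code{\link{centerline}} objects, or a \code{curvature_map} (in which
#'   case the postural measures -- curling, travel speed, brush stroke,
#'   activity index -- are unavailable).
#' @param frame_rate frames per second (taken from the track/map when
#'   available).
#' @param window_fraction arc fraction for the curvature circle fit.
#' @param windows short-time transform window lengths, frames.
#' @param eps_mode mode dominance threshold.
#' @param eps_range motionless-head guard for attenuation.
#' @param auto_orient swap head/tail when reverse fraction exceeds 50%.
#' @return An object of class \code{"swim_trial"}.
#' @examples
#' sim <- simulate(swim_scenario(f = 1.5, n = 1.5, duration_s = 10))
#' trial <- swim_trial(sim$track)
#' coef(trial)
#' @export
swim_trial <- function(track, frame_rate = NULL, window_fraction = 1 / 12,
                       windows = .default_windows, eps_mode = 0.02,
                       eps_range = 0.1, auto_orient = TRUE) {
  if (inherits(track, "swim_sim")) track <- track$track
  if (is.list(track) && !inherits(track, c("swim_track", "curvature_map")) &&
      all(vapply(track, inherits, logical(1), "centerline")))
    track <- swim_track(track, if (is.null(frame_rate)) 18 else frame_rate)
  map_only <- inherits(track, "curvature_map")
  if (map_only) {
    map <- track; track <- NULL
    if (is.null(frame_rate)) frame_rate <- map$frame_rate
  } else {
    stopifnot(inherits(track, "swim_track"))
    if (is.null(frame_rate)) frame_rate <- track$frame_rate
    map <- build_curvature_map(track, frame_rate, window_fraction)
  }
  pass <- function(track, map) {
    modes <- spectral_modes(map, windows, eps_mode)
    clock <- stroke_clock(modes, frame_rate)
    rev_ <- reverse_swimming(modes)
    list(modes = modes, clock = clock, reverse = rev_)
  }
  p1 <- pass(track, map)
  swapped <- FALSE
  if (auto_orient && !is.na(p1$reverse$percentage) &&
      p1$reverse$percentage > 50) {
    swapped <- TRUE
    if (map_only) {
      map$values <- -map$values[nrow(map$values):1, , drop = FALSE]
    } else {
      track <- flip_head_tail(track)
      map <- build_curvature_map(track, frame_rate, window_fraction)
    }
    p1 <- pass(track, map)
  }
  out <- summarize_trial(track, map, p1$modes, p1$clock,
                         eps_range = eps_range)
  out$head_tail_swapped <- swapped
  out$window_fraction <- window_fraction
  class(out) <- "swim_trial"
  out
}

#' Summarize a trial from its computed pieces
#'
#' @param track a \code{\link{swim_track}} or NULL (kymograph-only input).
#' @param map a \code{curvature_map}.
#' @param modes a \code{\link{spectral_modes}} data.frame.
#' @param clock a \code{\link{stroke_clock}}.
#' @param eps_range motionless-head guard for attenuation.
#' @return A list with the ten \code{\link{measure_series}}, the summary
#'   data.frame, \code{reverse_fraction} and \code{curl_fraction} (percent
#'   of time), \code{n_valid_frames}, \code{frame_rate}, \code{animal_id}.
#' @export
summarize_trial <- function(track, map, modes, clock, eps_range = 0.1) {
  if (!any(map$valid_frames))
    stop("cannot summarize trial: all frames are invalid")
  if (!any(modes$defined))
    stop("cannot summarize trial: no dominant wave mode in any frame")
  ms <- list(
    wave_initiation_rate = wave_initiation_rate(modes),
    body_wave_number = body_wave_number(modes),
    asymmetry = asymmetry(map, clock),
    stretch = stretch(map, clock),
    attenuation = attenuation(map, clock, eps_range),
    reverse_swimming = reverse_swimming(modes))
  if (!is.null(track)) {
    ms$curling <- curling(track)
    ms$travel_speed <- travel_speed(track, clock, map$frame_rate)
    ms$brush_stroke <- brush_stroke(track, clock)
    ms$activity_index <- activity_index(ms$brush_stroke, clock,
                                        map$frame_rate)
  } else {
    na_series <- function(nm, units)
      measure_series(nm, rep(NA_real_, ncol(map$values)), units)
    ms$curling <- na_series("curling", "binary")
    ms$curling$percentage <- NA_real_
    ms$travel_speed <- na_series("travel_speed", "body lengths/s")
    ms$brush_stroke <- na_series("brush_stroke", "body areas")
    ms$activity_index <- na_series("activity_index", "body areas/s")
  }
  ms <- ms[measure_names]
  score <- vapply(measure_names, function(nm) {
    if (nm %in% c("reverse_swimming", "curling")) ms[[nm]]$percentage
    else ms[[nm]]$median
  }, numeric(1))
  summary_df <- data.frame(
    measure = measure_names,
    score = unname(score),
    p10 = vapply(ms, `[[`, numeric(1), "p10"),
    p90 = vapply(ms, `[[`, numeric(1), "p90"),
    units = vapply(ms, `[[`, character(1), "units"),
    row.names = NULL)
  summary_df$units[summary_df$measure %in%
                     c("reverse_swimming", "curling")] <- "% of time"
  list(measures = ms, summary = summary_df,
       reverse_fraction = ms$reverse_swimming$percentage,
       curl_fraction = ms$curling$percentage,
       n_valid_frames = sum(map$valid_frames),
       frame_rate = map$frame_rate,
       animal_id = if (!is.null(track)) track$animal_id else NA_character_,
       track = track, map = map, modes = modes, clock = clock)
}

#' @export
print.swim_trial <- function(x, digits = 3, ...) {
  cat(sprintf("Swim trial '%s': %d valid frames @ %g fps%s\n",
              x$animal_id, x$n_valid_frames, x$frame_rate,
              if (x$head_tail_swapped) " (head/tail swapped)" else ""))
  df <- x$summary
  df$score <- signif(df$score, digits)
  df$p10 <- signif(df$p10, digits)
  df$p90 <- signif(df$p90, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.swim_trial <- function(object, ...) {
  object$summary
}

#' Trial summary scores
#'
#' @param object a \code{\link{swim_trial}}.
#' @param ... unused.
#' @return Named numeric vector of the ten summary scores: temporal
#'   medians, except reverse swimming and curling which are percentages of
#'   time.
#' @export
coef.swim_trial <- function(object, ...) {
  stats::setNames(object$summary$score, object$summary$measure)
}

#' Plot a swim trial: kymograph and measure traces
#'
#' @param x a \code{\link{swim_trial}}.
#' @param measures which measure series to draw below the kymograph.
#' @param ... unused.
#' @export
plot.swim_trial <- function(x, measures = c("wave_initiation_rate",
                                            "asymmetry", "attenuation"),
                            ...) {
  op <- graphics::par(mfrow = c(length(measures) + 1L, 1L),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  vals <- x$map$values
  tt <- (seq_len(ncol(vals)) - 1) / x$frame_rate
  lim <- max(abs(vals), na.rm = TRUE)
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  graphics::image(tt, seq_len(nrow(vals)), t(vals), zlim = c(-lim, lim),
                  col = pal, xlab = "", ylab = "body segment (tail..head)",
                  main = "curvature kymograph", useRaster = TRUE)
  for (nm in measures) {
    s <- x$measures[[nm]]
    graphics::plot(tt, s$values, type = "l", xlab = "", ylab = s$units,
                   main = nm)
    graphics::abline(h = s$median, col = "red")
    graphics::rect(tt[1], s$p10, tt[length(tt)], s$p90,
                   col = grDevices::adjustcolor("gray", 0.3), border = NA)
  }
  invisible(x)
}

#' One-row per-animal record of summary scores joined to trial metadata
#'
#' @param trial a \code{\link{swim_trial}}.
#' @param meta named list or one-row data.frame of metadata tags (strain,
#'   animal_age, ...).
#' @return One-row data.frame: metadata columns, ten scores, and
#'   p10/p90 pairs for the continuous measures.
#' @export
swim_record <- function(trial, meta = list()) {
  stopifnot(inherits(trial, "swim_trial"))
  sc <- as.list(coef(trial))
  extras <- list()
  for (nm in measure_names) {
    if (nm %in% c("reverse_swimming", "curling")) next
    extras[[paste0(nm, "_p10")]] <- trial$measures[[nm]]$p10
    extras[[paste0(nm, "_p90")]] <- trial$measures[[nm]]$p90
  }
  meta <- as.list(meta)
  if (is.null(meta$animal_id)) meta$animal_id <- trial$animal_id
  as.data.frame(c(meta, sc, extras), stringsAsFactors = FALSE)
}
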