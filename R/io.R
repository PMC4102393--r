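#' @name io
#' @title Centerline tables and result files
#'
#' @description
#' Centerline tables are the import/export surface for third-party
#' trackers: any tracking method that provides body coordinates and
#' widths can feed the measures. The CSV layout is one row per (frame,
#' point): columns \code{frame} (1-based), \code{animal}, \code{point_index}
#' (0-based, tail first), \code{x}, \code{y}, \code{half_width},
#' \code{valid} (0/1).
NULL

#' Write tracks as a centerline CSV table
#'
#' @param tracks a \code{\link{swim_track}} or list of them.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_centerlines <- function(tracks, path) {
  if (inherits(tracks, "swim_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    do.call(rbind, lapply(seq_along(tr$frames), function(t) {
      f <- tr$frames[[t]]
      data.frame(frame = t, animal = tr$animal_id,
                 point_index = seq_len(nrow(f$points)) - 1L,
                 x = f$points[, 1], y = f$points[, 2],
                 half_width = f$half_widths,
                 valid = as.integer(f$valid))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a centerline CSV table into tracks
#'
#' @param path CSV path in the layout written by
#'   \code{\link{write_centerlines}}.
#' @param frame_rate frames per second to attach to the tracks.
#' @return List of \code{\link{swim_track}} objects (one per animal).
#' @export
read_centerlines <- function(path, frame_rate = 18) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "point_index", "x", "y", "half_width", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("centerline table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$animal)) df$animal <- "animal1"
  lapply(split(df, df$animal), function(sub) {
    frames <- lapply(split(sub, sub$frame), function(fr) {
      fr <- fr[order(fr$point_index), ]
      centerline(cbind(fr$x, fr$y), fr$half_width, fr$frame[1],
                 valid = all(fr$valid == 1L))
    })
    swim_track(frames[order(as.integer(names(frames)))], frame_rate,
               sub$animal[1])
  })
}

#' Write the per-frame flags sidecar of tracked animals
#'
#' @param tracks a \code{\link{swim_track}} or list of them.
#' @param path output CSV path (columns frame, animal, flag_type, source).
#' @return The path, invisibly.
#' @export
write_flags <- function(tracks, path) {
  if (inherits(tracks, "swim_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    if (!nrow(tr$flags)) return(NULL)
    cbind(animal = tr$animal_id, tr$flags)
  }))
  if (is.null(rows))
    rows <- data.frame(animal = character(), frame = integer(),
                       flag_type = character(), source = character())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Apply a manual review file to tracked animals
#'
#' The review file is a CSV with columns \code{animal}, \code{frame},
#' \code{new_validity}; \code{frame = 0} switches the verdict for the
#' whole animal.
#'
#' @param tracks list of \code{\link{swim_track}} objects.
#' @param path review CSV path.
#' @return The tracks with overrides applied (via
#'   \code{\link{quality_check}}).
#' @export
apply_review <- function(tracks, path) {
  ov <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(tracks, function(tr) {
    sub <- ov[ov$animal == tr$animal_id, , drop = FALSE]
    if (!nrow(sub)) return(tr)
    quality_check(tr, overrides = sub)
  })
}

#' Write a curvature kymograph as CSV (segments x frames)
#'
#' @param map a \code{curvature_map}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_kymograph <- function(map, path) {
  utils::write.csv(as.data.frame(map$values), path, row.names = FALSE)
  invisible(path)
}

#' Write the full per-frame series and summary of a trial as JSON
#'
#' @param trial a \code{\link{swim_trial}}.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_trial_json <- function(trial, path) {
  out <- list(
    animal_id = trial$animal_id,
    frame_rate = trial$frame_rate,
    n_valid_frames = trial$n_valid_frames,
    head_tail_swapped = trial$head_tail_swapped,
    summary = trial$summary,
    series = lapply(trial$measures, function(s) s$values))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
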