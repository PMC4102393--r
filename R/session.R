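#' @name session
#' @title Trial registry and grouped comparison
#'
#' @description
#' Desk-scale session layer: a flat-file (CSV) registry of recorded videos
#' with their identifying tags, plus grouped statistics and plots over
#' per-animal summary records. The registry is plain text so it can be
#' versioned and inspected.
NULL

.registry_required <- c("sample_number", "date_recorded", "investigator",
                        "experiment", "trial_number", "strain",
                        "animal_age", "n_animals", "duration_s", "path")

#' Register a video in a flat-file registry
#'
#' @param meta named list or one-row data.frame with at least the standard
#'   tags: sample_number (unique), date_recorded, investigator,
#'   experiment, trial_number, strain, animal_age, n_animals, duration_s,
#'   path. Additional tags may be added at any point (new columns are
#'   created; existing rows get NA).
#' @param registry path of the registry CSV (created if missing).
#' @param check_path require that \code{meta$path} exists on disk.
#' @return The updated registry data.frame, invisibly.
#' @export
register_video <- function(meta, registry, check_path = TRUE) {
  meta <- as.data.frame(as.list(meta), stringsAsFactors = FALSE)
  miss <- setdiff(.registry_required, names(meta))
  if (length(miss))
    stop("missing registry tags: ", paste(miss, collapse = ", "))
  if (!is.finite(meta$duration_s) || meta$duration_s <= 0)
    stop("duration_s must be > 0")
  if (check_path && !file.exists(meta$path))
    stop("video path does not exist: ", meta$path)
  reg <- if (file.exists(registry)) read_registry(registry) else NULL
  if (!is.null(reg) && meta$sample_number %in% reg$sample_number)
    stop("duplicate sample_number: ", meta$sample_number)
  if (!is.null(reg)) {
    for (nm in setdiff(names(reg), names(meta))) meta[[nm]] <- NA
    for (nm in setdiff(names(meta), names(reg))) reg[[nm]] <- NA
    reg <- rbind(reg, meta[names(reg)])
  } else reg <- meta
  utils::write.csv(reg, registry, row.names = FALSE)
  invisible(reg)
}

#' Read a registry file
#'
#' @param registry path of the registry CSV.
#' @return Data frame of registered videos.
#' @export
read_registry <- function(registry) {
  utils::read.csv(registry, stringsAsFactors = FALSE)
}

#' Query a registry by tag values
#'
#' @param registry path of the registry CSV or a registry data.frame.
#' @param ... named tag filters, e.g. \code{strain = "N2", animal_age = 4}.
#' @return The matching rows.
#' @export
query_registry <- function(registry, ...) {
  reg <- if (is.character(registry)) read_registry(registry) else registry
  filt <- list(...)
  keep <- rep(TRUE, nrow(reg))
  for (nm in names(filt)) {
    if (!nm %in% names(reg)) stop("unknown tag: ", nm)
    keep <- keep & (reg[[nm]] %in% filt[[nm]])
  }
  reg[keep, , drop = FALSE]
}

.stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Covariance ellipse of a 2D point cloud
#'
#' Axes are the principal directions of the sample covariance; the
#' half-axis lengths are one standard deviation along each.
#'
#' @param x,y coordinates.
#' @param n_points polygon resolution.
#' @return List with \code{center}, \code{axes} (2x2, columns = unit
#'   principal directions), \code{radii} (SDs), and \code{polygon}
#'   (n_points x 2 outline).
#' @export
cov_ellipse <- function(x, y, n_points = 100L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  ctr <- c(mean(x), mean(y))
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
  radii <- sqrt(pmax(ev$values, 0))
  th <- seq(0, 2 * pi, length.out = n_points)
  pts <- t(ctr + ev$vectors %*% rbind(radii[1] * cos(th),
                                      radii[2] * sin(th)))
  list(center = ctr, axes = ev$vectors, radii = radii, polygon = pts)
}

#' Compare summary scores between groups of animals
#'
#' Computes per-group n, mean, SEM and median of each requested measure
#' and pairwise two-sided Mann-Whitney U tests with Holm correction
#' (configurable to Welch's t). Asymmetry enters group statistics as the
#' absolute value of the per-animal median, so animals that happen to
#' favor left or right do not cancel out.
#'
#' @param records data.frame of per-animal records
#'   (\code{\link{swim_record}} rows plus metadata).
#' @param group_by column name(s) defining the groups.
#' @param measures measure columns to analyze (default: all ten present).
#' @param test "wilcox" (Mann-Whitney U) or "t" (Welch).
#' @return An object of class \code{"group_comparison"}: list with
#'   \code{stats} (group x measure summary), \code{tests} (pairwise
#'   p-values, Holm-adjusted, significance stars at the ns/*/**/***/****
#'   tiers), \code{group_by}, \code{records}.
#' @export
compare_groups <- function(records, group_by,
                           measures = intersect(measure_names,
                                                names(records)),
                           test = c("wilcox", "t")) {
  test <- match.arg(test)
  stopifnot(all(group_by %in% names(records)))
  miss <- setdiff(measures, names(records))
  if (length(miss))
    stop("measure(s) missing from records: ", paste(miss, collapse = ", "))
  for (m in measures) {
    bad <- which(!is.finite(records[[m]]) & !is.na(records[[m]]))
    if (length(bad))
      stop("non-finite ", m, " in record(s) ", paste(bad, collapse = ", "))
  }
  rec <- records
  if ("asymmetry" %in% measures) rec$asymmetry <- abs(rec$asymmetry)
  key <- interaction(rec[group_by], drop = TRUE, sep = ":")
  groups <- levels(key)
  if (any(table(key) < 1L)) stop("every group needs at least one record")
  stats_df <- do.call(rbind, lapply(groups, function(g) {
    sub <- rec[key == g, , drop = FALSE]
    do.call(rbind, lapply(measures, function(m) {
      v <- sub[[m]][is.finite(sub[[m]])]
      data.frame(group = g, measure = m, n = length(v),
                 mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                 median = stats::median(v))
    }))
  }))
  tests_df <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    tests_df <- do.call(rbind, lapply(measures, function(m) {
      p <- vapply(pairs, function(pr) {
        a <- rec[[m]][key == pr[1]]; b <- rec[[m]][key == pr[2]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 1L || length(b) < 1L) return(NA_real_)
        if (test == "wilcox")
          stats::wilcox.test(a, b, exact = FALSE)$p.value
        else stats::t.test(a, b)$p.value
      }, numeric(1))
      data.frame(measure = m,
                 group1 = vapply(pairs, `[`, character(1), 1L),
                 group2 = vapply(pairs, `[`, character(1), 2L),
                 p = p, p_adj = stats::p.adjust(p, "holm"))
    }))
    tests_df$stars <- vapply(tests_df$p_adj, .stars, character(1))
  }
  structure(list(stats = stats_df, tests = tests_df, group_by = group_by,
                 measures = measures, records = rec, test = test,
                 .key = key),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison by", paste(x$group_by, collapse = ", "), "\n\n")
  print(x$stats, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nPairwise", if (x$test == "wilcox") "Mann-Whitney U (Holm)"
        else "Welch t (Holm)", "\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a group comparison
#'
#' \code{type = "dot"}: per-animal dots with group mean and SEM bars.
#' \code{type = "hist"}: line histogram of per-animal medians binned to
#' integers (the plot line delineates the contour of the bins).
#' \code{type = "scatter2d"}: one measure against another, with per-group
#' covariance ellipses (principal directions, 1 SD half-axes).
#'
#' @param x a \code{\link{compare_groups}} result.
#' @param type plot type.
#' @param measure measure to plot (first analyzed measure by default).
#' @param measure2 second measure for \code{type = "scatter2d"}.
#' @param ... passed to the underlying plot call.
#' @export
plot.group_comparison <- function(x, type = c("dot", "hist", "scatter2d"),
                                  measure = x$measures[1],
                                  measure2 = NULL, ...) {
  type <- match.arg(type)
  key <- x$.key
  groups <- levels(key)
  cols <- grDevices::hcl.colors(max(3L, length(groups)), "Dark 3")
  if (type == "dot") {
    v <- x$records[[measure]]
    gi <- as.integer(key)
    graphics::plot(gi + stats::runif(length(gi), -0.12, 0.12), v,
                   xaxt = "n", xlab = "", ylab = measure,
                   col = cols[gi], pch = 16, xlim = c(0.5, length(groups) + 0.5),
                   ...)
    graphics::axis(1, at = seq_along(groups), labels = groups)
    st <- x$stats[x$stats$measure == measure, ]
    graphics::segments(seq_along(groups) - 0.2, st$mean,
                       seq_along(groups) + 0.2, st$mean, lwd = 2)
    graphics::arrows(seq_along(groups), st$mean - st$sem,
                     seq_along(groups), st$mean + st$sem,
                     angle = 90, code = 3, length = 0.05)
  } else if (type == "hist") {
    v <- round(x$records[[measure]])
    rng <- range(v, na.rm = TRUE)
    bins <- rng[1]:rng[2]
    first <- TRUE
    for (g in seq_along(groups)) {
      cnt <- tabulate(factor(v[key == groups[g]], levels = bins),
                      nbins = length(bins))
      if (first) {
        graphics::plot(bins, cnt, type = "s", col = cols[g],
                       xlab = paste("median", measure),
                       ylab = "number of individuals", ...)
        first <- FALSE
      } else graphics::lines(bins, cnt, type = "s", col = cols[g])
    }
    graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                     lty = 1, bty = "n")
  } else {
    stopifnot(!is.null(measure2))
    vx <- x$records[[measure]]; vy <- x$records[[measure2]]
    graphics::plot(vx, vy, col = cols[as.integer(key)], pch = 16,
                   xlab = measure, ylab = measure2, ...)
    for (g in seq_along(groups)) {
      sel <- key == groups[g]
      if (sum(sel) >= 3L) {
        el <- cov_ellipse(vx[sel], vy[sel])
        graphics::lines(el$polygon, col = cols[g], lwd = 2)
      }
    }
    graphics::legend("topright", legend = groups,
                     col = cols[seq_along(groups)], pch = 16, bty = "n")
  }
  invisible(x)
}

#' Export per-animal records to CSV
#'
#' Writes a wide table (one row per animal, stable column order) and a
#' tidy table (one row per animal per measure). Reading the wide file back
#' returns identical values.
#'
#' @param records data.frame of per-animal records.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Named character vector with the paths written.
#' @export
export_results <- function(records, dir, prefix = "swim_results") {
  stopifnot(nrow(records) > 0L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide_path <- file.path(dir, paste0(prefix, "_wide.csv"))
  tidy_path <- file.path(dir, paste0(prefix, "_tidy.csv"))
  utils::write.csv(records, wide_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  present <- intersect(measure_names, names(records))
  id_cols <- setdiff(names(records), c(present,
    paste0(rep(present, each = 2), c("_p10", "_p90"))))
  tidy <- do.call(rbind, lapply(present, function(m)
    cbind(records[id_cols], measure = m, value = records[[m]])))
  utils::write.csv(tidy, tidy_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  c(wide = wide_path, tidy = tidy_path)
}

#' Read back exported records
#'
#' @param path a wide CSV written by \code{\link{export_results}}.
#' @return Data frame of records.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
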