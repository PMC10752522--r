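# Retention counting, suspension statistics, and text-based result I/O
# (CSV time series, JSON summaries, legacy VTK snapshots).

#' Retention criterion
#'
#' A cell counts as retained when it has held at least `min_bonds` live
#' bonds continuously for `min_duration` seconds and its centroid speed is
#' below the threshold (by default 10% of the instantaneous bulk velocity
#' around the macrophages, mimicking the visual "firmly adhered"
#' classification; transient touches are excluded).
#'
#' @param min_bonds minimum live bond count (0 counts every cell).
#' @param min_duration minimum continuous bound time, s.
#' @param max_speed absolute centroid speed threshold, um/s (overrides
#'   `max_speed_frac` when given).
#' @param max_speed_frac speed threshold as a fraction of the bulk velocity.
#' @return a `retention_criterion` list.
#' @export
retention_criterion <- function(min_bonds = 1L, min_duration = 0.05,
                                max_speed = NULL, max_speed_frac = 0.1) {
  stopifnot(min_bonds >= 0, min_duration >= 0,
            is.null(max_speed) || max_speed >= 0, max_speed_frac >= 0)
  structure(list(min_bonds = as.integer(min_bonds),
                 min_duration = min_duration, max_speed = max_speed,
                 max_speed_frac = max_speed_frac),
            class = "retention_criterion")
}

#' Count retained cells over time
#'
#' Pure function of a trajectory and a criterion: per-snapshot retained
#' flags from the bond-count and centroid-speed channels, aggregated to the
#' retention time series (reported time, retained count, mean suspension
#' velocity).
#'
#' @param traj a `splenosim_trajectory`.
#' @param criterion a [retention_criterion()].
#' @return data.frame `time`, `retained`, `mean_velocity`, plus the
#'   per-cell logical matrix as attribute `"retained_matrix"`.
#' @export
count_retained <- function(traj, criterion = retention_criterion()) {
  if (is.null(traj$nb)) stop("trajectory lacks a bond-count channel")
  nb <- traj$nb
  nsnap <- nrow(nb); ncell <- ncol(nb)
  if (criterion$min_bonds == 0L) {
    ret <- matrix(TRUE, nsnap, ncell)
  } else {
    ok <- nb >= criterion$min_bonds
    dt_rec <- if (nsnap > 1) stats::median(diff(traj$t_sim)) else Inf
    need <- if (criterion$min_duration > 0)
      ceiling(criterion$min_duration / dt_rec) + 1L else 1L
    ret <- matrix(FALSE, nsnap, ncell)
    for (c in seq_len(ncell)) {
      r <- 0L
      for (k in seq_len(nsnap)) {
        r <- if (ok[k, c]) r + 1L else 0L
        ret[k, c] <- r >= need
      }
    }
    vmax <- if (!is.null(criterion$max_speed)) rep(criterion$max_speed, nsnap)
            else criterion$max_speed_frac * bulk_velocity_at(traj, traj$t_sim)
    ret <- ret & (traj$speed < matrix(vmax, nsnap, ncell))
  }
  out <- data.frame(time = traj$t, retained = as.integer(rowSums(ret)),
                    mean_velocity = rowMeans(traj$speed))
  attr(out, "retained_matrix") <- ret
  out
}

#' Mean suspension velocity
#'
#' Mean centroid speed over all cells (free and retained) at each snapshot;
#' decreases towards a baseline as capture proceeds.
#'
#' @param traj a `splenosim_trajectory` with at least one cell.
#' @return data.frame `time`, `mean_velocity`.
#' @export
mean_suspension_velocity <- function(traj) {
  if (ncol(traj$speed) < 1) stop("trajectory has no cells")
  data.frame(time = traj$t, mean_velocity = rowMeans(traj$speed))
}

#' Plateau summary of a retention series
#'
#' The retained count is considered at plateau when it does not change over
#' the trailing `trailing_frac` of the run.
#'
#' @param series data.frame from [count_retained()].
#' @param trailing_frac trailing window fraction.
#' @return list `value` (count over the trailing window), `reached`
#'   (logical), `time_to_plateau` (first time the series reaches its final
#'   value and stays there; NA if not reached).
#' @export
plateau_info <- function(series, trailing_frac = 0.2) {
  n <- nrow(series)
  win <- max(2L, ceiling(trailing_frac * n))
  tailc <- series$retained[(n - win + 1):n]
  reached <- max(tailc) == min(tailc)
  value <- tailc[length(tailc)]
  ttp <- NA_real_
  if (reached) {
    stable_from <- n
    for (k in n:1) {
      if (series$retained[k] == value) stable_from <- k else break
    }
    ttp <- series$time[stable_from]
  }
  list(value = value, reached = reached, time_to_plateau = ttp)
}

# ---- file output ----------------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

write_series_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,retained,mean_velocity", con)
  writeLines(paste(fmt_num(series$time), series$retained,
                   fmt_num(series$mean_velocity), sep = ","), con)
  invisible(path)
}

#' Read a retention time-series CSV
#' @param path CSV written by [write_outputs()].
#' @return data.frame `time`, `retained`, `mean_velocity`.
#' @export
read_retention_csv <- function(path) {
  df <- utils::read.csv(path)
  df$retained <- as.integer(df$retained)
  df
}

#' Write assay outputs
#'
#' Writes one RFC-4180 CSV per replicate (`series_seed<k>.csv`: time,
#' retained count, mean suspension velocity), a JSON summary
#' (`summary.json`: assay name, config hash, seeds, plateau statistics,
#' criterion), and, when the result carries final cell outlines, a legacy
#' VTK polydata snapshot. Exported numbers reproduce the in-memory arrays
#' exactly (17 significant digits); files round-trip losslessly.
#'
#' @param result an assay result (see [retention_assay()]).
#' @param dir output directory.
#' @param overwrite allow overwriting existing files.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(result$series)) {
    p <- file.path(dir, sprintf("series_seed%d.csv", result$seeds[k]))
    if (file.exists(p) && !overwrite) stop("refusing to overwrite ", p)
    write_series_csv(result$series[[k]], p)
    paths <- c(paths, p)
  }
  sj <- file.path(dir, "summary.json")
  if (file.exists(sj) && !overwrite) stop("refusing to overwrite ", sj)
  summary <- list(
    assay = result$name, config_hash = result$config_hash,
    seeds = result$seeds,
    plateau = result$plateau, plateau_mean = mean(result$plateau),
    plateau_sd = stats::sd(result$plateau),
    reached = result$reached,
    criterion = unclass(result$criterion))
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, sj)
  if (!is.null(result$final_outlines)) {
    vp <- file.path(dir, "final_snapshot.vtk")
    if (file.exists(vp) && !overwrite) stop("refusing to overwrite ", vp)
    write_outlines_vtk(result$final_outlines, result$macs, vp)
    paths <- c(paths, vp)
  }
  invisible(paths)
}

#' Validate an assay summary JSON
#'
#' Structural validation against the shipped schema
#' (`inst/schema/assay_summary.schema.json`): required fields and types.
#'
#' @param path summary.json path.
#' @return invisibly TRUE, or an error.
#' @export
validate_summary_json <- function(path) {
  x <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(system.file("schema",
                                            "assay_summary.schema.json",
                                            package = "splenosim"))
  req <- unlist(schema$required)
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("summary.json missing required fields: ", paste(miss, collapse = ", "))
  types <- schema$properties
  for (nm in intersect(names(types), names(x))) {
    ty <- types[[nm]]$type
    okay <- switch(ty,
      string = is.character(x[[nm]]),
      number = is.numeric(x[[nm]]),
      array = is.list(x[[nm]]) || length(x[[nm]]) >= 1,
      object = is.list(x[[nm]]),
      TRUE)
    if (!okay) stop(sprintf("summary.json field '%s' is not of type %s",
                            nm, ty))
  }
  invisible(TRUE)
}

#' Write 2D outlines as legacy VTK polydata
#'
#' Cell polygons and macrophage cap circles in the z = 0 plane, as an
#' ASCII legacy-VTK POLYDATA file.
#'
#' @param outlines list of n x 2 vertex matrices.
#' @param macs optional matrix (cx, cz, R) of caps (discretised to 48-gons).
#' @param path output file.
#' @export
write_outlines_vtk <- function(outlines, macs = NULL, path) {
  polys <- outlines
  if (!is.null(macs) && nrow(macs) > 0) {
    th <- seq(0, 2 * pi, length.out = 49)[-49]
    for (i in seq_len(nrow(macs)))
      polys[[length(polys) + 1]] <-
        cbind(macs[i, 1] + macs[i, 3] * cos(th),
              macs[i, 2] + macs[i, 3] * sin(th))
  }
  npts <- sum(vapply(polys, nrow, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "splenosim 2D snapshot",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", npts)), con)
  for (p in polys)
    writeLines(sprintf("%.10g %.10g 0", p[, 1], p[, 2]), con)
  nf <- length(polys)
  tot <- nf + npts
  writeLines(sprintf("POLYGONS %d %d", nf, tot), con)
  off <- 0L
  for (p in polys) {
    writeLines(paste(c(nrow(p), off:(off + nrow(p) - 1L)), collapse = " "),
               con)
    off <- off + nrow(p)
  }
  invisible(path)
}
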