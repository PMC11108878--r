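## The mutually-exclusive distance-occupancy statistic.  For a threshold d
## (nm) and contraction factor C in (0, 1], a frame is counted when the
## PscC-PscC distance is below C*d while the PscA-PscC distance exceeds d,
## or vice versa.  Peaks of the resulting occupancy-vs-d curves locate the
## alternating ("shuttle") distance regimes.

#' Mutually-exclusive occupancy fraction at one (C, d)
#'
#' Fraction of frames in which one distance is small (\code{< C*d}) while the
#' other is simultaneously large (\code{> d}), counting both assignments:
#' \deqn{f(C,d) = \frac{1}{n}\,\left|\{t : (D_1(t) < Cd \wedge D_2(t) > d)
#'   \vee (D_1(t) > d \wedge D_2(t) < Cd)\}\right|.}
#' Inequalities are strict; frames exactly at a threshold count for neither
#' branch (a measure-zero event under continuous noise).
#'
#' @param d1 PscC-PscC (Fe-Fe) distances: numeric vector or
#'   \code{\link{distance_series}}.
#' @param d2 PscA-PscC (Fe-Mg) distances, frame-aligned with \code{d1}.
#' @param d threshold in nm (> 0).
#' @param C contraction factor in (0, 1].
#' @return the occupancy fraction in [0, 1].
#' @examples
#' exclusion_fraction(rep(2, 10), rep(3, 10), d = 2.5, C = 1)  # 1
#' @export
exclusion_fraction <- function(d1, d2, d, C = 1) {
  v1 <- series_values(d1)
  v2 <- series_values(d2)
  if (length(v1) != length(v2))
    stop("alignment error: series differ in length (", length(v1), " vs ",
         length(v2), ")")
  if (length(v1) == 0L) stop("empty series")
  if (!is.numeric(d) || d <= 0) stop("'d' must be > 0 nm")
  if (!is.numeric(C) || C <= 0 || C > 1) stop("'C' must be in (0, 1]")
  cd <- C * d
  mean((v1 < cd & v2 > d) | (v1 > d & v2 < cd))
}

#' Sweep the occupancy statistic over (C, d)
#'
#' Evaluates \code{\link{exclusion_fraction}} on a grid of thresholds d and
#' contraction factors C.  Defaults follow the published sweep: C from 0.67
#' to 1.00 in steps of 0.01 (34 curves) and d from 1.5 to 4.5 nm in steps of
#' 0.01 nm, which resolves peak positions quoted at 0.1 nm granularity with
#' margin.
#'
#' @param d1,d2 frame-aligned distance inputs as in
#'   \code{\link{exclusion_fraction}}.
#' @param C numeric vector of contraction factors.
#' @param d_grid strictly increasing numeric vector of thresholds in nm.
#' @return an object of class \code{"occupancy_scan"}: list with \code{C},
#'   \code{d_grid}, \code{fraction} (matrix, rows = C, columns = d),
#'   \code{n_frames} and \code{pair_labels}.
#' @examples
#' sim <- simulate_switching_distances(switching_params(n_frames = 2000))
#' sc <- occupancy_scan(sim$fefe, sim$femg, C = c(0.9, 1),
#'                      d_grid = seq(2, 4, 0.05))
#' peaks(sc)
#' @export
occupancy_scan <- function(d1, d2, C = seq(0.67, 1, by = 0.01),
                           d_grid = seq(1.5, 4.5, by = 0.01)) {
  v1 <- series_values(d1)
  v2 <- series_values(d2)
  if (length(v1) != length(v2))
    stop("alignment error: series differ in length")
  if (length(C) == 0L || length(d_grid) == 0L)
    stop("empty C or d grid")
  if (any(diff(d_grid) <= 0)) stop("'d_grid' must be strictly increasing")
  frac <- matrix(0, length(C), length(d_grid),
                 dimnames = list(sprintf("C=%.2f", C), NULL))
  for (i in seq_along(C)) {
    cd <- C[i] * d_grid
    for (j in seq_along(d_grid)) {
      frac[i, j] <- mean((v1 < cd[j] & v2 > d_grid[j]) |
                           (v1 > d_grid[j] & v2 < cd[j]))
    }
  }
  lab1 <- if (inherits(d1, "distance_series")) d1$pair_label else "PscC-PscC"
  lab2 <- if (inherits(d2, "distance_series")) d2$pair_label else "PscA-PscC"
  structure(list(C = C, d_grid = d_grid, fraction = frac,
                 n_frames = length(v1), pair_labels = c(lab1, lab2)),
            class = "occupancy_scan")
}

#' @export
print.occupancy_scan <- function(x, ...) {
  cat(sprintf("occupancy_scan: %d curves (C %.2f..%.2f), d %.2f..%.2f nm (%d points), %d frames\n",
              length(x$C), min(x$C), max(x$C), min(x$d_grid), max(x$d_grid),
              length(x$d_grid), x$n_frames))
  best <- which(x$fraction == max(x$fraction), arr.ind = TRUE)[1L, ]
  cat(sprintf("  max occupancy %.3f at C=%.2f, d=%.2f nm\n",
              max(x$fraction), x$C[best[1L]], x$d_grid[best[2L]]))
  invisible(x)
}

#' @export
summary.occupancy_scan <- function(object, ...) {
  pk <- peaks(object)
  cat("Peak occupancy by C value:\n")
  print(utils::head(pk[order(-pk$fraction), ], 10L), row.names = FALSE)
  invisible(pk)
}

#' Peaks of occupancy curves
#'
#' Finds local maxima of the occupancy-vs-d curve for each C, with
#' topographic prominence at least \code{min_prominence} (default 0.02, i.e.
#' two percentage points, below the coarsest differences worth reporting).
#' Within a curve, peaks are sorted by occupancy descending, ties toward
#' smaller d.
#'
#' @param scan an \code{"occupancy_scan"}.
#' @param min_prominence minimum prominence (occupancy fraction units).
#' @return data.frame with columns \code{C}, \code{d_peak},
#'   \code{low_threshold} (\code{C*d_peak}), \code{fraction},
#'   \code{prominence}.
#' @export
peaks <- function(scan, min_prominence = 0.02) {
  stopifnot(inherits(scan, "occupancy_scan"))
  out <- lapply(seq_along(scan$C), function(i) {
    pk <- grid_peaks(scan$fraction[i, ], min_prominence)
    if (nrow(pk) == 0L) return(NULL)
    pk <- pk[order(-pk$height, pk$index), , drop = FALSE]
    data.frame(C = scan$C[i], d_peak = scan$d_grid[pk$index],
               low_threshold = scan$C[i] * scan$d_grid[pk$index],
               fraction = pk$height, prominence = pk$prominence)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(C = numeric(0), d_peak = numeric(0),
                      low_threshold = numeric(0), fraction = numeric(0),
                      prominence = numeric(0))
  rownames(out) <- NULL
  out
}

#' Peak table for selected C values
#'
#' Formats occupancy peaks for a subset of C values in the style of the
#' published summary table: for each peak, the small-distance threshold
#' \code{C*d}, the large-distance threshold \code{d}, and the percentage of
#' simulation time (pooled frames) spent in the mutually-exclusive regime.
#'
#' @param scan an \code{"occupancy_scan"}.
#' @param C_subset C values to report (must be present in the scan, matched
#'   within 1e-9).
#' @param min_prominence passed to \code{\link{peaks}}.
#' @return data.frame with columns \code{C}, \code{d_peak_nm},
#'   \code{low_threshold_nm}, \code{percent}.
#' @export
peak_table <- function(scan, C_subset = c(1.0, 0.9, 0.8),
                       min_prominence = 0.02) {
  stopifnot(inherits(scan, "occupancy_scan"))
  if (length(C_subset) == 0L)
    return(data.frame(C = numeric(0), d_peak_nm = numeric(0),
                      low_threshold_nm = numeric(0), percent = numeric(0)))
  idx <- vapply(C_subset, function(cc) {
    hit <- which(abs(scan$C - cc) < 1e-9)
    if (length(hit) != 1L)
      stop("lookup error: C = ", cc, " was not computed in this scan")
    hit
  }, 1L)
  pk <- peaks(scan, min_prominence)
  pk <- pk[pk$C %in% scan$C[idx], , drop = FALSE]
  data.frame(C = pk$C, d_peak_nm = pk$d_peak,
             low_threshold_nm = pk$low_threshold,
             percent = 100 * pk$fraction)
}

#' Two-vector projection of sampled frames
#'
#' Projects every analyzed frame onto the (Fe-Fe, Fe-Mg) distance plane, one
#' point per frame, ready for scatter plotting.  Membership flags for a
#' given (C, d) mark the frames satisfying either branch of the
#' mutually-exclusive predicate, mirroring the coloring of the published
#' projection.
#'
#' @param d1,d2 frame-aligned distance inputs.
#' @return a data.frame of class \code{"projection_cloud"} with columns
#'   \code{frame}, \code{fefe_nm}, \code{femg_nm}.
#' @export
project_frames <- function(d1, d2) {
  v1 <- series_values(d1)
  v2 <- series_values(d2)
  if (length(v1) != length(v2))
    stop("alignment error: series differ in length")
  out <- data.frame(frame = seq_along(v1), fefe_nm = v1, femg_nm = v2)
  class(out) <- c("projection_cloud", "data.frame")
  out
}

#' Membership flags of projected frames at one (C, d)
#'
#' @param cloud a \code{\link{project_frames}} result.
#' @param C contraction factor in (0, 1].
#' @param d threshold in nm.
#' @return logical vector, \code{TRUE} for frames in either branch; the
#'   mean of the flags equals \code{\link{exclusion_fraction}} at (C, d).
#' @export
flag_membership <- function(cloud, C, d) {
  stopifnot(inherits(cloud, "projection_cloud"))
  if (d <= 0 || C <= 0 || C > 1) stop("'d' must be > 0 and 'C' in (0, 1]")
  cd <- C * d
  (cloud$fefe_nm < cd & cloud$femg_nm > d) |
    (cloud$fefe_nm > d & cloud$femg_nm < cd)
}

#' Export an occupancy scan as TSV
#'
#' Long-format table with columns \code{C}, \code{d_nm}, \code{fraction}.
#'
#' @param scan an \code{"occupancy_scan"}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_occupancy_tsv <- function(scan, file) {
  stopifnot(inherits(scan, "occupancy_scan"))
  tab <- data.frame(C = rep(scan$C, each = length(scan$d_grid)),
                    d_nm = rep(scan$d_grid, times = length(scan$C)),
                    fraction = as.vector(t(scan$fraction)))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
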