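## distance_series: a timestamped scalar distance trace for one marker pair.

#' Construct a distance time series
#'
#' A \code{distance_series} holds one scalar distance trace (in nm) for a
#' single marker pair within one trajectory, together with its time axis (ns)
#' and, after concatenation, the indices at which independent segments join.
#'
#' @param time numeric vector of times in ns, strictly increasing within each
#'   segment.
#' @param value numeric vector of distances in nm, same length as \code{time}.
#' @param pair_label label of the marker pair, e.g. \code{"Fe_docked-Mg_P840"}.
#' @param trajectory_id identifier of the source trajectory.
#' @param boundaries integer indices of the last frame of each segment except
#'   the final one (empty for a single un-concatenated trace).
#' @param t0 nominal start time in ns used by equilibration trimming;
#'   defaults to \code{time[1]}.
#' @return an object of class \code{"distance_series"}.
#' @seealso [extract_distance()], [concatenate_series()], [trim_equilibration()]
#' @export
distance_series <- function(time, value, pair_label = "distance",
                            trajectory_id = "traj1",
                            boundaries = integer(0), t0 = NULL) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value))
    stop("'time' and 'value' must have the same length")
  if (length(value) < 1L) stop("empty series")
  seg <- segment_index(length(time), boundaries)
  for (s in unique(seg)) {
    ts <- time[seg == s]
    if (length(ts) > 1L && any(diff(ts) <= 0))
      stop("times must be strictly increasing within each segment")
  }
  if (any(!is.finite(value))) stop("non-finite distance values")
  if (any(value < 0)) stop("negative distance values")
  if (any(value == 0))
    warning("series contains zero distances (coincident sites?)")
  structure(list(time = time, value = value, pair_label = pair_label,
                 trajectory_id = trajectory_id,
                 boundaries = as.integer(boundaries),
                 t0 = if (is.null(t0)) time[1] else t0),
            class = "distance_series")
}

## per-frame segment labels implied by concatenation boundaries
segment_index <- function(n, boundaries) {
  if (length(boundaries) == 0L) return(rep.int(1L, n))
  b <- sort(as.integer(boundaries))
  if (any(b < 1L) || any(b >= n)) stop("boundaries out of range")
  findInterval(seq_len(n) - 1L, b) + 1L
}

#' @export
length.distance_series <- function(x) length(x$value)

#' @export
print.distance_series <- function(x, ...) {
  nseg <- length(x$boundaries) + 1L
  cat(sprintf("distance_series '%s' (%s): %d frames, %d segment%s\n",
              x$pair_label, x$trajectory_id, length(x$value), nseg,
              if (nseg > 1L) "s" else ""))
  cat(sprintf("  time %.4g..%.4g ns, distance %.3f..%.3f nm (mean %.3f)\n",
              min(x$time), max(x$time), min(x$value), max(x$value),
              mean(x$value)))
  invisible(x)
}

#' @export
as.data.frame.distance_series <- function(x, ...) {
  data.frame(time_ns = x$time, distance_nm = x$value,
             trajectory_id = x$trajectory_id,
             segment_index = segment_index(length(x$value), x$boundaries))
}

## coerce numeric or distance_series to bare values
series_values <- function(x) {
  if (inherits(x, "distance_series")) x$value else as.numeric(x)
}

#' Concatenate distance series end to end
#'
#' Appends several distance traces (typically one per independent trajectory)
#' into a single pooled series.  The resulting time axis is an arbitrary frame
#' index, not physical time: the joined trace is a pooled sample of the
#' configurational space, not a single course of events.  Segment boundaries
#' are recorded so that autocorrelation-aware statistics can avoid
#' cross-boundary frame pairs; frame-wise statistics ignore them.
#'
#' @param series_list list of \code{distance_series} sharing one
#'   \code{pair_label}.
#' @return a \code{distance_series} whose \code{time} is the 0-based frame
#'   index and whose \code{boundaries} mark the joins.
#' @export
concatenate_series <- function(series_list) {
  if (inherits(series_list, "distance_series")) series_list <- list(series_list)
  if (length(series_list) == 0L) stop("no series to concatenate")
  stopifnot(all(vapply(series_list, inherits, TRUE, "distance_series")))
  labs <- unique(vapply(series_list, `[[`, "", "pair_label"))
  if (length(labs) > 1L)
    stop("cannot concatenate series with different pair labels: ",
         paste(labs, collapse = ", "))
  lens <- vapply(series_list, function(s) length(s$value), 1L)
  values <- unlist(lapply(series_list, `[[`, "value"), use.names = FALSE)
  n <- length(values)
  bnd <- cumsum(lens)
  bnd <- bnd[-length(bnd)]
  ids <- paste(vapply(series_list, `[[`, "", "trajectory_id"),
               collapse = "+")
  distance_series(time = seq_len(n) - 1, value = values, pair_label = labs,
                  trajectory_id = ids, boundaries = bnd)
}

#' Export distance series as TSV
#'
#' Writes one or more series as a tab-separated table with columns
#' \code{time_ns}, \code{distance_nm}, \code{trajectory_id},
#' \code{segment_index}.
#'
#' @param series a \code{distance_series} or list of them.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_series_tsv <- function(series, file) {
  if (inherits(series, "distance_series")) series <- list(series)
  tab <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

## ---- peak detection on a regular grid ----------------------------------

## Local maxima of y with scipy-style topographic prominence.  Plateaus
## collapse to their first index, so ties break toward smaller x.  Endpoints
## are not peaks.  Returns a data.frame(index, height, prominence).
grid_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3L) return(empty)
  r <- rle(y)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  peaks <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
      peaks <- c(peaks, starts[j])
  }
  if (length(peaks) == 0L) return(empty)
  prom <- vapply(peaks, function(p) {
    h <- y[p]
    i <- p; lmin <- h
    while (i > 1L && y[i - 1L] <= h) { i <- i - 1L; lmin <- min(lmin, y[i]) }
    i <- p; rmin <- h
    while (i < n && y[i + 1L] <= h) { i <- i + 1L; rmin <- min(rmin, y[i]) }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = peaks[keep], height = y[peaks[keep]],
             prominence = prom[keep])
}
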