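## Trajectory ensemble container, site selection, distance extraction,
## equilibration trimming and sampling-time accounting.

#' Construct a trajectory for an ensemble
#'
#' @param coords numeric array \code{[n_frames, n_sites, 3]} in nm.
#' @param frame_interval time between frames in ns (> 0).
#' @param t0 time of the first frame in ns.
#' @param trajectory_id identifier string.
#' @param model_tag model label, e.g. \code{"2xPscC"} or \code{"1xPscC"}.
#' @return a list of class \code{"cs_trajectory"}.
#' @export
make_trajectory <- function(coords, frame_interval, t0 = 0,
                            trajectory_id = "traj1", model_tag = "2xPscC") {
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("'coords' must be an [n_frames, n_sites, 3] array")
  if (frame_interval <= 0) stop("'frame_interval' must be > 0")
  structure(list(coords = coords, frame_interval = frame_interval, t0 = t0,
                 times = t0 + (seq_len(dim(coords)[1L]) - 1) * frame_interval,
                 trajectory_id = trajectory_id, model_tag = model_tag),
            class = "cs_trajectory")
}

traj_times <- function(traj) traj$times

#' Construct a trajectory ensemble
#'
#' A \code{traj_ensemble} bundles one or more independent trajectories that
#' share a topology: a per-site table of site name (\code{elety}), 1-based
#' residue number (\code{resno}), residue name (\code{resname}) and subunit
#' label (\code{subunit}, e.g. \code{"PscA"}, \code{"PscC_docked"},
#' \code{"PscC_distant"}).
#'
#' @param trajectories list of \code{\link{make_trajectory}} objects with
#'   identical site count and ordering.
#' @param topology data.frame with columns \code{elety}, \code{resno},
#'   \code{resname}, \code{subunit}, one row per site.
#' @return an object of class \code{"traj_ensemble"}.
#' @export
traj_ensemble <- function(trajectories, topology) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1L)
  need <- c("elety", "resno", "resname", "subunit")
  if (!all(need %in% names(topology)))
    stop("topology must have columns ", paste(need, collapse = ", "))
  if (any(topology$resno < 1L)) stop("residue indices must be >= 1")
  nsites <- nrow(topology)
  for (tr in trajectories) {
    stopifnot(inherits(tr, "cs_trajectory"))
    if (dim(tr$coords)[2L] != nsites)
      stop("structure error: trajectory '", tr$trajectory_id,
           "' has ", dim(tr$coords)[2L], " sites, topology has ", nsites)
  }
  structure(list(trajectories = trajectories, topology = topology),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  nf <- vapply(x$trajectories, function(t) dim(t$coords)[1L], 1L)
  cat(sprintf("traj_ensemble: %d trajector%s, %d sites, %s frames\n",
              length(x$trajectories),
              if (length(x$trajectories) > 1L) "ies" else "y",
              nrow(x$topology), paste(nf, collapse = "+")))
  cat("  subunits:", paste(unique(x$topology$subunit), collapse = ", "), "\n")
  invisible(x)
}

## ---- site selection -----------------------------------------------------

## Parse "subunit[:resno-range[:elety]]" into a selector list; "*" matches
## anything.  Ranges: "1-100", "840", or "*".
parse_selection <- function(x) {
  if (is.list(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1L]]
  sel <- list(subunit = NULL, resno = NULL, elety = NULL)
  if (length(parts) >= 1L && nzchar(parts[1L]) && parts[1L] != "*")
    sel$subunit <- parts[1L]
  if (length(parts) >= 2L && nzchar(parts[2L]) && parts[2L] != "*") {
    rr <- strsplit(parts[2L], "-", fixed = TRUE)[[1L]]
    sel$resno <- if (length(rr) == 2L) {
      as.integer(rr[1L]):as.integer(rr[2L])
    } else as.integer(rr)
  }
  if (length(parts) >= 3L && nzchar(parts[3L]) && parts[3L] != "*")
    sel$elety <- parts[3L]
  sel
}

#' Resolve a selection to site indices
#'
#' Selections name sites by (subunit label, 1-based residue index, site
#' name), either as a list with elements \code{subunit}, \code{resno},
#' \code{elety} (each optional) or as a compact string
#' \code{"subunit:resnos:elety"}, e.g. \code{"PscC_docked:1-100:CA"} or
#' \code{"PscA:840:MG"}.  Omitted or \code{"*"} fields match everything.
#'
#' @param ensemble a \code{\link{traj_ensemble}}.
#' @param selection selection string or list.
#' @return integer vector of site indices into the topology.
#' @export
select_sites <- function(ensemble, selection) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  sel <- parse_selection(selection)
  topo <- ensemble$topology
  keep <- rep.int(TRUE, nrow(topo))
  if (!is.null(sel$subunit)) keep <- keep & topo$subunit %in% sel$subunit
  if (!is.null(sel$resno)) keep <- keep & topo$resno %in% sel$resno
  if (!is.null(sel$elety)) keep <- keep & topo$elety %in% sel$elety
  which(keep)
}

site_label <- function(topo, i) {
  sprintf("%s:%d:%s", topo$subunit[i], topo$resno[i], topo$elety[i])
}

## resolve to exactly one site or fail listing candidates
select_one_site <- function(ensemble, selection) {
  idx <- select_sites(ensemble, selection)
  if (length(idx) == 1L) return(idx)
  cand <- if (length(idx) == 0L) "none" else
    paste(site_label(ensemble$topology, idx), collapse = ", ")
  stop(sprintf(paste("selection error: selector must resolve to exactly one",
                     "site; candidates: %s"), cand))
}

## ---- distance extraction ------------------------------------------------

#' Extract a distance time series for a marker pair
#'
#' Computes the per-frame Euclidean distance between two uniquely selected
#' sites, one series per trajectory.  Each selector must resolve to exactly
#' one site; otherwise the error lists the matching candidates.  Coincident
#' sites produce a warning (zero distance), not an error.
#'
#' @param ensemble a \code{\link{traj_ensemble}}.
#' @param site_a,site_b selectors (see \code{\link{select_sites}}).
#' @return a list of \code{\link{distance_series}}, one per trajectory.
#' @examples
#' sim <- simulate_switching_distances(switching_params(n_frames = 100))
#' ens <- embed_distances_as_trajectory(sim)
#' d <- extract_distance(ens, "PscC_docked:1:FE", "PscA:840:MG")
#' all.equal(d[[1]]$value, sim$femg$value)
#' @export
extract_distance <- function(ensemble, site_a, site_b) {
  ia <- select_one_site(ensemble, site_a)
  ib <- select_one_site(ensemble, site_b)
  lab <- paste(site_label(ensemble$topology, ia),
               site_label(ensemble$topology, ib), sep = "--")
  lapply(ensemble$trajectories, function(tr) {
    dxyz <- tr$coords[, ia, , drop = FALSE] - tr$coords[, ib, , drop = FALSE]
    d <- sqrt(rowSums(matrix(dxyz, nrow = dim(tr$coords)[1L])^2))
    distance_series(traj_times(tr), d, pair_label = lab,
                    trajectory_id = tr$trajectory_id, t0 = tr$t0)
  })
}

## ---- equilibration trimming ---------------------------------------------

#' Discard an initial equilibration segment
#'
#' Removes all frames earlier than \code{t0 + t_discard} from every
#' trajectory (or series) independently and advances the nominal start time
#' \code{t0} by \code{t_discard}, so that trimming composes exactly:
#' \code{trim(trim(x, t1), t2) == trim(x, t1 + t2)}.
#'
#' @param x a \code{\link{traj_ensemble}}, \code{"cs_trajectory"} or
#'   \code{\link{distance_series}}.
#' @param t_discard equilibration time to drop, in ns (>= 0).
#' @return an object of the same class with early frames removed.
#' @export
trim_equilibration <- function(x, t_discard) {
  if (!is.numeric(t_discard) || t_discard < 0)
    stop("'t_discard' must be >= 0 ns")
  UseMethod("trim_equilibration")
}

#' @export
trim_equilibration.distance_series <- function(x, t_discard) {
  cut <- x$t0 + t_discard
  keep <- x$time >= cut
  if (!any(keep))
    stop(sprintf("empty-trajectory error: trimming %g ns leaves no frames in '%s'",
                 t_discard, x$trajectory_id))
  if (length(x$boundaries))
    stop("cannot trim a concatenated series; trim before concatenating")
  distance_series(x$time[keep], x$value[keep], pair_label = x$pair_label,
                  trajectory_id = x$trajectory_id, t0 = cut)
}

#' @export
trim_equilibration.cs_trajectory <- function(x, t_discard) {
  times <- traj_times(x)
  cut <- x$t0 + t_discard
  keep <- times >= cut
  if (!any(keep))
    stop(sprintf("empty-trajectory error: trimming %g ns leaves no frames in '%s'",
                 t_discard, x$trajectory_id))
  x$coords <- x$coords[keep, , , drop = FALSE]
  x$times <- times[keep]
  x$t0 <- cut
  x
}

#' @export
trim_equilibration.traj_ensemble <- function(x, t_discard) {
  x$trajectories <- lapply(x$trajectories, trim_equilibration, t_discard)
  x
}

## ---- sampling-plan accounting -------------------------------------------

#' Summarise a sampling plan
#'
#' Exact accounting of scheduled, discarded and analyzed simulation time for
#' a block-structured sampling plan.  Each row of \code{plan} describes one
#' block of identical runs: \code{count} runs of \code{duration_ns} each, of
#' which the first \code{discard_ns} are treated as further equilibration.
#' Analyzed time is \code{count * (duration_ns - discard_ns)}; a block whose
#' discard equals its duration (e.g. a pure equilibration stage) contributes
#' zero analyzed time.
#'
#' @param plan data.frame with columns \code{block}, \code{count},
#'   \code{duration_ns}, \code{discard_ns}.
#' @return a data.frame of class \code{"sampling_summary"} with per-block
#'   \code{scheduled_ns}, \code{discarded_ns}, \code{analyzed_ns} and a
#'   \code{totals} attribute.
#' @seealso [gsb_rc_sampling_plan()] for the reaction-center study plan.
#' @export
sampling_plan_summary <- function(plan) {
  if (is.null(plan) || nrow(plan) == 0L) {
    out <- data.frame(block = character(0), count = numeric(0),
                      scheduled_ns = numeric(0), discarded_ns = numeric(0),
                      analyzed_ns = numeric(0))
    attr(out, "totals") <- c(scheduled_ns = 0, discarded_ns = 0,
                             analyzed_ns = 0)
    class(out) <- c("sampling_summary", "data.frame")
    return(out)
  }
  need <- c("block", "count", "duration_ns", "discard_ns")
  if (!all(need %in% names(plan)))
    stop("plan must have columns ", paste(need, collapse = ", "))
  if (any(plan$duration_ns < 0) || any(plan$discard_ns < 0) ||
      any(plan$count < 0))
    stop("negative durations or counts in sampling plan")
  if (any(plan$discard_ns > plan$duration_ns))
    stop("discard exceeds duration in sampling plan")
  out <- data.frame(block = plan$block, count = plan$count,
                    scheduled_ns = plan$count * plan$duration_ns,
                    discarded_ns = plan$count * plan$discard_ns,
                    analyzed_ns = plan$count *
                      (plan$duration_ns - plan$discard_ns))
  attr(out, "totals") <- c(scheduled_ns = sum(out$scheduled_ns),
                           discarded_ns = sum(out$discarded_ns),
                           analyzed_ns = sum(out$analyzed_ns))
  class(out) <- c("sampling_summary", "data.frame")
  out
}

#' @export
print.sampling_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  tot <- attr(x, "totals")
  cat(sprintf("totals: scheduled %.4g us, discarded %.4g us, analyzed %.4g us\n",
              tot["scheduled_ns"] / 1000, tot["discarded_ns"] / 1000,
              tot["analyzed_ns"] / 1000))
  invisible(x)
}

#' Sampling plan of the reaction-center shuttle study
#'
#' The published sampling plan for the PscA-PscC super-complex: for each of
#' the two models (2xPscC and 1xPscC), a 1 us classical MD equilibration
#' (fully discarded from analysis), 20 REST2 replicas of 200 ns with the
#' first 50 ns discarded, and 3 representative conformations x 2 independent
#' classical production trajectories of 1 us with the first 200 ns discarded.
#' Totals: 22 us scheduled; 9.6 us analyzed classical production
#' (12 x 0.8 us, i.e. 4.8 us per model); 6 us analyzed REST2 (40 x 150 ns).
#'
#' @return a data.frame usable with \code{\link{sampling_plan_summary}}.
#' @examples
#' attr(sampling_plan_summary(gsb_rc_sampling_plan()), "totals")
#' @export
gsb_rc_sampling_plan <- function() {
  data.frame(
    block = c("classical equilibration", "REST2 replicas",
              "classical production"),
    count = c(2, 2 * 20, 2 * 3 * 2),
    duration_ns = c(1000, 200, 1000),
    discard_ns = c(1000, 50, 200),
    stringsAsFactors = FALSE)
}
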