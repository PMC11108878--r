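## Backbone superposition (Kabsch), per-frame RMSD, per-residue RMSF and
## per-subunit flexibility comparison.

## Kabsch: proper rotation R and translation minimizing ||mob %*% R + t - ref||
## over matched m x 3 coordinate sets.  Reflections are disallowed.
kabsch_fit <- function(mobile, ref) {
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(ref, 2L, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  list(R = R, center_mobile = cm, center_ref = cr)
}

rmsd_value <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

## degenerate-fit guard: need >= 3 sites spanning at least a plane
check_fit_selection <- function(coords) {
  if (nrow(coords) < 3L)
    stop("degenerate-fit error: need >= 3 sites for superposition")
  sv <- svd(sweep(coords, 2L, colMeans(coords)))$d
  if (sv[2L] < 1e-10 * max(sv[1L], 1e-300))
    stop("degenerate-fit error: selected sites are collinear")
}

#' Superpose one frame onto a reference (Kabsch)
#'
#' Finds the proper rotation and translation of \code{mobile_frame} that
#' minimizes the RMSD to \code{reference_frame} over the fit selection, via
#' the SVD-based Kabsch algorithm with a determinant guard against
#' reflections.  The transform is fitted on \code{selection} and applied to
#' the whole frame.
#'
#' @param mobile_frame,reference_frame numeric \code{n_sites x 3} matrices
#'   (nm) with matched site ordering.
#' @param selection integer site indices used for the fit (default: all
#'   sites); must give >= 3 non-collinear sites.
#' @return list with \code{coords} (the fitted mobile frame) and \code{rmsd}
#'   (post-fit RMSD over the selection, nm).
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
#'                          0, 0, 1), 3, 3)
#' superpose(ref %*% R + 5, ref)$rmsd  # ~0
#' @export
superpose <- function(mobile_frame, reference_frame, selection = NULL) {
  mobile_frame <- as.matrix(mobile_frame)
  reference_frame <- as.matrix(reference_frame)
  if (!all(dim(mobile_frame) == dim(reference_frame)))
    stop("frames must have matched dimensions")
  if (is.null(selection)) selection <- seq_len(nrow(mobile_frame))
  mob <- mobile_frame[selection, , drop = FALSE]
  ref <- reference_frame[selection, , drop = FALSE]
  check_fit_selection(ref)
  fit <- kabsch_fit(mob, ref)
  fitted_all <- sweep(mobile_frame, 2L, fit$center_mobile) %*% fit$R
  fitted_all <- sweep(fitted_all, 2L, fit$center_ref, "+")
  list(coords = fitted_all,
       rmsd = rmsd_value(fitted_all[selection, , drop = FALSE], ref))
}

## pool frames of an ensemble over a selection into one [frames, m, 3] array
pooled_coords <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  idx <- if (is.null(selection)) seq_len(nrow(ensemble$topology)) else
    select_sites(ensemble, selection)
  if (length(idx) == 0L) stop("selection error: no sites selected")
  parts <- lapply(ensemble$trajectories, function(tr)
    tr$coords[, idx, , drop = FALSE])
  nf <- vapply(parts, function(p) dim(p)[1L], 1L)
  co <- array(0, dim = c(sum(nf), length(idx), 3L))
  at <- 0L
  for (p in parts) {
    co[at + seq_len(dim(p)[1L]), , ] <- p
    at <- at + dim(p)[1L]
  }
  list(coords = co, idx = idx,
       trajectory_id = rep(vapply(ensemble$trajectories, `[[`, "",
                                  "trajectory_id"), nf))
}

## pool frames of an ensemble over a selection into a list of m x 3 matrices
pooled_frames <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  idx <- if (is.null(selection)) seq_len(nrow(ensemble$topology)) else
    select_sites(ensemble, selection)
  if (length(idx) == 0L) stop("selection error: no sites selected")
  frames <- list()
  ids <- character(0)
  for (tr in ensemble$trajectories) {
    nf <- dim(tr$coords)[1L]
    for (f in seq_len(nf))
      frames[[length(frames) + 1L]] <- matrix(tr$coords[f, idx, ], ncol = 3L)
    ids <- c(ids, rep(tr$trajectory_id, nf))
  }
  list(frames = frames, idx = idx, trajectory_id = ids)
}

#' Per-frame RMSD series
#'
#' Superposes every frame of the ensemble onto a reference over the given
#' selection and records the post-fit RMSD.  The default reference is the
#' first analyzed frame (the first frame of the first trajectory, after any
#' trimming); \code{"mean"} uses the iteratively fitted mean structure of
#' \code{\link{rmsf_profile}}.
#'
#' @param ensemble a \code{\link{traj_ensemble}}.
#' @param selection site selection (see \code{\link{select_sites}}).
#' @param reference \code{"first"}, \code{"mean"}, or an explicit
#'   \code{m x 3} matrix over the selection.
#' @return data.frame with columns \code{frame}, \code{trajectory_id},
#'   \code{rmsd_nm}.
#' @export
rmsd_series <- function(ensemble, selection = NULL, reference = "first") {
  pf <- pooled_frames(ensemble, selection)
  ref <- if (is.matrix(reference)) {
    reference
  } else if (identical(reference, "first")) {
    pf$frames[[1L]]
  } else if (identical(reference, "mean")) {
    iterative_mean_structure(pf$frames)$mean
  } else stop("unknown reference '", reference, "'")
  check_fit_selection(ref)
  vals <- vapply(pf$frames, function(fr) {
    fit <- kabsch_fit(fr, ref)
    fitted <- sweep(sweep(fr, 2L, fit$center_mobile) %*% fit$R, 2L,
                    fit$center_ref, "+")
    rmsd_value(fitted, ref)
  }, numeric(1))
  data.frame(frame = seq_along(vals), trajectory_id = pf$trajectory_id,
             rmsd_nm = vals)
}

## iteratively superpose frames onto their running mean structure until the
## mean moves by less than tol (max per-site displacement, nm)
iterative_mean_structure <- function(frames, tol = 1e-6, max_iter = 50L) {
  cur <- frames
  ref <- cur[[1L]]
  for (it in seq_len(max_iter)) {
    cur <- lapply(cur, function(fr) {
      fit <- kabsch_fit(fr, ref)
      sweep(sweep(fr, 2L, fit$center_mobile) %*% fit$R, 2L,
            fit$center_ref, "+")
    })
    new_ref <- Reduce(`+`, cur) / length(cur)
    delta <- max(sqrt(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (delta < tol) break
  }
  list(frames = cur, mean = ref, iterations = it, delta = delta)
}

#' Per-residue RMSF profile
#'
#' Iteratively superposes all frames (pooled over trajectories) onto their
#' running mean structure until the mean moves by less than \code{tol}, then
#' computes per-site root-mean-square fluctuations about the converged mean:
#' \deqn{\mathrm{RMSF}_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2
#'   \rangle}.}
#'
#' @param ensemble a \code{\link{traj_ensemble}} with >= 2 frames in total.
#' @param selection site selection; one bead per residue is assumed, so the
#'   result is indexed by residue number.
#' @param tol convergence tolerance on the mean structure (nm).
#' @param fit if \code{FALSE}, skip the superposition (for data already in a
#'   common frame).
#' @return an object of class \code{"flex_profile"}: list with
#'   \code{selection}, \code{rmsf} (named by residue number, nm),
#'   \code{resno}, \code{subunit}, \code{mean_structure}, \code{n_frames},
#'   \code{reference}.
#' @export
rmsf_profile <- function(ensemble, selection = NULL, tol = 1e-6, fit = TRUE) {
  pc <- pooled_coords(ensemble, selection)
  nf <- dim(pc$coords)[1L]
  if (nf < 2L)
    stop("undefined-fluctuation error: need >= 2 frames for RMSF")
  co <- pc$coords
  if (fit) {
    frames <- lapply(seq_len(nf), function(f) matrix(co[f, , ], ncol = 3L))
    ims <- iterative_mean_structure(frames, tol = tol)
    for (f in seq_len(nf)) co[f, , ] <- ims$frames[[f]]
    m <- ims$mean
  } else {
    m <- cbind(colMeans(co[, , 1L]), colMeans(co[, , 2L]),
               colMeans(co[, , 3L]))
  }
  sq <- colMeans(sweep(co[, , 1L], 2L, m[, 1L])^2) +
    colMeans(sweep(co[, , 2L], 2L, m[, 2L])^2) +
    colMeans(sweep(co[, , 3L], 2L, m[, 3L])^2)
  rmsf <- sqrt(sq)
  topo <- ensemble$topology[pc$idx, , drop = FALSE]
  names(rmsf) <- topo$resno
  structure(list(selection = selection, rmsf = rmsf, resno = topo$resno,
                 subunit = topo$subunit, mean_structure = m,
                 n_frames = nf,
                 reference = if (fit) "iterative mean" else "raw mean"),
            class = "flex_profile")
}

#' @export
print.flex_profile <- function(x, ...) {
  cat(sprintf("flex_profile (%s): %d residues, %d frames, reference: %s\n",
              if (is.null(x$selection)) "all sites" else
                paste(x$selection, collapse = ","),
              length(x$rmsf), x$n_frames, x$reference))
  cat(sprintf("  RMSF median %.4f nm, max %.4f nm at residue %s\n",
              stats::median(x$rmsf), max(x$rmsf),
              names(x$rmsf)[which.max(x$rmsf)]))
  invisible(x)
}

#' Compare flexibility of two selections
#'
#' Per-residue RMSF differences between two profiles over the same residue
#' range (e.g. the transmembrane helices of the docked and the distant PscC),
#' with a verdict naming the selection that is more mobile by median RMSF.
#' Differences are oriented \code{a - b} and negate under argument swap.
#'
#' @param profile_a,profile_b \code{\link{rmsf_profile}} results over the
#'   same residue numbers.
#' @param labels length-2 labels for the two selections.
#' @return a list of class \code{"flex_comparison"} with \code{resno},
#'   \code{rmsf_diff}, \code{median_rmsf} (named), \code{verdict}.
#' @export
flexibility_compare <- function(profile_a, profile_b,
                                labels = c("docked", "distant")) {
  stopifnot(inherits(profile_a, "flex_profile"),
            inherits(profile_b, "flex_profile"))
  if (length(profile_a$rmsf) != length(profile_b$rmsf) ||
      any(profile_a$resno != profile_b$resno))
    stop("range error: profiles cover different residue ranges")
  med <- c(stats::median(profile_a$rmsf), stats::median(profile_b$rmsf))
  names(med) <- labels
  verdict <- if (med[1L] > med[2L]) labels[1L]
  else if (med[2L] > med[1L]) labels[2L]
  else "tie"
  structure(list(resno = profile_a$resno,
                 rmsf_diff = unname(profile_a$rmsf - profile_b$rmsf),
                 median_rmsf = med, verdict = verdict, labels = labels),
            class = "flex_comparison")
}

#' @export
print.flex_comparison <- function(x, ...) {
  cat(sprintf("flex_comparison %s vs %s: median RMSF %.4f vs %.4f nm\n",
              x$labels[1L], x$labels[2L], x$median_rmsf[1L],
              x$median_rmsf[2L]))
  cat("  more mobile:", x$verdict, "\n")
  invisible(x)
}
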