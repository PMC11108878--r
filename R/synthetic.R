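## Synthetic trajectory generators: OU distance traces, two-state Markov
## switching, and planted residue-correlation networks.  These supply the
## analytic ground truth for every downstream analysis stage, standing in for
## MD trajectories that are not deposited.

#' Simulate an Ornstein-Uhlenbeck distance trace
#'
#' Mean-reverting Gaussian process used as the fluctuation model for synthetic
#' distance series.  The update uses the exact discrete-time solution
#' \deqn{x_{t+1} = \mu + (x_t - \mu) e^{-\theta \Delta t} + \sigma
#'   \sqrt{1 - e^{-2\theta\Delta t}}\, Z_t,}
#' so the stationary standard deviation is exactly \code{sigma} and the lag-k
#' autocorrelation is exactly \code{exp(-theta * k * dt)} for any step size.
#' The first value is drawn from the stationary distribution unless \code{x0}
#' is given.
#'
#' @param theta relaxation rate in 1/ns (> 0).
#' @param mu stationary mean in nm (> 0).
#' @param sigma stationary standard deviation in nm (>= 0; 0 gives a constant
#'   series at \code{mu}).
#' @param dt frame interval in ns (> 0).
#' @param n number of frames (>= 2).
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @param x0 optional initial value in nm.
#' @return a \code{\link{distance_series}} of length \code{n}.
#' @examples
#' s <- simulate_ou(theta = 1, mu = 2.5, sigma = 0.1, dt = 0.1, n = 1000,
#'                  seed = 7)
#' sd(s$value)  # close to 0.1
#' @export
simulate_ou <- function(theta, mu, sigma, dt, n, seed = NULL, x0 = NULL) {
  if (!is.numeric(theta) || theta <= 0) stop("'theta' must be > 0")
  if (!is.numeric(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be > 0 nm")
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  dev <- ou_deviations(theta, sigma, dt, n,
                       dev0 = if (is.null(x0)) NULL else x0 - mu)
  distance_series(time = (seq_len(n) - 1) * dt, value = mu + dev,
                  pair_label = "ou", trajectory_id = "ou")
}

## zero-mean OU deviations via the exact discrete recursion (vectorised with
## a recursive filter); dev0 = NULL draws the start from stationarity
ou_deviations <- function(theta, sigma, dt, n, dev0 = NULL) {
  a <- exp(-theta * dt)
  if (sigma == 0)
    return(rep.int(if (is.null(dev0)) 0 else dev0, n))
  innov <- stats::rnorm(n, sd = sigma * sqrt(1 - a^2))
  first <- if (is.null(dev0)) stats::rnorm(1, sd = sigma) else dev0
  x <- c(first, innov[-1L])
  as.numeric(stats::filter(x, a, method = "recursive"))
}

#' Parameters of the two-state anticorrelated switching generator
#'
#' Defines the synthetic stand-in for the alternating shuttle motion: a hidden
#' two-state continuous-time Markov chain selects, per frame, one of two mean
#' pairs for the Fe-Fe (PscC-PscC) and Fe-Mg (PscA-PscC) distances, and
#' Ornstein-Uhlenbeck fluctuations are superimposed on each trace.
#'
#' The default means put state A at (Fe-Fe 3.2, Fe-Mg 2.5) nm and state B at
#' (Fe-Fe 2.7, Fe-Mg 2.8) nm: when the two PscC domains approach each other
#' the docked PscC backs away from the special pair, and vice versa, matching
#' the regime in which the observed distance modes lie (Fe-Mg near 2.5 and
#' 2.8 nm; Fe-Fe near 2.7-3.2 nm).
#'
#' @param mean_A,mean_B length-2 numeric vectors \code{c(fefe, femg)} in nm.
#' @param sigma stationary fluctuation std in nm.
#' @param theta OU relaxation rate in 1/ns.
#' @param k_AB,k_BA state transition rates in 1/ns.
#' @param dt frame interval in ns.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param coupled if \code{TRUE} both distances switch together (the
#'   correlated shuttle); if \code{FALSE} each trace gets an independent
#'   hidden chain (the uncorrelated null model).
#' @return an object of class \code{"switching_params"}.
#' @export
switching_params <- function(mean_A = c(fefe = 3.2, femg = 2.5),
                             mean_B = c(fefe = 2.7, femg = 2.8),
                             sigma = 0.1, theta = 1, k_AB = 0.01,
                             k_BA = 0.01, dt = 0.1, n_frames = 48000L,
                             seed = 1L, coupled = TRUE) {
  p <- list(mean_A = mean_A, mean_B = mean_B, sigma = sigma, theta = theta,
            k_AB = k_AB, k_BA = k_BA, dt = dt,
            n_frames = as.integer(n_frames), seed = as.integer(seed),
            coupled = isTRUE(coupled))
  if (length(p$mean_A) != 2L || length(p$mean_B) != 2L)
    stop("'mean_A' and 'mean_B' must each give (fefe, femg) in nm")
  if (any(c(p$mean_A, p$mean_B) <= 0)) stop("state means must be > 0 nm")
  if (p$sigma < 0) stop("'sigma' must be >= 0")
  if (p$theta <= 0 || p$k_AB <= 0 || p$k_BA <= 0 || p$dt <= 0)
    stop("rates and 'dt' must be > 0")
  if (p$n_frames < 2L) stop("'n_frames' must be >= 2")
  class(p) <- "switching_params"
  p
}

#' @export
print.switching_params <- function(x, ...) {
  cat("switching_params:",
      sprintf("state A (FeFe %.2f, FeMg %.2f) nm, state B (FeFe %.2f, FeMg %.2f) nm",
              x$mean_A[1], x$mean_A[2], x$mean_B[1], x$mean_B[2]), "\n")
  cat(sprintf("  sigma %.3g nm, theta %.3g /ns, k_AB %.3g /ns, k_BA %.3g /ns\n",
              x$sigma, x$theta, x$k_AB, x$k_BA))
  cat(sprintf("  %d frames at dt %.3g ns, seed %d, %s switching\n",
              x$n_frames, x$dt, x$seed,
              if (x$coupled) "coupled" else "independent"))
  invisible(x)
}

## discretised 2-state Markov chain using the exact CTMC transition matrix
## over one frame interval: p(A->B) = (k_AB/l)(1 - exp(-l dt)) with
## l = k_AB + k_BA, so the stationary occupancy is k_BA/l for any dt;
## initial state drawn from the stationary distribution
simulate_markov2 <- function(n, k_AB, k_BA, dt) {
  l <- k_AB + k_BA
  p_ab <- (k_AB / l) * (1 - exp(-l * dt))
  p_ba <- (k_BA / l) * (1 - exp(-l * dt))
  u <- stats::runif(n)
  s <- integer(n)
  s[1L] <- if (u[1L] < k_BA / (k_AB + k_BA)) 1L else 2L
  for (t in 2L:n) {
    s[t] <- if (s[t - 1L] == 1L) {
      if (u[t] < p_ab) 2L else 1L
    } else {
      if (u[t] < p_ba) 1L else 2L
    }
  }
  s
}

#' Simulate the two-state switching distance pair
#'
#' Generates the Fe-Fe (PscC-PscC) and Fe-Mg (PscA-PscC) distance traces of
#' the synthetic shuttle: a hidden two-state Markov chain (discretised per
#' frame with the exact continuous-time transition matrix over one frame
#' interval, so the stationary state-A occupancy is exactly
#' \code{k_BA / (k_AB + k_BA)} at any \code{dt}) selects the mean pair,
#' and independent OU fluctuations ride on each trace.  With
#' \code{coupled = FALSE} each trace follows its own hidden chain, giving the
#' independent-switching null.  Distances are clamped to a floor of 0.1 nm
#' after noise addition for physical positivity.
#'
#' @param params a \code{\link{switching_params}} object.
#' @return a list of class \code{"switching_sim"} with elements \code{fefe}
#'   and \code{femg} (\code{\link{distance_series}}), the hidden
#'   \code{states} (integer, 1 = A, 2 = B; a 2-column matrix when
#'   \code{coupled = FALSE}), and \code{params}.
#' @examples
#' sim <- simulate_switching_distances(switching_params(n_frames = 2000))
#' mean(sim$states == 1)  # near k_BA / (k_AB + k_BA) = 0.5
#' @export
simulate_switching_distances <- function(params = switching_params()) {
  stopifnot(inherits(params, "switching_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_frames
  s1 <- simulate_markov2(n, p$k_AB, p$k_BA, p$dt)
  s2 <- if (p$coupled) s1 else simulate_markov2(n, p$k_AB, p$k_BA, p$dt)
  mu_fefe <- ifelse(s1 == 1L, p$mean_A[1], p$mean_B[1])
  mu_femg <- ifelse(s2 == 1L, p$mean_A[2], p$mean_B[2])
  fefe <- pmax(mu_fefe + ou_deviations(p$theta, p$sigma, p$dt, n, dev0 = 0),
               0.1)
  femg <- pmax(mu_femg + ou_deviations(p$theta, p$sigma, p$dt, n, dev0 = 0),
               0.1)
  times <- (seq_len(n) - 1) * p$dt
  structure(list(
    fefe = distance_series(times, fefe, pair_label = "Fe_distant-Fe_docked",
                           trajectory_id = "synthetic"),
    femg = distance_series(times, femg, pair_label = "Fe_docked-Mg_P840",
                           trajectory_id = "synthetic"),
    states = if (p$coupled) s1 else cbind(fefe = s1, femg = s2),
    params = p), class = "switching_sim")
}

#' @export
print.switching_sim <- function(x, ...) {
  st <- if (is.matrix(x$states)) x$states[, 1L] else x$states
  cat(sprintf("switching_sim: %d frames, %s, fraction in state A %.3f\n",
              x$params$n_frames,
              if (x$params$coupled) "coupled" else "independent",
              mean(st == 1L)))
  invisible(x)
}

#' Embed a distance pair as a three-bead marker trajectory
#'
#' Builds a trajectory ensemble with three labelled marker beads placed
#' collinearly on the x axis: the P840 Mg at the origin, the docked-PscC heme
#' Fe at the Fe-Mg distance, and the distant-PscC heme Fe beyond it at the
#' Fe-Fe distance.  Re-extracting distances from the coordinates reproduces
#' the input series to floating-point tolerance, which makes the generator a
#' round-trip oracle for the trajectory reader.
#'
#' @param fefe,femg \code{\link{distance_series}} sharing one time axis, or a
#'   \code{"switching_sim"} passed as \code{fefe} (in which case \code{femg}
#'   is ignored).
#' @param frame_interval frame interval in ns (defaults to the series time
#'   step, or 1 ns for a single frame).
#' @param trajectory_id,model_tag metadata attached to the trajectory.
#' @return a \code{\link{traj_ensemble}} with one trajectory and three sites.
#' @export
embed_distances_as_trajectory <- function(fefe, femg = NULL,
                                          frame_interval = NULL,
                                          trajectory_id = "synthetic",
                                          model_tag = "2xPscC") {
  if (inherits(fefe, "switching_sim")) {
    femg <- fefe$femg
    fefe <- fefe$fefe
  }
  stopifnot(inherits(fefe, "distance_series"),
            inherits(femg, "distance_series"))
  if (length(fefe$time) != length(femg$time) ||
      any(fefe$time != femg$time))
    stop("alignment error: the two series must share timestamps")
  n <- length(fefe$value)
  if (is.null(frame_interval))
    frame_interval <- if (n > 1L) fefe$time[2] - fefe$time[1] else 1
  coords <- array(0, dim = c(n, 3L, 3L))
  coords[, 2L, 1L] <- femg$value
  coords[, 3L, 1L] <- femg$value + fefe$value
  topo <- data.frame(
    elety = c("MG", "FE", "FE"),
    resno = c(840L, 1L, 1L),
    resname = c("BCL", "HEM", "HEM"),
    subunit = c("PscA", "PscC_docked", "PscC_distant"),
    stringsAsFactors = FALSE)
  traj_ensemble(list(make_trajectory(coords, frame_interval = frame_interval,
                                     t0 = fefe$time[1],
                                     trajectory_id = trajectory_id,
                                     model_tag = model_tag)),
                topology = topo)
}

#' Parameters of the planted-correlation network generator
#'
#' Ground-truth generator for pathway recovery: beads are laid out on a ring
#' (so that the planted route competes with a genuine alternative route), and
#' per-frame displacements are drawn from a zero-mean Gaussian whose
#' correlation matrix carries the planted structure.  Consecutive beads on the
#' planted path get correlation exactly \code{on_path_correlation}; a pair of
#' planted beads k steps apart gets \code{on_path_correlation^k} (geometric
#' decay along the path, which keeps the matrix positive semidefinite — a
#' matrix with high correlation only between consecutive pairs is not a valid
#' correlation matrix for paths of three or more beads); every other pair gets
#' \code{off_path_correlation}.  Displacements are drawn along a single axis
#' normal to the ring plane so that the displacement-vector dot-product
#' correlation equals this scalar correlation matrix exactly.
#'
#' @param n_residues number of beads on the ring.
#' @param planted_path ordered, consecutive residue indices forming the
#'   planted arc (e.g. \code{1:8}).
#' @param on_path_correlation correlation between consecutive planted beads,
#'   in (0, 1].
#' @param off_path_correlation correlation elsewhere, in
#'   [0, \code{on_path_correlation}).
#' @param chain_geometry inter-bead spacing along the ring in nm; the default
#'   0.38 nm is a typical C-alpha virtual bond length and lies inside the
#'   0.5 nm contact cutoff used downstream.
#' @param amplitude displacement standard deviation in nm.
#' @param n_frames,dt,seed sampling controls.
#' @return an object of class \code{"planted_network_params"}.
#' @export
planted_network_params <- function(n_residues = 20L, planted_path = 1:8,
                                   on_path_correlation = 0.9,
                                   off_path_correlation = 0.1,
                                   chain_geometry = 0.38, amplitude = 0.05,
                                   n_frames = 50000L, dt = 0.1, seed = 1L) {
  p <- list(n_residues = as.integer(n_residues),
            planted_path = as.integer(planted_path),
            on_path_correlation = on_path_correlation,
            off_path_correlation = off_path_correlation,
            chain_geometry = chain_geometry, amplitude = amplitude,
            n_frames = as.integer(n_frames), dt = dt,
            seed = as.integer(seed))
  if (p$n_residues < 4L) stop("'n_residues' must be >= 4")
  pp <- p$planted_path
  if (length(pp) < 2L || anyDuplicated(pp) ||
      any(pp < 1L) || any(pp > p$n_residues))
    stop("'planted_path' must be >= 2 distinct valid residue indices")
  if (any(diff(pp) != 1L))
    stop("'planted_path' must be consecutive residue indices along the ring")
  if (p$on_path_correlation <= 0 || p$on_path_correlation > 1)
    stop("'on_path_correlation' must be in (0, 1]")
  if (p$off_path_correlation < 0 ||
      p$off_path_correlation >= p$on_path_correlation)
    stop("'off_path_correlation' must be in [0, on_path_correlation)")
  if (p$chain_geometry <= 0 || p$amplitude < 0 || p$dt <= 0)
    stop("'chain_geometry' and 'dt' must be > 0, 'amplitude' >= 0")
  if (p$n_frames < 2L) stop("'n_frames' must be >= 2")
  class(p) <- "planted_network_params"
  p
}

## target correlation matrix implied by the planted structure
planted_correlation_matrix <- function(p) {
  n <- p$n_residues
  R <- matrix(p$off_path_correlation, n, n)
  diag(R) <- 1
  pp <- p$planted_path
  for (i in seq_along(pp)) {
    for (j in seq_along(pp)) {
      if (i != j)
        R[pp[i], pp[j]] <- p$on_path_correlation^abs(i - j)
    }
  }
  R
}

#' Generate a bead trajectory with a planted correlation pathway
#'
#' Draws \code{n_frames} displacement vectors from the planted Gaussian model
#' of \code{\link{planted_network_params}} and adds them to bead rest
#' positions on a ring.  The requested correlation matrix is checked for
#' positive semidefiniteness before sampling; an invalid request fails with
#' the offending eigenvalue.
#'
#' @param params a \code{\link{planted_network_params}} object.
#' @return a list of class \code{"planted_network_sim"} with the
#'   \code{ensemble} (a \code{\link{traj_ensemble}}), the target
#'   \code{correlation} matrix, and \code{params}.
#' @examples
#' sim <- generate_planted_network_trajectory(
#'   planted_network_params(n_frames = 500))
#' dim(sim$ensemble$trajectories[[1]]$coords)
#' @export
generate_planted_network_trajectory <- function(params =
                                                  planted_network_params()) {
  stopifnot(inherits(params, "planted_network_params"))
  p <- params
  R <- planted_correlation_matrix(p)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop(sprintf(paste("requested correlation structure is not positive",
                       "semidefinite (smallest eigenvalue %.4g)"),
                 min(ev$values)))
  set.seed(p$seed)
  n <- p$n_residues
  ## ring rest positions: adjacent beads exactly chain_geometry apart
  radius <- p$chain_geometry / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  rest <- cbind(radius * cos(ang), radius * sin(ang), 0)
  ## displacements along z: s = Z %*% t(sqrt-factor), cov(s) = amplitude^2 R
  fac <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)
  z <- matrix(stats::rnorm(p$n_frames * n), p$n_frames, n) %*% t(fac) *
    p$amplitude
  coords <- array(0, dim = c(p$n_frames, n, 3L))
  coords[, , 1L] <- matrix(rest[, 1L], p$n_frames, n, byrow = TRUE)
  coords[, , 2L] <- matrix(rest[, 2L], p$n_frames, n, byrow = TRUE)
  coords[, , 3L] <- z
  topo <- data.frame(elety = rep("CA", n), resno = seq_len(n),
                     resname = rep("ALA", n),
                     subunit = rep("NET", n), stringsAsFactors = FALSE)
  ens <- traj_ensemble(list(make_trajectory(coords, frame_interval = p$dt,
                                            trajectory_id = "planted",
                                            model_tag = "planted_network")),
                       topology = topo)
  structure(list(ensemble = ens, correlation = R, params = p),
            class = "planted_network_sim")
}

#' Write generator provenance sidecar files
#'
#' Persists the hidden-state sequence of a switching simulation as a TSV and
#' the generator parameters as YAML, so that synthetic data written to disk
#' stays reproducible and ground truth stays available for tests.
#'
#' @param sim a \code{"switching_sim"}.
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_sim_sidecar <- function(sim, dir) {
  stopifnot(inherits(sim, "switching_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- sim$states
  tab <- if (is.matrix(st)) {
    data.frame(frame = seq_len(nrow(st)), state_fefe = st[, 1L],
               state_femg = st[, 2L])
  } else data.frame(frame = seq_along(st), state = st)
  f1 <- file.path(dir, "hidden_states.tsv")
  utils::write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "generator_params.yaml")
  pl <- sim$params
  class(pl) <- NULL
  pl$mean_A <- as.numeric(pl$mean_A)
  pl$mean_B <- as.numeric(pl$mean_B)
  yaml::write_yaml(pl, f2)
  invisible(c(states = f1, params = f2))
}
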