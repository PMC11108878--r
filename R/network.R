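## Dynamical-network analysis: displacement-correlation matrix,
## contact-filtered weighted graph, shortest allosteric pathways, betweenness
## centrality, and a geometric aromatic-hop pathway surrogate.

#' Residue-displacement correlation matrix
#'
#' Normalised dot-product covariance of per-site displacement vectors about
#' their mean positions,
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}},}
#' the standard correlation measure of dynamical-network analysis.  Frames
#' are pooled over all trajectories.  Rigid-body motion is assumed to have
#' been removed beforehand (e.g. by superposition onto a mean structure); set
#' \code{fit = TRUE} to apply the iterative mean-structure fit first.
#' Zero-variance sites are flagged with a warning and get zero off-diagonal
#' correlation.
#'
#' @param ensemble a \code{\link{traj_ensemble}} with >= 2 frames.
#' @param selection node selection (one representative bead per residue).
#' @param fit superpose frames onto their iterative mean structure first.
#' @return symmetric correlation matrix with unit diagonal, with node labels
#'   as dimnames.
#' @examples
#' sim <- generate_planted_network_trajectory(
#'   planted_network_params(n_frames = 2000))
#' C <- displacement_correlation(sim$ensemble)
#' C[1, 2]  # near 0.9
#' @export
displacement_correlation <- function(ensemble, selection = NULL,
                                     fit = FALSE) {
  pc <- pooled_coords(ensemble, selection)
  n_frames <- dim(pc$coords)[1L]
  if (n_frames < 2L) stop("need >= 2 frames for correlations")
  if (fit) {
    frames <- lapply(seq_len(n_frames), function(f)
      matrix(pc$coords[f, , ], ncol = 3L))
    frames <- iterative_mean_structure(frames)$frames
    for (f in seq_len(n_frames)) pc$coords[f, , ] <- frames[[f]]
  }
  n <- dim(pc$coords)[2L]
  ## frames x n deviation matrices per axis
  cent <- function(M) sweep(M, 2L, colMeans(M))
  Dx <- cent(pc$coords[, , 1L, drop = TRUE])
  Dy <- cent(pc$coords[, , 2L, drop = TRUE])
  Dz <- cent(pc$coords[, , 3L, drop = TRUE])
  num <- crossprod(Dx) + crossprod(Dy) + crossprod(Dz)
  v <- diag(num)
  zero <- v <= 0
  if (any(zero))
    warning("zero-variance node(s): ",
            paste(which(zero), collapse = ", "),
            "; off-diagonal correlations set to 0")
  denom <- sqrt(outer(pmax(v, .Machine$double.eps),
                      pmax(v, .Machine$double.eps)))
  C <- num / denom
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  labs <- site_label(ensemble$topology, pc$idx)
  dimnames(C) <- list(labs, labs)
  C
}

## fraction of frames in which each node pair is within cutoff;
## coords is a [frames, n, 3] array
contact_fraction <- function(coords, cutoff) {
  n <- dim(coords)[2L]
  nf <- dim(coords)[1L]
  acc <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d2 <- (coords[, i, 1L] - coords[, j, 1L])^2 +
        (coords[, i, 2L] - coords[, j, 2L])^2 +
        (coords[, i, 3L] - coords[, j, 3L])^2
      acc[i, j] <- acc[j, i] <- sum(d2 < cutoff^2) / nf
    }
  }
  acc
}

#' Build the contact-filtered correlation graph
#'
#' Connects node pairs whose representative beads are within
#' \code{contact_cutoff} in at least a fraction \code{occupancy} of frames,
#' weighting each edge \eqn{w_{ij} = -\log |C_{ij}|} so that shortest paths
#' maximise the product of correlation magnitudes along the route.  Contacts
#' with exactly zero correlation get no edge.
#'
#' @param correlations correlation matrix from
#'   \code{\link{displacement_correlation}}.
#' @param ensemble the \code{\link{traj_ensemble}} the correlations came
#'   from (for contact geometry).
#' @param selection node selection matching \code{correlations}.
#' @param contact_cutoff contact distance cutoff in nm (> 0; default 0.5).
#' @param occupancy minimum contact occupancy fraction in (0, 1] (default
#'   0.75).
#' @return an object of class \code{"corr_graph"}: list with \code{graph}
#'   (igraph), \code{C}, \code{contact_frac}, \code{nodes},
#'   \code{contact_cutoff}, \code{occupancy}.
#' @export
build_graph <- function(correlations, ensemble, selection = NULL,
                        contact_cutoff = 0.5, occupancy = 0.75) {
  if (contact_cutoff <= 0) stop("'contact_cutoff' must be > 0")
  if (occupancy <= 0 || occupancy > 1) stop("'occupancy' must be in (0, 1]")
  pc <- pooled_coords(ensemble, selection)
  n <- dim(pc$coords)[2L]
  if (nrow(correlations) != n)
    stop("correlation matrix does not match the node selection (",
         nrow(correlations), " vs ", n, " nodes)")
  cf <- contact_fraction(pc$coords, contact_cutoff)
  labs <- rownames(correlations)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  edges <- which(upper.tri(cf) & cf >= occupancy & abs(correlations) > 0,
                 arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (nrow(edges) > 0L) {
    w <- -log(abs(correlations[edges]))
    g <- igraph::add_edges(g, t(edges))
    g <- igraph::set_edge_attr(g, "weight", value = w)
    g <- igraph::set_edge_attr(g, "correlation", value = correlations[edges])
  }
  topo <- ensemble$topology[pc$idx, , drop = FALSE]
  structure(list(graph = g, C = correlations, contact_frac = cf,
                 nodes = topo, contact_cutoff = contact_cutoff,
                 occupancy = occupancy),
            class = "corr_graph")
}

#' @export
print.corr_graph <- function(x, ...) {
  cat(sprintf("corr_graph: %d nodes, %d edges (cutoff %.2f nm, occupancy >= %.2f)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$contact_cutoff, x$occupancy))
  invisible(x)
}

## resolve a node argument (index or name/selector string) to a vertex index
resolve_node <- function(graph, node) {
  nm <- igraph::V(graph)$name
  if (is.numeric(node)) {
    i <- as.integer(node)
    if (i < 1L || i > igraph::vcount(graph)) stop("node index out of range")
    return(i)
  }
  hit <- which(nm == node)
  if (length(hit) == 0L) hit <- grep(node, nm, fixed = TRUE)
  if (length(hit) != 1L)
    stop("node '", node, "' matches ", length(hit), " vertices")
  hit
}

#' Shortest correlation pathway between two nodes
#'
#' Minimum-total-weight path (Dijkstra on the \eqn{-\log|C|} weights, i.e.
#' the maximum-correlation-product route).  When several paths tie, the
#' lexicographically smallest node-name sequence is returned, so results are
#' deterministic.  Disconnected endpoints raise an error naming the
#' connected component of each endpoint.
#'
#' @param graph a \code{"corr_graph"} (or bare igraph with edge weights).
#' @param source,sink node names (matched exactly, then as substrings) or
#'   indices.
#' @return an object of class \code{"cs_pathway"}: list with \code{nodes}
#'   (ordered labels), \code{edge_weights}, \code{total}, \code{endpoints}.
#' @export
shortest_pathway <- function(graph, source, sink) {
  g <- if (inherits(graph, "corr_graph")) graph$graph else graph
  s <- resolve_node(g, source)
  t <- resolve_node(g, sink)
  dist <- igraph::distances(g, v = s, to = t,
                            weights = igraph::E(g)$weight)[1L, 1L]
  if (!is.finite(dist)) {
    comp <- igraph::components(g)$membership
    stop(sprintf(paste("no-path error: endpoints are disconnected",
                       "(source in component %d, sink in component %d)"),
                 comp[s], comp[t]))
  }
  allp <- igraph::all_shortest_paths(g, from = s, to = t,
                                     weights = igraph::E(g)$weight)$vpaths
  seqs <- lapply(allp, function(p) igraph::V(g)$name[as.integer(p)])
  ## deterministic tie-break: lexicographically smallest name sequence
  key <- vapply(seqs, paste, "", collapse = "\r")
  path <- seqs[[order(key)[1L]]]
  vidx <- vapply(path, function(nm) which(igraph::V(g)$name == nm), 1L)
  ew <- vapply(seq_len(length(vidx) - 1L), function(k) {
    e <- igraph::get_edge_ids(g, c(vidx[k], vidx[k + 1L]))
    igraph::E(g)$weight[e]
  }, numeric(1))
  structure(list(nodes = path, edge_weights = ew, total = sum(ew),
                 endpoints = c(igraph::V(g)$name[s], igraph::V(g)$name[t])),
            class = "cs_pathway")
}

#' @export
print.cs_pathway <- function(x, ...) {
  cat(sprintf("pathway %s -> %s (%d nodes, total weight %.4f):\n",
              x$endpoints[1L], x$endpoints[2L], length(x$nodes), x$total))
  cat(" ", paste(x$nodes, collapse = " -> "), "\n")
  invisible(x)
}

#' Weighted betweenness centrality
#'
#' Normalised shortest-path betweenness on the correlation graph's
#' \eqn{-\log|C|} weights; high-centrality residues are candidate relay
#' points through which allosteric perturbations propagate.
#'
#' @param graph a \code{"corr_graph"} or igraph.
#' @return named numeric vector of centralities in [0, 1].
#' @export
betweenness_centrality <- function(graph) {
  g <- if (inherits(graph, "corr_graph")) graph$graph else graph
  if (igraph::vcount(g) == 0L) stop("empty graph")
  igraph::betweenness(g, weights = igraph::E(g)$weight, normalized = TRUE)
}

#' Geometric aromatic-hop pathway
#'
#' Declared geometric surrogate for an electronic-coupling pathway
#' calculation: builds a graph over aromatic residue centroids (Trp, Tyr,
#' Phe side chains or their representative beads) plus the cofactor
#' endpoints, connects centroids within \code{hop_cutoff}, weights edges by
#' centroid distance and returns the shortest (minimum total hop length)
#' route from source to sink.  No electronic structure is computed; short
#' hops are simply treated as good hops.
#'
#' @param ensemble a \code{\link{traj_ensemble}}; the first frame of the
#'   first trajectory is used as the structure.
#' @param aromatic_selection selector for the aromatic relay sites.
#' @param source,sink selectors resolving to one cofactor site each.
#' @param hop_cutoff maximum hop distance in nm (default 0.8).
#' @param frame frame index to use (default 1).
#' @return a \code{"cs_pathway"}.
#' @export
aromatic_hop_pathway <- function(ensemble, aromatic_selection, source, sink,
                                 hop_cutoff = 0.8, frame = 1L) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  if (hop_cutoff <= 0) stop("'hop_cutoff' must be > 0")
  aro <- select_sites(ensemble, aromatic_selection)
  if (length(aro) == 0L) stop("selection error: no aromatic sites selected")
  is_ <- select_one_site(ensemble, source)
  it_ <- select_one_site(ensemble, sink)
  idx <- unique(c(is_, it_, aro))
  co <- matrix(ensemble$trajectories[[1L]]$coords[frame, idx, ], ncol = 3L)
  labs <- site_label(ensemble$topology, idx)
  d <- as.matrix(stats::dist(co))
  edges <- which(upper.tri(d) & d < hop_cutoff, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
    g <- igraph::set_edge_attr(g, "weight", value = d[edges])
  }
  tryCatch(shortest_pathway(g, labs[1L], labs[2L]),
           error = function(e) {
             if (grepl("no-path", conditionMessage(e)))
               stop("no-path error: no aromatic hop route within ",
                    hop_cutoff, " nm; try a larger 'hop_cutoff'")
             stop(e)
           })
}

#' Export a correlation graph as edge-list TSV (and optionally GraphML)
#'
#' @param graph a \code{"corr_graph"}.
#' @param file TSV output path (columns \code{i}, \code{j}, \code{C_ij},
#'   \code{weight}).
#' @param graphml optional GraphML output path.
#' @return the TSV path, invisibly.
#' @export
write_graph_tsv <- function(graph, file, graphml = NULL) {
  stopifnot(inherits(graph, "corr_graph"))
  el <- igraph::as_edgelist(graph$graph)
  tab <- data.frame(i = el[, 1L], j = el[, 2L],
                    C_ij = igraph::E(graph$graph)$correlation,
                    weight = igraph::E(graph$graph)$weight)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(graph$graph, graphml, format = "graphml")
  invisible(file)
}
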