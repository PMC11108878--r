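## Independent oracles and fixture builders used across the suite.

## naive per-frame loop oracle for the mutually-exclusive occupancy fraction
naive_exclusion_fraction <- function(v1, v2, d, C) {
  hits <- 0L
  for (t in seq_along(v1)) {
    if ((v1[t] < C * d && v2[t] > d) || (v1[t] > d && v2[t] < C * d))
      hits <- hits + 1L
  }
  hits / length(v1)
}

## rotation matrix from z-y-z Euler angles
euler_rotation <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  rz(a) %*% ry(b) %*% rz(g)
}

## brute-force minimum RMSD over rotations: coarse Euler grid followed by
## Nelder-Mead refinement; independent of the SVD-based Kabsch route
brute_force_rmsd <- function(mobile, ref, grid_step = 20) {
  P <- sweep(mobile, 2L, colMeans(mobile))
  Q <- sweep(ref, 2L, colMeans(ref))
  obj <- function(ang) {
    R <- euler_rotation(ang[1L], ang[2L], ang[3L])
    sqrt(mean(rowSums((P %*% R - Q)^2)))
  }
  step <- grid_step * pi / 180
  best <- NULL
  best_val <- Inf
  for (a in seq(0, 2 * pi - step / 2, by = step)) {
    for (b in seq(0, pi, by = step)) {
      for (g in seq(0, 2 * pi - step / 2, by = step)) {
        v <- obj(c(a, b, g))
        if (v < best_val) { best_val <- v; best <- c(a, b, g) }
      }
    }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

## all simple paths between s and t in a weighted adjacency matrix (0 = no
## edge); returns the minimal total weight and all argmin node sequences
enumerate_shortest <- function(W, s, t) {
  n <- nrow(W)
  best <- list(total = Inf, paths = list())
  walk <- function(path, total) {
    u <- path[length(path)]
    if (u == t) {
      if (total < best$total - 1e-12) {
        best$total <<- total
        best$paths <<- list(path)
      } else if (abs(total - best$total) <= 1e-12) {
        best$paths <<- c(best$paths, list(path))
      }
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (W[u, v] > 0 && !(v %in% path))
        walk(c(path, v), total + W[u, v])
    }
  }
  walk(s, 0)
  best
}

## brute-force normalized weighted betweenness via path enumeration
enumerate_betweenness <- function(W) {
  n <- nrow(W)
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      res <- enumerate_shortest(W, s, t)
      if (!is.finite(res$total) || length(res$paths) == 0L) next
      for (p in res$paths) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(res$paths)
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

## tiny bead ensemble from an explicit coords array
bead_ensemble <- function(coords, dt = 0.1, subunit = NULL) {
  n <- dim(coords)[2L]
  topo <- data.frame(elety = rep("CA", n), resno = seq_len(n),
                     resname = rep("ALA", n),
                     subunit = if (is.null(subunit)) rep("A", n) else subunit,
                     stringsAsFactors = FALSE)
  traj_ensemble(list(make_trajectory(coords, frame_interval = dt)),
                topology = topo)
}

## weighted graph (igraph) from an adjacency matrix, names "1".."n"
graph_from_W <- function(W) {
  n <- nrow(W)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  e <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(e)) {
    g <- igraph::add_edges(g, t(e))
    g <- igraph::set_edge_attr(g, "weight", value = W[e])
  }
  g
}
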