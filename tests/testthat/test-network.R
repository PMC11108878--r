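test_that("displacement correlations hit the exact limits", {
  ## two beads moving in lockstep: correlation 1; equal-and-opposite: -1
  set.seed(401)
  n <- 200
  z <- rnorm(n, 0, 0.1)
  coords <- array(0, dim = c(n, 3, 3))
  coords[, 1, 3] <- z
  coords[, 2, 3] <- z
  coords[, 3, 3] <- -z
  coords[, 2, 1] <- 1   # rest offsets
  coords[, 3, 1] <- 2
  C <- displacement_correlation(bead_ensemble(coords))
  expect_equal(unname(C[1, 2]), 1)
  expect_equal(unname(C[1, 3]), -1)
  ## symmetry and unit diagonal
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 3))
})

test_that("zero-variance nodes are flagged and zeroed", {
  set.seed(402)
  coords <- array(0, dim = c(100, 3, 3))
  coords[, 1, 3] <- rnorm(100)
  coords[, 2, 1] <- 1  # static bead
  coords[, 3, 2] <- 1
  coords[, 3, 3] <- rnorm(100)
  expect_warning(C <- displacement_correlation(bead_ensemble(coords)),
                 "zero-variance")
  expect_equal(unname(C[1, 2]), 0)
  expect_equal(unname(C[2, 2]), 1)
})

test_that("correlation estimates converge to the planted covariance", {
  p <- planted_network_params(n_frames = 50000, seed = 23)
  sim <- generate_planted_network_trajectory(p)
  C <- displacement_correlation(sim$ensemble)
  expect_lt(max(abs(C - sim$correlation)), 0.03)
})

test_that("graph construction applies geometry, weights and occupancy filter", {
  ## chain of beads 0.4 nm apart -> path-graph adjacency at 0.5 nm cutoff
  n <- 6
  coords <- array(0, dim = c(10, n, 3))
  for (b in 1:n) coords[, b, 1] <- 0.4 * (b - 1)
  coords[, , 3] <- matrix(rnorm(10 * n, 0, 1e-3), 10, n)
  ens <- bead_ensemble(coords)
  C <- displacement_correlation(ens)
  g <- build_graph(C, ens, contact_cutoff = 0.5, occupancy = 1.0)
  A <- igraph::as_adjacency_matrix(g$graph, sparse = FALSE)
  expected <- abs(outer(1:n, 1:n, "-")) == 1
  expect_equal(unname(A > 0), expected)

  ## weight formula: |C| = 1 -> 0; |C| = e^-1 -> 1
  W <- matrix(c(1, 1, 1, 1), 2, 2)
  co2 <- array(0, dim = c(4, 2, 3))
  co2[, 2, 1] <- 0.3
  co2[, 1, 3] <- c(-1, 1, -1, 1) * 0.1
  co2[, 2, 3] <- c(-1, 1, -1, 1) * 0.1
  ens2 <- bead_ensemble(co2)
  C2 <- displacement_correlation(ens2)
  g2 <- build_graph(C2, ens2)
  expect_equal(igraph::E(g2$graph)$weight, 0)
  C2[1, 2] <- C2[2, 1] <- exp(-1)
  g3 <- build_graph(C2, ens2)
  expect_equal(igraph::E(g3$graph)$weight, 1)

  ## a contact present in only 50% of frames fails a 75% occupancy filter
  co3 <- array(0, dim = c(10, 2, 3))
  co3[1:5, 2, 1] <- 0.3   # close half the time
  co3[6:10, 2, 1] <- 2.0  # far the other half
  co3[, , 3] <- matrix(rnorm(20, 0, 1e-3), 10, 2)
  ens3 <- bead_ensemble(co3)
  C3 <- displacement_correlation(ens3)
  g4 <- build_graph(C3, ens3, contact_cutoff = 0.5, occupancy = 0.75)
  expect_equal(igraph::ecount(g4$graph), 0)

  ## parameter validation
  expect_error(build_graph(C3, ens3, contact_cutoff = -1), "cutoff")
  expect_error(build_graph(C3, ens3, occupancy = 0), "occupancy")
})

test_that("shortest pathways match brute-force enumeration on small graphs", {
  ## two-node single-edge graph
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  pw2 <- shortest_pathway(graph_from_W(W2), "1", "2")
  expect_equal(pw2$nodes, c("1", "2"))
  expect_equal(pw2$total, 1)

  ## fixed 6-node fixture with a tempting-but-worse shortcut
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 1] <- 0.2
  W[2, 3] <- W[3, 2] <- 0.2
  W[3, 6] <- W[6, 3] <- 0.2
  W[1, 4] <- W[4, 1] <- 0.25
  W[4, 6] <- W[6, 4] <- 0.4
  W[1, 5] <- W[5, 1] <- 1.5
  W[5, 6] <- W[6, 5] <- 0.1
  oracle <- enumerate_shortest(W, 1, 6)
  got <- shortest_pathway(graph_from_W(W), "1", "6")
  expect_equal(got$total, oracle$total, tolerance = 1e-12)
  expect_true(any(vapply(oracle$paths, function(p)
    identical(as.character(p), got$nodes), TRUE)))

  ## random graphs: totals equal enumeration exactly
  set.seed(403)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) W[i, j] <- W[j, i] <- runif(1, 0.05, 2)
    }
    o <- enumerate_shortest(W, 1, n)
    if (!is.finite(o$total)) {
      expect_error(shortest_pathway(graph_from_W(W), "1", as.character(n)),
                   "no-path")
    } else {
      g <- shortest_pathway(graph_from_W(W), "1", as.character(n))
      expect_equal(g$total, o$total, tolerance = 1e-12)
      expect_equal(sum(g$edge_weights), g$total)
    }
  }
})

test_that("tied shortest paths break lexicographically", {
  ## 1->2->4 and 1->3->4 tie; "1,2,4" sorts before "1,3,4"
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 4] <- W[4, 2] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.5
  pw <- shortest_pathway(graph_from_W(W), "1", "4")
  expect_equal(pw$nodes, c("1", "2", "4"))
})

test_that("betweenness matches star/path intuition and enumeration", {
  ## path graph: interior nodes dominate; star: hub 1, leaves 0
  Wp <- matrix(0, 5, 5)
  for (i in 1:4) Wp[i, i + 1] <- Wp[i + 1, i] <- 1
  bp <- betweenness_centrality(graph_from_W(Wp))
  expect_equal(unname(which.max(bp)), 3)
  expect_equal(unname(bp[c(1, 5)]), c(0, 0))

  Ws <- matrix(0, 6, 6)
  Ws[1, 2:6] <- Ws[2:6, 1] <- 1
  bs <- betweenness_centrality(graph_from_W(Ws))
  expect_equal(unname(bs[1]), 1)
  expect_equal(unname(bs[2:6]), rep(0, 5))

  ## random <= 8 node graphs against the enumeration oracle
  set.seed(404)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.6) W[i, j] <- W[j, i] <- runif(1, 0.05, 2)
    }
    expect_equal(unname(betweenness_centrality(graph_from_W(W))),
                 enumerate_betweenness(W), tolerance = 1e-10)
  }
})

test_that("the planted pathway is recovered across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    p <- planted_network_params(n_frames = 20000, seed = seed)
    sim <- generate_planted_network_trajectory(p)
    C <- displacement_correlation(sim$ensemble)
    g <- build_graph(C, sim$ensemble)
    pw <- shortest_pathway(g, "NET:1:CA", "NET:8:CA")
    want <- sprintf("NET:%d:CA", 1:8)
    if (identical(pw$nodes, want)) hits <- hits + 1L
  }
  expect_gte(hits, 19)  # >= 95% of seeds
})

test_that("a length-2 planted path is recovered exactly", {
  p <- planted_network_params(planted_path = 4:5, n_frames = 5000, seed = 30)
  sim <- generate_planted_network_trajectory(p)
  C <- displacement_correlation(sim$ensemble)
  g <- build_graph(C, sim$ensemble)
  pw <- shortest_pathway(g, "NET:4:CA", "NET:5:CA")
  expect_equal(pw$nodes, c("NET:4:CA", "NET:5:CA"))
})

test_that("edge-weight decrease never lengthens a shortest path", {
  set.seed(405)
  W <- matrix(0, 6, 6)
  for (i in 1:5) W[i, i + 1] <- W[i + 1, i] <- runif(1, 0.2, 1)
  W[1, 4] <- W[4, 1] <- 1.5
  before <- shortest_pathway(graph_from_W(W), "1", "6")$total
  W[1, 4] <- W[4, 1] <- 0.1
  after <- shortest_pathway(graph_from_W(W), "1", "6")$total
  expect_lte(after, before)
})

test_that("aromatic hop pathways follow geometry", {
  ## colinear W-Y-F chain between two cofactors, 0.6 nm spacing
  coords <- array(0, dim = c(2, 5, 3))
  coords[, , 1] <- matrix(rep(c(0, 0.6, 1.2, 1.8, 2.4), each = 2), 2, 5)
  topo <- data.frame(elety = c("MG", "CZ", "CZ", "CZ", "FE"),
                     resno = c(840L, 10L, 11L, 12L, 1L),
                     resname = c("BCL", "TRP", "TYR", "PHE", "HEM"),
                     subunit = c("PscA", "PscA", "PscA", "PscA",
                                 "PscC_docked"),
                     stringsAsFactors = FALSE)
  ens <- traj_ensemble(list(make_trajectory(coords, frame_interval = 1)),
                       topo)
  pw <- aromatic_hop_pathway(ens, "PscA:10-12:CZ", "PscA:840:MG",
                             "PscC_docked:1:FE", hop_cutoff = 0.8)
  expect_equal(length(pw$nodes), 5)  # visits all three aromatics
  expect_equal(pw$total, 2.4, tolerance = 1e-9)

  ## cutoff below the minimal spacing: no path, helpful message
  expect_error(aromatic_hop_pathway(ens, "PscA:10-12:CZ", "PscA:840:MG",
                                    "PscC_docked:1:FE", hop_cutoff = 0.5),
               "larger 'hop_cutoff'")

  ## a shorter shortcut is preferred over more, longer hops
  coords2 <- coords
  coords2[, 3, 2] <- 0.7  # lift the middle aromatic off the line
  ens2 <- traj_ensemble(list(make_trajectory(coords2, frame_interval = 1)),
                        topo)
  pw2 <- aromatic_hop_pathway(ens2, "PscA:10-12:CZ", "PscA:840:MG",
                              "PscC_docked:1:FE", hop_cutoff = 1.3)
  W <- matrix(0, 5, 5)
  fr <- matrix(coords2[1, , ], ncol = 3)
  D <- as.matrix(dist(fr))
  W[D < 1.3] <- D[D < 1.3]
  diag(W) <- 0
  oracle <- enumerate_shortest(W, 1, 5)
  expect_equal(pw2$total, oracle$total, tolerance = 1e-9)
})

test_that("graph exports write edge lists and GraphML", {
  sim <- generate_planted_network_trajectory(
    planted_network_params(n_frames = 2000, seed = 31))
  C <- displacement_correlation(sim$ensemble)
  g <- build_graph(C, sim$ensemble)
  f <- file.path(tempdir(), "edges.tsv")
  gm <- file.path(tempdir(), "net.graphml")
  write_graph_tsv(g, f, graphml = gm)
  tab <- read.delim(f)
  expect_equal(nrow(tab), igraph::ecount(g$graph))
  expect_true(all(tab$weight >= 0))
  expect_true(file.exists(gm))
})
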