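make_test_ensemble <- function(n_frames = 5, n_traj = 1, dt = 0.1, t0 = 0,
                               jitter = 0) {
  topo <- data.frame(elety = c("MG", "FE", "FE", "CA"),
                     resno = c(840L, 1L, 1L, 2L),
                     resname = c("BCL", "HEM", "HEM", "ALA"),
                     subunit = c("PscA", "PscC_docked", "PscC_distant",
                                 "PscA"),
                     stringsAsFactors = FALSE)
  trajs <- lapply(seq_len(n_traj), function(k) {
    coords <- array(0, dim = c(n_frames, 4, 3))
    coords[, 2, 1] <- 3
    coords[, 3, 2] <- 4
    coords[, 4, ] <- matrix(c(1, 1, 1), n_frames, 3, byrow = TRUE)
    if (jitter > 0) coords <- coords + array(rnorm(length(coords), 0, jitter),
                                             dim = dim(coords))
    make_trajectory(coords, frame_interval = dt, t0 = t0,
                    trajectory_id = paste0("run", k))
  })
  traj_ensemble(trajs, topo)
}

test_that("distance extraction computes per-frame Euclidean distances", {
  ens <- make_test_ensemble()
  ## sites at (3,0,0) and (0,4,0): the 3-4-5 triangle
  d <- extract_distance(ens, "PscC_docked:1:FE", "PscC_distant:1:FE")
  expect_equal(d[[1]]$value, rep(5, 5))
  ## one series per trajectory
  ens2 <- make_test_ensemble(n_traj = 3)
  expect_length(extract_distance(ens2, "PscA:840:MG", "PscC_docked:1:FE"), 3)
})

test_that("ambiguous and empty selectors fail with candidate listings", {
  ens <- make_test_ensemble()
  expect_error(extract_distance(ens, "PscA", "PscC_docked:1:FE"),
               "candidates:.*PscA:840:MG")
  expect_error(extract_distance(ens, "PscB:1:FE", "PscC_docked:1:FE"),
               "candidates: none")
})

test_that("coincident sites give a zero-distance warning, not an error", {
  ens <- make_test_ensemble()
  ens$trajectories[[1]]$coords[, 2, ] <- 0  # collapse FE onto MG
  expect_warning(
    d <- extract_distance(ens, "PscA:840:MG", "PscC_docked:1:FE"),
    "zero")
  expect_equal(d[[1]]$value, rep(0, 5))
})

test_that("distance extraction is invariant under global rigid motion", {
  set.seed(31)
  ens <- make_test_ensemble(n_frames = 4, jitter = 0.1)
  d0 <- extract_distance(ens, "PscA:840:MG", "PscC_distant:1:FE")[[1]]$value
  R <- euler_rotation(0.4, 1.1, -0.3)
  shift <- c(5, -2, 7)
  ens2 <- ens
  for (f in 1:4) {
    fr <- matrix(ens$trajectories[[1]]$coords[f, , ], ncol = 3)
    ens2$trajectories[[1]]$coords[f, , ] <- fr %*% R +
      matrix(shift, 4, 3, byrow = TRUE)
  }
  d1 <- extract_distance(ens2, "PscA:840:MG", "PscC_distant:1:FE")[[1]]$value
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("equilibration trimming drops the right frames and composes", {
  ## 1 us at 0.1 ns/frame, discard 200 ns -> 0.8 us analyzed
  s <- distance_series(seq(0, 999.9, by = 0.1), rep(2.5, 10000))
  tr <- trim_equilibration(s, 200)
  expect_length(tr$value, 8000)
  expect_equal(min(tr$time), 200)

  ## identity at zero discard
  expect_equal(trim_equilibration(s, 0)$value, s$value)

  ## composition: trim(t1) then trim(t2) == trim(t1 + t2)
  a <- trim_equilibration(trim_equilibration(s, 130), 170)
  b <- trim_equilibration(s, 300)
  expect_equal(a$time, b$time)
  expect_equal(a$value, b$value)

  ## over-trimming names the trajectory
  expect_error(trim_equilibration(s, 1e6), "traj1")
})

test_that("ensemble trimming applies per trajectory with correct accounting", {
  ens <- make_test_ensemble(n_frames = 10000, n_traj = 2, dt = 0.1)
  tr <- trim_equilibration(ens, 200)
  for (t in tr$trajectories) {
    expect_equal(dim(t$coords)[1], 8000)
    expect_equal(t$t0, 200)
  }
})

test_that("concatenation pools frames, records boundaries, stays order-invariant", {
  s1 <- distance_series(seq_len(100) - 1, runif(100, 2, 3), pair_label = "p",
                        trajectory_id = "a")
  s2 <- distance_series(seq_len(50) - 1, runif(50, 2, 3), pair_label = "p",
                        trajectory_id = "b")
  cc <- concatenate_series(list(s1, s2))
  expect_length(cc$value, 150)
  expect_equal(cc$boundaries, 100L)

  ## mixed labels refuse
  s3 <- distance_series(0:9, runif(10, 2, 3), pair_label = "q")
  expect_error(concatenate_series(list(s1, s3)), "pair label")

  ## frame-wise occupancy is invariant to concatenation order when both
  ## members of the pair are permuted together
  p1 <- distance_series(seq_len(100) - 1, runif(100, 2, 3), pair_label = "q",
                        trajectory_id = "a")
  p2 <- distance_series(seq_len(50) - 1, runif(50, 2, 3), pair_label = "q",
                        trajectory_id = "b")
  expect_equal(
    exclusion_fraction(concatenate_series(list(s1, s2)),
                       concatenate_series(list(p1, p2)), d = 2.5, C = 0.9),
    exclusion_fraction(concatenate_series(list(s2, s1)),
                       concatenate_series(list(p2, p1)), d = 2.5, C = 0.9))
})

test_that("six trimmed 0.8-us trajectories concatenate to 48000 frames", {
  sers <- lapply(1:6, function(k) {
    s <- distance_series(seq(0, 999.9, by = 0.1), rep(2.5, 10000),
                         pair_label = "FeFe", trajectory_id = paste0("r", k))
    trim_equilibration(s, 200)
  })
  cc <- concatenate_series(sers)
  expect_length(cc$value, 48000)
  expect_equal(length(cc$boundaries), 5)
})

test_that("sampling-plan accounting reproduces the published bookkeeping", {
  sm <- sampling_plan_summary(gsb_rc_sampling_plan())
  tot <- attr(sm, "totals")
  ## 22 us scheduled in total
  expect_equal(unname(tot["scheduled_ns"]), 22000)
  ## 9.6 us analyzed classical production, 6 us analyzed REST2
  expect_equal(sm$analyzed_ns[sm$block == "classical production"], 9600)
  expect_equal(sm$analyzed_ns[sm$block == "REST2 replicas"], 6000)
  ## equilibration contributes nothing to analysis
  expect_equal(sm$analyzed_ns[sm$block == "classical equilibration"], 0)
  ## identity sum(count * (duration - discard)) holds exactly
  plan <- gsb_rc_sampling_plan()
  expect_identical(unname(tot["analyzed_ns"]),
                   sum(plan$count * (plan$duration_ns - plan$discard_ns)))

  ## empty plan gives zeros; negative durations refuse
  e <- sampling_plan_summary(NULL)
  expect_equal(unname(attr(e, "totals")["scheduled_ns"]), 0)
  bad <- gsb_rc_sampling_plan()
  bad$duration_ns[1] <- -5
  expect_error(sampling_plan_summary(bad), "egative")
})

test_that("PDB write/read round trip preserves coordinates and labels", {
  set.seed(8)
  ens <- make_test_ensemble(n_frames = 3, jitter = 0.2)
  f <- file.path(tempdir(), "rt.pdb")
  info <- write_ensemble(ens, f)
  back <- read_ensemble(f, frame_interval = 0.1, chain_map = info$chain_map)
  expect_equal(dim(back$trajectories[[1]]$coords),
               dim(ens$trajectories[[1]]$coords))
  ## PDB stores 3 decimals in Angstrom: 1e-3 A = 1e-4 nm tolerance
  expect_lt(max(abs(back$trajectories[[1]]$coords -
                      ens$trajectories[[1]]$coords)), 1e-4 + 1e-12)
  expect_equal(back$topology$subunit, ens$topology$subunit)
  expect_equal(back$topology$resno, ens$topology$resno)

  ## a 25 A coordinate is stored as 2.5 nm
  ens$trajectories[[1]]$coords[1, 1, 1] <- 2.5
  write_ensemble(ens, f)
  raw <- readLines(f)
  expect_match(raw[grep("^ATOM", raw)[1]], "25\\.000")
})

test_that("XYZ write/read round trip preserves coordinates", {
  set.seed(9)
  ens <- make_test_ensemble(n_frames = 4, jitter = 0.3)
  f <- file.path(tempdir(), "rt.xyz")
  write_ensemble(ens, f)
  back <- read_ensemble(f, frame_interval = 0.1, topology = ens$topology)
  expect_lt(max(abs(back$trajectories[[1]]$coords -
                      ens$trajectories[[1]]$coords)), 1e-5)
  ## without a topology the names still come through
  anon <- read_ensemble(f)
  expect_equal(anon$topology$elety, ens$topology$elety)
})

test_that("unsupported formats and broken files fail informatively", {
  f <- file.path(tempdir(), "traj.dcd")
  file.create(f)
  expect_error(read_ensemble(f), "format error")
  g <- file.path(tempdir(), "broken.xyz")
  writeLines(c("3", "comment", "CA 0 0 0"), g)  # promises 3 atoms, has 1
  expect_error(read_ensemble(g), "structure error")
  expect_error(read_ensemble(file.path(tempdir(), "absent.pdb")),
               "not found")
})
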