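test_that("OU generator matches its closed-form stationary moments", {
  ## zero-noise limit: constant at the mean
  s0 <- simulate_ou(theta = 1, mu = 2.5, sigma = 0, dt = 0.1, n = 50, seed = 1)
  expect_equal(s0$value, rep(2.5, 50))

  s <- simulate_ou(theta = 1, mu = 2.5, sigma = 0.1, dt = 0.1, n = 200000,
                   seed = 42)
  expect_lt(abs(sd(s$value) - 0.1) / 0.1, 0.02)
  expect_lt(abs(mean(s$value) - 2.5), 0.01)
  ## lag-k autocorrelation at k*dt = 1/theta is e^-1
  k <- round(1 / (1 * 0.1))
  ac <- cor(s$value[-(1:k)], s$value[1:(length(s$value) - k)])
  expect_lt(abs(ac - exp(-1)), 0.05)
})

test_that("OU generator validates parameters and is seed-reproducible", {
  expect_error(simulate_ou(theta = -1, mu = 2.5, sigma = 0.1, dt = 0.1,
                           n = 10), "theta")
  expect_error(simulate_ou(theta = 1, mu = 2.5, sigma = 0.1, dt = 0, n = 10),
               "dt")
  expect_error(simulate_ou(theta = 1, mu = 2.5, sigma = 0.1, dt = 0.1, n = 1),
               "n")
  a <- simulate_ou(1, 2.5, 0.1, 0.1, 1000, seed = 9)
  b <- simulate_ou(1, 2.5, 0.1, 0.1, 1000, seed = 9)
  expect_identical(a$value, b$value)
})

test_that("hidden two-state chain has the analytic stationary occupancy", {
  ## symmetric rates: half the frames in each state
  p <- switching_params(k_AB = 0.5, k_BA = 0.5, n_frames = 100000, dt = 0.1,
                        seed = 11)
  sim <- simulate_switching_distances(p)
  expect_lt(abs(mean(sim$states == 1L) - 0.5), 0.05)

  ## asymmetric rates: fraction in A = k_BA / (k_AB + k_BA) = 0.75,
  ## within 3 autocorrelation-corrected standard errors
  p2 <- switching_params(k_AB = 1, k_BA = 3, n_frames = 100000, dt = 0.01,
                         seed = 5)
  sim2 <- simulate_switching_distances(p2)
  pA <- 3 / 4
  l <- (1 + 3) * 0.01
  rho <- exp(-l)                      # per-frame state autocorrelation
  se <- sqrt(pA * (1 - pA) * (1 + rho) / (1 - rho) / 100000)
  expect_lt(abs(mean(sim2$states == 1L) - pA), 3 * se)
})

test_that("noiseless coupled switching gives perfectly anticorrelated steps", {
  p <- switching_params(mean_A = c(3, 2), mean_B = c(2, 3), sigma = 0,
                        k_AB = 0.5, k_BA = 0.5, n_frames = 2000, dt = 0.1,
                        seed = 2)
  sim <- simulate_switching_distances(p)
  expect_gt(length(unique(sim$states)), 1)  # chain actually switches
  expect_equal(cor(sim$fefe$value, sim$femg$value), -1)
})

test_that("independent switching uses two distinct hidden chains", {
  p <- switching_params(coupled = FALSE, k_AB = 0.5, k_BA = 0.5,
                        n_frames = 5000, dt = 0.1, seed = 3)
  sim <- simulate_switching_distances(p)
  expect_true(is.matrix(sim$states))
  expect_false(all(sim$states[, 1L] == sim$states[, 2L]))
})

test_that("switching output is bit-identical for a fixed seed", {
  a <- simulate_switching_distances(switching_params(n_frames = 500, seed = 7))
  b <- simulate_switching_distances(switching_params(n_frames = 500, seed = 7))
  expect_identical(a$fefe$value, b$fefe$value)
  expect_identical(a$states, b$states)
})

test_that("embedding distances as beads is exactly invertible", {
  sim <- simulate_switching_distances(switching_params(n_frames = 200,
                                                       seed = 4))
  ens <- embed_distances_as_trajectory(sim)
  fefe <- extract_distance(ens, "PscC_distant:1:FE", "PscC_docked:1:FE")[[1]]
  femg <- extract_distance(ens, "PscC_docked:1:FE", "PscA:840:MG")[[1]]
  expect_lt(max(abs(fefe$value - sim$fefe$value)), 1e-9)
  expect_lt(max(abs(femg$value - sim$femg$value)), 1e-9)

  ## collinear placement by construction
  tr <- ens$trajectories[[1]]
  expect_equal(tr$coords[1, 1, ], c(0, 0, 0))
  expect_equal(tr$coords[1, 2, 1], sim$femg$value[1])
  expect_equal(tr$coords[1, 3, 1], sim$femg$value[1] + sim$fefe$value[1])
})

test_that("embedding rejects series with mismatched timestamps", {
  a <- simulate_ou(1, 2.5, 0.1, 0.1, 50, seed = 1)
  b <- simulate_ou(1, 3.0, 0.1, 0.2, 50, seed = 2)
  expect_error(embed_distances_as_trajectory(a, b), "alignment")
})

test_that("single-frame embedding writes a readable single-model trajectory", {
  one <- distance_series(0, 3.0, pair_label = "p")
  two <- distance_series(0, 2.5, pair_label = "p")
  ens <- embed_distances_as_trajectory(one, two)
  f <- file.path(tempdir(), "single.pdb")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  expect_equal(dim(back$trajectories[[1]]$coords)[1], 1)
  expect_equal(back$trajectories[[1]]$coords[1, 2, 1], 2.5,
               tolerance = 1e-3)
})

test_that("planted network sampling reproduces the requested correlations", {
  p <- planted_network_params(n_frames = 50000, seed = 21)
  sim <- generate_planted_network_trajectory(p)
  C <- displacement_correlation(sim$ensemble)
  pp <- p$planted_path
  ## consecutive planted pairs near on_path_correlation
  for (k in seq_len(length(pp) - 1L))
    expect_lt(abs(C[pp[k], pp[k + 1L]] - 0.9), 0.03)
  ## off-path pairs near off_path_correlation
  expect_lt(abs(C[15, 16] - 0.1), 0.03)
  expect_lt(abs(C[2, 14] - 0.1), 0.03)
})

test_that("zero off-path correlation gives independent off-path beads", {
  p <- planted_network_params(off_path_correlation = 0, n_frames = 50000,
                              seed = 22)
  sim <- generate_planted_network_trajectory(p)
  C <- displacement_correlation(sim$ensemble)
  expect_lt(abs(C[12, 17]), 0.03)
  expect_lt(abs(C[14, 18]), 0.03)
})

test_that("non-PSD correlation requests fail with the offending eigenvalue", {
  ## direct construction of an invalid planted structure is prevented by
  ## geometric decay, so force one through the internal matrix builder
  p <- planted_network_params()
  R <- corrshuttle:::planted_correlation_matrix(p)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)  # defaults are valid

  ## a high uniform off-path correlation with near-1 on-path decay can break
  ## PSD; check the guard fires with a helpful message
  bad <- planted_network_params(on_path_correlation = 0.99,
                                off_path_correlation = 0.98)
  Rbad <- corrshuttle:::planted_correlation_matrix(bad)
  if (min(eigen(Rbad, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    expect_error(generate_planted_network_trajectory(bad), "eigenvalue")
  } else {
    succeed("constructed matrix happened to be PSD; guard not exercised")
  }
})

test_that("planted generator validates its parameters", {
  expect_error(planted_network_params(planted_path = c(1, 3)), "consecutive")
  expect_error(planted_network_params(planted_path = 1:30), "valid")
  expect_error(planted_network_params(on_path_correlation = 0.2,
                                      off_path_correlation = 0.5),
               "off_path")
})
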