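test_that("diamond lattices have the right size, coordination and density", {
  lat <- build_lattice("cubic", 3, density = 0.98)
  expect_identical(n_particles(lat), 216L)
  expect_equal(config_density(lat), 0.98, tolerance = 1e-10)
  expect_true(all(lengths(neighbor_list(lat, 3.2)) == 4))
  lath <- build_lattice("hexagonal", c(3, 2, 3), density = 0.98)
  expect_equal(config_density(lath), 0.98, tolerance = 1e-10)
  expect_true(all(lengths(neighbor_list(lath, 3.2)) == 4))
  # small noise leaves the bond length within 1%
  noisy <- build_lattice("cubic", 2, density = 0.98, noise = 0.01, seed = 4)
  nl <- neighbor_list(noisy, 3.2)
  b0 <- lattice_bond_length("cubic", 0.98)
  d1 <- sqrt(sum((noisy$positions[nl[[1]][1], ] - noisy$positions[1, ])^2))
  expect_lt(abs(d1 - b0) / b0, 0.01)
  expect_error(build_lattice("cubic", 3, density = 12), "overlap")
  # determinism given spec + seed
  a <- build_lattice("cubic", 2, 0.98, noise = 0.05, seed = 7)
  b <- build_lattice("cubic", 2, 0.98, noise = 0.05, seed = 7)
  expect_identical(a$positions, b$positions)
})

test_that("generated liquids hit the requested density and are liquid", {
  liq <- liquid_216()
  expect_equal(config_density(liq), 1.0, tolerance = 1e-10)
  expect_lt(mean(classify_crystalline(liq)$crystalline), 0.01)
  # seeding: same seed identical, different seed distinct
  a <- generate_liquid(40, 0.95, 280, seed = 3, round_ps = 2)
  b <- generate_liquid(40, 0.95, 280, seed = 3, round_ps = 2)
  d <- generate_liquid(40, 0.95, 280, seed = 4, round_ps = 2)
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, d$positions))
})

test_that("flat-profile walks reproduce the unbiased random-walk MFPT", {
  # flat landscape: up/down rates equal, MFPT(0 -> m) = m^2/(2 k+) ... the
  # recursion is the reference; verify it against the closed form first
  M <- 12
  flat <- rep(0, M + 1)
  exact <- bd_mfpt_exact(flat, kplus = 2)
  # reflecting-at-0 walk: T(m) = sum_{j<m} (j+1)/k+ = m(m+1)/(2 k+)
  closed <- (1:M) * (2:(M + 1)) / (2 * 2)
  expect_equal(exact, closed, tolerance = 1e-12)
  walks <- simulate_walks(flat, kplus = 2, n_traj = 600, seed = 11)
  emp <- colMeans(walks$fpt)[-1]
  expect_lt(max(abs(emp - exact) / exact), 0.1)
})

test_that("an infinite barrier is never crossed", {
  prof <- c(0, 0, 0, 0, 0, Inf, Inf)
  walks <- simulate_walks(prof, kplus = 5, n_traj = 20, seed = 2,
                          max_events = 2e4)
  expect_true(all(is.na(walks$fpt[, 7])))     # n = 6 is never reached
  expect_true(all(!is.na(walks$fpt[, 5])))    # n = 4 always is
})

test_that("walk ensembles match the recursion at a CNT barrier", {
  prof <- cnt_profile(0:40, delta_mu = 0.5, n_c = 16)  # barrier 4 kBT
  walks <- simulate_walks(prof, kplus = 30, n_traj = 500, seed = 5)
  exact <- bd_mfpt_exact(prof, 30)
  emp <- colMeans(walks$fpt, na.rm = TRUE)[-1]
  se <- apply(walks$fpt[, -1], 2, sd) / sqrt(500)
  sel <- 10:40  # away from the tiny-time region where relative error is noisy
  # mean relative agreement within 5%; every point within 4 standard errors
  expect_lt(mean(abs(emp[sel] - exact[sel]) / exact[sel]), 0.05)
  expect_true(all(abs(emp[sel] - exact[sel]) < 4 * se[sel]))
})

test_that("two-level Boltzmann occupancy and perfect-bias uniformity", {
  two <- c(0, 1)
  cnt <- sample_landscape_1d(two, NULL, n_moves = 2e5, seed = 6, step = 1)
  expect_equal(cnt[["0"]] / cnt[["1"]], exp(1), tolerance = 0.05)
  # a bias equal to the negative profile flattens sampling: implemented as
  # zero total landscape
  flat <- rep(0, 21)
  cnt2 <- sample_landscape_1d(flat, NULL, n_moves = 2e5, seed = 7)
  expect_lt(max(cnt2) / min(cnt2), 1.2)
})

test_that("kinetics round trip: walks -> first_passage -> fit recovers n_c", {
  prof <- cnt_profile(0:60, delta_mu = 0.45, n_c = 30)  # barrier ~6.8 kBT
  walks <- simulate_walks(prof, kplus = 40, n_traj = 300, seed = 8)
  fp <- first_passage(walks$series)
  fit <- fit_mfpt(fp, V = 1, fit_max_n = 55)
  expect_lt(abs(fit$n_c - 30) / 30, 0.10)
})
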