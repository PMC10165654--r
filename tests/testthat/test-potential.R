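test_that("pair term matches the closed-form evaluation and its cutoff", {
  p <- mw_params()
  # independent scalar evaluation of the pair formula
  r <- p$sigma
  sr <- p$sigma / r
  oracle <- p$A * p$epsilon * (p$B * sr^p$p - sr^p$q) *
    exp(p$sigma / (r - p$a * p$sigma))
  expect_equal(mw_pair_energy(r), oracle, tolerance = 1e-12)
  expect_equal(mw_pair_energy(r), -4.972, tolerance = 1e-3)
  expect_identical(mw_pair_energy(p$a * p$sigma), 0)
  expect_identical(mw_pair_energy(10 * p$a * p$sigma), 0)
  # smooth approach to zero at the cutoff
  expect_lt(abs(mw_pair_energy(p$a * p$sigma - 1e-6)), 1e-10)
  expect_error(mw_pair_energy(-1), "positive")
})

test_that("triplet term vanishes at the ideal angle and at the cutoff", {
  p <- mw_params()
  expect_equal(mw_triplet_energy(2.5, 2.8, -1 / 3), 0)
  expect_equal(mw_triplet_energy(p$a * p$sigma, 2.5, 0.2), 0)
  expect_lt(mw_triplet_energy(p$a * p$sigma - 1e-7, 2.5, 0.2), 1e-12)
  # equilateral triplet at r = sigma against a direct scalar evaluation
  oracle <- p$lam * p$epsilon * (0.5 + 1 / 3)^2 *
    exp(p$gamma * p$sigma / (p$sigma - p$a * p$sigma))^2
  expect_equal(mw_triplet_energy(p$sigma, p$sigma, 0.5), oracle,
               tolerance = 1e-12)
})

test_that("evaluate decomposes into pair + triplet sums on a trimer", {
  pos <- rbind(c(10, 10, 10), c(12.2, 10.5, 10.3), c(9.1, 12.1, 10.8))
  cfg <- configuration(pos, c(40, 40, 40))
  ang <- function(a, b, c) {
    u <- b - a; v <- c - a
    sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  r <- as.matrix(dist(pos))
  U_manual <-
    mw_pair_energy(r[1, 2]) + mw_pair_energy(r[1, 3]) + mw_pair_energy(r[2, 3]) +
    mw_triplet_energy(r[1, 2], r[1, 3], ang(pos[1, ], pos[2, ], pos[3, ])) +
    mw_triplet_energy(r[1, 2], r[2, 3], ang(pos[2, ], pos[1, ], pos[3, ])) +
    mw_triplet_energy(r[1, 3], r[2, 3], ang(pos[3, ], pos[1, ], pos[2, ]))
  expect_equal(mw_evaluate(cfg)$U, U_manual, tolerance = 1e-12)
})

test_that("forces are the exact gradient and obey Newton's third law", {
  cfg <- random_config(30, 12, seed = 2)
  ev <- mw_evaluate(cfg)
  h <- 1e-5
  for (i in c(1, 7, 18)) {
    for (k in 1:3) {
      cp <- cfg; cp$positions[i, k] <- cp$positions[i, k] + h
      cm <- cfg; cm$positions[i, k] <- cm$positions[i, k] - h
      fd <- -(mw_evaluate(cp)$U - mw_evaluate(cm)$U) / (2 * h)
      expect_equal(ev$forces[i, k], fd,
                   tolerance = 1e-6 * max(1, abs(fd)))
    }
  }
  expect_lt(max(abs(colSums(ev$forces))), 1e-9)
})

test_that("energy is invariant under translation and isolated pairs see nothing", {
  cfg <- random_config(20, 14, seed = 3)
  U0 <- mw_evaluate(cfg)$U
  cfg2 <- cfg
  cfg2$positions <- sweep(cfg2$positions, 2, c(1.37, -2.91, 0.48), "+")
  expect_equal(mw_evaluate(cfg2)$U, U0, tolerance = 1e-10)
  # two particles beyond the cutoff
  far <- configuration(rbind(c(2, 2, 2), c(12, 12, 12)), c(24, 24, 24))
  evf <- mw_evaluate(far)
  expect_identical(evf$U, 0)
  expect_true(all(evf$forces == 0))
})

test_that("virial pressure of a non-interacting system is ideal", {
  # particles beyond cutoff: W = 0 so P reduces to N kB T / V
  cfg <- configuration(rbind(c(3, 3, 3), c(15, 15, 15)), c(30, 30, 30))
  expect_identical(mw_evaluate(cfg)$virial, 0)
})

test_that("neighbor list matches a brute-force scan and honours the box limit", {
  cfg <- random_config(40, 13, seed = 4, min_dist = 1.5)
  cutoff <- 4.0
  nl <- neighbor_list(cfg, cutoff)
  # O(N^2) oracle
  for (i in seq_len(40)) {
    d <- sweep(cfg$positions, 2, cfg$positions[i, ], "-")
    d <- d - round(d / 13) * 13
    r <- sqrt(rowSums(d^2))
    expect_setequal(nl[[i]], setdiff(which(r < cutoff), i))
  }
  # symmetry
  for (i in seq_len(40)) for (j in nl[[i]]) expect_true(i %in% nl[[j]])
  expect_error(neighbor_list(cfg, 7), "too large")
  # two particles just beyond cutoff + skin are not neighbours
  sep <- configuration(rbind(c(1, 1, 1), c(1 + 3.3 + 1e-6, 1, 1)), c(30, 30, 30))
  nl2 <- neighbor_list(sep, 3.0, skin = 0.3)
  expect_length(nl2[[1]], 0)
  # diamond lattice coordination at the first-shell cutoff
  lat <- build_lattice("cubic", 3, density = 0.98)
  nl3 <- neighbor_list(lat, 3.2)
  expect_true(all(lengths(nl3) == 4))
})

test_that("box smaller than twice the cutoff is rejected", {
  small <- configuration(matrix(runif(9, 0, 6), 3, 3), c(6, 6, 6))
  expect_error(mw_evaluate(small), "configuration error")
})
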