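test_that("q12 vectors match a direct spherical-harmonics summation", {
  pos <- rbind(c(5, 5, 5), c(7, 5.5, 5.2), c(4.2, 6.3, 5.9),
               c(5.1, 3.9, 6.2), c(5.8, 5.2, 3.4))
  cfg <- configuration(pos, c(50, 50, 50))
  qv <- q12_vectors(cfg, cutoff = 3.2)
  ylm <- function(m, th, ph) {
    P <- pracma::legendre(12, cos(th))[m + 1, ]
    sqrt((2 * 12 + 1) / (4 * pi) * factorial(12 - m) / factorial(12 + m)) *
      P * exp(1i * m * ph)
  }
  for (i in 1:2) {
    nb <- qv$neighbors[[i]]
    q_or <- sapply(0:12, function(m) {
      s <- 0
      for (j in nb) {
        d <- pos[j, ] - pos[i, ]
        r <- sqrt(sum(d^2))
        s <- s + ylm(m, acos(d[3] / r), atan2(d[2], d[1]))
      }
      s / length(nb)
    })
    expect_lt(max(abs(q_or - qv$q[i, ])), 1e-10)
  }
})

test_that("a single bond along +z has only the m = 0 component", {
  cfg <- configuration(rbind(c(10, 10, 10), c(10, 10, 12)), c(40, 40, 40))
  qv <- q12_vectors(cfg, cutoff = 3)
  expect_lt(max(abs(qv$q[1, -1])), 1e-12)
  expect_gt(abs(qv$q[1, 1]), 0.1)
})

test_that("rotations preserve q-vector norms (isolated cluster)", {
  # a compact cluster far from the boundaries, so the periodic images play
  # no role and a rigid rotation is a true symmetry
  cl <- random_config(16, 12, seed = 6, min_dist = 1.8)
  cl$positions <- sweep(cl$positions / 3, 2, c(20, 20, 20), "+")
  cl$box <- c(48, 48, 48)
  qv <- q12_vectors(cl, 3.51)
  th <- 0.93
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cl2 <- cl
  cl2$positions <- t(R %*% t(cl$positions - 20)) + 20
  qv2 <- q12_vectors(cl2, 3.51)
  expect_equal(qv$qnorm, qv2$qnorm, tolerance = 1e-10)
})

test_that("perfect diamond lattices are fully crystalline, liquids are not", {
  for (poly in c("cubic", "hexagonal")) {
    cells <- if (poly == "cubic") c(3, 3, 3) else c(3, 2, 3)
    lat <- build_lattice(poly, cells, density = 0.98)
    res <- classify_crystalline(lat)
    expect_equal(mean(res$crystalline), 1)
    expect_equal(largest_cluster(res)$n, n_particles(lat))
  }
  liq <- liquid_216()
  expect_lt(mean(classify_crystalline(liq)$crystalline), 0.01)
  # unreachable threshold labels nothing
  res0 <- classify_crystalline(liq, op_config(d_c = 1 + 1e-9))
  expect_identical(sum(res0$crystalline), 0L)
  expect_identical(largest_cluster(res0)$n, 0L)
})

test_that("n is monotone non-increasing in d_c and xi_c", {
  lat <- build_lattice("cubic", 3, density = 0.98, noise = 0.15, seed = 8)
  ns_d <- sapply(c(0.5, 0.7, 0.9, 0.99),
                 function(dc) largest_cluster_size(lat, op_config(d_c = dc)))
  expect_true(all(diff(ns_d) <= 0))
  ns_x <- sapply(1:6,
                 function(xc) largest_cluster_size(lat, op_config(xi_c = xc)))
  expect_true(all(diff(ns_x) <= 0))
})

test_that("cluster decomposition equals a brute-force flood fill", {
  cfg <- random_config(60, 12, seed = 7, min_dist = 1.6)
  res <- classify_crystalline(cfg)
  set.seed(3)
  res$crystalline <- runif(60) < 0.5   # random label set
  cl <- largest_cluster(res)
  # flood-fill oracle in plain R
  comp_or <- integer(60); cid <- 0
  for (s in which(res$crystalline)) {
    if (comp_or[s] > 0) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp_or[u] > 0) next
      comp_or[u] <- cid
      nb <- res$neighbors[[u]]
      queue <- c(queue, nb[res$crystalline[nb] & comp_or[nb] == 0])
    }
  }
  expect_identical(max(tabulate(comp_or)), cl$n)
  # same partition up to relabelling
  split_a <- split(seq_len(60), cl$membership)
  split_b <- split(seq_len(60), comp_or)
  expect_setequal(
    unname(sapply(split_a[names(split_a) != "0"], paste, collapse = ",")),
    unname(sapply(split_b[names(split_b) != "0"], paste, collapse = ",")))
})

test_that("two planted clusters yield the larger one as n", {
  # chains of 3 and 5 bonded particles far apart, no bridge
  mk <- function(org, k) cbind(org[1] + 2.8 * (seq_len(k) - 1), org[2], org[3])
  pos <- rbind(mk(c(2, 2, 2), 3), mk(c(20, 20, 20), 5))
  cfg <- configuration(pos, c(40, 40, 40))
  res <- classify_crystalline(cfg)
  res$crystalline <- rep(TRUE, 8)
  expect_identical(largest_cluster(res)$n, 5L)
})

test_that("polymorph labels separate cubic from hexagonal diamond", {
  lat_c <- build_lattice("cubic", 3, density = 0.98, noise = 0.02, seed = 2)
  res_c <- classify_crystalline(lat_c)
  lab_c <- classify_polymorph(lat_c, res_c)
  expect_gt(mean(lab_c == "cubic"), 0.99)
  lat_h <- build_lattice("hexagonal", c(3, 2, 3), density = 0.98,
                         noise = 0.02, seed = 2)
  res_h <- classify_crystalline(lat_h)
  lab_h <- classify_polymorph(lat_h, res_h)
  expect_gt(mean(lab_h == "hexagonal"), 0.99)
  # liquid particles carry no sub-label
  liq <- liquid_216()
  res_l <- classify_crystalline(liq)
  expect_true(all(classify_polymorph(liq, res_l) == "none"))
})

test_that("thermally equilibrated ice is still classified as crystalline", {
  for (poly in c("cubic", "hexagonal")) {
    cells <- if (poly == "cubic") c(3, 3, 3) else c(3, 2, 3)
    lat <- build_lattice(poly, cells, density = 0.98)
    cfg <- draw_velocities(lat, 218, seed = 44)
    cfg <- integrate_nvt(md_state(cfg), 1000, 4, T = 218, damping = 0.5,
                         seed = 44)$config
    res <- classify_crystalline(cfg)
    expect_gte(mean(res$crystalline), 0.99)
    expect_gte(largest_cluster(res)$n, 0.99 * n_particles(cfg))
  }
})
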