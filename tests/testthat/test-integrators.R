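test_that("reduced temperature conversion reproduces the stated state points", {
  expect_equal(reduced_to_kelvin(0.07), 218.0, tolerance = 0.0005)
  expect_equal(reduced_to_kelvin(0.065), 202.4, tolerance = 0.0005)
  expect_identical(reduced_to_kelvin(0), 0)
})

test_that("Maxwell-Boltzmann velocities have the right variance and are seeded", {
  cfg <- configuration(matrix(1, 1, 3), c(100, 100, 100))
  draws <- replicate(3e4, 0)
  big <- configuration(matrix(1, 3e4, 3), c(1e4, 1e4, 1e4))
  v <- draw_velocities(big, 300, seed = 9)$velocities
  expect_equal(stats::var(as.vector(v)),
               kB * 300 / (mw_params()$mass * 1 / 4.184e-4),
               tolerance = 0.02)
  # determinism contract
  a <- draw_velocities(big, 300, seed = 42)$velocities
  b <- draw_velocities(big, 300, seed = 42)$velocities
  d <- draw_velocities(big, 300, seed = 43)$velocities
  expect_identical(a, b)
  expect_false(identical(a, d))
  # T = 0 gives all zeros
  z <- draw_velocities(cfg, 0, seed = 1)$velocities
  expect_true(all(z == 0))
})

test_that("dt = 4 fs for 5 steps advances time by exactly 0.02 ps", {
  cfg <- draw_velocities(configuration(rbind(c(2, 2, 2), c(15, 15, 15)),
                                       c(30, 30, 30)), 200, seed = 1)
  st <- md_state(cfg)
  st2 <- integrate_nve(st, 5, 4)
  expect_equal(st2$t - st$t, 0.02, tolerance = 1e-12)
})

test_that("isolated resting particles do not move in NVE", {
  cfg <- configuration(rbind(c(3, 3, 3), c(18, 18, 18)), c(36, 36, 36),
                       velocities = matrix(0, 2, 3))
  st <- integrate_nve(md_state(cfg), 100, 4)
  expect_equal(st$config$positions, cfg$positions, tolerance = 1e-12)
  expect_identical(st$U, 0)
})

test_that("NVE conserves energy at the production time step", {
  liq <- liquid_216()
  st <- md_state(liq)
  st <- integrate_nve(st, 200, 4)   # settle away from the thermostat state
  e0 <- st$U + st$K
  st2 <- integrate_nve(st, 1000, 4, sample_every = 10)
  E <- st2$trajectory$series$U + st2$trajectory$series$K
  drift <- abs(unname(coef(stats::lm(E ~ seq_along(E)))[2])) * 100 / 216
  expect_lt(drift, 1e-4)  # kcal/mol per particle per 1000 steps
})

test_that("Langevin thermostat reaches and holds the target temperature", {
  liq <- liquid_216()
  st <- md_state(liq)
  st <- integrate_nvt(st, 8000, 4, T = 270.9, damping = 0.5, seed = 7,
                      sample_every = 40)
  Tm <- mean(tail(st$trajectory$series$T_inst, 150))
  expect_lt(abs(Tm - 270.9) / 270.9, 0.02)
  # velocity components pass a Maxwell-Boltzmann chi-square test
  v <- as.vector(st$config$velocities)
  sd_th <- sqrt(kB * 270.9 / (mw_params()$mass / 4.184e-4))
  qs <- qnorm(seq(0, 1, 0.1), 0, sd_th)
  obs <- table(cut(v, qs))
  expect_gt(chisq.test(as.vector(obs), p = rep(0.1, 10))$p.value, 0.01)
})

test_that("infinite damping recovers NVE, and a seeded NVT run is reproducible", {
  liq <- liquid_216()
  st <- md_state(liq)
  nve <- integrate_nve(st, 50, 4)
  nvt <- integrate_nvt(st, 50, 4, T = 270.9, damping = 1e9, seed = 1)
  expect_equal(nvt$config$positions, nve$config$positions, tolerance = 1e-6)
  a <- integrate_nvt(st, 100, 4, T = 250, damping = 0.5, seed = 11)
  b <- integrate_nvt(st, 100, 4, T = 250, damping = 0.5, seed = 11)
  expect_identical(a$config$positions, b$config$positions)
})

test_that("barostat holds a stable density for the mW liquid", {
  liq <- liquid_216()
  st <- md_state(liq)
  st <- integrate_npt(st, 6000, 4, T = 270.9, P = 1.01325, damping = 0.5,
                      seed = 3, sample_every = 60)
  V <- st$trajectory$series$V
  half1 <- mean(V[26:60]); half2 <- mean(V[61:100])
  expect_lt(abs(half2 - half1) / half1, 0.02)  # no drift trend
  rho <- 216 * mw_params()$mass / (6.02214076e23 * mean(tail(V, 50)) * 1e-24)
  expect_gt(rho, 0.9); expect_lt(rho, 1.1)
})

test_that("momentum can be zeroed exactly", {
  liq <- liquid_216()
  cfg <- zero_momentum(liq)
  expect_lt(max(abs(colMeans(cfg$velocities))), 1e-15)
})
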