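# shared fixtures, generated once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixture_env)) assign(key, make(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small random configuration with a safe minimum separation
random_config <- function(N, L, seed = 1, min_dist = 2.0) {
  set.seed(seed)
  pos <- matrix(NA_real_, N, 3)
  placed <- 0
  while (placed < N) {
    cand <- stats::runif(3, 0, L)
    ok <- placed == 0 || {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand, "-")
      d <- d - round(d / L) * L
      min(rowSums(d^2)) > min_dist^2
    }
    if (ok) { placed <- placed + 1; pos[placed, ] <- cand }
  }
  configuration(pos, rep(L, 3))
}

# equilibrated mW liquid, N = 216 at 270.9 K (used by several files)
liquid_216 <- function() cached("liquid_216", function() {
  generate_liquid(216, 1.0, 270.9, seed = 5)
})

# harmonic-well engine centred in the box (toy system for samplers)
harmonic_engine <- function(k = 50, center = c(25, 25, 25)) {
  custom_engine(function(cfg) {
    x <- sweep(cfg$positions, 2, center, "-")
    list(U = 0.5 * k * sum(x^2), forces = -k * x, virial = 0)
  }, cutoff = 0)
}

# ideal-gas engine (no interactions)
ideal_engine <- function() {
  custom_engine(function(cfg)
    list(U = 0, forces = cfg$positions * 0, virial = 0), cutoff = 0)
}

op_zero <- function(config) 0L

# small pair-only (three-body strength ~ 0) reference corpus for NNP tests
pair_corpus <- function() cached("pair_corpus", function() {
  pp <- mw_params(lam = 1e-12)
  lapply(1:12, function(s) {
    cfg <- random_config(32, box_edge_for_density(32, 0.95),
                         seed = 100 + s, min_dist = 2.2)
    st <- md_state(draw_velocities(cfg, 250, seed = s), mw_engine(pp))
    st <- integrate_nvt(st, 400, 4, T = 250, damping = 0.2,
                        engine = mw_engine(pp), seed = s)
    ev <- mw_evaluate(st$config, pp)
    list(config = st$config, energy = ev$U, forces = ev$forces,
         virial = ev$virial)
  })
})
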