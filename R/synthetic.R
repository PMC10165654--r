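#' Build a periodic diamond lattice
#'
#' Generates the cubic-diamond or hexagonal-diamond (lonsdaleite, i.e.
#' wurtzite-topology with ideal c/a) crystal at a target density in an
#' orthorhombic periodic cell, optionally with Gaussian positional noise.
#' Interior coordination is 4 at the first-shell cutoff for zero noise.
#'
#' @param polymorph `"cubic"` or `"hexagonal"`
#' @param cells unit cells per axis (scalar or length 3), >= 2 for periodic
#'   validity
#' @param density target density, g/cm^3
#' @param noise Gaussian positional noise amplitude, Angstrom
#' @param seed integer seed for the noise
#' @param mass particle mass, g/mol
#' @return a [configuration()] with 8 particles per unit cell
#' @export
build_lattice <- function(polymorph = c("cubic", "hexagonal"), cells = 3,
                          density = 0.98, noise = 0, seed = 1,
                          mass = mw_params()$mass) {
  polymorph <- match.arg(polymorph)
  cells <- rep(as.integer(cells), length.out = 3)
  stopifnot(all(cells >= 2), density > 0, noise >= 0)
  if (polymorph == "cubic") {
    a <- (8 * mass / (.N_A * density) * 1e24)^(1 / 3)
    fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
    frac <- rbind(fcc, sweep(fcc, 2, c(.25, .25, .25), "+") %% 1)
    cell <- c(a, a, a)
  } else {
    # orthorhombic lonsdaleite cell (a, sqrt(3) a, c), ideal c/a = sqrt(8/3)
    ca <- sqrt(8 / 3)
    a <- (8 * mass / (.N_A * density) / (sqrt(3) * ca) * 1e24)^(1 / 3)
    base <- rbind(c(0, 1 / 3, 0), c(.5, 1 / 6, .5),
                  c(0, 1 / 3, 3 / 8), c(.5, 1 / 6, 7 / 8))
    frac <- rbind(base, sweep(base, 2, c(.5, .5, 0), "+") %% 1)
    cell <- c(a, sqrt(3) * a, ca * a)
  }
  bond <- if (polymorph == "cubic") sqrt(3) / 4 * a else sqrt(3 / 8) * a
  if (bond < 1.2)
    stop("density implies overlapping particles (bond length < 1.2 A)")
  grid <- as.matrix(expand.grid(x = seq_len(cells[1]) - 1,
                                y = seq_len(cells[2]) - 1,
                                z = seq_len(cells[3]) - 1))
  pos <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sweep(frac, 2, grid[g, ], "+")
  }))
  pos <- sweep(pos, 2, cell, "*")
  if (noise > 0) {
    set.seed(seed)
    pos <- pos + matrix(stats::rnorm(length(pos), 0, noise), ncol = 3)
  }
  configuration(pos, cell * cells)
}

#' Nearest-neighbour distance of a diamond lattice at a given density
#' @inheritParams build_lattice
#' @export
lattice_bond_length <- function(polymorph = c("cubic", "hexagonal"),
                                density = 0.98, mass = mw_params()$mass) {
  polymorph <- match.arg(polymorph)
  if (polymorph == "cubic") {
    a <- (8 * mass / (.N_A * density) * 1e24)^(1 / 3)
    sqrt(3) / 4 * a
  } else {
    ca <- sqrt(8 / 3)
    a <- (8 * mass / (.N_A * density) / (sqrt(3) * ca) * 1e24)^(1 / 3)
    sqrt(3 / 8) * a
  }
}

.trend_ok <- function(u) {
  tail_u <- u[(length(u) %/% 2 + 1):length(u)]
  if (length(tail_u) < 8) return(FALSE)
  t <- seq_along(tail_u)
  fit <- stats::lm(tail_u ~ t)
  s <- summary(fit)$coefficients
  abs(s[2, 1]) < 2 * s[2, 2]
}

#' Generate an equilibrated liquid configuration
#'
#' Random insertion with overlap rejection followed by Langevin NVT
#' equilibration until the potential energy shows no trend over the trailing
#' half of a round (slope within two standard errors of zero).
#'
#' @param N particle count
#' @param rho density, g/cm^3 (reproduced exactly by box construction)
#' @param T temperature, K
#' @param params an [mw_params()] object
#' @param seed integer seed
#' @param round_ps length of one equilibration round, ps
#' @param max_rounds giving-up point
#' @param dt time step, fs
#' @return an equilibrated [configuration()] (with velocities), labelled with
#'   its state point
#' @export
generate_liquid <- function(N, rho, T, params = mw_params(), seed = 1,
                            round_ps = 10, max_rounds = 8, dt = 4) {
  set.seed(seed)
  L <- box_edge_for_density(N, rho, params$mass)
  pos <- matrix(NA_real_, N, 3)
  placed <- 0
  min_d2 <- 2.0^2
  while (placed < N) {
    cand <- stats::runif(3, 0, L)
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand, "-")
      d <- d - round(d / L) * L
      if (min(rowSums(d^2)) < min_d2) ok <- FALSE
    }
    if (ok) { placed <- placed + 1; pos[placed, ] <- cand }
  }
  cfg <- configuration(pos, rep(L, 3), temperature = T)
  cfg <- draw_velocities(cfg, T, mass = params$mass)
  st <- md_state(cfg, mw_engine(params))
  n_steps <- max(1, round(round_ps * 1e3 / dt))
  for (round in seq_len(max_rounds)) {
    st <- integrate_nvt(st, n_steps, dt, T = T, damping = 0.5,
                        engine = mw_engine(params),
                        sample_every = max(1, n_steps %/% 50))
    if (.trend_ok(st$trajectory$series$U)) {
      cfg <- st$config
      cfg$temperature <- T
      return(cfg)
    }
  }
  stop("equilibration not reached within max_rounds (energy still trending)")
}

#' Exact mean first passage times of the birth-death surrogate
#'
#' For the continuous-time birth-death walk with constant attachment rate
#' `k+` and detailed-balance detachment rates on a profile `betaG(n)`, the
#' mean first passage time from 0 (reflecting) to level `m` is the standard
#' double sum `T(m) = sum_{j<m} 1/(k+ pi_j) sum_{i<=j} pi_i` with
#' `pi_n = exp(-betaG(n))`.
#'
#' @param betaG numeric vector of the profile over `n = 0..M` (kB*T units)
#' @param kplus attachment rate, 1/ns
#' @return vector of MFPTs (ns) to levels `1..M`
#' @export
bd_mfpt_exact <- function(betaG, kplus = 1) {
  pi_n <- exp(-(betaG - min(betaG)))
  M <- length(betaG) - 1
  cum <- cumsum(pi_n)
  terms <- cum[1:M] / (kplus * pi_n[1:M])
  cumsum(terms)
}

#' Simulate birth-death nucleation walks
#'
#' Continuous-time walks of the largest-cluster-size surrogate: size-
#' independent attachment rate `k+`, detachment rates fixed by detailed
#' balance against `exp(-betaG(n))`, reflecting at 0, absorbing at the top
#' of the range. The exact MFPT of this process ([bd_mfpt_exact()]) makes it
#' an oracle for the MFPT estimators.
#'
#' @param betaG profile over `n = 0..M`, kB*T units
#' @param kplus attachment rate, 1/ns
#' @param n_traj number of trajectories
#' @param seed integer seed
#' @param max_events per-walk event cap
#' @return list with `series` (list of data.frames `time`, `n` of
#'   new-maximum events), `fpt` (trajectory x level matrix of first passage
#'   times, ns)
#' @export
simulate_walks <- function(betaG, kplus = 1, n_traj = 100, seed = 1,
                           max_events = 1e7) {
  stopifnot(all(is.finite(betaG)) || any(is.infinite(betaG)),
            kplus > 0, n_traj >= 1)
  set.seed(seed)
  fpt <- bd_walks_cpp(betaG, kplus, as.integer(n_traj), max_events)
  M <- length(betaG) - 1
  series <- lapply(seq_len(n_traj), function(w) {
    t <- fpt[w, ]
    keep <- !is.na(t)
    data.frame(time = t[keep], n = (0:M)[keep])
  })
  list(series = series, fpt = fpt, betaG = betaG, kplus = kplus)
}

#' Metropolis sampling of a one-dimensional landscape
#'
#' Samples `P(n) ~ exp(-betaG(n) - beta*eta(n))` with symmetric integer
#' proposals; the validation surrogate for the umbrella sampler that feeds
#' [reconstruct_barrier()] without any molecular dynamics.
#'
#' @param betaG profile over `n = 0..M`, kB*T units
#' @param bias a [bias_spec()] or `NULL`
#' @param T temperature, K (converts the bias to kB*T units)
#' @param n_moves number of Metropolis moves
#' @param seed integer seed
#' @param start starting n
#' @param step maximum proposal step
#' @return named counts over n (class `table`-like named numeric), with the
#'   acceptance fraction as attribute
#' @export
sample_landscape_1d <- function(betaG, bias = NULL, T = 218, n_moves = 1e6,
                                seed = 1, start = 0, step = 3) {
  stopifnot(all(is.finite(betaG)))
  n <- seq_along(betaG) - 1
  beta_eta <- if (is.null(bias)) rep(0, length(n)) else
    bias_potential(n, bias, T) * thermo_beta(T)
  set.seed(seed)
  out <- metropolis1d_cpp(betaG + beta_eta, n_moves, as.integer(start),
                          as.integer(step))
  counts <- as.numeric(out$counts)
  names(counts) <- n
  attr(counts, "acceptance") <- out$acceptance
  counts
}

#' CNT-shaped free-energy profile
#'
#' `betaG(n) = -dmu*n + (3/2)*dmu*n_c^(1/3)*n^(2/3)` (kB*T units): barrier
#' top at `n = n_c` with height `0.5*dmu*n_c`. Mirror image of
#' [bias_potential()].
#'
#' @param n sizes (>= 0)
#' @param delta_mu driving force, kB*T units
#' @param n_c critical size
#' @export
cnt_profile <- function(n, delta_mu, n_c) {
  -delta_mu * n + 1.5 * delta_mu * n_c^(1 / 3) * n^(2 / 3)
}
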