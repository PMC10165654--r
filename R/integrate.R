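#' Instantaneous mechanical state of an MD system
#'
#' Bundles a configuration with its potential energy `U`, kinetic energy `K`,
#' interaction virial `W` (all kcal/mol) and elapsed time `t` (ps).
#'
#' @param config a [configuration()]; velocities may be `NULL` (treated as at
#'   rest)
#' @param engine an engine (see [mw_engine()]) used to evaluate `U` and `W`
#' @return object of class `md_state`
#' @export
md_state <- function(config, engine = mw_engine()) {
  ev <- engine$evaluate(config)
  K <- if (is.null(config$velocities)) 0 else
    kinetic_energy(config$velocities, engine$mass)
  structure(list(config = config, U = ev$U, K = K, W = ev$virial,
                 forces = ev$forces, t = 0),
            class = "md_state")
}

#' Kinetic energy of a velocity set
#' @param velocities `N x 3` matrix, Angstrom/fs
#' @param mass particle mass, g/mol
#' @return kinetic energy in kcal/mol
#' @export
kinetic_energy <- function(velocities, mass = mw_params()$mass) {
  0.5 * mass * sum(velocities^2) * .mvv2e
}

#' Instantaneous kinetic temperature
#' @param K kinetic energy, kcal/mol
#' @param N particle count
#' @export
kinetic_temperature <- function(K, N) 2 * K / (3 * N * kB)

#' Draw velocities from the Maxwell-Boltzmann distribution
#'
#' Each Cartesian component is drawn independently from
#' `Normal(0, kB*T/m)` (in the package's units the standard deviation is
#' `sqrt(kB*T/(m*mvv2e))` Angstrom/fs).
#'
#' @param config a [configuration()]
#' @param T temperature, K (T = 0 gives all-zero velocities)
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so Monte Carlo drivers can consume one reproducible stream)
#' @param mass particle mass, g/mol
#' @return the configuration with fresh velocities
#' @export
draw_velocities <- function(config, T, seed = NULL, mass = mw_params()$mass) {
  stopifnot(T >= 0)
  if (!is.null(seed)) set.seed(seed)
  N <- n_particles(config)
  sd <- sqrt(kB * T / (mass * .mvv2e))
  config$velocities <- matrix(stats::rnorm(3 * N, 0, sd), N, 3)
  config$temperature <- T
  config
}

#' Remove the net momentum of a configuration
#'
#' Subtracts the mean velocity so the total momentum is exactly zero; used
#' before NVE production runs so that centre-of-mass drift left by a
#' stochastic thermostat does not contaminate transport measurements.
#'
#' @param config a [configuration()] with velocities
#' @export
zero_momentum <- function(config) {
  stopifnot(!is.null(config$velocities))
  config$velocities <- sweep(config$velocities, 2,
                             colMeans(config$velocities), "-")
  config
}

.run_md <- function(state, engine, ensemble, n_steps, dt, T = 0,
                    damping = 0, P = 0, piston_period = 0.5,
                    piston_damping = 0.2, seed = NULL, sample_every = 0) {
  stopifnot(inherits(state, "md_state"), n_steps >= 0, dt > 0)
  cfg <- state$config
  if (is.null(cfg$velocities))
    stop("velocities required: call draw_velocities() first")
  if (!is.null(seed)) set.seed(seed)
  if (engine$kind == "mw") {
    out <- run_md_cpp(cfg$positions, cfg$velocities, cfg$box, engine$params,
                      ensemble, as.integer(n_steps), dt, T,
                      damping * 1e3, P, piston_period * 1e3,
                      piston_damping * 1e3, as.integer(sample_every))
    new_cfg <- configuration(out$pos, out$box, out$vel,
                             temperature = if (ensemble > 0) T else
                               cfg$temperature,
                             pressure = if (ensemble == 2) P else cfg$pressure)
    st <- structure(list(config = new_cfg, U = out$U, K = out$K, W = out$W,
                         forces = NULL, t = state$t + n_steps * dt * 1e-3),
                    class = "md_state")
    if (sample_every > 0) {
      ser <- as.data.frame(out$series)
      names(ser) <- c("time", "U", "K", "T_inst", "P_inst", "V")
      ser$time <- ser$time + state$t
      st$trajectory <- structure(
        list(times = ser$time, frames = out$frames,
             boxes = out$boxes, series = ser),
        class = "md_trajectory")
    }
    return(st)
  }
  if (ensemble == 2)
    stop("the Langevin-piston barostat is implemented for the mW engine only")
  if (ensemble == 1)
    return(.baoab_r(state, engine, n_steps, dt, T, damping, sample_every))
  verlet_segment(state, engine, n_steps, dt)
}

#' Velocity-Verlet NVE integration
#'
#' @param state an [md_state()] with velocities
#' @param n_steps number of steps
#' @param dt time step, fs
#' @param engine potential engine
#' @param sample_every if > 0, store a frame every this many steps; the
#'   returned state then carries a `trajectory` element with unwrapped
#'   positions, thermodynamic series and per-frame boxes
#' @return the advanced [md_state()]
#' @export
integrate_nve <- function(state, n_steps, dt, engine = mw_engine(),
                          sample_every = 0) {
  .run_md(state, engine, 0L, n_steps, dt, sample_every = sample_every)
}

#' Langevin (BAOAB) NVT integration
#'
#' @inheritParams integrate_nve
#' @param T target temperature, K
#' @param damping Langevin damping time, ps; the friction is `1/damping`
#' @param seed optional integer seed
#' @return the advanced [md_state()]
#' @export
integrate_nvt <- function(state, n_steps, dt, T, damping = 1,
                          engine = mw_engine(), seed = NULL,
                          sample_every = 0) {
  stopifnot(T > 0, damping > 0)
  .run_md(state, engine, 1L, n_steps, dt, T = T, damping = damping,
          seed = seed, sample_every = sample_every)
}

#' Langevin-piston NPT integration
#'
#' Isotropic barostat acting on the volume logarithm with a piston of period
#' `piston_period` thermalised on the `piston_damping` timescale; the box is
#' rescaled affinely.
#'
#' @inheritParams integrate_nvt
#' @param P target pressure, bar
#' @param piston_period piston oscillation period, ps
#' @param piston_damping piston Langevin damping time, ps
#' @return the advanced [md_state()]
#' @export
integrate_npt <- function(state, n_steps, dt, T, P, damping = 1,
                          piston_period = 0.5, piston_damping = 0.2,
                          engine = mw_engine(), seed = NULL,
                          sample_every = 0) {
  stopifnot(T > 0, P >= 0)
  .run_md(state, engine, 2L, n_steps, dt, T = T, damping = damping, P = P,
          piston_period = piston_period, piston_damping = piston_damping,
          seed = seed, sample_every = sample_every)
}

## R-level BAOAB Langevin thermostat for engines without a compiled driver
.baoab_r <- function(state, engine, n_steps, dt, T, damping_ps,
                     sample_every = 0) {
  cfg <- state$config
  x <- cfg$positions
  v <- cfg$velocities
  N <- nrow(x)
  am <- .acc_conv / engine$mass
  c1 <- exp(-dt / (damping_ps * 1e3))
  c2 <- sqrt((1 - c1^2) * kB * T / (engine$mass * .mvv2e))
  F <- engine$evaluate(cfg)$forces
  frames <- list(); times <- numeric(0); Us <- numeric(0)
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * F * am
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * matrix(stats::rnorm(3 * N), N, 3)
    x <- x + 0.5 * dt * v
    cfg$positions <- x
    ev <- engine$evaluate(cfg)
    F <- ev$forces
    v <- v + 0.5 * dt * F * am
    if (sample_every > 0 && s %% sample_every == 0) {
      frames[[length(frames) + 1]] <- x
      times <- c(times, state$t + s * dt * 1e-3)
      Us <- c(Us, ev$U)
    }
  }
  cfg$velocities <- v
  cfg$temperature <- T
  ev <- engine$evaluate(cfg)
  st <- structure(list(config = cfg, U = ev$U,
                       K = kinetic_energy(v, engine$mass), W = ev$virial,
                       forces = ev$forces, t = state$t + n_steps * dt * 1e-3),
                  class = "md_state")
  if (sample_every > 0) {
    st$trajectory <- structure(
      list(times = times, frames = frames,
           boxes = matrix(rep(cfg$box, length(frames)), ncol = 3,
                          byrow = TRUE),
           series = data.frame(time = times, U = Us)),
      class = "md_trajectory")
  }
  st
}

#' Plain velocity-Verlet segment for arbitrary engines
#'
#' Energy-conserving propagation used for hybrid Monte Carlo proposals and
#' for toy systems; works with any engine that provides forces.
#'
#' @inheritParams integrate_nve
#' @export
verlet_segment <- function(state, engine, n_steps, dt) {
  cfg <- state$config
  x <- cfg$positions
  v <- cfg$velocities
  am <- .acc_conv / engine$mass
  F <- if (!is.null(state$forces)) state$forces else engine$evaluate(cfg)$forces
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * F * am
    x <- x + dt * v
    cfg$positions <- x
    ev <- engine$evaluate(cfg)
    if (!is.finite(ev$U)) stop("integration error: non-finite energy")
    F <- ev$forces
    v <- v + 0.5 * dt * F * am
  }
  cfg$velocities <- v
  ev <- engine$evaluate(cfg)
  structure(list(config = cfg, U = ev$U,
                 K = kinetic_energy(v, engine$mass), W = ev$virial,
                 forces = ev$forces, t = state$t + n_steps * dt * 1e-3),
            class = "md_state")
}
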