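#' CNT-shaped bias specification
#'
#' The umbrella bias is the negative of a classical-nucleation-theory
#' free-energy curve, `eta(n) = kB*T * (dmu*n - (3/2)*dmu*n_b^(1/3)*n^(2/3))`,
#' parameterised by the chemical-potential difference `dmu` (in units of
#' kB*T) and the single adjustable parameter `n_b`, the size at which the
#' bias is stationary. If the CNT shape were exact with critical size `n_b`,
#' adding `eta` would flatten the barrier completely.
#'
#' @param delta_mu chemical-potential difference between bulk crystal and
#'   liquid, in kB*T units; 0.57 is the known value for mW at 218 K and
#'   ambient pressure
#' @param n_b bias critical-size parameter
#' @export
bias_spec <- function(delta_mu = 0.57, n_b = 90) {
  stopifnot(delta_mu > 0, n_b >= 1)
  structure(list(delta_mu = delta_mu, n_b = n_b), class = "bias_spec")
}

#' Evaluate the CNT-shaped bias potential
#'
#' @param n cluster size(s), >= 0
#' @param spec a [bias_spec()]
#' @param T temperature, K (sets the kB*T energy scale)
#' @return bias energy in kcal/mol; `eta(0) = 0` and
#'   `eta(n_b) = -0.5 * dmu * n_b * kB*T`
#' @export
bias_potential <- function(n, spec = bias_spec(), T) {
  stopifnot(all(n >= 0), T > 0)
  kB * T * (spec$delta_mu * n -
              1.5 * spec$delta_mu * spec$n_b^(1 / 3) * n^(2 / 3))
}

#' Hybrid Monte Carlo configuration
#'
#' @param T target temperature, K
#' @param P target pressure, bar
#' @param segment_ps NVE segment length per move, ps
#' @param dt integration time step, fs; `segment_ps/dt` must be an integer
#' @param vol_prob probability of attempting an isobaric volume move after
#'   each HMC move
#' @param max_dlnv half-width of the uniform log-volume proposal
#' @export
hmc_config <- function(T, P = 1.01325, segment_ps = 0.02, dt = 4,
                       vol_prob = 0.01, max_dlnv = 0.02) {
  n_steps <- segment_ps * 1e3 / dt
  if (abs(n_steps - round(n_steps)) > 1e-9 || n_steps < 1)
    stop("segment_ps / dt must be a positive integer number of steps")
  structure(list(T = T, P = P, segment_ps = segment_ps, dt = dt,
                 n_steps = as.integer(round(n_steps)),
                 vol_prob = vol_prob, max_dlnv = max_dlnv),
            class = "hmc_config")
}

#' One hybrid Monte Carlo move
#'
#' Draws fresh Maxwell-Boltzmann velocities, proposes a short NVE segment,
#' and accepts with probability `min(1, exp(-beta*(dK + dU + d_eta(n))))`
#' where `n` is recomputed from scratch on the trial frame. On rejection the
#' pre-move state is restored exactly.
#'
#' @param state an [md_state()]
#' @param engine a potential engine
#' @param bias a [bias_spec()], or `NULL` for unbiased sampling
#' @param cfg an [hmc_config()]
#' @param op_fn order-parameter function `configuration -> n`; defaults to
#'   the Q12 largest-cluster size
#' @param n_current current order-parameter value (recomputed when `NULL`)
#' @return list with the new `state`, logical `accepted`, the order
#'   parameter `n`, and the energy change `delta`
#' @export
hmc_move <- function(state, engine, bias, cfg, op_fn = NULL,
                     n_current = NULL) {
  if (is.null(op_fn)) op_fn <- function(config) largest_cluster_size(config)
  beta <- thermo_beta(cfg$T)
  eta <- function(n) if (is.null(bias)) 0 else bias_potential(n, bias, cfg$T)

  cfg0 <- draw_velocities(state$config, cfg$T, mass = engine$mass)
  state0 <- state
  state0$config <- cfg0
  state0$K <- kinetic_energy(cfg0$velocities, engine$mass)
  state0$forces <- NULL
  if (is.null(n_current)) n_current <- op_fn(cfg0)

  trial <- tryCatch(verlet_segment(state0, engine, cfg$n_steps, cfg$dt),
                    error = function(e) NULL)
  if (is.null(trial)) {
    warning("HMC proposal failed; move rejected")
    return(list(state = state0, accepted = FALSE, n = n_current, delta = NA))
  }
  n_trial <- tryCatch(op_fn(trial$config), error = function(e) NA_integer_)
  if (is.na(n_trial)) {
    warning("order-parameter failure on trial frame; move rejected")
    return(list(state = state0, accepted = FALSE, n = n_current, delta = NA))
  }
  delta <- (trial$K - state0$K) + (trial$U - state0$U) +
    (eta(n_trial) - eta(n_current))
  if (delta <= 0 || stats::runif(1) < exp(-beta * delta)) {
    list(state = trial, accepted = TRUE, n = n_trial, delta = delta)
  } else {
    list(state = state0, accepted = FALSE, n = n_current, delta = delta)
  }
}

#' One isobaric (log-volume) Monte Carlo move
#'
#' Proposes a uniform step in `ln V`, rescales positions affinely, and
#' accepts with
#' `min(1, exp(-beta*(dU + P dV + d_eta) + (N+1) dlnV))` (the `(N+1)` term is
#' the Jacobian of the log-volume proposal).
#'
#' @inheritParams hmc_move
#' @return list with the new `state`, `accepted`, `n`, and the volume
#' @export
volume_move <- function(state, engine, bias, cfg, op_fn = NULL,
                        n_current = NULL) {
  if (is.null(op_fn)) op_fn <- function(config) largest_cluster_size(config)
  beta <- thermo_beta(cfg$T)
  eta <- function(n) if (is.null(bias)) 0 else bias_potential(n, bias, cfg$T)
  if (is.null(n_current)) n_current <- op_fn(state$config)
  N <- n_particles(state$config)
  V0 <- prod(state$config$box)
  dlnv <- stats::runif(1, -cfg$max_dlnv, cfg$max_dlnv)
  sc <- exp(dlnv / 3)
  trial_cfg <- state$config
  trial_cfg$positions <- trial_cfg$positions * sc
  trial_cfg$box <- trial_cfg$box * sc
  ev <- tryCatch(engine$evaluate(trial_cfg), error = function(e) NULL)
  if (is.null(ev))
    return(list(state = state, accepted = FALSE, n = n_current, V = V0))
  n_trial <- tryCatch(op_fn(trial_cfg), error = function(e) NA_integer_)
  if (is.na(n_trial))
    return(list(state = state, accepted = FALSE, n = n_current, V = V0))
  dV <- V0 * (exp(dlnv) - 1)
  P_int <- cfg$P / .press_conv  # bar -> kcal/mol/A^3
  arg <- -beta * ((ev$U - state$U) + P_int * dV +
                    (eta(n_trial) - eta(n_current))) + (N + 1) * dlnv
  if (arg >= 0 || stats::runif(1) < exp(arg)) {
    st <- state
    st$config <- trial_cfg
    st$U <- ev$U; st$W <- ev$virial; st$forces <- ev$forces
    list(state = st, accepted = TRUE, n = n_trial, V = prod(trial_cfg$box))
  } else {
    list(state = state, accepted = FALSE, n = n_current, V = V0)
  }
}

#' Run a CNT-US (umbrella sampling) simulation
#'
#' Alternates hybrid Monte Carlo moves with probability-`vol_prob` isobaric
#' volume moves, recording the largest-cluster size after every move.
#'
#' @inheritParams hmc_move
#' @param n_moves number of HMC moves
#' @param seed optional integer seed
#' @param min_acceptance abort threshold: if the HMC acceptance over the
#'   trailing 500 moves falls below this, the run stops with a tuning
#'   diagnostic
#' @return object of class `biased_histogram`: `counts` (table over n),
#'   `movelog` (move index, type, n, accepted, U, V), acceptance fractions,
#'   the bias and settings
#' @export
run_cntus <- function(state, engine, bias, cfg, n_moves, op_fn = NULL,
                      seed = NULL, min_acceptance = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(op_fn)) op_fn <- function(config) largest_cluster_size(config)
  n_cur <- op_fn(state$config)
  log_type <- character(0); log_n <- integer(0); log_acc <- logical(0)
  log_U <- numeric(0); log_V <- numeric(0)
  acc_h <- acc_v <- att_v <- 0
  recent <- logical(0)
  for (m in seq_len(n_moves)) {
    mv <- hmc_move(state, engine, bias, cfg, op_fn, n_cur)
    state <- mv$state; n_cur <- mv$n
    acc_h <- acc_h + mv$accepted
    recent <- c(recent, mv$accepted)
    log_type <- c(log_type, "hmc"); log_n <- c(log_n, n_cur)
    log_acc <- c(log_acc, mv$accepted)
    log_U <- c(log_U, state$U); log_V <- c(log_V, prod(state$config$box))
    if (stats::runif(1) < cfg$vol_prob) {
      vm <- volume_move(state, engine, bias, cfg, op_fn, n_cur)
      state <- vm$state; n_cur <- vm$n
      att_v <- att_v + 1; acc_v <- acc_v + vm$accepted
      log_type <- c(log_type, "volume"); log_n <- c(log_n, n_cur)
      log_acc <- c(log_acc, vm$accepted)
      log_U <- c(log_U, state$U); log_V <- c(log_V, prod(state$config$box))
    }
    if (length(recent) >= 500) {
      if (mean(recent) < min_acceptance)
        stop(sprintf(
          "HMC acceptance %.3f below %.3f over the last 500 moves; ",
          mean(recent), min_acceptance),
          "reduce the segment length or time step")
      recent <- logical(0)
    }
  }
  counts <- table(factor(log_n, levels = 0:max(log_n)))
  structure(list(counts = counts,
                 movelog = data.frame(move = seq_along(log_type),
                                      type = log_type, n = log_n,
                                      accepted = log_acc, U = log_U,
                                      V = log_V),
                 acceptance_hmc = acc_h / n_moves,
                 acceptance_volume = if (att_v > 0) acc_v / att_v else NA,
                 bias = bias, cfg = cfg, state = state),
            class = "biased_histogram")
}

#' Reconstruct the free-energy profile from a biased histogram
#'
#' Removes the bias from the sampled distribution of the largest-cluster
#' size: `beta*dG(n) = -ln P_biased(n) - beta*eta(n) + const`, with the
#' constant chosen so the minimum is zero. Empty interior bins up to
#' `max_gap` wide are linearly interpolated and flagged; wider gaps mean the
#' sampling never bridged the landscape and raise an error.
#'
#' @param hist a `biased_histogram`, a named count vector/table (names = n),
#'   or an integer vector of sampled n values
#' @param bias the [bias_spec()] used during sampling (`NULL` for unbiased)
#' @param T temperature, K
#' @param max_gap widest run of empty interior bins to interpolate
#' @return data.frame of class `free_energy_profile` with columns `n`,
#'   `betaG`, `interpolated`; attributes `barrier` (height) and `n_c`
#'   (argmax)
#' @export
reconstruct_barrier <- function(hist, bias, T, max_gap = 5) {
  if (inherits(hist, "biased_histogram")) {
    counts <- as.numeric(hist$counts)
    nval <- as.integer(names(hist$counts))
  } else if (!is.null(names(hist))) {
    counts <- as.numeric(hist)
    nval <- as.integer(names(hist))
  } else {
    tb <- table(hist)
    counts <- as.numeric(tb)
    nval <- as.integer(names(tb))
    full <- seq(min(nval), max(nval))
    cc <- numeric(length(full)); cc[match(nval, full)] <- counts
    counts <- cc; nval <- full
  }
  if (sum(counts > 0) < 2) stop("histogram needs at least 2 nonzero bins")
  occ <- which(counts > 0)
  gaps <- diff(occ) - 1
  if (any(gaps > max_gap))
    stop("disconnected histogram support (empty run of ", max(gaps),
         " bins): the landscape was not bridged")
  n <- nval
  beta_eta <- if (is.null(bias)) rep(0, length(n)) else
    bias_potential(n, bias, T) * thermo_beta(T)
  betaG <- rep(NA_real_, length(n))
  betaG[occ] <- -log(counts[occ] / sum(counts)) - beta_eta[occ]
  interp <- is.na(betaG) & seq_along(n) > min(occ) & seq_along(n) < max(occ)
  if (any(interp))
    betaG[interp] <- stats::approx(n[occ], betaG[occ], xout = n[interp])$y
  keep <- !is.na(betaG)
  out <- data.frame(n = n[keep], betaG = betaG[keep] - min(betaG[keep]),
                    interpolated = interp[keep])
  class(out) <- c("free_energy_profile", "data.frame")
  attr(out, "barrier") <- max(out$betaG[out$n >= 1])
  attr(out, "n_c") <- out$n[which.max(out$betaG)]
  out
}
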