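#' Radial distribution function
#'
#' Standard pair-histogram g(r): per frame, pair distances under minimum image
#' are binned and normalised by the ideal-gas shell count
#' `4/3 pi (r2^3 - r1^3) * N/V` per particle, then averaged over frames.
#'
#' @param traj a trajectory: either an `md_trajectory` (from the integrators),
#'   a list of [configuration()]s, or a single configuration
#' @param r_max histogram range, Angstrom; must not exceed half the smallest
#'   box edge
#' @param n_bins number of bins
#' @return data.frame of class `rdf` with columns `r` (bin centres) and `g`
#' @export
compute_rdf <- function(traj, r_max, n_bins = 200) {
  frames <- .as_frames(traj)
  if (length(frames$pos) < 1) stop("at least one frame required")
  for (b in frames$box) {
    if (r_max > min(b) / 2) stop("r_max exceeds half the smallest box edge")
  }
  g <- numeric(n_bins)
  edges <- seq(0, r_max, length.out = n_bins + 1)
  shell <- 4 / 3 * pi * diff(edges^3)
  for (f in seq_along(frames$pos)) {
    pos <- frames$pos[[f]]
    N <- nrow(pos)
    V <- prod(frames$box[[f]])
    h <- rdf_count_cpp(pos, frames$box[[f]], r_max, n_bins)
    g <- g + h / (shell * N * (N / V))
  }
  out <- data.frame(r = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    g = g / length(frames$pos))
  class(out) <- c("rdf", "data.frame")
  out
}

.as_frames <- function(traj) {
  if (inherits(traj, "md_trajectory")) {
    boxes <- lapply(seq_len(nrow(traj$boxes)), function(i) traj$boxes[i, ])
    list(pos = traj$frames, box = boxes, times = traj$times)
  } else if (inherits(traj, "configuration")) {
    list(pos = list(traj$positions), box = list(traj$box), times = 0)
  } else if (is.list(traj) && all(vapply(traj, inherits, TRUE, "configuration"))) {
    list(pos = lapply(traj, `[[`, "positions"),
         box = lapply(traj, `[[`, "box"),
         times = seq_along(traj) - 1)
  } else stop("unsupported trajectory type")
}

#' Time-origin-averaged mean-square displacement
#'
#' Requires unwrapped coordinates (the integrators keep positions unwrapped;
#' wrapped input is rejected by a jump heuristic: consecutive-frame particle
#' displacements of more than half a box edge indicate wrapping).
#'
#' @param traj an `md_trajectory` with frames at a constant stride
#' @param max_lag_frac largest lag as a fraction of the trajectory length
#' @param n_lags number of lag times to evaluate
#' @param remove_com subtract the per-frame centre-of-mass displacement
#'   before computing displacements (default); without this, any residual
#'   net momentum (e.g. left over from a stochastic thermostat) adds a
#'   spurious `(v_com t)^2` term that can dominate the self-diffusion signal
#' @return data.frame of class `msd_series` with columns `lag` (ps) and `msd`
#'   (Angstrom^2), starting at lag 0
#' @export
compute_msd <- function(traj, max_lag_frac = 0.5, n_lags = 120,
                        remove_com = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- length(traj$frames)
  if (nf < 3) stop("too few frames")
  N <- nrow(traj$frames[[1]])
  arr <- array(unlist(traj$frames), dim = c(N, 3, nf))
  if (remove_com) {
    for (f in seq_len(nf)) {
      com <- colMeans(arr[, , f])
      arr[, , f] <- sweep(arr[, , f], 2, com, "-")
    }
  }
  db <- arr[, , 2:min(nf, 20), drop = FALSE] -
    arr[, , 1:(min(nf, 20) - 1), drop = FALSE]
  if (max(abs(db)) > min(traj$boxes[1, ]) / 2)
    stop("wrapped trajectory detected: MSD requires unwrapped coordinates")
  max_lag <- max(2, floor(nf * max_lag_frac))
  lags <- unique(round(seq(1, max_lag, length.out = min(n_lags, max_lag))))
  dt_frame <- traj$times[2] - traj$times[1]
  msd <- vapply(lags, function(l) {
    d <- arr[, , (1 + l):nf, drop = FALSE] - arr[, , 1:(nf - l), drop = FALSE]
    mean(colSums(aperm(d^2, c(2, 1, 3))))  # mean over particles & origins of |dr|^2
  }, numeric(1))
  out <- data.frame(lag = c(0, lags * dt_frame), msd = c(0, msd))
  class(out) <- c("msd_series", "data.frame")
  out
}

#' Diffusion coefficient from the MSD slope
#'
#' Least-squares fit of `<dr^2> = 6 D t` on a lag window.
#'
#' @param msd an `msd_series` from [compute_msd()]
#' @param window length-2 lag window in ps; defaults to the second half of the
#'   available lags (the diffusive regime for the runs this package performs)
#' @return list with `D` (Angstrom^2/ns), `window`, and the fitted intercept
#' @export
fit_diffusion <- function(msd, window = NULL) {
  if (is.null(window)) window <- c(max(msd$lag) / 4, max(msd$lag))
  sel <- msd$lag >= window[1] & msd$lag <= window[2]
  if (sum(sel) < 2) stop("fit window contains fewer than 2 points")
  fit <- stats::lm(msd ~ lag, data = msd[sel, ])
  D_ps <- unname(stats::coef(fit)[2]) / 6   # A^2/ps
  list(D = D_ps * 1e3, window = window,
       intercept = unname(stats::coef(fit)[1]))
}

#' Self-diffusion coefficient of the mW liquid at a state point
#'
#' The full measurement protocol in one call: equilibrate a liquid at the
#' requested temperature, find the ambient-pressure density with the
#' barostat, fix the box at that density, thermalise, remove the net
#' momentum, calibrate the total energy so the microcanonical mean kinetic
#' temperature matches the target, run energy-conserving production
#' dynamics, and fit the time-origin-averaged MSD as `<dr^2> = 6 D t`.
#'
#' @param T temperature, K
#' @param N particle count
#' @param seed integer seed controlling every stochastic step
#' @param P pressure, bar
#' @param npt_ps,nvt_ps,production_ps stage lengths, ps
#' @param dt time step, fs
#' @param fit_window lag window (ps) for the diffusive-regime fit
#' @param params an [mw_params()]
#' @return list with `D` (Angstrom^2/ns), the production mean temperature
#'   `T_mean`, the ambient density `rho` (g/cm^3), and the `msd` series
#' @export
measure_diffusion <- function(T = 218, N = 216, seed = 1, P = 1.01325,
                              npt_ps = 60, nvt_ps = 100,
                              production_ps = 200, dt = 4,
                              fit_window = c(20, 100),
                              params = mw_params()) {
  liq <- generate_liquid(N, 0.99, T, params, seed = seed)
  st <- md_state(liq, mw_engine(params))
  st <- integrate_npt(st, round(npt_ps * 1e3 / dt), dt, T = T, P = P,
                      damping = 1, seed = seed + 1,
                      sample_every = 50)
  V <- st$trajectory$series$V
  rho <- mean(N * params$mass /
                (.N_A * tail(V, length(V) %/% 2) * 1e-24))
  L <- box_edge_for_density(N, rho, params$mass)
  sc <- L / st$config$box[1]
  cfg <- st$config
  cfg$positions <- cfg$positions * sc
  cfg$box <- cfg$box * sc
  st <- md_state(cfg, mw_engine(params))
  st <- integrate_nvt(st, round(nvt_ps * 1e3 / dt), dt, T = T, damping = 1,
                      engine = mw_engine(params), seed = seed + 2)
  st$config <- zero_momentum(st$config)
  st <- md_state(st$config, mw_engine(params))
  ## iterate velocity rescaling so the NVE mean kinetic T hits the target
  ## (a single rescale relaxes about half the adjustment back into potential
  ## energy, so several damped iterations are needed)
  for (it in 1:7) {
    probe <- integrate_nve(st, 2500, dt, sample_every = 25)
    Tm <- mean(probe$trajectory$series$T_inst)
    st <- probe
    if (abs(Tm - T) / T < 0.005) break
    st$config$velocities <- st$config$velocities * (T / Tm)
    st <- md_state(st$config, mw_engine(params))
  }
  st <- integrate_nve(st, round(production_ps * 1e3 / dt), dt,
                      sample_every = 100)
  msd <- compute_msd(st$trajectory)
  fit <- fit_diffusion(msd, fit_window)
  list(D = fit$D, T_mean = mean(st$trajectory$series$T_inst), rho = rho,
       msd = msd, fit = fit)
}
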