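#' Largest-cluster time series of a trajectory
#'
#' Applies the Q12 classification and cluster decomposition frame by frame,
#' stopping at a termination criterion (by default once the largest cluster
#' comprises half the system, the point at which production nucleation runs
#' are interrupted).
#'
#' @param traj an `md_trajectory` or list of configurations
#' @param op an [op_config()]
#' @param stop_frac termination threshold as a fraction of N (set above 1 to
#'   disable)
#' @return data.frame with columns `time` (ps) and `n`
#' @export
n_series <- function(traj, op = op_config(), stop_frac = 0.5) {
  fr <- .as_frames(traj)
  times <- n <- numeric(0)
  for (i in seq_along(fr$pos)) {
    cfg <- configuration(fr$pos[[i]], fr$box[[i]])
    ni <- largest_cluster_size(cfg, op)
    times <- c(times, fr$times[i]); n <- c(n, ni)
    if (ni >= stop_frac * n_particles(cfg)) break
  }
  data.frame(time = times, n = as.integer(n))
}

#' Mean first passage time over a trajectory ensemble
#'
#' For each threshold `n`, the first passage time of one trajectory is the
#' earliest time its series reaches `>= n`; `tau(n)` is the mean over the
#' trajectories that reach `n`. Trajectories that never reach a threshold are
#' excluded there and counted as censored.
#'
#' @param series_list list (>= 2) of data.frames with columns `time` and `n`
#' @param thresholds integer thresholds; default `1..max(n)` observed
#' @return data.frame of class `fpt_curve`: `n`, `tau` (mean first passage
#'   time, same units as `time`), `n_reached`, `n_censored`, `tau_se`
#' @export
first_passage <- function(series_list, thresholds = NULL) {
  stopifnot(is.list(series_list), length(series_list) >= 2)
  if (is.null(thresholds))
    thresholds <- seq_len(max(vapply(series_list, function(s) max(s$n), 1)))
  fpt <- vapply(series_list, function(s) {
    vapply(thresholds, function(th) {
      idx <- which(s$n >= th)
      if (length(idx) == 0) NA_real_ else min(s$time[idx])
    }, numeric(1))
  }, numeric(length(thresholds)))
  fpt <- matrix(fpt, nrow = length(thresholds))
  tau <- rowMeans(fpt, na.rm = TRUE)
  cnt <- rowSums(!is.na(fpt))
  se <- apply(fpt, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  })
  out <- data.frame(n = thresholds, tau = tau, n_reached = cnt,
                    n_censored = length(series_list) - cnt, tau_se = se)
  out <- out[cnt > 0, ]
  class(out) <- c("fpt_curve", "data.frame")
  out
}

#' Theoretical mean-first-passage-time curve
#'
#' The sigmoidal Wedekind-Reguera form
#' `tau(n) = 1/(2 J V) * (1 + erf(c (n - n_c)))`, whose plateau is `1/(J V)`,
#' whose inflection sits at the critical size `n_c`, and whose steepness `c`
#' is proportional to the square root of the barrier curvature at the top.
#'
#' @param n cluster-size threshold(s)
#' @param J nucleation rate (1/(time * volume))
#' @param V system volume
#' @param n_c critical nucleus size
#' @param c curvature parameter
#' @return tau in the time units implied by `J`
#' @export
mfpt_model <- function(n, J, V, n_c, c) {
  stopifnot(J > 0, V > 0, c > 0)
  1 / (2 * J * V) * (1 + erf(c * (n - n_c)))
}

#' Error function
#' @param x numeric
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Fit the MFPT curve for rate, critical size and curvature
#'
#' Nonlinear least squares of [mfpt_model()] to an empirical
#' [first_passage()] curve restricted to `n < fit_max_n`. Weights are
#' uniform by default: the sigmoid is an asymptotic (high-barrier) form
#' whose small residual misspecification sits at small `n`, exactly where
#' inverse-variance weights would concentrate, which biases the plateau and
#' hence the rate. Inverse across-trajectory variances remain available via
#' `weighting = "invvar"` (ignored when fewer than 5 trajectories
#' contribute). Initial guesses: `n_c` at the steepest point of `tau(n)`,
#' the plateau from the top decile of `tau`, and `c = 0.05`; on
#' non-convergence two further starts perturb the guesses.
#'
#' @param curve an `fpt_curve`
#' @param V system volume (Angstrom^3) entering the plateau `1/(J V)`
#' @param fit_max_n restrict the fit to thresholds below this size
#' @param weighting `"uniform"` (default) or `"invvar"`
#' @return object of class `mfpt_fit`: `J`, `n_c`, `c`, `V`, `tau_max`
#'   (fitted plateau), the covariance of `(tau_max/2, n_c, c)`, and the fit
#'   input
#' @export
fit_mfpt <- function(curve, V, fit_max_n = 100,
                     weighting = c("uniform", "invvar")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(curve, "data.frame"), V > 0)
  d <- curve[curve$n < fit_max_n & is.finite(curve$tau), ]
  if (nrow(d) < 4) stop("need at least 4 usable points below fit_max_n")
  viol <- diff(d$tau) < -3 * stats::median(d$tau_se, na.rm = TRUE)
  if (any(viol, na.rm = TRUE) && mean(viol, na.rm = TRUE) > 0.2)
    stop("tau(n) decreases well beyond noise level; not a first-passage curve")
  w <- rep(1, nrow(d))
  if (weighting == "invvar" && !is.null(d$tau_se) &&
      all(is.finite(d$tau_se)) && !is.null(d$n_reached) &&
      min(d$n_reached) >= 5)
    w <- 1 / pmax(d$tau_se, max(d$tau_se) * 1e-3)^2

  slope <- diff(d$tau) / diff(d$n)
  nc0 <- d$n[which.max(c(slope, 0))]
  A0 <- mean(stats::quantile(d$tau, probs = seq(0.9, 1, 0.05))) / 2
  starts <- list(c(A = A0, n_c = nc0, cc = 0.05),
                 c(A = max(d$tau) / 2, n_c = stats::median(d$n), cc = 0.02),
                 c(A = max(d$tau), n_c = nc0 * 1.5 + 1, cc = 0.1))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        tau ~ A * (1 + erf(cc * (n - n_c))), data = d, weights = w,
        start = as.list(st),
        lower = c(A = 0, n_c = 0, cc = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("fit_mfpt failed to converge from all starts; last data shown",
         call. = FALSE)
  p <- stats::coef(fit)
  structure(list(J = 1 / (2 * p[["A"]] * V), n_c = p[["n_c"]], c = p[["cc"]],
                 V = V, tau_max = 2 * p[["A"]],
                 cov = tryCatch(stats::vcov(fit), error = function(e) NULL),
                 fit_max_n = fit_max_n, curve = d, nls = fit),
            class = "mfpt_fit")
}

#' @export
print.mfpt_fit <- function(x, ...) {
  cat(sprintf("MFPT fit: J = %.3g / (ns A^3), n_c = %.1f, c = %.3g (V = %.0f A^3)\n",
              x$J, x$n_c, x$c, x$V))
  invisible(x)
}
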