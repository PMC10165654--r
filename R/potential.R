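#' mW pair interaction energy
#'
#' Stillinger-Weber two-body term
#' `A*eps*(B*(sigma/r)^p - (sigma/r)^q) * exp(sigma/(r - a*sigma))` for
#' for distances below `a*sigma`, identically zero at and beyond the cutoff;
#' the exponential
#' factor makes the term and all its derivatives vanish smoothly at the
#' cutoff.
#'
#' @param r pair distance(s), Angstrom, > 0
#' @param params an [mw_params()] object
#' @return energy in kcal/mol (vectorised over `r`)
#' @export
mw_pair_energy <- function(r, params = mw_params()) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("pair distance must be positive")
  rc <- params$cutoff
  out <- numeric(length(r))
  ok <- r < rc
  if (any(ok)) {
    sr <- params$sigma / r[ok]
    out[ok] <- params$A * params$epsilon *
      (params$B * sr^params$p - sr^params$q) *
      exp(params$sigma / (r[ok] - rc))
  }
  out
}

#' mW three-body interaction energy of one triplet
#'
#' `lam*eps*(cos_theta - cos_theta0)^2 * exp(gamma*sigma/(r_ij - a*sigma)) *
#' exp(gamma*sigma/(r_ik - a*sigma))`, with the angle at the central particle.
#' Returns 0 when either arm reaches the cutoff.
#'
#' @param r_ij,r_ik arm distances, Angstrom
#' @param cos_theta cosine of the angle subtended at the central particle
#' @param params an [mw_params()] object
#' @return energy in kcal/mol
#' @export
mw_triplet_energy <- function(r_ij, r_ik, cos_theta, params = mw_params()) {
  stopifnot(r_ij > 0, r_ik > 0, abs(cos_theta) <= 1 + 1e-12)
  rc <- params$cutoff
  if (r_ij >= rc || r_ik >= rc) return(0)
  params$lam * params$epsilon * (cos_theta - params$cos_theta0)^2 *
    exp(params$gamma * params$sigma / (r_ij - rc)) *
    exp(params$gamma * params$sigma / (r_ik - rc))
}

#' Evaluate the mW potential on a configuration
#'
#' Total potential energy, analytic forces `-grad U`, and the interaction
#' virial `W = sum r_ij . f_ij` (so that the pressure is
#' `(N kB T + W/3)/V`), all under the minimum-image convention.
#'
#' @param config a [configuration()]
#' @param params an [mw_params()] object
#' @return list with `U` (kcal/mol), `forces` (`N x 3`, kcal/mol/A) and
#'   `virial` (kcal/mol)
#' @export
mw_evaluate <- function(config, params = mw_params()) {
  .check_box_cutoff(config, params$cutoff)
  sw_eval_cpp(config$positions, config$box, params)
}

#' Potential engines
#'
#' An engine bundles an `evaluate(config) -> list(U, forces, virial)` closure
#' with the metadata the integrators and samplers need (cutoff, particle
#' mass). `mw_engine()` wraps the analytic mW potential; [nnp_engine()] wraps
#' a neural-network potential; `custom_engine()` adapts any energy/force
#' function (used for toy systems in validation).
#'
#' @param params an [mw_params()] object
#' @return an object of class `engine`
#' @export
mw_engine <- function(params = mw_params()) {
  structure(list(evaluate = function(config) mw_evaluate(config, params),
                 cutoff = params$cutoff, mass = params$mass,
                 kind = "mw", params = params),
            class = "engine")
}

#' @rdname mw_engine
#' @param evaluate function of a configuration returning
#'   `list(U, forces, virial)`
#' @param cutoff interaction cutoff, Angstrom
#' @param mass particle mass, g/mol
#' @export
custom_engine <- function(evaluate, cutoff = 0, mass = mw_params()$mass) {
  structure(list(evaluate = evaluate, cutoff = cutoff, mass = mass,
                 kind = "custom"),
            class = "engine")
}

#' Verlet neighbour list
#'
#' Symmetric neighbour list containing every pair with minimum-image distance
#' below `cutoff + skin`.
#'
#' @param config a [configuration()]
#' @param cutoff base cutoff, Angstrom; `cutoff + skin` must not exceed half
#'   the smallest box edge
#' @param skin extra margin, Angstrom
#' @return list of integer vectors, `[[i]]` holding the neighbours of `i`
#' @export
neighbor_list <- function(config, cutoff, skin = 0) {
  stopifnot(cutoff > 0, skin >= 0)
  if (cutoff + skin > min(config$box) / 2)
    stop("cutoff too large for box: cutoff + skin must be <= min(box)/2")
  neighbor_list_cpp(config$positions, config$box, cutoff + skin)
}
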