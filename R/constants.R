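#' Physical constants and unit conversions
#'
#' The package works throughout in kcal/mol (energy), Angstrom (length),
#' fs (time), K (temperature), bar (pressure) and g/mol (mass).
#'
#' @name units
NULL

#' Boltzmann constant in kcal mol^-1 K^-1
#' @export
kB <- 0.0019872041

## F[kcal/mol/A] / m[g/mol] * .acc_conv = a[A/fs^2]
.acc_conv <- 4.184e-4
## K[kcal/mol] = 0.5 * m[g/mol] * v^2[A^2/fs^2] * .mvv2e
.mvv2e <- 1 / .acc_conv
## kcal/mol/A^3 -> bar
.press_conv <- 69476.95457
## Avogadro constant, mol^-1
.N_A <- 6.02214076e23

#' Parameters of the mW coarse-grained water potential
#'
#' Returns the Stillinger-Weber-form parameter set of the mW monatomic water
#' model: a single site per molecule, a short-ranged pair term and a
#' three-body term that penalises deviations from the tetrahedral angle
#' (`cos_theta0 = -1/3`). Constants are the published reference values of the
#' mW model; the strong tetrahedral coupling `lam = 23.15` is what
#' distinguishes mW from silicon-like Stillinger-Weber parameterisations.
#'
#' @param epsilon energy scale, kcal/mol
#' @param sigma length scale, Angstrom
#' @param A,B dimensionless pair coefficients
#' @param p,q pair exponents
#' @param a dimensionless cutoff multiplier; the interaction cutoff is
#'   `a * sigma`
#' @param gamma dimensionless three-body decay
#' @param lam dimensionless three-body strength
#' @param cos_theta0 ideal bond-angle cosine
#' @param mass particle mass, g/mol (one mW site represents a whole water
#'   molecule)
#' @return a list of class `mw_params` with an additional `cutoff` entry
#' @export
mw_params <- function(epsilon = 6.189, sigma = 2.3925,
                      A = 7.049556277, B = 0.6022245584,
                      p = 4, q = 0, a = 1.8, gamma = 1.2, lam = 23.15,
                      cos_theta0 = -1 / 3, mass = 18.015) {
  stopifnot(epsilon > 0, sigma > 0, a > 1, mass > 0)
  out <- list(epsilon = epsilon, sigma = sigma, A = A, B = B, p = p, q = q,
              a = a, gamma = gamma, lam = lam, cos_theta0 = cos_theta0,
              mass = mass, cutoff = a * sigma)
  class(out) <- "mw_params"
  out
}

#' Convert a reduced mW temperature to Kelvin
#'
#' Temperatures in mW internal units are measured in units of the energy scale
#' `epsilon`, so `T = t_star * epsilon / kB`.
#'
#' @param t_star reduced temperature (dimensionless, >= 0)
#' @param params an [mw_params()] object
#' @return temperature in K
#' @examples
#' reduced_to_kelvin(0.07)  # 218 K
#' @export
reduced_to_kelvin <- function(t_star, params = mw_params()) {
  stopifnot(all(t_star >= 0))
  t_star * params$epsilon / kB
}

#' Inverse thermal energy beta = 1/(kB T)
#' @param T temperature in K
#' @return beta in mol/kcal
#' @export
thermo_beta <- function(T) {
  stopifnot(T > 0)
  1 / (kB * T)
}
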