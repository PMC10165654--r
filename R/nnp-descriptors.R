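#' Atomic fingerprint set
#'
#' The descriptor basis of the neural-network potential: 5 two-body radial
#' fingerprints `G2(i) = sum_j exp(-(r_ij - R_s)^2/w^2) f_c(r_ij)` with
#' trainable centre `R_s`, width `w` and smooth cosine cutoff `r_c`, and 5
#' three-body angular fingerprints
#' `G3(i) = sum_{j<k} 2^(1-zeta) (1 + lambda cos(theta_jik))^zeta
#' exp(-(r_ij^2 + r_ik^2)/w3^2) f_c(r_ij) f_c(r_ik)` with trainable angular
#' sharpness `zeta`, angular offset `lambda` and radial decay `w3`. All
#' fingerprints are smooth in the positions and vanish beyond their cutoff.
#'
#' @param two_body 5 x 3 matrix with columns `Rs`, `w`, `rc` (Angstrom)
#' @param three_body 5 x 4 matrix with columns `zeta`, `lambda`, `w3`, `rc`
#'   (the three-body cutoff is held fixed)
#' @return object of class `af_set`
#' @export
af_set <- function(two_body = NULL, three_body = NULL) {
  if (is.null(two_body)) {
    two_body <- cbind(Rs = seq(2.35, 4.2, length.out = 5),
                      w = rep(0.6, 5), rc = rep(4.5, 5))
  }
  if (is.null(three_body)) {
    three_body <- cbind(zeta = c(1, 2, 4, 8, 16),
                        lambda = c(1, -1, 1, -1, 1) * 0.8,
                        w3 = rep(3.0, 5), rc = rep(4.0, 5))
  }
  two_body <- as.matrix(two_body); three_body <- as.matrix(three_body)
  stopifnot(nrow(two_body) == 5, ncol(two_body) == 3,
            nrow(three_body) == 5, ncol(three_body) == 4)
  colnames(two_body) <- c("Rs", "w", "rc")
  colnames(three_body) <- c("zeta", "lambda", "w3", "rc")
  structure(list(two_body = two_body, three_body = three_body),
            class = "af_set")
}

.af_max_cutoff <- function(af) max(af$two_body[, "rc"], af$three_body[, "rc"])

## flatten the 30 trainable parameters (two-body Rs,w,rc; three-body
## zeta,lambda,w3) into a vector and back, with box constraints
.af_to_vec <- function(af) {
  c(af$two_body[, 1:3], af$three_body[, 1:3])
}
.vec_to_af <- function(v, af) {
  af$two_body[, 1:3] <- matrix(v[1:15], 5, 3)
  af$three_body[, 1:3] <- matrix(v[16:30], 5, 3)
  ## projection onto the feasible box
  af$two_body[, "w"] <- pmax(af$two_body[, "w"], 0.1)
  af$two_body[, "rc"] <- pmin(pmax(af$two_body[, "rc"], 2.5), 6.0)
  af$two_body[, "Rs"] <- pmax(af$two_body[, "Rs"], 0.5)
  af$three_body[, "zeta"] <- pmax(af$three_body[, "zeta"], 1)
  af$three_body[, "lambda"] <- pmin(pmax(af$three_body[, "lambda"], -0.95),
                                    0.95)
  af$three_body[, "w3"] <- pmax(af$three_body[, "w3"], 0.3)
  af
}

#' Compute atomic fingerprints of a configuration
#'
#' @param config a [configuration()]
#' @param af an [af_set()]
#' @return `N x 10` matrix (5 two-body columns, then 5 three-body columns);
#'   rows of isolated particles are zero
#' @export
compute_afs <- function(config, af = af_set()) {
  afs_cpp(config$positions, config$box, af$two_body, af$three_body)
}

#' Dense Jacobian of the fingerprints (small systems)
#'
#' `d G[i,k] / d x[a, alpha]` as an `N x 10 x N x 3` array; intended for
#' gradient verification, memory grows as `N^2`.
#'
#' @inheritParams compute_afs
#' @export
compute_afs_jacobian <- function(config, af = af_set()) {
  afs_jacobian_cpp(config$positions, config$box, af$two_body,
                   af$three_body)$J
}
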