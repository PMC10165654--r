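#' Particle configuration in a periodic orthorhombic box
#'
#' The basic container for a snapshot: `N x 3` positions (Angstrom), an
#' orthorhombic box given by its three edge lengths (Angstrom), optional
#' `N x 3` velocities (Angstrom/fs), and an attached state point.
#'
#' @param positions numeric `N x 3` matrix, Angstrom
#' @param box numeric length-3 vector of edge lengths, Angstrom
#' @param velocities optional numeric `N x 3` matrix, Angstrom/fs
#' @param temperature state-point temperature, K (optional)
#' @param pressure state-point pressure, bar (optional)
#' @return an object of class `configuration`
#' @export
configuration <- function(positions, box, velocities = NULL,
                          temperature = NA_real_, pressure = NA_real_) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive edge lengths")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    storage.mode(velocities) <- "double"
    if (!all(dim(velocities) == dim(positions)))
      stop("velocities must match positions in shape")
  }
  structure(list(positions = positions, box = box, velocities = velocities,
                 temperature = temperature, pressure = pressure),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: N = %d, box = [%.3f %.3f %.3f] A", nrow(x$positions),
              x$box[1], x$box[2], x$box[3]))
  if (is.finite(x$temperature)) cat(sprintf(", T = %.1f K", x$temperature))
  cat(sprintf(", rho = %.4f g/cm^3\n", config_density(x)))
  invisible(x)
}

#' Number of particles in a configuration
#' @param config a [configuration()]
#' @export
n_particles <- function(config) nrow(config$positions)

#' Mass density of a configuration in g/cm^3
#' @param config a [configuration()]
#' @param mass particle mass in g/mol
#' @export
config_density <- function(config, mass = mw_params()$mass) {
  V_cm3 <- prod(config$box) * 1e-24
  n_particles(config) * mass / (.N_A * V_cm3)
}

#' Box edge length of a cubic box holding N particles at a target density
#' @param N particle count
#' @param rho density, g/cm^3
#' @param mass particle mass, g/mol
#' @return edge length in Angstrom
#' @export
box_edge_for_density <- function(N, rho, mass = mw_params()$mass) {
  (N * mass / (.N_A * rho) * 1e24)^(1 / 3)
}

#' Wrap positions into the primary periodic cell
#' @param config a [configuration()]
#' @return the configuration with positions wrapped into `[0, box)`
#' @export
wrap_positions <- function(config) {
  p <- config$positions
  for (k in 1:3) p[, k] <- p[, k] %% config$box[k]
  config$positions <- p
  config
}

#' Replicate a periodic configuration
#'
#' Tiles the cell `reps[k]` times along each axis; velocities (if present)
#' are copied unchanged. Used for extensivity checks.
#'
#' @param config a [configuration()]
#' @param reps integer length-3 replication counts
#' @export
replicate_config <- function(config, reps = c(2, 2, 2)) {
  reps <- as.integer(reps)
  stopifnot(length(reps) == 3, all(reps >= 1))
  shifts <- as.matrix(expand.grid(x = seq_len(reps[1]) - 1,
                                  y = seq_len(reps[2]) - 1,
                                  z = seq_len(reps[3]) - 1))
  pos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
    sweep(config$positions, 2, shifts[s, ] * config$box, "+")
  }))
  vel <- if (is.null(config$velocities)) NULL else
    do.call(rbind, rep(list(config$velocities), nrow(shifts)))
  configuration(pos, config$box * reps, vel,
                temperature = config$temperature, pressure = config$pressure)
}

.check_box_cutoff <- function(config, cutoff) {
  if (any(config$box < 2 * cutoff))
    stop(sprintf(
      "configuration error: box edge %.3f A below twice the cutoff %.3f A",
      min(config$box), cutoff))
  invisible(TRUE)
}
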