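#' Order-parameter configuration
#'
#' The thresholds of the Q12 crystallinity classification, kept in one object
#' so that biased sampling and post-hoc analysis can never disagree.
#'
#' @param cutoff neighbour cutoff, Angstrom. The default 4.5 A spans the
#'   first shell and part of the second (~12 neighbours): averaging the
#'   rank-12 harmonics over only the 4 first-shell bonds (first g(r) minimum
#'   at 3.51 A) is so noise-sensitive that thermally fluctuating ice is
#'   indistinguishable from liquid, while at 4.5 A the two d12 distributions
#'   separate almost completely
#' @param d_c bond-coherence threshold on `d12`; 0.5 is the classic
#'   connected-neighbour threshold and sits far above the liquid d12
#'   distribution at this cutoff
#' @param xi_c minimum number of coherent bonds for a crystalline label
#' @export
op_config <- function(cutoff = 4.5, d_c = 0.5, xi_c = 4) {
  stopifnot(cutoff > 0, d_c > -1, xi_c >= 1)
  structure(list(cutoff = cutoff, d_c = d_c, xi_c = as.integer(xi_c)),
            class = "op_config")
}

#' Per-particle Q12 bond-orientational vectors
#'
#' For every particle, `q_{12,m}(i)` is the average of the rank-12 spherical
#' harmonics `Y_{12,m}` over the bonds to its neighbours within the cutoff.
#' Components for `m = 0..12` are returned (negative `m` follow from
#' conjugation symmetry).
#'
#' @param config a [configuration()]
#' @param cutoff neighbour cutoff, Angstrom
#' @return list with complex matrix `q` (`N x 13`), `qnorm` (the full-vector
#'   norm including negative m), `nneigh`, and the neighbour list
#' @export
q12_vectors <- function(config, cutoff = op_config()$cutoff) {
  res <- qlm_cpp(config$positions, config$box, cutoff)
  q <- matrix(complex(real = res$qre, imaginary = res$qim),
              nrow = nrow(res$qre))
  qnorm <- sqrt(res$qre[, 1]^2 +
                  2 * rowSums(res$qre[, -1, drop = FALSE]^2 +
                                res$qim[, -1, drop = FALSE]^2))
  list(q = q, qre = res$qre, qim = res$qim, qnorm = qnorm,
       nneigh = res$nneigh, neighbors = res$neighbors)
}

#' Classify particles as crystalline or liquid
#'
#' A bond (i, j) is coherent when the normalised inner product
#' `d12(i,j) = Re<q_hat(i), q_hat(j)>` exceeds `d_c`; a particle is
#' crystalline when it has at least `xi_c` coherent bonds. Particles without
#' neighbours are labelled liquid.
#'
#' @param config a [configuration()]
#' @param op an [op_config()]
#' @return object of class `op_result`: logical `crystalline`, integer
#'   `n_coherent`, per-bond `d12` values, the neighbour list, and the
#'   thresholds used
#' @export
classify_crystalline <- function(config, op = op_config()) {
  qv <- q12_vectors(config, op$cutoff)
  cl <- d12_classify_cpp(qv$qre, qv$qim, qv$neighbors, op$d_c, op$xi_c)
  structure(list(crystalline = as.logical(cl$crystalline),
                 n_coherent = cl$n_coherent, d12 = cl$d12,
                 qnorm = cl$qnorm, q = qv$q, nneigh = qv$nneigh,
                 neighbors = qv$neighbors, op = op),
            class = "op_result")
}

#' Largest crystalline cluster
#'
#' Connected components of crystalline-labelled particles over the neighbour
#' graph; `n` is the size of the largest component (0 for a fully liquid
#' frame).
#'
#' @param result an `op_result` from [classify_crystalline()]
#' @return object of class `cluster_result`: integer `n`, `membership`
#'   (component id per particle, 0 = liquid), and the id of the largest
#'   cluster
#' @export
largest_cluster <- function(result) {
  comp <- cluster_components_cpp(result$crystalline, result$neighbors)
  n <- 0L; top <- 0L
  if (any(comp > 0)) {
    tab <- tabulate(comp)
    n <- max(tab)
    top <- which.max(tab)
  }
  structure(list(n = as.integer(n), membership = comp,
                 largest_id = as.integer(top)),
            class = "cluster_result")
}

#' Size of the largest crystalline cluster of a configuration
#'
#' Convenience composition of [classify_crystalline()] and
#' [largest_cluster()]; this is the nucleation order parameter `n`.
#'
#' @inheritParams classify_crystalline
#' @return integer cluster size
#' @export
largest_cluster_size <- function(config, op = op_config()) {
  largest_cluster(classify_crystalline(config, op))$n
}

#' Cubic/hexagonal polymorph sub-labels
#'
#' Discriminates the two diamond polymorphs through the torsional arrangement
#' of bonds between crystalline particles: the mean of `cos(3 phi)` over the
#' torsion angles around a bond is negative for staggered (cubic-diamond)
#' bonds and positive for eclipsed (hexagonal-diamond) bonds. A crystalline
#' particle with at least one eclipsed bond is labelled hexagonal, one with
#' only staggered bonds cubic; particles with no classifiable bond (or
#' liquid particles) stay unassigned.
#'
#' @param config a [configuration()]
#' @param result an `op_result` from [classify_crystalline()]
#' @param bond_cutoff first-shell bond cutoff, Angstrom (torsions are a
#'   property of the 4 tetrahedral bonds, independent of the wider
#'   neighbourhood used for crystallinity)
#' @return factor of per-particle labels in `{cubic, hexagonal, none}`
#' @export
classify_polymorph <- function(config, result, bond_cutoff = 3.51) {
  bonds <- neighbor_list_cpp(config$positions, config$box, bond_cutoff)
  pm <- polymorph_cpp(config$positions, config$box, bonds,
                      result$crystalline)
  lab <- rep("none", n_particles(config))
  cry <- result$crystalline
  lab[cry & pm$n_eclipsed >= 1] <- "hexagonal"
  lab[cry & pm$n_eclipsed == 0 & pm$n_staggered >= 1] <- "cubic"
  factor(lab, levels = c("cubic", "hexagonal", "none"))
}

#' Per-frame crystallinity analysis of a trajectory
#'
#' Applies the Q12 classification and cluster decomposition to each frame and
#' tabulates the order parameter.
#'
#' @param traj an `md_trajectory` or list of configurations
#' @param op an [op_config()]
#' @param polymorph also compute cubic/hexagonal fractions
#' @return data.frame with columns `frame`, `time`, `n`, `frac_crystalline`
#'   (and `frac_cubic`, `frac_hex` when requested)
#' @export
analyze_frames <- function(traj, op = op_config(), polymorph = FALSE) {
  fr <- .as_frames(traj)
  rows <- lapply(seq_along(fr$pos), function(i) {
    cfg <- configuration(fr$pos[[i]], fr$box[[i]])
    res <- classify_crystalline(cfg, op)
    cl <- largest_cluster(res)
    row <- data.frame(frame = i, time = fr$times[i], n = cl$n,
                      frac_crystalline = mean(res$crystalline))
    if (polymorph) {
      lab <- classify_polymorph(cfg, res)
      row$frac_cubic <- mean(lab == "cubic")
      row$frac_hex <- mean(lab == "hexagonal")
    }
    row
  })
  do.call(rbind, rows)
}
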