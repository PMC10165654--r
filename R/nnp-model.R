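#' Neural-network potential model
#'
#' A feed-forward network (default two hidden tanh layers of 25 units) maps
#' each particle's 10 fingerprints to a per-particle energy; the total energy
#' is the sum over particles, which makes the model permutation invariant and
#' extensive by construction. Fingerprint inputs are standardised by a
#' per-descriptor centre/scale fixed from the training data.
#'
#' @param af an [af_set()]
#' @param hidden hidden layer widths
#' @param seed integer seed for weight initialisation
#' @return object of class `nnp_model`
#' @export
nnp_model <- function(af = af_set(), hidden = c(25, 25), seed = 1) {
  stopifnot(length(hidden) == 2)
  set.seed(seed)
  nd <- 10
  W1 <- matrix(stats::rnorm(hidden[1] * nd, 0, 1 / sqrt(nd)), hidden[1], nd)
  b1 <- numeric(hidden[1])
  W2 <- matrix(stats::rnorm(hidden[2] * hidden[1], 0, 1 / sqrt(hidden[1])),
               hidden[2], hidden[1])
  b2 <- numeric(hidden[2])
  w3 <- stats::rnorm(hidden[2], 0, 1 / sqrt(hidden[2]))
  b3 <- 0
  structure(list(af = af, W1 = W1, b1 = b1, W2 = W2, b2 = b2, w3 = w3,
                 b3 = b3, center = numeric(nd), scale = rep(1, nd)),
            class = "nnp_model")
}

## forward pass on a descriptor matrix G (N x 10)
.nnp_forward <- function(model, G) {
  Z <- sweep(sweep(G, 2, model$center, "-"), 2, model$scale, "/")
  A1 <- Z %*% t(model$W1)
  A1 <- sweep(A1, 2, model$b1, "+")
  H1 <- tanh(A1)
  A2 <- H1 %*% t(model$W2)
  A2 <- sweep(A2, 2, model$b2, "+")
  H2 <- tanh(A2)
  e <- drop(H2 %*% model$w3) + model$b3
  list(Z = Z, H1 = H1, H2 = H2, e = e)
}

## dE/dG rows (N x 10): gradient of each per-particle energy wrt its raw
## fingerprints (chain rule through the standardisation)
.nnp_gradG <- function(model, fw) {
  D2 <- (1 - fw$H2^2) * matrix(model$w3, nrow(fw$H2), length(model$w3),
                               byrow = TRUE)
  D1 <- (1 - fw$H1^2) * (D2 %*% model$W2)
  A <- D1 %*% model$W1
  sweep(A, 2, model$scale, "/")
}

#' Evaluate the neural-network potential
#'
#' Total energy `U = sum_i net(AF_i)`, analytic forces by the chain rule
#' through the fingerprints, and the interaction virial, under the same
#' contract as [mw_evaluate()].
#'
#' @param config a [configuration()]
#' @param model an [nnp_model()]
#' @return list with `U` (kcal/mol), `forces` (`N x 3`) and `virial`
#' @export
nnp_evaluate <- function(config, model) {
  .check_box_cutoff(config, .af_max_cutoff(model$af))
  G <- compute_afs(config, model$af)
  fw <- .nnp_forward(model, G)
  A <- .nnp_gradG(model, fw)
  fr <- afs_force_cpp(config$positions, config$box, model$af$two_body,
                      model$af$three_body, A)
  list(U = sum(fw$e), forces = fr$forces, virial = fr$virial,
       per_particle = fw$e)
}

#' @rdname mw_engine
#' @param model an [nnp_model()]
#' @export
nnp_engine <- function(model, mass = mw_params()$mass) {
  structure(list(evaluate = function(config) nnp_evaluate(config, model),
                 cutoff = .af_max_cutoff(model$af), mass = mass,
                 kind = "nnp", model = model),
            class = "engine")
}

## ---- gradient machinery for training -------------------------------------

## weight vector <-> model
.w_to_vec <- function(m) c(m$W1, m$b1, m$W2, m$b2, m$w3, m$b3)
.vec_to_w <- function(v, m) {
  i <- 0
  take <- function(n) { out <- v[(i + 1):(i + n)]; i <<- i + n; out }
  m$W1 <- matrix(take(length(m$W1)), nrow(m$W1), ncol(m$W1))
  m$b1 <- take(length(m$b1))
  m$W2 <- matrix(take(length(m$W2)), nrow(m$W2), ncol(m$W2))
  m$b2 <- take(length(m$b2))
  m$w3 <- take(length(m$w3))
  m$b3 <- take(1)
  m
}

## backprop of a scalar sum(coef_i * e_i) wrt weights; coef length N
.nnp_backprop_e <- function(model, fw, coef) {
  d_e <- coef                                        # N
  d_H2 <- outer(d_e, model$w3)                       # N x h2
  g_w3 <- colSums(fw$H2 * d_e)
  g_b3 <- sum(d_e)
  d_A2 <- d_H2 * (1 - fw$H2^2)
  g_W2 <- t(d_A2) %*% fw$H1
  g_b2 <- colSums(d_A2)
  d_H1 <- d_A2 %*% model$W2
  d_A1 <- d_H1 * (1 - fw$H1^2)
  g_W1 <- t(d_A1) %*% fw$Z
  g_b1 <- colSums(d_A1)
  c(g_W1, g_b1, g_W2, g_b2, g_w3, g_b3)
}

## gradient wrt weights of sum_i <gradG e(G_i), v_i>, where v_i (N x 10) is a
## direction in raw-G space: forward tangent through the net followed by
## reverse mode (exact mixed second derivatives of the force loss).
.nnp_fwdrev <- function(model, fw, V) {
  Vz <- sweep(V, 2, model$scale, "/")                # direction in Z space
  T1 <- Vz %*% t(model$W1)                           # zdot1
  H1d <- (1 - fw$H1^2)
  Hd1 <- H1d * T1                                    # h1dot
  T2 <- Hd1 %*% t(model$W2)                          # zdot2
  H2d <- (1 - fw$H2^2)
  Hd2 <- H2d * T2                                    # h2dot
  ## s = sum_i w3 . Hd2_i ; reverse pass:
  d_Hd2 <- matrix(model$w3, nrow(Hd2), length(model$w3), byrow = TRUE)
  g_w3 <- colSums(Hd2)
  g_b3 <- 0
  ## Hd2 = H2d * T2
  d_T2 <- d_Hd2 * H2d
  d_H2 <- d_Hd2 * (-2 * fw$H2 * T2)
  ## T2 = Hd1 %*% t(W2)
  g_W2 <- t(d_T2) %*% Hd1
  d_Hd1 <- d_T2 %*% model$W2
  ## H2 = tanh(A2), A2 = H1 W2^T + b2
  d_A2 <- d_H2 * H2d
  g_W2 <- g_W2 + t(d_A2) %*% fw$H1
  g_b2 <- colSums(d_A2)
  d_H1 <- d_A2 %*% model$W2
  ## Hd1 = H1d * T1
  d_T1 <- d_Hd1 * H1d
  d_H1 <- d_H1 + d_Hd1 * (-2 * fw$H1 * T1)
  ## T1 = Vz W1^T
  g_W1 <- t(d_T1) %*% Vz
  ## H1 = tanh(A1), A1 = Z W1^T + b1
  d_A1 <- d_H1 * H1d
  g_W1 <- g_W1 + t(d_A1) %*% fw$Z
  g_b1 <- colSums(d_A1)
  c(g_W1, g_b1, g_W2, g_b2, g_w3, g_b3)
}

## loss (and optionally weight-gradient) of one config entry
## entry: list(config, energy, forces)
.nnp_loss_entry <- function(model, entry, w_e, w_f, grad = FALSE, G = NULL) {
  cfg <- entry$config
  N <- nrow(cfg$positions)
  if (is.null(G)) G <- compute_afs(cfg, model$af)
  fw <- .nnp_forward(model, G)
  U <- sum(fw$e)
  A <- .nnp_gradG(model, fw)
  fr <- afs_force_cpp(cfg$positions, cfg$box, model$af$two_body,
                      model$af$three_body, A)
  dE <- (U - entry$energy) / N
  dF <- fr$forces - entry$forces
  loss <- w_e * dE^2 + w_f * mean(dF^2)
  if (!grad) return(list(loss = loss, U = U, forces = fr$forces,
                         virial = fr$virial))
  ## energy term
  g <- .nnp_backprop_e(model, fw, rep(2 * w_e * dE / N, N))
  ## force term: dLf/dw = sum_i d/dw <gradG e(G_i), v_i>,
  ## v_i = -sum_a Rm_a dG_i/dx_a with Rm = 2 w_f dF/(3N)
  Rm <- 2 * w_f * dF / (3 * N)
  vc <- afs_vcontract_cpp(cfg$positions, cfg$box, model$af$two_body,
                          model$af$three_body, Rm)
  g <- g + .nnp_fwdrev(model, fw, -vc$V)
  list(loss = loss, grad = g, U = U, forces = fr$forces, virial = fr$virial)
}

## total loss over a list of entries (no gradient)
.nnp_loss_total <- function(model, entries, w_e, w_f) {
  mean(vapply(entries, function(en)
    .nnp_loss_entry(model, en, w_e, w_f)$loss, numeric(1)))
}
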