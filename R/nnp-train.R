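#' Training configuration for the neural-network potential
#'
#' The loss is the mean over configurations of
#' `w_energy * ((U - U_ref)/N)^2 + w_force * mean((F - F_ref)^2)`; the virial
#' is monitored but never trained. The learning rate follows cosine annealing
#' between `lr_max` and `lr_min` with warm restarts at logarithmically spaced
#' epochs.
#'
#' @param n_epochs number of epochs
#' @param split train fraction (configurations are split whole, seeded)
#' @param w_energy,w_force loss weights
#' @param lr_max,lr_min learning-rate bounds
#' @param n_restarts number of warm restarts
#' @param train_af also train the 30 fingerprint parameters (centres, widths,
#'   cutoffs, angular sharpness/offset/decay)
#' @param seed integer seed (split and initialisation stream)
#' @export
train_config <- function(n_epochs = 4000, split = 0.8, w_energy = 1,
                         w_force = 0.1, lr_max = 1e-3, lr_min = 1e-5,
                         n_restarts = 4, train_af = TRUE, seed = 1) {
  stopifnot(n_epochs >= 1, split > 0, split < 1)
  structure(list(n_epochs = as.integer(n_epochs), split = split,
                 w_energy = w_energy, w_force = w_force, lr_max = lr_max,
                 lr_min = lr_min, n_restarts = as.integer(n_restarts),
                 train_af = isTRUE(train_af), seed = as.integer(seed)),
            class = "train_config")
}

## restart boundaries at logarithmically spaced epochs, and the cosine lr
.lr_schedule <- function(cfg) {
  ne <- cfg$n_epochs
  bounds <- unique(c(1, round(ne^(seq_len(cfg$n_restarts) / cfg$n_restarts)),
                     ne + 1))
  bounds <- sort(unique(pmin(bounds, ne + 1)))
  function(epoch) {
    seg <- max(which(bounds <= epoch))
    lo <- bounds[seg]
    hi <- if (seg < length(bounds)) bounds[seg + 1] else ne + 1
    s <- (epoch - lo) / max(1, hi - lo)
    cfg$lr_min + 0.5 * (cfg$lr_max - cfg$lr_min) * (1 + cos(pi * s))
  }
}

#' Build a liquid-state training corpus from the reference potential
#'
#' Runs NVT molecular dynamics of the mW model at each state point, samples
#' decorrelated configurations, and stores the reference energy, forces and
#' virial of each. Defaults mirror the standard protocol (three liquid state
#' points, 70 configurations each of N = 1000) but every size is an argument
#' so the same generator produces desk-scale corpora.
#'
#' @param params an [mw_params()]
#' @param state_points data.frame with columns `rho` (g/cm^3) and `T` (K)
#' @param n_per_state configurations per state point
#' @param N particles per configuration
#' @param stride_ps sampling stride, ps
#' @param seed integer seed
#' @param dt time step, fs
#' @param max_autocor reject the corpus when the lag-1 autocorrelation of the
#'   sampled potential energies exceeds this
#' @return list of class `nnp_corpus`: entries with `config`, `energy`,
#'   `forces`, `virial`, plus the state-point table
#' @export
build_training_corpus <- function(params = mw_params(),
                                  state_points = data.frame(
                                    rho = c(0.92, 0.92, 1.15),
                                    T = c(221.1, 270.9, 270.9)),
                                  n_per_state = 70, N = 1000,
                                  stride_ps = 16, seed = 1, dt = 4,
                                  max_autocor = 0.2) {
  entries <- list()
  eng <- mw_engine(params)
  stride <- max(1, round(stride_ps * 1e3 / dt))
  for (s in seq_len(nrow(state_points))) {
    rho <- state_points$rho[s]; T <- state_points$T[s]
    cfg <- generate_liquid(N, rho, T, params, seed = seed + 101 * s)
    st <- md_state(cfg, eng)
    set.seed(seed + 101 * s + 1)
    st <- integrate_nvt(st, n_per_state * stride, dt, T = T, damping = 0.5,
                        engine = eng, sample_every = stride)
    Us <- numeric(0)
    for (f in seq_along(st$trajectory$frames)) {
      c2 <- configuration(st$trajectory$frames[[f]],
                          st$trajectory$boxes[f, ], temperature = T)
      ev <- mw_evaluate(c2, params)
      entries[[length(entries) + 1]] <-
        list(config = c2, energy = ev$U, forces = ev$forces,
             virial = ev$virial, rho = rho, T = T)
      Us <- c(Us, ev$U)
    }
    if (length(Us) > 4) {
      ac <- stats::cor(Us[-1], Us[-length(Us)])
      ## the lag-1 estimate from n samples carries sd ~ sqrt((1-ac^2)/n);
      ## reject only when the correlation is significantly above threshold
      se <- sqrt((1 - min(ac^2, 1)) / length(Us))
      if (is.finite(ac) && ac - se > max_autocor)
        stop(sprintf(
          "corpus rejected: energy autocorrelation %.2f (se %.2f) at stride %.1f ps",
          ac, se, stride_ps))
    }
  }
  structure(list(entries = entries, state_points = state_points,
                 N = N, n_per_state = n_per_state), class = "nnp_corpus")
}

#' Train the neural-network potential
#'
#' Full-batch Adam on the energy+force loss. Network-weight gradients are
#' analytic (including the exact mixed second derivatives required by the
#' force term); fingerprint-parameter gradients are central finite
#' differences over the 30 trainable descriptor parameters. Per-epoch test
#' errors (energy per particle, force components, virial pressure) are
#' recorded and a checkpoint is kept for every epoch.
#'
#' @param corpus an `nnp_corpus` or plain list of entries
#'   (`config`/`energy`/`forces`/`virial`)
#' @param cfg a [train_config()]
#' @param model starting [nnp_model()]; a fresh one by default
#' @param verbose print progress every 50 epochs
#' @return list of class `nnp_training`: `model` (final), `history`
#'   (data.frame per epoch: `loss_train`, `loss_test`, `delta_eps`,
#'   `delta_f`, `delta_P`, `lr`), `checkpoints`, `test_idx`
#' @export
train_nnp <- function(corpus, cfg = train_config(), model = NULL,
                      verbose = FALSE) {
  entries <- if (inherits(corpus, "nnp_corpus")) corpus$entries else corpus
  stopifnot(length(entries) >= 2)
  set.seed(cfg$seed)
  n <- length(entries)
  idx <- sample(n)
  n_train <- max(1, round(cfg$split * n))
  train_set <- entries[idx[seq_len(n_train)]]
  test_set <- entries[idx[(n_train + 1):n]]
  if (is.null(model)) {
    model <- nnp_model(seed = cfg$seed)
    ## standardise inputs on the training set and anchor the output bias at
    ## the mean energy per particle so the network only has to learn
    ## fluctuations around it (a user-supplied model is used exactly as is)
    G_all <- do.call(rbind, lapply(train_set, function(en)
      compute_afs(en$config, model$af)))
    model$center <- colMeans(G_all)
    model$scale <- pmax(apply(G_all, 2, stats::sd), 1e-8)
    model$b3 <- mean(vapply(train_set, function(en)
      en$energy / nrow(en$config$positions), numeric(1)))
  }

  lr_of <- .lr_schedule(cfg)
  w <- .w_to_vec(model)
  av <- .af_to_vec(model$af)
  mw_ <- rep(0, length(w)); vw_ <- rep(0, length(w))
  ma_ <- rep(0, length(av)); va_ <- rep(0, length(av))
  b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
  hist <- data.frame(epoch = integer(0))
  checkpoints <- list()
  G_cache <- NULL
  for (epoch in seq_len(cfg$n_epochs)) {
    lr <- lr_of(epoch)
    if (!cfg$train_af && is.null(G_cache))
      G_cache <- lapply(train_set, function(en)
        compute_afs(en$config, model$af))
    gsum <- rep(0, length(w)); lsum <- 0
    for (k in seq_along(train_set)) {
      le <- .nnp_loss_entry(model, train_set[[k]], cfg$w_energy, cfg$w_force,
                            grad = TRUE,
                            G = if (!cfg$train_af) G_cache[[k]] else NULL)
      gsum <- gsum + le$grad; lsum <- lsum + le$loss
    }
    gsum <- gsum / length(train_set); lsum <- lsum / length(train_set)
    if (!is.finite(lsum)) stop("divergent loss (non-finite) at epoch ", epoch)
    mw_ <- b1 * mw_ + (1 - b1) * gsum
    vw_ <- b2 * vw_ + (1 - b2) * gsum^2
    what <- mw_ / (1 - b1^epoch); vhat <- vw_ / (1 - b2^epoch)
    w <- w - lr * what / (sqrt(vhat) + epsl)
    model <- .vec_to_w(w, model)
    if (cfg$train_af) {
      ga <- .af_fd_grad(model, train_set, cfg)
      ma_ <- b1 * ma_ + (1 - b1) * ga
      va_ <- b2 * va_ + (1 - b2) * ga^2
      ahat <- ma_ / (1 - b1^epoch); avhat <- va_ / (1 - b2^epoch)
      av <- av - lr * ahat / (sqrt(avhat) + epsl)
      model$af <- .vec_to_af(av, model$af)
      av <- .af_to_vec(model$af)
    }
    em <- error_metrics(model, test_set)
    hist <- rbind(hist, data.frame(
      epoch = epoch, loss_train = lsum,
      loss_test = .nnp_loss_total(model, test_set, cfg$w_energy, cfg$w_force),
      delta_eps = em$delta_eps, delta_f = em$delta_f, delta_P = em$delta_P,
      lr = lr))
    checkpoints[[epoch]] <- list(w = w, af = model$af,
                                 center = model$center, scale = model$scale)
    if (verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d  loss %.3g  d_eps %.3g  d_f %.3g",
                      epoch, lsum, em$delta_eps, em$delta_f))
  }
  structure(list(model = model, history = hist, checkpoints = checkpoints,
                 test_idx = idx[(n_train + 1):n], cfg = cfg),
            class = "nnp_training")
}

## central-difference gradient of the loss wrt the 30 fingerprint parameters
.af_fd_grad <- function(model, entries, cfg, h = 1e-4) {
  av <- .af_to_vec(model$af)
  g <- numeric(length(av))
  for (p in seq_along(av)) {
    for (sgn in c(1, -1)) {
      av2 <- av; av2[p] <- av2[p] + sgn * h
      m2 <- model; m2$af <- .vec_to_af(av2, model$af)
      l <- .nnp_loss_total(m2, entries, cfg$w_energy, cfg$w_force)
      g[p] <- g[p] + sgn * l / (2 * h)
    }
  }
  g
}

## restore a model from a checkpoint
.model_from_checkpoint <- function(model, ck) {
  m <- .vec_to_w(ck$w, model)
  m$af <- ck$af; m$center <- ck$center; m$scale <- ck$scale
  m
}

#' Select the best model from a training history
#'
#' Restricts attention to the trailing fraction of training (where force
#' errors are lowest) and returns the checkpoint that is a simultaneous local
#' minimum of the test energy error and the test virial-pressure error; if no
#' epoch is a local minimum of both, falls back to the checkpoint minimising
#' the larger of the two error ranks. Deterministic given a history.
#'
#' @param training an `nnp_training`, or a history data.frame (then
#'   `checkpoints` must be given)
#' @param checkpoints list of checkpoints parallel to the history rows
#' @param trailing_frac fraction of final epochs considered
#' @return list with the selected `model` (when checkpoints carry enough to
#'   rebuild one), `epoch`, and the selection `rule` applied
#' @export
select_best_model <- function(training, checkpoints = NULL,
                              trailing_frac = 0.25) {
  if (inherits(training, "nnp_training")) {
    hist <- training$history
    checkpoints <- training$checkpoints
    base_model <- training$model
  } else {
    hist <- training
    base_model <- NULL
  }
  ne <- nrow(hist)
  if (ne < 1 || is.null(checkpoints) || length(checkpoints) < 1)
    stop("empty candidate set")
  first <- max(1, ne - ceiling(trailing_frac * ne) + 1)
  cand <- first:ne
  is_locmin <- function(v, i) {
    left <- if (i > 1) v[i] <= v[i - 1] else TRUE
    right <- if (i < length(v)) v[i] <= v[i + 1] else TRUE
    left && right
  }
  both <- cand[vapply(cand, function(i)
    is_locmin(hist$delta_eps, i) && is_locmin(hist$delta_P, i), logical(1))]
  if (length(both) > 0) {
    pick <- both[which.min(pmax(rank(hist$delta_eps[cand]),
                                rank(hist$delta_P[cand]))[match(both, cand)])]
    rule <- "simultaneous local minimum"
  } else {
    rk <- pmax(rank(hist$delta_eps[cand], ties.method = "first"),
               rank(hist$delta_P[cand], ties.method = "first"))
    pick <- cand[which.min(rk)]
    rule <- "min-max rank fallback"
  }
  model <- if (!is.null(base_model))
    .model_from_checkpoint(base_model, checkpoints[[pick]]) else NULL
  list(model = model, epoch = hist$epoch[pick], rule = rule)
}

#' Test-set error metrics of a model against its reference data
#'
#' Root-mean-square differences between model and reference: energy per
#' particle (kcal/mol), force Cartesian components (kcal/mol/nm), and virial
#' pressure (bar).
#'
#' @param model an [nnp_model()]
#' @param test_set list of entries (`config`, `energy`, `forces`, `virial`)
#' @return list with `delta_eps`, `delta_f`, `delta_P`
#' @export
error_metrics <- function(model, test_set) {
  stopifnot(length(test_set) >= 1)
  de <- df2 <- dp <- numeric(0)
  for (en in test_set) {
    ev <- nnp_evaluate(en$config, model)
    N <- nrow(en$config$positions)
    V <- prod(en$config$box)
    de <- c(de, (ev$U - en$energy) / N)
    df2 <- c(df2, mean((ev$forces - en$forces)^2))
    dp <- c(dp, (ev$virial - en$virial) / (3 * V) * .press_conv)
  }
  list(delta_eps = sqrt(mean(de^2)),
       delta_f = sqrt(mean(df2)) * 10,  # kcal/mol/A -> kcal/mol/nm
       delta_P = sqrt(mean(dp^2)))
}

#' Energy-error map over the temperature-density plane
#'
#' For each grid point, runs NVT simulations with the reference mW potential
#' and with the trained model and records the absolute difference of the mean
#' energies per particle. The production grid of the accuracy map is 6
#' densities in [0.92, 1.22] g/cm^3 by 8 temperatures in [221.1, 373.7] K;
#' sizes are arguments so a desk-scale map runs in minutes.
#'
#' @param model an [nnp_model()]
#' @param params an [mw_params()]
#' @param temps,rhos grid axes (K, g/cm^3)
#' @param N particles per cell
#' @param equil_ps,prod_ps equilibration and production length per potential
#' @param seed integer seed
#' @return data.frame with `T`, `rho`, `e_mw`, `e_nnp`, `delta_e`,
#'   `flagged` (TRUE when either average still trended)
#' @export
energy_error_map <- function(model, params = mw_params(),
                             temps = seq(221.1, 373.7, length.out = 8),
                             rhos = seq(0.92, 1.22, length.out = 6),
                             N = 128, equil_ps = 4, prod_ps = 8, seed = 1,
                             dt = 4) {
  grid <- expand.grid(T = temps, rho = rhos)
  eng_nnp <- nnp_engine(model, mass = params$mass)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    T <- grid$T[g]; rho <- grid$rho[g]
    cfg <- generate_liquid(N, rho, T, params, seed = seed + g)
    means <- vapply(list(mw_engine(params), eng_nnp), function(eng) {
      st <- md_state(cfg, eng)
      set.seed(seed + g)
      st <- integrate_nvt(st, round(equil_ps * 1e3 / dt), dt, T = T,
                          damping = 0.5, engine = eng)
      st <- integrate_nvt(st, round(prod_ps * 1e3 / dt), dt, T = T,
                          damping = 0.5, engine = eng,
                          sample_every = max(1, round(250 / dt)))
      u <- st$trajectory$series$U
      c(mean(u) / N, .trend_ok(u))
    }, numeric(2))
    data.frame(T = T, rho = rho, e_mw = means[1, 1], e_nnp = means[1, 2],
               delta_e = abs(means[1, 1] - means[1, 2]),
               flagged = !(means[2, 1] > 0 && means[2, 2] > 0))
  })
  do.call(rbind, rows)
}
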