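#' Write configurations to an extended-XYZ file
#'
#' One or more frames in extended-XYZ: the comment line carries the
#' orthorhombic cell as `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`, a `Properties`
#' descriptor for the per-atom columns (species, positions, optional
#' velocities, optional per-atom auxiliary columns), and any per-frame
#' scalars (e.g. `energy=`, `virial=`, `time=`).
#'
#' @param frames a [configuration()] or list of configurations; per-frame
#'   scalars may be attached as an `extras` attribute (named list) on each
#'   configuration
#' @param path output file
#' @param species atom label
#' @param wrap wrap positions into the primary cell on output
#' @param digits number of significant digits
#' @return `path`, invisibly
#' @export
write_xyz <- function(frames, path, species = "W", wrap = TRUE,
                      digits = 10) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.*g", digits, x)
  for (cfg in frames) {
    if (wrap) cfg <- wrap_positions(cfg)
    N <- n_particles(cfg)
    props <- "species:S:1:pos:R:3"
    cols <- cfg$positions
    if (!is.null(cfg$velocities)) {
      props <- paste0(props, ":vel:R:3")
      cols <- cbind(cols, cfg$velocities)
    }
    extras <- attr(cfg, "extras")
    extra_str <- ""
    if (!is.null(extras))
      extra_str <- paste0(" ", paste(names(extras), "=",
                                     vapply(extras, fmt, ""), sep = "",
                                     collapse = " "))
    lat <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s"',
                   fmt(cfg$box[1]), fmt(cfg$box[2]), fmt(cfg$box[3]))
    writeLines(as.character(N), con)
    writeLines(paste0(lat, " Properties=", props, extra_str), con)
    body <- apply(cols, 1, function(r) paste(fmt(r), collapse = " "))
    writeLines(paste(species, body), con)
  }
  invisible(path)
}

#' Read configurations from an extended-XYZ file
#'
#' @param path input file
#' @return list of [configuration()]s; per-frame scalars from the comment
#'   line are attached as an `extras` attribute
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("parse error at line %d: expected atom count", i))
    N <- as.integer(lines[i])
    if (i + 1 > length(lines))
      stop(sprintf("parse error at line %d: missing comment line", i + 1))
    comment <- lines[i + 1]
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]*"', comment))
    if (length(lat) == 0)
      stop(sprintf("parse error at line %d: missing Lattice entry", i + 1))
    lv <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
    if (length(lv) != 9 || any(!is.finite(lv)))
      stop(sprintf("parse error at line %d: malformed Lattice", i + 1))
    box <- lv[c(1, 5, 9)]
    has_vel <- grepl("vel:R:3", comment)
    if (i + 1 + N > length(lines))
      stop(sprintf("parse error: truncated frame starting at line %d", i))
    body <- lines[(i + 2):(i + 1 + N)]
    tok <- strsplit(trimws(body), "\\s+")
    vals <- t(vapply(tok, function(t) as.numeric(t[-1]),
                     numeric(length(tok[[1]]) - 1)))
    pos <- vals[, 1:3, drop = FALSE]
    vel <- if (has_vel && ncol(vals) >= 6) vals[, 4:6, drop = FALSE] else NULL
    cfg <- configuration(pos, box, vel)
    kv <- regmatches(comment,
                     gregexpr('[A-Za-z_][A-Za-z0-9_]*=[-+0-9.eE]+', comment))[[1]]
    if (length(kv) > 0) {
      ex <- as.list(as.numeric(sub("^[^=]*=", "", kv)))
      names(ex) <- sub("=.*$", "", kv)
      attr(cfg, "extras") <- ex
    }
    frames[[length(frames) + 1]] <- cfg
    i <- i + 2 + N
  }
  frames
}

#' Run one pipeline stage from a structured configuration
#'
#' Dispatches to the package's module operations from a single config object
#' (a named list, or a YAML file path). Every stage writes its artifacts plus
#' a JSON provenance file (`provenance.json`: the full config echo, the seed,
#' and the package version) into the output directory, so a run can be
#' reproduced bit-exactly.
#'
#' Stages: `make-fixtures`, `run-md`, `analyze-structure`, `analyze-mfpt`,
#' `build-corpus`, `train-nnp`, `eval-nnp`, `error-map`, `run-cntus`,
#' `analyze-barrier`.
#'
#' @param config named list with at least `stage` and `outdir`, or a path to
#'   a YAML file with those keys
#' @return the stage's main result, invisibly; artifacts on disk
#' @export
run_stage <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stages <- c("make-fixtures", "run-md", "analyze-structure", "analyze-mfpt",
              "build-corpus", "train-nnp", "eval-nnp", "error-map",
              "run-cntus", "analyze-barrier")
  need <- function(field) {
    if (is.null(config[[field]]))
      stop(sprintf("validation error: required field '%s' missing", field))
    config[[field]]
  }
  stage <- need("stage")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; available: ",
         paste(stages, collapse = ", "))
  outdir <- need("outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(need("seed"))

  result <- switch(
    stage,
    "make-fixtures" = {
      kind <- need("kind")
      obj <- switch(kind,
        lattice = build_lattice(config$polymorph %||% "cubic",
                                cells = config$cells %||% 3,
                                density = config$density %||% 0.98,
                                noise = config$noise %||% 0, seed = seed),
        liquid = generate_liquid(need("N"), need("rho"), need("T"),
                                 seed = seed),
        walks = simulate_walks(cnt_profile(0:(config$n_max %||% 60),
                                           config$delta_mu %||% 0.4,
                                           config$n_c %||% 25),
                               kplus = config$kplus %||% 50,
                               n_traj = config$n_traj %||% 100, seed = seed),
        stop("unknown fixture kind '", kind, "'"))
      if (inherits(obj, "configuration"))
        write_xyz(obj, file.path(outdir, paste0(kind, ".xyz")))
      else {
        fpt <- obj$fpt
        utils::write.table(fpt, file.path(outdir, "walks_fpt.tsv"),
                           sep = "\t", row.names = FALSE)
      }
      obj
    },
    "run-md" = {
      frames <- read_xyz(need("input"))
      cfg0 <- frames[[length(frames)]]
      if (is.null(cfg0$velocities))
        cfg0 <- draw_velocities(cfg0, need("T"), seed = seed)
      st <- md_state(cfg0, mw_engine())
      set.seed(seed)
      ens <- config$ensemble %||% "nvt"
      st <- switch(ens,
        nve = integrate_nve(st, need("n_steps"), config$dt %||% 4,
                            sample_every = config$sample_every %||% 100),
        nvt = integrate_nvt(st, need("n_steps"), config$dt %||% 4,
                            T = need("T"), damping = config$damping %||% 1,
                            sample_every = config$sample_every %||% 100),
        npt = integrate_npt(st, need("n_steps"), config$dt %||% 4,
                            T = need("T"), P = config$P %||% 1.01325,
                            sample_every = config$sample_every %||% 100),
        stop("unknown ensemble '", ens, "'"))
      utils::write.table(st$trajectory$series,
                         file.path(outdir, "thermo.tsv"),
                         sep = "\t", row.names = FALSE)
      cfgs <- lapply(seq_along(st$trajectory$frames), function(i)
        configuration(st$trajectory$frames[[i]], st$trajectory$boxes[i, ]))
      write_xyz(cfgs, file.path(outdir, "traj.xyz"))
      st
    },
    "analyze-structure" = {
      frames <- read_xyz(need("input"))
      tab <- analyze_frames(frames, polymorph = isTRUE(config$polymorph))
      utils::write.table(tab, file.path(outdir, "crystallinity.tsv"),
                         sep = "\t", row.names = FALSE)
      tab
    },
    "analyze-mfpt" = {
      fpt <- as.matrix(utils::read.table(need("series"), header = TRUE,
                                         sep = "\t"))
      series <- lapply(seq_len(nrow(fpt)), function(w) {
        t <- fpt[w, ]; keep <- is.finite(t)
        data.frame(time = t[keep], n = (seq_along(t) - 1)[keep])
      })
      curve <- first_passage(series)
      fit <- fit_mfpt(curve, V = config$volume %||% 1,
                      fit_max_n = config$fit_max_n %||% 100)
      utils::write.table(curve, file.path(outdir, "fpt_curve.tsv"),
                         sep = "\t", row.names = FALSE)
      jsonlite::write_json(
        list(J = fit$J, n_c = fit$n_c, c = fit$c, V = fit$V),
        file.path(outdir, "mfpt_fit.json"), auto_unbox = TRUE, digits = NA)
      fit
    },
    "build-corpus" = {
      corpus <- build_training_corpus(
        n_per_state = config$n_per_state %||% 70, N = config$N %||% 1000,
        seed = seed)
      for (k in seq_along(corpus$entries)) {
        en <- corpus$entries[[k]]
        cf <- en$config
        attr(cf, "extras") <- list(energy = en$energy, virial = en$virial)
        write_xyz(cf, file.path(outdir, sprintf("conf_%04d.xyz", k)))
      }
      corpus
    },
    "train-nnp" = {
      corpus <- need("corpus")  # an nnp_corpus object passed in-process
      tr <- train_nnp(corpus, train_config(
        n_epochs = config$n_epochs %||% 4000, seed = seed,
        train_af = config$train_af %||% TRUE))
      utils::write.table(tr$history, file.path(outdir, "history.tsv"),
                         sep = "\t", row.names = FALSE)
      tr
    },
    "eval-nnp" = {
      tr <- need("training")
      sel <- select_best_model(tr)
      em <- error_metrics(sel$model, tr$checkpoints[["test_set"]] %||%
                            need("test_set"))
      jsonlite::write_json(em, file.path(outdir, "errors.json"),
                           auto_unbox = TRUE, digits = NA)
      em
    },
    "error-map" = {
      map <- energy_error_map(need("model"), seed = seed,
                              N = config$N %||% 128)
      utils::write.table(map, file.path(outdir, "energy_map.tsv"),
                         sep = "\t", row.names = FALSE)
      map
    },
    "run-cntus" = {
      frames <- read_xyz(need("input"))
      cfg0 <- frames[[length(frames)]]
      hist <- run_cntus(md_state(cfg0, mw_engine()), mw_engine(),
                        bias_spec(config$delta_mu %||% 0.57,
                                  config$n_b %||% 90),
                        hmc_config(T = need("T")),
                        n_moves = need("n_moves"), seed = seed)
      utils::write.table(hist$movelog, file.path(outdir, "movelog.tsv"),
                         sep = "\t", row.names = FALSE)
      hist
    },
    "analyze-barrier" = {
      movelog <- utils::read.table(need("movelog"), header = TRUE,
                                   sep = "\t")
      prof <- reconstruct_barrier(movelog$n,
                                  bias_spec(config$delta_mu %||% 0.57,
                                            config$n_b %||% 90),
                                  T = need("T"))
      utils::write.table(prof, file.path(outdir, "barrier.tsv"),
                         sep = "\t", row.names = FALSE)
      prof
    })

  prov <- list(stage = stage, seed = seed,
               config = config[!vapply(config, is.object, TRUE)],
               package_version = as.character(utils::packageVersion("icenuc")),
               timestamp = format(Sys.time(), tz = "UTC"))
  ok <- tryCatch({
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, force = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) warning("provenance echo could not be serialised completely")
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
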