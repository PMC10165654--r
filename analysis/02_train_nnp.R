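#!/usr/bin/env Rscript
## Train a neural-network potential on liquid configurations of the
## reference potential and report its test errors. The production corpus is
## 70 configurations of N = 1000 per state point trained for 4000 epochs;
## this driver runs the identical pipeline at desk scale (N = 128, 12
## configurations per state point, 800 epochs) so it completes in tens of
## minutes on one core. Writes results/nnp_history.tsv and
## results/nnp_errors.json.

suppressPackageStartupMessages(library(icenuc))
dir.create("results", showWarnings = FALSE)
seed <- 1

message("building liquid corpus (three state points) ...")
corpus <- build_training_corpus(
  state_points = data.frame(rho = c(0.92, 0.92, 1.15),
                            T = c(221.1, 270.9, 270.9)),
  n_per_state = 12, N = 128, stride_ps = 16, seed = seed)
message(sprintf("  %d configurations of N = %d", length(corpus$entries), 128))

message("training (800 epochs, energies + forces) ...")
tr <- train_nnp(corpus, train_config(n_epochs = 800, split = 0.8,
                                     w_energy = 1, w_force = 0.1,
                                     lr_max = 5e-3, lr_min = 1e-4,
                                     n_restarts = 4, train_af = FALSE,
                                     seed = seed))
write.table(tr$history, "results/nnp_history.tsv", sep = "\t",
            row.names = FALSE)

sel <- select_best_model(tr)
test_set <- (if (inherits(corpus, "nnp_corpus")) corpus$entries else
               corpus)[tr$test_idx]
em <- error_metrics(sel$model, test_set)
frms <- sqrt(mean(unlist(lapply(test_set, function(e) e$forces^2)))) * 10
jsonlite::write_json(
  list(epoch = sel$epoch, rule = sel$rule,
       delta_eps_kcal_mol = em$delta_eps,
       delta_f_kcal_mol_nm = em$delta_f,
       delta_P_bar = em$delta_P,
       force_rms_kcal_mol_nm = frms),
  "results/nnp_errors.json", auto_unbox = TRUE, digits = NA)
message(sprintf("  selected epoch %d (%s)", sel$epoch, sel$rule))
message(sprintf("  delta_eps = %.4g kcal/mol, delta_f = %.3g kcal/mol/nm (force RMS %.3g), delta_P = %.3g bar",
                em$delta_eps, em$delta_f, frms, em$delta_P))
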