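#!/usr/bin/env Rscript
## Structure and dynamics of the mW liquid at the two nucleation state
## points: g(r) of the supercooled liquid and the bulk cubic-diamond
## crystal at 202.4 K, and the self-diffusion coefficient at 218 K from
## the MSD. Writes results/rdf_202K.tsv, results/msd_218K.tsv,
## results/diffusion_218K.json.

suppressPackageStartupMessages(library(icenuc))
dir.create("results", showWarnings = FALSE)
seed <- 1

## -- g(r) at 202.4 K: liquid and cubic diamond ------------------------------
message("g(r) at 202.4 K ...")
liq <- generate_liquid(216, 0.99, 202.4, seed = seed)
st <- md_state(liq)
st <- integrate_nvt(st, 15000, 4, T = 202.4, damping = 1, seed = seed + 1,
                    sample_every = 250)
rdf_liq <- compute_rdf(st$trajectory, r_max = 8, n_bins = 160)

lat <- build_lattice("cubic", 3, density = 0.978)
lat <- draw_velocities(lat, 202.4, seed = seed + 2)
stc <- md_state(lat)
stc <- integrate_nvt(stc, 10000, 4, T = 202.4, damping = 1, seed = seed + 3,
                     sample_every = 250)
rdf_cry <- compute_rdf(stc$trajectory, r_max = 8, n_bins = 160)

rdf <- data.frame(r = rdf_liq$r, g_liquid = rdf_liq$g, g_crystal = rdf_cry$g)
write.table(rdf, "results/rdf_202K.tsv", sep = "\t", row.names = FALSE)
i1 <- which.max(rdf_liq$g)
message(sprintf("  liquid first peak: g = %.2f at r = %.2f A",
                rdf_liq$g[i1], rdf_liq$r[i1]))
message(sprintf("  crystal stays crystalline: %.0f%%",
                100 * mean(classify_crystalline(stc$config)$crystalline)))

## -- D at 218 K --------------------------------------------------------------
message("diffusion at 218 K (a few minutes) ...")
res <- measure_diffusion(T = 218, N = 216, seed = seed,
                         production_ps = 250, fit_window = c(20, 120))
write.table(res$msd, "results/msd_218K.tsv", sep = "\t", row.names = FALSE)
jsonlite::write_json(list(D = res$D, T_mean = res$T_mean, rho = res$rho,
                          N = 216, window_ps = c(20, 120)),
                     "results/diffusion_218K.json", auto_unbox = TRUE,
                     digits = NA)
message(sprintf("  D = %.1f A^2/ns at <T> = %.1f K, rho = %.4f g/cm^3",
                res$D, res$T_mean, res$rho))
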