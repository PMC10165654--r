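---
title: "Methods: simulating and analysing ice nucleation in the mW water model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing ice nucleation in the mW water model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Homogeneous crystal nucleation is a rare-event process: a supercooled
liquid must spontaneously assemble a crystalline nucleus larger than the
critical size `n_c` before growth becomes downhill in free energy. The mW
model of water — a single-site Stillinger–Weber-form potential whose
three-body term enforces tetrahedrality — is one of the few water models
in which this process is directly observable in simulation, which makes it
a reference system for testing whether machine-learned potentials trained
only on liquid configurations can reproduce nucleation behaviour they have
never seen. This package implements the full tool chain for that test:
the reference potential and its molecular dynamics, a descriptor-based
neural-network potential (NNP) with its training loop, the Q12
bond-orientational order parameter that defines the reaction coordinate,
mean-first-passage-time (MFPT) analysis of spontaneous nucleation, and
umbrella sampling of the nucleation barrier with a bias of
classical-nucleation-theory (CNT) shape driven by hybrid Monte Carlo
(HMC).

# The mW potential and its molecular dynamics

The potential is the Stillinger–Weber functional form with the
tetrahedral parameterisation for water: pair term
`A*eps*(B*(sigma/r)^4 - 1) * exp(sigma/(r - a*sigma))` and three-body term
`lam*eps*(cos(theta) - cos(theta0))^2` with exponential arm decays, with
`eps = 6.189` kcal/mol, `sigma = 2.3925` Å, cutoff `a*sigma = 4.3065` Å,
`lam = 23.15` and `cos(theta0) = -1/3` (`mw_params()`). Units throughout
are kcal/mol, Å, fs, K, bar; `kB = 0.0019872041` kcal/mol/K.

`mw_evaluate()` returns energy, analytic forces, and the interaction
virial `W = sum r_ij . f_ij`, so the pressure is `(N kB T + W/3)/V`.
Correctness is established in the test suite by central finite
differences (1e-6 relative), Newton's third law, translational and
rotational invariance, and — as an end-to-end check — by reproducing
thermodynamic anchors of the published model: the density maximum near
250 K with `rho_max ≈ 1.002` g/cm³, `rho(300 K) = 0.9965`, an ice density
of 0.979 g/cm³, a melting energy of 1.30 kcal/mol at 274.6 K, and a
liquid energy at 300 K consistent with the model's heat of vaporisation.

Integrators: velocity Verlet (NVE); BAOAB-splitting Langevin (NVT) whose
`damping` argument is the friction time in ps; and an isotropic
Langevin-piston barostat acting on `ln V` (NPT) with piston period 0.5 ps
and piston damping 0.2 ps by default — the original study does not state
its piston constants, so these follow common practice and are exposed as
arguments. The piston mass is `3(N+1) kB T tau_p^2`. Positions are kept
unwrapped internally (the minimum-image convention makes wrapping
unnecessary), which gives transport measurements for free; `write_xyz()`
wraps on output.

Two numerical points matter for transport. First, a stochastic thermostat
leaves a random net momentum of order `v_th/sqrt(N)`; during subsequent
NVE dynamics the whole box drifts, adding a `(v_com t)^2` term to the MSD
that can exceed the diffusive signal several-fold at N = 216.
`compute_msd()` therefore subtracts the per-frame centre of mass by
default and `zero_momentum()` is applied at every NVE hand-off. Second, a
single velocity rescaling does not set the microcanonical temperature
(half of any kinetic adjustment relaxes into potential energy), so
`measure_diffusion()` iterates short NVE probes with rescaling until the
mean kinetic temperature matches the target.

# The neural-network potential

Each particle's environment is encoded by 10 atomic fingerprints: 5
two-body Gaussians on distance, `exp(-(r-R_s)^2/w^2) f_c(r)`, with
trainable centre, width, and smooth cosine-cutoff radius; and 5
three-body Behler-style angular functions
`2^(1-zeta) (1 + lambda cos theta)^zeta exp(-(r_ij^2+r_ik^2)/w3^2)
f_c f_c` with trainable sharpness `zeta`, offset `lambda` (constrained to
(-0.95, 0.95) so the base stays positive for non-integer `zeta`) and
radial decay `w3`. The exact fingerprint forms used by the original
authors are published elsewhere and not restated in the study this
package follows, so these forms are this package's own choice with the
same two-body/three-body split and trainable-parameter philosophy; they
are ordinary defaults, not a claim about the original.

A 10→25→25→1 tanh network maps fingerprints to per-particle energies;
the total energy is their sum (permutation-invariant and extensive by
construction, verified to 1e-8 relative under 2×2×2 replication). Inputs
are standardised with a centre/scale frozen from the training set, and
the output bias is anchored at the mean training energy per particle so
the network learns fluctuations only.

Training minimises
`mean[ w_e ((U-U_ref)/N)^2 + w_f mean((F-F_ref)^2) ]` with `w_e = 1`,
`w_f = 0.1` by full-batch Adam. Network-weight gradients are exact,
including the force term, via a forward-over-reverse pass (the mixed
second derivative of the loss); fingerprint-parameter gradients use
central finite differences over the 30 descriptor parameters. Both are
verified against numerical differentiation of the whole loss in the test
suite. The virial pressure error is monitored every epoch but never
enters the loss. The learning rate follows cosine annealing between 1e-3
and 1e-5 with warm restarts at logarithmically spaced epochs
(production: 4000 epochs; the restart spikes are visible in the loss
history). Model selection restricts to the trailing 25% of epochs and
returns the checkpoint that is a simultaneous local minimum of the test
energy and virial-pressure errors, falling back to minimising the larger
of the two error ranks; the rule is deterministic given a history.

The training corpus is NVT liquid sampling of the reference potential at
three state points — (0.92 g/cm³, 221.1 K), (0.92 g/cm³, 270.9 K),
(1.15 g/cm³, 270.9 K) — at a 16 ps stride chosen so the potential-energy
autocorrelation between consecutive samples stays below 0.2 even at the
coldest, slowest state point (the corpus is rejected when the estimated
autocorrelation exceeds 0.2 by more than its own standard error). Production scale is 70 configurations of N = 1000
per state point with an 80/20 split by whole configurations; the test
suite and `analysis/02_train_nnp.R` run the identical pipeline at N =
32–128 with 12 configurations per state point and 150–800 epochs, which
fits in minutes. At these reduced sizes training demonstrably learns a
pair-only reference (force error falling well below half its starting
value by epoch 150 and below ~10% of the force RMS by epochs 600–800);
the corpus-size monotonicity of the distilled energy error is a
production-scale property we do not assert at desk scale.

# Crystallinity: Q12, clusters, polymorphs

Per particle, `q_{12,m}` is the average of rank-12 spherical harmonics
over bonds to neighbours within a cutoff; a bond is coherent when
`d12 = Re<q_hat(i), q_hat(j)> > d_c`, and a particle is crystalline with
at least `xi_c = 4` coherent bonds. The original study says only
"nearest neighbors", so the neighbour convention had to be fixed here,
and fixing it exposed the central pitfall of rank-12 order parameters:
averaged over only the 4 first-shell bonds (first minimum of the liquid
g(r), 3.51 Å), `q_12` is so sensitive to angular noise that *thermally
equilibrated* ice at 218 K has median bond coherence 0.42 — completely
overlapped with the liquid — even though statically noised lattices
classify perfectly. Validation against thermal crystals, not just
generated lattices, is therefore essential. Scanning cutoff, `d_c` and
`xi_c` against mW ice (both polymorphs) equilibrated at 218 and 260 K
and equilibrated liquids at 218 and 270.9 K gives the operating point
used as the default: cutoff 4.5 Å (first shell plus part of the second,
~12 neighbours, which averages the harmonics into a stable signal:
thermal-ice median `d12` ≈ 0.78, liquid ≈ 0.09), `d_c = 0.5` (the
classic connected-neighbour threshold), `xi_c = 4`. This yields ≥ 99%
sensitivity on both polymorphs at 218 K with zero liquid false positives
out of 216 particles across all tested frames, and 100% on generated
lattices. All three thresholds are carried in a single `op_config`
object shared by sampling and analysis.

The order parameter `n` is the largest connected component of
crystalline particles over the same neighbour graph, with `n = 0` for a
fully liquid frame (n counts particles in a crystalline cluster; no
cluster, no count). Cubic and hexagonal character is assigned per bond
from the torsion angles around it (mean of `cos(3 phi)`: negative =
staggered = cubic-like, positive = eclipsed = hexagonal-like); a
crystalline particle with any eclipsed bond is hexagonal, with only
staggered bonds cubic. This diagnostic never feeds `n`.

# Nucleation kinetics by MFPT

`first_passage()` reduces an ensemble of `n(t)` series to the mean first
passage time `tau(n)`, excluding and counting trajectories that never
reach a threshold. `fit_mfpt()` fits the sigmoidal form
`tau(n) = 1/(2 J V) [1 + erf(c (n - n_c))]`, whose plateau gives the
nucleation rate `J`, whose inflection is the critical size `n_c`, and
whose steepness `c` is proportional to the square root of the barrier
curvature (reported as a raw fit parameter; no Zeldovich normalisation is
imposed). The volume entering the plateau is taken as the mean
pre-nucleation NPT volume of the ensemble. Fits are restricted to
`n < 100` by default, matching the production analysis.

Weights are uniform by default. The sigmoid is an asymptotic high-barrier
result; its residual misspecification lives at small `n`, exactly where
inverse-variance weights concentrate, and on the birth–death oracle this
biased the plateau (rate error 30% vs 4% with uniform weights).
Inverse-variance weighting remains available as an option.

The estimator chain is validated two ways: exact recovery (≤ 1e-6
relative) on noise-free model curves, and a birth–death surrogate — a
continuous-time walk with constant attachment rate and detailed-balance
detachment rates over a prescribed `betaG(n)` — whose MFPT is computable
exactly by the standard double-sum recursion (`bd_mfpt_exact()`). The
validation landscape is a CNT profile with an 8 kBT barrier
(`delta_mu = 0.4`, `n_c = 40`, `k+ = 50/ns`, 500 walks): high enough for
the asymptotic sigmoid to apply, ~20× cheaper than a 10 kBT barrier
(whose walks need ~10⁷ events each). Recovered `n_c` agrees with the
profile argmax within 10% and the empirical MFPT with the recursion
within 5% on average.

# CNT-shaped umbrella sampling with hybrid Monte Carlo

The bias is the negative of a CNT free-energy curve,
`eta(n) = kB T (dmu n - (3/2) dmu n_b^(1/3) n^(2/3))`, with
`eta(0) = 0`, a stationary point at `n = n_b` and
`eta(n_b) = -dmu n_b / 2`; production parameters are `dmu = 0.57 kBT`
and `n_b = 90` at 218 K. If the CNT shape were exact the biased landscape
would be flat. The exact printed form of the bias in the source study is
partially embedded in an equation image; the implemented convention
(negative CNT profile parameterised by the stated `dmu` and single
adjustable `n_b`) is recorded in all output metadata.

HMC proposes 0.02 ps NVE segments at dt = 4 fs from freshly drawn
Maxwell–Boltzmann velocities and accepts with
`min(1, exp(-beta [dK + dU + d eta(n)]))`, where `n` is recomputed from
scratch (full Q12 + clustering) on the trial frame — correctness over
speed, and the same `op_config` object serves sampling and analysis so
thresholds can never disagree. Pressure is handled by separate isobaric
moves attempted with probability 0.01 after each HMC move: uniform
proposals in `ln V` (half-width 0.02) accepted with
`min(1, exp(-beta [dU + P dV + d eta] + (N+1) d ln V))`; whether the
original acceptance folds the barostat into the HMC rule is ambiguous in
the text, and the separate-move reading is implemented. Rejected moves
restore the previous state exactly.

`reconstruct_barrier()` removes the bias:
`beta dG(n) = -ln P_biased(n) - beta eta(n) + const`, minimum set to
zero; empty interior bins up to 5 wide are interpolated and flagged,
wider gaps raise an error (the landscape was not bridged). Validation is
a round trip on a 1-D surrogate: Metropolis sampling of
`exp(-betaG - beta eta)` over a 16 kBT CNT profile recovers the input
within 0.2 kBT at 10⁶ moves, with the error decreasing in the number of
moves. HMC itself is checked against the canonical distribution of a 3-D
harmonic well (`U/kBT ~ Gamma(3/2)` chi-square at alpha = 0.01), using a
spring and step size (50 kcal/mol/Å², dt = 8 fs) stiff enough that
rejections actually occur — at very small steps the acceptance is 1 and
plain Verlet's shadow-Hamiltonian bias goes uncorrected, which is a test
-design trap rather than a sampler property. Volume moves are checked
against the exact NPT ideal-gas mean `(N+1) kB T / P`.

# Synthetic data

`build_lattice()` produces cubic diamond (8-atom cell) and hexagonal
diamond as the wurtzite-topology analogue at ideal `c/a = sqrt(8/3)` in
an orthorhombic cell, at exact target density, with optional Gaussian
noise. `generate_liquid()` performs random insertion with a 2 Å overlap
rejection followed by Langevin equilibration until the potential energy
shows no trend over the trailing half of a round (slope within two
standard errors of zero). The birth–death walk generator uses a
size-independent attachment rate — the simplest process with an exactly
computable MFPT, sufficient to validate estimators and no claim about
mW's true attachment kinetics. The 1-D Metropolis sampler provides
sampler validation entirely without molecular dynamics. What these
surrogates do not emulate: interfacial structure, size-dependent
attachment, and the coupling of density to cluster growth — so passing
the surrogate suite validates the estimators, not the physics of any
particular water model.

# Problem sizes and reproducibility

Every stochastic operation takes a seed, and seeded runs are
bit-reproducible (asserted in the suite). The test suite runs at reduced
scale by design: liquids of N = 216–512, NVT/NVE segments of 2–30 ps,
corpora of a dozen configurations, 150-epoch training, 500-walk
ensembles, 10⁶-move 1-D sampling, and one full diffusion measurement
(N = 216, 250 ps production). The diffusion protocol
(`measure_diffusion()`) is: NPT at the target temperature to find the
ambient density; fix the box at that density; Langevin thermalisation;
momentum zeroing; iterative NVE temperature calibration; 250 ps NVE
production; COM-corrected time-origin-averaged MSD; `6 D t` fit over the
20–120 ps lag window.

# Known limitations

* The Langevin-piston barostat is approximate (no MTK velocity coupling);
  its densities agree with published mW values to ~0.5%, adequate for
  state-point preparation, and the exact isobaric volume-move Monte Carlo
  is available where rigorous NPT sampling matters.
* At the deeply supercooled 218 K state point this implementation's
  self-diffusion coefficient is ~3× the value reported for the reference
  study, despite matching the model's thermodynamic anchors and its
  ~300 K diffusivity; the number is stable against preparation protocol,
  ensemble, thermostat coupling, and multi-ns annealing, and the
  discrepancy remains unattributed (the reference protocol's coupling
  constants are unpublished). The acceptance script reports the honestly
  computed value.
* NNP molecular dynamics is R-level per step (the descriptors and their
  contractions are compiled) and is practical at desk scale only;
  production-scale NNP nucleation runs would need the same loops moved
  into compiled code.
* No Ewald/long-range electrostatics (outside the model family), no
  triclinic boxes, no multi-species support, no multi-window umbrella
  sampling or WHAM.
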