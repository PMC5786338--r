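# ribotasep

Stochastic modeling and inference of mRNA translation dynamics from
ribosome profiling.

Ribosome profiling reports, for each codon of a transcript, how many
ribosome-protected footprints mapped there — a marginal density that
mixes decoding speed, initiation flux, and queueing between ribosomes,
and that silently drops closely stacked ribosomes whose joint footprint
is too long for the standard size selection. `ribotasep` is for
computational biologists who want to turn such profiles into
interpretable kinetic parameters and to study what shapes elongation
speed along the ORF.

## The model

Translation is modeled as an inhomogeneous totally asymmetric simple
exclusion process (TASEP) with extended particles. A transcript of L
codons carries ribosomes identified by their A-site position; each
ribosome occupies ℓ = 10 codons (30 nt, A-site at codon 6 of the
footprint):

- **initiation** — a ribosome enters with its A-site at codon 2 at
  exponential rate α, provided no other A-site lies within ℓ codons;
- **elongation** — a ribosome at codon *i* hops to *i* + 1 at rate
  λᵢ, conditioned on the next ribosome's A-site being beyond *i* + ℓ;
- **termination** — at the stop codon it unbinds at rate λ_L,
  producing one protein (the flux *J*);
- **detection** — two ribosomes whose A-sites are ≤ 12 codons apart
  are "closely stacked" and are detected with scenario probability
  1, 0.5 or 0 when footprint profiles are sampled;
- **drop-off** (optional) — each completed elongation step is followed
  by premature unbinding with probability *r*.

The simulator uses the next reaction method (exact exponential clocks,
suspended while blocked) and samples steady-state snapshots at
Poisson-distributed times, so occupancies are unbiased estimates of the
continuous-time stationary law; an exact master-equation solver
(`exact_steady_state()`) serves as an oracle for small systems.

Inference (`infer_gene()`) reverses the model: per-position rates are
first approximated by the inverse footprint counts (exact without
interference), the initiation rate is found by a simulation-based
search matching the detected density derived from translation
efficiency (TE = footprint RPKM / mRNA RPKM, calibrated against
polysome densities by `fit_te_scaling()`), "error-sites" where
simulation and experiment disagree are corrected by joint local
optimization, and the global scale — otherwise unidentifiable — is
fixed so the simulated mean speed between codon 150 and the stop codon
is 5.6 codons/s.

Downstream analyses: metagene ramp and codon-group curves, observed
versus unobstructed rate gaps (the footprint of ribosomal
interference), the positional linear model
yᵢ = Σₖ βₖ xᵢ,ₖ + ε of mean elongation-rate deviations with windowed
nascent-chain covariates (charge counts, Kyte–Doolittle hydropathy,
PARS scores) and exhaustive window scanning, exit-tunnel entropic
(S(x) = ln π r(x)²) and Coulomb potentials, and drop-off estimation by
binned exponential decay (A e^(−QX), r = 1 − e^(−Q/bin)).

## Worked example

Generate a synthetic gene set (codon-dependent rates, 5' ramp,
positional rate variation, lognormal initiation rates), sample a deep
footprint profile under the no-detection scenario, and re-infer the
rates:

```r
library(ribotasep)

scen <- detection_scenario(detect_prob = 0)   # stacked ribosomes undetected
spec <- synth_spec(n_genes = 3, length = 300, seed = 42)
genes <- generate_gene_set(spec)
prof  <- generate_profiles(genes, scen, sim_config(n_samples = 1e5, seed = 42))

fit <- infer_gene(prof$profiles[[1]], genes[[1]]$model$codons,
                  te = prof$te$te[1], te_scaling = 0.83,
                  scenario = scen, seed = 1)
fit
#> <tasep_fit> gene: alpha = 0.09245, 0 error site(s), 0 correction(s), converged: TRUE
fit$model
#> <gene_model> gene: L = 300 codons, alpha = 0.09245, footprint = 10
#>   lambda: mean 9.57, range [0.905, 47.3]
```

The fitted initiation rate of 0.0925 s⁻¹ (≈ 11 s between initiation
events) recovers the generating value within a few percent, with no
error-site corrections needed in this interference-light regime.
Re-simulating the fitted model closes the loop:

```r
sim <- simulate_tasep(fit$model, sim_config(n_samples = 3e4, seed = 2,
                                            detect_prob = 0))
round(region_speed(sim, from = 150), 2)     # calibrated translation speed
#> [1] 5.62
round(100 * sim$rho_detected, 2)            # detected ribosomes / 100 codons
#> [1] 1.32
round(prof$te$te[1] / 0.83, 2)              # TE-derived target density
#> [1] 1.31
```

Drop-off arithmetic works standalone:

```r
q_to_rate(0.048, bin_size = 25)       # per-bin decay -> per-codon rate
#> [1] 0.001918158
dropoff_survival(0.002, n_codons = 200)
#> [1] 0.6700516
```

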