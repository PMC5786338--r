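---
title: "Modeling and inferring translation dynamics with ribotasep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inferring translation dynamics with ribotasep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotasep)
```

## The process being modeled

`ribotasep` treats a translating mRNA as a one-dimensional exclusion
process with extended particles. A ribosome is represented solely by
the codon index of its A-site; it physically covers ten codons (30 nt),
five upstream and four downstream of the A-site. Initiation places an
A-site at codon 2 at exponential rate $\alpha$ whenever no other A-site
lies within the footprint length $\ell = 10$ of that position (a
footprint overhanging the 5' end imposes no constraint); elongation
moves the A-site from $i$ to $i+1$ at rate $\lambda_i$ provided the
next A-site downstream is beyond $i + \ell$; at the stop codon $L$ the
ribosome unbinds at rate $\lambda_L$, and each unbinding counts toward
the protein production flux $J$. All waiting times are exponential, so
the whole system is a continuous-time Markov jump process.

Two ribosomes whose A-sites sit within 12 codons of one another (a free
gap of at most two codons) are *closely stacked*: their joint protected
fragment is too long for the standard footprint size selection, so a
detection scenario assigns each stacked ribosome an independent
detection probability (1, 0.5 or 0); isolated ribosomes are always
detected. The package defaults to the no-detection scenario, the
variant that best reproduces the relation between translation
efficiency and polysome-measured densities in yeast. Optionally, every
completed elongation step is followed by premature unbinding
(drop-off) with probability $r$.

### Assumptions worth stating

- one mRNA copy per simulation; no shared ribosome pool across genes;
- rates are position-specific but time-homogeneous (steady state);
- exclusion is the only interaction; no codon-level nucleotide
  dynamics or tRNA diffusion;
- detection failures are independent per ribosome and per snapshot.

## Simulation and sampling

The simulator (`simulate_tasep()`, C++ core) uses the next reaction
method. Each ribosome carries one pending event time; a blocked
ribosome's clock is suspended and redrawn when it unblocks, which is
exact for exponential clocks. After a burn-in counted in reaction
events (default $10^4$), snapshots of all A-site positions are
recorded until `n_samples` (default $3\times10^4$) exist.

One numerical choice deserves emphasis: snapshots are taken at
Poisson-distributed *times*, with mean spacing equal to
`sample_interval` (default 50) mean inter-event times measured during
burn-in. Sampling the state every $N$ reaction events would draw from
the embedded jump chain, which over-weights configurations with high
total event rate and is measurably biased — on a two-site system it can
return occupancy 0 for a site that is occupied half the time, by a
parity artifact. Poisson sampling instants see time averages, so the
snapshot occupancies converge to the continuous-time stationary law;
this is verified in the test suite against `exact_steady_state()`, a
full master-equation solve over all admissible ribosome configurations
(feasible up to a few thousand states; the state count is checked
first).

Dwell times are logged per event (entry and exit time of each A-site
position), not from snapshots, so *observed rates* — the inverse mean
time at a position, including time spent blocked — are unbiased. The
difference between $\lambda_i$ (the *unobstructed* rate) and the
observed rate is the per-position signature of ribosomal interference;
`interference_prob` reports how often a ribosome co-occurs with a
trailing neighbour at the minimal distance $\ell$.

## Inference

`infer_gene()` estimates $(\alpha, \lambda_1..\lambda_L)$ from one
experimental profile plus a TE-derived target density:

1. **Naive rates.** Without interference the steady-state A-site
   density is proportional to $\alpha/\lambda_i$, so
   $\lambda_i \propto 1/p(i)$. Rates are expressed in units where the
   mean finite naive rate is 10; zero-count sites get the cap
   $\lambda_{\max} = 50$ (five times the mean) — such sites are
   unidentifiable from data and the cap keeps them from dominating.
2. **Initiation search.** The detected density rises with $\alpha$
   until the transcript jams; under partial/no detection it then
   *falls*, because jammed ribosomes are stacked and invisible. The
   search therefore expands a geometric bracket along the rising branch
   only, then bisects on the log scale to relative tolerance
   `alpha_tol` (2%), using one common seed for all evaluations so the
   stochastic objective behaves quasi-deterministically. Targets above
   the reachable peak are reported as non-convergent with the
   best-achieving rate (such profiles — high mean density combined with
   tall peaks — are physically unrepresentable, and real data contain
   them).
3. **Error-site correction.** The fitted model is simulated; positions
   where the normalized simulated and experimental profiles differ by
   more than a threshold are flagged, 5'-most first, and $\alpha$
   together with the rates within ±2 codons of the site are jointly
   re-optimized (Nelder–Mead on log rates, common random numbers,
   bounded iterations). After an accepted correction, flagging resumes
   strictly downstream. The default threshold is $0.3/L$ (30% of the
   gene's mean normalized density) raised per site to four standard
   errors of the counting noise implied by the two profiles' depths;
   without that floor, finite simulated profiles would flag pure
   sampling fluctuations at high-occupancy sites. A scalar threshold
   can be supplied instead.
4. **Normalization.** Occupancies and profiles are invariant under a
   common scaling of all rates, so the absolute scale must be imposed:
   all rates are multiplied by one constant such that the simulated
   mean observed speed between codon 150 and the stop codon equals
   5.6 codons/s. "Mean speed" is the region length divided by the
   summed mean dwell times — the speed of an actual transit, dominated
   by slow sites as a ribosome is. Genes must exceed 200 codons so the
   calibration region avoids the 5' ramp.

Because of the scale invariance, recovery experiments must fix the
gauge before comparing: the test suite normalizes inferred models to
the *true* model's measured region speed and then compares $\alpha$ and
$\lambda$ directly.

## The synthetic data generator

`synth_spec()`/`generate_gene_set()` define the study conditions the
package is validated under; they are fixed choices, not tuning knobs:

- **codon base rates** (`default_codon_rates()`): the 61 sense codons
  in five groups of 4/13/13/16/15 codons with rates spread across
  [4,6), [6,8), [8,10), [10,12) and [12,14) codons/s, emulating the
  reported distribution of codon-specific mean elongation rates in
  yeast; assignment to codons is deterministic.
- **5' ramp**: a multiplier rising linearly from 0.85 at codon 1 to 1
  at codon 200 — the ~2 codons/s speed increase over the ramp region.
- **positional noise**: mean-one lognormal with `sdlog = 0.7`,
  standing in for the sequence-context modulation (nascent-chain
  charge, hydropathy, mRNA structure) that the feature regression
  later models. This spread also makes the transit speed of the late
  ORF land near the 5.6 codons/s calibration while per-codon mean
  rates average ~10 codons/s, as in the data — slow sites dominate
  transit time. The multiplier is winsorised at ±2 log-sd: per-site
  rates beyond roughly 1–40 codons/s are physiologically implausible
  and, at the high end, leave essentially no footprints, so no finite
  profile could constrain them.
- **initiation rates**: lognormal with median 0.1 s⁻¹ (`sdlog` 0.3),
  i.e. a 10 s median time between initiations spanning roughly
  5–20 s — the regime where initiation, not elongation, limits flux.
- **termination**: 2 s⁻¹ at the stop codon; termination is not fast,
  and a slow stop codon reproduces the queueing signature one
  footprint upstream.
- **profile depth**: `generate_profiles()` samples $10^5$ footprints
  per gene by default (~330 per codon for a 300-codon gene), the
  deep-coverage tier of genes passing the >10 reads/codon selection.
  One footprint per profile is drawn per snapshot — uniformly among
  detected ribosomes for the detected profile, among all for the total
  profile.
- **TE**: detected density per 100 codons times 0.83, closing the loop
  with `fit_te_scaling()`.

What the generator does *not* emulate: sequencing errors and mapping
biases, nuclease footprint-length distributions, codon-usage
correlation structure along real genes, and gene-length variation
within a batch (lengths are set per spec). Passing tests therefore
demonstrate correctness of the machinery under the model's own
assumptions, not robustness to protocol artifacts in real libraries.

## Feature regression and window scanning

The dependent variable is the positional mean deviation
$y_i = \langle \lambda_i^g - \bar\lambda_{c(g,i)} \rangle_g$ of
inferred rates from codon-type means. Covariates are windowed
aggregates per A-site $i$: counts of K/R (positive) and D/E (negative)
residues over an upstream window $[a\!:\!b]$ (codons $i-b..i-a$,
inclusive ends, truncated at the ORF start; an empty truncated window
counts 0), mean Kyte–Doolittle hydropathy upstream, and mean per-codon
PARS score (average of the codon's three nucleotide scores) over a
downstream window. Fits are ordinary least squares with an intercept —
the deviations need not be mean-zero over a sub-region, and the
intercept is reported separately. `scan_windows()` searches all
windows with $a \in [0, 15]$, $b \in [a, 45]$: one- and two-feature
scans are exhaustive (reduced to correlation algebra, so the full
two-feature grid of ~380k pairs costs seconds), three or more features
use coordinate ascent on the same grids. Ties within $10^{-9}$ of the
best $R^2$ go to the smaller window. Charge covariates are raw counts,
not per-length densities; the distinction is absorbed by the
coefficient.

## Tunnel biophysics

The exit-tunnel centerline is fitted by total least squares (first
principal axis); its $R^2$ is the explained-variance fraction, and arc
coordinates are projections with the peptidyl transferase center at 0.
The entropic potential of the one-dimensional (Fick–Jacobs) reduction
is $S(x) = \ln(\pi r(x)^2)$; the electrostatic potential is the bare
Coulomb sum $V(x) = \sum_j q_j / d_j$ over charges within 20 Å of the
evaluation point (the per-point reading of "within a radius of the
tunnel center", which keeps $V$ local), prefactor 1 — the solvent
inside the tunnel is too heterogeneous for a meaningful dielectric
constant, so the potential is in arbitrary units and only signs and
shapes are interpreted. Charges are ±1 e on one representative atom
per charged group (P; LYS NZ, ARG CZ; ASP CG, GLU CD), histidine
neutral at physiological pH. Gradients are central finite differences
on the (possibly non-uniform) arc grid, smoothed by a 10 Å moving
average truncated at the ends; charges coinciding with a centerline
point are excluded with a warning.

## Drop-off estimation

Per-gene profiles normalized by their own mean are pooled into 25-codon
bins; the log bin means are fitted by OLS against the 1-based bin index
(the indexing base affects only the amplitude $A$, never the decay
$Q$), and the per-codon drop-off probability follows from compounding:
$(1-r)^{25} = e^{-Q}$. A bootstrap over genes supplies the sampling
distribution of $Q$. Note the conversion gives $r = 0.00192$ for
$Q = 0.048$, which rounds to the 0.002 conventionally quoted at one
significant figure; the package reports full precision.

## Numerical choices and degenerate inputs

- Snapshot spacing (50 events' worth of time) trades decorrelation
  against runtime; standard errors in tests use batch means, which are
  robust to residual autocorrelation.
- Problem sizes in the test suite (20 genes of 300 codons, $10^5$
  footprints, $3\times10^4$ snapshots) mirror the simulation protocol
  while keeping a full run under a minute on one core.
- `exact_steady_state()` refuses state spaces above a guard (default
  $2\times10^4$ configurations) with a size estimate computed by
  dynamic programming before any enumeration.
- Empty snapshot streams yield empty profiles with a warning; all-zero
  profiles, non-positive rates, unsorted A-sites, and length mismatches
  are rejected with errors.
- Never-visited positions have `NA` observed rates (missing, not
  zero); metagene operators carry per-position support counts and
  truncate smoothing windows at sequence ends rather than fabricating
  data.

## Known limitations

- Elongation rates at footprint-free sites are reported at the cap, a
  convention rather than an estimate.
- The correction loop optimizes locally; overlapping error-sites
  closer than the correction window can interact, and profiles that are
  physically unrepresentable under the exclusion dynamics stay
  unresolved (they are flagged, not dropped).
- The detected-density search assumes a single rising branch; rate
  landscapes engineered with several jamming transitions could defeat
  the bracket heuristic.
- No multi-gene joint fitting (shared codon parameters) and no
  nonlinear or interaction terms in the feature model.
- The Coulomb sum is not a Poisson–Boltzmann solution; it supports
  qualitative statements about field direction only.
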