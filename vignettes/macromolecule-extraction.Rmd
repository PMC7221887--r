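---
title: "Extracting macromolecular signal profiles from conventional 1H NMR spectra"
author: "macrosep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting macromolecular signal profiles from conventional 1H NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional 1D ^1^H-NMR spectra of complex biological mixtures — muscle
extracts, biofluids, food matrices — are dominated by sharp, high-intensity
signals from small-molecule metabolites.  Soluble macromolecules (lipid
assemblies, collagen fragments and other polymers) are present in the same
spectra only as broad, low-lying envelopes near the baseline, effectively
masked by the metabolite signal.  Acquiring diffusion-edited spectra, in
which a pulsed-field-gradient filter attenuates fast-diffusing small
molecules, makes the macromolecular envelopes visible — but large legacy
databases consist of conventional spectra only, and re-measuring every
sample is rarely possible.

`macrosep` implements a two-stage strategy around that constraint:

1. **Training stage.** A *small* set of diffusion-edited spectra is bucketed,
   normalized, and resolved into pure macromolecular component spectra by
   multivariate curve resolution–alternating least squares (MCR-ALS).  The
   component count is chosen from a scan of model orders using the relative
   residual sum of squares (RSS) and a per-sample Durbin–Watson (DW)
   diagnostic.  The resulting pure-spectra matrix (k components × buckets)
   is frozen as a reusable component library.
2. **Projection stage.** Every spectrum of a *large* conventional dataset is
   decomposed onto the frozen library by per-sample non-negative least
   squares, yielding a macromolecule distribution matrix (samples ×
   components).  The sharp small-molecule signal is deliberately **not**
   masked or filtered: it simply cannot be explained by broad macromolecular
   spectra and therefore lands in the residual, whose per-sample relative
   norm is reported.

## Model

Both stages rest on the bilinear mixture model implied by the generalized
Lambert–Beer law: a mixture spectrum is a concentration-weighted sum of pure
component spectra,

$$X = A\,B^{\mathsf T} + E,$$

where $X$ (samples × buckets) holds the bucketed spectra, $A \ge 0$ the
per-sample component intensities, $B^{\mathsf T} \ge 0$ the pure component
spectra, and $E$ the residual.  The alternating least-squares loop solves
each factor in turn by non-negative least squares, renormalizes the rows of
$B^{\mathsf T}$ to unit Euclidean norm (folding the scale into $A$), and
stops when the relative RSS change falls below a tolerance.  Non-negativity
of *both* factors is the package default: Lambert–Beer concentrations and
absorption-like spectra are physically non-negative, and the constraint is
what gives the factorization a usable degree of identifiability.  The
constraint set is configurable (`nonneg = c("A", "BT")`, either, or
`character(0)`).

Two conventions resolve the scale and permutation ambiguity of any bilinear
model: unit-norm spectra rows, and components ordered by descending total
concentration (ties broken by the spectrum's maximum-intensity bucket).
Refitting from a returned solution therefore reproduces it.

### Model-order selection

For $k = 1, \dots, k_\max$ the scan fits the best-of-restarts model and
records

* the relative RSS, $100\,\lVert E \rVert_F^2 / \lVert X \rVert_F^2$
  (with $k = 0$, "the data", defined as 100%), and
* the Durbin–Watson statistic
  $\mathrm{DW}(e) = \sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2$
  of every sample's residual row ordered by ascending ppm.

DW is a noise diagnostic: it approaches 0 for a smooth (autocorrelated)
signal and 2 for white noise, with 4 attained by perfect alternation.  A
residual row that still contains smooth structure (DW well below 2) signals
an underfitted model; once the residual is pure noise, adding components
only fits noise.  DW is computed on the *residual* rows — the only reading
under which it can diagnose overfitting as $k$ grows; the extracted
component spectra themselves are smooth at every $k$.

`select_k()` returns the smallest $k$ whose relative RSS falls at or below a
threshold (default 2%).  The DW matrix is attached for inspection, along
with the $k$ at which the per-sample median residual DW first exceeds
$2 - 0.2$, but it does not override the RSS rule: a combined automatic
criterion would be an invention, and practitioners inspect both curves.
One consequence, measured on synthetic data, is worth knowing: a *minor*
component whose share of the variance is near the threshold (e.g. a third
component leaving the 2-component model at RSS ≈ 1–4%) is selected only
about half the time, even when the RSS elbow at the true order is
unambiguous.  The threshold encodes "good enough reconstruction", not
"all resolvable components"; lower it if minor components matter.

The scan enforces *solution nesting*: the best spectra at $k$, padded with
one fresh row, are always among the candidate starts at $k + 1$.  RSS is
therefore non-increasing in $k$ by construction, and the monotone decay of
the RSS curve is a guarantee, not an accident of restarts.

### Initialization and restarts

The first start is deterministic (purest-variables): greedily select $k$
mutually dissimilar high-intensity bucket columns — largest column norm
first, then repeatedly the column minimizing the maximum cosine similarity
to those already chosen — use them as initial concentration profiles, and
lift to spectra by one NNLS solve.  Remaining starts are seeded
uniform-random spectra.  The model with the lowest RSS wins.  Every random
quantity descends from one integer seed; runs are bit-reproducible.

### Numerical notes

* NNLS subproblems are solved on the $k \times k$ Gram system: closed-form
  support enumeration for $k \le 2$, exact vectorized enumeration of all
  $2^k - 1$ supports for $k \le 6$, and a Lawson–Hanson active-set solver
  above that, all behind a fast path that accepts the unconstrained
  normal-equations solution when it is already feasible.  The solvers are
  cross-checked against an independent implementation
  (`pracma::lsqnonneg`) in the test suite.
* The ALS objective decreases monotonically; the package asserts this at
  every iteration.  With the default tolerance (`tol = 1e-8` on the
  relative RSS change) the slow ALS tail usually runs to `max_iter`; a
  tolerance of `1e-7` with 100–200 iterations gives visually identical
  solutions in a fraction of the time and is what the examples and tests
  use at small scale.
* A component whose spectrum collapses to zero during ALS is replaced by a
  random unit row with zero concentration — the objective is unchanged and
  the unit-norm invariant holds.
* Residual rows whose relative norm falls below 1e-6 (the measured ALS
  convergence floor on noiseless data, orders of magnitude below any
  data-driven residual) are numerically perfect fits; their DW entries are
  flagged missing values rather than statistics of rounding error.

## Preprocessing

**Bucketing.** Full-resolution spectra are reduced to half-open fixed-width
chemical-shift intervals, each summarized by its *integral* (trapezoidal
rule with interpolated interval endpoints) — integrals, unlike means, are
conserved under rebinning and make bucketing exactly linear.  The default
grid (0.45–8.20 ppm, 0.05 ppm width) spans 155 intervals; the terminal
interval is dropped by default, giving the conventional 154-column matrix.
Whether published 154-column matrices arise from this terminal-interval
rule or from removal of some unstated region is not documentable; the rule
is explicit and configurable (`drop_terminal`).

**Normalization.** Probabilistic quotient normalization (PQN) divides each
spectrum by its most probable dilution factor: the median, over buckets
where the reference is non-negligible (above $10^{-12} \times$ its
maximum), of the bucket-wise sample/reference quotients.  The reference is
the dataset's element-wise median spectrum; an external reference (e.g. the
training reference applied to a test set) is available, though the default
normalizes the test set against its own median.  No prior total-area
scaling is applied: the quotient step alone removes global scale and is not
biased by a few strongly changing signals the way integral normalization
is.

PQN's validity rests on its own assumption: *most* signals differ between
samples only by dilution.  When that holds, the operation is also
idempotent (and exactly so with a fixed external reference, or on data that
follow the pure dilution model).  On data whose every signal varies
strongly and independently, the quotient median tracks composition rather
than dilution, re-application is no longer a no-op, and each sample is
effectively rescaled by a composition-dependent factor.  This matters for
interpretation of the projection stage: the recovered distribution matrix
is identifiable only up to that per-sample factor, so its values are
*relative* intensities, most meaningful in rank-based, between-group
comparisons — which is how they are summarized.

## The synthetic data generator

No public diffusion-edited/conventional spectral pairs exist at the scale
of interest, so the package ships a generator that emulates the paired
design with known ground truth; it is first-class, tested code, and every
pipeline claim is exercised against it.

Each dataset is built on the 154-bucket grid from $k$ true macromolecule
spectra: sums of broad Gaussian envelopes (σ between 0.05 and 0.3 ppm) at
positions typical of the component class — a lipid-like component with
bands at 0.9, 1.3, 2.0, 2.8, 4.2 and 5.4 ppm (methyl/methylene chains,
glycerol, unsaturated methine) and a collagen-like component at 1.0, 1.7,
2.3, 3.2, 3.9, 4.4 and 7.4 ppm (side chains plus the broad backbone N–H
region).  Sample rows mix these with i.i.d. log-normal(0, 0.5) weights — a
positive, realistically skewed spread for between-specimen variation — and
add:

* a shared set of sharp small-molecule peaks (default 60; σ between 0.005
  and 0.02 ppm) with heavy-tailed heights up to 20× the macromolecule
  maximum, so a few dominant metabolite signals tower over the baseline as
  in a real conventional spectrum while most peaks are modest, each varying
  log-normally (σ = 0.15) per sample;
* a per-sample dilution factor, log-uniform in [1/2, 2];
* additive Gaussian noise at 1% of the mean signal intensity (clamped at
  zero — intensities are non-negative).

The *training* set attenuates the sharp peaks to 2% of their conventional
amplitude — a single attenuation factor standing in for the diffusion
filter, sufficient to reproduce the qualitative contrast the method relies
on (the mean sharp-peak amplitude ratio between the paired sets is 50×).
All values are bucket *integrals* of the underlying Gaussian shapes, so
peaks narrower than a bucket contribute their area, as real bucketing would
have it.  One master seed drives fixed per-stage streams: the training set
is unchanged by a different test-set size.

What the generator does **not** emulate: multiplet structure and
J-coupling, chemical-shift drift between samples, baseline and phase
artifacts, a physical diffusion model, and — importantly — a metabolome
whose *composition* is mostly stable across samples.  Because both planted
macromolecule components vary strongly and independently, the generated
data sit deliberately outside PQN's comfort zone; consequences are
quantified below.

## What passing tests do and do not show

The test suite and the acceptance checks establish, on generated data:

* the structural constants (154 buckets; 82 × 154 and 800 × 154 shapes);
* RSS of the 2-component model of 1%-noise training data far below the 2%
  selection threshold;
* the DW limits (white noise → 2 ± 0.05; smooth signal → < 0.05), checked
  against an independent regression-diagnostic implementation;
* exact agreement of the per-sample NNLS decomposition with a brute-force
  grid-search oracle, and of the internal NNLS solvers with
  `pracma::lsqnonneg`;
* recovery of the true component count in ≥ 90% of seeded replicates for
  one- and two-component mixtures;
* bit-determinism of the full pipeline under a fixed seed.

Two stronger recovery statements do **not** hold at their nominal levels,
for structural reasons worth stating plainly:

* *Spectral accuracy.* With strictly positive mixing weights no sample is
  component-pure, so non-negativity leaves a feasible rotation cone (width
  set by the least-mixed sample, about 15% admixture at these weight
  distributions) within which the RSS is flat; noise parks the ALS solution
  anywhere inside it.  Recovered spectra match the truth at cosine ≈
  0.97–0.999 depending on the seed — high enough for annotation, but not a
  guaranteed 0.99.  This is the classical rotational ambiguity of
  self-modeling curve resolution, not a solver deficiency.
* *Distribution-matrix accuracy.* Because the test set is PQN-normalized
  against its own median, each recovered row is scaled by a
  composition-dependent factor (see above); with independently varying
  components the per-component Spearman correlation against the planted
  weights plateaus around 0.7 even with no interference at all.  On real
  data with a largely stable metabolite background, PQN tracks dilution and
  this ceiling relaxes; on data like the generator's, absolute per-sample
  levels should not be over-read.

Group-level conclusions are robust to both effects, which is why the
projection stage summarizes components with rank-based two-group tests
(Wilcoxon rank-sum by default; Welch's *t* available) and per-group
descriptives.

## Problem sizes and runtime choices

The packaged examples and tests run the scan at `k_max` 3–4 with 2–3
restarts, `max_iter` 100–200 and `tol = 1e-7` on training sets of 20–82
samples; the full acceptance computation fits the 82 × 154 training matrix
with 10 restarts at package defaults.  These sizes resolve everything the
diagnostics need; the defaults (`k_max = 20`, `n_restarts = 10`,
`max_iter = 500`, `tol = 1e-8`) remain available for production scans.

## Known limitations

* No solvent-region masking is built in (none is universally right); pass a
  user-supplied bucket mask upstream if the water region must be excluded.
* The pipeline starts from processed ppm/intensity data: Fourier transform,
  phasing and baseline correction belong to the spectrometer software.
* Spreadsheet ingestion is deliberately replaced by CSV/TSV; convert legacy
  exports before use.
* `select_k`'s fixed RSS threshold is blind to minor components near the
  threshold; inspect the full RSS/DW report rather than trusting the single
  returned number.
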