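---
title: "Models and methods in heatomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in heatomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatomics)
```

heatomics implements the analysis chain for paired transcriptome–
proteome heat-stress time courses of *Chlamydomonas reinhardtii* grown
in turbidostatic photobioreactors, plus the physiological calculators
that accompany such experiments. This vignette is the package's own
account of the models, the tunable parameters, the numerical choices,
and what the synthetic-data tests do and do not demonstrate.

## The experimental design the package assumes

All statistics are organized around a `tc_design`: each sample belongs
to a treatment (`ctrl25`, `heat35`, `heat40`), a phase (`pre_heat`,
`heat`, `recovery`), a time in hours within the phase, and a biological
replicate. The built-in grid (`default_design()`) has one pre-heat
point, eight heat points (0, 0.5, 1, 2, 4, 8, 16, 24 h after reaching
temperature) and six recovery points (0, 2, 4, 8, 24, 48 h after return
to 25 °C), three replicates each. A replicate group is a
(treatment, phase, time) cell; "adjacent time points" always means the
previous and next cell in this phase-ordered sequence, with pre-heat
adjacent to heat 0 h.

## Differential expression

Counts are filtered (≥ 10 reads in ≥ `ceiling(0.1 · n)` samples) and
TPM-normalized using exon-union gene lengths (GFF3 coordinates are
1-based inclusive; internally intervals are treated half-open and
reduced before summing). Each post-pre-heat time point is contrasted
against its treatment's pre-heat group with a negative binomial GLM
(edgeR: common/trended/tagwise dispersion on the six samples of the
contrast, likelihood-ratio test on the group coefficient). The
"mixed-effect" phrasing sometimes attached to such designs adds nothing
at n = 3 exchangeable replicates per group, so a fixed-effect NB
regression per contrast is used. BH correction is applied across genes
*within* each contrast, matching the per-time-point reporting of DEG
counts; a pooled-across-contrasts switch was considered and rejected
because the per-contrast variant is the one the DEG-count figures imply.

A gene is significant only if all three criteria hold: |log2 FC| > 1
(model coefficient), FDR < 0.05, and |mean TPM difference| ≥ 1 on raw
TPM means. The third criterion removes genes whose fold-change is large
only because their absolute abundance is negligible. The reported TPM
means are raw; a 0.01 pseudocount is used only when fold-changes of TPM
are taken for the integration stage.

Calibration on null simulations (2000 genes, no planted effects,
dispersion 0.1) keeps the flagged fraction well under 7 % at every time
point — in practice near zero, because the three-criterion rule is
stricter than the FDR cut alone. Planted 4-fold changes at n = 3 are
recovered with > 80 % power.

## Surprisal-style decomposition

The replicate-averaged `ln(TPM + 1)` matrix (genes × time points, one
treatment) is factored by SVD. The leading component is the baseline
expression state (α = 0); components α = 1..3 are retained as
time-dependent constraints with potentials `λ_α(t) = d_α v_α(t)` and
gene weights `u_iα`, ordered by singular value. `ln(x + 1)` rather than
`ln x` admits zeros after filtering; with ≥ 4 time points required, the
decomposition is well posed, and reconstruction error is non-increasing
in the number of retained components by SVD optimality.

## Proteome normalization, imputation, Dunnett testing

Normalization is median-of-ratios on the completely observed rows: the
reference for such a protein is its geometric mean across samples, a
sample's size factor is the median ratio to the reference, and columns
are divided by their factors. Size factors are defined only up to a
global constant (the geometric-mean reference absorbs scale), which is
why the tests assert factor *ratios* and scale-invariance of the
normalized matrix rather than absolute factors. Normalization and
imputation run independently per heat time course, both because the
label-free batches are independent and because complete rows across a
whole multi-treatment experiment are rare.

Imputation works on log2 intensities with three rules per
protein × replicate group: (i) a partially observed group draws its
missing entries from `Normal(group mean, global sd)`, where the global
sd is the pooled within-group standard deviation over all proteins —
recomputed after normalization; (ii) a wholly missing group whose
adjacent time points contain data receives a k-nearest-neighbour group
mean (k = 3; neighbours must be observed in the query group; distance
is the root-mean-square difference over shared group-mean time points)
and then samples entries as in (i); (iii) a wholly missing group whose
adjacent groups are also empty is left missing — the signal is treated
as genuinely absent rather than interpolated across a gap. The
imputation report lists every originally missing cell with its rule,
value, and neighbour ids, so imputed values are never silently mixed
with observed ones. Because rule (i) deliberately re-adds the global sd,
the per-cell absolute error of imputed values has a noise floor of
roughly `sqrt(2) ×` the replicate noise; the meaningful accuracy measure
is the *bias* of recovered group means, which is near zero (|bias| ≪ 0.2
log2 units on masked-group experiments).

Differential accumulation uses Dunnett's many-to-one procedure on log2
intensities: per protein, every time point versus pre-heat, pooled
within-group variance, and single-step multivariate-t adjustment. For
balanced replicate counts the adjusted p is computed by direct nested
quadrature of the equicorrelated (ρ = 1/2) multivariate-t probability
(vectorized over proteins via a monotone spline on a fine t-grid; exact
`2 pt(−|t|, df)` for a single comparison; Bonferroni tail bound beyond
t = 9). Unbalanced layouts fall back to a seeded Monte-Carlo estimate of
the max-|T| distribution with the exact unbalanced correlation. Proteins
with ambiguous (non-proteotypic) peptides or a missing replicate are
excluded from testing. Null calibration at 5000 proteins, eight
comparisons, n = 3 gives a familywise error of ~0.05 at α = 0.05.

## RMT-thresholded correlation networks

The network stage asks: at what absolute correlation does the
protein–protein correlation matrix stop looking like correlated noise
and start looking like separate modules? Random-matrix theory supplies
the test statistic. For each candidate threshold (0.50–0.99, step 0.01)
sub-threshold entries are zeroed and the eigenvalue spectrum computed.
Degenerate eigenvalues (spacing < 1e−8) are deduplicated, the cumulative
spectral function is unfolded with a cubic smoothing spline of *few*
degrees of freedom (df = 5 — a flexible GCV fit follows the empirical
staircase and collapses all spacings toward 1, mimicking level
repulsion), and the nearest-neighbour spacing distribution is binned at
width 0.25 on [0, 3]. The chosen ρ* is the first threshold at which the
χ² distance to the Poisson law `e^{−s}` drops below the distance to the
Wigner–Dyson surmise `(πs/2) e^{−πs²/4}`. Two caveats that the tests
encode: (a) a *pure-noise* correlation matrix (full-rank Wishart) shows
Wigner-like spacings before thresholding; (b) two genuinely decoupled
blocks are a superposition of independent spectra and show *Poisson*
spacings at every threshold — the scan then correctly transitions
immediately, because the structure is already modular. If the NNSD never
transitions the scan maximum is returned with a `no_transition` flag; a
degenerate spectrum (e.g. the identity) yields `no_signal`.

Modules are communities of the |r| ≥ ρ* graph under greedy modularity
(Louvain, deterministic via a fixed internal seed); singletons are
discarded. A module's eigenvector is the leading principal component of
its members' z-scored time profiles, standardized to zero mean and unit
variance; members negatively correlated with it carry sign −1, and the
global sign is chosen so the mean member correlation is positive.
Entities are assigned to modules by regressing their profile on each
eigenvector (F-test), BH over all entity × module tests, best module
below FDR 0.05. Enrichment expands each entity's annotations to all
ancestor terms, applies the upper-tail hypergeometric test per term
(verified against direct enumeration for universes ≤ 20), and BH within
the module.

## Windowed transcript–protein correlation

Fold-changes versus pre-heat (TPM + 0.01 for transcripts, normalized
intensities for proteins) are averaged within six windows — heat 0–1,
2–8, 16–24 h; recovery 0–2, 4–8, 24–48 h. Identifiers present in both
omics layers form one fold-change pair per window; ambiguous protein
groups are duplicated to singletons so each member gene pairs with its
transcript. Pearson correlations are computed per tree-expanded
functional term (minimum 3 pairs — Pearson is undefined below, and terms
this small carry no distributional information), and the per-window set
of term correlations is smoothed with a Gaussian KDE using Silverman's
bandwidth `0.9 min(sd, IQR/1.34) n^{−1/5}` (floored at 1e−3 for
degenerate spreads). The all-pairs scatter per window reports Pearson r,
the OLS fit of protein on transcript fold-change, and the top-correlated
term.

## Synthetic data: what it emulates and what it does not

`simulate_omics()` is the package's stand-in for a deposited multi-omics
experiment. Counts are negative binomial, `Var = µ + φµ²` with φ = 0.1
by default (typical bulk RNA-seq scale), around means proportional to
library size (1–2 M by default), gene length, and `2^{log2FC}` from
temporal archetypes (early-heat-up, late-heat-up, heat-down,
recovery-up; 5 % of genes each; the acute treatment scaled 1.5×).
Protein log2 fold-changes track transcripts with phase-dependent
coupling: per time point, `pfc = ρ · tfc + sqrt(1 − ρ²) · sd(tfc) · ε`,
with ρ_heat = 0.8 and ρ_recovery = 0.1 by default, so the across-gene
Pearson correlation per window is approximately ρ. The decoupled
component ε is drawn once per gene per *phase*, not per time point: a
protein's deviation from its transcript reflects protein-specific
translation and turnover, which persists over a phase. This persistence
is also what makes planted truths recoverable — i.i.d. per-time-point
deviations would make wholly missing groups unpredictable in principle,
for any imputer. Replicate noise is Gaussian on log2 (sd 0.3);
missingness is 5 % MCAR plus a logistic intensity-dependent MNAR
component (low-abundance proteins drop out more, as in LFQ data); 5 % of
proteins are merged into two-member ambiguous groups.

What the generator does not emulate: circadian structure (deliberately —
the experimental design it mirrors held light constant to suppress it),
batch effects beyond a per-sample loading factor, peptide-level
variance, and correlated gene–gene noise outside the planted archetypes.
Passing tests therefore demonstrate that the *procedures* recover what
was planted under realistic marginal distributions, not that real data
meet these assumptions.

Trace generators follow the models their estimators fit: exponential
OD growth between dilutions at ±8 % of the target density; first-order
exponential decays for ECS (300 ms dark interval) and P700⁺ re-reduction
(5 s); piecewise-constant fluorescence levels; two Gaussian emission
peaks (686/714 nm) for 77 K spectra; log-normal per-cell FACS signals
`background + ploidy · unit` binned into 256 log-spaced bins. Pigment
absorbances come from inverting the (exactly invertible) pigment
equations, so forward evaluation recovers the requested concentrations
to machine precision.

## Numerical choices and degenerate inputs

* Exponential fits use Levenberg–Marquardt (minpack.lm) with log-linear
  initialization, τ bounded to (1e−5, 100) s, and a short ladder of
  fallback starting values; flat or non-decaying segments are errors,
  and a residual RMS more than 3× the first-difference noise estimate
  flags a misfit (e.g. a two-exponential trace forced through a
  single-exponential model).
* Dilution events in OD traces are drops exceeding half the turbidostat
  band within one sampling step; each inter-dilution segment is fitted
  by least squares on log2 OD over the full segment.
* FACS peaks are local maxima of a 5-bin moving average, ranked by true
  topographic prominence (drop to the valley floor toward the nearest
  higher ground); peak positions are histogram modes, not mixture-model
  means. Ploidy ratios must fall within 0.85–1.15 of a power of two to
  be labeled.
* All generators and all stochastic stages take explicit seeds;
  `run_pipeline()` writes the seed and parameters to its log, and
  identical (config, seed) reproduce numeric tables byte for byte.
* Zero-variance cases are handled explicitly: identical Welch groups
  give p = 1, zero-spread KDE inputs floor the bandwidth with a warning,
  degenerate RMT spectra are flagged rather than thresholded.

## Problem sizes used by the test suite

The suite is sized for a single CPU: calibration runs use 2000 null
genes (one time course) and 5000 null proteins; planted-coupling
recovery uses 20 seeds at 800 genes / 400 proteins; RMT checks use
200-entity matrices; Monte-Carlo fit checks use 100 seeds. These sizes
were chosen as the smallest at which the asserted properties are stable
across seeds, and the full suite runs in a few minutes.

## Known limitations

* The DE model is per-contrast NB regression; it does not share
  dispersion information across contrasts or model time as continuous.
* The RMT transition statistic depends on the unfolding bandwidth; the
  df = 5 spline is a convention, and thresholds published for specific
  real datasets are reproducible only with the identical unfolding.
* Dunnett's Monte-Carlo fallback has sampling error ~1/√B (B = 20 000);
  balanced layouts use the deterministic quadrature path.
* Imputed values carry the global sd by construction; downstream users
  who need observed-only analyses can exclude imputed cells via the
  imputation report (`exclude_imputed` in the pipeline config).
* The CLI surface is R itself: the exported functions plus
  `run_pipeline()` cover the simulate/transcriptome/proteome/network/
  integrate stages; no shell wrapper is shipped.
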