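---
title: "Models and methods: protein turnover and proteome aging trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: protein turnover and proteome aging trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoturn)
```

## The measurement problem

When mice are switched to a diet in which leucine is fully replaced by
deuterated (²H₃) leucine, every protein molecule synthesized after the
switch incorporates heavy leucine at its leucine positions. A peptide with
`L` leucines is observed by LC-MS as an isotopologue envelope over
`m = 0..L` heavy leucines (mass steps of 3.0188325 Da per heavy leucine).
Two biological quantities shape this envelope:

* the **fraction newly synthesized** `f` — the proportion of the peptide's
  molecules made after label onset, and
* the **precursor pool enrichment** `p` — the fraction of free leucine
  available for synthesis that is heavy. Recycling of unlabeled amino acids
  from protein breakdown keeps `p` below 1 even on a fully labeled diet, and
  uncorrected estimates of `f` would be biased low.

Pre-existing molecules carry zero heavy leucines; new molecules draw each
leucine heavy independently with probability `p`. The envelope is therefore
the two-component mixture

$$P(m) = (1-f)\,[m=0] + f\binom{L}{m} p^m (1-p)^{L-m}.$$

`theoretical_distribution()` implements this model. We work in
heavy-leucine-count space: the natural ¹³C fine structure is assumed to be
collapsed upstream during envelope integration, which trades fidelity to raw
spectra for a cleanly identifiable two-parameter model.

## Deconvolution and pool estimation

`deconvolve_spectrum()` minimizes the sum of squared differences between the
unit-normalized observed envelope and the mixture model. The objective is
exactly quadratic in `f` at fixed `p`, so `f` is profiled in closed form and
the search reduces to one dimension in `p` (coarse 201-point grid, then
golden-section/Brent refinement to tolerance 1e-10). Tests verify the
optimum against a brute-force 1000 × 1000 grid over `(f, p)`.

At `L = 1` the envelope is a two-point distribution in which `f` and `p`
enter only through their product, so they are not jointly identifiable;
single-leucine peptides are only deconvolved at a fixed `p`. In practice
`estimate_pool_enrichment()` pools all spectra of one sample with `L ≥ 2`
and profiles each spectrum's `f` out, estimating one enrichment per sample.
Per-sample estimation (rather than per peptide or global) matches the
biology — enrichment is a property of an animal's free amino-acid pool at
harvest — and lends the estimate the precision of hundreds of peptides.
The default simulated plateau is 0.5: the dietary label is complete but
diluted roughly half-and-half by recycled unlabeled leucine. A time-rising
pool `p(t) = plateau · (1 − e^{−rate·t})` is available but the default is a
constant plateau, since the labeling model identifies `p` per sample
without assuming a rise law.

### Envelope quality: the turnover score

The turnover score is the cosine similarity between the observed envelope
and its best-fitting theoretical envelope — scale-invariant, 1 exactly at
proportionality, 0 at orthogonality. Measurements with score below 0.98 are
removed by `filter_by_score()`; the cutoff can be re-derived for a dataset
with `derive_score_cutoff()`, which labels a measurement "true" when its
per-peptide enrichment estimate falls within 2 SD of the mean enrichment,
sweeps all observed score thresholds, and returns the threshold maximizing
Youden's J (ties resolved toward the most stringent threshold). One caveat
found during validation and worth knowing: at `L = 2` the two-parameter
model saturates the normalized envelope, so badly corrupted two-channel
envelopes can still score near 1 — the enrichment-outlier labeling, not the
score, is what flags those.

## Turnover kinetics

Under first-order turnover the percent newly synthesized follows
`y(t) = 100 + β₁·e^{αt}` with `α < 0` and `β₁ = −100` for complete
labeling; the half-life is `t½ = ln 2 / (−α)`. `fit_half_life()` solves the
nonlinear least-squares problem by variable projection: `β₁` is linear in
the model, so it is profiled in closed form over a log-spaced grid of `α`
(half-lives 0.05–5000 days), refined by golden-section, then polished with
damped Gauss–Newton until the relative SSE change falls below 1e-10 (at
most 500 iterations). This reaches the same optimum as a standard `nls()`
call with starts `β₁ = −100, α = −ln 2 / median(day)`, but does not fail
with singular gradients on noise-free data and needs no starting values.
Non-convergence is flagged, not raised, and flagged fits are excluded from
medians and comparisons.

Group comparisons linearize the model: `z = ln(100 − y)` equals
`ln(−β₁) + αt`, so equality of turnover rates is the equality of slopes in
an analysis of covariance, `z ~ peptide + day × group`, with peptide as a
blocking factor whenever a protein has more than one peptide. The p-value
is the F-test of the day-by-group interaction. Observations at or above
100 % are clipped to 99.9 before the transform and counted; a group whose
observations are all clipped is rejected as unreliable.

Two numerical notes on this linearization:

* It is exactly calibrated when the error is multiplicative on the
  *unlabeled* fraction `100 − y` — the model under which `z` has additive
  homoscedastic noise. The test suite verifies type-I error at the nominal
  0.05 (2000 null replicates, CV 5 %) under that model.
* When noise instead enters at the envelope level, the propagated error of
  `y` is roughly constant on the percent scale, which the log transform
  turns heteroscedastic across labeling days; the unweighted ANCOVA is then
  mildly anticonservative. Weighting is deliberately not applied — it would
  require a variance model the data do not identify — so p-values under
  strong envelope noise should be read with that caveat.

Benjamini–Hochberg is used wherever q-values are reported, and a
"significant" selection uses a strict `<` threshold.

## Abundance, contrasts, and the shared-denominator trap

Protein relative abundance is the sum of the protein's unique peptides'
total envelope areas per sample (the standard MS1 label-free roll-up); a
peptide missing from a sample is absent from the sum, not zero-imputed.
Group contrasts are `log2` ratios of group means on the linear scale.

Comparing two ratio contrasts that share a term — for example old/young
wild type against young-mCAT/young-wild-type, both over YWT — induces
*spurious correlation*: ratios of independent quantities correlate because
the shared denominator appears in both. `partial_correlation()` controls
the shared term with the first-order partial correlation

$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
{\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}},$$

rank-transformed by default (a Spearman-style partial correlation), with
the p-value from `t = r\sqrt{(n-3)/(1-r^2)}` on `n − 3` df. The test suite
demonstrates the trap: ratios of independent log-normals over a common
denominator show raw Spearman correlation above 0.3 at `n = 2000` while the
partial correlation controlling the log denominator is within ±0.05 of
zero.

Per-pathway association uses Spearman correlations on the protein
intersection (pathways with fewer than 3 shared proteins are skipped), plus
a pooled regression over the union of the top pathways; proteins belonging
to several top pathways are pooled once by default (`dedupe = TRUE`), since
double-counting would overweight multi-pathway proteins — the alternative
is exposed as a flag. Gene-set enrichment is the one-sided hypergeometric
upper tail (Fisher's exact test) against a user-supplied universe, BH
adjusted. Heatmap orderings use agglomerative clustering on Euclidean
distances, complete linkage by default for protein matrices and Ward's
method (`ward.D2`) as the intended option for pathway z-score matrices;
missing entries are imputed by the row mean for the distance computation
only, and the row-centered ("difference from row mean") convention is
available via `center = TRUE`.

## The aging-trajectory index

To condense proteome displacement into one number per group, proteins
significantly changed with age (old vs young wild type; default `P < 0.05`,
with `q < 0.05` selectable — the two conventions coexist in the source
analyses, so both are exposed and neither is silently preferred) are
projected onto the aging axis. For protein *i*,
`a_i = log2(OWT/YWT)` is the aging effect and `d_i = log2(group/YWT)` the
group's displacement; changes in the direction of aging count positive, so

$$\mathrm{index} = 100 \cdot \frac{\mathrm{mean}_i\,
\mathrm{sign}(a_i)\, d_i}{\mathrm{mean}_i\, |a_i|}.$$

Young wild type scores 0 and old wild type 100 *exactly*, for any selection
with a non-degenerate aging effect, and a group constructed at
`YWT + λ(OWT − YWT)` in log space scores `100λ` — both properties are
tested. The projection is computed in log2 space: the source analyses mix
linear fold-change language with signed averaging, and log space is the
only scale on which "opposite direction" is symmetric. The companion
magnitude statistic `wt_aging_magnitude()` is reported on the linear
`max(r, 1/r)` scale (so "a 5.66-fold average aging change" reads as usual),
and proteins lacking a finite ratio in any group are dropped from all
groups so the indices stay comparable.

## The synthetic cohort generator

`simulate_labeling_cohort()` emulates the study design so that every stage
has a test surface with known truth: 4 groups (young/old × wild-type/mCAT),
labeling days 3/7/12/17, 3 animals per group per day (48 samples), group
median half-lives 6.43 (YWT), 5.37 (OWT), 4.86 (YmCAT) and 7.71 (OmCAT)
days — the heart values. Defaults chosen here where the design leaves them
open, with the reasoning:

* **Half-life heterogeneity**: log-normal around the group median,
  log-scale SD 0.45 — reproduces the right-skewed half-life histograms
  typical of tissue proteomes; configurable.
* **Envelope noise**: multiplicative log-normal per isotopologue channel,
  CV 5 % — the standard magnitude for replicate MS1 peak areas.
* **Missingness**: completely at random at rate 5 %. Real missingness is
  partly intensity-dependent; MCAR is deliberate so that estimator checks
  are not confounded by informative dropout, and passing tests therefore do
  not certify behaviour under intensity-dependent missingness.
* **Pool enrichment**: constant plateau 0.5 per sample (see above); a
  rising-pool option exists.
* **Peptides per protein 2–4, leucines per peptide 1–6**, with
  tryptic-looking random sequences whose leucine counts match by
  construction.

`simulate_abundance_matrix()` adds the abundance layer: log-normal baseline
intensities, an "aging subset" (30 % of proteins) receiving a signed log2
shift in OWT, with young mCAT receiving `λ_young` times the shift and old
mCAT `λ_old` times it. The defaults `λ_young = 1, λ_old = 0` encode the
heart pattern — the young mCAT proteome resembles old wild type while old
mCAT resembles young wild type. Effect magnitudes are drawn with
heterogeneity (sdlog 0.5 on fold change minus one) and then rescaled so the
subset's realized mean absolute linear fold change equals the configured
5.66 exactly; the configuration parameter thus *is* the cohort's realized
aging magnitude, and the recovery test exercises the estimator rather than
sampling noise. Per-cell noise is 0.2 log2 units.

What the generator does **not** emulate: raw spectra, retention time and
peak shape, chimeric spectra, natural-isotope fine structure, correlated
peptide-level missingness, and shared-peptide protein inference beyond the
unique-mapping rule. Conclusions from passing tests are about the
statistical machinery, not about instrument-level artifacts.

## Peptide-to-protein mapping and I/O

Mapping is two-tier: exact substring search against the curated (primary)
database; a unique hit assigns the peptide, multiple hits drop it as
ambiguous, and only peptides with *no* primary hit are searched against the
secondary tier under the same rule. Matching is by exact residues —
isoleucine/leucine equivalence is off by default and available as a flag.
An upstream spectrum-match q-value column (`psm_q`), when present in a
peptide table, is filtered at 0.01 on read.

Problem sizes used in the shipped checks — 100 envelopes against a
1000 × 1000 grid, 200-protein cohorts on the 4×4×3 design, 2000-replicate
null calibrations, 2000-point spurious-correlation draws, 120-protein
cohorts across 5 seeds for the median ordering — were chosen as the
smallest sizes at which the sampling error of each check is comfortably
below its assertion band.

## Reproducing the headline numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` recomputes
every quantity above from scratch — solver-versus-grid deviations, pool and
half-life recovery, recovered group medians, ANCOVA null calibration,
spurious-versus-partial correlation, trajectory indices and the aging
magnitude, and the worked Fisher/BH/mapping examples — and writes them as
JSON. All randomness derives from `--seed`.

## Known limitations

* Numeric parity with the original Topograph software is not claimed: the
  mixture and score formulas are reconstructed from their described
  behaviour (range, "closeness", best-match theoretical distribution), not
  from published formulas.
* The kinetic model is single-pool first-order; no delay or two-pool label
  uptake models, and no mixed-effects or Bayesian kinetics.
* ANCOVA p-values are exact only under multiplicative error on the
  unlabeled fraction (see above).
* The index of aging change inherits the instability of small aging
  effects: its denominator is the mean absolute aging effect, so selections
  with near-zero aging change are rejected rather than reported.
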