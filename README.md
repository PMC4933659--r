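# proteoturn

Protein turnover kinetics and proteome aging trajectories from heavy-leucine
(²H₃-leucine) metabolic labeling proteomics.

When an animal is switched to a diet with fully deuterated leucine, newly
synthesized protein incorporates heavy leucine while pre-existing protein
does not. A peptide with `L` leucines is observed as an isotopologue
envelope over `m = 0..L` heavy leucines following the binomial mixture

    P(m) = (1 − f)·[m = 0] + f·C(L, m)·pᵐ·(1 − p)^(L−m)

where `f` is the fraction of the protein pool newly synthesized and `p` is
the precursor pool enrichment (< 1 because of amino-acid recycling).
`proteoturn` implements the downstream analysis of such experiments, for
proteomics researchers studying turnover and for anyone re-analyzing
cross-sectional labeling cohorts:

* **Isotopologue deconvolution** — least-squares estimation of `f` (and `p`)
  per spectrum, per-sample pool-enrichment estimation with per-spectrum `f`
  profiled out, a cosine-similarity *turnover score* for envelope quality,
  ROC-based cutoff derivation (Youden's J) and the ≥ 0.98 score filter.
* **Turnover kinetics** — nonlinear fits of `y = 100 + β₁·e^(αt)` per
  protein and group; half-life `t½ = ln 2/(−α)`; group comparison of rates
  by ANCOVA on `ln(100 − y)` with peptide as a blocking factor; reference
  normalization `log2(t½/t½,ref)`; group medians; Benjamini–Hochberg
  q-values.
* **Abundance contrasts** — MS1 peptide-area roll-up to proteins, log2
  group-contrast ratios, rank-based partial correlations that remove the
  spurious correlation of shared-denominator ratios, per-pathway Spearman
  correlations, hypergeometric (Fisher) gene-set enrichment, and
  hierarchical-clustering leaf orders for heatmaps.
* **Aging-trajectory index** — each group's proteome displacement from
  young wild type expressed as a signed percentage of the old-vs-young
  wild-type aging effect (young WT ≡ 0, old WT ≡ 100 by construction).
* **Synthetic cohort generator** — a four-group (young/old ×
  wild-type/mCAT), 4-day-point, 3-animal labeling cohort with known true
  half-lives, pool enrichments and abundance structure, so the whole
  pipeline is testable without any external data.
* **Two-tier peptide mapping and I/O** — unique substring mapping against a
  curated then a secondary FASTA tier, TSV peptide tables, GMT pathway
  sets, YAML configs, and `run_pipeline()` to chain every stage with a JSON
  run manifest.

## Worked example

```r
library(proteoturn)

cfg    <- default_cohort_config(n_proteins = 60)
cohort <- simulate_labeling_cohort(cfg, seed = 42)
deconv <- deconvolve_table(cohort$spectra, pool = "per-sample")
kept   <- filter_by_score(deconv, cutoff = 0.98)
fits   <- fit_half_lives(kept)
round(summarize_medians(fits), 2)
#> OmCAT   OWT YmCAT   YWT
#>  7.15  5.67  4.63  6.51
```

The recovered group medians reproduce the configured heart ordering
(OmCAT 7.71 > YWT 6.43 > OWT 5.37 > YmCAT 4.86 days, up to sampling noise
at 60 proteins): old wild-type protein half-lives are shorter than young,
while mitochondrial-catalase (mCAT) expression lengthens them in old mice
and shortens them in young mice.

```r
abund <- simulate_abundance_matrix(cfg, seed = 42)
sel   <- select_aging_proteins(aging_abundance_stats(abund))
traj  <- aging_trajectory(abund, sel)
transform(traj, index_percent = round(index_percent, 1))
#>   group index_percent  n
#> 1   YWT           0.0 22
#> 2   OWT         100.0 22
#> 3 YmCAT          98.4 22
#> 4 OmCAT           0.1 22
round(attr(traj, "wt_aging_magnitude"), 2)
#> [1] 4.86
```

The trajectory index condenses abundance changes of the 22 significantly
aging proteins into one number per group: 0 % is the young wild-type state
and 100 % the old wild-type state. The young mCAT proteome sits at ≈ 100 %
(as "aged" as old wild type) while old mCAT sits at ≈ 0 % (as "young" as
young wild type) — the reverse-aging abundance pattern the generator
encodes. The companion magnitude is the mean absolute linear fold change of
those selected proteins from young to old wild type (4.86-fold here; it is
estimated over the p-value-selected set, so it differs from the generator's
configured 5.66 for the true aging subset).

Rate comparisons between groups, with q-values across proteins:

```r
cmp <- compare_groups_table(kept, "YWT", "OWT")
c(tested = nrow(cmp), significant = sum(cmp$q_value < 0.05))
#>      tested significant
#>          60          56
```

`run_pipeline(cfg, seed = 1, out_dir = "run/")` chains all stages and
writes per-stage TSVs plus `manifest.json` with seeds, thresholds and
record counts.

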