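#' Run the full labeling-cohort analysis pipeline
#'
#' Chains every stage on a simulated cohort: simulate -> deconvolve
#' (per-sample pool correction) -> turnover-score filter -> half-life fits
#' -> per-protein ANCOVA group comparisons -> normalization to the reference
#' group -> abundance contrasts -> partial correlations of shared-term
#' ratios -> optional gene-set enrichment -> aging-trajectory indices.
#' Stage outputs are written as TSV under `out_dir` together with a
#' machine-readable JSON manifest (seed, thresholds, record counts at each
#' stage). Any stage error aborts with the stage name.
#'
#' @param config a `sim_config`; see [default_cohort_config()].
#' @param seed integer seed driving both simulators.
#' @param out_dir output directory (created if needed).
#' @param cutoff turnover-score cutoff (study default 0.98).
#' @param ref_group reference group for normalization and trajectories.
#' @param aging_group the old wild-type aging endpoint.
#' @param pathways optional named list of gene sets (see [read_gmt()]) for
#'   Fisher enrichment against the aging selection.
#' @param p_threshold significance threshold for the aging selection.
#' @param use_q select aging proteins on q-values instead of p-values.
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results (`cohort`, `deconv`, `fits`, `medians`, `comparisons`,
#'   `normalized`, `contrasts`, `partial`, `trajectory`, `enrichment`).
#' @export
run_pipeline <- function(config = default_cohort_config(), seed = config$seed,
                         out_dir = tempfile("proteoturn_run_"),
                         cutoff = 0.98, ref_group = "YWT",
                         aging_group = "OWT", pathways = NULL,
                         p_threshold = 0.05, use_q = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  counts <- list()
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }

  cohort <- stage("simulate", simulate_labeling_cohort(config, seed))
  write_peptide_table(cohort$spectra, file.path(out_dir, "peptide_table.tsv"))
  tsv(cohort$truth_halflife, "truth_halflife.tsv")
  tsv(cohort$truth_pool, "truth_pool.tsv")
  counts$samples <- length(unique(cohort$spectra$sample))
  counts$spectra <- nrow(cohort$spectra)

  deconv <- stage("deconvolve",
                  deconvolve_table(cohort$spectra, pool = "per-sample"))
  tsv(deconv, "deconvolution.tsv")
  counts$deconvolved <- nrow(deconv)

  filt <- stage("filter", filter_by_score(deconv, cutoff))
  counts$filtered_out <- attr(filt, "n_removed")
  counts$retained <- nrow(filt)

  fits <- stage("fit", fit_half_lives(filt))
  tsv(fits, "halflife_fits.tsv")
  counts$fits <- nrow(fits)
  counts$fits_converged <- sum(fits$converged)

  medians <- stage("medians", summarize_medians(fits))

  comparisons <- stage("compare", {
    other <- setdiff(config$groups, ref_group)
    do.call(rbind, lapply(other, function(g)
      compare_groups_table(filt, ref_group, g)))
  })
  tsv(comparisons, "group_comparisons.tsv")
  counts$comparisons <- nrow(comparisons)

  normalized <- stage("normalize", normalize_to_reference(fits, ref_group))
  tsv(normalized, "halflife_normalized.tsv")

  amat <- stage("abundance", simulate_abundance_matrix(config, seed))
  # exercise the roll-up path on the peptide table as well
  rollup <- stage("abundance", protein_abundance(cohort$spectra))
  counts$abundance_proteins <- nrow(amat$areas)
  counts$rollup_proteins <- nrow(rollup$areas)

  contrast_list <- list(c(aging_group, ref_group), c("OmCAT", "YmCAT"),
                        c("YmCAT", ref_group), c("OmCAT", aging_group))
  contrast_list <- Filter(function(ct) all(ct %in% config$groups),
                          contrast_list)
  contrasts <- stage("contrast", contrast_ratios(amat, contrast_list))
  tsv(contrasts, "contrast_ratios.tsv")

  partial <- stage("pcor", {
    ywt <- log(.group_mean(amat$areas, amat$groups, ref_group))
    cr <- function(lbl) {
      x <- contrasts[contrasts$contrast == lbl, ]
      stats::setNames(x$log2_ratio, x$protein)
    }
    pairs <- list(
      c(x = "YmCAT/YWT", y = "OWT/YWT", control = ref_group),
      c(x = "OmCAT/OWT", y = "OWT/YWT", control = aging_group))
    lapply(pairs, function(pp) {
      x <- cr(pp[["x"]]); y <- cr(pp[["y"]])
      prot <- intersect(names(x), names(y))
      ctrl <- log(.group_mean(amat$areas, amat$groups,
                              pp[["control"]]))[prot]
      pc <- partial_correlation(x[prot], y[prot], ctrl,
                                controlled_label = pp[["control"]])
      data.frame(x = pp[["x"]], y = pp[["y"]], control = pp[["control"]],
                 r_partial = pc$r_partial, p_value = pc$p_value, n = pc$n)
    })
  })
  tsv(do.call(rbind, partial), "partial_correlations.tsv")

  ag_stats <- stage("aging_stats",
                    aging_abundance_stats(amat, aging_group, ref_group))
  selected <- stage("select",
                    select_aging_proteins(ag_stats, p_threshold, use_q))
  counts$aging_selected <- length(selected)

  trajectory <- stage("trajectory",
                      aging_trajectory(amat, selected, ref_group,
                                       aging_group))
  tsv(trajectory, "trajectory_index.tsv")

  enrichment <- NULL
  if (!is.null(pathways)) {
    enrichment <- stage("enrich",
                        fisher_enrichment(selected, pathways,
                                          rownames(amat$areas)))
    tsv(enrichment, "enrichment.tsv")
  }

  manifest <- list(
    package = "proteoturn",
    version = as.character(utils::packageVersion("proteoturn")),
    seed = as.integer(seed),
    score_cutoff = cutoff,
    p_threshold = p_threshold,
    use_q = use_q,
    reference_group = ref_group,
    aging_group = aging_group,
    counts = counts,
    median_half_life = as.list(medians),
    wt_aging_magnitude = attr(trajectory, "wt_aging_magnitude"),
    trajectory_index = stats::setNames(as.list(trajectory$index_percent),
                                       trajectory$group)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, out_dir = out_dir, cohort = cohort,
                 deconv = deconv, fits = fits, medians = medians,
                 comparisons = comparisons, normalized = normalized,
                 contrasts = contrasts, partial = partial,
                 trajectory = trajectory, enrichment = enrichment))
}
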