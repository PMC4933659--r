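#' Default configuration for the synthetic labeling cohort
#'
#' Builds the study-design configuration used by [simulate_labeling_cohort()]
#' and [simulate_abundance_matrix()]: four treatment groups (young/old
#' wild-type and young/old mCAT), labeling days 3, 7, 12 and 17, three
#' animals per group per day, and group median half-lives matching the
#' heart proteome (OmCAT 7.71 d > YWT 6.43 d > OWT 5.37 d > YmCAT 4.86 d).
#'
#' Protein half-lives are drawn log-normally around the group median with
#' log-scale spread `halflife_spread`. Precursor-pool enrichment per sample
#' is `pool_plateau * (1 - exp(-pool_rise_rate * day))` when
#' `pool_rise_rate > 0`, else constant at `pool_plateau`. Peak areas carry
#' multiplicative log-normal noise with coefficient of variation
#' `envelope_cv`, and whole peptide-sample observations are dropped
#' completely at random with probability `missing_rate`.
#'
#' `abundance_effect` parameterizes the group structure of the simulated
#' abundance matrix: a fraction `frac_aging` of proteins receives a log2
#' shift in old wild-type whose realized mean absolute linear fold change
#' equals `mean_abs_fc`; young and old mCAT receive `lambda_young` and
#' `lambda_old` times that shift (defaults 1 and 0: the young mCAT proteome
#' resembles old wild-type while old mCAT resembles young wild-type).
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range (min, max) of peptides per
#'   protein.
#' @param leucines_per_peptide integer range (min, max) of leucine residues
#'   per peptide; minimum must be >= 1.
#' @param group_median_halflife named numeric vector, days, one per group.
#' @param halflife_spread log-scale SD of protein half-lives about the group
#'   median (dimensionless).
#' @param pool_plateau plateau precursor-pool enrichment, in (0, 1].
#' @param pool_rise_rate per-day rate of pool enrichment rise; 0 means the
#'   pool is at plateau throughout.
#' @param envelope_cv coefficient of variation of multiplicative peak-area
#'   noise.
#' @param missing_rate probability in [0, 1) that a peptide-sample
#'   observation is missing.
#' @param abundance_effect list: `frac_aging`, `mean_abs_fc`, `fc_spread`
#'   (sdlog of fold-change heterogeneity), `lambda_young`, `lambda_old`,
#'   `noise_sd_log2` (per-cell abundance noise, log2 units),
#'   `baseline_meanlog`, `baseline_sdlog` (log-normal baseline intensities).
#' @param seed default random seed echoed into the config.
#'
#' @return an object of class `sim_config` (a named list; see fields above
#'   plus `groups`, `days`, `animals_per_day`).
#' @examples
#' cfg <- default_cohort_config(n_proteins = 10)
#' cfg$group_median_halflife[["OmCAT"]]
#' @export
default_cohort_config <- function(n_proteins = 100,
                                  peptides_per_protein = c(2L, 4L),
                                  leucines_per_peptide = c(1L, 6L),
                                  group_median_halflife = c(
                                    YWT = 6.43, OWT = 5.37,
                                    YmCAT = 4.86, OmCAT = 7.71),
                                  halflife_spread = 0.45,
                                  pool_plateau = 0.5,
                                  pool_rise_rate = 0,
                                  envelope_cv = 0.05,
                                  missing_rate = 0.05,
                                  abundance_effect = list(),
                                  seed = 1L) {
  ab <- utils::modifyList(list(
    frac_aging = 0.3,
    mean_abs_fc = 5.66,
    fc_spread = 0.5,
    lambda_young = 1,
    lambda_old = 0,
    noise_sd_log2 = 0.2,
    baseline_meanlog = log(1e7),
    baseline_sdlog = 1
  ), abundance_effect)
  cfg <- structure(list(
    groups = c("YWT", "OWT", "YmCAT", "OmCAT"),
    days = c(3, 7, 12, 17),
    animals_per_day = 3L,
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    leucines_per_peptide = as.integer(leucines_per_peptide),
    group_median_halflife = group_median_halflife,
    halflife_spread = halflife_spread,
    pool_plateau = pool_plateau,
    pool_rise_rate = pool_rise_rate,
    envelope_cv = envelope_cv,
    missing_rate = missing_rate,
    abundance_effect = ab,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks field types, ranges and cross-field invariants (every group with a
#' configured median half-life appears in `groups`; days strictly
#' increasing; leucine minimum >= 1). Non-finite values are rejected with an
#' error naming the offending field.
#'
#' @param config a `sim_config`.
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config (see default_cohort_config())")
  with(config, {
    if (length(groups) < 1L || anyDuplicated(groups))
      stop("'groups' must be a non-empty set of unique labels")
    if (any(!is.finite(days)) || any(days < 0))
      stop("'days' must be finite non-negative")
    if (is.unsorted(days, strictly = TRUE))
      stop("'days' must be strictly increasing")
    .check_scalar(animals_per_day, "animals_per_day", 1, integer = TRUE)
    .check_scalar(n_proteins, "n_proteins", 1, integer = TRUE)
    if (length(peptides_per_protein) != 2L ||
        peptides_per_protein[1] > peptides_per_protein[2] ||
        peptides_per_protein[1] < 1L)
      stop("'peptides_per_protein' must be an increasing range of ",
           "positive integers")
    if (length(leucines_per_peptide) != 2L ||
        leucines_per_peptide[1] > leucines_per_peptide[2] ||
        leucines_per_peptide[1] < 1L)
      stop("'leucines_per_peptide' min must be >= 1")
    if (!all(groups %in% names(group_median_halflife)) ||
        !all(names(group_median_halflife) %in% groups))
      stop("'group_median_halflife' groups must match 'groups'")
    if (any(!is.finite(group_median_halflife)) ||
        any(group_median_halflife <= 0))
      stop("'group_median_halflife' values must be finite and > 0 days")
    .check_scalar(halflife_spread, "halflife_spread", 0)
    .check_scalar(pool_plateau, "pool_plateau", 0, 1, allow_lower = FALSE)
    .check_scalar(pool_rise_rate, "pool_rise_rate", 0)
    .check_scalar(envelope_cv, "envelope_cv", 0)
    .check_scalar(missing_rate, "missing_rate", 0, 1, allow_upper = FALSE)
    for (fld in c("frac_aging", "mean_abs_fc", "fc_spread", "lambda_young",
                  "lambda_old", "noise_sd_log2", "baseline_sdlog")) {
      .check_scalar(abundance_effect[[fld]],
                    paste0("abundance_effect$", fld))
    }
    if (abundance_effect$mean_abs_fc < 1)
      stop("'abundance_effect$mean_abs_fc' must be >= 1")
  })
  invisible(config)
}

#' Read / write a simulation configuration as YAML
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$group_median_halflife <- as.list(out$group_median_halflife)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$group_median_halflife <- unlist(raw$group_median_halflife)
  raw$groups <- as.character(raw$groups)
  cfg <- structure(raw, class = "sim_config")
  validate_config(cfg)
  cfg
}
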