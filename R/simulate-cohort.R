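#' Simulate a heavy-leucine labeling cohort with known ground truth
#'
#' Generates peptide-level isotopologue envelopes for a cross-sectional
#' labeling design: for every protein and group a half-life is drawn
#' log-normally about the configured group median; each sample (group x day
#' x animal) gets a precursor-pool enrichment; each peptide-sample envelope
#' is the binomial mixture `theoretical_distribution(L, f, p)` with
#' `f = 1 - exp(-day * log(2) / halflife)`, scaled by a peptide-specific
#' ionization factor, with multiplicative log-normal noise of the configured
#' CV, and dropped completely at random with probability `missing_rate`.
#'
#' Identical `(config, seed)` pairs produce identical cohorts.
#'
#' @param config a `sim_config`, see [default_cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `synthetic_cohort`: list with
#'   * `spectra`: data.frame, one row per observed peptide-sample envelope
#'     (columns `peptide, protein, group, sample, day, leucine_count,
#'     area_m0...area_mLmax`, `NA` beyond each peptide's L),
#'   * `truth_halflife`: data.frame (protein, group, half_life),
#'   * `truth_pool`: data.frame (sample, enrichment),
#'   * `config`: the config used.
#' @examples
#' cohort <- simulate_labeling_cohort(default_cohort_config(n_proteins = 5))
#' head(cohort$spectra)
#' @export
simulate_labeling_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  .check_scalar(seed, "seed", integer = TRUE)
  set.seed(as.integer(seed))

  groups <- config$groups
  np <- config$n_proteins
  proteins <- sprintf("P%05d", seq_len(np))

  # per protein x group true half-lives, log-normal about the group median
  hl <- expand.grid(protein = proteins, group = groups,
                    stringsAsFactors = FALSE)
  med <- config$group_median_halflife[hl$group]
  hl$half_life <- exp(log(med) + stats::rnorm(nrow(hl), 0,
                                              config$halflife_spread))

  # peptides: count, leucine content, sequence, ionization factor
  ppp <- config$peptides_per_protein
  n_pep <- sample(seq(ppp[1], ppp[2]), np, replace = TRUE)
  pep_protein <- rep(proteins, n_pep)
  total_pep <- length(pep_protein)
  lpp <- config$leucines_per_peptide
  leu <- sample(seq(lpp[1], lpp[2]), total_pep, replace = TRUE)
  pep_seq <- .random_peptides(total_pep, leu)
  ion <- stats::rlnorm(total_pep, meanlog = log(1e5), sdlog = 1)
  peptides <- data.frame(peptide = pep_seq, protein = pep_protein,
                         leucine_count = leu, ion = ion,
                         stringsAsFactors = FALSE)

  # samples: group x day x animal; per-sample pool enrichment
  samples <- expand.grid(animal = seq_len(config$animals_per_day),
                         day = config$days, group = groups,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_d%02d_r%d", samples$group, samples$day,
                            samples$animal)
  samples$enrichment <- if (config$pool_rise_rate > 0) {
    config$pool_plateau * (1 - exp(-config$pool_rise_rate * samples$day))
  } else {
    rep(config$pool_plateau, nrow(samples))
  }

  # all peptide x sample observations
  obs <- merge(peptides, samples, by = NULL)  # cross join
  key <- paste(obs$protein, obs$group)
  hl_key <- paste(hl$protein, hl$group)
  obs$half_life <- hl$half_life[match(key, hl_key)]
  obs$f_true <- 1 - exp(-obs$day * log(2) / obs$half_life)
  # fixed row order so the RNG stream is reproducible
  obs <- obs[order(obs$peptide, obs$sample), ]

  l_max <- max(obs$leucine_count)
  areas <- matrix(NA_real_, nrow(obs), l_max + 1L,
                  dimnames = list(NULL, paste0("area_m", 0:l_max)))
  s_log <- sqrt(log(1 + config$envelope_cv^2))
  for (L in sort(unique(obs$leucine_count))) {
    idx <- which(obs$leucine_count == L)
    # binomial mixture envelope for every observation with this L
    pm <- vapply(0:L, function(m)
      obs$f_true[idx] * stats::dbinom(m, L, obs$enrichment[idx]),
      numeric(length(idx)))
    pm <- matrix(pm, nrow = length(idx))
    pm[, 1] <- pm[, 1] + (1 - obs$f_true[idx])
    a <- pm * obs$ion[idx]
    if (config$envelope_cv > 0) {
      noise <- matrix(stats::rlnorm(length(a), -s_log^2 / 2, s_log),
                      nrow = nrow(a))
      a <- a * noise
    }
    areas[idx, 1:(L + 1L)] <- a
  }

  keep <- if (config$missing_rate > 0) {
    stats::runif(nrow(obs)) >= config$missing_rate
  } else rep(TRUE, nrow(obs))

  spectra <- cbind(
    obs[keep, c("peptide", "protein", "group", "sample", "day",
                "leucine_count")],
    as.data.frame(areas[keep, , drop = FALSE])
  )
  rownames(spectra) <- NULL

  structure(list(
    spectra = spectra,
    truth_halflife = hl,
    truth_pool = samples[, c("sample", "enrichment")],
    config = config
  ), class = "synthetic_cohort")
}

# random tryptic-looking peptide sequences with a fixed leucine count;
# unique within the cohort
.random_peptides <- function(n, leucine_counts) {
  aa <- setdiff(strsplit("ACDEFGHIKMNPQRSTVWY", "")[[1]], c("K", "R"))
  make_one <- function(L) {
    len <- sample(max(8L, L + 2L):max(20L, L + 4L), 1L)
    body <- sample(aa, len - L - 1L, replace = TRUE)
    res <- sample(c(body, rep("L", L)))
    paste0(paste(res, collapse = ""), sample(c("K", "R"), 1L))
  }
  out <- vapply(leucine_counts, make_one, character(1))
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- vapply(leucine_counts[dup], make_one, character(1))
  }
  out
}

#' Simulate a protein x sample abundance matrix with an aging subset
#'
#' Baseline protein intensities are log-normal. A designated "aging subset"
#' (fraction `frac_aging` of proteins) receives a signed log2 shift in old
#' wild-type relative to young wild-type; drawn shift magnitudes are
#' heterogeneous (sdlog `fc_spread`) and rescaled so the subset's realized
#' mean absolute linear fold change equals `mean_abs_fc` exactly. Young mCAT
#' receives `lambda_young` times the shift and old mCAT `lambda_old` times
#' (defaults 1 and 0: the heart pattern in which young mCAT resembles old
#' wild-type and old mCAT resembles young wild-type). Per-cell log-normal
#' noise of `noise_sd_log2` log2 units is then added.
#'
#' @inheritParams simulate_labeling_cohort
#' @return list of class `synthetic_abundance`:
#'   * `areas`: protein x sample matrix of non-negative intensities,
#'   * `groups`: named character vector mapping sample -> group,
#'   * `truth`: data.frame (protein, is_aging, delta_log2),
#'   * `config`: the config used.
#' @export
simulate_abundance_matrix <- function(config, seed = config$seed) {
  validate_config(config)
  .check_scalar(seed, "seed", integer = TRUE)
  set.seed(as.integer(seed))
  ab <- config$abundance_effect
  np <- config$n_proteins
  proteins <- sprintf("P%05d", seq_len(np))

  samples <- expand.grid(animal = seq_len(config$animals_per_day),
                         day = config$days, group = config$groups,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_d%02d_r%d", samples$group, samples$day,
                            samples$animal)

  baseline <- stats::rlnorm(np, ab$baseline_meanlog, ab$baseline_sdlog)

  n_aging <- max(1L, round(ab$frac_aging * np))
  aging_idx <- sample(np, n_aging)
  delta <- numeric(np)
  if (ab$mean_abs_fc > 1) {
    # heterogeneous |FC|, rescaled so mean(|FC|) hits the configured value
    x <- stats::rlnorm(n_aging, meanlog = -ab$fc_spread^2 / 2,
                       sdlog = ab$fc_spread)
    x <- x * (ab$mean_abs_fc - 1) / mean(x)
    sgn <- sample(c(-1, 1), n_aging, replace = TRUE)
    delta[aging_idx] <- sgn * log2(1 + x)
  } else {
    delta[aging_idx] <- 0
  }

  lambda <- c(YWT = 0, OWT = 1,
              YmCAT = ab$lambda_young, OmCAT = ab$lambda_old)
  extra <- setdiff(config$groups, names(lambda))
  if (length(extra)) lambda[extra] <- 0

  mat <- matrix(0, np, nrow(samples),
                dimnames = list(proteins, samples$sample))
  for (j in seq_len(nrow(samples))) {
    shift <- lambda[[samples$group[j]]] * delta
    mat[, j] <- baseline * 2^shift
  }
  if (ab$noise_sd_log2 > 0) {
    mat <- mat * 2^matrix(stats::rnorm(length(mat), 0, ab$noise_sd_log2),
                          nrow = np)
  }

  structure(list(
    areas = mat,
    groups = stats::setNames(samples$group, samples$sample),
    truth = data.frame(protein = proteins,
                       is_aging = seq_len(np) %in% aging_idx,
                       delta_log2 = delta,
                       stringsAsFactors = FALSE),
    config = config
  ), class = "synthetic_abundance")
}
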