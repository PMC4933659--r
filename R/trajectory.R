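#' Per-protein differential-abundance statistics for the aging contrast
#'
#' Welch two-sample t-tests per protein on log2 abundance between two groups
#' (default old vs young wild-type), with Benjamini-Hochberg q-values. These
#' are the statistics from which the aging protein subset is selected.
#'
#' @param amat an `abundance_matrix`.
#' @param group_a,group_b groups to compare (aging contrast by default).
#' @return data.frame `protein, log2_fc, p_value, q_value`; proteins with
#'   insufficient observations in either group are dropped.
#' @export
aging_abundance_stats <- function(amat, group_a = "OWT", group_b = "YWT") {
  a_cols <- names(amat$groups)[amat$groups == group_a]
  b_cols <- names(amat$groups)[amat$groups == group_b]
  if (length(a_cols) == 0L || length(b_cols) == 0L)
    stop("both groups need at least one sample")
  rows <- lapply(rownames(amat$areas), function(pr) {
    a <- log2(amat$areas[pr, a_cols])
    b <- log2(amat$areas[pr, b_cols])
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) return(NULL)
    data.frame(protein = pr, log2_fc = mean(a) - mean(b),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no protein had enough observations in both groups")
  out$q_value <- adjust_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Select proteins significantly changed with age
#'
#' Proteins passing a strict threshold on the aging p-value (default
#' P < 0.05) or, when `use_q = TRUE`, on the BH q-value (q < 0.05).
#'
#' @param stats data.frame with columns `protein`, `p_value` and (when
#'   `use_q = TRUE`) `q_value`.
#' @param threshold significance threshold, default 0.05.
#' @param use_q threshold the q-value instead of the p-value.
#' @return character vector of selected protein accessions.
#' @export
select_aging_proteins <- function(stats, threshold = 0.05, use_q = FALSE) {
  stopifnot(is.data.frame(stats), "protein" %in% names(stats))
  col <- if (use_q) "q_value" else "p_value"
  if (!col %in% names(stats)) stop(sprintf("column '%s' missing", col))
  sel <- stats$protein[stats[[col]] < threshold]
  if (length(sel) == 0L)
    stop("empty selection: no protein passes the threshold; ",
         "consider relaxing it")
  sel
}

#' Mean absolute linear fold change of wild-type aging
#'
#' For the selected proteins, the per-protein magnitude is
#' `max(r, 1/r)` with `r = mean(OWT) / mean(YWT)`; the statistic is the
#' arithmetic mean of these magnitudes (the scale on which a 5.66-fold
#' average aging change is expressed). Proteins with a zero or non-finite
#' ratio are dropped and counted.
#'
#' @param amat an `abundance_matrix`.
#' @param proteins selected protein accessions.
#' @param aging_group,ref_group numerator and denominator groups.
#' @return list: `magnitude` (mean |fold change|), `n` (proteins used),
#'   `n_dropped`.
#' @export
wt_aging_magnitude <- function(amat, proteins, aging_group = "OWT",
                               ref_group = "YWT") {
  num <- .group_mean(amat$areas, amat$groups, aging_group)[proteins]
  den <- .group_mean(amat$areas, amat$groups, ref_group)[proteins]
  r <- num / den
  ok <- is.finite(r) & r > 0
  mags <- pmax(r[ok], 1 / r[ok])
  list(magnitude = mean(mags), n = sum(ok), n_dropped = sum(!ok))
}

#' Aging-trajectory index of one group
#'
#' Expresses a group's proteome displacement from young wild-type as a
#' signed percentage of the wild-type aging effect. Per selected protein,
#' `d_i = log2(group / YWT)` and `a_i = log2(OWT / YWT)`; changes in the
#' direction of aging count positive (`s_i = sign(a_i) * d_i`) and
#' `index = 100 * mean(s_i) / mean(|a_i|)`. By construction the young
#' wild-type group scores 0 and old wild-type scores 100 on the same
#' protein set.
#'
#' @param group_means,ywt_means,owt_means named per-protein mean abundances
#'   of the scored group, the young-WT reference and the old-WT aging
#'   endpoint.
#' @param proteins selected protein accessions.
#' @return list of class `trajectory_index`: `index_percent`, `n`.
#' @export
trajectory_index <- function(group_means, ywt_means, owt_means, proteins) {
  g <- group_means[proteins]
  yw <- ywt_means[proteins]
  ow <- owt_means[proteins]
  a <- log2(ow / yw)
  d <- log2(g / yw)
  ok <- is.finite(a) & is.finite(d)
  if (!any(ok)) stop("no protein has finite log-ratios for this group")
  a <- a[ok]; d <- d[ok]
  denom <- mean(abs(a))
  if (denom == 0)
    stop("undefined index: the aging effect is degenerate (mean |a| = 0)")
  structure(list(index_percent = 100 * mean(sign(a) * d) / denom,
                 n = sum(ok)),
            class = "trajectory_index")
}

#' Aging-trajectory indices for every group
#'
#' Computes [trajectory_index()] for each group of an abundance matrix over
#' one common protein selection, so the endpoint anchoring (YWT = 0,
#' OWT = 100) holds exactly. Proteins lacking a finite log-ratio in any
#' group are dropped from all groups to keep the sets comparable.
#'
#' @param amat an `abundance_matrix`.
#' @param proteins selected aging proteins (see [select_aging_proteins()]).
#' @param ref_group young wild-type reference (index 0).
#' @param aging_group old wild-type endpoint (index 100).
#' @return data.frame `group, index_percent, n`; attribute
#'   `wt_aging_magnitude` carries the mean absolute linear fold change of
#'   the `aging_group` vs `ref_group` on the same protein set.
#' @export
aging_trajectory <- function(amat, proteins, ref_group = "YWT",
                             aging_group = "OWT") {
  groups <- unique(unname(amat$groups))
  means <- lapply(stats::setNames(groups, groups), function(g)
    .group_mean(amat$areas, amat$groups, g))
  # common finite set across all groups
  keep <- proteins
  for (g in groups) {
    lr <- log2(means[[g]][keep] / means[[ref_group]][keep])
    keep <- keep[is.finite(lr)]
  }
  if (length(keep) == 0L) stop("no protein usable in every group")
  rows <- lapply(groups, function(g) {
    ti <- trajectory_index(means[[g]], means[[ref_group]],
                           means[[aging_group]], keep)
    data.frame(group = g, index_percent = ti$index_percent, n = ti$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "wt_aging_magnitude") <-
    wt_aging_magnitude(amat, keep, aging_group, ref_group)$magnitude
  out
}
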