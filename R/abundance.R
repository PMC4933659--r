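#' Roll peptide areas up to protein-level relative abundance
#'
#' Protein abundance in a sample is the sum of its uniquely mapped peptides'
#' total MS1 envelope areas in that sample. A peptide missing in a sample is
#' absent from the sum (not zero-imputed); the number of such absences is
#' recorded.
#'
#' @param spectra peptide-table data.frame (`peptide`, `protein`, `sample`,
#'   `group`, `area_m0...`).
#' @return list of class `abundance_matrix`: `areas` (protein x sample
#'   matrix, `NA` where no peptide of the protein was observed), `groups`
#'   (named sample -> group map), `n_missing_peptide_obs` (count of absent
#'   peptide-sample pairs among peptides otherwise observed).
#' @export
protein_abundance <- function(spectra) {
  stopifnot(is.data.frame(spectra),
            all(c("peptide", "protein", "sample") %in% names(spectra)))
  am <- .area_matrix(spectra)
  total <- rowSums(am, na.rm = TRUE)
  proteins <- sort(unique(spectra$protein))
  samples <- sort(unique(spectra$sample))
  mat <- matrix(NA_real_, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  agg <- stats::aggregate(total,
                          by = list(protein = spectra$protein,
                                    sample = spectra$sample), FUN = sum)
  mat[cbind(match(agg$protein, proteins), match(agg$sample, samples))] <- agg$x

  groups <- NULL
  if ("group" %in% names(spectra)) {
    first <- !duplicated(spectra$sample)
    groups <- stats::setNames(spectra$group[first], spectra$sample[first])
    groups <- groups[samples]
  }
  n_pep <- length(unique(spectra$peptide))
  n_missing <- n_pep * length(samples) -
    nrow(unique(spectra[, c("peptide", "sample")]))
  structure(list(areas = mat, groups = groups,
                 n_missing_peptide_obs = n_missing),
            class = "abundance_matrix")
}

# per-protein group means of an areas matrix given a sample -> group map
.group_mean <- function(areas, groups, group) {
  cols <- names(groups)[groups == group]
  if (length(cols) == 0L) stop(sprintf("group '%s' has no samples", group))
  rowMeans(areas[, cols, drop = FALSE], na.rm = TRUE)
}

#' Log2 group-contrast ratios of protein abundance
#'
#' For each contrast (numerator group, denominator group), reports per
#' protein `log2(mean(numerator) / mean(denominator))` on the linear scale.
#' Proteins with a zero or non-finite group mean are dropped and counted.
#'
#' @param amat an `abundance_matrix` (or any list with `areas` and `groups`).
#' @param contrasts list of 2-vectors `c(numerator, denominator)`.
#' @return data.frame `contrast, protein, log2_ratio`; attribute
#'   `n_dropped` is a named count of dropped proteins per contrast.
#' @export
contrast_ratios <- function(amat, contrasts) {
  stopifnot(is.list(contrasts), length(contrasts) > 0L)
  dropped <- integer(0)
  rows <- lapply(contrasts, function(ct) {
    stopifnot(length(ct) == 2L)
    num <- .group_mean(amat$areas, amat$groups, ct[1])
    den <- .group_mean(amat$areas, amat$groups, ct[2])
    lr <- log2(num / den)
    ok <- is.finite(lr)
    label <- paste0(ct[1], "/", ct[2])
    dropped[label] <<- sum(!ok)
    data.frame(contrast = label, protein = names(lr)[ok],
               log2_ratio = unname(lr[ok]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' First-order partial correlation controlling a shared variable
#'
#' Computes `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) *
#' (1 - r_yz^2))`, with the p-value from `t = r * sqrt((n - 3) / (1 - r^2))`
#' on `n - 3` degrees of freedom. With `rank_based = TRUE` (the default) all
#' three vectors are rank-transformed first, giving a Spearman-style partial
#' correlation — the appropriate guard against the spurious correlation that
#' arises between ratios sharing a denominator.
#'
#' @param x,y,z equal-length numeric vectors, `n >= 4`.
#' @param rank_based replace values by ranks before correlating.
#' @param controlled_label name of the controlled variable for the report.
#' @return list of class `partial_correlation`: `r_partial`, `p_value`, `n`,
#'   `controlled_variable`, `method`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partial_correlation(x, y, z)$r_partial
#' @export
partial_correlation <- function(x, y, z, rank_based = TRUE,
                                controlled_label = "z") {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y and z must have equal length")
  if (n < 4L) stop("need n >= 4 for a partial correlation")
  if (any(!is.finite(c(x, y, z)))) stop("inputs must be finite")
  if (rank_based) {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("degenerate variance: a vector is constant")
  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, z)
  r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("partial correlation undefined: |r| with the control equals 1")
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 3) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 3)
  }
  structure(list(r_partial = r, p_value = p, n = n,
                 controlled_variable = controlled_label,
                 method = if (rank_based) "spearman" else "pearson"),
            class = "partial_correlation")
}

#' Per-pathway Spearman correlations and a pooled top-pathway regression
#'
#' Correlates two per-protein statistics (e.g. half-life log-ratios of two
#' groups) within each pathway, on the intersection of proteins; pathways
#' with fewer than `min_shared` shared proteins are skipped and logged.
#' Additionally pools the proteins of the `n_top` smallest-p pathways
#' (deduplicated union by default) and reports the pooled Spearman
#' correlation and the ordinary least-squares slope of `y ~ x`.
#'
#' @param x,y named numeric vectors keyed by protein accession.
#' @param pathways named list of accession vectors (see [read_gmt()]).
#' @param min_shared minimum shared proteins per reported pathway.
#' @param n_top number of pathways pooled for the overall regression.
#' @param dedupe pool each protein once even if it belongs to several top
#'   pathways (default) or once per membership.
#' @return list: `per_pathway` (data.frame pathway/n/rho/p_value), `pooled`
#'   (list rho/p_value/slope/n/pathways), `skipped` (character).
#' @export
pathway_correlations <- function(x, y, pathways, min_shared = 3L,
                                 n_top = 10L, dedupe = TRUE) {
  stopifnot(!is.null(names(x)), !is.null(names(y)), is.list(pathways))
  shared <- intersect(names(x), names(y))
  skipped <- character(0)
  rows <- lapply(names(pathways), function(pw) {
    prot <- intersect(pathways[[pw]], shared)
    if (length(prot) < min_shared) {
      skipped <<- c(skipped, pw)
      return(NULL)
    }
    ct <- suppressWarnings(
      stats::cor.test(x[prot], y[prot], method = "spearman", exact = FALSE))
    data.frame(pathway = pw, n = length(prot),
               rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  pooled <- NULL
  if (!is.null(per) && nrow(per) > 0L) {
    top <- per$pathway[order(per$p_value)][seq_len(min(n_top, nrow(per)))]
    prot <- unlist(lapply(pathways[top], intersect, shared),
                   use.names = FALSE)
    if (dedupe) prot <- unique(prot)
    ct <- suppressWarnings(
      stats::cor.test(x[prot], y[prot], method = "spearman", exact = FALSE))
    slope <- unname(stats::coef(stats::lm(y[prot] ~ x[prot]))[2])
    pooled <- list(rho = unname(ct$estimate), p_value = ct$p.value,
                   slope = slope, n = length(prot), pathways = top)
  }
  if (!is.null(per)) rownames(per) <- NULL
  list(per_pathway = per, pooled = pooled, skipped = skipped)
}

#' Gene-set enrichment by the one-sided hypergeometric (Fisher) test
#'
#' For each pathway, the upper-tail probability of observing at least the
#' seen overlap between the significant set and the pathway, given the
#' universe; Benjamini-Hochberg q-values across pathways.
#'
#' @param significant character vector of significant accessions, a subset
#'   of `universe`.
#' @param pathways named list of accession vectors; intersected with the
#'   universe before testing.
#' @param universe character vector of all tested accessions.
#' @return data.frame `pathway, overlap, pathway_size, n_significant,
#'   p_value, q_value`.
#' @examples
#' fisher_enrichment(c("g1", "g2"), list(pw = c("g1", "g2")),
#'                   paste0("g", 1:4))  # p = 1/6
#' @export
fisher_enrichment <- function(significant, pathways, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  significant <- unique(significant)
  if (!all(significant %in% universe))
    stop("'significant' must be a subset of 'universe'")
  n_u <- length(universe)
  n_s <- length(significant)
  rows <- lapply(names(pathways), function(pw) {
    set <- intersect(unique(pathways[[pw]]), universe)
    k <- length(intersect(significant, set))
    p <- stats::phyper(k - 1, length(set), n_u - length(set), n_s,
                       lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, pathway_size = length(set),
               n_significant = n_s, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- adjust_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Hierarchical-clustering leaf order for heatmap rows or columns
#'
#' Agglomerative clustering with Euclidean distance; the linkage method is
#' configurable (`"complete"` is the default used for protein heatmaps;
#' `"ward.D2"` suits pathway z-score heatmaps). Missing entries are imputed
#' by the row mean for the distance computation only. Tie handling is
#' deterministic (lowest index first, the behaviour of [stats::hclust()]).
#'
#' @param mat numeric matrix.
#' @param axis cluster `"rows"` or `"columns"`.
#' @param method linkage method passed to [stats::hclust()].
#' @param center subtract each row's mean first (the "difference from row
#'   mean" heatmap convention).
#' @return integer leaf order (named by dimnames when present).
#' @export
cluster_order <- function(mat, axis = c("rows", "columns"),
                          method = c("complete", "ward.D2", "average",
                                     "single"),
                          center = FALSE) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (center) mat <- mat - rowMeans(mat, na.rm = TRUE)
  if (axis == "columns") mat <- t(mat)
  if (nrow(mat) == 0L) stop("nothing to cluster")
  if (nrow(mat) == 1L) {
    ord <- 1L
    names(ord) <- rownames(mat)
    return(ord)
  }
  all_na <- apply(mat, 1, function(r) all(!is.finite(r)))
  if (any(all_na))
    stop("all-missing row(s): ", paste(which(all_na), collapse = ", "))
  imp <- mat
  for (i in seq_len(nrow(imp))) {
    r <- imp[i, ]
    r[!is.finite(r)] <- mean(r[is.finite(r)])
    imp[i, ] <- r
  }
  hc <- stats::hclust(stats::dist(imp, method = "euclidean"),
                      method = method)
  ord <- hc$order
  names(ord) <- rownames(mat)[ord]
  ord
}
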