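#' Theoretical isotopologue distribution under the binomial labeling model
#'
#' Probability of observing `m` heavy leucines (m = 0..L) in a peptide with
#' `L` leucine residues when a fraction `f` of the protein pool was
#' synthesized after label onset and the precursor pool enrichment is `p`:
#' old molecules carry zero labels, new molecules draw each leucine heavy
#' independently with probability `p`, so
#' `P(m) = (1 - f) * [m == 0] + f * choose(L, m) * p^m * (1 - p)^(L - m)`.
#'
#' @param L integer >= 1, number of leucine residues.
#' @param f fraction newly synthesized, in [0, 1].
#' @param p precursor pool enrichment, in [0, 1].
#' @return numeric probability vector over m = 0..L (sums to 1).
#' @examples
#' theoretical_distribution(2, 0.5, 0.5)  # 0.625 0.250 0.125
#' @export
theoretical_distribution <- function(L, f, p) {
  .check_scalar(L, "L", 1, integer = TRUE)
  .check_scalar(f, "f", 0, 1)
  .check_scalar(p, "p", 0, 1)
  d <- f * stats::dbinom(0:L, L, p)
  d[1] <- d[1] + (1 - f)
  d
}

#' Turnover score: closeness of an observed envelope to a theoretical one
#'
#' Cosine similarity between the observed isotopologue area vector and
#' `theoretical_distribution(L, f, p)`. Scale-invariant; equals 1 exactly
#' when the two are proportional and 0 when orthogonal.
#'
#' @param observed non-negative area vector of length `L + 1`, not all zero.
#' @inheritParams theoretical_distribution
#' @return score in [0, 1].
#' @examples
#' turnover_score(c(0.6, 0.4), 1, 0.4, 0.5)
#' @export
turnover_score <- function(observed, L, f, p) {
  if (length(observed) != L + 1L)
    stop("'observed' must have length L + 1")
  if (any(!is.finite(observed)) || any(observed < 0))
    stop("'observed' areas must be finite and non-negative")
  if (all(observed == 0))
    stop("turnover score undefined for an all-zero envelope")
  th <- theoretical_distribution(L, f, p)
  sum(observed * th) / sqrt(sum(observed^2) * sum(th^2))
}

# least-squares f at fixed p for one (or many) unit-normalized envelopes.
# The objective is quadratic in f: with e0 = (1,0,...,0), B = binomial pmf,
# a = B - e0, c = obs - e0, SSE(f) = |c - f a|^2, so f* = <c,a>/<a,a>
# clamped to [0,1].
.profile_f <- function(obs_mat, L, p) {
  b <- stats::dbinom(0:L, L, p)
  a <- b
  a[1] <- a[1] - 1
  cmat <- obs_mat
  cmat[, 1] <- cmat[, 1] - 1
  denom <- sum(a^2)
  f <- if (denom == 0) rep(0, nrow(obs_mat)) else
    pmin(pmax(as.vector(cmat %*% a) / denom, 0), 1)
  resid <- cmat - outer(f, a)
  list(f = f, ss = rowSums(resid^2))
}

.normalize_envelope <- function(areas) {
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("envelope areas must be finite and non-negative")
  tot <- sum(areas)
  if (tot == 0) stop("cannot deconvolve an all-zero envelope")
  areas / tot
}

# golden-section refinement of a 1-D objective around a coarse-grid minimum
.grid_then_optimize <- function(fun, grid, tol = 1e-10) {
  vals <- vapply(grid, fun, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(list(minimum = lo, objective = vals[i]))
  opt <- stats::optimize(fun, c(lo, hi), tol = tol)
  if (opt$objective <= vals[i]) list(minimum = opt$minimum,
                                     objective = opt$objective)
  else list(minimum = grid[i], objective = vals[i])
}

#' Deconvolve one peptide isotopologue envelope
#'
#' Estimates the fraction newly synthesized `f` (and, unless `p_fixed` is
#' given, the precursor pool enrichment `p`) by least squares between the
#' unit-normalized observed envelope and [theoretical_distribution()]. With
#' `p` free the envelope must have `L >= 2`: at `L = 1` the model is a
#' two-point distribution in which `f` and `p` enter only through their
#' product, so they are not jointly identifiable.
#'
#' @param spectrum either a numeric area vector of length `L + 1`, or a
#'   one-row data.frame in the peptide-table dialect (columns
#'   `leucine_count`, `area_m0...`).
#' @param L integer number of leucines; ignored when `spectrum` is a
#'   data.frame row.
#' @param p_fixed optional pool enrichment in [0, 1]; when supplied only `f`
#'   is estimated.
#' @return list of class `deconv_result`: `fraction_new`, `pool_enrichment`,
#'   `turnover_score`, `residual_ss` (on the normalized scale),
#'   `percent_new = 100 * fraction_new`.
#' @examples
#' env <- theoretical_distribution(3, 0.3, 0.45)
#' deconvolve_spectrum(env, L = 3)
#' @export
deconvolve_spectrum <- function(spectrum, L = NULL, p_fixed = NULL) {
  if (is.data.frame(spectrum)) {
    stopifnot(nrow(spectrum) == 1L)
    L <- spectrum$leucine_count
    areas <- as.numeric(spectrum[1, .area_cols(spectrum)])[seq_len(L + 1L)]
  } else {
    areas <- as.numeric(spectrum)
    if (is.null(L)) L <- length(areas) - 1L
  }
  .check_scalar(L, "L", 1, integer = TRUE)
  if (length(areas) != L + 1L) stop("'spectrum' must have length L + 1")
  obs <- .normalize_envelope(areas)
  obs_mat <- matrix(obs, nrow = 1)

  if (!is.null(p_fixed)) {
    .check_scalar(p_fixed, "p_fixed", 0, 1)
    pr <- .profile_f(obs_mat, L, p_fixed)
    f <- pr$f
    p <- p_fixed
    ss <- pr$ss
  } else {
    if (L < 2L)
      stop("f and p are not jointly identifiable at L = 1; supply p_fixed")
    fun <- function(p) .profile_f(obs_mat, L, p)$ss
    opt <- .grid_then_optimize(fun, seq(0, 1, length.out = 201L))
    p <- opt$minimum
    pr <- .profile_f(obs_mat, L, p)
    f <- pr$f
    ss <- pr$ss
  }
  structure(list(
    fraction_new = unname(f),
    pool_enrichment = unname(p),
    turnover_score = turnover_score(obs, L, f, p),
    residual_ss = unname(ss),
    percent_new = 100 * unname(f)
  ), class = "deconv_result")
}

#' Estimate the precursor pool enrichment of one sample
#'
#' Pools information across all usable spectra of a sample with `L >= 2`
#' leucines: a single enrichment `p` is chosen to minimize the total residual
#' sum of squares, with each spectrum's fraction-new profiled out in closed
#' form.
#'
#' @param spectra data.frame of the sample's rows in the peptide-table
#'   dialect.
#' @return list: `p_hat` (the estimate), `n_spectra` (spectra used).
#' @export
estimate_pool_enrichment <- function(spectra) {
  use <- spectra[spectra$leucine_count >= 2L, , drop = FALSE]
  if (nrow(use) == 0L)
    stop("no spectra with L >= 2 in this sample; ",
         "fix the pool with p_fixed instead")
  am <- .area_matrix(use)
  by_l <- split(seq_len(nrow(use)), use$leucine_count)
  norm_by_l <- lapply(names(by_l), function(l) {
    L <- as.integer(l)
    m <- am[by_l[[l]], seq_len(L + 1L), drop = FALSE]
    t(apply(m, 1, .normalize_envelope))
  })
  names(norm_by_l) <- names(by_l)
  fun <- function(p) {
    tot <- 0
    for (l in names(norm_by_l)) {
      tot <- tot + sum(.profile_f(norm_by_l[[l]], as.integer(l), p)$ss)
    }
    tot
  }
  opt <- .grid_then_optimize(fun, seq(0, 1, length.out = 201L))
  list(p_hat = opt$minimum, n_spectra = nrow(use))
}

#' Deconvolve every spectrum of a peptide table
#'
#' Applies [deconvolve_spectrum()] to each row. With `pool = "per-sample"`
#' (the default) the enrichment is first estimated per sample from all
#' spectra with `L >= 2` via [estimate_pool_enrichment()] and then held
#' fixed for every spectrum of that sample (including single-leucine
#' peptides). `pool = "fixed"` uses the supplied `p_fixed` everywhere;
#' `pool = "free"` fits `(f, p)` per spectrum (rows with `L = 1` get `NA`).
#'
#' @param spectra peptide-table data.frame (see [read_peptide_table()]).
#' @param pool one of `"per-sample"`, `"fixed"`, `"free"`.
#' @param p_fixed enrichment used when `pool = "fixed"`.
#' @return data.frame: the identifying columns of `spectra` plus
#'   `fraction_new`, `pool_enrichment`, `turnover_score`, `residual_ss`,
#'   `percent_new`.
#' @export
deconvolve_table <- function(spectra,
                             pool = c("per-sample", "fixed", "free"),
                             p_fixed = NULL) {
  pool <- match.arg(pool)
  stopifnot(is.data.frame(spectra), nrow(spectra) > 0L)
  am <- .area_matrix(spectra)

  n <- nrow(spectra)
  f <- p <- score <- ss <- rep(NA_real_, n)

  if (pool == "free") {
    for (i in seq_len(n)) {
      L <- spectra$leucine_count[i]
      if (L < 2L) next
      r <- deconvolve_spectrum(am[i, seq_len(L + 1L)], L = L)
      f[i] <- r$fraction_new; p[i] <- r$pool_enrichment
      score[i] <- r$turnover_score; ss[i] <- r$residual_ss
    }
  } else {
    p_of_row <- if (pool == "fixed") {
      .check_scalar(p_fixed, "p_fixed", 0, 1)
      rep(p_fixed, n)
    } else {
      by_sample <- split(seq_len(n), spectra$sample)
      p_hat <- vapply(by_sample, function(idx)
        estimate_pool_enrichment(spectra[idx, , drop = FALSE])$p_hat,
        numeric(1))
      p_hat[spectra$sample]
    }
    for (l in sort(unique(spectra$leucine_count))) {
      idx <- which(spectra$leucine_count == l)
      m <- am[idx, seq_len(l + 1L), drop = FALSE]
      m <- m / rowSums(m)
      for (pp in unique(p_of_row[idx])) {
        sub <- idx[p_of_row[idx] == pp]
        msub <- m[p_of_row[idx] == pp, , drop = FALSE]
        pr <- .profile_f(msub, l, pp)
        f[sub] <- pr$f
        ss[sub] <- pr$ss
        p[sub] <- pp
        th <- theoretical_vectorized(l, pr$f, pp)
        score[sub] <- rowSums(msub * th) /
          sqrt(rowSums(msub^2) * rowSums(th^2))
      }
    }
  }

  id_cols <- intersect(c("peptide", "protein", "group", "sample", "day",
                         "leucine_count"), names(spectra))
  out <- cbind(spectra[, id_cols, drop = FALSE],
               data.frame(fraction_new = f, pool_enrichment = p,
                          turnover_score = score, residual_ss = ss,
                          percent_new = 100 * f))
  rownames(out) <- NULL
  out
}

# rows of theoretical distributions for vectors of f (fixed L, p)
theoretical_vectorized <- function(L, f, p) {
  b <- stats::dbinom(0:L, L, p)
  th <- outer(f, b)
  th[, 1] <- th[, 1] + (1 - f)
  th
}

#' Derive the turnover-score cutoff from an ROC sweep
#'
#' Labels each peptide measurement true-positive when its pool-enrichment
#' estimate falls within `k_sd` standard deviations of the mean enrichment
#' across all measurements, sweeps score thresholds over the observed scores,
#' and returns the threshold maximizing Youden's J = TPR - FPR (ties broken
#' toward the most stringent threshold).
#'
#' @param scores numeric turnover scores in [0, 1].
#' @param enrichment per-measurement pool-enrichment estimates, same length.
#' @param k_sd width of the truth band in standard deviations (default 2).
#' @return list: `cutoff`, `roc` (data.frame threshold/tpr/fpr/youden),
#'   `labels` (logical true-positive flags), `j` (J at the cutoff).
#' @export
derive_score_cutoff <- function(scores, enrichment, k_sd = 2) {
  stopifnot(length(scores) == length(enrichment))
  ok <- is.finite(scores) & is.finite(enrichment)
  scores <- scores[ok]; enrichment <- enrichment[ok]
  if (length(scores) < 10L)
    stop("need at least 10 scored measurements to derive a cutoff")
  mu <- mean(enrichment)
  sdv <- stats::sd(enrichment)
  labels <- abs(enrichment - mu) <= k_sd * sdv
  if (all(labels) || !any(labels))
    stop("degenerate ROC: all measurements carry the same label")
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  j <- tpr - fpr
  best <- max(which(j == max(j)))  # most stringent among ties
  list(cutoff = thr[best],
       roc = data.frame(threshold = thr, tpr = tpr, fpr = fpr, youden = j),
       labels = labels,
       j = j[best])
}

#' Filter deconvolution results by turnover score
#'
#' Retains rows with `turnover_score >= cutoff` (the study default 0.98
#' keeps the boundary) and records how many were removed.
#'
#' @param results data.frame with a `turnover_score` column.
#' @param cutoff score threshold, default 0.98.
#' @return the retained rows; attributes `n_removed` and `cutoff` record the
#'   rejection log.
#' @export
filter_by_score <- function(results, cutoff = 0.98) {
  stopifnot(is.data.frame(results), "turnover_score" %in% names(results))
  keep <- !is.na(results$turnover_score) & results$turnover_score >= cutoff
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "cutoff") <- cutoff
  out
}
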