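#' Fit a first-order labeling curve and half-life for one protein x group
#'
#' Fits `y = 100 + beta1 * exp(alpha * t)` to percent-newly-synthesized
#' observations by nonlinear least squares (alpha < 0, beta1 <= 0 at a valid
#' optimum; for complete labeling beta1 = -100). The optimum is located by
#' variable projection — beta1 is linear in the model so it is profiled in
#' closed form over a log-spaced grid of alpha, refined by golden-section —
#' and polished with damped Gauss-Newton iterations until the relative SSE
#' change drops below 1e-10 (max 500 iterations). The half-life is
#' `log(2) / (-alpha)`.
#'
#' @param observations data.frame with columns `day` and `percent_new`
#'   (optionally `peptide`, used only for the peptide count).
#' @return list of class `halflife_fit`: `alpha` (per day), `beta1`,
#'   `half_life` (days), `se_alpha`, `residual_ss`, `n_obs`, `n_peptides`,
#'   `converged`.
#' @examples
#' d <- data.frame(day = c(3, 7, 12, 17),
#'                 percent_new = 100 * (1 - exp(-c(3, 7, 12, 17) * log(2) / 5)))
#' fit_half_life(d)$half_life
#' @export
fit_half_life <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("day", "percent_new") %in% names(observations)))
  t <- observations$day
  y <- observations$percent_new
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(y) < 3L || length(unique(t)) < 2L)
    stop("insufficient data: need >= 3 observations over >= 2 distinct days")

  # beta1 profiled in closed form at fixed alpha (clamped non-positive)
  prof <- function(alpha) {
    x <- exp(alpha * t)
    b <- min(0, sum((y - 100) * x) / sum(x^2))
    r <- y - 100 - b * x
    list(beta1 = b, ss = sum(r^2))
  }
  hl_grid <- exp(seq(log(0.05), log(5000), length.out = 400L))
  a_grid <- -log(2) / hl_grid
  opt <- .grid_then_optimize(function(a) prof(a)$ss, sort(a_grid),
                             tol = 1e-12)
  alpha <- opt$minimum
  pr <- prof(alpha)
  beta1 <- pr$beta1
  ss <- pr$ss

  # damped Gauss-Newton polish on (alpha, beta1)
  converged <- FALSE
  for (it in seq_len(500L)) {
    x <- exp(alpha * t)
    r <- y - 100 - beta1 * x
    jac <- cbind(-beta1 * t * x, -x)
    step <- tryCatch(qr.solve(jac, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    improved <- FALSE
    for (h in 1:20) {
      a2 <- alpha - lam * step[1]
      b2 <- min(0, beta1 - lam * step[2])
      if (a2 < 0) {
        ss2 <- sum((y - 100 - b2 * exp(a2 * t))^2)
        if (ss2 <= ss) {
          rel <- if (ss > 0) (ss - ss2) / ss else 0
          alpha <- a2; beta1 <- b2; ss <- ss2
          improved <- TRUE
          if (rel < 1e-10) converged <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  if (alpha >= 0 || !is.finite(alpha)) converged <- FALSE

  # standard NLS covariance for the rate
  x <- exp(alpha * t)
  jac <- cbind(-beta1 * t * x, -x)
  se_alpha <- tryCatch({
    dof <- length(y) - 2L
    sigma2 <- if (dof > 0) ss / dof else NA_real_
    sqrt(sigma2 * solve(crossprod(jac))[1, 1])
  }, error = function(e) NA_real_)

  structure(list(
    alpha = alpha,
    beta1 = beta1,
    half_life = log(2) / (-alpha),
    se_alpha = se_alpha,
    residual_ss = ss,
    n_obs = length(y),
    n_peptides = if ("peptide" %in% names(observations))
      length(unique(observations$peptide[ok])) else NA_integer_,
    converged = converged
  ), class = "halflife_fit")
}

#' Fit half-lives for every protein x group of a deconvolution table
#'
#' Splits the table by protein and group and applies [fit_half_life()].
#' Combinations with insufficient data (fewer than 3 observations or a
#' single labeling day) are skipped and counted rather than raised.
#'
#' @param deconv data.frame with columns `protein`, `group`, `day`,
#'   `percent_new` (and optionally `peptide`).
#' @return data.frame, one row per fitted protein x group, with columns
#'   `protein, group, alpha, beta1, half_life, se_alpha, n_obs, n_peptides,
#'   converged`; attribute `n_skipped` counts unfit combinations.
#' @export
fit_half_lives <- function(deconv) {
  stopifnot(is.data.frame(deconv))
  if (nrow(deconv) == 0L)
    stop("insufficient data: no observations to fit")
  parts <- split(deconv, list(deconv$protein, deconv$group), drop = TRUE)
  skipped <- 0L
  rows <- lapply(parts, function(d) {
    if (nrow(d) < 3L || length(unique(d$day)) < 2L) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    ft <- fit_half_life(d)
    data.frame(protein = d$protein[1], group = d$group[1],
               alpha = ft$alpha, beta1 = ft$beta1,
               half_life = ft$half_life, se_alpha = ft$se_alpha,
               n_obs = ft$n_obs, n_peptides = ft$n_peptides,
               converged = ft$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("insufficient data: no protein x group had >= 3 observations ",
         "over >= 2 days")
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Compare turnover slopes between two groups by ANCOVA
#'
#' Linearizes the labeling curve as `z = log(100 - percent_new)` (which is
#' `log(-beta1) + alpha * day` under the first-order model) and fits
#' `z ~ peptide + day * group`, using peptide as a blocking factor when more
#' than one peptide is present. The p-value tests the day-by-group
#' interaction, i.e. equality of the rate constants; `delta_alpha` is the
#' fitted slope difference (group B minus group A). Observations at or above
#' 100 percent are clipped to 99.9 before the transform and counted.
#'
#' @param obs_a,obs_b data.frames with columns `day`, `percent_new` and
#'   optionally `peptide`, one per group.
#' @param label_a,label_b group labels for the report.
#' @return list of class `group_comparison`: `group_a`, `group_b`,
#'   `delta_alpha`, `p_value`, `n_clipped`, `n_obs`.
#' @export
compare_groups_ancova <- function(obs_a, obs_b, label_a = "A",
                                  label_b = "B") {
  check <- function(d) {
    stopifnot(is.data.frame(d), all(c("day", "percent_new") %in% names(d)))
    if (nrow(d) < 3L || length(unique(d$day)) < 2L)
      stop("insufficient data: each group needs >= 3 observations over ",
           ">= 2 distinct days")
    d
  }
  obs_a <- check(obs_a); obs_b <- check(obs_b)
  build <- function(d, g) data.frame(
    day = d$day, y = d$percent_new,
    peptide = if ("peptide" %in% names(d)) as.character(d$peptide) else "pep",
    group = g, stringsAsFactors = FALSE)
  dat <- rbind(build(obs_a, label_a), build(obs_b, label_b))
  clipped <- dat$y >= 100
  if (all(clipped[dat$group == label_a]) || all(clipped[dat$group == label_b]))
    stop("unreliable fit: every observation of one group is at or above ",
         "100 percent new")
  dat$y[clipped] <- 99.9
  dat$z <- log(100 - dat$y)
  dat$group <- factor(dat$group, levels = c(label_a, label_b))
  dat$peptide <- factor(dat$peptide)

  form <- if (nlevels(dat$peptide) > 1L) z ~ peptide + day * group
          else z ~ day * group
  fit <- stats::lm(form, data = dat)
  an <- stats::anova(fit)
  p <- an["day:group", "Pr(>F)"]
  cf <- stats::coef(fit)
  delta <- unname(cf[grep("^day:group", names(cf))])

  structure(list(
    group_a = label_a, group_b = label_b,
    delta_alpha = delta, p_value = p,
    n_clipped = sum(clipped), n_obs = nrow(dat)
  ), class = "group_comparison")
}

#' Per-protein ANCOVA comparison between two groups
#'
#' Runs [compare_groups_ancova()] for every protein present in both groups
#' with enough data, then attaches Benjamini-Hochberg q-values across
#' proteins.
#'
#' @param deconv deconvolution table (`protein`, `group`, `day`,
#'   `percent_new`, optionally `peptide`).
#' @param group_a,group_b the two group labels to compare.
#' @return data.frame: `protein, group_a, group_b, delta_alpha, p_value,
#'   q_value, n_clipped`; attribute `n_skipped`.
#' @export
compare_groups_table <- function(deconv, group_a, group_b) {
  stopifnot(all(c(group_a, group_b) %in% deconv$group))
  skipped <- 0L
  rows <- lapply(split(deconv, deconv$protein), function(d) {
    a <- d[d$group == group_a, , drop = FALSE]
    b <- d[d$group == group_b, , drop = FALSE]
    enough <- function(x) nrow(x) >= 3L && length(unique(x$day)) >= 2L
    if (!enough(a) || !enough(b)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    cmp <- tryCatch(compare_groups_ancova(a, b, group_a, group_b),
                    error = function(e) NULL)
    if (is.null(cmp)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    data.frame(protein = d$protein[1], group_a = group_a, group_b = group_b,
               delta_alpha = cmp$delta_alpha, p_value = cmp$p_value,
               n_clipped = cmp$n_clipped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no protein had sufficient data in both groups")
  out$q_value <- adjust_fdr(out$p_value)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out[, c("protein", "group_a", "group_b", "delta_alpha", "p_value",
          "q_value", "n_clipped")]
}

#' Normalize half-lives to a reference group
#'
#' For each protein, reports `log2(half_life[group] / half_life[reference])`
#' per group. Positive values mean a longer half-life than the reference.
#' Proteins lacking a converged reference fit are dropped and counted.
#'
#' @param fits data.frame from [fit_half_lives()].
#' @param reference_group reference group label (e.g. `"YWT"`).
#' @return data.frame `protein, group, log2_hl_ratio`; attribute
#'   `n_dropped` counts proteins without a converged reference fit.
#' @export
normalize_to_reference <- function(fits, reference_group) {
  stopifnot(is.data.frame(fits))
  if (!reference_group %in% fits$group)
    stop(sprintf("unknown reference group '%s'", reference_group))
  ref <- fits[fits$group == reference_group & fits$converged, ]
  ref_hl <- stats::setNames(ref$half_life, ref$protein)
  use <- fits[fits$converged & fits$protein %in% names(ref_hl), ]
  dropped <- length(setdiff(unique(fits$protein), names(ref_hl)))
  out <- data.frame(
    protein = use$protein, group = use$group,
    log2_hl_ratio = log2(use$half_life / ref_hl[use$protein]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Median half-life per group
#'
#' Medians are taken over converged fits only (even counts use the midpoint
#' of the central pair). Groups with no converged fit are omitted with a
#' warning.
#'
#' @param fits data.frame from [fit_half_lives()].
#' @return named numeric vector, group -> median half-life in days.
#' @export
summarize_medians <- function(fits) {
  stopifnot(is.data.frame(fits))
  conv <- fits[fits$converged, ]
  groups <- unique(fits$group)
  out <- vapply(groups, function(g) {
    hl <- conv$half_life[conv$group == g]
    if (length(hl) == 0L) NA_real_ else stats::median(hl)
  }, numeric(1))
  if (anyNA(out)) {
    warning("groups with zero converged fits omitted: ",
            paste(groups[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; q >= p elementwise and q is
#' monotone along sorted p.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjust_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
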