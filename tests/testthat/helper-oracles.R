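# Independent oracles and small simulation helpers shared across tests.

# Brute-force dense grid search minimizing the same normalized-envelope SSE
# that the solver minimizes; used as the deconvolution oracle. The per-p
# inner minimization over f is an exact algebraic expansion of the SSE on
# the f grid (cross-checked against naive_grid_oracle below).
grid_oracle <- function(obs, L, ngrid = 1000L) {
  obs <- obs / sum(obs)
  fs <- seq(0, 1, length.out = ngrid)
  ps <- seq(0, 1, length.out = ngrid)
  e0 <- c(1, rep(0, L))
  cvec <- obs - e0
  s_cc <- sum(cvec^2)
  best <- c(ss = Inf, f = NA_real_, p = NA_real_)
  for (p in ps) {
    a <- dbinom(0:L, L, p) - e0
    sse <- s_cc - 2 * fs * sum(cvec * a) + fs^2 * sum(a^2)
    i <- which.min(sse)
    if (sse[i] < best["ss"]) best <- c(ss = sse[i], f = fs[i], p = p)
  }
  best
}

# literal double-loop version of the oracle (small grids only)
naive_grid_oracle <- function(obs, L, ngrid = 51L) {
  obs <- obs / sum(obs)
  fs <- seq(0, 1, length.out = ngrid)
  ps <- seq(0, 1, length.out = ngrid)
  best <- c(ss = Inf, f = NA_real_, p = NA_real_)
  for (p in ps) {
    for (f in fs) {
      th <- f * dbinom(0:L, L, p)
      th[1] <- th[1] + (1 - f)
      ss <- sum((obs - th)^2)
      if (ss < best["ss"]) best <- c(ss = ss, f = f, p = p)
    }
  }
  best
}

# binomial-mixture envelope built directly from dbinom (independent of
# theoretical_distribution), optionally scaled and noised
make_envelope <- function(L, f, p, ion = 1, cv = 0) {
  th <- f * dbinom(0:L, L, p)
  th[1] <- th[1] + (1 - f)
  a <- ion * th
  if (cv > 0) {
    s <- sqrt(log(1 + cv^2))
    a <- a * rlnorm(L + 1, -s^2 / 2, s)
  }
  a
}

# labeling-curve observations with multiplicative log-normal error on the
# unlabeled fraction -- the error model under which the log-linearized
# ANCOVA is exactly calibrated
sim_curve_obs <- function(t_half, cv, days = rep(c(3, 7, 12, 17), each = 3),
                          n_pep = 3) {
  s <- sqrt(log(1 + cv^2))
  do.call(rbind, lapply(seq_len(n_pep), function(k) {
    surv <- exp(-days * log(2) / t_half) * rlnorm(length(days), -s^2 / 2, s)
    data.frame(day = days, percent_new = 100 * (1 - surv),
               peptide = paste0("pep", k), stringsAsFactors = FALSE)
  }))
}

# peptide-table rows for a set of envelopes (minimal columns)
envelope_table <- function(envelopes, L, sample = "s1", day = 7,
                           group = "YWT") {
  n <- length(envelopes)
  am <- matrix(NA_real_, n, max(L) + 1L,
               dimnames = list(NULL, paste0("area_m", 0:max(L))))
  for (i in seq_len(n)) am[i, seq_len(L[i] + 1L)] <- envelopes[[i]]
  cbind(data.frame(peptide = paste0("PEP", seq_len(n)),
                   protein = paste0("P", seq_len(n)),
                   group = group, sample = sample, day = day,
                   leucine_count = L, stringsAsFactors = FALSE),
        as.data.frame(am))
}

# hand abundance_matrix construction for trajectory/abundance tests
make_amat <- function(areas, groups) {
  structure(list(areas = areas, groups = groups), class = "abundance_matrix")
}

# abundance matrix with each group displaced by lambda * aging effect in
# log2 space
lambda_amat <- function(lambdas, n = 30, seed = 20) {
  set.seed(seed)
  base <- rlnorm(n, log(1e6), 1)
  delta <- rnorm(n, 0, 1.2)
  groups <- names(lambdas)
  areas <- vapply(groups, function(g) base * 2^(lambdas[[g]] * delta),
                  numeric(n))
  rownames(areas) <- paste0("P", seq_len(n))
  colnames(areas) <- groups
  make_amat(areas, setNames(groups, groups))
}

# explicit hypergeometric upper-tail sum via choose(), the Fisher oracle
hyper_tail_oracle <- function(k, K, N, n) {
  j <- seq(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
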