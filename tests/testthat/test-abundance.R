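test_that("protein roll-up sums unique peptide areas per sample", {
  tab <- envelope_table(list(c(1, 2), c(3, 4), c(2, 3)), c(1L, 1L, 1L))
  tab$protein <- c("PA", "PA", "PB")
  tab2 <- tab; tab2$sample <- "s2"
  tab2 <- tab2[-1, ]  # first peptide of PA missing in s2
  full <- rbind(tab, tab2)
  ab <- protein_abundance(full)
  expect_equal(ab$areas["PA", "s1"], 1 + 2 + 3 + 4)
  expect_equal(ab$areas["PB", "s1"], 5)
  # missing peptide is absent from the sum, not zero-imputed
  expect_equal(ab$areas["PA", "s2"], 7)
  expect_equal(ab$n_missing_peptide_obs, 1L)
  # permuting peptide order changes nothing
  ab2 <- protein_abundance(full[rev(seq_len(nrow(full))), ])
  expect_identical(ab$areas, ab2$areas)
})

test_that("contrast ratios are log2 ratios of group means with drop rules", {
  areas <- rbind(P1 = c(2, 2, 8, 8), P2 = c(4, 4, 4, 4), P3 = c(1, 1, 0, 0))
  colnames(areas) <- paste0("s", 1:4)
  am <- make_amat(areas, setNames(c("A", "A", "B", "B"), paste0("s", 1:4)))
  cr <- contrast_ratios(am, list(c("B", "A")))
  expect_equal(cr$log2_ratio[cr$protein == "P1"], 2)
  expect_equal(cr$log2_ratio[cr$protein == "P2"], 0)
  expect_false("P3" %in% cr$protein)  # log2(0) dropped
  expect_equal(unname(attr(cr, "n_dropped")["B/A"]), 1L)
  # antisymmetry
  rev_cr <- contrast_ratios(am, list(c("A", "B")))
  both <- intersect(cr$protein, rev_cr$protein)
  expect_equal(cr$log2_ratio[match(both, cr$protein)],
               -rev_cr$log2_ratio[match(both, rev_cr$protein)])
  expect_error(contrast_ratios(am, list(c("A", "C"))), "no samples")
})

test_that("partial correlation matches the closed form and its contracts", {
  # r_xy = r_xz = r_yz = 0.5 -> r_partial = 1/3
  expect_equal((0.5 - 0.25) / sqrt(0.75^2), 1 / 3)
  # construct vectors with those exact rank correlations is fiddly; check
  # the closed form directly on raw (non-rank) data instead
  set.seed(16)
  n <- 60
  z <- rnorm(n); x <- z + rnorm(n); y <- z + rnorm(n)
  pc <- partial_correlation(x, y, z, rank_based = FALSE)
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  expect_equal(pc$r_partial,
               (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)))
  tval <- pc$r_partial * sqrt((n - 3) / (1 - pc$r_partial^2))
  expect_equal(pc$p_value, 2 * pt(-abs(tval), n - 3))

  # symmetry in (x, y)
  pc2 <- partial_correlation(y, x, z, rank_based = FALSE)
  expect_equal(pc$r_partial, pc2$r_partial)
  # rank-based version is invariant to positive affine transforms
  pr1 <- partial_correlation(x, y, z)
  pr2 <- partial_correlation(3 * x + 5, 0.2 * y - 1, 10 * z)
  expect_equal(pr1$r_partial, pr2$r_partial)
  # self-correlation with independent control approaches 1
  big <- rnorm(500)
  expect_gt(partial_correlation(big, big + rnorm(500, 0, 1e-6),
                                rnorm(500))$r_partial, 0.99)

  expect_error(partial_correlation(x, y, rep(1, n), rank_based = FALSE),
               "degenerate")
  expect_error(partial_correlation(x, y, x, rank_based = FALSE),
               "undefined")
  expect_error(partial_correlation(1:3, 1:3, 1:3), "n >= 4")
})

test_that("shared denominators induce spurious correlation that the
           partial correlation removes", {
  set.seed(18)
  n <- 600
  a <- rlnorm(n); b <- rlnorm(n); cc <- rlnorm(n)
  u <- log(a / cc); v <- log(b / cc)
  raw <- cor(u, v, method = "spearman")
  expect_gt(raw, 0.3)
  pc <- partial_correlation(u, v, log(cc))
  expect_lt(abs(pc$r_partial), 0.1)
})

test_that("per-pathway Spearman correlations and pooled regression", {
  prot <- paste0("P", 1:10)
  x <- setNames(1:10, prot)
  # exact agreement
  res <- pathway_correlations(x, x, list(pw = prot), n_top = 1)
  expect_equal(res$per_pathway$rho, 1)
  expect_equal(res$pooled$slope, 1)
  # exact reversal
  res2 <- pathway_correlations(x, setNames(-(1:10), prot), list(pw = prot))
  expect_equal(res2$per_pathway$rho, -1)
  # permuting two of ten members: hand Spearman rho = 1 - 6*2/(10*99)
  y <- x; y[c("P1", "P2")] <- x[c("P2", "P1")]
  res3 <- pathway_correlations(x, y, list(pw = prot))
  expect_equal(res3$per_pathway$rho, 1 - 12 / 990, tolerance = 1e-12)
  # small pathways are skipped with a log entry
  res4 <- pathway_correlations(x, y, list(tiny = prot[1:2], pw = prot))
  expect_equal(res4$skipped, "tiny")
  expect_equal(res4$per_pathway$pathway, "pw")
})

test_that("Fisher enrichment equals the hypergeometric tail sum", {
  uni <- paste0("g", 1:4)
  res <- fisher_enrichment(c("g1", "g2"), list(pw = c("g1", "g2")), uni)
  expect_equal(res$p_value, 1 / 6, tolerance = 1e-12)
  # pathway = universe: no enrichment possible
  res2 <- fisher_enrichment(c("g1", "g2"), list(pw = uni), uni)
  expect_equal(res2$p_value, 1)
  # empty overlap when some overlap is expected: p well above 0.5
  set.seed(19)
  uni50 <- paste0("g", 1:50)
  res3 <- fisher_enrichment(uni50[26:50], list(pw = uni50[1:25]), uni50)
  expect_equal(res3$overlap, 0L)
  expect_equal(res3$p_value, hyper_tail_oracle(0, 25, 50, 25))
  expect_gte(res3$p_value, 0.5)
  expect_error(fisher_enrichment("g1", list(pw = "g1"), character(0)),
               "empty universe")
  expect_error(fisher_enrichment("zz", list(pw = "g1"), uni), "subset")
})

test_that("clustering leaf order is deterministic with sane merges", {
  m <- matrix(c(0, 0.1, 10), ncol = 1,
              dimnames = list(c("a", "b", "c"), NULL))
  ord <- cluster_order(m)
  # nearest pair {0, 0.1} merges first, so a and b are adjacent
  pos <- match(c("a", "b"), names(ord))
  expect_equal(abs(diff(pos)), 1)
  # single row is the identity
  expect_equal(unname(cluster_order(m[1, , drop = FALSE])), 1L)
  # duplicate rows merge at distance zero and sit adjacent, matching the
  # hand-built dendrogram on 4 points: {1,3} first, then {2}, then {4}
  m4 <- matrix(c(1, 5, 1, 20), ncol = 1,
               dimnames = list(paste0("r", 1:4), NULL))
  ord4 <- cluster_order(m4)
  pos13 <- match(c("r1", "r3"), names(ord4))
  expect_equal(abs(diff(pos13)), 1)
  # the distant point joins last, so it sits at one end of the leaf order
  expect_true(match("r4", names(ord4)) %in% c(1L, 4L))
  # and r2 sits between r4 and the duplicate pair
  expect_true(match("r2", names(ord4)) %in% c(2L, 3L))
  # missing entries are imputed by row mean for the distance only
  mna <- matrix(c(1, NA, 1, 1.1, 1.1, 1.1, 9, 9, 9), nrow = 3, byrow = TRUE,
                dimnames = list(c("x", "y", "z"), NULL))
  ordna <- cluster_order(mna)
  expect_equal(abs(diff(match(c("x", "y"), names(ordna)))), 1)
  expect_error(cluster_order(matrix(NA_real_, 2, 2)), "all-missing")
  # column clustering transposes
  mc <- cbind(s1 = c(1, 2), s2 = c(1.05, 2.05), s3 = c(9, 9))
  oc <- cluster_order(mc, axis = "columns")
  expect_equal(abs(diff(match(c("s1", "s2"), names(oc)))), 1)
})
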