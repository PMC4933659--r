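fixture <- function(name) system.file("extdata", name, package = "proteoturn")

test_that("FASTA databases load with UniProt accession parsing", {
  db <- read_fasta_db(fixture("primary_synthetic.fasta"), "primary")
  expect_equal(db$tier, "primary")
  expect_setequal(names(db$sequences), sprintf("P%05d", 1:5))
  expect_true(all(grepl("^[A-Z]+$", db$sequences)))
})

test_that("two-tier mapping matches an exhaustive substring oracle", {
  primary <- read_fasta_db(fixture("primary_synthetic.fasta"), "primary")
  secondary <- read_fasta_db(fixture("secondary_synthetic.fasta"),
                             "secondary")
  peptides <- c("SPEPTIDEAVK",  # unique in primary P00001
                "QVMGATRYH",    # unique in primary P00003
                "SHAREDSEGK",   # two primary hits -> ambiguous
                "AGRSEQCMK",    # unique in primary P00004
                "SECONDPEPK",   # absent in primary, unique in secondary
                "TRSHAREDK",    # absent in primary, two secondary hits
                "WWWWAAAA",     # nowhere
                "KKKKYYYY")     # nowhere
  res <- map_peptides_two_tier(peptides, primary, secondary)
  expect_equal(unname(attr(res, "summary")),
               c(4L, 2L, 2L))  # assigned, ambiguous, unmatched

  # independent oracle: raw-file exhaustive substring search
  read_raw <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    acc <- sub("^>[a-z]+\\|([^|]+)\\|.*$", "\\1", lines[hdr])
    seqs <- vapply(seq_along(hdr), function(i) {
      end <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
      paste(lines[(hdr[i] + 1):end], collapse = "")
    }, character(1))
    setNames(seqs, acc)
  }
  s1 <- read_raw(fixture("primary_synthetic.fasta"))
  s2 <- read_raw(fixture("secondary_synthetic.fasta"))
  for (i in seq_along(peptides)) {
    h1 <- names(s1)[vapply(s1, function(s)
      length(gregexpr(peptides[i], s, fixed = TRUE)[[1]]) > 0 &&
        gregexpr(peptides[i], s, fixed = TRUE)[[1]][1] != -1, logical(1))]
    h2 <- names(s2)[vapply(s2, function(s)
      gregexpr(peptides[i], s, fixed = TRUE)[[1]][1] != -1, logical(1))]
    expected <- if (length(h1) == 1) c(h1, "primary", "assigned")
      else if (length(h1) > 1) c(NA, "primary", "ambiguous")
      else if (length(h2) == 1) c(h2, "secondary", "assigned")
      else if (length(h2) > 1) c(NA, "secondary", "ambiguous")
      else c(NA, NA, "unmatched")
    expect_equal(res$accession[i], as.character(expected[1]))
    expect_equal(res$status[i], expected[3])
    expect_equal(res$n_primary[i], length(h1))
  }
  # summary counts partition the peptide list
  expect_equal(sum(attr(res, "summary")), length(peptides))
  # order independence
  res_rev <- map_peptides_two_tier(rev(peptides), primary, secondary)
  expect_equal(res_rev$status, rev(res$status))
})

test_that("peptide tables round-trip losslessly through TSV", {
  coh <- simulate_labeling_cohort(default_cohort_config(n_proteins = 4), 6)
  path <- tempfile(fileext = ".tsv")
  write_peptide_table(coh$spectra, path)
  back <- read_peptide_table(path)
  expect_equal(back$peptide, coh$spectra$peptide)
  expect_equal(back$leucine_count, coh$spectra$leucine_count)
  acols <- grep("^area_m", names(coh$spectra), value = TRUE)
  for (cc in acols) {
    expect_equal(back[[cc]], coh$spectra[[cc]], tolerance = 1e-12)
  }
})

test_that("peptide-table validation names the offending row", {
  tab <- envelope_table(list(c(1, 2), c(2, 1, 1)), c(1L, 2L))
  tab$peptide <- c("ALGK", "LALYK")  # 1 and 2 leucines
  path <- tempfile(fileext = ".tsv")

  bad <- tab; bad$leucine_count[2] <- 1L
  write_peptide_table(bad, path)
  expect_error(read_peptide_table(path), "row 2")

  bad2 <- tab; bad2$area_m0[1] <- -3
  write_peptide_table(bad2, path)
  expect_error(read_peptide_table(path), "row 1.*negative")

  write_peptide_table(tab[0, ], path)
  expect_warning(empty <- read_peptide_table(path), "empty")
  expect_equal(nrow(empty), 0L)

  # header mismatch
  writeLines("foo\tbar", path)
  expect_error(read_peptide_table(path), "header")

  # upstream PSM q-value filter at 0.01 when the column is present
  tab$psm_q <- c(0.001, 0.5)
  write_peptide_table(tab, path)
  expect_equal(nrow(read_peptide_table(path)), 1L)
})

test_that("GMT pathway files parse into named sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("pw1\tfirst pathway\tP1\tP2\tP3",
               "pw2\tsecond pathway\tP2\tP4"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("pw1", "pw2"))
  expect_equal(sets$pw2, c("P2", "P4"))
  writeLines("only_name\tdesc", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("config YAML round-trips", {
  cfg <- default_cohort_config(n_proteins = 12, envelope_cv = 0.07)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_proteins, 12L)
  expect_equal(back$envelope_cv, 0.07)
  expect_equal(back$group_median_halflife, cfg$group_median_halflife)
})

test_that("the pipeline runs end to end with a consistent manifest", {
  cfg <- default_cohort_config(n_proteins = 25)
  out1 <- tempfile("run1_"); out2 <- tempfile("run2_")
  res1 <- run_pipeline(cfg, seed = 1, out_dir = out1)
  m <- res1$manifest
  expect_equal(m$counts$samples, 48L)
  expect_equal(m$counts$retained + m$counts$filtered_out,
               m$counts$deconvolved)
  expect_equal(m$counts$deconvolved, m$counts$spectra)
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "halflife_fits.tsv")))

  # determinism: identical manifest on re-run
  res2 <- run_pipeline(cfg, seed = 1, out_dir = out2)
  expect_identical(readLines(file.path(out1, "manifest.json")),
                   readLines(file.path(out2, "manifest.json")))

  # the heart pattern: old mCAT sits closer to young WT than young mCAT
  idx <- setNames(res1$trajectory$index_percent, res1$trajectory$group)
  expect_lt(idx["OmCAT"], idx["YmCAT"])

  # enrichment stage runs when pathways are supplied
  pws <- list(pwA = rownames(res1$cohort$truth_halflife)[1:5])
  pws$pwA <- unique(res1$cohort$truth_halflife$protein)[1:5]
  res3 <- run_pipeline(cfg, seed = 1, out_dir = tempfile(), pathways = pws)
  expect_true(is.data.frame(res3$enrichment))

  unlink(c(out1, out2), recursive = TRUE)
})

test_that("an impossible score cutoff aborts at the fit stage", {
  cfg <- default_cohort_config(n_proteins = 5)
  expect_error(
    run_pipeline(cfg, seed = 2, out_dir = tempfile(), cutoff = 1.01),
    "stage 'fit'.*insufficient")
})
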