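#' Load a protein sequence database from FASTA
#'
#' Reads a FASTA file into an accession -> sequence map. The accession is
#' the first whitespace-delimited token of the header; UniProt pipe-delimited
#' headers (`db|ACCESSION|NAME`) yield the second pipe field.
#'
#' @param path FASTA file path.
#' @param tier database tier label, `"primary"` (curated, e.g. Swiss-Prot)
#'   or `"secondary"` (e.g. TrEMBL).
#' @return list of class `protein_db`: `tier`, `sequences` (named uppercase
#'   character vector).
#' @export
read_fasta_db <- function(path, tier = c("primary", "secondary")) {
  tier <- match.arg(tier)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty database: ", path)
  acc <- vapply(strsplit(names(aa), "[ \t]"), `[[`, character(1), 1L)
  piped <- grepl("|", acc, fixed = TRUE)
  acc[piped] <- vapply(strsplit(acc[piped], "|", fixed = TRUE),
                       `[[`, character(1), 2L)
  if (anyDuplicated(acc))
    stop("duplicate accessions within tier '", tier, "'")
  seqs <- toupper(as.character(aa))
  names(seqs) <- acc
  structure(list(tier = tier, sequences = seqs), class = "protein_db")
}

#' Two-tier unique peptide-to-protein mapping
#'
#' Each peptide is searched as an exact substring against the primary
#' (curated) tier: a unique hit assigns it; multiple hits drop it as
#' ambiguous. Peptides with no primary hit are searched against the
#' secondary tier under the same uniqueness rule. Only uniquely mapped
#' peptides are retained for quantification.
#'
#' @param peptides character vector of peptide sequences.
#' @param primary_db,secondary_db `protein_db` objects (secondary optional).
#' @param il_equivalent treat isoleucine and leucine as interchangeable
#'   during matching (default FALSE: exact residues).
#' @return data.frame, one row per input peptide: `peptide, accession
#'   (NA if not assigned), tier (NA/"primary"/"secondary"), n_primary,
#'   n_secondary, status ("assigned"/"ambiguous"/"unmatched")`; attribute
#'   `summary` holds the three counts.
#' @export
map_peptides_two_tier <- function(peptides, primary_db, secondary_db = NULL,
                                  il_equivalent = FALSE) {
  if (length(peptides) == 0L || any(!nzchar(peptides)))
    stop("peptides must be non-empty strings")
  stopifnot(inherits(primary_db, "protein_db"))
  if (length(primary_db$sequences) == 0L) stop("empty primary database")

  canon <- function(s) if (il_equivalent) gsub("I", "L", s) else s
  seq1 <- canon(primary_db$sequences)
  seq2 <- if (!is.null(secondary_db)) canon(secondary_db$sequences)

  hits <- function(pep, seqs) {
    if (is.null(seqs)) return(character(0))
    names(seqs)[grepl(pep, seqs, fixed = TRUE)]
  }

  rows <- lapply(peptides, function(pep) {
    pc <- canon(pep)
    h1 <- hits(pc, seq1)
    n1 <- length(h1)
    acc <- NA_character_; tier <- NA_character_; status <- "unmatched"
    n2 <- 0L
    if (n1 == 1L) {
      acc <- h1; tier <- "primary"; status <- "assigned"
    } else if (n1 > 1L) {
      status <- "ambiguous"; tier <- "primary"
    } else {
      h2 <- hits(pc, seq2)
      n2 <- length(h2)
      if (n2 == 1L) {
        acc <- h2; tier <- "secondary"; status <- "assigned"
      } else if (n2 > 1L) {
        status <- "ambiguous"; tier <- "secondary"
      }
    }
    data.frame(peptide = pep, accession = acc, tier = tier,
               n_primary = n1, n_secondary = n2, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- c(assigned = sum(out$status == "assigned"),
                            ambiguous = sum(out$status == "ambiguous"),
                            unmatched = sum(out$status == "unmatched"))
  out
}

.required_table_cols <- c("peptide", "protein", "group", "sample", "day",
                          "leucine_count")

#' Read and validate a peptide isotopologue table
#'
#' The table is tab-separated with columns `peptide, protein, group, sample,
#' day, leucine_count, area_m0...area_mLmax` (areas beyond a peptide's L are
#' empty). Each row's `leucine_count` must equal the number of `L` residues
#' in the peptide sequence; negative areas are rejected. When a `psm_q`
#' column is present (upstream spectrum-match q-values), rows with
#' `psm_q >= 0.01` are removed.
#'
#' @param path TSV file path.
#' @return data.frame in the peptide-table dialect.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(.required_table_cols, names(df))
  if (length(missing_cols))
    stop("header mismatch: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty peptide table: ", path)
    return(df)
  }
  acols <- .area_cols(df)
  if (length(acols) == 0L)
    stop("header mismatch: no area_m* columns found")
  n_leu <- vapply(strsplit(df$peptide, ""), function(ch) sum(ch == "L"),
                  integer(1))
  bad <- which(n_leu != df$leucine_count)
  if (length(bad))
    stop(sprintf(
      "row %d: leucine_count %d disagrees with %d L residue(s) in '%s'",
      bad[1], df$leucine_count[bad[1]], n_leu[bad[1]], df$peptide[bad[1]]))
  am <- as.matrix(df[, acols, drop = FALSE])
  neg <- which(apply(am, 1, function(r) any(is.finite(r) & r < 0)))
  if (length(neg))
    stop(sprintf("row %d: negative peak area", neg[1]))
  short <- which(vapply(seq_len(nrow(df)), function(i)
    any(!is.finite(am[i, seq_len(df$leucine_count[i] + 1L)])),
    logical(1)))
  if (length(short))
    stop(sprintf("row %d: missing area within m = 0..L", short[1]))
  if ("psm_q" %in% names(df)) df <- df[df$psm_q < 0.01, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a peptide isotopologue table as TSV
#'
#' @param spectra peptide-table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(spectra, path) {
  utils::write.table(spectra, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read GMT-style pathway gene sets
#'
#' Tab-separated: set name, description, then member accessions.
#'
#' @param path GMT file path.
#' @return named list of accession vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("line %d: a GMT record needs name, description and at ",
                 bad[1]), "least one member")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}
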