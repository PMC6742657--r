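#' Read a peptide-ion quantification table
#'
#' Reads a CSV export of aligned peptide-ion intensities: one row per
#' peptide ion with columns `peptide_id`, `sequence`, `modifications`
#' (semicolon-separated `offset:label` pairs, 1-based within the peptide),
#' `accession`, `unique`, `score`, and one intensity column per sample.
#' Empty intensity cells and zeros are treated as missing (ion
#' non-detection is censoring, not a measured zero).
#'
#' @param path CSV file path.
#' @param design experiment design tibble (`sample_id`, `group`, `donor`);
#'   every non-metadata column of the file must appear in
#'   `design$sample_id`, otherwise an error names the offending column.
#' @return a peptide table tibble.
#' @export
read_peptide_table <- function(path, design) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  assert_design(design)
  # numeric fields come in as text and convert through base R's strtod,
  # which round-trips doubles exactly (fast approximate float parsers can
  # be one ulp off)
  tb <- readr::read_csv(path, col_types = readr::cols(
    unique = readr::col_logical(),
    .default = readr::col_character()), progress = FALSE)
  assert_peptide_table(tb)
  for (col in setdiff(names(tb), c("peptide_id", "sequence",
                                   "modifications", "accession", "unique"))) {
    tb[[col]] <- as.numeric(tb[[col]])
  }
  unknown <- setdiff(sample_cols(tb), design$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown sample column(s) not in design: ",
                 paste(unknown, collapse = ", ")))
  }
  tb$modifications[is.na(tb$modifications)] <- ""
  validate_peptide_table(tb)
}

validate_peptide_table <- function(tb) {
  scols <- sample_cols(tb)
  for (s in scols) {
    v <- tb[[s]]
    v[!is.na(v) & v <= 0] <- NA_real_
    tb[[s]] <- v
  }
  if (any(tb$score < 0, na.rm = TRUE)) abort("id scores must be >= 0")
  mods <- withCallingHandlers(
    parse_modifications(tb$modifications),
    error = function(e) e)
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    if (nrow(m) > 0 && any(m$offset < 1 | m$offset > nchar(tb$sequence[i]))) {
      abort(paste0("row ", i, " (", tb$peptide_id[i],
                   "): modification offset outside peptide of length ",
                   nchar(tb$sequence[i])))
    }
  }
  tb
}

#' Write a peptide table to CSV
#'
#' Inverse of [read_peptide_table()]; round-trips all values.
#'
#' @param peptides peptide table tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  assert_peptide_table(peptides)
  readr::write_csv(peptides, path, progress = FALSE)
  invisible(path)
}

#' Read an experiment design table
#'
#' @param path CSV with columns `sample_id`, `group`, `donor`.
#' @return design tibble.
#' @export
read_design <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  assert_design(tb)
  tb
}

#' Read pathway membership sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list mapping pathway id to a character vector of members.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  fgsea::gmtPathways(path)
}

#' Read a proteome FASTA into a named character vector
#'
#' @param path FASTA file of protein sequences; names are taken as
#'   accessions (first whitespace-delimited token of the header).
#' @return named character vector accession -> sequence.
#' @export
read_proteome <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aas)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Modification mass-delta registry
#'
#' The default registry covers the searched modifications of a strained-cell
#' LFQ experiment: carbamidomethyl cysteine (57.021 Da), oxidized methionine
#' (15.995 Da), hydroxylation of N/D/P/K (15.995 Da), phosphorylation of
#' S/T/Y/H/D (79.966 Da) and the thiol label monobromobimane on cysteine in
#' its two oxidation states (133.053 and 150.056 Da).
#'
#' @return tibble with columns `label`, `mass_delta`, `residues`.
#' @export
default_mass_registry <- function() {
  tibble(
    label = c("carbamidomethyl", "oxidation", "hydroxylation",
              "phospho", "mBBr", "mBBr_ox"),
    mass_delta = c(57.021, 15.995, 15.995, 79.966, 133.053, 150.056),
    residues = c("C", "M", "NDPK", "STYHD", "C", "C"))
}

#' Filter peptides by identification confidence
#'
#' Maps each Mascot-style score to the random-match probability
#' `p = 10^(-score/10)`, adjusts across all peptides by Benjamini-Hochberg,
#' and removes peptides whose adjusted value is at or above the threshold
#' (the retained set has BH-FDR below `fdr_threshold`).
#'
#' @param peptides peptide table.
#' @param fdr_threshold BH-FDR threshold in (0, 1]; default 0.2.
#' @return filtered peptide table.
#' @export
filter_by_confidence <- function(peptides, fdr_threshold = 0.2) {
  assert_peptide_table(peptides)
  if (nrow(peptides) == 0) abort("empty peptide table")
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1) {
    abort("fdr_threshold must lie in (0, 1]")
  }
  q <- p.adjust(score_to_p(peptides$score), method = "BH")
  peptides[q < fdr_threshold, , drop = FALSE]
}

#' Filter proteins by unique-peptide support
#'
#' Removes every peptide of proteins identified by fewer than `min_unique`
#' distinct unique peptide sequences (peptides shared between proteins do
#' not count). Idempotent.
#'
#' @param peptides peptide table.
#' @param min_unique minimum distinct unique sequences per protein
#'   (default 3; proteins with exactly `min_unique` are retained).
#' @return filtered peptide table.
#' @export
filter_by_peptide_count <- function(peptides, min_unique = 3) {
  assert_peptide_table(peptides)
  support <- peptides |>
    filter(.data$unique) |>
    group_by(.data$accession) |>
    summarise(n_unique = dplyr::n_distinct(.data$sequence), .groups = "drop")
  keep <- support$accession[support$n_unique >= min_unique]
  dropped <- setdiff(unique(peptides$accession), keep)
  if (length(dropped) > 0) {
    inform(paste0(length(dropped), " protein(s) dropped with < ", min_unique,
                  " unique peptides"))
  }
  peptides[peptides$accession %in% keep, , drop = FALSE]
}

#' Log-transform and median-normalize intensities
#'
#' Replaces each present intensity by its log2 and subtracts the sample
#' median of the log2 intensities, so every sample's median transformed
#' intensity is exactly 0. Missing cells stay missing.
#'
#' @param peptides peptide table with raw intensities.
#' @param design experiment design (identifies the sample columns).
#' @return peptide table with log2, median-centered intensities.
#' @export
log_and_normalize <- function(peptides, design) {
  assert_peptide_table(peptides)
  assert_design(design)
  scols <- intersect(sample_cols(peptides), design$sample_id)
  for (s in scols) {
    v <- log2(peptides[[s]])
    if (all(is.na(v))) abort(paste0("sample '", s, "' has no present intensities"))
    peptides[[s]] <- v - median(v, na.rm = TRUE)
  }
  peptides
}

#' Annotate PTM sites on protein coordinates
#'
#' Locates each modified peptide in its parent protein by leftmost exact
#' substring match and converts peptide-local modification offsets to
#' protein positions (`match_start + offset - 1`). Peptides matching at
#' several positions are annotated at the leftmost and flagged ambiguous.
#'
#' @param peptides peptide table.
#' @param proteome named character vector accession -> protein sequence
#'   (see [read_proteome()]).
#' @param registry modification registry (see [default_mass_registry()]);
#'   used to attach mass deltas and check residue compatibility.
#' @return tibble of site annotations: `peptide_id`, `accession`, `label`,
#'   `mass_delta`, `residue`, `protein_position`, `site` (e.g. `"S21"`),
#'   `ambiguous`.
#' @export
annotate_ptm_sites <- function(peptides, proteome,
                               registry = default_mass_registry()) {
  assert_peptide_table(peptides)
  mods <- parse_modifications(peptides$modifications)
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    m <- mods[[i]]
    if (nrow(m) == 0) next
    acc <- peptides$accession[i]
    if (!acc %in% names(proteome)) {
      abort(paste0("protein ", acc, " missing from proteome"))
    }
    prot <- proteome[[acc]]
    hits <- gregexpr(peptides$sequence[i], prot, fixed = TRUE)[[1]]
    if (hits[1] == -1) {
      abort(paste0("peptide ", peptides$peptide_id[i], " ('",
                   peptides$sequence[i], "') is not a substring of ", acc))
    }
    start <- hits[1]
    ambiguous <- length(hits) > 1
    pos <- start + m$offset - 1L
    residue <- substr(rep(prot, nrow(m)), pos, pos)
    reg <- registry[match(m$label, registry$label), ]
    ok <- is.na(reg$residues) |
      mapply(grepl, residue, reg$residues, MoreArgs = list(fixed = TRUE))
    if (any(!ok, na.rm = TRUE)) {
      warn(paste0("peptide ", peptides$peptide_id[i], ": residue ",
                  residue[!ok][1], " not an allowed target of ",
                  m$label[!ok][1]))
    }
    rows[[length(rows) + 1]] <- tibble(
      peptide_id = peptides$peptide_id[i], accession = acc,
      label = m$label, mass_delta = reg$mass_delta,
      residue = residue, protein_position = pos,
      site = paste0(residue, pos), ambiguous = ambiguous)
  }
  if (length(rows) == 0) {
    return(tibble(peptide_id = character(), accession = character(),
                  label = character(), mass_delta = numeric(),
                  residue = character(), protein_position = integer(),
                  site = character(), ambiguous = logical()))
  }
  list_rbind(rows)
}
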