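# shared internal helpers

# metadata columns of a peptide table; everything else is a sample column
PEPTIDE_META_COLS <- c("peptide_id", "sequence", "modifications",
                       "accession", "unique", "score")

sample_cols <- function(peptides) {
  setdiff(names(peptides), PEPTIDE_META_COLS)
}

assert_peptide_table <- function(peptides, call = rlang::caller_env()) {
  missing_cols <- setdiff(PEPTIDE_META_COLS, names(peptides))
  if (length(missing_cols) > 0) {
    abort(paste0("not a peptide table; missing column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  invisible(peptides)
}

assert_design <- function(design, call = rlang::caller_env()) {
  missing_cols <- setdiff(c("sample_id", "group", "donor"), names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("not a design table; missing column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  if (anyDuplicated(design$sample_id)) {
    abort("design sample_ids must be unique", call = call)
  }
  if (length(unique(design$group)) < 2) {
    abort("design must contain at least 2 groups", call = call)
  }
  invisible(design)
}

# Mascot-style identification confidence: the score is -10 log10 of the
# random-match probability, so p = 10^(-S/10) and qc = 1 - p, clipped to [0, 1).
score_to_p <- function(score) 10^(-score / 10)

score_to_confidence <- function(score) {
  pmin(pmax(1 - score_to_p(score), 0), 1 - 1e-12)
}

# peptide-table modification strings: "offset:label" joined by ";"
parse_modifications <- function(mods) {
  map(mods, function(m) {
    if (is.na(m) || !nzchar(m)) {
      return(tibble(offset = integer(), label = character()))
    }
    parts <- strsplit(m, ";", fixed = TRUE)[[1]]
    pieces <- strsplit(parts, ":", fixed = TRUE)
    bad <- lengths(pieces) != 2
    if (any(bad)) {
      abort(paste0("malformed modification string: '", m, "'"))
    }
    offs <- suppressWarnings(as.integer(vapply(pieces, `[[`, "", 1L)))
    if (anyNA(offs)) {
      abort(paste0("malformed modification string: '", m, "'"))
    }
    tibble(offset = offs, label = vapply(pieces, `[[`, "", 2L))
  })
}

format_modifications <- function(mod_tbls) {
  vapply(mod_tbls, function(tb) {
    if (nrow(tb) == 0) return("")
    paste(paste0(tb$offset, ":", tb$label), collapse = ";")
  }, character(1))
}

# split-half Rhat on a single chain
split_rhat <- function(draws) {
  m <- length(draws)
  if (m < 4) return(NA_real_)
  half <- floor(m / 2)
  chains <- cbind(draws[seq_len(half)], draws[(m - half + 1):m])
  nchain <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# batch-means Monte Carlo standard error
mcse_batch <- function(draws, n_batches = 30) {
  m <- length(draws)
  n_batches <- min(n_batches, floor(m / 2))
  if (n_batches < 2) return(NA_real_)
  size <- floor(m / n_batches)
  bm <- vapply(seq_len(n_batches), function(b) {
    mean(draws[((b - 1) * size + 1):(b * size)])
  }, numeric(1))
  sd(bm) / sqrt(n_batches)
}

# column-wise sd and batch-means MCSE for a draws matrix (vectorized: the
# per-protein summary path is hot when thousands of proteins are fitted)
col_sds <- function(x) {
  m <- nrow(x)
  cm <- colMeans(x)
  sqrt(pmax(colMeans(x^2) - cm^2, 0) * m / (m - 1))
}

col_mcse_batch <- function(x, n_batches = 30) {
  m <- nrow(x)
  n_batches <- min(n_batches, floor(m / 2))
  if (n_batches < 2) return(rep(NA_real_, ncol(x)))
  size <- floor(m / n_batches)
  idx <- rep(seq_len(n_batches), each = size)
  bm <- rowsum(x[seq_along(idx), , drop = FALSE], idx) / size
  col_sds(bm) / sqrt(n_batches)
}

# seeds derived from one master seed, kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) + 48271L * as.integer(k)) %% 2147483629L
}

utils::globalVariables(".")
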