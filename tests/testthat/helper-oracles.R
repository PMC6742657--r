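# independent oracles and small fixture builders shared across tests

# Benjamini-Hochberg by its step-up definition, independent of p.adjust
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- (n / seq_len(n)) * p[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# least squares by direct normal-equations solve
ols_solve <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

make_design <- function(groups = c("ctl", "trt"), donors = c("D1", "D2")) {
  tidyr::expand_grid(group = groups, donor = donors) |>
    dplyr::mutate(sample_id = paste(group, donor, sep = "_")) |>
    dplyr::select(sample_id, group, donor)
}

# wide peptide table with log2-scale values supplied directly (stored as
# 2^value so log_and_normalize() round-trips them)
make_peptides <- function(log2_mat, design, accession = "P1",
                          scores = NULL, modifications = NULL,
                          sequences = NULL, unique = TRUE) {
  nF <- nrow(log2_mat)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(sequences)) {
    sequences <- vapply(seq_len(nF), function(i) {
      paste(aa[((i * 7 + seq_len(10)) %% 20) + 1], collapse = "")
    }, character(1))
  }
  tb <- tibble::tibble(
    peptide_id = paste0("p", seq_len(nF)),
    sequence = sequences,
    modifications = modifications %||% rep("", nF),
    accession = rep_len(accession, nF),
    unique = rep_len(unique, nF),
    score = scores %||% rep(60, nF))
  m <- 2^log2_mat
  colnames(m) <- design$sample_id
  dplyr::bind_cols(tb, tibble::as_tibble(m))
}

# log2 without median centering (for constructions where the signal must
# not be normalized away)
log2_only <- function(peptides, design) {
  for (s in design$sample_id) peptides[[s]] <- log2(peptides[[s]])
  peptides
}

quiet <- function(expr) suppressMessages(expr)
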