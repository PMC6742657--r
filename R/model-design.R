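#' MCMC configuration for the confidence-weighted elastic-net sampler
#'
#' @param iterations total Gibbs iterations (default 4000).
#' @param burn_in iterations discarded (default 1000); must be <
#'   `iterations`.
#' @param seed optional integer seed; identical seed and inputs give
#'   bit-identical posterior summaries.
#' @param a1,r1 gamma hyperprior (shape, rate) on the lasso penalty
#'   `lambda1^2`.
#' @param a2,r2 gamma hyperprior (shape, rate) on the ridge penalty
#'   `lambda2`.
#' @param lambda1_sq,lambda2 optional fixed penalty values; `NULL` (default)
#'   samples them under the gamma hyperpriors. Setting both near zero gives
#'   the weak-prior (least-squares) limit.
#' @param weight_c robustness scale constant of the observation-weight
#'   function, in standardized-residual units (default 3).
#' @param use_weights recompute confidence-blended observation weights each
#'   iteration (default TRUE); FALSE forces all weights to 1.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(iterations = 4000, burn_in = 1000, seed = NULL,
                        a1 = 1, r1 = 1, a2 = 1, r2 = 1,
                        lambda1_sq = NULL, lambda2 = NULL,
                        weight_c = 3, use_weights = TRUE) {
  stopifnot(iterations > burn_in, burn_in > 0, weight_c > 0)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 seed = if (!is.null(seed)) as.integer(seed),
                 a1 = a1, r1 = r1, a2 = a2, r2 = r2,
                 lambda1_sq = lambda1_sq, lambda2 = lambda2,
                 weight_c = weight_c, use_weights = isTRUE(use_weights)),
            class = "mcmc_config")
}

#' Build the peptide-level design for one protein
#'
#' Encodes the hierarchical peptide-level model for one protein: treatment
#' with reference-cell coding (so the group coefficients are directly log2
#' fold changes versus the reference group), peptide and donor effects with
#' sum-to-zero coding, plus peptide-by-treatment and peptide-by-donor
#' interaction columns. Rows are included only for observed (non-missing)
#' intensities, and peptides flagged non-unique are excluded. Degenerate
#' factors (a single peptide or a single donor) drop their columns. If
#' missingness leaves some interaction columns aliased, those columns are
#' removed (by QR pivoting) and the affected expanded effects are reported
#' as `NA`.
#'
#' @param peptides peptide table rows for one protein, log2-normalized.
#' @param design experiment design tibble.
#' @param reference reference group label (default: first group in the
#'   design).
#' @return a `protein_design` list: response `y`, design matrix `X`,
#'   per-observation `scores` and `obs` metadata, and the expansion map
#'   from model coefficients to interpretable effects (every peptide,
#'   group, donor and interaction effect).
#' @export
build_design <- function(peptides, design, reference = design$group[1]) {
  assert_peptide_table(peptides)
  assert_design(design)
  if (!reference %in% design$group) abort("reference must be one of the design groups")
  acc <- unique(peptides$accession)
  if (length(acc) != 1) abort("build_design expects peptides of a single protein")

  peptides <- peptides[peptides$unique, , drop = FALSE]
  if (nrow(peptides) == 0) abort(paste0(acc, ": no unique peptides"))

  scols <- intersect(sample_cols(peptides), design$sample_id)
  long <- peptides |>
    select("peptide_id", "score", dplyr::all_of(scols)) |>
    pivot_longer(dplyr::all_of(scols), names_to = "sample_id",
                 values_to = "y") |>
    filter(!is.na(.data$y)) |>
    left_join(design, by = "sample_id")

  groups <- c(reference, setdiff(unique(design$group), reference))
  missing_grp <- setdiff(groups, unique(long$group))
  if (length(missing_grp) > 0) {
    abort(paste0(acc, ": group '", missing_grp[1], "' has zero observations"))
  }

  peps <- sort(unique(long$peptide_id))
  donors <- sort(unique(long$donor))
  nF <- length(peps); nG <- length(groups); nD <- length(donors)
  n <- nrow(long)

  fidx <- match(long$peptide_id, peps)
  gidx <- match(long$group, groups)
  didx <- match(long$donor, donors)

  Cf <- if (nF > 1) contr.sum(nF) else matrix(0, 1, 0)
  Cd <- if (nD > 1) contr.sum(nD) else matrix(0, 1, 0)

  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  if (nF > 1) {
    Zf <- Cf[fidx, , drop = FALSE]
    colnames(Zf) <- paste0("pep:", peps[-nF])
    blocks$peptide <- Zf
  }
  Zg <- matrix(0, n, nG - 1,
               dimnames = list(NULL, paste0("grp:", groups[-1])))
  for (g in 2:nG) Zg[gidx == g, g - 1] <- 1
  blocks$group <- Zg
  if (nD > 1) {
    Zd <- Cd[didx, , drop = FALSE]
    colnames(Zd) <- paste0("don:", donors[-nD])
    blocks$donor <- Zd
  }
  if (nF > 1) {
    Zfg <- do.call(cbind, lapply(2:nG, function(g) {
      M <- blocks$peptide * (gidx == g)
      colnames(M) <- paste0(colnames(blocks$peptide), ":grp:", groups[g])
      M
    }))
    blocks$pep_grp <- Zfg
    if (nD > 1) {
      Zfd <- do.call(cbind, lapply(seq_len(nD - 1), function(k) {
        M <- blocks$peptide * Cd[didx, k]
        colnames(M) <- paste0(colnames(blocks$peptide), ":don:", donors[k])
        M
      }))
      blocks$pep_don <- Zfd
    }
  }
  X <- do.call(cbind, blocks)

  # expansion from coefficients to interpretable effects; built with plain
  # vectors (this path runs once per protein and is hot in large batches)
  p <- ncol(X)
  cn <- colnames(X)
  m_type <- character(0); m_pep <- character(0)
  m_grp <- character(0); m_don <- character(0)
  Erows <- list()
  add <- function(type, peptide_id, group, donor, load) {
    v <- numeric(p); v[match(names(load), cn)] <- unlist(load)
    Erows[[length(Erows) + 1]] <<- v
    m_type[length(m_type) + 1] <<- type
    m_pep[length(m_pep) + 1] <<- peptide_id
    m_grp[length(m_grp) + 1] <<- group
    m_don[length(m_don) + 1] <<- donor
  }
  add("intercept", NA, NA, NA, c(`(Intercept)` = 1))
  if (nF > 1) {
    for (f in seq_len(nF)) {
      add("peptide", peps[f], NA, NA, setNames(Cf[f, ], paste0("pep:", peps[-nF])))
    }
  }
  for (g in groups[-1]) {
    add("group", NA, g, NA, setNames(1, paste0("grp:", g)))
  }
  if (nD > 1) {
    for (d in seq_len(nD)) {
      add("donor", NA, NA, donors[d], setNames(Cd[d, ], paste0("don:", donors[-nD])))
    }
  }
  if (nF > 1) {
    for (g in groups[-1]) for (f in seq_len(nF)) {
      add("pep_grp", peps[f], g, NA,
          setNames(Cf[f, ], paste0("pep:", peps[-nF], ":grp:", g)))
    }
    if (nD > 1) {
      for (d in seq_len(nD)) for (f in seq_len(nF)) {
        ld <- unlist(lapply(seq_len(nD - 1), function(k) {
          setNames(Cf[f, ] * Cd[d, k],
                   paste0("pep:", peps[-nF], ":don:", donors[k]))
        }))
        add("pep_don", peps[f], NA, donors[d], ld)
      }
    }
  }
  # occupancy contrasts: a modified peptide's treatment interaction minus
  # the mean interaction of unmodified peptides. Under sum-to-zero coding
  # the raw interaction of a modified peptide is deflated by k/F when k of
  # F peptides carry a modification; this contrast recovers the site
  # occupancy shift exactly for any k < F.
  modified <- peptides$peptide_id[peptides$modifications != "" &
                                    !is.na(peptides$modifications)]
  modified <- intersect(modified, peps)
  unmod <- setdiff(peps, modified)
  if (nF > 1 && length(modified) > 0 && length(unmod) > 0) {
    for (g in groups[-1]) for (fm in modified) {
      ld <- setNames(Cf[match(fm, peps), ] -
                       colMeans(Cf[match(unmod, peps), , drop = FALSE]),
                     paste0("pep:", peps[-nF], ":grp:", g))
      add("occupancy", fm, g, NA, ld)
    }
  }
  E <- do.call(rbind, Erows)
  emeta <- tibble(type = m_type, peptide_id = m_pep,
                  group = m_grp, donor = m_don)

  # drop aliased columns if missingness broke full rank
  qrx <- qr(X)
  dropped <- character(0)
  if (qrx$rank < p) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- cn[-keep]
    estimable <- rowSums(abs(E[, -keep, drop = FALSE])) < 1e-12
    X <- X[, keep, drop = FALSE]
    E <- E[, keep, drop = FALSE]
    emeta$estimable <- estimable
  } else {
    emeta$estimable <- TRUE
  }

  structure(list(
    accession = acc, y = long$y, X = X,
    scores = long$score,
    obs = long |> select("peptide_id", "sample_id", "group", "donor"),
    expansion = E, expansion_meta = emeta,
    groups = groups, peptides = peps, donors = donors,
    reference = reference, rank = qr(X)$rank, dropped = dropped),
    class = "protein_design")
}
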