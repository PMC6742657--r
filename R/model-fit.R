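#' Confidence-blended robust observation weights
#'
#' The weight of an observation blends a redescending Cauchy-type residual
#' weight with the identification confidence of the peptide ion,
#' `qc = 1 - 10^(-score/10)` (clipped to `[0, 1)`):
#' \deqn{w = qc + (1 - qc) \frac{1}{1 + (r/c)^2}}
#' so a confidently identified observation keeps weight close to 1 however
#' large its residual, while a low-confidence outlier is down-weighted.
#' Monotone increasing in score at fixed residual, monotone decreasing in
#' |residual| at fixed score, and `w = 1` at `r = 0` for any score.
#'
#' @param residuals standardized residuals.
#' @param scores identification scores (Mascot-style, >= 0).
#' @param c robustness scale constant in standardized-residual units
#'   (default 3).
#' @return weights in (0, 1].
#' @examples
#' compute_observation_weights(6, 20, c = 3)  # 0.992
#' @export
compute_observation_weights <- function(residuals, scores, c = 3) {
  if (c <= 0) abort("c must be > 0")
  qc <- score_to_confidence(scores)
  qc + (1 - qc) / (1 + (residuals / c)^2)
}

#' Fit the peptide-level model for one protein
#'
#' Samples the hierarchical peptide-level model with a Bayesian elastic net
#' (Gaussian scale-mixture representation, gamma hyperpriors on both
#' penalties) by Gibbs sampling. Observation weights are recomputed every
#' iteration from the current standardized residuals and each ion's
#' identification confidence via [compute_observation_weights()].
#' Penalization covers the nuisance coefficient families (peptide
#' ionization effects, donor effects, peptide-by-donor interactions);
#' the intercept and the inferential targets — group effects and
#' peptide-by-group interactions — are unpenalized, so reported fold
#' changes and occupancy contrasts carry no shrinkage bias.
#' Posterior means, sds and batch-means Monte
#' Carlo standard errors are reported for every interpretable effect
#' (intercept, per-peptide, per-group, per-donor and both interaction
#' families), along with a split-half Rhat per group effect.
#'
#' @param pdesign a `protein_design` from [build_design()].
#' @param config an [mcmc_config()].
#' @return a `protein_fit` object; see [tidy.protein_fit()] for the
#'   coefficient table.
#' @export
fit_protein_model <- function(pdesign, config = mcmc_config()) {
  stopifnot(inherits(pdesign, "protein_design"),
            inherits(config, "mcmc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  qc <- score_to_confidence(pdesign$scores)
  # regularize nuisance families only (peptide and donor mains, peptide x
  # donor); the intercept and the inferential targets -- group effects and
  # peptide x group interactions -- stay unpenalized so reported fold
  # changes and occupancy contrasts are not shrunk
  cn <- colnames(pdesign$X)
  penalize <- as.integer(grepl("^pep:[^:]+$|^don:|:don:", cn))
  draws <- .gibbs_enet(
    pdesign$y, pdesign$X, qc, penalize,
    config$weight_c, config$iterations, config$burn_in,
    config$a1, config$r1, config$a2, config$r2,
    config$lambda1_sq %||% -1, config$lambda2 %||% -1,
    config$use_weights)

  # expanded interpretable effects are linear maps of the coefficients
  expd <- draws$beta %*% t(pdesign$expansion)
  est <- colMeans(expd)
  psd <- col_sds(expd)
  mcse <- col_mcse_batch(expd)
  coefs <- pdesign$expansion_meta |>
    mutate(estimate = ifelse(.data$estimable, est, NA_real_),
           sd = ifelse(.data$estimable, psd, NA_real_),
           mcse = ifelse(.data$estimable, mcse, NA_real_))

  grp_cols <- grep("^grp:", colnames(pdesign$X))
  rhat <- vapply(grp_cols, function(j) split_rhat(draws$beta[, j]), numeric(1))
  names(rhat) <- sub("^grp:", "", colnames(pdesign$X)[grp_cols])

  structure(list(
    accession = pdesign$accession,
    coefficients = coefs,
    sigma2 = mean(draws$sigma2),
    sigma2_draws_sd = sd(draws$sigma2),
    lambda1_sq = mean(draws$lambda1_sq),
    lambda2 = mean(draws$lambda2),
    rhat = rhat,
    converged = all(rhat < 1.1, na.rm = TRUE),
    weights = pdesign$obs |>
      mutate(w_mean = draws$w_mean, w_min = draws$w_min),
    n_obs = length(pdesign$y),
    n_peptides = length(pdesign$peptides),
    df_residual = length(pdesign$y) - pdesign$rank,
    groups = pdesign$groups, reference = pdesign$reference,
    config = config), class = "protein_fit")
}

#' Fit peptide-level models for every protein in a table
#'
#' Splits a filtered, normalized peptide table by protein, builds each
#' design with [build_design()] and fits it with [fit_protein_model()].
#' Proteins whose design cannot be built (e.g. a group entirely missing)
#' are skipped with a message. The RNG is seeded once from
#' `config$seed` and proteins are fitted in sorted accession order, so a
#' given configuration reproduces identical results.
#'
#' @param peptides log2-normalized peptide table.
#' @param design experiment design tibble.
#' @param reference reference group label.
#' @param config an [mcmc_config()].
#' @return a `protein_fits` object (list of `protein_fit` keyed by
#'   accession).
#' @export
fit_proteins <- function(peptides, design, reference = design$group[1],
                         config = mcmc_config()) {
  assert_peptide_table(peptides)
  assert_design(design)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg1 <- config
  cfg1$seed <- NULL  # stream already seeded; per-protein order is fixed
  accs <- sort(unique(peptides$accession))
  fits <- list()
  for (acc in accs) {
    sub <- peptides[peptides$accession == acc, , drop = FALSE]
    pd <- tryCatch(build_design(sub, design, reference),
                   error = function(e) e)
    if (inherits(pd, "error")) {
      inform(paste0("skipping ", acc, ": ", conditionMessage(pd)))
      next
    }
    fits[[acc]] <- fit_protein_model(pd, cfg1)
  }
  if (length(fits) == 0) abort("no protein could be fitted")
  structure(list(fits = fits, reference = reference, config = config),
            class = "protein_fits")
}
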