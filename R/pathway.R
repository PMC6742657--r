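#' Pathway-level linear models on protein fold changes
#'
#' For each pathway with at least `min_members` quantified member proteins,
#' fits the pathway model: log2 fold change of protein `p` in group `g`
#' modeled as a pathway-level treatment effect per group plus a
#' sum-to-zero protein effect,
#' \deqn{y_{gp} = \beta_g + \beta_p + \varepsilon_{gp},}
#' by least squares with cell-means group coding (each `beta_g` is the
#' pathway-level mean log2 fold change in group `g`; their mean is
#' reported as `beta0`). Each `beta_g` is tested against zero two-tailed
#' and p-values are Benjamini-Hochberg adjusted across all pathways and
#' groups. The fold-change response carries no observation-level
#' identification scores, so plain least squares is the estimator here.
#'
#' @param fold_changes tibble with columns `accession`, `group`, `log2fc`
#'   (e.g. from [test_differential()]).
#' @param membership named list pathway id -> character vector of member
#'   accessions (see [read_gmt()]).
#' @param min_members minimum quantified members (default 3); smaller
#'   pathways are dropped.
#' @return a `pathway_tbl` tibble: `pathway_id`, `group`, `beta_g`, `se`,
#'   `p`, `q`, `n_proteins`, `beta0`; per-pathway protein effects are in
#'   `attr(, "protein_effects")`.
#' @export
fit_pathway_model <- function(fold_changes, membership, min_members = 3) {
  stopifnot(all(c("accession", "group", "log2fc") %in% names(fold_changes)))
  if (length(unique(fold_changes$group)) < 1) abort("no groups in fold changes")
  rows <- list()
  peffects <- list()
  for (pw in names(membership)) {
    dat <- fold_changes |>
      filter(.data$accession %in% membership[[pw]],
             is.finite(.data$log2fc))
    if (dplyr::n_distinct(dat$accession) < min_members) next
    if (dplyr::n_distinct(dat$group) < 2) {
      abort(paste0("pathway ", pw,
                   ": degenerate design (a single group); cannot separate ",
                   "treatment from protein effects"))
    }
    dat$group <- factor(dat$group)
    dat$protein <- factor(dat$accession)
    fit <- lm(log2fc ~ 0 + group + protein, data = dat,
              contrasts = list(protein = "contr.sum"))
    sm <- summary(fit)$coefficients
    gnames <- levels(dat$group)
    gi <- match(paste0("group", gnames), rownames(sm))
    est <- unname(sm[gi, 1]); se <- unname(sm[gi, 2])
    # a literally perfect fit (zero residual) carries no evidence against
    # a zero effect and certainty for a nonzero one
    tt <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
    dfres <- df.residual(fit)
    rows[[pw]] <- tibble(
      pathway_id = pw, group = gnames,
      beta_g = est, se = se,
      p = 2 * pt(-abs(tt), df = dfres),
      n_proteins = dplyr::n_distinct(dat$accession),
      beta0 = mean(est))
    cs <- coef(fit)
    pidx <- grep("^protein", names(cs))
    bp <- cs[pidx]
    bp <- c(bp, -sum(bp))
    names(bp) <- levels(dat$protein)
    peffects[[pw]] <- bp
  }
  if (length(rows) == 0) {
    out <- tibble(pathway_id = character(), group = character(),
                  beta_g = numeric(), se = numeric(), p = numeric(),
                  q = numeric(), n_proteins = integer(), beta0 = numeric())
  } else {
    out <- list_rbind(rows) |>
      mutate(q = p.adjust(.data$p, method = "BH")) |>
      select("pathway_id", "group", "beta_g", "se", "p", "q",
             "n_proteins", "beta0")
  }
  class(out) <- c("pathway_tbl", class(out))
  attr(out, "protein_effects") <- peffects
  out
}
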