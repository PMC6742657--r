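#' Tidy a protein model fit
#'
#' @param x a `protein_fit`.
#' @param ... unused.
#' @return tibble of interpretable effects: `type` (intercept, peptide,
#'   group, donor, pep_grp, pep_don), identifying columns, posterior
#'   `estimate`, `sd` and Monte-Carlo standard error `mcse`.
#' @method tidy protein_fit
#' @export
tidy.protein_fit <- function(x, ...) {
  x$coefficients |>
    mutate(accession = x$accession, .before = 1)
}

#' @rdname tidy.protein_fit
#' @method glance protein_fit
#' @export
glance.protein_fit <- function(x, ...) {
  tibble(accession = x$accession, sigma2 = x$sigma2,
         lambda1_sq = x$lambda1_sq, lambda2 = x$lambda2,
         n_obs = x$n_obs, n_peptides = x$n_peptides,
         df_residual = x$df_residual,
         rhat_max = suppressWarnings(max(x$rhat, na.rm = TRUE)),
         converged = x$converged)
}

#' @export
print.protein_fit <- function(x, ...) {
  cat("Peptide-level model fit: ", x$accession, "\n",
      "  ", x$n_obs, " observations, ", x$n_peptides, " peptides, sigma2 = ",
      signif(x$sigma2, 4), "\n", sep = "")
  gg <- x$coefficients |> filter(.data$type == "group")
  for (i in seq_len(nrow(gg))) {
    cat("  log2FC ", gg$group[i], ": ", signif(gg$estimate[i], 4),
        " (sd ", signif(gg$sd[i], 3), ", Rhat ",
        signif(x$rhat[[gg$group[i]]], 4), ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy a batch of protein fits
#'
#' @param x a `protein_fits`.
#' @param ... unused.
#' @return row-bound [tidy.protein_fit()] tables.
#' @method tidy protein_fits
#' @export
tidy.protein_fits <- function(x, ...) {
  list_rbind(map(unname(x$fits), tidy))
}

#' @rdname tidy.protein_fits
#' @method glance protein_fits
#' @export
glance.protein_fits <- function(x, ...) {
  list_rbind(map(unname(x$fits), glance))
}

#' @export
print.protein_fits <- function(x, ...) {
  cat("Peptide-level model fits for ", length(x$fits), " protein(s); ",
      "reference group '", x$reference, "'\n", sep = "")
  invisible(x)
}

#' Tidy a moderation state
#'
#' @param x a `moderation_state`.
#' @param ... unused.
#' @return per-protein tibble with `s2`, `df`, `s_tilde2`.
#' @method tidy moderation_state
#' @export
tidy.moderation_state <- function(x, ...) x$table

#' @rdname tidy.moderation_state
#' @method glance moderation_state
#' @export
glance.moderation_state <- function(x, ...) {
  tibble(d0 = x$d0, s0_2 = x$s0_2, n_proteins = nrow(x$table))
}

#' @export
print.moderation_state <- function(x, ...) {
  cat("Empirical-Bayes variance moderation: d0 = ", signif(x$d0, 4),
      ", s0^2 = ", signif(x$s0_2, 4), " (", nrow(x$table),
      " proteins)\n", sep = "")
  invisible(x)
}

#' Tidy a group/donor morphometry model
#'
#' @param x a `group_model`.
#' @param ... unused.
#' @return tibble of group effects (`term`, `estimate`, `se`, `t`, `p`)
#'   plus donor effects.
#' @method tidy group_model
#' @export
tidy.group_model <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = rownames(sm), estimate = unname(sm[, 1]),
         se = unname(sm[, 2]), t = unname(sm[, 3]), p = unname(sm[, 4]))
}

#' @rdname tidy.group_model
#' @method glance group_model
#' @export
glance.group_model <- function(x, ...) {
  s <- summary(x$model)
  tibble(measure = x$measure, reference = x$reference,
         sigma = s$sigma, r_squared = s$r.squared,
         df_residual = df.residual(x$model), n = nrow(x$model$model))
}

#' Tidy a Gaussian histogram fit
#'
#' @param x a `gaussian_fit`.
#' @param ... unused.
#' @return one-row tibble of the fitted parameters.
#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, center = x$center, width = x$width,
         fwhm = x$fwhm, fit_rmse = x$fit_rmse, poor_fit = x$poor_fit,
         n = x$n)
}

#' Tidy a time-course clustering
#'
#' @param x a `timecourse_clustering`.
#' @param ... unused.
#' @return tibble of per-protein cluster labels.
#' @method tidy timecourse_clustering
#' @export
tidy.timecourse_clustering <- function(x, ...) {
  tibble(protein = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy.timecourse_clustering
#' @method glance timecourse_clustering
#' @export
glance.timecourse_clustering <- function(x, ...) {
  tibble(k_selected = x$k_selected,
         mean_silhouette = unname(x$selection_score[as.character(x$k_selected)]),
         tot_withinss = x$tot_withinss, degenerate = x$degenerate,
         n = length(x$labels))
}

#' Tidy a scaling fit
#'
#' @param x a `scaling_fit`.
#' @param ... unused.
#' @return one-row tibble with slope `b`, its sd, intercept and R-squared.
#' @method tidy scaling_fit
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble(slope = x$slope, slope_sd = x$slope_sd,
         intercept = x$intercept, intercept_sd = x$intercept_sd,
         r_squared = x$r_squared, n = x$n)
}
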