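#' Inverse of the trigamma function
#'
#' Newton solve of `trigamma(x) = y`, used by the empirical-Bayes variance
#' moderation moment matcher.
#'
#' @param y positive value(s).
#' @return x with `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Pools information across proteins by modeling the per-protein residual
#' variances as draws from a scaled inverse chi-square prior with `d0`
#' degrees of freedom and scale `s0^2`, estimated by matching the first two
#' moments of `log(s^2)` (accounting for the chi-square sampling
#' distribution of each `s^2` given its residual degrees of freedom). Each
#' protein's variance is then shrunk to
#' \deqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d).}
#' With fewer than two distinct finite variances the state falls back to no
#' moderation (`d0 = 0`), with a message.
#'
#' @param fits a `protein_fits` object (or plain list of `protein_fit`).
#' @return a `moderation_state`: `d0`, `s0_2` and a per-protein table of
#'   `s2`, `df` and the moderated `s_tilde2`.
#' @export
moderate_variances <- function(fits) {
  flist <- if (inherits(fits, "protein_fits")) fits$fits else fits
  tab <- tibble(
    accession = vapply(flist, `[[`, "", "accession"),
    s2 = vapply(flist, `[[`, 0, "sigma2"),
    df = vapply(flist, `[[`, 0, "df_residual"))
  ok <- is.finite(tab$s2) & tab$s2 > 0 & tab$df > 0
  if (sum(ok) < 2 || length(unique(signif(tab$s2[ok], 9))) < 2) {
    inform("fewer than 2 distinct variances; falling back to no moderation (d0 = 0)")
    d0 <- 0; s0_2 <- if (any(ok)) exp(mean(log(tab$s2[ok]))) else 1
  } else {
    z <- log(tab$s2[ok])
    df1 <- tab$df[ok]
    e <- z - digamma(df1 / 2) + log(df1 / 2)
    emean <- mean(e)
    nn <- length(e)
    evar <- sum((e - emean)^2) / (nn - 1) - mean(trigamma(df1 / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(emean)
    }
  }
  tab <- tab |>
    mutate(s_tilde2 = ifelse(
      rep(is.infinite(d0), dplyr::n()), s0_2,
      (d0 * s0_2 + .data$df * .data$s2) / (d0 + .data$df)))
  structure(list(d0 = d0, s0_2 = s0_2, table = tab),
            class = "moderation_state")
}

#' Moderated differential-abundance tests
#'
#' For every protein and non-reference group, forms the moderated
#' t-statistic: the posterior mean log2 fold change divided by its
#' posterior standard error scaled by the variance-moderation factor
#' `s_tilde / s`. Two-tailed p-values use `d0 + d` degrees of freedom and
#' are Benjamini-Hochberg adjusted across all proteins and contrasts in
#' the batch.
#'
#' @param fits a `protein_fits` object.
#' @param moderation a `moderation_state` computed on the same batch.
#' @return a `differential_tbl` tibble: `accession`, `group`, `log2fc`,
#'   `se`, `t`, `p`, `q`, `n_peptides`, `rhat_max`.
#' @export
test_differential <- function(fits, moderation) {
  stopifnot(inherits(fits, "protein_fits"),
            inherits(moderation, "moderation_state"))
  mt <- moderation$table
  rows <- map(fits$fits, function(ft) {
    m <- mt[mt$accession == ft$accession, ]
    scale <- sqrt(m$s_tilde2 / ft$sigma2)
    gg <- ft$coefficients |> filter(.data$type == "group")
    se <- gg$sd * scale
    bad <- se <= 0 & gg$estimate != 0
    if (any(bad, na.rm = TRUE)) {
      abort(paste0(ft$accession, ": zero standard error with nonzero effect"))
    }
    tstat <- ifelse(se > 0, gg$estimate / se, 0)
    df_total <- moderation$d0 + m$df
    tibble(accession = ft$accession, group = gg$group,
           log2fc = gg$estimate, se = se, t = tstat,
           p = 2 * pt(-abs(tstat), df = df_total),
           n_peptides = ft$n_peptides,
           rhat_max = suppressWarnings(max(ft$rhat, na.rm = TRUE)))
  })
  out <- list_rbind(rows) |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    select("accession", "group", "log2fc", "se", "t", "p", "q",
           "n_peptides", "rhat_max")
  out[] <- lapply(out, unname)
  class(out) <- c("differential_tbl", class(out))
  attr(out, "d0") <- moderation$d0
  attr(out, "s0_2") <- moderation$s0_2
  out
}
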