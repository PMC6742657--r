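#' PTM site-occupancy fold changes from interaction terms
#'
#' The peptide-by-treatment interaction effect of a modified peptide
#' measures the log2 fold change in site occupancy — the change in the
#' fraction of the protein carrying the modification — over and above the
#' protein-level abundance change. The occupancy estimate is the contrast
#' between the modified peptide's interaction and the mean interaction of
#' the protein's unmodified peptides (under sum-to-zero coding the raw
#' interaction of a modified peptide is deflated by k/F when k of the
#' protein's F peptides carry a modification; the contrast removes that).
#' This extracts those estimates for every annotated site and
#' non-reference group, combines
#' multiple peptides covering one site by inverse-variance weighting,
#' scales the standard errors by the empirical-Bayes moderation factor and
#' tests each combined estimate with a moderated t, Benjamini-Hochberg
#' adjusted across all sites.
#'
#' @param fits a `protein_fits` object.
#' @param annotations site annotations from [annotate_ptm_sites()].
#' @param moderation a `moderation_state` for the same batch.
#' @param include_ambiguous include sites whose protein position could not
#'   be resolved uniquely (default FALSE).
#' @return a `ptm_tbl` tibble: `accession`, `site`, `label`, `group`,
#'   `occupancy_log2fc`, `se`, `t`, `p`, `q`, `n_peptides`.
#' @export
site_occupancy_changes <- function(fits, annotations, moderation,
                                   include_ambiguous = FALSE) {
  stopifnot(inherits(fits, "protein_fits"),
            inherits(moderation, "moderation_state"))
  ann <- annotations
  if (!include_ambiguous && nrow(ann) > 0) {
    ann <- ann[!ann$ambiguous, , drop = FALSE]
  }
  mt <- moderation$table
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    ft <- fits$fits[[a$accession]]
    if (is.null(ft)) next
    fg <- ft$coefficients |>
      filter(.data$type == "occupancy", .data$peptide_id == a$peptide_id,
             !is.na(.data$estimate))
    if (nrow(fg) == 0) {
      inform(paste0("site ", a$accession, " ", a$site,
                    ": no fitted occupancy contrast; skipped"))
      next
    }
    rows[[length(rows) + 1]] <- fg |>
      mutate(accession = a$accession, site = a$site, label = a$label)
  }
  if (length(rows) == 0) {
    out <- tibble(accession = character(), site = character(),
                  label = character(), group = character(),
                  occupancy_log2fc = numeric(), se = numeric(),
                  t = numeric(), p = numeric(), q = numeric(),
                  n_peptides = integer())
    class(out) <- c("ptm_tbl", class(out))
    return(out)
  }
  combined <- list_rbind(rows) |>
    group_by(.data$accession, .data$site, .data$label, .data$group) |>
    summarise(
      occupancy_log2fc = sum(.data$estimate / .data$sd^2) /
        sum(1 / .data$sd^2),
      se_raw = sqrt(1 / sum(1 / .data$sd^2)),
      n_peptides = dplyr::n_distinct(.data$peptide_id),
      .groups = "drop")
  # moderation scaling + test, per parent protein
  prot <- tibble(
    accession = vapply(fits$fits, `[[`, "", "accession"),
    sigma2 = vapply(fits$fits, `[[`, 0, "sigma2"))
  out <- combined |>
    left_join(mt, by = "accession") |>
    left_join(prot, by = "accession") |>
    mutate(se = .data$se_raw * sqrt(.data$s_tilde2 / .data$sigma2),
           t = .data$occupancy_log2fc / .data$se,
           p = 2 * pt(-abs(.data$t), df = moderation$d0 + .data$df),
           q = p.adjust(.data$p, method = "BH")) |>
    select("accession", "site", "label", "group", "occupancy_log2fc",
           "se", "t", "p", "q", "n_peptides")
  out[] <- lapply(out, unname)
  class(out) <- c("ptm_tbl", class(out))
  out
}
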