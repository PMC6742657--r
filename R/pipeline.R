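#' Configuration for an end-to-end differential run
#'
#' @param peptides peptide table tibble, or path to a peptide CSV.
#' @param design design tibble, or path to a design CSV.
#' @param reference reference group label.
#' @param fdr_threshold peptide confidence BH-FDR threshold (default 0.2).
#' @param min_unique minimum distinct unique peptides per protein
#'   (default 3).
#' @param mcmc an [mcmc_config()].
#' @param gmt optional path to a GMT file (or a membership list) for
#'   pathway fitting.
#' @param proteome optional named character vector (or FASTA path) for PTM
#'   site annotation.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for the whole run.
#' @return a `run_config` list.
#' @export
run_config <- function(peptides, design, reference = NULL,
                       fdr_threshold = 0.2, min_unique = 3,
                       mcmc = mcmc_config(), gmt = NULL, proteome = NULL,
                       out_dir = tempfile("pepnet_run_"), seed = 1L) {
  if (fdr_threshold <= 0 || fdr_threshold > 1) {
    abort("fdr_threshold must lie in (0, 1]")
  }
  if (min_unique < 1) abort("min_unique must be >= 1")
  structure(list(peptides = peptides, design = design, reference = reference,
                 fdr_threshold = fdr_threshold, min_unique = min_unique,
                 mcmc = mcmc, gmt = gmt, proteome = proteome,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv_with_header <- function(tb, path, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# pepnet ", as.character(packageVersion("pepnet")),
                    " seed=", seed), con)
  utils::write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the differential-abundance pipeline end to end
#'
#' Applies the fixed stage order: identification-confidence filter,
#' unique-peptide count filter, log2/median normalization, per-protein
#' confidence-weighted elastic-net fits, empirical-Bayes variance
#' moderation, moderated t-tests with Benjamini-Hochberg adjustment, and
#' (optionally) PTM site-occupancy quantification and pathway-level
#' models. All stage outputs are written to `out_dir` as TSV with a header
#' comment carrying the tool version and seed, plus a JSON manifest with
#' per-stage record counts and output checksums. A rerun with the same
#' configuration reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; outputs on disk in
#'   `config$out_dir`.
#' @export
run_differential <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- if (is.character(config$design)) {
    read_design(config$design)
  } else as_tibble(config$design)
  assert_design(design)
  peptides <- if (is.character(config$peptides)) {
    read_peptide_table(config$peptides, design)
  } else validate_peptide_table(as_tibble(config$peptides))
  reference <- config$reference %||% design$group[1]

  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[stage]] <<- list(n_in = n_in, n_out = n_out)
  }

  n0 <- nrow(peptides)
  pep_conf <- filter_by_confidence(peptides, config$fdr_threshold)
  note("confidence_filter", n0, nrow(pep_conf))

  pep_count <- filter_by_peptide_count(pep_conf, config$min_unique)
  note("peptide_count_filter", nrow(pep_conf), nrow(pep_count))

  pep_norm <- log_and_normalize(pep_count, design)
  note("normalize", nrow(pep_count), nrow(pep_norm))

  mcmc <- config$mcmc
  mcmc$seed <- config$seed
  fits <- fit_proteins(pep_norm, design, reference, mcmc)
  note("fit", dplyr::n_distinct(pep_norm$accession), length(fits$fits))

  moderation <- moderate_variances(fits)
  results <- test_differential(fits, moderation)
  note("test", length(fits$fits), nrow(results))

  files <- list()
  files$proteins <- file.path(config$out_dir, "protein_differential.tsv")
  write_tsv_with_header(results, files$proteins, config$seed)

  if (!is.null(config$proteome)) {
    proteome <- if (is.character(config$proteome) &&
                    length(config$proteome) == 1 &&
                    file.exists(config$proteome)) {
      read_proteome(config$proteome)
    } else config$proteome
    ann <- annotate_ptm_sites(pep_norm, proteome)
    sites <- site_occupancy_changes(fits, ann, moderation)
    note("ptm_sites", nrow(ann), nrow(sites))
    files$ptm_sites <- file.path(config$out_dir, "ptm_site_occupancy.tsv")
    write_tsv_with_header(sites, files$ptm_sites, config$seed)
    ambiguous <- ann[ann$ambiguous, , drop = FALSE]
    if (nrow(ambiguous) > 0) {
      files$ambiguous_sites <- file.path(config$out_dir, "ambiguous_sites.tsv")
      write_tsv_with_header(ambiguous, files$ambiguous_sites, config$seed)
    }
  }

  if (!is.null(config$gmt)) {
    membership <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
    pw <- fit_pathway_model(
      results |> select("accession", "group", "log2fc"), membership)
    note("pathways", length(membership), dplyr::n_distinct(pw$pathway_id))
    files$pathways <- file.path(config$out_dir, "pathway_differential.tsv")
    write_tsv_with_header(pw, files$pathways, config$seed)
  }

  manifest <- list(
    tool = "pepnet",
    version = as.character(packageVersion("pepnet")),
    seed = config$seed,
    reference = reference,
    parameters = list(fdr_threshold = config$fdr_threshold,
                      min_unique = config$min_unique,
                      mcmc_iterations = config$mcmc$iterations,
                      mcmc_burn_in = config$mcmc$burn_in),
    stages = stages,
    moderation = list(d0 = moderation$d0, s0_2 = moderation$s0_2),
    rhat_max = suppressWarnings(max(results$rhat_max, na.rm = TRUE)),
    outputs = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
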