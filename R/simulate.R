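#' Configuration for the proteomics experiment generator
#'
#' Collects the generative parameters for [simulate_proteomics()]. The
#' defaults emulate a label-free strain-response experiment on primary cells:
#' 3 donors, a control and a treated group, proteins carrying a variable
#' number of peptide ions (triangular between 3 and 30, mode 5), strong
#' peptide-to-peptide ionization differences, donor variability at both the
#' protein and peptide level, intensity-correlated identification scores and
#' missing observations.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein length-3 numeric (min, mode, max) of the
#'   triangular distribution of peptide-ion counts per protein.
#' @param n_donors number of donors (one sample per donor and group).
#' @param groups character vector of treatment group labels; the first is
#'   the reference unless `reference` says otherwise.
#' @param reference reference group label.
#' @param fraction_differential fraction of proteins with a true abundance
#'   change; non-differential proteins have treatment effect exactly 0.
#' @param effect_size_range range of |log2 fold change| for differential
#'   proteins; the sign is random.
#' @param donor_sd_protein,donor_sd_peptide standard deviations (log2) of
#'   protein-level and peptide-level donor effects.
#' @param peptide_sd standard deviation (log2) of per-peptide ionization
#'   offsets.
#' @param residual_sd residual standard deviation (log2) of a single
#'   peptide-ion observation.
#' @param baseline_mean,baseline_sd mean and sd (log2) of protein baseline
#'   intensities.
#' @param ptm_fraction fraction of peptides carrying a PTM (a phosphosite).
#' @param ptm_effect log2 occupancy shift added to modified peptides in
#'   every non-reference group (a peptide-by-treatment interaction); 0 means
#'   modified peptides track their protein.
#' @param missingness fraction of intensity cells masked as missing.
#' @param missing_mode `"mcar"` (completely at random) or `"censor"`
#'   (left-censored: low-intensity cells are more likely to be missing).
#' @param score_base,score_slope,score_sd identification-score model:
#'   `score = score_base + score_slope * z + N(0, score_sd)` floored at 1,
#'   where `z` is the standardized mean log2 intensity of the peptide.
#' @param fraction_nonunique fraction of peptides flagged as shared between
#'   proteins (excluded from model fitting downstream).
#' @param seed integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return a `proteomics_sim_config` list.
#' @export
proteomics_sim_config <- function(n_proteins = 100,
                                  peptides_per_protein = c(3, 5, 30),
                                  n_donors = 3,
                                  groups = c("control", "strain"),
                                  reference = groups[1],
                                  fraction_differential = 0.2,
                                  effect_size_range = c(0.5, 1.5),
                                  donor_sd_protein = 0.2,
                                  donor_sd_peptide = 0.1,
                                  peptide_sd = 1.5,
                                  residual_sd = 0.2,
                                  baseline_mean = 20,
                                  baseline_sd = 2,
                                  ptm_fraction = 0.1,
                                  ptm_effect = 0,
                                  missingness = 0.1,
                                  missing_mode = c("mcar", "censor"),
                                  score_base = 15,
                                  score_slope = 5,
                                  score_sd = 3,
                                  fraction_nonunique = 0.05,
                                  seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(length(peptides_per_protein) == 3,
            peptides_per_protein[1] <= peptides_per_protein[2],
            peptides_per_protein[2] <= peptides_per_protein[3])
  if (peptides_per_protein[3] < 3) {
    abort("peptides_per_protein implies < 3 peptides for every protein; everything would be filtered out")
  }
  fracs <- c(fraction_differential, ptm_fraction, missingness, fraction_nonunique)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (any(c(donor_sd_protein, donor_sd_peptide, peptide_sd, residual_sd) < 0)) {
    abort("standard deviations must be >= 0")
  }
  if (n_donors < 1) abort("n_donors must be >= 1")
  if (!reference %in% groups) abort("reference must be one of the groups")
  structure(list(
    n_proteins = n_proteins, peptides_per_protein = peptides_per_protein,
    n_donors = n_donors, groups = groups, reference = reference,
    fraction_differential = fraction_differential,
    effect_size_range = effect_size_range,
    donor_sd_protein = donor_sd_protein, donor_sd_peptide = donor_sd_peptide,
    peptide_sd = peptide_sd, residual_sd = residual_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    ptm_fraction = ptm_fraction, ptm_effect = ptm_effect,
    missingness = missingness, missing_mode = missing_mode,
    score_base = score_base, score_slope = score_slope, score_sd = score_sd,
    fraction_nonunique = fraction_nonunique,
    seed = as.integer(seed)), class = "proteomics_sim_config")
}

rtriangular_int <- function(n, lo, mode, hi) {
  u <- runif(n)
  fc <- (mode - lo) / (hi - lo + 1e-12)
  x <- ifelse(u < fc,
              lo + sqrt(u * (hi - lo) * (mode - lo)),
              hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
  pmin(pmax(round(x), lo), hi)
}

random_peptide_sequences <- function(n, min_len = 8, max_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- character(0)
  while (length(seqs) < n) {
    need <- n - length(seqs)
    lens <- sample(min_len:max_len, need, replace = TRUE)
    new <- vapply(lens, function(l) {
      paste(sample(aa, l, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, new))
  }
  seqs[seq_len(n)]
}

#' Simulate a peptide-level label-free proteomics experiment
#'
#' Generates a peptide-ion quantification table, a sample design and the
#' ground truth that produced them. Log2 intensities are composed exactly as
#' the hierarchical peptide-level model assumes: protein baseline + peptide
#' ionization effect + treatment effect + donor effects (protein- and
#' peptide-level) + PTM occupancy interaction + Gaussian residual, then
#' exponentiated to the raw scale. Identification scores increase with mean
#' peptide intensity and missing cells are masked at the configured rate.
#'
#' @param config a [proteomics_sim_config()].
#' @return a list with elements `peptides` (wide peptide table, one column
#'   per sample), `design` (tibble `sample_id`, `group`, `donor`), and
#'   `truth` (list of tibbles: `proteins` with per-group true effects,
#'   `sites` with true occupancy shifts, plus the config).
#' @examples
#' sim <- simulate_proteomics(proteomics_sim_config(n_proteins = 5, seed = 7))
#' sim$peptides
#' @export
simulate_proteomics <- function(config = proteomics_sim_config()) {
  stopifnot(inherits(config, "proteomics_sim_config"))
  withr::with_seed(config$seed, simulate_proteomics_impl(config))
}

simulate_proteomics_impl <- function(cfg) {
  non_ref <- setdiff(cfg$groups, cfg$reference)
  design <- tidyr::expand_grid(group = cfg$groups,
                               donor = paste0("D", seq_len(cfg$n_donors))) |>
    mutate(sample_id = paste(.data$group, .data$donor, sep = "_")) |>
    select("sample_id", "group", "donor")

  acc <- sprintf("P%05d", seq_len(cfg$n_proteins))
  n_pep <- rtriangular_int(cfg$n_proteins, cfg$peptides_per_protein[1],
                           cfg$peptides_per_protein[2], cfg$peptides_per_protein[3])
  n_pep <- pmax(n_pep, 1L)

  differential <- runif(cfg$n_proteins) < cfg$fraction_differential
  truth_proteins <- tidyr::expand_grid(accession = acc, group = non_ref) |>
    left_join(tibble(accession = acc, differential = differential),
              by = "accession") |>
    mutate(beta_g = ifelse(
      .data$differential,
      runif(dplyr::n(), cfg$effect_size_range[1], cfg$effect_size_range[2]) *
        sample(c(-1, 1), dplyr::n(), replace = TRUE),
      0))

  total_pep <- sum(n_pep)
  sequences <- random_peptide_sequences(total_pep)
  pep <- tibble(
    peptide_id = sprintf("pep%06d", seq_len(total_pep)),
    sequence = sequences,
    accession = rep(acc, n_pep),
    unique = runif(total_pep) >= cfg$fraction_nonunique,
    pep_effect = rnorm(total_pep, 0, cfg$peptide_sd))

  # PTM assignment: a phosphosite at a random offset, residue forced to S/T/Y
  has_ptm <- runif(total_pep) < cfg$ptm_fraction
  mods <- rep("", total_pep)
  for (i in which(has_ptm)) {
    off <- sample(nchar(pep$sequence[i]), 1)
    res <- sample(c("S", "T", "Y"), 1)
    substr(pep$sequence[i], off, off) <- res
    mods[i] <- paste0(off, ":phospho")
  }
  pep$modifications <- mods

  baseline <- rnorm(cfg$n_proteins, cfg$baseline_mean, cfg$baseline_sd)
  donor_prot <- matrix(rnorm(cfg$n_proteins * cfg$n_donors, 0, cfg$donor_sd_protein),
                       cfg$n_proteins, cfg$n_donors)
  donor_pep <- matrix(rnorm(total_pep * cfg$n_donors, 0, cfg$donor_sd_peptide),
                      total_pep, cfg$n_donors)

  beta_g_wide <- matrix(0, cfg$n_proteins, length(cfg$groups),
                        dimnames = list(acc, cfg$groups))
  for (g in non_ref) {
    beta_g_wide[, g] <- truth_proteins$beta_g[truth_proteins$group == g]
  }

  prot_idx <- rep(seq_len(cfg$n_proteins), n_pep)
  logI <- matrix(NA_real_, total_pep, nrow(design))
  for (s in seq_len(nrow(design))) {
    g <- design$group[s]
    d <- match(design$donor[s], paste0("D", seq_len(cfg$n_donors)))
    mu <- baseline[prot_idx] + pep$pep_effect +
      beta_g_wide[prot_idx, g] + donor_prot[prot_idx, d] + donor_pep[, d]
    if (g != cfg$reference) mu <- mu + ifelse(has_ptm, cfg$ptm_effect, 0)
    logI[, s] <- mu + rnorm(total_pep, 0, cfg$residual_sd)
  }

  # intensity-correlated identification scores
  mean_logI <- rowMeans(logI)
  z <- if (sd(mean_logI) > 0) (mean_logI - mean(mean_logI)) / sd(mean_logI) else 0
  score <- pmax(cfg$score_base + cfg$score_slope * z +
                  rnorm(total_pep, 0, cfg$score_sd), 1)

  # missingness mask
  if (cfg$missingness > 0) {
    if (cfg$missing_mode == "mcar") {
      mask <- matrix(runif(length(logI)) < cfg$missingness, nrow(logI))
    } else {
      # left censoring: probability decreasing in intensity, calibrated so the
      # marginal rate matches cfg$missingness
      r <- rank(logI) / length(logI)
      pmiss <- 2 * cfg$missingness * (1 - r)
      mask <- matrix(runif(length(logI)) < pmiss, nrow(logI))
    }
    logI[mask] <- NA_real_
  }

  intensities <- as_tibble(2^logI, .name_repair = "minimal")
  names(intensities) <- design$sample_id

  peptides <- tibble(
    peptide_id = pep$peptide_id, sequence = pep$sequence,
    modifications = pep$modifications, accession = pep$accession,
    unique = pep$unique, score = score) |>
    dplyr::bind_cols(intensities)

  sites <- pep |>
    filter(has_ptm) |>
    mutate(offset = as.integer(sub(":phospho", "", .data$modifications)),
           residue = substr(.data$sequence, .data$offset, .data$offset),
           occupancy_shift = cfg$ptm_effect) |>
    select("accession", "peptide_id", "offset", "residue", "occupancy_shift")

  list(peptides = peptides, design = design,
       truth = list(proteins = truth_proteins, sites = sites, config = cfg))
}

#' Simulate a global-null proteomics experiment
#'
#' Identical to [simulate_proteomics()] with all treatment effects (protein
#' abundance and PTM occupancy alike) forced to zero, for false-discovery
#' calibration.
#'
#' @inheritParams simulate_proteomics
#' @return as [simulate_proteomics()]; the truth table contains only zeros.
#' @export
simulate_null <- function(config = proteomics_sim_config()) {
  config$fraction_differential <- 0
  config$ptm_effect <- 0
  simulate_proteomics(config)
}

#' Simulate per-cell morphometry data
#'
#' Generates lognormal per-cell measures with additive donor and treatment
#' effects on the log2 scale, mirroring the group/donor linear model used
#' for imaging statistics.
#'
#' @param n_cells_per_group cells per (group, donor is nested within).
#' @param groups group labels; first is the reference.
#' @param n_donors donors; cells are split evenly across donors.
#' @param group_effects named numeric of log2 effects for non-reference
#'   groups (unnamed groups get 0).
#' @param donor_sd sd (log2) of donor effects.
#' @param cell_sd per-cell residual sd (log2).
#' @param baselines named numeric of raw-scale baseline levels per measure.
#' @param seed integer seed.
#' @return list with `records` (tibble: cell_id, donor, group, one column
#'   per measure) and `truth`.
#' @export
simulate_morphometry <- function(n_cells_per_group = 200,
                                 groups = c("control", "strain"),
                                 n_donors = 3,
                                 group_effects = c(strain = 0.3),
                                 donor_sd = 0.2,
                                 cell_sd = 0.25,
                                 baselines = c(nuclear_area = 170,
                                               cytoplasmic_area = 1800),
                                 seed = 1L) {
  stopifnot(all(baselines > 0), n_donors >= 1, length(groups) >= 1)
  withr::with_seed(seed, {
    donors <- paste0("D", seq_len(n_donors))
    grid <- tidyr::expand_grid(group = groups,
                               cell = seq_len(n_cells_per_group)) |>
      mutate(donor = donors[(.data$cell - 1L) %% n_donors + 1L],
             cell_id = paste0(.data$group, "_c", .data$cell))
    donor_eff <- setNames(rnorm(n_donors, 0, donor_sd), donors)
    donor_eff <- donor_eff - mean(donor_eff)
    geff <- setNames(rep(0, length(groups)), groups)
    geff[names(group_effects)] <- group_effects
    measures <- map(names(baselines), function(m) {
      mu <- log2(baselines[[m]]) + geff[grid$group] + donor_eff[grid$donor]
      2^(mu + rnorm(nrow(grid), 0, cell_sd))
    })
    names(measures) <- names(baselines)
    records <- dplyr::bind_cols(
      grid |> select("cell_id", "donor", "group"),
      as_tibble(measures))
    truth <- list(group_effects = geff, donor_effects = donor_eff,
                  cell_sd = cell_sd, baselines = baselines, seed = seed)
    list(records = records, truth = truth)
  })
}
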