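test_that("design construction counts rows and columns under the stated coding", {
  design <- make_design()           # 2 groups x 2 donors
  tb <- make_peptides(matrix(rnorm(8, 20), 2), design)
  pd <- build_design(log2_only(tb, design), design, reference = "ctl")
  expect_equal(nrow(pd$X), 8)
  # 1 intercept + 1 peptide + 1 group + 1 donor + 1 pep:grp + 1 pep:don
  expect_equal(ncol(pd$X), 6)
  expect_equal(pd$rank, 6)

  # a missing observation drops its row, not its columns
  tb2 <- tb
  tb2$ctl_D1[1] <- NA
  pd2 <- build_design(log2_only(tb2, design), design, reference = "ctl")
  expect_equal(nrow(pd2$X), 7)
  expect_equal(ncol(pd2$X), 6)

  # single donor: donor columns dropped, model still full rank
  d1 <- make_design(donors = "D1")
  tb3 <- make_peptides(matrix(rnorm(4, 20), 2), d1)
  pd3 <- build_design(log2_only(tb3, d1), d1, reference = "ctl")
  expect_equal(ncol(pd3$X), 4)      # intercept, peptide, group, pep:grp
  expect_equal(pd3$rank, 4)

  # a group with zero observations is an error naming the group
  tb4 <- tb
  tb4$trt_D1 <- NA_real_
  tb4$trt_D2 <- NA_real_
  expect_error(build_design(log2_only(tb4, design), design, reference = "ctl"),
               "trt")

  # sum-to-zero coding: expanded peptide and donor effects sum to zero
  expect_lt(max(abs(colSums(pd$expansion[pd$expansion_meta$type == "peptide", , drop = FALSE]))), 1e-12)
  expect_lt(max(abs(colSums(pd$expansion[pd$expansion_meta$type == "donor", , drop = FALSE]))), 1e-12)
})

test_that("observation weights blend confidence with a redescending residual weight", {
  expect_equal(compute_observation_weights(6, 20, c = 3), 0.99 + 0.01 / 5)
  expect_equal(compute_observation_weights(6, 0, c = 3), 0.2)
  expect_equal(compute_observation_weights(0, 0, c = 3), 1)
  expect_equal(compute_observation_weights(0, 50, c = 3), 1)
  expect_error(compute_observation_weights(1, 10, c = 0), "c must be")

  r <- seq(0, 10, by = 0.5)
  for (s in c(0, 5, 20)) {
    w <- compute_observation_weights(r, s, c = 3)
    expect_true(all(diff(w) <= 1e-12))          # decreasing in |residual|
    expect_true(all(w > 0 & w <= 1))
  }
  s <- seq(0, 60, by = 5)
  for (rr in c(1, 4, 8)) {
    w <- compute_observation_weights(rr, s, c = 3)
    expect_true(all(diff(w) >= -1e-12))         # increasing in score
  }
})

test_that("weak-prior posterior matches least squares on a balanced design", {
  design <- make_design()
  set.seed(11)
  tb <- make_peptides(matrix(rnorm(12, 18, 1), 3), design)
  pd <- build_design(log2_only(tb, design), design, reference = "ctl")
  ols <- ols_solve(pd$X, pd$y)
  ft <- fit_protein_model(pd, mcmc_config(iterations = 4000, burn_in = 1000,
                                          seed = 3, lambda1_sq = 1e-8,
                                          lambda2 = 1e-8))
  ols_exp <- as.numeric(pd$expansion %*% ols)
  ok <- !is.na(ft$coefficients$mcse) & ft$coefficients$mcse > 0
  z <- abs(ft$coefficients$estimate - ols_exp)[ok] / ft$coefficients$mcse[ok]
  expect_lt(max(z), 5)
  expect_gte(mean(z <= 3), 0.9)
})

test_that("a no-signal protein yields group effects at zero", {
  design <- make_design(donors = c("D1", "D2", "D3"))
  tb <- make_peptides(matrix(rep(c(18, 20, 22), 6), 3), design)
  pd <- build_design(log2_only(tb, design), design, reference = "ctl")
  ft <- fit_protein_model(pd, mcmc_config(iterations = 2000, burn_in = 500, seed = 5))
  gg <- ft$coefficients[ft$coefficients$type == "group", ]
  expect_lt(abs(gg$estimate), 3 * gg$mcse + 1e-8)
})

test_that("identical seed and inputs give bit-identical fits", {
  design <- make_design()
  set.seed(21)
  tb <- make_peptides(matrix(rnorm(16, 20, 1), 4), design)
  cfg <- mcmc_config(iterations = 800, burn_in = 200, seed = 99)
  pd <- build_design(log2_only(tb, design), design, reference = "ctl")
  f1 <- fit_protein_model(pd, cfg)
  f2 <- fit_protein_model(pd, cfg)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$sigma2, f2$sigma2)
})

test_that("enlarging the ridge penalty never inflates penalized effects", {
  design <- make_design(donors = c("D1", "D2", "D3"))
  set.seed(31)
  for (i in 1:8) {
    tb <- make_peptides(matrix(rnorm(18, 19, 1.2), 3), design)
    pd <- build_design(log2_only(tb, design), design, reference = "ctl")
    prev <- NULL
    for (l2 in c(1e-6, 1, 100, 1e4)) {
      ft <- fit_protein_model(pd, mcmc_config(iterations = 1200, burn_in = 300,
                                              seed = 7, lambda1_sq = 1e-8,
                                              lambda2 = l2))
      cur <- ft$coefficients[ft$coefficients$type %in% c("peptide", "donor", "pep_don"), ]
      if (!is.null(prev)) {
        slack <- 3 * (cur$mcse + prev$mcse)
        expect_true(all(abs(cur$estimate) <= abs(prev$estimate) + slack))
      }
      prev <- cur
    }
  }
})

test_that("simulated group effects are recovered at the constructed rate", {
  # oracle: the group effect is a two-group mean contrast over F*D cells,
  # se = sigma * sqrt(2 / (F*D)); with 6 peptides, 3 donors, sigma = 0.3
  # the probability of landing in [0.8, 1.2] is 2*pnorm(0.2/se) - 1
  sigma <- 0.3; nF <- 6; nD <- 3
  se <- sigma * sqrt(2 / (nF * nD))
  p_true <- 2 * pnorm(0.2 / se) - 1
  n_rep <- 100
  hits <- 0
  for (r in seq_len(n_rep)) {
    cfg <- proteomics_sim_config(
      n_proteins = 1, peptides_per_protein = c(nF, nF, nF), residual_sd = sigma,
      fraction_differential = 1, effect_size_range = c(1, 1),
      ptm_fraction = 0, missingness = 0, seed = 5000 + r)
    sim <- simulate_proteomics(cfg)
    pep <- log2_only(sim$peptides, sim$design)   # single protein: no
    # median centering, it would absorb the very effect under study
    pd <- build_design(pep, sim$design, reference = "control")
    ft <- fit_protein_model(pd, mcmc_config(iterations = 1200, burn_in = 300, seed = r))
    est <- ft$coefficients$estimate[ft$coefficients$type == "group"]
    truth <- sim$truth$proteins$beta_g
    hits <- hits + as.integer(abs(est - truth) <= 0.2)
  }
  # exact binomial lower bound at the oracle success probability
  expect_gte(hits, qbinom(0.005, n_rep, p_true))
})

test_that("batch fitting skips unfittable proteins and stays deterministic", {
  sim <- simulate_proteomics(proteomics_sim_config(n_proteins = 6, seed = 3))
  pep <- quiet(log_and_normalize(
    filter_by_peptide_count(filter_by_confidence(sim$peptides), 3), sim$design))
  cfg <- mcmc_config(iterations = 600, burn_in = 200, seed = 8)
  f1 <- quiet(fit_proteins(pep, sim$design, reference = "control", cfg))
  f2 <- quiet(fit_proteins(pep, sim$design, reference = "control", cfg))
  expect_identical(tidy(f1), tidy(f2))
  expect_s3_class(glance(f1), "tbl_df")
  expect_true(all(glance(f1)$sigma2 > 0))
})
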