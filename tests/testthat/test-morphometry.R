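test_that("group effects are exact on balanced constructed data", {
  # two groups, two donors, donor effects cancel; group means differ by 1
  rec <- tibble::tibble(
    cell_id = paste0("c", 1:8),
    donor = rep(c("D1", "D2"), 4),
    group = rep(c("ctl", "trt"), each = 4),
    y = c(0.2, -0.2, 0.2, -0.2, 1.2, 0.8, 1.2, 0.8))
  fit <- fit_group_donor_model(rec, "y", reference_group = "ctl",
                               log2_transform = FALSE)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "grouptrt"], 1, tolerance = 1e-12)

  # identical groups: zero effect, p = 1
  rec0 <- rec
  rec0$y <- rep(c(0.1, -0.1, 0.3, -0.3), 2)
  fit0 <- fit_group_donor_model(rec0, "y", reference_group = "ctl",
                                log2_transform = FALSE)
  td0 <- tidy(fit0)
  expect_equal(td0$estimate[td0$term == "grouptrt"], 0, tolerance = 1e-12)
  expect_equal(td0$p[td0$term == "grouptrt"], 1, tolerance = 1e-12)
})

test_that("a single donor reduces to the two-sample t-test", {
  set.seed(61)
  rec <- tibble::tibble(
    cell_id = paste0("c", 1:40),
    donor = "D1",
    group = rep(c("ctl", "trt"), each = 20),
    y = rnorm(40) + rep(c(0, 0.5), each = 20))
  fit <- fit_group_donor_model(rec, "y", reference_group = "ctl",
                               log2_transform = FALSE)
  td <- tidy(fit)
  tt <- t.test(y ~ group, data = rec, var.equal = TRUE)
  expect_equal(td$p[td$term == "grouptrt"], tt$p.value, tolerance = 1e-12)
  expect_equal(td$estimate[td$term == "grouptrt"],
               unname(diff(tt$estimate)), tolerance = 1e-12)
})

test_that("the group/donor fit equals the normal-equations oracle", {
  set.seed(62)
  for (i in 1:100) {
    nG <- sample(2:3, 1); nD <- sample(2:3, 1); n_per <- sample(4:8, 1)
    rec <- tidyr::expand_grid(group = LETTERS[seq_len(nG)],
                              donor = paste0("D", seq_len(nD)),
                              rep = seq_len(n_per)) |>
      dplyr::mutate(cell_id = dplyr::row_number(),
                    y = rnorm(dplyr::n()))
    fit <- fit_group_donor_model(rec, "y", reference_group = "A",
                                 log2_transform = FALSE)
    g <- factor(rec$group); d <- factor(rec$donor)
    X <- cbind(stats::model.matrix(~ g),
               stats::model.matrix(~ d, contrasts.arg = list(d = "contr.sum"))[, -1, drop = FALSE])
    beta <- ols_solve(X, rec$y)
    td <- tidy(fit)
    est <- td$estimate[match(paste0("group", levels(g)[-1]), td$term)]
    expect_equal(est, unname(beta[2:nG]), tolerance = 1e-10)
    # fitted-model residuals sum to zero
    expect_lt(abs(sum(resid(fit$model))), 1e-8)
  }
})

test_that("donor-adjusted recovery works on simulated cells", {
  sim <- simulate_morphometry(n_cells_per_group = 200,
                              group_effects = c(strain = 0.3),
                              donor_sd = 0.2, cell_sd = 0.25, seed = 71)
  fit <- fit_group_donor_model(sim$records, "nuclear_area",
                               reference_group = "control")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "groupstrain"], 0.3, tolerance = 0.2)
  expect_lt(td$p[td$term == "groupstrain"], 1e-6)
})

test_that("complete confounding of donor and group is an error", {
  rec <- tibble::tibble(cell_id = paste0("c", 1:20),
                        donor = rep(c("D1", "D2"), each = 10),
                        group = rep(c("ctl", "trt"), each = 10),
                        y = rnorm(20))
  expect_error(fit_group_donor_model(rec, "y", reference_group = "ctl",
                                     log2_transform = FALSE), "confounded")
})

test_that("ratio measures divide per cell and respect scale invariance", {
  rec <- tibble::tibble(cell_id = c("a", "b", "c"), donor = "D1",
                        group = c("ctl", "ctl", "trt"),
                        nuclear_area = c(50, 60, 80),
                        cytoplasmic_area = c(200, 0, 160))
  out <- quiet(ratio_metric(rec, "nuclear_area", "cytoplasmic_area"))
  expect_equal(nrow(out), 2)       # zero denominator excluded
  expect_equal(out$nuclear_area_to_cytoplasmic_area, c(0.25, 0.5))
  doubled <- rec
  doubled$nuclear_area <- doubled$nuclear_area * 2
  doubled$cytoplasmic_area <- doubled$cytoplasmic_area * 2
  out2 <- quiet(ratio_metric(doubled, "nuclear_area", "cytoplasmic_area"))
  expect_equal(out2$nuclear_area_to_cytoplasmic_area,
               out$nuclear_area_to_cytoplasmic_area)
})

test_that("normalization to control is per donor", {
  rec <- tibble::tibble(
    cell_id = paste0("c", 1:8),
    donor = rep(c("D1", "D2"), each = 4),
    group = rep(c("control", "control", "strain", "strain"), 2),
    area = c(10, 30, 40, 40, 100, 300, 400, 400))
  out <- normalize_to_control(rec, "area", "control")
  expect_equal(out$area[out$donor == "D1"], c(0.5, 1.5, 2, 2))
  expect_equal(out$area[out$donor == "D2"], c(0.5, 1.5, 2, 2))
})

test_that("log-log scaling regression returns the constructed exponent", {
  x <- seq(-2, 2, length.out = 50)
  d <- data.frame(expr = x, meas = 0.38 * x)
  fit <- loglog_scaling(d, "expr", "meas")
  expect_equal(fit$slope, 0.38, tolerance = 1e-10)
  expect_lt(fit$slope_sd, 1e-10)

  shifted <- loglog_scaling(data.frame(expr = x, meas = 0.38 * x + 2),
                            "expr", "meas")
  expect_equal(shifted$slope, fit$slope, tolerance = 1e-10)
  expect_equal(shifted$intercept, fit$intercept + 2, tolerance = 1e-10)

  set.seed(81)
  perm <- data.frame(expr = rnorm(2000), meas = rnorm(2000))
  pf <- loglog_scaling(perm, "expr", "meas")
  expect_lt(abs(pf$slope), 3 * pf$slope_sd + 1e-9)

  expect_error(loglog_scaling(data.frame(expr = rep(1, 5), meas = rnorm(5)),
                              "expr", "meas"), "variance")
  # per-condition means mode
  d2 <- data.frame(expr = rep(c(-1, 0, 1), each = 10) + rnorm(30, 0, 0.01),
                   meas = rep(c(-0.38, 0, 0.38), each = 10) + rnorm(30, 0, 0.01),
                   cond = rep(c("a", "b", "c"), each = 10))
  fm <- loglog_scaling(d2, "expr", "meas", mode = "means", by = "cond")
  expect_equal(fm$n, 3)
  expect_equal(fm$slope, 0.38, tolerance = 0.05)
})
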