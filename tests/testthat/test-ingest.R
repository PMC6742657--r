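test_that("peptide tables round-trip through CSV bit-for-bit", {
  design <- make_design()
  set.seed(1)
  tb <- make_peptides(matrix(rnorm(12, 20, 2), 3), design,
                      modifications = c("2:phospho", "", "1:mBBr"),
                      scores = c(17.3, 42.123456, 8.05))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peptide_table(tb, path)
  back <- read_peptide_table(path, design)
  expect_identical(as.data.frame(back), as.data.frame(tb))
})

test_that("reading validates sample columns, missing cells and offsets", {
  design <- make_design()
  tb <- make_peptides(matrix(c(20, 21, NA, 22, 20, 21, 22, 20), 2), design,
                      sequences = c("ACDK", "LMNPK"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peptide_table(tb, path)
  back <- read_peptide_table(path, design)
  expect_equal(nrow(back), 2)
  expect_true(is.na(back$ctl_D2[1]))  # empty cell stays missing

  # unknown sample column is a hard error naming the column
  tb2 <- tb
  names(tb2)[names(tb2) == "trt_D2"] <- "mystery_sample"
  readr::write_csv(tb2, path)
  expect_error(read_peptide_table(path, design), "mystery_sample")

  # zero intensities are censored non-detections, not measured zeros
  tb3 <- tb
  tb3$ctl_D1[1] <- 0
  readr::write_csv(tb3, path)
  expect_true(is.na(read_peptide_table(path, design)$ctl_D1[1]))

  # modification offset beyond the peptide errors with the row number
  tb4 <- tb
  tb4$modifications[2] <- "9:phospho"
  readr::write_csv(tb4, path)
  expect_error(read_peptide_table(path, design), "row 2")

  expect_error(read_peptide_table(path, design[0, ]), "2 groups")
})

test_that("confidence filter maps scores to p-values and applies BH", {
  # score 20 corresponds to p = 10^(-20/10) = 0.01
  expect_equal(pepnet:::score_to_p(20), 0.01)
  design <- make_design()
  # scores chosen so mapped p = 0.01, 0.02, 0.04, 0.5
  p_target <- c(0.01, 0.02, 0.04, 0.5)
  tb <- make_peptides(matrix(20, 4, 4), design, scores = -10 * log10(p_target))
  kept <- filter_by_confidence(tb, 0.2)
  # brute-force BH gives q = 0.04, 0.04, 0.0533, 0.5: first three kept
  expect_equal(bh_brute(p_target), c(0.04, 0.04, 0.16 / 3, 0.5),
               tolerance = 1e-12)
  expect_identical(kept$peptide_id, c("p1", "p2", "p3"))

  # ties share one adjusted value: all kept or all removed together
  tb_tie <- make_peptides(matrix(20, 4, 4), design, scores = rep(9, 4))
  expect_true(nrow(filter_by_confidence(tb_tie, 0.2)) %in% c(0, 4))

  expect_error(filter_by_confidence(tb[0, ], 0.2), "empty")
  expect_error(filter_by_confidence(tb, 0), "0, 1")
  expect_error(filter_by_confidence(tb, 1.2), "0, 1")
})

test_that("BH inside the confidence filter matches brute force on random vectors", {
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), bh_brute(p), tolerance = 0)
  }
})

test_that("peptide-count filter removes weakly supported proteins and is idempotent", {
  design <- make_design()
  m <- matrix(20, 10, 4)
  tb <- make_peptides(m, design,
                      accession = rep(c("A", "B", "C"), c(2, 3, 5)))
  # C has 5 rows but only 2 distinct sequences
  tb$sequence[9:10] <- tb$sequence[6:7]
  tb$sequence[8] <- tb$sequence[6]
  out <- quiet(filter_by_peptide_count(tb, 3))
  expect_identical(sort(unique(out$accession)), "B")   # 2 unique -> dropped; 3 -> kept
  expect_identical(quiet(filter_by_peptide_count(out, 3)), out)

  # non-unique peptides do not count towards support
  tb2 <- make_peptides(m[1:3, ], design, accession = "D")
  tb2$unique[3] <- FALSE
  expect_equal(nrow(quiet(filter_by_peptide_count(tb2, 3))), 0)
})

test_that("log2 median normalization centers every sample at exactly zero", {
  design <- make_design()
  tb <- make_peptides(matrix(c(1, 2, 3), 3, 4), design)
  out <- log_and_normalize(tb, design)
  expect_equal(out$ctl_D1, c(-1, 0, 1))
  set.seed(7)
  tb2 <- make_peptides(matrix(rnorm(40, 20, 3), 10), design)
  tb2$ctl_D1[c(2, 5)] <- NA
  out2 <- log_and_normalize(tb2, design)
  for (s in design$sample_id) {
    expect_lt(abs(median(out2[[s]], na.rm = TRUE)), 1e-12)
  }
  expect_identical(which(is.na(out2$ctl_D1)), c(2L, 5L))

  # samples with disjoint peptides are centered independently
  tb3 <- make_peptides(matrix(c(1, 2, NA, NA, NA, NA, 5, 9), 4, 2), make_design(donors = "D1"))
  out3 <- log_and_normalize(tb3, make_design(donors = "D1"))
  expect_equal(out3$ctl_D1[1:2], c(-0.5, 0.5))
  expect_equal(out3$trt_D1[3:4], c(-2, 2))

  tb4 <- tb
  tb4$trt_D2 <- NA_real_
  expect_error(log_and_normalize(tb4, design), "trt_D2")
})

test_that("PTM sites map onto protein coordinates by leftmost match", {
  design <- make_design(donors = "D1")
  tb <- make_peptides(matrix(20, 3, 2), design,
                      sequences = c("VSSR", "CCAK", "ACDK"),
                      modifications = c("2:phospho", "1:mBBr", ""))
  proteome <- c(P1 = "MKVSSRWCCAKQACDK")
  ann <- annotate_ptm_sites(tb, proteome)
  # peptide VSSR matches at 3; phospho offset 2 -> protein position 4 = S4
  expect_equal(ann$site[ann$peptide_id == "p1"], "S4")
  expect_false(ann$ambiguous[1])
  # mBBr keeps its registry label and mass delta
  expect_equal(ann$label[ann$peptide_id == "p2"], "mBBr")
  expect_equal(ann$mass_delta[ann$peptide_id == "p2"], 133.053)

  # a peptide occurring twice is flagged ambiguous at the leftmost match
  tb2 <- make_peptides(matrix(20, 1, 2), design, sequences = "VSSR",
                       modifications = "2:phospho")
  ann2 <- annotate_ptm_sites(tb2, c(P1 = "AVSSRKKVSSR"))
  expect_true(ann2$ambiguous)
  expect_equal(ann2$protein_position, 3L)

  tb3 <- make_peptides(matrix(20, 1, 2), design, sequences = "WWWW",
                       modifications = "1:phospho")
  expect_error(annotate_ptm_sites(tb3, c(P1 = "MKVSSR")), "not a substring")
})
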