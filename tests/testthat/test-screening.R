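# the worked 8-patient ratio set consistent with the published ROC numbers
worked_ratios <- function() {
  tibble::tibble(
    patient_id = sprintf("p%d", 1:8),
    positive_ratio = c(0.10, 0.20, 0.30, 0.45, 0.40, 0.94, 0.95, 0.96),
    n_cells = 40L,
    genotype = rep(c("WT", "MUT"), each = 4))
}

test_that("patient ratio aggregation is plain arithmetic", {
  preds <- tibble::tibble(
    patient_id = rep("a", 12),
    label = rep(c("MUT", "WT"), c(3, 9)),
    genotype = "MUT")
  pr <- patient_ratios(preds)
  expect_identical(pr$n_cells, 12L)
  expect_equal(pr$positive_ratio, 0.25)
  all_mut <- patient_ratios(tibble::tibble(patient_id = "b",
                                           label = rep("MUT", 5)))
  expect_identical(all_mut$positive_ratio, 1)
  expect_error(patient_ratios(tibble::tibble()), "nrow")
})

test_that("the worked example reproduces the published screening numbers", {
  roc <- roc_auc(worked_ratios())
  expect_identical(roc$auc, 0.9375)
  expect_identical(roc$auc, roc$concordance)
  op <- operating_points(roc)
  expect_identical(op$tpr_at_zero_fpr$value, 0.75)
  iv <- op$tpr_at_zero_fpr$threshold_interval
  expect_true(iv[1] < 0.933 && 0.933 <= iv[2])
  expect_identical(op$fpr_at_full_tpr$value, 0.25)
  iv2 <- op$fpr_at_full_tpr$threshold_interval
  expect_true(iv2[1] < 0.392 && 0.392 <= iv2[2])
})

test_that("degenerate ratio configurations give the expected AUC", {
  sep <- tibble::tibble(positive_ratio = c(0.1, 0.2, 0.8, 0.9),
                        genotype = c("WT", "WT", "MUT", "MUT"))
  expect_identical(roc_auc(sep)$auc, 1)
  op <- operating_points(roc_auc(sep))
  expect_identical(op$tpr_at_zero_fpr$value, 1)
  expect_identical(op$fpr_at_full_tpr$value, 0)
  tied <- tibble::tibble(positive_ratio = rep(0.5, 6),
                         genotype = rep(c("WT", "MUT"), 3))
  expect_identical(roc_auc(tied)$auc, 0.5)
  expect_error(roc_auc(tibble::tibble(positive_ratio = 0.3,
                                      genotype = "WT")),
               "both genotypes")
})

test_that("trapezoid AUC equals pair concordance on random instances", {
  set.seed(10)
  for (i in 1:500) {
    n1 <- sample(2:10, 1)
    n0 <- sample(2:10, 1)
    # discretized ratios so ties are frequent
    r <- tibble::tibble(
      positive_ratio = sample(0:8, n1 + n0, replace = TRUE) / 8,
      genotype = rep(c("MUT", "WT"), c(n1, n0)))
    roc <- roc_auc(r)
    expect_identical(roc$auc, roc$concordance)
  }
})

test_that("AUC is invariant to strictly increasing ratio transforms", {
  set.seed(11)
  r <- tibble::tibble(positive_ratio = runif(12),
                      genotype = rep(c("MUT", "WT"), 6))
  a <- roc_auc(r)$auc
  r2 <- r
  r2$positive_ratio <- plogis(3 * r2$positive_ratio - 1)
  expect_identical(roc_auc(r2)$auc, a)
})

test_that("cross-check against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  r <- tibble::tibble(
    positive_ratio = sample(0:20, 30, replace = TRUE) / 20,
    genotype = rep(c("MUT", "WT"), 15))
  mine <- roc_auc(r)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = r$genotype, predictor = r$positive_ratio,
    levels = c("WT", "MUT"), direction = "<")))
  expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
})

test_that("duplicating a patient at an existing ratio keeps operating points feasible", {
  base <- worked_ratios()
  op0 <- operating_points(roc_auc(base))
  dup <- dplyr::bind_rows(base, base[6, ])
  op1 <- operating_points(roc_auc(dup))
  expect_identical(op0$tpr_at_zero_fpr$threshold_interval,
                   op1$tpr_at_zero_fpr$threshold_interval)
  expect_gte(op1$tpr_at_zero_fpr$value, op0$tpr_at_zero_fpr$value)
})

test_that("tidy and glance summarize screening results", {
  sc <- screen_patients(tibble::tibble(
    patient_id = rep(c("a", "b"), each = 10),
    label = c(rep("MUT", 8), rep("WT", 2), rep("WT", 9), "MUT"),
    genotype = rep(c("MUT", "WT"), each = 10)))
  g <- glance(sc$roc)
  expect_identical(g$auc, 1)
  expect_identical(g$n_positive, 1L)
  td <- tidy(sc$roc)
  expect_true(all(c("threshold", "fpr", "tpr") %in% names(td)))
})
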