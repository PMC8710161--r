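test_that("group_summary and welch_from_summary validate inputs", {
  expect_error(group_summary(1, 0, 1), "n")
  expect_error(group_summary(10, 0, 0), "sd")
  a <- group_summary(10, 5, 2, "benign", "CT@40keV")
  b <- group_summary(12, 7, 3, "malignant", "CT@70keV")
  expect_error(welch_from_summary(a, b), "feature names disagree")
})

test_that("identical summaries give t = 0, p = 1", {
  a <- group_summary(20, 3.5, 1.2)
  w <- welch_from_summary(a, a)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
})

test_that("Welch statistic matches the direct formula and quadrature p", {
  a <- group_summary(25, 41.24, 18.45)
  b <- group_summary(72, 0.96, 19.45)
  w <- welch_from_summary(a, b)
  # independent evaluation of the formula, term by term
  se <- sqrt(18.45^2 / 25 + 19.45^2 / 72)
  t_direct <- (41.24 - 0.96) / se
  va <- 18.45^2 / 25; vb <- 19.45^2 / 72
  df_direct <- (va + vb)^2 / (va^2 / 24 + vb^2 / 71)
  expect_equal(w$t, t_direct)
  expect_equal(w$df, df_direct)
  # p-value by numeric integration of the t density
  tdens <- function(x) {
    gamma((df_direct + 1) / 2) / (sqrt(df_direct * pi) *
      gamma(df_direct / 2)) * (1 + x^2 / df_direct)^(-(df_direct + 1) / 2)
  }
  p_quad <- 2 * stats::integrate(tdens, abs(t_direct), Inf)$value
  expect_equal(w$p, p_quad, tolerance = 1e-6)
})

test_that("Welch agrees with stats::t.test on reconstructed samples", {
  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(20)
    a <- group_summary(15, mean(x), sd(x))
    b <- group_summary(20, mean(y), sd(y))
    ref <- stats::t.test(x, y)
    w <- welch_from_summary(a, b)
    expect_equal(w$t, unname(ref$statistic))
    expect_equal(w$df, unname(ref$parameter))
    expect_equal(w$p, ref$p.value)
    refp <- stats::t.test(x, y, var.equal = TRUE)
    wp <- welch_from_summary(a, b, pooled = TRUE)
    expect_equal(wp$t, unname(refp$statistic))
    expect_equal(wp$p, refp$p.value)
  }
})

test_that("reference summaries hold 14 features at the published sizes", {
  ref <- effusion_reference_summaries()
  expect_equal(nrow(ref), 14L)
  expect_setequal(unique(ref$n_benign), 25L)
  expect_setequal(unique(ref$n_malignant), 72L)
  expect_true(all(sprintf("CT@%dkeV", seq(40, 140, 10)) %in% ref$feature))
  expect_true(all(c("lipid_water", "water_iodine", "water_calcium")
                  %in% ref$feature))
})

test_that("synthetic cohorts are seeded, sized and centred correctly", {
  spec <- cohort_spec(seed = 3)
  coh <- synth_cohort(spec)
  expect_identical(coh, synth_cohort(cohort_spec(seed = 3)))
  expect_equal(nrow(coh), 97L)
  expect_equal(sum(coh$group == "benign"), 25L)
  expect_equal(sum(coh$group == "malignant"), 72L)
  ref <- effusion_reference_summaries()
  expect_true(all(ref$feature %in% names(coh)))
  # sample means within 4 standard errors of the generating means
  for (i in seq_len(nrow(ref))) {
    fe <- ref$feature[i]
    m_mal <- mean(coh[[fe]][coh$group == "malignant"])
    expect_lt(abs(m_mal - ref$malignant_mean[i]),
              4 * ref$malignant_sd[i] / sqrt(72))
    m_ben <- mean(coh[[fe]][coh$group == "benign"])
    expect_lt(abs(m_ben - ref$benign_mean[i]),
              4 * ref$benign_sd[i] / sqrt(25))
  }
})

test_that("near-zero spread collapses samples onto the spec means", {
  ref <- effusion_reference_summaries()
  ref$benign_sd <- 0
  ref$malignant_sd <- 0
  coh <- synth_cohort(cohort_spec(features = ref, seed = 1))
  for (i in c(1, 14)) {
    fe <- ref$feature[i]
    expect_equal(mean(coh[[fe]][coh$group == "benign"]),
                 ref$benign_mean[i], tolerance = 1e-9)
  }
})

test_that("cohort Welch table recovers the generating effect directions", {
  coh <- synth_cohort(cohort_spec(seed = 3))
  tab <- cohort_welch(coh)
  ref <- effusion_reference_summaries()
  for (i in seq_len(nrow(ref))) {
    row <- tab[tab$feature == ref$feature[i], ]
    true_dir <- sign(ref$malignant_mean[i] - ref$benign_mean[i])
    # only assert direction where the generating effect is sizeable
    pooled_se <- sqrt(ref$malignant_sd[i]^2 / 72 + ref$benign_sd[i]^2 / 25)
    if (abs(ref$malignant_mean[i] - ref$benign_mean[i]) > 4 * pooled_se)
      expect_equal(sign(row$mean_diff), true_dir)
  }
})

test_that("ROC analysis is exact under perfect separation", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c("benign", "malignant"), each = 3)
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$sens_at_cutoff, 1)
  expect_equal(r$spec_at_cutoff, 1)
  expect_true(r$youden_cutoff > 3 && r$youden_cutoff <= 10)
  expect_error(roc_analysis(scores, rep("benign", 6)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney oracle with ties", {
  set.seed(52)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties on purpose
    labels <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, mw_auc(scores, labels, "malignant"))
  }
})

test_that("uninformative scores give AUC near one half", {
  set.seed(53)
  scores <- rnorm(2000)
  labels <- sample(c("benign", "malignant"), 2000, replace = TRUE)
  r <- roc_analysis(scores, labels)
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("ROC curve points are monotone and AUC matches pROC", {
  set.seed(54)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- rep(c("malignant", "benign"), c(40, 60))
  r <- roc_analysis(scores, labels)
  fpr <- 1 - r$specificity
  ord <- order(fpr, r$sensitivity)
  expect_true(all(diff(r$sensitivity[ord]) >= 0))
  skip_if_not_installed("pROC")
  ref <- pROC::roc(labels, scores, levels = c("benign", "malignant"),
                   direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
})

test_that("diagnostic_eval matches a hand tally and its edge cases", {
  coh <- data.frame(
    patient_id = sprintf("P%d", 1:6),
    group = c("malignant", "malignant", "malignant",
              "benign", "benign", "benign"),
    lipid_water = c(120, 95, 130, 90, 110, 80))
  # threshold 100: TP = {120, 130} = 2, FN = {95} = 1,
  #                TN = {90, 80} = 2, FP = {110} = 1
  out <- diagnostic_eval(coh, "lipid_water", 100)
  expect_equal(unname(out["sensitivity"]), 2 / 3)
  expect_equal(unname(out["specificity"]), 2 / 3)
  expect_equal(attr(out, "counts"), c(tp = 2L, fp = 1L, tn = 2L, fn = 1L))
  low <- diagnostic_eval(coh, "lipid_water", 0)
  expect_equal(as.numeric(low), c(1, 0))
  high <- diagnostic_eval(coh, "lipid_water", 1e6)
  expect_equal(as.numeric(high), c(0, 1))
  expect_error(diagnostic_eval(coh, "missing_col", 1), "not found")
  expect_error(diagnostic_eval(coh, "lipid_water", Inf), "finite")
})

test_that("Youden cutoff maximizes sensitivity + specificity - 1", {
  set.seed(55)
  scores <- c(rnorm(30, 2), rnorm(30))
  labels <- rep(c("malignant", "benign"), each = 30)
  r <- roc_analysis(scores, labels)
  youden <- r$sensitivity + r$specificity - 1
  expect_equal(r$sens_at_cutoff + r$spec_at_cutoff - 1, max(youden))
  # brute check against every threshold via diagnostic_eval
  coh <- data.frame(group = labels, x = scores)
  vals <- vapply(r$thresholds[is.finite(r$thresholds)], function(th) {
    se_sp <- diagnostic_eval(coh, "x", th)
    sum(se_sp) - 1
  }, numeric(1))
  expect_equal(max(youden), max(vals))
})
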