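#' Group summary statistics for one feature
#'
#' The `(n, mean, sd)` triplet in which spectral-CT effusion measurements
#' are reported: CT values (HU) at single energies and base-material
#' concentrations (g/L) for a benign or malignant patient group.
#'
#' @param n Number of patients (>= 2).
#' @param mean Feature mean (HU or g/L).
#' @param sd Standard deviation (> 0, same units).
#' @param label Group label, e.g. `"benign"` or `"malignant"`.
#' @param feature Feature name, e.g. `"CT@40keV"` or `"water_calcium"`.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd, label = "", feature = "") {
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  structure(list(n = n, mean = as.numeric(mean), sd = as.numeric(sd),
                 label = label, feature = feature),
            class = "group_summary")
}

#' Welch two-sample t-test from group summaries
#'
#' Computes the unequal-variance (Welch) two-sample t statistic directly
#' from `(n, mean, sd)` summaries:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)`, with
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value. With
#' `pooled = TRUE` the classical equal-variance test is used instead.
#' Welch is the default because the groups compared here have unequal
#' sizes (25 vs 72) and visibly unequal spreads.
#'
#' @param a,b [group_summary()] objects. If both carry non-empty feature
#'   names they must match.
#' @param pooled Use the pooled-variance (Student) test instead of Welch.
#' @return An object of class `welch_result` with `t`, `df`, `p`,
#'   `mean_diff`, `feature`.
#' @examples
#' benign <- group_summary(25, 41.24, 18.45, "benign", "CT@40keV")
#' malignant <- group_summary(72, 0.96, 19.45, "malignant", "CT@40keV")
#' welch_from_summary(benign, malignant)
#' @export
welch_from_summary <- function(a, b, pooled = FALSE) {
  if (!inherits(a, "group_summary") || !inherits(b, "group_summary"))
    stop("`a` and `b` must be group_summary objects", call. = FALSE)
  if (nzchar(a$feature) && nzchar(b$feature) &&
      !identical(a$feature, b$feature))
    stop("feature names disagree: ", a$feature, " vs ", b$feature,
         call. = FALSE)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (pooled) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, mean_diff = a$mean - b$mean,
                 feature = a$feature, pooled = pooled),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result>%s t = %.4f, df = %.2f, p = %.4g (%s)\n",
              if (nzchar(x$feature)) paste0(" ", x$feature, ":") else "",
              x$t, x$df, x$p,
              if (x$pooled) "pooled variance" else "Welch"))
  invisible(x)
}

#' Published per-group feature summaries for serous cavity effusion
#'
#' The benign (n = 25) versus malignant (n = 72) group means and standard
#' deviations for monoenergetic CT values at 40–140 keV (10 keV steps, HU)
#' and for the three base-material concentration pairs (g/L). These values
#' parameterize the default synthetic cohort and are the inputs to the
#' summary-statistics Welch tests.
#'
#' @return A data.frame with columns `feature`, `unit`, `benign_mean`,
#'   `benign_sd`, `malignant_mean`, `malignant_sd`, `n_benign`,
#'   `n_malignant`.
#' @export
effusion_reference_summaries <- function() {
  kev <- seq(40, 140, by = 10)
  ct <- data.frame(
    feature = sprintf("CT@%dkeV", kev),
    unit = "HU",
    benign_mean = c(41.24, 31.75, 25.78, 21.15, 18.11, 15.99, 15.24,
                    15.02, 14.71, 14.11, 13.56),
    benign_sd = c(18.45, 12.8, 11.12, 6.27, 6.33, 5.24, 8.45, 4.21,
                  6.66, 6.17, 6.54),
    malignant_mean = c(0.96, 7.99, 12.57, 15.82, 17.55, 19.33, 20.01,
                       20.14, 21.98, 21.44, 21.97),
    malignant_sd = c(19.45, 12.48, 11.22, 7.67, 10.63, 11.27, 9.67,
                     10.44, 10.57, 11.66, 12.57))
  base <- data.frame(
    feature = c("lipid_water", "water_iodine", "water_calcium"),
    unit = "g/L",
    benign_mean = c(201.45, 1008.48, 1009.48),
    benign_sd = c(197.56, 18.27, 9.21),
    malignant_mean = c(221.44, 1024.69, 1027.87),
    malignant_sd = c(189.45, 19.48, 11.66))
  out <- rbind(ct, base)
  out$n_benign <- 25L
  out$n_malignant <- 72L
  out
}

#' Specification of a synthetic two-group effusion cohort
#'
#' Per-feature, per-group Gaussian parameters plus group sizes. The
#' default reproduces the published group structure: 25 benign and 72
#' malignant patients, features drawn independently around the reference
#' means/SDs of [effusion_reference_summaries()]. An optional common
#' correlation `rho` induces equicorrelated features within a patient via
#' a shared latent factor.
#'
#' @param features Data.frame shaped like [effusion_reference_summaries()].
#' @param n_benign,n_malignant Group sizes (>= 2).
#' @param rho Common within-patient feature correlation in `[0, 1)`.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(features = effusion_reference_summaries(),
                        n_benign = 25L, n_malignant = 72L, rho = 0,
                        seed = 1L) {
  needed <- c("feature", "benign_mean", "benign_sd", "malignant_mean",
              "malignant_sd")
  missing <- setdiff(needed, names(features))
  if (length(missing))
    stop("`features` is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(features$feature))
    stop("`features$feature` must be unique", call. = FALSE)
  sds <- c(features$benign_sd, features$malignant_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("feature SDs must be finite and >= 0", call. = FALSE)
  if (n_benign < 2L || n_malignant < 2L)
    stop("group sizes must be >= 2", call. = FALSE)
  if (rho < 0 || rho >= 1)
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  structure(list(features = features, n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant), rho = rho,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw a synthetic patient cohort
#'
#' One row per synthetic patient with a group label and every feature
#' drawn Gaussian per the spec (standard deviations of exactly zero are
#' floored at `.Machine$double.eps`). Seeded and reproducible.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame: `patient_id`, `group`, then one column per
#'   feature.
#' @examples
#' head(synth_cohort(cohort_spec(seed = 3)))
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec"))
    stop("`spec` must be a cohort_spec", call. = FALSE)
  set.seed(spec$seed)
  f <- spec$features
  draw_group <- function(n, means, sds) {
    sds <- pmax(sds, .Machine$double.eps)
    z <- matrix(stats::rnorm(n * nrow(f)), n, nrow(f))
    if (spec$rho > 0) {
      shared <- stats::rnorm(n)
      z <- sqrt(spec$rho) * shared + sqrt(1 - spec$rho) * z
    }
    sweep(sweep(z, 2L, sds, "*"), 2L, means, "+")
  }
  ben <- draw_group(spec$n_benign, f$benign_mean, f$benign_sd)
  mal <- draw_group(spec$n_malignant, f$malignant_mean, f$malignant_sd)
  vals <- rbind(ben, mal)
  colnames(vals) <- f$feature
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(nrow(vals))),
    group = rep(c("benign", "malignant"),
                c(spec$n_benign, spec$n_malignant)),
    check.names = FALSE)
  cbind(out, as.data.frame(vals, check.names = FALSE))
}

#' Per-feature Welch tests on a cohort table
#'
#' Summarizes each feature by group and applies [welch_from_summary()],
#' optionally with Bonferroni adjustment across features (off by
#' default, matching the source analysis which applies none).
#'
#' @param cohort A cohort data.frame as from [synth_cohort()].
#' @param group_col Name of the group column.
#' @param positive_label Group treated as "malignant" in the mean
#'   difference sign (reported as `malignant_mean - benign_mean`).
#' @param bonferroni Apply Bonferroni correction across features.
#' @return Data.frame with one row per feature: group means/SDs, `t`,
#'   `df`, `p` (and `p_adj` if requested).
#' @export
cohort_welch <- function(cohort, group_col = "group",
                         positive_label = "malignant",
                         bonferroni = FALSE) {
  groups <- unique(cohort[[group_col]])
  if (length(groups) != 2L)
    stop("cohort must contain exactly two groups", call. = FALSE)
  neg <- setdiff(groups, positive_label)
  feats <- setdiff(names(cohort), c("patient_id", group_col))
  rows <- lapply(feats, function(fe) {
    x <- cohort[[fe]][cohort[[group_col]] == positive_label]
    y <- cohort[[fe]][cohort[[group_col]] == neg]
    w <- welch_from_summary(
      group_summary(length(x), mean(x), stats::sd(x), positive_label, fe),
      group_summary(length(y), mean(y), stats::sd(y), neg, fe))
    data.frame(feature = fe,
               malignant_mean = mean(x), malignant_sd = stats::sd(x),
               benign_mean = mean(y), benign_sd = stats::sd(y),
               mean_diff = mean(x) - mean(y),
               t = w$t, df = w$df, p = w$p)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_adj <- pmin(1, out$p * nrow(out))
  out
}

#' ROC curve, AUC and Youden cutoff for a continuous score
#'
#' Sweeps thresholds (midpoints between consecutive sorted unique scores,
#' plus infinite sentinels) under the convention "positive if
#' score > threshold", computes sensitivity and specificity at each,
#' trapezoidal AUC, and the Youden cutoff (threshold maximizing
#' sensitivity + specificity - 1; the lower threshold wins ties). The
#' trapezoidal AUC over this sweep equals the Mann–Whitney statistic
#' `U / (n_pos * n_neg)` with ties credited 1/2.
#'
#' @param scores Numeric scores (higher = more suspicious of the positive
#'   class).
#' @param labels Class labels, same length as `scores`.
#' @param positive_label The label counted as positive; default
#'   `"malignant"`.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_cutoff`, `sens_at_cutoff`,
#'   `spec_at_cutoff`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive_label = "malignant") {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive_label
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
                  Inf)
  sens <- vapply(thresholds, function(th) mean(scores[pos] > th),
                 numeric(1))
  spec <- vapply(thresholds, function(th) mean(scores[!pos] <= th),
                 numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(sens)]) / 2)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[which.min(thresholds[best])]
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 youden_cutoff = thresholds[best],
                 sens_at_cutoff = sens[best],
                 spec_at_cutoff = spec[best],
                 n_pos = sum(pos), n_neg = sum(!pos),
                 positive_label = positive_label),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f | Youden cutoff %.4g (sens %.3f, spec %.3f) | %d pos / %d neg\n",
              x$auc, x$youden_cutoff, x$sens_at_cutoff, x$spec_at_cutoff,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity and specificity of a fixed decision threshold
#'
#' Applies the rule "feature value > threshold implies positive
#' (malignant)" to a cohort table and tallies the confusion counts.
#'
#' @param cohort A cohort data.frame.
#' @param feature Feature column name.
#' @param threshold Finite decision threshold.
#' @param group_col,positive_label As in [cohort_welch()].
#' @return Named numeric vector `c(sensitivity, specificity)` with the
#'   confusion counts attached as the `"counts"` attribute.
#' @export
diagnostic_eval <- function(cohort, feature, threshold,
                            group_col = "group",
                            positive_label = "malignant") {
  if (!feature %in% names(cohort))
    stop("feature not found in cohort: ", feature, call. = FALSE)
  if (!is.finite(threshold))
    stop("`threshold` must be finite", call. = FALSE)
  truth <- cohort[[group_col]] == positive_label
  call_pos <- cohort[[feature]] > threshold
  tp <- sum(call_pos & truth); fn <- sum(!call_pos & truth)
  tn <- sum(!call_pos & !truth); fp <- sum(call_pos & !truth)
  structure(c(sensitivity = tp / (tp + fn),
              specificity = tn / (tn + fp)),
            counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}
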