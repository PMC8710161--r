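#' Tolerance rule defining a registration mismatch
#'
#' A trial counts as a mismatch (gross registration failure) when any
#' error component of the recovered transform versus ground truth exceeds
#' its tolerance. Defaults — 2 degrees rotation, 0.05 absolute scale, 2 px
#' translation — are an order looser than typical converged accuracy, so
#' the rule flags gross failures rather than imprecision.
#'
#' @param rot_tol Rotation tolerance in degrees (> 0).
#' @param scale_tol Absolute per-axis scale-factor tolerance (> 0).
#' @param trans_tol Per-axis translation tolerance in pixels (> 0).
#' @return An object of class `mismatch_rule`.
#' @export
mismatch_rule <- function(rot_tol = 2, scale_tol = 0.05, trans_tol = 2) {
  if (any(c(rot_tol, scale_tol, trans_tol) <= 0))
    stop("all mismatch tolerances must be strictly positive", call. = FALSE)
  structure(list(rot_tol = rot_tol, scale_tol = scale_tol,
                 trans_tol = trans_tol), class = "mismatch_rule")
}

#' Angular difference folded to [0, 180] degrees
#' @param a,b Angles in degrees.
#' @return Absolute difference on the circle.
#' @export
angle_error <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Classify a registration result as mismatch or success
#'
#' @param result A `registration_result` from [run_csa()]/[run_ga()], or a
#'   bare [transform_params()].
#' @param truth The ground-truth [transform_params()].
#' @param rule A [mismatch_rule()].
#' @return `TRUE` iff any error component exceeds its tolerance. The error
#'   components are attached as the `"errors"` attribute (rotation error on
#'   the circle; max per-axis scale and translation errors).
#' @export
classify_mismatch <- function(result, truth, rule = mismatch_rule()) {
  rec <- if (inherits(result, "registration_result")) result$best_params
         else result
  if (!inherits(rec, "transform_params") ||
      !inherits(truth, "transform_params"))
    stop("need transform_params for both recovered and truth", call. = FALSE)
  err <- c(rotation = angle_error(rec$rotation, truth$rotation),
           scale = max(abs(rec$scale - truth$scale)),
           translation = max(abs(rec$translation - truth$translation)))
  out <- err["rotation"] > rule$rot_tol ||
         err["scale"] > rule$scale_tol ||
         err["translation"] > rule$trans_tol
  structure(unname(out), errors = err)
}

#' Paired CSA-vs-GA registration benchmark on seeded phantoms
#'
#' Draws `n_trials` phantom pairs with fresh ground truths (per-trial seeds
#' derived deterministically from `master_seed`), registers each with the
#' clonal selection algorithm and — on bit-identical inputs and a matched
#' objective-evaluation budget — with the genetic-algorithm baseline, and
#' classifies every trial with the mismatch rule.
#'
#' @param n_trials Number of phantom pairs (>= 1).
#' @param spec A [phantom_spec()] template; its seed is overridden per
#'   trial.
#' @param config A [csa_config()] used for both algorithms (the GA reads
#'   the shared probabilities and bounds from it); its seed is likewise
#'   overridden per trial.
#' @param rule A [mismatch_rule()].
#' @param master_seed Seed from which all per-trial seeds derive.
#' @param algorithms Character subset of `c("csa", "ga")`.
#' @return A `benchmark_report`: `records` (one data.frame row per trial
#'   and algorithm: seed, truth, recovered transform, error components,
#'   mismatch flag, best NMI, evaluations, wall time — the last is
#'   informational only and excluded from reproducibility comparisons),
#'   `mismatch_count` and `mean_best_nmi` per algorithm, `n_trials`,
#'   `master_seed`.
#' @export
run_benchmark <- function(n_trials = 20L, spec = phantom_spec(),
                          config = csa_config(), rule = mismatch_rule(),
                          master_seed = 42L,
                          algorithms = c("csa", "ga")) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  set.seed(master_seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  rows <- list()
  for (trial in seq_len(n_trials)) {
    sp <- spec
    sp$seed <- trial_seeds[trial]
    ph <- generate_phantom(sp)
    cfg <- config
    cfg$seed <- trial_seeds[trial]
    budget <- NULL
    for (algo in algorithms) {
      row <- tryCatch({
        t0 <- proc.time()[["elapsed"]]
        res <- if (algo == "csa") run_csa(ph$fixed, ph$moving, cfg)
               else run_ga(ph$fixed, ph$moving, cfg,
                           max_evaluations = budget)
        wall <- proc.time()[["elapsed"]] - t0
        mis <- classify_mismatch(res, ph$truth, rule)
        err <- attr(mis, "errors")
        if (algo == "csa") budget <- res$evaluations
        data.frame(trial = trial, algo = algo, seed = cfg$seed,
                   true_rotation = ph$truth$rotation,
                   true_scale_r = ph$truth$scale[1],
                   true_scale_c = ph$truth$scale[2],
                   true_trans_r = ph$truth$translation[1],
                   true_trans_c = ph$truth$translation[2],
                   rec_rotation = res$best_params$rotation,
                   rec_scale_r = res$best_params$scale[1],
                   rec_scale_c = res$best_params$scale[2],
                   rec_trans_r = res$best_params$translation[1],
                   rec_trans_c = res$best_params$translation[2],
                   err_rotation = err[["rotation"]],
                   err_scale = err[["scale"]],
                   err_translation = err[["translation"]],
                   mismatch = as.logical(mis),
                   best_nmi = res$best_nmi,
                   evaluations = res$evaluations,
                   generations = res$generations_run,
                   wall_time_s = wall,
                   error = NA_character_)
      }, error = function(e) {
        data.frame(trial = trial, algo = algo, seed = cfg$seed,
                   true_rotation = NA, true_scale_r = NA, true_scale_c = NA,
                   true_trans_r = NA, true_trans_c = NA,
                   rec_rotation = NA, rec_scale_r = NA, rec_scale_c = NA,
                   rec_trans_r = NA, rec_trans_c = NA,
                   err_rotation = NA, err_scale = NA, err_translation = NA,
                   mismatch = NA, best_nmi = NA, evaluations = NA,
                   generations = NA, wall_time_s = NA,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  records <- do.call(rbind, rows)
  by_algo <- split(records, records$algo)
  mismatch_count <- vapply(by_algo, function(d)
    sum(d$mismatch, na.rm = TRUE) + sum(is.na(d$mismatch)), numeric(1))
  mean_best_nmi <- vapply(by_algo, function(d)
    mean(d$best_nmi, na.rm = TRUE), numeric(1))
  structure(list(records = records, mismatch_count = mismatch_count,
                 mean_best_nmi = mean_best_nmi, n_trials = n_trials,
                 master_seed = master_seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", x$n_trials, " trials (master seed ",
      x$master_seed, ")\n", sep = "")
  for (algo in names(x$mismatch_count)) {
    cat(sprintf("  %s: %d mismatches, mean best NMI %.5f\n",
                toupper(algo), x$mismatch_count[[algo]],
                x$mean_best_nmi[[algo]]))
  }
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Produces `report.csv` (one row per trial and algorithm) and
#' `summary.json` in `dir`. Wall-time columns are informational and
#' excluded from `summary.json` so that equal master seeds give
#' byte-identical summaries.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if needed).
#' @param extra Named list merged into the JSON summary (e.g. resolved
#'   configuration).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$records, file.path(dir, "report.csv"),
                   row.names = FALSE)
  summary <- c(list(version = as.character(utils::packageVersion("clonereg")),
                    n_trials = report$n_trials,
                    master_seed = report$master_seed,
                    mismatch_count = as.list(report$mismatch_count),
                    mean_best_nmi = as.list(report$mean_best_nmi)),
               extra)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
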