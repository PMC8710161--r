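#' Configuration for the clonal selection optimizer
#'
#' Collects every tunable of the clonal selection algorithm (CSA) and of
#' the genetic-algorithm baseline that shares its objective. Defaults
#' follow the published configuration where one is stated (crossover
#' probability Yi = 0.7, mutation probability Yt = 0.02, memory set of 30)
#' and standard CLONALG practice elsewhere.
#'
#' @param pop_size Antibodies per generation (default 400). The large
#'   default buys global coverage: the remainder set Pm = pop_size -
#'   memory_size supplies `d` fresh random probes per generation, and
#'   the initial draw must place candidates near the (often narrow) NMI
#'   basin for the clone refinement to capture it.
#' @param memory_size Size of the elite memory set Pn (default 30).
#' @param crossover_prob Per-pair crossover probability Yi in `[0, 1]`.
#' @param mutation_prob Per-gene mutation probability Yt in `[0, 1]`.
#' @param K Number of top memory antibodies cloned each generation
#'   (default 10; cloning more distinct parents keeps the crossover hull
#'   wide enough to track curved ridges of the NMI surface).
#' @param clone_factor Clone-count scale beta: the rank-i parent receives
#'   `max(1, round(beta * |Pn| / i))` clones.
#' @param d Number of lowest-affinity remainder (Pm) antibodies
#'   reinitialized each generation ("extinction"); default 20% of
#'   `pop_size - memory_size`.
#' @param max_generations Hard generation cap.
#' @param stall_generations,stall_tol Terminate once the best affinity has
#'   improved by less than `stall_tol` for `stall_generations` consecutive
#'   generations.
#' @param sigma_max Per-gene hypermutation scale ceiling; default 10% of
#'   each gene's bound range. Scalar or per-gene vector.
#' @param bounds A [param_bounds()] object (carries the gene layout).
#' @param bins,min_overlap,interpolation Passed to the NMI objective
#'   ([nmi()]); nearest-neighbour interpolation makes the objective
#'   piecewise constant (useful for integer-displacement searches).
#' @param seed RNG seed recorded with every run.
#' @param single_replacement If `TRUE`, the memory re-selection step
#'   replaces at most the single worst memory antibody per generation
#'   instead of merging all improving clones.
#' @return An object of class `csa_config`.
#' @export
csa_config <- function(pop_size = 400L, memory_size = 30L,
                       crossover_prob = 0.7, mutation_prob = 0.02,
                       K = 10L, clone_factor = 1, d = NULL,
                       max_generations = 100L, stall_generations = 15L,
                       stall_tol = 1e-5, sigma_max = NULL,
                       bounds = param_bounds(), bins = 16L,
                       min_overlap = 0.25,
                       interpolation = c("linear", "nearest"),
                       seed = NULL, single_replacement = FALSE) {
  interpolation <- match.arg(interpolation)
  pop_size <- as.integer(pop_size)
  memory_size <- as.integer(memory_size)
  K <- as.integer(K)
  if (is.null(d)) d <- round(0.2 * max(0L, pop_size - memory_size))
  d <- as.integer(d)
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1)
    stop("crossover_prob and mutation_prob must lie in [0, 1]",
         call. = FALSE)
  if (pop_size < 1L) stop("pop_size must be >= 1", call. = FALSE)
  if (memory_size > pop_size)
    stop("memory_size must not exceed pop_size", call. = FALSE)
  if (K < 1L || K > memory_size)
    stop("K must satisfy 1 <= K <= memory_size", call. = FALSE)
  if (d < 0L || d > pop_size - memory_size)
    stop("d must satisfy 0 <= d <= pop_size - memory_size", call. = FALSE)
  if (clone_factor <= 0) stop("clone_factor must be > 0", call. = FALSE)
  if (is.null(sigma_max)) sigma_max <- 0.1 * (bounds$upper - bounds$lower)
  sigma_max <- rep_len(as.numeric(sigma_max), length(bounds$lower))
  structure(list(pop_size = pop_size, memory_size = memory_size,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, K = K,
                 clone_factor = clone_factor, d = d,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 stall_tol = stall_tol, sigma_max = sigma_max,
                 bounds = bounds, bins = as.integer(bins),
                 min_overlap = min_overlap, interpolation = interpolation,
                 seed = seed,
                 single_replacement = isTRUE(single_replacement)),
            class = "csa_config")
}

new_antibody <- function(genes, affinity = NA_real_) {
  list(genes = genes, affinity = affinity)
}

affinities <- function(pop) vapply(pop, `[[`, numeric(1), "affinity")

random_antibody <- function(bounds, affinity_fn) {
  g <- stats::runif(length(bounds$lower), bounds$lower, bounds$upper)
  new_antibody(g, affinity_fn(g))
}

#' Build the NMI affinity function for an image pair
#'
#' Returns a closure mapping a gene vector to the normalized mutual
#' information between the fixed image warped by the decoded transform and
#' the moving image. Used internally by [run_csa()] and [run_ga()];
#' exported so that custom searches and exhaustive oracles can score the
#' identical objective.
#'
#' @param fixed,moving Equal-shape images.
#' @param config A [csa_config()] (supplies bins, overlap floor, layout).
#' @return `function(genes) -> affinity` (NMI, or 0 for invalid overlap).
#' @export
nmi_affinity <- function(fixed, moving, config = csa_config()) {
  a <- as_pixels(fixed)
  b <- as_pixels(moving)
  if (!identical(dim(a), dim(b)))
    stop("fixed and moving must have identical shapes", call. = FALSE)
  layout <- config$bounds$layout
  bins <- config$bins
  floor_frac <- config$min_overlap
  interp <- if (is.null(config$interpolation)) "linear"
            else config$interpolation
  b_finite <- is.finite(b)
  function(genes) {
    w <- apply_transform(a, decode_params(genes, layout), interp)
    ok <- is.finite(w) & b_finite
    if (mean(ok) < floor_frac) return(0)
    nmi_from_valid(w[ok], b[ok], bins)
  }
}

#' Initialize a random antibody population
#'
#' Genes are drawn uniformly within the configured bounds and affinities
#' are evaluated immediately (every selection step relies on them).
#'
#' @param config A [csa_config()].
#' @param affinity_fn Objective closure, e.g. from [nmi_affinity()].
#' @return List of `pop_size` antibodies (`genes`, `affinity`).
#' @export
initialize_population <- function(config, affinity_fn) {
  lapply(seq_len(config$pop_size), function(i)
    random_antibody(config$bounds, affinity_fn))
}

#' Split a population into memory set Pn and remainder Pm
#'
#' The `memory_size` highest-affinity antibodies form the memory set Pn
#' (sorted best-first); the rest form Pm. Ties are broken by original
#' position (stable sort), and populations smaller than `memory_size`
#' yield an all-memory split.
#'
#' @param population List of evaluated antibodies.
#' @param memory_size Target memory-set size (default 30).
#' @return List with elements `Pn` and `Pm`.
#' @export
evaluate_and_select <- function(population, memory_size = 30L) {
  aff <- affinities(population)
  if (anyNA(aff))
    stop("all antibodies must have evaluated affinities", call. = FALSE)
  ord <- order(-aff)  # stable: ties keep original index order
  k <- min(as.integer(memory_size), length(population))
  list(Pn = population[ord[seq_len(k)]],
       Pm = if (k < length(population))
         population[ord[(k + 1L):length(population)]] else list())
}

#' Clone the top-K memory antibodies in proportion to rank
#'
#' The rank-i selected antibody (i = 1 is the best) receives
#' `max(1, round(beta * |Pn| / i))` exact copies, the standard CLONALG
#' rank-proportional clone rule.
#'
#' @param Pn Memory set, sorted best-first (as returned in
#'   [evaluate_and_select()]'s `Pn`).
#' @param K How many top antibodies to clone.
#' @param beta Clone-count scale.
#' @return List of clones (copies carrying their parent's affinity).
#' @export
clone_expand <- function(Pn, K, beta) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > length(Pn)) stop("K must not exceed |Pn|", call. = FALSE)
  counts <- clone_counts(length(Pn), K, beta)
  unlist(lapply(seq_len(K), function(i)
    rep(Pn[i], counts[i])), recursive = FALSE)
}

clone_counts <- function(n_memory, K, beta) {
  vapply(seq_len(K), function(i) max(1, round(beta * n_memory / i)),
         numeric(1))
}

#' Crossover and affinity-scaled hypermutation of a clone pool
#'
#' Consecutive clone pairs undergo arithmetic crossover with probability
#' `crossover_prob` (a fresh uniform blend weight per gene). Each gene then
#' mutates with probability `mutation_prob` by a Gaussian step whose scale
#' is `sigma_max * (1 - a_hat)`, where `a_hat` is the clone's parent
#' affinity min-max normalized over the pool — the hypermutation rate is
#' inversely proportional to fitness, so the best clones are perturbed
#' least. Genes are clipped to bounds and affinities re-evaluated.
#'
#' @param clones Clone list from [clone_expand()].
#' @param config A [csa_config()].
#' @param affinity_fn Objective closure.
#' @return List of mutated, re-evaluated antibodies (same length).
#' @export
crossover_mutate <- function(clones, config, affinity_fn) {
  n <- length(clones)
  if (n < 1L) stop("need at least one clone", call. = FALSE)
  genes <- do.call(rbind, lapply(clones, `[[`, "genes"))
  parent_aff <- affinities(clones)
  ng <- ncol(genes)
  if (n >= 2L) {
    # pair shuffled partners: clones of one parent sit adjacent in the
    # pool, so consecutive pairing would mostly cross identical copies
    perm <- sample.int(n)
    for (i in seq(1L, n - 1L, by = 2L)) {
      if (stats::runif(1) < config$crossover_prob) {
        alpha <- stats::runif(ng)
        g1 <- genes[perm[i], ]; g2 <- genes[perm[i + 1L], ]
        genes[perm[i], ] <- alpha * g1 + (1 - alpha) * g2
        genes[perm[i + 1L], ] <- (1 - alpha) * g1 + alpha * g2
      }
    }
  }
  rng_aff <- range(parent_aff)
  a_hat <- if (rng_aff[2] > rng_aff[1])
    (parent_aff - rng_aff[1]) / (rng_aff[2] - rng_aff[1])
  else rep(0.5, n)
  sig <- outer(1 - a_hat, config$sigma_max)
  mutate_mask <- matrix(stats::runif(n * ng) < config$mutation_prob, n, ng)
  if (any(mutate_mask)) {
    steps <- stats::rnorm(sum(mutate_mask)) * sig[mutate_mask]
    genes[mutate_mask] <- genes[mutate_mask] + steps
  }
  genes <- pmin(pmax(genes, rep(config$bounds$lower, each = n)),
                rep(config$bounds$upper, each = n))
  lapply(seq_len(n), function(i)
    new_antibody(genes[i, ], affinity_fn(genes[i, ])))
}

#' Re-select the memory set against a mutated clone pool
#'
#' Every mutated antibody whose affinity beats the current worst memory
#' member displaces it, repeatedly — equivalent to merging both pools and
#' keeping the top `|Pn|` (the default). With `single_replacement = TRUE`
#' in the config, at most the single worst memory member is replaced per
#' call. The memory size never changes and its minimum affinity never
#' decreases.
#'
#' @param Pn Current memory set (best-first).
#' @param mutated Mutated clone pool.
#' @param single_replacement Replace at most one member.
#' @return New memory set, sorted best-first.
#' @export
reselect <- function(Pn, mutated, single_replacement = FALSE) {
  k <- length(Pn)
  if (isTRUE(single_replacement)) {
    best_mut <- mutated[[which.max(affinities(mutated))]]
    worst_idx <- which.min(affinities(Pn))
    if (best_mut$affinity > Pn[[worst_idx]]$affinity)
      Pn[[worst_idx]] <- best_mut
    return(Pn[order(-affinities(Pn))])
  }
  merged <- c(Pn, mutated)
  merged[order(-affinities(merged))][seq_len(k)]
}

#' Extinction: reinitialize the weakest remainder antibodies
#'
#' The `d` lowest-affinity members of the remainder set Pm are replaced by
#' fresh uniform-random antibodies (evaluated on creation); all others are
#' returned untouched. Mimics natural cell death and keeps the search
#' diverse.
#'
#' @param Pm Remainder set.
#' @param d How many to reinitialize (`0 <= d <= |Pm|`).
#' @param config A [csa_config()].
#' @param affinity_fn Objective closure.
#' @return The refreshed remainder set.
#' @export
extinction <- function(Pm, d, config, affinity_fn) {
  d <- as.integer(d)
  if (d < 0L || d > length(Pm))
    stop("d must satisfy 0 <= d <= |Pm|", call. = FALSE)
  if (d == 0L || length(Pm) == 0L) return(Pm)
  worst <- order(affinities(Pm))[seq_len(d)]
  for (i in worst) Pm[[i]] <- random_antibody(config$bounds, affinity_fn)
  Pm
}

new_registration_result <- function(best, layout, trace, converged, seed,
                                    evaluations, algorithm) {
  structure(list(best_params = decode_params(best$genes, layout),
                 best_genes = best$genes,
                 best_nmi = best$affinity,
                 generations_run = length(trace),
                 trace = trace, converged = converged, seed = seed,
                 evaluations = evaluations, algorithm = algorithm),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s | best NMI %.5f | %d generations (%s) | %d evaluations\n",
              toupper(x$algorithm), x$best_nmi, x$generations_run,
              if (x$converged) "converged" else "budget exhausted",
              x$evaluations))
  print(x$best_params)
  invisible(x)
}

#' Register two images with the clonal selection algorithm
#'
#' Maximizes the normalized mutual information between `fixed` (warped by
#' the candidate transform) and `moving` by iterating the clonal selection
#' loop: evaluate and select the memory set Pn, clone the top K in
#' proportion to rank, crossover + affinity-scaled hypermutation,
#' re-select the memory set, and extinction of the weakest remainder
#' antibodies, until the generation cap or a best-affinity stall. The
#' memory set makes the search elitist: the best affinity never decreases.
#'
#' @param fixed,moving Equal-shape images ([image_grid()] or matrices).
#' @param config A [csa_config()].
#' @return A `registration_result`: `best_params`, `best_nmi`, `trace`
#'   (per-generation best affinity, non-decreasing), `generations_run`,
#'   `converged`, `seed`, `evaluations`.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(size = 48, seed = 1),
#'                        true_params = transform_params(rotation = 6))
#' res <- run_csa(ph$fixed, ph$moving,
#'                csa_config(seed = 1, max_generations = 30))
#' res$best_params
#' }
#' @export
run_csa <- function(fixed, moving, config = csa_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  affinity_fn <- nmi_affinity(fixed, moving, config)
  evals <- 0L
  counting_fn <- function(genes) {
    evals <<- evals + 1L
    affinity_fn(genes)
  }
  pop <- initialize_population(config, counting_fn)
  trace <- numeric(0)
  stall <- 0L
  converged <- FALSE
  sel <- NULL
  for (gen in seq_len(config$max_generations)) {
    sel <- evaluate_and_select(pop, config$memory_size)
    clones <- clone_expand(sel$Pn, config$K, config$clone_factor)
    mutated <- crossover_mutate(clones, config, counting_fn)
    Pn <- reselect(sel$Pn, mutated, config$single_replacement)
    Pm <- extinction(sel$Pm, min(config$d, length(sel$Pm)), config,
                     counting_fn)
    pop <- c(Pn, Pm)
    best <- Pn[[1L]]$affinity
    improvement <- if (gen == 1L) Inf else best - trace[gen - 1L]
    trace <- c(trace, best)
    stall <- if (improvement < config$stall_tol) stall + 1L else 0L
    if (stall >= config$stall_generations) {
      converged <- TRUE
      break
    }
  }
  final <- evaluate_and_select(pop, config$memory_size)
  new_registration_result(final$Pn[[1L]], config$bounds$layout, trace,
                          converged, config$seed, evals, "csa")
}

#' Register two images with the genetic-algorithm baseline
#'
#' A generational real-coded genetic algorithm sharing the CSA's NMI
#' objective, bounds and operator probabilities: tournament selection of
#' size 2, arithmetic crossover with probability `crossover_prob`,
#' per-gene Gaussian mutation with probability `mutation_prob` (scale
#' `sigma_max`), and elitism of 1. Intended as the paired comparison arm:
#' pass `max_evaluations` equal to the CSA run's evaluation count so both
#' optimizers spend the same objective budget.
#'
#' @inheritParams run_csa
#' @param max_evaluations Optional cap on objective evaluations; the run
#'   stops at the first generation boundary at or beyond it.
#' @return A `registration_result` (see [run_csa()]).
#' @export
run_ga <- function(fixed, moving, config = csa_config(),
                   max_evaluations = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  affinity_fn <- nmi_affinity(fixed, moving, config)
  evals <- 0L
  counting_fn <- function(genes) {
    evals <<- evals + 1L
    affinity_fn(genes)
  }
  bounds <- config$bounds
  ng <- length(bounds$lower)
  pop <- initialize_population(config, counting_fn)
  n <- config$pop_size
  trace <- numeric(0)
  stall <- 0L
  converged <- FALSE
  tournament <- function(pop) {
    idx <- sample.int(n, 2L)
    i <- idx[which.max(affinities(pop[idx]))]
    pop[[i]]
  }
  for (gen in seq_len(config$max_generations)) {
    if (!is.null(max_evaluations) && evals >= max_evaluations) break
    elite <- pop[[which.max(affinities(pop))]]
    offspring <- vector("list", 0L)
    while (length(offspring) < n - 1L) {
      p1 <- tournament(pop)$genes
      p2 <- tournament(pop)$genes
      if (stats::runif(1) < config$crossover_prob) {
        alpha <- stats::runif(ng)
        kids <- rbind(alpha * p1 + (1 - alpha) * p2,
                      (1 - alpha) * p1 + alpha * p2)
      } else kids <- rbind(p1, p2)
      for (r in 1:2) {
        if (length(offspring) >= n - 1L) break
        g <- kids[r, ]
        mut <- stats::runif(ng) < config$mutation_prob
        if (any(mut))
          g[mut] <- g[mut] + stats::rnorm(sum(mut)) * config$sigma_max[mut]
        g <- pmin(pmax(g, bounds$lower), bounds$upper)
        offspring[[length(offspring) + 1L]] <-
          new_antibody(g, counting_fn(g))
      }
    }
    pop <- c(list(elite), offspring)
    best <- max(affinities(pop))
    improvement <- if (gen == 1L) Inf else best - trace[gen - 1L]
    trace <- c(trace, best)
    stall <- if (improvement < config$stall_tol) stall + 1L else 0L
    if (stall >= config$stall_generations) {
      converged <- TRUE
      break
    }
  }
  best_ab <- pop[[which.max(affinities(pop))]]
  new_registration_result(best_ab, bounds$layout, trace, converged,
                          config$seed, evals, "ga")
}
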