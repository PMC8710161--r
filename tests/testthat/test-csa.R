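test_that("csa_config enforces its parameter invariants", {
  expect_error(csa_config(crossover_prob = 1.2), "\\[0, 1\\]")
  expect_error(csa_config(memory_size = 50, pop_size = 40), "memory_size")
  expect_error(csa_config(K = 0), "K must")
  expect_error(csa_config(K = 31), "K must")
  expect_error(csa_config(pop_size = 40, d = 11), "d must")
  expect_error(csa_config(clone_factor = 0), "clone_factor")
  cfg <- csa_config()
  expect_equal(cfg$crossover_prob, 0.7)
  expect_equal(cfg$mutation_prob, 0.02)
  expect_equal(cfg$memory_size, 30L)
})

test_that("initialization respects bounds and the seed", {
  cfg <- csa_config(pop_size = 40,
                    bounds = param_bounds(rotation = c(0, 1),
                                          scale = c(0.5, 1),
                                          translation = c(0, 1)))
  fn <- flat_affinity(1.5)
  set.seed(31)
  pop <- initialize_population(cfg, fn)
  expect_length(pop, 40L)
  for (ab in pop) {
    expect_true(all(ab$genes >= cfg$bounds$lower &
                    ab$genes <= cfg$bounds$upper))
    expect_equal(ab$affinity, 1.5)
  }
  set.seed(31)
  pop2 <- initialize_population(cfg, fn)
  expect_identical(pop, pop2)
  cfg1 <- csa_config(pop_size = 1, memory_size = 1, K = 1, d = 0)
  set.seed(31)
  expect_length(initialize_population(cfg1, fn), 1L)
})

test_that("selection splits the top memory_size antibodies, stably", {
  set.seed(32)
  pool <- random_pool(100)
  sel <- evaluate_and_select(pool, 30)
  aff <- pool_affinities(pool)
  expect_length(sel$Pn, 30L)
  expect_length(sel$Pm, 70L)
  expect_equal(sort(pool_affinities(sel$Pn), decreasing = TRUE),
               sort(aff, decreasing = TRUE)[1:30])
  expect_gte(min(pool_affinities(sel$Pn)), max(pool_affinities(sel$Pm)))
  # tie-break: equal affinities keep original order
  tied <- lapply(1:40, function(i) list(genes = i, affinity = 1))
  sel2 <- evaluate_and_select(tied, 30)
  expect_equal(vapply(sel2$Pn, `[[`, numeric(1), "genes"), as.numeric(1:30))
  # small population: everything goes to memory
  sel3 <- evaluate_and_select(random_pool(10), 30)
  expect_length(sel3$Pn, 10L)
  expect_length(sel3$Pm, 0L)
})

test_that("clone counts follow the rank-proportional rule", {
  set.seed(33)
  pool <- random_pool(30)
  sel <- evaluate_and_select(pool, 30)
  clones <- clone_expand(sel$Pn, K = 3, beta = 1)
  # rank-i count = max(1, round(beta * 30 / i)): 30, 15, 10
  expect_length(clones, 55L)
  top3 <- sel$Pn[1:3]
  expect_identical(clones[1:30], rep(top3[1], 30))
  expect_identical(clones[31:45], rep(top3[2], 15))
  expect_identical(clones[46:55], rep(top3[3], 10))
  expect_length(clone_expand(sel$Pn, K = 1, beta = 0.5), 15L)
  expect_error(clone_expand(sel$Pn, K = 0, beta = 1), "K must be >= 1")
  expect_error(clone_expand(sel$Pn, K = 31, beta = 1), "exceed")
})

# bounds covering the unit cube, so [0, 1] test genes are never clipped
unit_bounds <- function() {
  param_bounds(rotation = c(0, 1), scale = c(0, 1),
               translation = c(0, 1))
}

test_that("crossover and mutation are no-ops at zero probabilities", {
  set.seed(34)
  pool <- random_pool(12, ngenes = 5L)
  cfg <- csa_config(crossover_prob = 0, mutation_prob = 0,
                    bounds = unit_bounds())
  out <- crossover_mutate(pool, cfg, flat_affinity(2))
  expect_equal(lapply(out, `[[`, "genes"), lapply(pool, `[[`, "genes"))
})

test_that("the uniquely best clone is never mutated (sigma = 0)", {
  set.seed(35)
  pool <- random_pool(10, ngenes = 5L)
  best_idx <- which.max(pool_affinities(pool))
  cfg <- csa_config(crossover_prob = 0, mutation_prob = 1,
                    bounds = unit_bounds())
  out <- crossover_mutate(pool, cfg, flat_affinity(1))
  expect_equal(out[[best_idx]]$genes, pool[[best_idx]]$genes)
  moved <- vapply(seq_along(out), function(i)
    max(abs(out[[i]]$genes - pool[[i]]$genes)), numeric(1))
  expect_true(any(moved[-best_idx] > 0))
})

test_that("crossover_mutate is reproducible under a fixed seed", {
  pool <- random_pool(8, ngenes = 5L)
  cfg <- csa_config(mutation_prob = 1, sigma_max = 0.1)
  set.seed(36)
  a <- crossover_mutate(pool, cfg, flat_affinity(1))
  set.seed(36)
  b <- crossover_mutate(pool, cfg, flat_affinity(1))
  expect_identical(a, b)
})

test_that("mutated genes stay clipped to the search bounds", {
  set.seed(37)
  pool <- random_pool(20, ngenes = 5L)
  cfg <- csa_config(mutation_prob = 1, sigma_max = 50)
  out <- crossover_mutate(pool, cfg, flat_affinity(1))
  for (ab in out)
    expect_true(all(ab$genes >= cfg$bounds$lower &
                    ab$genes <= cfg$bounds$upper))
})

test_that("reselect equals merge-and-truncate and never loses ground", {
  set.seed(38)
  for (i in 1:200) {
    Pn <- random_pool(sample(3:10, 1))
    Pn <- Pn[order(-pool_affinities(Pn))]
    mutated <- random_pool(sample(1:15, 1))
    out <- reselect(Pn, mutated)
    # oracle: merge both pools, sort, keep top |Pn|
    merged <- c(Pn, mutated)
    expected <- sort(pool_affinities(merged), decreasing = TRUE)[
      seq_along(Pn)]
    expect_equal(pool_affinities(out), expected)
    expect_gte(min(pool_affinities(out)), min(pool_affinities(Pn)))
    expect_gte(max(pool_affinities(out)), max(pool_affinities(Pn)))
  }
})

test_that("reselect leaves the memory set alone when nothing improves", {
  set.seed(39)
  Pn <- lapply(1:5, function(i) list(genes = i, affinity = 10 - i))
  worse <- lapply(1:4, function(i) list(genes = 100 + i, affinity = 1))
  expect_identical(reselect(Pn, worse), Pn)
  better <- list(list(genes = 0, affinity = 99))
  out <- reselect(Pn, better)
  expect_equal(out[[1]]$affinity, 99)
  expect_false(5 %in% vapply(out, `[[`, numeric(1), "genes"))
})

test_that("extinction reinitializes exactly the d worst, leaving survivors", {
  set.seed(40)
  cfg <- csa_config()
  Pm <- random_pool(10, ngenes = 5L)
  expect_identical(extinction(Pm, 0, cfg, flat_affinity(1)), Pm)
  out <- extinction(Pm, 3, cfg, flat_affinity(0.5))
  worst <- order(pool_affinities(Pm))[1:3]
  for (i in seq_along(Pm)) {
    if (i %in% worst) {
      expect_false(identical(out[[i]]$genes, Pm[[i]]$genes))
      expect_equal(out[[i]]$affinity, 0.5)
    } else {
      expect_identical(out[[i]], Pm[[i]])
    }
  }
  full <- extinction(Pm, 10, cfg, flat_affinity(0.5))
  expect_true(all(pool_affinities(full) == 0.5))
  expect_error(extinction(Pm, 11, cfg, flat_affinity(1)), "d must")
})

test_that("self-registration converges numerically to the identity", {
  ph <- generate_phantom(phantom_spec(size = 32, seed = 4, noise_sd = 0,
                                      blur_sigma = 0,
                                      intensity_map = identity),
                         true_params = identity_params())
  # the objective itself is exactly 2 at the identity
  expect_identical(nmi(ph$fixed, ph$moving), 2)
  res <- run_csa(ph$fixed, ph$moving, csa_config(seed = 2))
  expect_gt(res$best_nmi, 1.9)
  expect_lt(abs(res$best_params$rotation), 0.5)
  expect_lt(max(abs(res$best_params$translation)), 0.5)
  expect_lt(max(abs(res$best_params$scale - 1)), 0.05)
})

test_that("the best-affinity trace is non-decreasing and ends at best_nmi", {
  ph <- generate_phantom(phantom_spec(size = 32, seed = 6))
  res <- run_csa(ph$fixed, ph$moving,
                 csa_config(seed = 3, max_generations = 25,
                            stall_generations = 5))
  expect_true(all(diff(res$trace) >= 0))
  expect_equal(res$best_nmi, res$trace[length(res$trace)])
  expect_equal(res$generations_run, length(res$trace))
})

test_that("run_csa is deterministic and its evaluation count is analytic", {
  ph <- generate_phantom(phantom_spec(size = 32, seed = 8))
  cfg <- csa_config(seed = 11, max_generations = 12,
                    stall_generations = 12)
  a <- run_csa(ph$fixed, ph$moving, cfg)
  b <- run_csa(ph$fixed, ph$moving, cfg)
  expect_identical(a$best_genes, b$best_genes)
  expect_identical(a$trace, b$trace)
  # per generation: clones for ranks 1..K plus d extinction draws
  clones_per_gen <- sum(vapply(1:cfg$K, function(i)
    max(1, round(cfg$clone_factor * cfg$memory_size / i)), numeric(1)))
  expected <- cfg$pop_size +
    a$generations_run * (clones_per_gen + cfg$d)
  expect_equal(a$evaluations, expected)
})
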