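# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (tabulate/vectorized binning, analytic AUC).

# Brute-force joint tally: loop over every pixel pair, no tabulate().
brute_joint_counts <- function(a, b, bins) {
  bin_of <- function(x) {
    mn <- min(x); mx <- max(x)
    if (mx == mn) return(rep(1L, length(x)))
    i <- 1L + floor((x - mn) / (mx - mn) * bins)
    pmin(as.integer(i), bins)
  }
  ia <- bin_of(as.vector(a)); ib <- bin_of(as.vector(b))
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ia))
    counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1L
  counts
}

# Direct-summation Shannon entropy in bits.
brute_entropy <- function(counts) {
  p <- as.numeric(counts) / sum(counts)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# NMI assembled from the brute-force histogram.
brute_nmi <- function(a, b, bins) {
  counts <- brute_joint_counts(a, b, bins)
  (brute_entropy(rowSums(counts)) + brute_entropy(colSums(counts))) /
    brute_entropy(counts)
}

# Pairwise Mann-Whitney AUC with 1/2 tie credit.
mw_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Random evaluated antibody population for operator-level tests.
random_pool <- function(n, ngenes = 3L) {
  lapply(seq_len(n), function(i)
    list(genes = stats::runif(ngenes), affinity = stats::runif(1)))
}

pool_affinities <- function(pool) vapply(pool, `[[`, numeric(1), "affinity")

# Constant-intensity objective stub: affinity independent of genes.
flat_affinity <- function(value = 1) function(genes) value

# Small asymmetric test image (values distinct so permutations are visible).
asym_image <- function(n, seed = 1) {
  set.seed(seed)
  matrix(sample(seq_len(n * n)), n, n)
}
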