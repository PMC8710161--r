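#' Joint intensity histogram of two aligned images
#'
#' Bins each image over its own intensity range (equal-width bins computed
#' on the jointly valid pixels) and tallies co-occurring bin pairs. Pixels
#' that are `NA` in either image (e.g. outside a warped domain) are
#' excluded. A constant image occupies a single bin.
#'
#' @param fixed,moving Equal-shape numeric matrices or [image_grid()]s.
#' @param bins Number of bins per image (>= 2), default 16.
#' @return An object of class `joint_histogram`: `counts` (bins x bins
#'   integer matrix, fixed on rows), `marginal_fixed`, `marginal_moving`,
#'   `bins`, `n` (valid pixel count).
#' @export
joint_histogram <- function(fixed, moving, bins = 16L) {
  a <- as_pixels(fixed); b <- as_pixels(moving)
  if (!identical(dim(a), dim(b)))
    stop("fixed and moving must have identical shapes", call. = FALSE)
  bins <- as.integer(bins)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  n <- sum(ok)
  if (n == 0L) stop("no jointly valid pixels", call. = FALSE)
  ia <- bin_index(a[ok], bins)
  ib <- bin_index(b[ok], bins)
  counts <- matrix(tabulate(ia + (ib - 1L) * bins, bins * bins), bins, bins)
  structure(list(counts = counts,
                 marginal_fixed = rowSums(counts),
                 marginal_moving = colSums(counts),
                 bins = bins, n = n),
            class = "joint_histogram")
}

bin_index <- function(x, bins) {
  mn <- min(x); mx <- max(x)
  if (mx == mn) return(rep(1L, length(x)))
  pmin(bins, 1L + as.integer(floor((x - mn) / (mx - mn) * bins)))
}

#' Shannon entropy of a count vector or matrix, in bits
#'
#' @param counts Non-negative counts (marginal vector or joint matrix)
#'   with positive total; `0 * log(0)` is taken as 0.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(1, 1))  # 1 bit
#' @export
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("counts must have a positive total", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Normalized mutual information between two images
#'
#' The Studholme entropy ratio `(H(A) + H(B)) / H(A, B)`, computed from the
#' joint histogram of the fixed image warped by `params` against the moving
#' image, over their jointly valid (overlapping) pixels. The value lies in
#' `[1, 2]`: 2 for identical images, 1 when either marginal is degenerate.
#'
#' If fewer than `min_overlap` of the pixels remain valid after warping,
#' the alignment is considered invalid and the sentinel affinity `0`
#' (strictly worse than any attainable NMI) is returned rather than an
#' error, so that optimizers can keep iterating.
#'
#' @param fixed,moving Equal-shape images.
#' @param params Optional [transform_params()] applied to `fixed` before
#'   comparison; `NULL` compares the images as-is.
#' @param bins Histogram bins per image.
#' @param min_overlap Minimum valid-pixel fraction, default 0.25.
#' @param interpolation Passed to [apply_transform()].
#' @return NMI in `[1, 2]`, or `0` for an invalid alignment.
#' @examples
#' img <- matrix(runif(256), 16, 16)
#' nmi(img, img)  # exactly 2
#' @export
nmi <- function(fixed, moving, params = NULL, bins = 16L,
                min_overlap = 0.25, interpolation = "linear") {
  a <- as_pixels(fixed); b <- as_pixels(moving)
  if (!identical(dim(a), dim(b)))
    stop("fixed and moving must have identical shapes", call. = FALSE)
  if (!is.null(params))
    a <- apply_transform(a, params, interpolation)
  ok <- is.finite(a) & is.finite(b)
  if (mean(ok) < min_overlap) return(0)
  nmi_from_valid(a[ok], b[ok], as.integer(bins))
}

# NMI on pre-masked intensity vectors; hot path for the optimizers.
nmi_from_valid <- function(a, b, bins) {
  ia <- bin_index(a, bins)
  ib <- bin_index(b, bins)
  joint <- tabulate(ia + (ib - 1L) * bins, bins * bins)
  n <- length(ia)
  pj <- joint[joint > 0] / n
  hab <- -sum(pj * log2(pj))
  if (hab == 0) return(1)
  pa <- tabulate(ia, bins); pa <- pa[pa > 0] / n
  pb <- tabulate(ib, bins); pb <- pb[pb > 0] / n
  (-sum(pa * log2(pa)) - sum(pb * log2(pb))) / hab
}
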