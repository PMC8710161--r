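#' Specification of a synthetic multimodal phantom pair
#'
#' Describes a piecewise-constant "CT-like" image (random ellipses with
#' distinct intensity plateaus on a dark background) and the degradations
#' applied to derive its "PET-like" counterpart: a known similarity
#' transform, a monotone nonlinear intensity remap (destroying the linear
#' intensity relationship, as a modality change does), Gaussian blur, and
#' additive Gaussian noise.
#'
#' @param size Pixels per axis (square image), >= 8.
#' @param n_blobs Number of elliptical structures (>= 1), default 5.
#' @param noise_sd Additive Gaussian noise SD on the PET-like channel, on
#'   the `[0, 1]` intensity scale (default 0.02).
#' @param blur_sigma Gaussian blur SD in pixels for the PET-like channel
#'   (default 1).
#' @param intensity_map Strictly monotone function applied to the
#'   `[0, 1]`-normalized PET-like intensities; default square-root (gamma
#'   0.5) remap.
#' @param rot_range,scale_range,trans_range `(lower, upper)` ranges from
#'   which a ground-truth transform is drawn when none is supplied to
#'   [generate_phantom()]. Defaults: rotation U(-15, 15) degrees, per-axis
#'   scale U(0.9, 1.1), per-axis translation U(-5, 5) px.
#' @param seed RNG seed; identical specs produce bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, n_blobs = 5L, noise_sd = 0.02,
                         blur_sigma = 1, intensity_map = sqrt,
                         rot_range = c(-15, 15),
                         scale_range = c(0.9, 1.1),
                         trans_range = c(-5, 5), seed = 1L) {
  size <- as.integer(size)
  n_blobs <- as.integer(n_blobs)
  if (size < 8L) stop("`size` must be >= 8", call. = FALSE)
  if (n_blobs < 1L) stop("`n_blobs` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)
  if (!is.function(intensity_map))
    stop("`intensity_map` must be a function", call. = FALSE)
  probe <- seq(0, 1, length.out = 64)
  vals <- intensity_map(probe)
  if (any(!is.finite(vals)) || any(diff(vals) <= 0))
    stop("`intensity_map` must be strictly monotone increasing on [0, 1]",
         call. = FALSE)
  structure(list(size = size, n_blobs = n_blobs, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, intensity_map = intensity_map,
                 rot_range = rot_range, scale_range = scale_range,
                 trans_range = trans_range, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a fixed/moving phantom pair with known ground truth
#'
#' The fixed (CT-like) image is a sum-of-ellipses raster. The moving
#' (PET-like) image is the fixed image warped by the ground-truth
#' transform, intensity-remapped, blurred and noised per the spec; pixels
#' warped in from outside the domain take the background intensity. The
#' whole construction is driven by `spec$seed`, so equal specs give
#' bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param true_params Optional [transform_params()] to use as ground
#'   truth; when `NULL` one is drawn uniformly from the spec's ranges.
#' @return List with `fixed`, `moving` (both [image_grid()]) and `truth`
#'   (a `transform_params`).
#' @examples
#' ph <- generate_phantom(phantom_spec(size = 32, seed = 7))
#' ph$truth
#' @export
generate_phantom <- function(spec, true_params = NULL) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  set.seed(spec$seed)
  n <- spec$size
  fixed <- ellipse_raster(n, spec$n_blobs)
  if (is.null(true_params)) {
    true_params <- transform_params(
      rotation = stats::runif(1, spec$rot_range[1], spec$rot_range[2]),
      scale = stats::runif(2, spec$scale_range[1], spec$scale_range[2]),
      translation = stats::runif(2, spec$trans_range[1],
                                 spec$trans_range[2]))
  }
  moving <- apply_transform(fixed, true_params, interpolation = "linear")
  moving[is.na(moving)] <- 0  # background flows in at the borders
  moving <- spec$intensity_map(pmin(pmax(moving, 0), 1))
  if (spec$blur_sigma > 0)
    moving <- gaussian_blur(moving, spec$blur_sigma)
  if (spec$noise_sd > 0)
    moving <- moving + stats::rnorm(length(moving), sd = spec$noise_sd)
  list(fixed = image_grid(fixed),
       moving = image_grid(matrix(moving, n, n)),
       truth = true_params)
}

# Piecewise-constant raster: ellipses with distinct intensity plateaus on
# a zero background; overlaps resolve to the brighter plateau.
ellipse_raster <- function(n, n_blobs) {
  img <- matrix(0, n, n)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  levels <- seq(0.35, 1, length.out = n_blobs)
  for (k in seq_len(n_blobs)) {
    ctr <- stats::runif(2, 0.25 * n, 0.75 * n)
    axes <- stats::runif(2, 0.08 * n, 0.22 * n)
    th <- stats::runif(1, 0, pi)
    dr <- rows - ctr[1]
    dc <- cols - ctr[2]
    u <- (cos(th) * dr + sin(th) * dc) / axes[1]
    v <- (-sin(th) * dr + cos(th) * dc) / axes[2]
    inside <- u * u + v * v <= 1
    img[inside] <- pmax(img[inside], levels[k])
  }
  img
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(px, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  px <- apply(px, 2L, convolve_replicate, kernel = k)
  t(apply(t(px), 2L, convolve_replicate, kernel = k))
}

convolve_replicate <- function(x, kernel) {
  r <- (length(kernel) - 1L) / 2L
  padded <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  stats::filter(padded, kernel, sides = 2L)[(r + 1L):(r + length(x))]
}
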