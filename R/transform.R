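#' Similarity transform parameters
#'
#' A 2-D similarity transform with per-axis scaling: rotation (degrees,
#' counter-clockwise in row/column coordinates), per-axis scale factors and
#' per-axis translation in pixels. The transform acts about the image
#' center: a point `q` (row, col) maps to
#' `R(theta) %*% diag(scale) %*% (q - center) + center + translation`.
#' These parameter vectors are the genotypes the optimizers search over.
#'
#' @param rotation Rotation angle in degrees.
#' @param scale Length-2 positive scale factors (recycled from length 1).
#' @param translation Length-2 shifts in pixels (recycled from length 1).
#' @return An object of class `transform_params`.
#' @examples
#' transform_params(rotation = 10, scale = c(1.05, 1.05))
#' @export
transform_params <- function(rotation = 0, scale = 1, translation = 0) {
  scale <- rep_len(as.numeric(scale), 2L)
  translation <- rep_len(as.numeric(translation), 2L)
  rotation <- as.numeric(rotation)[1L]
  if (!all(is.finite(c(rotation, scale, translation))))
    stop("transform parameters must be finite", call. = FALSE)
  if (any(scale <= 0))
    stop("scale factors must be strictly positive", call. = FALSE)
  structure(list(rotation = rotation, scale = scale,
                 translation = translation),
            class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf("<transform_params> rot %.3f deg | scale %.4f, %.4f | shift %.3f, %.3f px\n",
              x$rotation, x$scale[1], x$scale[2],
              x$translation[1], x$translation[2]))
  invisible(x)
}

#' Gene block layout for the flat parameter encoding
#'
#' The optimizers operate on flat real vectors. A layout declares how many
#' genes encode each block. The default (1 rotation + 2 scale +
#' 2 translation) is a minimal similarity parameterization. Redundant
#' layouts (e.g. `gene_layout(10, 9, 0)`, matching a 19-gene
#' rotation/scale configuration) are decoded by averaging the genes within
#' each block, which then acts isotropically.
#'
#' @param rotation,scale,translation Non-negative integer gene counts per
#'   block. A zero-length block pins that component to the identity.
#' @return An object of class `gene_layout`.
#' @export
gene_layout <- function(rotation = 1L, scale = 2L, translation = 2L) {
  lay <- c(rotation = as.integer(rotation), scale = as.integer(scale),
           translation = as.integer(translation))
  if (any(lay < 0L) || sum(lay) < 1L)
    stop("gene_layout blocks must be non-negative with at least one gene",
         call. = FALSE)
  structure(as.list(lay), class = "gene_layout")
}

layout_size <- function(layout) {
  layout$rotation + layout$scale + layout$translation
}

block_index <- function(layout, block) {
  start <- switch(block,
    rotation = 0L,
    scale = layout$rotation,
    translation = layout$rotation + layout$scale)
  n <- layout[[block]]
  if (n == 0L) integer(0) else start + seq_len(n)
}

#' Encode transform parameters as a flat gene vector
#'
#' @param params A [transform_params()].
#' @param layout A [gene_layout()].
#' @return Numeric vector of length `sum(unlist(layout))`.
#' @export
encode_params <- function(params, layout = gene_layout()) {
  genes <- numeric(layout_size(layout))
  if (layout$rotation > 0L)
    genes[block_index(layout, "rotation")] <- params$rotation
  if (layout$scale > 0L) {
    genes[block_index(layout, "scale")] <-
      if (layout$scale == 2L) params$scale else mean(params$scale)
  }
  if (layout$translation > 0L) {
    genes[block_index(layout, "translation")] <-
      if (layout$translation == 2L) params$translation
      else mean(params$translation)
  }
  genes
}

#' Decode a flat gene vector into transform parameters
#'
#' Blocks longer than the natural component size are aggregated by
#' averaging; absent blocks decode to the identity component.
#'
#' @param genes Numeric gene vector matching `layout`.
#' @param layout A [gene_layout()].
#' @return A [transform_params()].
#' @export
decode_params <- function(genes, layout = gene_layout()) {
  if (length(genes) != layout_size(layout))
    stop("gene vector length ", length(genes),
         " does not match layout size ", layout_size(layout), call. = FALSE)
  rot <- if (layout$rotation > 0L)
    mean(genes[block_index(layout, "rotation")]) else 0
  sc <- if (layout$scale == 0L) c(1, 1)
        else if (layout$scale == 2L) genes[block_index(layout, "scale")]
        else rep(mean(genes[block_index(layout, "scale")]), 2L)
  tr <- if (layout$translation == 0L) c(0, 0)
        else if (layout$translation == 2L)
          genes[block_index(layout, "translation")]
        else rep(mean(genes[block_index(layout, "translation")]), 2L)
  transform_params(rotation = rot, scale = sc, translation = tr)
}

#' Per-gene search bounds
#'
#' Expands per-block `(lower, upper)` ranges into per-gene bound matrices
#' for a given layout. Defaults cover the benchmark's ground-truth ranges
#' with margin.
#'
#' @param rotation,scale,translation Length-2 `(lower, upper)` ranges.
#' @param layout A [gene_layout()].
#' @return List with numeric vectors `lower` and `upper` (one entry per
#'   gene) and the `layout`.
#' @export
param_bounds <- function(rotation = c(-20, 20), scale = c(0.8, 1.2),
                         translation = c(-6, 6), layout = gene_layout()) {
  blocks <- list(rotation = rotation, scale = scale,
                 translation = translation)
  lower <- upper <- numeric(layout_size(layout))
  for (b in names(blocks)) {
    idx <- block_index(layout, b)
    if (length(idx) == 0L) next
    rng <- as.numeric(blocks[[b]])
    if (length(rng) != 2L || rng[1] >= rng[2])
      stop("bounds for ", b, " must be (lower, upper) with lower < upper",
           call. = FALSE)
    lower[idx] <- rng[1]
    upper[idx] <- rng[2]
  }
  list(lower = lower, upper = upper, layout = layout)
}

transform_matrix <- function(params) {
  th <- params$rotation * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  rot %*% diag(params$scale)
}

#' Warp an image by a similarity transform
#'
#' Resamples `image` so that the output is `image` transformed by `params`
#' about its center. Output pixels whose source coordinate falls outside
#' the input domain are marked `NA` (treated as invalid and excluded from
#' joint histograms), never zero-filled.
#'
#' @param image An [image_grid()] or numeric matrix (2-D only).
#' @param params A [transform_params()].
#' @param interpolation `"linear"` (bilinear) or `"nearest"`.
#' @return Same type as `image`, with `NA` outside the warped domain.
#' @examples
#' img <- matrix(1:64, 8, 8)
#' identical(apply_transform(img, transform_params()), img * 1.0)
#' @export
apply_transform <- function(image, params,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  px <- as_pixels(image)
  if (length(dim(px)) != 2L)
    stop("apply_transform supports 2-D images", call. = FALSE)
  if (!all(is.finite(c(params$rotation, params$scale, params$translation))))
    stop("transform parameters must be finite", call. = FALSE)
  nr <- nrow(px); nc <- ncol(px)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  minv <- solve(transform_matrix(params))
  # source coordinate of each output pixel: inverse map of the forward warp
  off_r <- seq_len(nr) - ctr[1] - params$translation[1]
  off_c <- seq_len(nc) - ctr[2] - params$translation[2]
  src_r <- outer(minv[1, 1] * off_r, minv[1, 2] * off_c, "+") + ctr[1]
  src_c <- outer(minv[2, 1] * off_r, minv[2, 2] * off_c, "+") + ctr[2]
  out <- resample_grid(px, src_r, src_c, interpolation)
  if (inherits(image, "image_grid")) {
    res <- image
    res$pixels <- out
    res
  } else out
}

resample_grid <- function(px, src_r, src_c, interpolation) {
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(NA_real_, nr, nc)
  if (interpolation == "nearest") {
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out[ok] <- px[ri[ok] + (ci[ok] - 1) * nr]
  } else {
    ok <- src_r >= 1 & src_r <= nr & src_c >= 1 & src_c <= nc
    r <- src_r[ok]; c <- src_c[ok]
    r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
    fr <- r - r0; fc <- c - c0
    i00 <- r0 + (c0 - 1) * nr
    out[ok] <- (1 - fr) * (1 - fc) * px[i00] +
               fr * (1 - fc) * px[i00 + 1] +
               (1 - fr) * fc * px[i00 + nr] +
               fr * fc * px[i00 + nr + 1]
  }
  out
}

#' Identity transform
#' @return A [transform_params()] with no rotation, unit scale, no shift.
#' @export
identity_params <- function() transform_params()
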