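#' Scalar image on a regular grid
#'
#' `image_grid()` wraps a numeric matrix (or 3-D array) of intensities with
#' physical pixel spacing and a world-coordinate origin. It is the carrier
#' for both the fixed (CT-like) and moving (PET-like) images throughout the
#' package.
#'
#' @param pixels Numeric matrix or 3-D array of finite intensities. Every
#'   dimension must be at least 8 (registration on smaller rasters is not
#'   meaningful; use raw matrices for toy computations).
#' @param spacing Numeric vector of strictly positive physical sizes per
#'   pixel, one per axis (recycled from length 1). Arbitrary units.
#' @param origin World coordinate of pixel (1,1), one value per axis.
#'
#' @return An object of class `image_grid` with elements `pixels`,
#'   `spacing`, `origin`.
#' @examples
#' img <- image_grid(matrix(runif(64), 8, 8))
#' dim(img$pixels)
#' @export
image_grid <- function(pixels, spacing = 1, origin = 0) {
  if (!is.numeric(pixels) || is.null(dim(pixels)))
    stop("`pixels` must be a numeric matrix or array", call. = FALSE)
  nd <- length(dim(pixels))
  if (nd < 2L || nd > 3L)
    stop("`pixels` must be 2-D or 3-D", call. = FALSE)
  if (any(dim(pixels) < 8L))
    stop("every image dimension must be >= 8", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("`pixels` must contain only finite intensities", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), nd)
  origin <- rep_len(as.numeric(origin), nd)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive and finite", call. = FALSE)
  structure(list(pixels = pixels, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<image_grid> ", paste(d, collapse = " x "),
      " | spacing ", paste(signif(x$spacing, 4), collapse = ", "),
      " | intensity range [", signif(min(x$pixels), 4), ", ",
      signif(max(x$pixels), 4), "]\n", sep = "")
  invisible(x)
}

as_pixels <- function(image) {
  if (inherits(image, "image_grid")) image$pixels else image
}

#' Write an image to disk
#'
#' PNG stores intensities min-max rescaled to the writer's 8-bit samples;
#' TIFF stores them min-max rescaled to 32-bit normalized samples; NIfTI
#' stores the raw double-precision intensities (lossless) along with the
#' pixel spacing. The absolute intensity scale is therefore preserved
#' only by NIfTI.
#'
#' @param image An [image_grid()].
#' @param path Output file path.
#' @param format One of `"png"`, `"tiff"`, `"nifti"`; defaults to the file
#'   extension (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @seealso [read_image()]
#' @export
write_image <- function(image, path, format = NULL) {
  if (!inherits(image, "image_grid"))
    stop("`image` must be an image_grid", call. = FALSE)
  format <- if (is.null(format)) guess_format(path) else match.arg(
    tolower(format), c("png", "tiff", "nifti"))
  px <- image$pixels
  if (format %in% c("png", "tiff")) {
    if (length(dim(px)) != 2L)
      stop("PNG/TIFF output supports 2-D images only", call. = FALSE)
    rng <- range(px)
    scaled <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
              else px * 0
    if (format == "png") {
      png::writePNG(scaled, target = path, dpi = NULL)
    } else {
      tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                      compression = "none")
    }
  } else {
    nd <- length(dim(px))
    pd <- rep(1, 8)
    pd[seq_len(nd) + 1L] <- image$spacing
    nif <- RNifti::asNifti(px, list(pixdim = pd), datatype = "double")
    RNifti::writeNifti(nif, path, datatype = "double")
  }
  invisible(path)
}

#' Read an image from disk
#'
#' The inverse of [write_image()]. PNG and TIFF intensities come back on
#' the normalized `[0, 1]` scale they were stored on; NIfTI returns the
#' original intensities and spacing.
#'
#' @param path File path; format inferred from the extension.
#' @return An [image_grid()].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("file does not exist: ", path, call. = FALSE)
  format <- guess_format(path)
  px <- switch(format,
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L) x <- x[, , 1L]  # collapse grey-encoded RGB
      x
    },
    tiff = {
      x <- tiff::readTIFF(path)
      if (length(dim(x)) == 3L) x <- x[, , 1L]
      x
    },
    nifti = {
      nif <- RNifti::readNifti(path)
      # drop the niftiImage class and header attributes; keep bare values
      arr <- array(as.vector(as.array(nif)), dim = dim(nif))
      sp <- RNifti::pixdim(nif)
      return(image_grid(arr, spacing = sp[seq_along(dim(arr))]))
    })
  image_grid(px)
}

guess_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) return("png")
  if (grepl("\\.tiff?$", lower)) return("tiff")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  stop("unknown image extension in: ", path,
       " (expected .png, .tif/.tiff, .nii/.nii.gz)", call. = FALSE)
}
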