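#' Load a fundus photograph
#'
#' Reads a PNG, TIFF or JPEG raster and returns a `fundus_image`: intensities
#' rescaled to \[0, 1\] from the source bit depth, channel count preserved
#' (grayscale stays a matrix, RGB an H x W x 3 array; an alpha channel, if
#' present, is dropped).
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return A `fundus_image` object: list with `pixels` (matrix or 3-d array in
#'   \[0, 1\]) and `source_path`.
#' @export
load_fundus <- function(path) {
  if (!is.character(path) || length(path) != 1)
    stop_io("path must be a single file path")
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE))
      stop_format(sprintf("package '%s' is required to read this format", pkg))
  }
  px <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = , tiff = { need("tiff"); tiff::readTIFF(path) },
      jpg = , jpeg = { need("jpeg"); jpeg::readJPEG(path) },
      stop_format(sprintf("unsupported image format: '%s'", ext))
    ),
    error = function(e) {
      if (inherits(e, "fundusreg_error")) stop(e)
      stop_format(sprintf("could not decode '%s': %s", path, conditionMessage(e)))
    }
  )
  # readers already rescale to [0,1]; drop alpha, collapse 1-channel arrays
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 4) px <- px[, , 1:3, drop = FALSE]
    if (dim(px)[3] == 1) px <- px[, , 1]
    if (length(dim(px)) == 3 && dim(px)[3] == 2) px <- px[, , 1]  # gray+alpha
  }
  fundus_image(px, source_path = path)
}

#' Fundus image container
#'
#' @param pixels Matrix (grayscale) or H x W x 3 array (RGB) with intensities
#'   in \[0, 1\].
#' @param source_path Optional path the image was read from.
#' @return A `fundus_image` object.
#' @export
fundus_image <- function(pixels, source_path = NULL) {
  if (!is.numeric(pixels)) stop_value("pixels must be numeric")
  d <- dim(pixels)
  if (is.null(d) || !(length(d) %in% c(2, 3)))
    stop_shape("pixels must be a 2-d matrix or an H x W x 3 array")
  if (d[1] < 8 || d[2] < 8) stop_shape("image must be at least 8 x 8")
  if (any(!is.finite(pixels)) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop_value("intensities must be finite and in [0, 1]")
  structure(
    list(pixels = pmin(pmax(pixels, 0), 1), source_path = source_path),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<fundus_image> %d x %d, %s, range [%.3f, %.3f]%s\n", d[1], d[2],
    if (length(d) == 3) "RGB" else "grayscale", min(x$pixels), max(x$pixels),
    if (is.null(x$source_path)) "" else paste0(" (", x$source_path, ")")
  ))
  invisible(x)
}

as_fundus <- function(x) {
  if (inherits(x, "fundus_image")) x else fundus_image(x)
}

#' Resize to the square working resolution
#'
#' Brings an image to the `size` x `size` raster the network operates on.
#' Resampling is bilinear (through the same sampler used for warping), with
#' corner pixels mapped to corner pixels, so resizing an image already at the
#' target size is an exact identity. Non-square inputs are stretched
#' anisotropically: all downstream shapes assume a square raster.
#'
#' @param img A `fundus_image` (or bare pixel array).
#' @param size Target side length in pixels; must be a positive multiple of 4
#'   so that the network's two pooling halvings are exact. Default 512, the
#'   resolution the full-scale model is meant to run at.
#' @return A `fundus_image` of size `size` x `size`.
#' @export
to_working_resolution <- function(img, size = 512) {
  img <- as_fundus(img)
  if (length(size) != 1 || !is.finite(size) || size <= 0 || size %% 4 != 0)
    stop_config("size must be a positive multiple of 4")
  px <- img$pixels
  d <- dim(px)
  if (d[1] == size && d[2] == size) return(img)
  rs <- function(m) resample_bilinear(m, size, size)
  out <- if (length(d) == 3) {
    a <- array(0, c(size, size, d[3]))
    for (k in seq_len(d[3])) a[, , k] <- rs(px[, , k])
    a
  } else {
    rs(px)
  }
  fundus_image(out, source_path = img$source_path)
}

# Bilinear resampling onto an Ho x Wo grid, corner-aligned.
resample_bilinear <- function(m, Ho, Wo) {
  H <- nrow(m); W <- ncol(m)
  rr <- if (Ho == 1) rep(0, Ho) else (seq_len(Ho) - 1) * (H - 1) / (Ho - 1)
  cc <- if (Wo == 1) rep(0, Wo) else (seq_len(Wo) - 1) * (W - 1) / (Wo - 1)
  coords <- array(0, c(Ho, Wo, 2))
  coords[, , 1] <- matrix(rr, Ho, Wo)
  coords[, , 2] <- matrix(cc, Ho, Wo, byrow = TRUE)
  bilinear_sample(m, coords)
}

#' Collapse to the structure (grayscale) channel
#'
#' For RGB input the green channel is returned: in fundus photography the
#' vessels have their highest contrast against the background in green light,
#' which is why vessel segmentation conventionally runs on it. Grayscale input
#' is returned unchanged.
#'
#' @param img A `fundus_image` (or bare pixel array).
#' @return A numeric matrix in \[0, 1\].
#' @export
extract_structure_channel <- function(img) {
  img <- as_fundus(img)
  px <- img$pixels
  if (length(dim(px)) == 3) px[, , 2] else px
}

#' Write an image to PNG
#'
#' @param pixels Matrix or H x W x 3 array in \[0, 1\], or a `fundus_image` /
#'   `vessel_map` (soft view is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  if (inherits(pixels, "fundus_image")) pixels <- pixels$pixels
  if (inherits(pixels, "vessel_map")) pixels <- pixels$soft
  png::writePNG(pmin(pmax(pixels, 0), 1), path)
  invisible(path)
}
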