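#' Validate an RGB image array
#'
#' Images throughout the package are plain numeric arrays of shape
#' `H x W x 3` holding intensities on the 8-bit scale `[0, 255]`.
#' `assert_rgb()` checks the contract and aborts with a classed condition on
#' violation; it is called at every user-facing entry point.
#'
#' @param img Object to validate.
#' @param arg Name used in error messages.
#' @return `img`, invisibly, if valid.
#' @keywords internal
assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    rlang::abort(
      sprintf("`%s` must be an H x W x 3 numeric array.", arg),
      class = "stainbench_error_invalid_argument"
    )
  }
  if (!is.numeric(img) || anyNA(img)) {
    rlang::abort(
      sprintf("`%s` contains non-numeric or missing values.", arg),
      class = "stainbench_error_invalid_argument"
    )
  }
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255) {
    rlang::abort(
      sprintf("`%s` has values outside [0, 255].", arg),
      class = "stainbench_error_invalid_argument"
    )
  }
  invisible(img)
}

#' Read an 8-bit RGB raster
#'
#' Reads a PNG or TIFF file into the package's `H x W x 3` array convention
#' (values in `[0, 255]`). Grayscale rasters are replicated to three
#' channels; images with an alpha channel are rejected because downstream
#' stain arithmetic assumes opaque tissue.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric `H x W x 3` array with values in `[0, 255]`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_image(synthetic_panel(n_labs = 2, size = 64, seed = 1)$images[[1]], f)
#' img <- read_image(f)
#' dim(img)
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    rlang::abort(
      sprintf("Unsupported raster format '.%s' (use PNG or TIFF).", ext),
      class = "stainbench_error_invalid_argument"
    )
  )
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  }
  if (dim(raw)[3] == 4L) {
    rlang::abort(
      "Image has an alpha channel; flatten it to opaque RGB before use.",
      class = "stainbench_error_invalid_argument"
    )
  }
  img <- round(raw[, , 1:3, drop = FALSE] * 255)
  assert_rgb(img, "read image")
  img
}

#' Write an 8-bit RGB raster
#'
#' @param img `H x W x 3` array with values in `[0, 255]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  arr <- round(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    rlang::abort(
      sprintf("Unsupported raster format '.%s' (use PNG or TIFF).", ext),
      class = "stainbench_error_invalid_argument"
    )
  )
  invisible(path)
}

# Flatten H x W x 3 to (H*W) x 3 and back; all colour math is row-wise.
flatten_rgb <- function(img) {
  d <- dim(img)
  matrix(img, nrow = d[1] * d[2], ncol = 3L)
}

unflatten_rgb <- function(mat, dims) {
  array(mat, dim = c(dims[1], dims[2], 3L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
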