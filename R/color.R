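# Colour-space conversions shared by the normalization methods and metrics:
# RGB <-> optical density (Beer-Lambert) and RGB <-> Ruderman l-alpha-beta.
#
# Both log transforms use base 10. The RGB->LMS matrix is the published
# Ruderman/Reinhard matrix with each row rescaled to unit sum so that the
# achromatic axis (R = G = B) maps exactly onto alpha = beta = 0; the raw
# published rows sum to 0.9996/0.9993/0.9973, which would leave a ~1e-3
# chroma residual on neutral pixels. The rescaling changes entries by < 0.3%.
.rgb2lms <- local({
  m <- matrix(c(
    0.3811, 0.5783, 0.0402,
    0.1967, 0.7244, 0.0782,
    0.0241, 0.1288, 0.8444
  ), nrow = 3, byrow = TRUE)
  m / rowSums(m)
})
.lms2rgb <- solve(.rgb2lms)

# Orthogonal decorrelation transform: rows (1,1,1)/sqrt(3), (1,1,-2)/sqrt(6),
# (1,-1,0)/sqrt(2). Orthogonality makes the inverse a transpose.
.lab_rot <- matrix(c(
  1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3),
  1 / sqrt(6), 1 / sqrt(6), -2 / sqrt(6),
  1 / sqrt(2), -1 / sqrt(2), 0
), nrow = 3, byrow = TRUE)

.lms_floor <- 1e-6

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert relation `od = -log10(I / I0)` per channel. To
#' keep the map finite at zero intensity the ratio is computed as
#' `(value + 1) / (i0 + 1)`, which is exact at `value = i0` (OD 0) and biases
#' other values by well under one intensity level.
#'
#' @param img `H x W x 3` array, values in `[0, 255]` (or `[0, i0]`).
#' @param i0 Incident (white) intensity; 255 for 8-bit rasters.
#' @return An `od_image`: list with `od` (`H x W x 3` array of nonnegative
#'   optical densities) and `i0`.
#' @export
#' @examples
#' od <- rgb_to_od(array(255, dim = c(2, 2, 3)))
#' all(od$od == 0)
rgb_to_od <- function(img, i0 = 255) {
  if (!is.numeric(i0) || length(i0) != 1L || i0 <= 0) {
    rlang::abort("`i0` must be a single positive number.",
      class = "stainbench_error_invalid_argument"
    )
  }
  assert_rgb(img)
  od <- -log10((img + 1) / (i0 + 1))
  structure(list(od = od, i0 = i0), class = "od_image")
}

#' Convert optical density back to RGB
#'
#' Inverse of [rgb_to_od()]: `pixels = clamp(round(i0 * 10^-od), 0, 255)`.
#'
#' @param od An `od_image`, or a bare `H x W x 3` array of optical densities.
#' @param i0 Incident intensity; ignored when `od` is an `od_image`.
#' @return `H x W x 3` RGB array.
#' @export
od_to_rgb <- function(od, i0 = 255) {
  if (inherits(od, "od_image")) {
    i0 <- od$i0
    od <- od$od
  }
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L) {
    rlang::abort("`od` must be an H x W x 3 array.",
      class = "stainbench_error_invalid_argument"
    )
  }
  if (min(od) < 0) {
    rlang::abort("Optical densities must be nonnegative.",
      class = "stainbench_error_invalid_argument"
    )
  }
  clamp(round(i0 * 10^(-od)), 0, 255)
}

#' Convert RGB to the Ruderman l-alpha-beta space
#'
#' RGB intensities (0-255 scale) are mapped through the (row-normalized)
#' RGB-to-LMS matrix, floored at `1e-6` before taking `log10`, and rotated
#' into the decorrelated luminance/chroma axes `l`, `alpha`, `beta`.
#' Achromatic pixels map to `alpha = beta = 0` exactly; `l = alpha =
#' beta = 0` corresponds to LMS = 1, a near-black pixel.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @return A `lab_image`: list of `H x W` matrices `l`, `alpha`, `beta`.
#' @export
#' @examples
#' lab <- rgb_to_lab(array(128, dim = c(2, 2, 3)))
#' max(abs(lab$alpha))
rgb_to_lab <- function(img) {
  assert_rgb(img)
  d <- dim(img)
  lms <- flatten_rgb(img) %*% t(.rgb2lms)
  lab <- log10(pmax(lms, .lms_floor)) %*% t(.lab_rot)
  structure(
    list(
      l = matrix(lab[, 1], d[1], d[2]),
      alpha = matrix(lab[, 2], d[1], d[2]),
      beta = matrix(lab[, 3], d[1], d[2])
    ),
    class = "lab_image"
  )
}

#' Convert l-alpha-beta back to RGB
#'
#' Exact algebraic inverse of [rgb_to_lab()] followed by rounding and
#' clamping to `[0, 255]`.
#'
#' @param lab A `lab_image`, or a list with `H x W` matrices `l`, `alpha`,
#'   `beta`.
#' @return `H x W x 3` RGB array.
#' @export
lab_to_rgb <- function(lab) {
  if (!all(c("l", "alpha", "beta") %in% names(lab))) {
    rlang::abort("`lab` must have components l, alpha, beta.",
      class = "stainbench_error_invalid_argument"
    )
  }
  d <- dim(lab$l)
  m <- cbind(as.vector(lab$l), as.vector(lab$alpha), as.vector(lab$beta))
  lms <- 10^(m %*% .lab_rot) # inverse rotation: orthogonal, so transpose-free
  rgb <- lms %*% t(.lms2rgb)
  unflatten_rgb(clamp(round(rgb), 0, 255), d)
}
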