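# Quantitative evaluation suite: four l-alpha-beta channel-histogram
# similarity measures, SSIM against the original image, and a Frechet
# distance on tile feature clouds.

#' Channel histograms of an image in l-alpha-beta space
#'
#' @param img `H x W x 3` RGB array.
#' @param bins Bins per channel (default 256).
#' @param ranges Optional list of `c(min, max)` per channel (`l`, `alpha`,
#'   `beta`); use [lab_ranges()] for panel-global ranges. Defaults to the
#'   image's own ranges.
#' @param mask Optional logical `H x W` matrix; only `TRUE` pixels are
#'   histogrammed (e.g. a tissue mask from [tissue_mask()]).
#' @return A `channel_histograms` object: list of three normalized
#'   histograms plus the binning used.
#' @export
lab_histograms <- function(img, bins = 256, ranges = NULL, mask = NULL) {
  lab <- rgb_to_lab(img)
  ranges <- ranges %||% purrr::map(lab, range)
  keep <- if (is.null(mask)) TRUE else as.vector(mask)
  hists <- purrr::map2(
    lab[c("l", "alpha", "beta")], ranges[c("l", "alpha", "beta")],
    function(plane, rg) normalized_hist(as.vector(plane)[keep], bins, rg)
  )
  structure(list(hists = hists, bins = bins, ranges = ranges),
    class = "channel_histograms"
  )
}

#' Tissue mask by optical-density threshold
#'
#' @param img `H x W x 3` RGB array.
#' @param od_threshold A pixel is tissue if any OD channel reaches this
#'   value (default 0.15).
#' @return Logical `H x W` matrix.
#' @export
tissue_mask <- function(img, od_threshold = 0.15) {
  od <- rgb_to_od(img)$od
  apply(od >= od_threshold, c(1, 2), any)
}

check_compatible <- function(a, b) {
  ok <- inherits(a, "channel_histograms") && inherits(b, "channel_histograms") &&
    a$bins == b$bins &&
    isTRUE(all.equal(a$ranges, b$ranges, tolerance = 1e-12))
  if (!ok) {
    rlang::abort(
      "Histogram sets have different binning; recompute over shared ranges.",
      class = "stainbench_error_invalid_argument"
    )
  }
}

per_channel <- function(a, b, f) {
  mean(purrr::map2_dbl(a$hists, b$hists, f))
}

#' Histogram intersection
#'
#' Per channel, the sum of bin-wise minima of the two normalized
#' histograms (1 for identical histograms, 0 for disjoint supports);
#' channels are averaged into one scalar.
#'
#' @param a,b `channel_histograms` over identical binning.
#' @return Scalar in `[0, 1]`.
#' @export
hist_intersection <- function(a, b) {
  check_compatible(a, b)
  per_channel(a, b, function(p, q) sum(pmin(p, q)))
}

#' Pearson correlation of histogram bins
#'
#' @inheritParams hist_intersection
#' @return Scalar in `[-1, 1]`. A zero-variance (uniform) histogram has no
#'   defined correlation and raises an undefined-correlation error; callers
#'   aggregating many samples should catch it and record a missing value.
#' @export
hist_pcc <- function(a, b) {
  check_compatible(a, b)
  per_channel(a, b, function(p, q) {
    if (stats::sd(p) < 1e-15 || stats::sd(q) < 1e-15) {
      rlang::abort(
        "Histogram has zero bin variance; correlation undefined.",
        class = "stainbench_error_undefined_correlation"
      )
    }
    stats::cor(p, q)
  })
}

#' Euclidean distance between histograms
#'
#' @inheritParams hist_intersection
#' @return Scalar `>= 0` (at most `sqrt(2)` per channel for normalized
#'   histograms).
#' @export
hist_euclidean <- function(a, b) {
  check_compatible(a, b)
  per_channel(a, b, function(p, q) sqrt(sum((p - q)^2)))
}

#' Jensen-Shannon divergence between histograms
#'
#' Base-2 logarithms, so the value lies in `[0, 1]`; `0 * log 0` is taken
#' as 0.
#'
#' @inheritParams hist_intersection
#' @return Scalar in `[0, 1]`.
#' @export
js_divergence <- function(a, b) {
  check_compatible(a, b)
  kl2 <- function(p, m) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / m[nz]))
  }
  per_channel(a, b, function(p, q) {
    m <- (p + q) / 2
    0.5 * kl2(p, m) + 0.5 * kl2(q, m)
  })
}

# Separable Gaussian filtering with symmetric (reflective) borders,
# implemented as a weighted sum of shifted copies; fast in R for the
# kernel widths SSIM uses.
gaussian_kernel_1d <- function(size, sigma) {
  r <- (size - 1) / 2
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

reflect_pad <- function(m, r) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c(r:1, seq_len(nr), nr - seq_len(r) + 1L)
  ci <- c(r:1, seq_len(nc), nc - seq_len(r) + 1L)
  m[ri, ci]
}

gauss_filter <- function(m, w) {
  r <- (length(w) - 1L) / 2L
  p <- reflect_pad(m, r)
  nr <- nrow(m)
  nc <- ncol(m)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (k in seq_along(w)) {
    tmp <- tmp + w[k] * p[(k - 1L) + seq_len(nr), ]
  }
  out <- matrix(0, nr, nc)
  for (k in seq_along(w)) {
    out <- out + w[k] * tmp[, (k - 1L) + seq_len(nc)]
  }
  out
}

#' Structural similarity index between two images
#'
#' Standard SSIM with Gaussian-weighted local statistics (11 x 11 window,
#' sigma 1.5 by default) and stabilizers `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2` with `L = 255`. Computed per RGB channel, averaged
#' over all window positions and then over channels.
#'
#' @param x,y `H x W x 3` RGB arrays of identical size.
#' @param window Odd window width (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @return Scalar in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(x, y, window = 11, sigma = 1.5) {
  assert_rgb(x, "x")
  assert_rgb(y, "y")
  if (!all(dim(x) == dim(y))) {
    rlang::abort("Images must have identical dimensions.",
      class = "stainbench_error_invalid_argument"
    )
  }
  w <- gaussian_kernel_1d(window, sigma)
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  vals <- vapply(1:3, function(ch) {
    a <- x[, , ch]
    b <- y[, , ch]
    mu_a <- gauss_filter(a, w)
    mu_b <- gauss_filter(b, w)
    var_a <- gauss_filter(a * a, w) - mu_a^2
    var_b <- gauss_filter(b * b, w) - mu_b^2
    cov_ab <- gauss_filter(a * b, w) - mu_a * mu_b
    s <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
    mean(s)
  }, numeric(1))
  mean(vals)
}

#' Construct a feature cloud
#'
#' @param vectors Numeric matrix, one row per tile/sample.
#' @param extractor_id Identifier of the extractor that produced the rows;
#'   clouds from different extractors are not comparable.
#' @return A `feature_cloud` object.
#' @export
feature_cloud <- function(vectors, extractor_id = "custom") {
  vectors <- as.matrix(vectors)
  structure(list(vectors = vectors, extractor_id = extractor_id),
    class = "feature_cloud"
  )
}

# Fixed seeded projection weights for the default extractor: eight 3x3x3
# convolution filters plus a dense projection of a 16x16x3 thumbnail.
# Generated once per (seed) and cached; the seed is part of the extractor
# id so mismatched clouds are refused.
.extractor_cache <- new.env(parent = emptyenv())

default_extractor_weights <- function(seed) {
  key <- as.character(seed)
  if (!exists(key, envir = .extractor_cache)) {
    weights <- withr::with_seed(seed, list(
      conv = array(stats::rnorm(3 * 3 * 3 * 8), dim = c(3, 3, 3, 8)),
      proj = matrix(stats::rnorm(16 * 16 * 3 * 8) / sqrt(768), 768, 8)
    ))
    assign(key, weights, envir = .extractor_cache)
  }
  get(key, envir = .extractor_cache)
}

# Block-mean downsample of one channel plane to size s x s.
block_mean <- function(plane, s) {
  nr <- nrow(plane)
  nc <- ncol(plane)
  ri <- floor((seq_len(nr) - 1) * s / nr) + 1L
  ci <- floor((seq_len(nc) - 1) * s / nc) + 1L
  sums <- rowsum(t(rowsum(plane, ri)), ci) # s x s, rows = column blocks
  t(sums / tcrossprod(tabulate(ci, s), tabulate(ri, s)))
}

default_tile_features <- function(tile, weights) {
  thumb <- vapply(1:3, function(ch) block_mean(tile[, , ch], 16L),
    matrix(0, 16, 16)
  ) / 255
  conv_stats <- as.vector(vapply(seq_len(dim(weights$conv)[4]), function(f) {
    resp <- matrix(0, 14, 14)
    for (dc in 1:3) {
      for (i in 1:3) {
        for (j in 1:3) {
          resp <- resp + weights$conv[i, j, dc, f] *
            thumb[i:(i + 13), j:(j + 13), dc]
        }
      }
    }
    resp <- pmax(resp, 0) # rectified response
    c(mean(resp), stats::sd(as.vector(resp)))
  }, numeric(2)))
  proj <- as.vector(matrix(thumb, 1, 768) %*% weights$proj)
  ch_mean <- vapply(1:3, function(ch) mean(tile[, , ch]), numeric(1)) / 255
  ch_sd <- vapply(1:3, function(ch) stats::sd(as.vector(tile[, , ch])), numeric(1)) / 255
  c(conv_stats, proj, ch_mean, ch_sd)
}

#' Extract a tile feature cloud from an image
#'
#' Tiles the image ([tile_image()]) and maps each tile to a feature vector
#' with the supplied extractor. The default extractor is self-contained and
#' deterministic: seeded fixed random 3 x 3 convolution filters (rectified,
#' mean/sd pooled) plus a seeded random projection of a 16 x 16 thumbnail
#' and channel moments, 38 dimensions in total. It plays the structural
#' role of a pretrained network bottleneck so Frechet distances are
#' comparable within a run; substitute pretrained features via `extractor`
#' for literal comparability with published FID values.
#'
#' @param img `H x W x 3` RGB array.
#' @param tile Tile side in pixels (default 128).
#' @param extractor `NULL` for the default, or a function `tile -> numeric
#'   vector`.
#' @param seed Seed of the default extractor's fixed weights (default 423).
#' @return A `feature_cloud` with one row per tile.
#' @export
extract_features <- function(img, tile = 128, extractor = NULL, seed = 423) {
  assert_rgb(img)
  ts <- tile_image(img, tile)
  if (length(ts$tiles) == 0L) {
    return(feature_cloud(matrix(numeric(0), 0, 0), "empty"))
  }
  if (is.null(extractor)) {
    weights <- default_extractor_weights(seed)
    fn <- function(t) default_tile_features(t, weights)
    id <- sprintf("rproj-conv-v1-seed%d", seed)
  } else {
    fn <- extractor
    id <- "custom"
  }
  feature_cloud(do.call(rbind, purrr::map(ts$tiles, fn)), id)
}

# Symmetric positive-semidefinite matrix square root via eigen
# decomposition; negative eigenvalues from roundoff are clipped.
sqrtm_sym <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two feature clouds
#'
#' Gaussian-fit distance
#' `||mu_a - mu_b||^2 + Tr(Sigma_a + Sigma_b - 2 (Sigma_a Sigma_b)^{1/2})`
#' with a symmetric matrix square root and `1e-6 * I` shrinkage on both
#' covariances for numerical stability. Nonnegative up to roundoff; tiny
#' negative values are clipped to zero.
#'
#' @param a,b `feature_cloud`s from the same extractor, each with at least
#'   two rows.
#' @return Scalar `>= 0`.
#' @export
frechet_distance <- function(a, b) {
  if (!inherits(a, "feature_cloud") || !inherits(b, "feature_cloud") ||
    !identical(a$extractor_id, b$extractor_id)) {
    rlang::abort(
      "Feature clouds must come from the same extractor.",
      class = "stainbench_error_invalid_comparison"
    )
  }
  if (nrow(a$vectors) < 2L || nrow(b$vectors) < 2L) {
    rlang::abort("Each cloud needs >= 2 rows for covariance estimation.",
      class = "stainbench_error_invalid_argument"
    )
  }
  mu_a <- colMeans(a$vectors)
  mu_b <- colMeans(b$vectors)
  eps <- 1e-6 * diag(ncol(a$vectors))
  sa <- stats::cov(a$vectors) + eps
  sb <- stats::cov(b$vectors) + eps
  sqrt_sa <- sqrtm_sym(sa)
  cross <- sqrtm_sym(sqrt_sa %*% sb %*% sqrt_sa)
  val <- sum((mu_a - mu_b)^2) + sum(diag(sa)) + sum(diag(sb)) -
    2 * sum(diag(cross))
  max(val, 0)
}

#' Evaluate one normalized sample against reference and original
#'
#' Computes the full metric record the benchmark tables are built from:
#' histogram intersection, Pearson correlation, Euclidean distance and
#' Jensen-Shannon divergence of l-alpha-beta channel histograms
#' (normalized vs reference), SSIM (normalized vs original, structural
#' integrity), and the Frechet feature distance between tile clouds
#' (normalized vs reference). An undefined histogram correlation is
#' recorded as `NA`.
#'
#' @param original,normalized,reference `H x W x 3` RGB arrays; `original`
#'   and `normalized` must share dimensions.
#' @param sample_id,method Identifiers copied into the record.
#' @param bins Histogram bins per channel (default 256).
#' @param ranges Channel ranges for the histograms; defaults to the joint
#'   ranges of the three images.
#' @param tile Tile side for the feature clouds (default 128).
#' @param mask_od `NULL` to include background pixels (the default), or an
#'   OD threshold so histograms cover tissue pixels only.
#' @param reference_hists,reference_features Optional precomputed reference
#'   histograms/features, to avoid recomputation across a panel.
#' @param extractor_seed Seed of the default feature extractor.
#' @return One-row tibble: `sample_id`, `method`, `intersection`, `pcc`,
#'   `euclidean`, `js`, `ssim`, `fid`.
#' @export
evaluate_sample <- function(original, normalized, reference,
                            sample_id = "sample", method = "method",
                            bins = 256, ranges = NULL, tile = 128,
                            mask_od = NULL,
                            reference_hists = NULL,
                            reference_features = NULL,
                            extractor_seed = 423) {
  ranges <- ranges %||% lab_ranges(list(original, normalized, reference))
  mask_n <- if (is.null(mask_od)) NULL else tissue_mask(normalized, mask_od)
  mask_r <- if (is.null(mask_od)) NULL else tissue_mask(reference, mask_od)
  h_n <- lab_histograms(normalized, bins, ranges, mask_n)
  h_r <- reference_hists %||% lab_histograms(reference, bins, ranges, mask_r)
  pcc <- tryCatch(
    hist_pcc(h_n, h_r),
    stainbench_error_undefined_correlation = function(e) NA_real_
  )
  f_n <- extract_features(normalized, tile, seed = extractor_seed)
  f_r <- reference_features %||% extract_features(reference, tile, seed = extractor_seed)
  fid <- if (nrow(f_n$vectors) >= 2L && nrow(f_r$vectors) >= 2L) {
    frechet_distance(f_n, f_r)
  } else {
    NA_real_
  }
  tibble::tibble(
    sample_id = sample_id,
    method = method,
    intersection = hist_intersection(h_n, h_r),
    pcc = pcc,
    euclidean = hist_euclidean(h_n, h_r),
    js = js_divergence(h_n, h_r),
    ssim = ssim(original, normalized),
    fid = fid
  )
}
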