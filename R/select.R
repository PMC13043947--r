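# Reference-sample selection (red-to-blue ratio rule) and clustering-based
# representative-sample selection.

#' Red-to-blue mean intensity ratio
#'
#' The ratio of the red channel's mean intensity to the blue channel's.
#' Hematoxylin expresses in blue and eosin in red, so a slide whose ratio
#' is close to 1 is colour balanced between the two stains.
#'
#' @param img `H x W x 3` RGB array.
#' @return A single positive number.
#' @export
#' @examples
#' rb_ratio(array(128, dim = c(4, 4, 3))) # gray -> exactly 1
rb_ratio <- function(img) {
  assert_rgb(img)
  b <- mean(img[, , 3])
  if (b <= 0) {
    rlang::abort("Blue channel mean is zero; ratio undefined.",
      class = "stainbench_error_degenerate_image"
    )
  }
  mean(img[, , 1]) / b
}

#' Select the reference sample of a panel
#'
#' The panel member whose red-to-blue mean intensity ratio is closest to 1
#' is chosen as the normalization reference. Ties are broken in favour of
#' the lowest index.
#'
#' @param panel List of `H x W x 3` RGB arrays, optionally named.
#' @return List with `index` (chosen sample) and `ratios`, a tibble of
#'   `sample_id` and `ratio` for plotting the panel's colour spread.
#' @export
select_reference <- function(panel) {
  if (!is.list(panel) || length(panel) == 0L) {
    rlang::abort("`panel` must be a nonempty list of RGB images.",
      class = "stainbench_error_invalid_argument"
    )
  }
  ids <- names(panel) %||% sprintf("sample_%02d", seq_along(panel))
  ratios <- vapply(panel, rb_ratio, numeric(1))
  idx <- which.min(abs(ratios - 1)) # which.min takes the first on ties
  list(
    index = unname(idx),
    ratios = tibble::tibble(sample_id = ids, ratio = unname(ratios))
  )
}

#' l-alpha-beta histogram feature vector of an image
#'
#' Converts the image to the Ruderman l-alpha-beta space, histograms each
#' channel over fixed ranges, normalizes each histogram to sum 1, and
#' concatenates the three blocks. These vectors are the clustering features
#' for representative-sample selection.
#'
#' @param img `H x W x 3` RGB array.
#' @param bins Bins per channel (default 64).
#' @param ranges Optional list with numeric `c(min, max)` ranges for `l`,
#'   `alpha`, `beta`. Defaults to the image's own channel ranges; for panel
#'   work pass the panel-global ranges from [lab_ranges()] so features are
#'   comparable.
#' @return Numeric vector of length `3 * bins`.
#' @export
histogram_features <- function(img, bins = 64, ranges = NULL) {
  if (bins < 2) {
    rlang::abort("`bins` must be at least 2.",
      class = "stainbench_error_invalid_argument"
    )
  }
  lab <- rgb_to_lab(img)
  ranges <- ranges %||% purrr::map(lab, range)
  blocks <- purrr::map2(lab[c("l", "alpha", "beta")],
    ranges[c("l", "alpha", "beta")],
    function(plane, rg) normalized_hist(as.vector(plane), bins, rg)
  )
  unlist(blocks, use.names = FALSE)
}

#' Panel-global l-alpha-beta channel ranges
#'
#' @param panel List of RGB images.
#' @return List of `c(min, max)` per channel (`l`, `alpha`, `beta`), padded
#'   by a tiny margin so boundary values fall inside the outer bins.
#' @export
lab_ranges <- function(panel) {
  labs <- purrr::map(panel, rgb_to_lab)
  purrr::map(
    stats::setNames(c("l", "alpha", "beta"), c("l", "alpha", "beta")),
    function(ch) {
      rg <- range(purrr::map(labs, function(x) range(x[[ch]])))
      if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
      rg + c(-1, 1) * 1e-9 * max(1, abs(rg))
    }
  )
}

# Histogram normalized to sum 1 over fixed bin edges; values outside the
# range are clamped into the outer bins.
normalized_hist <- function(x, bins, rg) {
  edges <- seq(rg[1], rg[2], length.out = bins + 1)
  idx <- findInterval(x, edges, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  counts / sum(counts)
}

#' Panel feature table for representative selection
#'
#' @param panel List of RGB images (optionally named).
#' @param bins Bins per l-alpha-beta channel (default 64).
#' @return Tibble with `sample_id` and a list-column `feature` of
#'   normalized histogram vectors over panel-global channel ranges.
#' @export
panel_features <- function(panel, bins = 64) {
  ids <- names(panel) %||% sprintf("sample_%02d", seq_along(panel))
  ranges <- lab_ranges(panel)
  tibble::tibble(
    sample_id = ids,
    feature = purrr::map(panel, histogram_features, bins = bins, ranges = ranges)
  )
}

#' Select representative samples by PCA + k-means
#'
#' Projects the panel's histogram features onto their first two principal
#' components (centred, unscaled), clusters the 2-D coordinates with seeded
#' k-means, and picks as each cluster's representative the member nearest
#' its centroid in Euclidean distance. A within-cluster sum-of-squares
#' curve over `k = 1..min(12, n)` is returned as an elbow diagnostic; the
#' study protocol fixes `k = 8` regardless, so the diagnostic is surfaced
#' rather than acted on.
#'
#' @param features Tibble from [panel_features()] (columns `sample_id`,
#'   `feature`), or a numeric matrix with one row per sample.
#' @param k Number of clusters (default 8).
#' @param seed Integer seed controlling the k-means restarts.
#' @return A `representative_set`: list with `assignments` (tibble
#'   `sample_id`, `cluster`, `pc1`, `pc2`), `representatives` (tibble
#'   `cluster`, `sample_id`), and `wcss` (tibble `k`, `wcss`).
#' @export
select_representatives <- function(features, k = 8, seed = 1) {
  if (is.data.frame(features)) {
    ids <- features$sample_id
    x <- do.call(rbind, features$feature)
  } else {
    x <- as.matrix(features)
    ids <- rownames(x) %||% sprintf("sample_%02d", seq_len(nrow(x)))
  }
  n <- nrow(x)
  if (n < k) {
    rlang::abort(
      sprintf("Need at least k = %d samples, got %d.", k, n),
      class = "stainbench_error_invalid_argument"
    )
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  coords <- pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE]
  if (ncol(coords) == 1L) coords <- cbind(coords, 0)
  withr::with_seed(seed, {
    km <- best_kmeans(coords, k)
    wcss <- vapply(
      seq_len(min(12L, n)),
      function(kk) best_kmeans(coords, kk)$tot.withinss,
      numeric(1)
    )
  })
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(km$cluster == cl)
    d2 <- rowSums((coords[members, , drop = FALSE] -
      matrix(km$centers[cl, ], length(members), 2, byrow = TRUE))^2)
    members[which.min(d2)]
  }, integer(1))
  structure(
    list(
      assignments = tibble::tibble(
        sample_id = ids, cluster = unname(km$cluster),
        pc1 = unname(coords[, 1]), pc2 = unname(coords[, 2])
      ),
      representatives = tibble::tibble(
        cluster = seq_len(k), sample_id = ids[reps]
      ),
      wcss = tibble::tibble(k = seq_along(wcss), wcss = unname(wcss)),
      k = k, seed = seed
    ),
    class = "representative_set"
  )
}

# k-means with 10 random restarts plus a greedy split of the previous
# solution cached across calls is overkill here; instead each k gets 10
# seeded restarts and, to guarantee the elbow curve is monotone, a farthest
# -point refinement start seeded from the best (k-1)-solution.
best_kmeans <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) {
    # singleton clusters: every sample is its own centroid
    return(list(
      cluster = seq_len(n), centers = coords, tot.withinss = 0
    ))
  }
  km <- stats::kmeans(coords, centers = k, nstart = 10, iter.max = 50)
  if (k > 1) {
    prev <- stats::kmeans(coords, centers = k - 1, nstart = 10, iter.max = 50)
    d2 <- rowSums((coords - prev$centers[prev$cluster, , drop = FALSE])^2)
    init <- rbind(prev$centers, coords[which.max(d2), ])
    km2 <- tryCatch(
      stats::kmeans(coords, centers = init, iter.max = 50),
      error = function(e) NULL
    )
    if (!is.null(km2) && km2$tot.withinss < km$tot.withinss) km <- km2
  }
  km
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf(
    "<representative_set> %d samples in %d clusters (seed %d)\n",
    nrow(x$assignments), x$k, x$seed
  ))
  print(x$representatives)
  invisible(x)
}

#' Tidy a representative set
#'
#' @param x A `representative_set`.
#' @param ... Unused.
#' @return The assignment tibble with a logical `representative` column.
#' @method tidy representative_set
#' @export
tidy.representative_set <- function(x, ...) {
  dplyr::mutate(
    x$assignments,
    representative = .data$sample_id %in% x$representatives$sample_id
  )
}

#' Plot a representative set in PCA space
#'
#' @param object A `representative_set`.
#' @param ... Unused.
#' @return A ggplot: samples in the first two principal components,
#'   coloured by cluster, representatives highlighted.
#' @method autoplot representative_set
#' @export
autoplot.representative_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
    colour = factor(.data$cluster)
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$representative),
      shape = 1, size = 5, stroke = 1.2, colour = "black"
    ) +
    ggplot2::labs(
      x = "PC1", y = "PC2", colour = "cluster",
      title = "Panel samples in histogram-feature PCA space",
      subtitle = "Circled points are cluster representatives"
    ) +
    ggplot2::theme_minimal()
}
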