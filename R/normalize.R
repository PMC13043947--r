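# The four classical stain-normalization methods, each mapping
# (source image, reference image) -> normalized image. All methods operate
# on the full image in one pass (never patchwise), which avoids tiling
# artifacts when whole slides are normalized against a whole-slide
# reference.

new_normalization <- function(image, method, diagnostics) {
  structure(
    list(image = image, method = method, diagnostics = diagnostics),
    class = "stain_normalization"
  )
}

#' @export
print.stain_normalization <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<stain_normalization> method '%s', %d x %d image\n",
    x$method, d[1], d[2]
  ))
  invisible(x)
}

#' Tidy a normalization result
#'
#' Returns the method's scalar diagnostics (percentile scales, channel
#' moments) as one row per quantity.
#'
#' @param x A `stain_normalization` object.
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `channel`, `value`.
#' @method tidy stain_normalization
#' @export
tidy.stain_normalization <- function(x, ...) {
  d <- x$diagnostics
  scalars <- d[vapply(d, function(v) is.numeric(v) && !is.matrix(v), logical(1))]
  purrr::imap_dfr(scalars, function(v, nm) {
    tibble::tibble(
      quantity = nm,
      channel = if (is.null(names(v))) as.character(seq_along(v)) else names(v),
      value = as.numeric(v)
    )
  })
}

#' @rdname tidy.stain_normalization
#' @method glance stain_normalization
#' @export
glance.stain_normalization <- function(x, ...) {
  d <- dim(x$image)
  tibble::tibble(method = x$method, height = d[1], width = d[2])
}

#' Histogram matching normalization
#'
#' Maps each RGB channel of the source through a monotone 256-level
#' quantile mapping so that its empirical CDF matches the reference
#' channel's. Ties share the averaged (cumulative) rank, and the inverse
#' reference CDF is linearly interpolated between occupied intensity
#' levels.
#'
#' @param source,reference `H x W x 3` RGB arrays.
#' @return A `stain_normalization` result; `$image` holds the normalized
#'   array.
#' @export
histogram_match <- function(source, reference) {
  assert_rgb(source, "source")
  assert_rgb(reference, "reference")
  d <- dim(source)
  out <- array(0, dim = d)
  channels <- c("R", "G", "B")
  for (ch in 1:3) {
    ref_vals <- as.vector(reference[, , ch])
    ref_counts <- tabulate(ref_vals + 1L, nbins = 256L)
    occupied <- which(ref_counts > 0L)
    if (length(occupied) < 2L) {
      rlang::abort(
        sprintf(
          "Reference channel %s is constant; cannot match histograms.",
          channels[ch]
        ),
        class = "stainbench_error_degenerate_reference"
      )
    }
    # Averaged ranks: level v carries the mid-CDF (F(v-) + F(v)) / 2, so a
    # mass spike maps onto the reference quantile at its centre.
    ref_cum <- cumsum(ref_counts) / length(ref_vals)
    ref_mid <- (ref_cum - ref_counts / (2 * length(ref_vals)))[occupied]
    src_vals <- as.vector(source[, , ch])
    src_counts <- tabulate(src_vals + 1L, nbins = 256L)
    src_cum <- cumsum(src_counts) / length(src_vals)
    src_mid <- src_cum - src_counts / (2 * length(src_vals))
    lut <- stats::approx(
      x = ref_mid, y = occupied - 1L, xout = src_mid,
      rule = 2, ties = "ordered"
    )$y
    out[, , ch] <- matrix(lut[src_vals + 1L], d[1], d[2])
  }
  new_normalization(clamp(round(out), 0, 255), "histmatch", list())
}

#' Reinhard colour transfer normalization
#'
#' Standardizes each Ruderman l-alpha-beta channel of the source (subtract
#' mean, divide by standard deviation) and rescales it to the reference
#' channel's mean and standard deviation, then converts back to RGB with
#' clamping. Before clamping, the output channel moments equal the
#' reference's by construction; the realized pre-clamp moments are recorded
#' in the diagnostics.
#'
#' @param source,reference `H x W x 3` RGB arrays.
#' @param zero_std_fallback If `TRUE`, a constant source channel is given a
#'   nominal standard deviation of `1e-6` instead of raising a
#'   degenerate-source error.
#' @return A `stain_normalization` result. Diagnostics include
#'   `source_mean/sd`, `reference_mean/sd` and the pre-clamp output
#'   moments `preclamp_mean/sd` per channel.
#' @export
reinhard <- function(source, reference, zero_std_fallback = FALSE) {
  assert_rgb(source, "source")
  assert_rgb(reference, "reference")
  src <- rgb_to_lab(source)
  ref <- rgb_to_lab(reference)
  chans <- c("l", "alpha", "beta")
  out <- list()
  stats_out <- list(
    source_mean = numeric(3), source_sd = numeric(3),
    reference_mean = numeric(3), reference_sd = numeric(3),
    preclamp_mean = numeric(3), preclamp_sd = numeric(3)
  )
  for (i in seq_along(chans)) {
    ch <- chans[i]
    m_s <- mean(src[[ch]])
    s_s <- stats::sd(as.vector(src[[ch]]))
    if (s_s < 1e-12) {
      if (!zero_std_fallback) {
        rlang::abort(
          sprintf("Source channel %s has zero variance.", ch),
          class = "stainbench_error_degenerate_source"
        )
      }
      s_s <- 1e-6
    }
    m_r <- mean(ref[[ch]])
    s_r <- stats::sd(as.vector(ref[[ch]]))
    plane <- (src[[ch]] - m_s) / s_s * s_r + m_r
    out[[ch]] <- plane
    stats_out$source_mean[i] <- m_s
    stats_out$source_sd[i] <- s_s
    stats_out$reference_mean[i] <- m_r
    stats_out$reference_sd[i] <- s_r
    stats_out$preclamp_mean[i] <- mean(plane)
    stats_out$preclamp_sd[i] <- stats::sd(as.vector(plane))
  }
  stats_out <- purrr::map(stats_out, stats::setNames, chans)
  new_normalization(lab_to_rgb(out), "reinhard", stats_out)
}

# Percentile robust scale of each stain channel; the 99th percentile tracks
# the strongly stained pixels without being hostage to outliers.
conc_scales <- function(conc, scale_percentile) {
  apply(matrix(conc, ncol = 2L), 2, stats::quantile,
    probs = scale_percentile / 100, names = FALSE
  )
}

#' Macenko stain normalization
#'
#' Fits stain matrices for source and reference by [macenko_fit()], solves
#' the source's per-pixel concentrations, rescales each stain channel so
#' its `scale_percentile`-th concentration percentile matches the
#' reference's, and reconstructs the image in the reference's stain basis.
#'
#' @param source,reference `H x W x 3` RGB arrays.
#' @param od_threshold,angle_percentile,i0 Passed to [macenko_fit()].
#' @param scale_percentile Concentration percentile matched between source
#'   and reference (default 99).
#' @return A `stain_normalization` result. Diagnostics hold the fitted
#'   `source_stains`, `reference_stains` and the per-stain `scale` factors.
#' @export
macenko_normalize <- function(source, reference, od_threshold = 0.15,
                              angle_percentile = 1, scale_percentile = 99,
                              i0 = 255) {
  assert_rgb(source, "source")
  assert_rgb(reference, "reference")
  w_src <- macenko_fit(source, od_threshold, angle_percentile, i0)
  w_ref <- macenko_fit(reference, od_threshold, angle_percentile, i0)
  c_src <- stain_concentrations(rgb_to_od(source, i0), w_src)
  c_ref <- stain_concentrations(rgb_to_od(reference, i0), w_ref)
  s_src <- conc_scales(c_src, scale_percentile)
  s_ref <- conc_scales(c_ref, scale_percentile)
  scale <- s_ref / pmax(s_src, 1e-12)
  d <- dim(source)
  cm <- sweep(matrix(c_src, ncol = 2L), 2, scale, "*")
  od_out <- array(cm %*% t(unclass(w_ref)), dim = d)
  new_normalization(
    od_to_rgb(od_out, i0), "macenko",
    list(
      source_stains = w_src, reference_stains = w_ref,
      scale = stats::setNames(scale, c("hematoxylin", "eosin"))
    )
  )
}

#' Vahadane stain normalization
#'
#' Estimates source and reference stain matrices by sparse non-negative
#' factorization ([vahadane_fit()]), rescales the source's per-pixel stain
#' densities to the reference's percentile scale, and recombines them with
#' the reference's colour-appearance matrix.
#'
#' @param source,reference `H x W x 3` RGB arrays.
#' @param sparsity,n_iter,od_threshold,i0 Passed to [vahadane_fit()].
#' @param scale_percentile Concentration percentile matched between source
#'   and reference (default 99).
#' @return A `stain_normalization` result. Diagnostics hold the fitted
#'   stain matrices, per-stain `scale` factors, and the source fit's
#'   `objective` trace.
#' @export
vahadane_normalize <- function(source, reference, sparsity = 0.1,
                               n_iter = 200, scale_percentile = 99,
                               od_threshold = 0.15, i0 = 255) {
  assert_rgb(source, "source")
  assert_rgb(reference, "reference")
  fit_src <- vahadane_fit(source, sparsity, n_iter, od_threshold, i0)
  fit_ref <- vahadane_fit(reference, sparsity, n_iter, od_threshold, i0)
  # Concentrations for every pixel (fits use tissue pixels only).
  c_src <- stain_concentrations(rgb_to_od(source, i0), fit_src$stains)
  c_ref <- stain_concentrations(rgb_to_od(reference, i0), fit_ref$stains)
  s_src <- conc_scales(c_src, scale_percentile)
  s_ref <- conc_scales(c_ref, scale_percentile)
  scale <- s_ref / pmax(s_src, 1e-12)
  d <- dim(source)
  cm <- sweep(matrix(c_src, ncol = 2L), 2, scale, "*")
  od_out <- array(cm %*% t(unclass(fit_ref$stains)), dim = d)
  new_normalization(
    od_to_rgb(od_out, i0), "vahadane",
    list(
      source_stains = fit_src$stains, reference_stains = fit_ref$stains,
      scale = stats::setNames(scale, c("hematoxylin", "eosin")),
      objective = fit_src$objective
    )
  )
}

#' Normalize an image by a named method
#'
#' Dispatch wrapper over the four implemented methods; the method registry
#' can be extended via [register_method()] so external normalizers can be
#' benchmarked with the same machinery.
#'
#' @param source,reference `H x W x 3` RGB arrays.
#' @param method One of `"histmatch"`, `"reinhard"`, `"macenko"`,
#'   `"vahadane"`, or a registered method name.
#' @param ... Method-specific parameters.
#' @return A `stain_normalization` result.
#' @export
#' @examples
#' p <- synthetic_panel(n_labs = 3, size = 96, seed = 7)
#' r <- normalize_stains(p$images[[2]], p$images[[1]], "reinhard")
#' r
normalize_stains <- function(source, reference, method = "reinhard", ...) {
  fn <- .method_registry$get(method)
  fn(source, reference, ...)
}

.method_registry <- local({
  registry <- new.env(parent = emptyenv())
  list(
    set = function(name, fn) assign(name, fn, envir = registry),
    get = function(name) {
      if (!exists(name, envir = registry, inherits = FALSE)) {
        rlang::abort(
          sprintf(
            "Unknown method '%s'. Available: %s.", name,
            paste(sort(ls(registry)), collapse = ", ")
          ),
          class = "stainbench_error_invalid_argument"
        )
      }
      get(name, envir = registry, inherits = FALSE)
    },
    names = function() sort(ls(registry))
  )
})

.method_registry$set("histmatch", function(source, reference, ...) {
  histogram_match(source, reference)
})
.method_registry$set("reinhard", function(source, reference, ...) {
  reinhard(source, reference, ...)
})
.method_registry$set("macenko", function(source, reference, ...) {
  macenko_normalize(source, reference, ...)
})
.method_registry$set("vahadane", function(source, reference, ...) {
  vahadane_normalize(source, reference, ...)
})

#' Register a normalization method for benchmarking
#'
#' @param name Method identifier used in [run_benchmark()] method lists.
#' @param fn Function `(source, reference, ...)` returning a
#'   `stain_normalization` object (or any list with an `$image` RGB array).
#' @return `name`, invisibly.
#' @export
register_method <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .method_registry$set(name, fn)
  invisible(name)
}

#' List registered normalization methods
#'
#' @return Character vector of method names usable in
#'   [normalize_stains()] and [run_benchmark()].
#' @export
available_methods <- function() .method_registry$names()
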