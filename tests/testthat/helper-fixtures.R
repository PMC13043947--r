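# Shared fixtures, built in code and memoized for the test run.

# Small mixed-variation panel (unevenness and tint on).
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_panel(n_labs = 5, size = 128, seed = 42)
    }
    cache
  }
})

# Small panel with unevenness and tint disabled: slides are exact
# Beer-Lambert renderings of the ground-truth stain model.
clean_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_panel(
        n_labs = 5, size = 128, seed = 43,
        unevenness = 0, tint_max = 0
      )
    }
    cache
  }
})

# The study-scale default panel (20 labs, 512 x 512, spread 0.2, seed 17).
default_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_panel()
    cache
  }
})

# Continuous-tone random image: every intensity level carries ~1/256 of the
# mass, so quantile-mapping properties are testable at quantization scale.
random_image <- function(seed, h = 64, w = 64) {
  withr::with_seed(seed, {
    array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  })
}

# Uniform single-colour image.
flat_image <- function(rgb, h = 16, w = 16) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Per-channel Kolmogorov-Smirnov distance between two images' empirical CDFs.
ks_per_channel <- function(x, y) {
  vapply(1:3, function(ch) {
    fx <- stats::ecdf(as.vector(x[, , ch]))
    fy <- stats::ecdf(as.vector(y[, , ch]))
    max(abs(fx(0:255) - fy(0:255)))
  }, numeric(1))
}

# Build a channel_histograms object directly from three histogram vectors
# (shared binning), for closed-form metric examples.
hist_set <- function(l, alpha = l, beta = l) {
  structure(
    list(
      hists = list(l = l, alpha = alpha, beta = beta),
      bins = length(l),
      ranges = list(l = c(0, 1), alpha = c(0, 1), beta = c(0, 1))
    ),
    class = "channel_histograms"
  )
}

max_stain_angle <- function(w, w_true) {
  w <- unclass(w)
  w_true <- unclass(w_true)
  max(stain_angle(w[, 1], w_true[, 1]), stain_angle(w[, 2], w_true[, 2]))
}
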