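# Synthetic multi-laboratory H&E panel generator.
#
# The generator emulates the study design of an external quality assessment
# round: one shared tissue morphology (sections of the same block) stained
# by N virtual laboratories that differ in stain colour (jittered stain
# matrices), staining intensity (log-normal over-/under-staining scales),
# and smooth staining unevenness. Slides are rendered through the
# Beer-Lambert model, so every stage of the pipeline can be validated
# against retained ground truth.

# Smooth random field in [lo, hi]: a sum of K random 2-D cosine waves,
# rescaled. Low frequencies only, so the field varies over length scales of
# a third of the image or more.
smooth_field <- function(h, w, lo, hi, k = 6, max_freq = 3) {
  xs <- seq(0, 1, length.out = w)
  ys <- seq(0, 1, length.out = h)
  f <- matrix(0, h, w)
  for (i in seq_len(k)) {
    fx <- stats::runif(1, 0.5, max_freq)
    fy <- stats::runif(1, 0.5, max_freq)
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    f <- f + amp * outer(
      cos(2 * pi * fy * ys + ph[1]),
      cos(2 * pi * fx * xs + ph[2])
    )
  }
  rg <- range(f)
  if (diff(rg) < 1e-12) {
    return(matrix((lo + hi) / 2, h, w))
  }
  lo + (f - rg[1]) / diff(rg) * (hi - lo)
}

# Filled rotated ellipse mask.
ellipse_mask <- function(h, w, cy, cx, ry, rx, theta) {
  ys <- seq_len(h) - cy
  xs <- seq_len(w) - cx
  yy <- matrix(ys, h, w)
  xx <- matrix(xs, h, w, byrow = TRUE)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate a synthetic tissue morphology
#'
#' Builds per-pixel hematoxylin-binding and eosin-binding density fields:
#' random elliptical nuclei (high hematoxylin, low eosin) on a textured
#' cytoplasm/stroma background (eosin-rich, trace hematoxylin), with a few
#' empty lumen regions and a white unstained margin. Fully deterministic
#' under `seed`.
#'
#' @param height,width Image size in pixels (each at least 64).
#' @param nucleus_count Number of nuclei to place (overlapping nuclei may
#'   merge into one connected component).
#' @param seed Integer seed.
#' @param nucleus_floor Minimum hematoxylin density inside nuclei
#'   (default 0.8 OD-equivalent units).
#' @return A `tissue_field`: list with `h_density`, `e_density` (`H x W`
#'   matrices), `nucleus_mask` (logical matrix), and `seed`.
#' @export
#' @examples
#' tf <- make_tissue(64, 64, nucleus_count = 5, seed = 1)
#' range(tf$h_density)
make_tissue <- function(height, width, nucleus_count = 60, seed = 1,
                        nucleus_floor = 0.8) {
  if (height < 64 || width < 64) {
    rlang::abort("Tissue fields must be at least 64 x 64.",
      class = "stainbench_error_invalid_argument"
    )
  }
  withr::with_seed(seed, {
    # Eosin-rich stroma with visible texture; hematoxylin trace goes close
    # to zero in places so eosin-pure pixels exist for stain estimation.
    e_density <- smooth_field(height, width, 0.18, 0.55, k = 8, max_freq = 5)
    h_density <- smooth_field(height, width, 0.01, 0.10, k = 8, max_freq = 5)
    # Empty lumen regions.
    n_lumen <- max(1L, round(height * width / 5e4))
    for (i in seq_len(n_lumen)) {
      m <- ellipse_mask(
        height, width,
        stats::runif(1, 0.2, 0.8) * height, stats::runif(1, 0.2, 0.8) * width,
        stats::runif(1, 0.04, 0.10) * height, stats::runif(1, 0.04, 0.10) * width,
        stats::runif(1, 0, pi)
      )
      e_density[m] <- e_density[m] * 0.05
      h_density[m] <- h_density[m] * 0.05
    }
    # Nuclei: high hematoxylin, depleted eosin.
    nucleus_mask <- matrix(FALSE, height, width)
    margin <- ceiling(0.05 * min(height, width))
    for (i in seq_len(nucleus_count)) {
      ry <- stats::runif(1, 3, 8)
      rx <- stats::runif(1, 3, 8)
      cy <- stats::runif(1, margin + ry + 2, height - margin - ry - 2)
      cx <- stats::runif(1, margin + rx + 2, width - margin - rx - 2)
      m <- ellipse_mask(height, width, cy, cx, ry, rx, stats::runif(1, 0, pi))
      nucleus_mask <- nucleus_mask | m
      h_density[m] <- nucleus_floor + stats::runif(1, 0, 0.4)
      e_density[m] <- stats::runif(1, 0.02, 0.06)
    }
    # Unstained white margin all around.
    keep <- matrix(FALSE, height, width)
    keep[(margin + 1):(height - margin), (margin + 1):(width - margin)] <- TRUE
    h_density[!keep] <- 0
    e_density[!keep] <- 0
    nucleus_mask <- nucleus_mask & keep
  })
  structure(
    list(
      h_density = h_density, e_density = e_density,
      nucleus_mask = nucleus_mask, seed = seed
    ),
    class = "tissue_field"
  )
}

# Canonical H&E optical-density directions (hematoxylin absorbs red/green,
# eosin absorbs green).
canonical_stains <- function() {
  stain_matrix(cbind(c(0.650, 0.704, 0.286), c(0.072, 0.990, 0.105)))
}

#' Construct a virtual laboratory staining profile
#'
#' @param stains A [stain_matrix()] for the lab's H&E colours.
#' @param h_scale,e_scale Positive multipliers for hematoxylin/eosin
#'   intensity (over-/under-staining).
#' @param unevenness `H x W` multiplicative field (1 = even staining), or
#'   `NULL` for perfectly even staining.
#' @param background_tint Length-3 nonnegative OD offset added everywhere
#'   (residual stain on glass).
#' @param seed Seed recorded for provenance.
#' @return A `lab_profile` object.
#' @export
lab_profile <- function(stains = canonical_stains(), h_scale = 1, e_scale = 1,
                        unevenness = NULL, background_tint = c(0, 0, 0),
                        seed = NA_integer_) {
  stopifnot(h_scale > 0, e_scale > 0, length(background_tint) == 3L)
  structure(
    list(
      stains = stains, h_scale = h_scale, e_scale = e_scale,
      unevenness = unevenness, background_tint = background_tint, seed = seed
    ),
    class = "lab_profile"
  )
}

#' Render a stained slide from tissue and a lab profile
#'
#' Beer-Lambert rendering: per-pixel optical density is
#' `(W %*% c(h_scale * h, e_scale * e)) * unevenness + background_tint`,
#' converted to RGB by [od_to_rgb()]. Deterministic.
#'
#' @param tissue A `tissue_field` from [make_tissue()].
#' @param lab A `lab_profile`.
#' @param i0 Incident white intensity (default 255).
#' @return `H x W x 3` RGB array.
#' @export
render_slide <- function(tissue, lab, i0 = 255) {
  w <- unclass(lab$stains)
  h <- lab$h_scale * tissue$h_density
  e <- lab$e_scale * tissue$e_density
  d <- dim(h)
  conc <- cbind(as.vector(h), as.vector(e))
  od <- conc %*% t(w)
  if (!is.null(lab$unevenness)) {
    od <- od * as.vector(lab$unevenness)
  }
  od <- sweep(od, 2, lab$background_tint, "+")
  od_to_rgb(array(od, dim = c(d[1], d[2], 3L)), i0)
}

# Jitter a unit stain vector: add isotropic Gaussian noise of sd `spread`
# (radians-scale angular perturbation), clamp nonnegative, renormalize.
jitter_stain <- function(v, spread) {
  u <- pmax(v + stats::rnorm(3, 0, spread), 0)
  n <- sqrt(sum(u^2))
  if (n < 1e-8) v else u / n
}

#' Generate a synthetic multi-laboratory panel
#'
#' One shared [make_tissue()] morphology rendered under `n_labs` staining
#' profiles. Lab 1 is a near-balanced baseline (canonical stains, unit
#' scales, even staining, no tint) so reference selection is meaningful;
#' the remaining labs draw jittered stain vectors, log-normal
#' over-/under-staining scales, smooth unevenness fields and small
#' background tints. Fully deterministic under `seed`.
#'
#' @param n_labs Number of virtual laboratories (at least 2; the emulated
#'   study had 66).
#' @param size Image side in pixels (default 512).
#' @param spread Stain-vector jitter magnitude; the main inter-lab colour
#'   variation knob (default 0.2).
#' @param scale_sigma Log-normal sigma of the staining intensity scales
#'   (default 0.25); 0 disables intensity variation.
#' @param unevenness Half-width `u` of the smooth multiplicative staining
#'   field, bounded in `[1 - u, 1 + u]` (default 0.15); 0 disables it.
#' @param tint_max Maximum per-channel background OD tint (default 0.01);
#'   0 disables tinting.
#' @param nucleus_count Nuclei in the shared tissue (default scales with
#'   area, 60 at 512 x 512... see [make_tissue()]).
#' @param seed Integer seed.
#' @return A `synthetic_panel`: list with `tissue`, `labs` (list of
#'   `lab_profile`s), `images` (named list of RGB arrays), and `truth`
#'   (tibble of per-lab stain vectors and scales).
#' @export
#' @examples
#' p <- synthetic_panel(n_labs = 3, size = 64, seed = 1)
#' names(p$images)
synthetic_panel <- function(n_labs = 20, size = 512, spread = 0.2,
                            scale_sigma = 0.25, unevenness = 0.15,
                            tint_max = 0.01, nucleus_count = NULL,
                            seed = 17) {
  if (n_labs < 2) {
    rlang::abort("A panel needs at least 2 laboratories.",
      class = "stainbench_error_invalid_argument"
    )
  }
  # Nucleus density chosen so nuclei cover roughly a fifth of the section,
  # as in cellular H&E tissue; mean nucleus area is ~95 px.
  nucleus_count <- nucleus_count %||% max(8L, round(size^2 / 500))
  tissue <- make_tissue(size, size, nucleus_count, seed = seed)
  base <- unclass(canonical_stains())
  labs <- withr::with_seed(seed + 1L, {
    purrr::map(seq_len(n_labs), function(i) {
      if (i == 1L) {
        return(lab_profile(seed = seed + 1L))
      }
      w <- stain_matrix(cbind(
        jitter_stain(base[, 1], spread),
        jitter_stain(base[, 2], spread)
      ))
      uneven <- if (unevenness > 0) {
        smooth_field(size, size, 1 - unevenness, 1 + unevenness)
      } else {
        NULL
      }
      lab_profile(
        stains = w,
        h_scale = stats::rlnorm(1, 0, scale_sigma),
        e_scale = stats::rlnorm(1, 0, scale_sigma),
        unevenness = uneven,
        background_tint = stats::runif(3, 0, tint_max),
        seed = seed + 1L
      )
    })
  })
  images <- purrr::map(labs, function(lab) render_slide(tissue, lab))
  names(images) <- sprintf("lab_%02d", seq_len(n_labs))
  truth <- purrr::imap_dfr(labs, function(lab, i) {
    w <- unclass(lab$stains)
    tibble::tibble(
      sample_id = sprintf("lab_%02d", i),
      h_scale = lab$h_scale, e_scale = lab$e_scale,
      h_r = w[1, 1], h_g = w[2, 1], h_b = w[3, 1],
      e_r = w[1, 2], e_g = w[2, 2], e_b = w[3, 2]
    )
  })
  structure(
    list(
      tissue = tissue, labs = labs, images = images, truth = truth,
      params = list(
        n_labs = n_labs, size = size, spread = spread,
        scale_sigma = scale_sigma, unevenness = unevenness,
        tint_max = tint_max, seed = seed
      )
    ),
    class = "synthetic_panel"
  )
}

#' @export
print.synthetic_panel <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<synthetic_panel> %d labs, %d x %d px, spread %.2g, seed %d\n",
    p$n_labs, p$size, p$size, p$spread, p$seed
  ))
  invisible(x)
}

#' Write a synthetic panel to disk
#'
#' Writes one PNG per laboratory plus a `truth.json` with the ground-truth
#' stain matrices, scales and generator parameters.
#'
#' @param panel A `synthetic_panel`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(panel$images, function(img, id) {
    write_image(img, file.path(dir, paste0(id, ".png")))
  })
  jsonlite::write_json(
    list(truth = panel$truth, params = panel$params),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
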