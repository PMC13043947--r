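# Stain-matrix estimation and deconvolution in optical-density space.
#
# A stain matrix is a 3 x 2 matrix of unit-norm, nonnegative OD direction
# vectors; column 1 is hematoxylin, column 2 eosin. Hematoxylin transmits
# blue and absorbs red, so its OD vector has a larger red than blue
# component; eosin is the opposite. Columns are ordered by decreasing
# (red - blue) OD difference.

#' Construct and validate a stain matrix
#'
#' @param w Numeric 3 x 2 matrix; columns are hematoxylin and eosin OD
#'   direction vectors. Columns are clamped to nonnegative, normalized to
#'   unit Euclidean norm, and ordered hematoxylin-first (the column with the
#'   larger red-minus-blue OD component).
#' @return A `stain_matrix` (3 x 2 matrix with rows R, G, B and columns
#'   `hematoxylin`, `eosin`).
#' @export
#' @examples
#' stain_matrix(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)))
stain_matrix <- function(w) {
  if (!is.matrix(w) || !all(dim(w) == c(3L, 2L)) || anyNA(w)) {
    rlang::abort("`w` must be a numeric 3 x 2 matrix.",
      class = "stainbench_error_invalid_argument"
    )
  }
  w <- apply(w, 2, function(v) {
    v <- pmax(v, 0)
    n <- sqrt(sum(v^2))
    if (n < 1e-8) {
      rlang::abort("Stain vector has (near-)zero norm.",
        class = "stainbench_error_degenerate_stain"
      )
    }
    v / n
  })
  w <- w[, order(w[1, ] - w[3, ], decreasing = TRUE), drop = FALSE]
  dimnames(w) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  structure(w, class = c("stain_matrix", "matrix"))
}

#' Angle in degrees between two stain vectors
#'
#' @param a,b Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
stain_angle <- function(a, b) {
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(clamp(cosang, -1, 1)) * 180 / pi
}

# Tissue-pixel OD matrix: n x 3 rows for pixels where at least one channel
# reaches od_threshold (blank/background pixels carry no stain signal).
tissue_od <- function(img, od_threshold, i0 = 255) {
  od <- flatten_rgb(rgb_to_od(img, i0)$od)
  od[rowSums(od >= od_threshold) > 0, , drop = FALSE]
}

# Deterministic thinning of the pixel set used by the fitters: an even
# stride over the flattened pixel order, so results are reproducible
# without touching the RNG.
stride_sample <- function(x, max_rows) {
  n <- nrow(x)
  if (n <= max_rows) {
    return(x)
  }
  x[unique(round(seq(1, n, length.out = max_rows))), , drop = FALSE]
}

#' Estimate the stain matrix by the Macenko SVD procedure
#'
#' Projects tissue-pixel optical densities onto the plane of the top two
#' right singular vectors and takes the stain vectors at the extreme
#' percentiles of the projected angle distribution.
#'
#' @param img `H x W x 3` RGB array.
#' @param od_threshold Pixels whose OD is below this on every channel are
#'   treated as background and discarded (default 0.15).
#' @param angle_percentile Percentile of the projected angle used for the
#'   extreme stain directions (default 1; the other extreme is
#'   `100 - angle_percentile`).
#' @param i0 Incident intensity (default 255).
#' @param max_pixels Cap on the number of tissue pixels entering the SVD,
#'   thinned by an even deterministic stride (default 200000).
#' @return A [stain_matrix()].
#' @export
macenko_fit <- function(img, od_threshold = 0.15, angle_percentile = 1,
                        i0 = 255, max_pixels = 2e5) {
  assert_rgb(img)
  x <- stride_sample(tissue_od(img, od_threshold, i0), max_pixels)
  if (nrow(x) < 100) {
    rlang::abort(
      sprintf("Only %d tissue pixels above OD %.3g; need >= 100.", nrow(x), od_threshold),
      class = "stainbench_error_insufficient_tissue"
    )
  }
  sv <- svd(x, nu = 0)
  if (sv$d[2] < 1e-4 * sv$d[1]) {
    rlang::abort(
      "Optical-density cloud is rank deficient (single stain?).",
      class = "stainbench_error_degenerate_stain"
    )
  }
  v <- sv$v[, 1:2]
  proj <- x %*% v
  # Orient the first plane axis into the data so angles are well defined.
  if (sum(proj[, 1]) < 0) {
    v[, 1] <- -v[, 1]
    proj[, 1] <- -proj[, 1]
  }
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(angle_percentile, 100 - angle_percentile) / 100,
    names = FALSE
  )
  vecs <- vapply(q, function(a) {
    u <- v %*% c(cos(a), sin(a))
    if (sum(u) < 0) u <- -u
    u[, 1]
  }, numeric(3))
  # H&E stain pairs are >= 15 degrees apart; an angle spread collapsed to a
  # few degrees means the OD cloud is effectively one stain plus noise.
  if (stain_angle(vecs[, 1], vecs[, 2]) < 3) {
    rlang::abort(
      "Extreme angle directions nearly coincide; stains are not separable.",
      class = "stainbench_error_degenerate_stain"
    )
  }
  stain_matrix(vecs)
}

#' Per-pixel stain concentrations by least squares
#'
#' Solves `od = W %*% c` per pixel in the least-squares sense and clamps
#' negative concentrations to zero.
#'
#' @param od An `od_image` (from [rgb_to_od()]) or a bare `H x W x 3` OD
#'   array.
#' @param stains A [stain_matrix()].
#' @return `H x W x 2` array of nonnegative stain amounts
#'   (hematoxylin, eosin).
#' @export
stain_concentrations <- function(od, stains) {
  if (inherits(od, "od_image")) od <- od$od
  w <- unclass(stains)
  g <- crossprod(w)
  if (abs(det(g)) < 1e-10) {
    rlang::abort("Stain matrix is singular; stains are collinear.",
      class = "stainbench_error_degenerate_stain"
    )
  }
  d <- dim(od)
  odm <- matrix(od, nrow = d[1] * d[2], ncol = 3L)
  conc <- odm %*% w %*% solve(g) # normal equations, row-wise
  conc <- pmax(conc, 0)
  array(conc, dim = c(d[1], d[2], 2L))
}

# Exact solver for n independent 2-variable nonnegative quadratic programs
#   min_h 0.5 h' G h - rhs' h   s.t. h >= 0
# (G a common 2x2 positive-definite Gram matrix, rhs a 2 x n matrix), by
# closed-form active-set enumeration: interior solution, each single-active
# face, and the origin. Vectorized over columns.
nnls2 <- function(g, rhs) {
  det_g <- g[1, 1] * g[2, 2] - g[1, 2]^2
  if (det_g < 1e-12 * max(g[1, 1] * g[2, 2], 1e-12)) {
    g <- g + diag(1e-8 * max(diag(g), 1e-8), 2)
    det_g <- g[1, 1] * g[2, 2] - g[1, 2]^2
  }
  r1 <- rhs[1, ]
  r2 <- rhs[2, ]
  # interior: G h = rhs; objective there is -0.5 rhs' h
  h1_i <- (g[2, 2] * r1 - g[1, 2] * r2) / det_g
  h2_i <- (g[1, 1] * r2 - g[1, 2] * r1) / det_g
  f_i <- ifelse(h1_i >= 0 & h2_i >= 0, -0.5 * (r1 * h1_i + r2 * h2_i), Inf)
  # faces h2 = 0 and h1 = 0
  h1_b <- pmax(r1, 0) / g[1, 1]
  f_b <- -0.5 * g[1, 1] * h1_b^2 # equals -0.5 r1^2/g11 when r1 > 0, else 0
  h2_c <- pmax(r2, 0) / g[2, 2]
  f_c <- -0.5 * g[2, 2] * h2_c^2
  pick_b <- f_b <= f_c
  h1 <- ifelse(pick_b, h1_b, 0)
  h2 <- ifelse(pick_b, 0, h2_c)
  use_i <- f_i <= pmin(f_b, f_c)
  rbind(
    ifelse(use_i, h1_i, h1),
    ifelse(use_i, h2_i, h2)
  )
}

#' Estimate stains and concentrations by sparse non-negative factorization
#'
#' Solves `min 0.5 * ||V - W H||_F^2 + sparsity * ||H||_1` subject to
#' `W >= 0` with unit-ball stain columns (`||w_j|| <= 1`, active at any
#' optimum) and `H >= 0`, over the tissue-pixel OD matrix `V` (3 x n) --
#' the sparse dictionary-learning form of stain separation. Optimization
#' is by exact alternating minimization: with two stains the per-pixel
#' concentration update is a 2-variable L1-shrunk nonnegative quadratic
#' program with a closed-form active-set solution, and each stain-column
#' update is a rank-1 least-squares fit followed by Euclidean projection
#' onto the nonnegative orthant intersected with the unit ball. Every step
#' solves its subproblem exactly, so the objective is non-increasing by
#' construction. `W` is initialized from the Macenko fit, making the
#' procedure fully deterministic.
#'
#' @inheritParams macenko_fit
#' @param sparsity L1 penalty weight on the concentration rows
#'   (default 0.1).
#' @param n_iter Number of alternating sweeps (default 50; exact block
#'   solves converge in far fewer sweeps than multiplicative updates).
#' @param max_pixels Cap on tissue pixels entering the factorization,
#'   thinned deterministically (default 50000).
#' @return List with `stains` (a [stain_matrix()]), `concentrations`
#'   (2 x n matrix for the fitted tissue pixels, after normalization), and
#'   `objective` (the per-sweep objective values).
#' @export
vahadane_fit <- function(img, sparsity = 0.1, n_iter = 50,
                         od_threshold = 0.15, i0 = 255, max_pixels = 5e4) {
  assert_rgb(img)
  x <- stride_sample(tissue_od(img, od_threshold, i0), max_pixels)
  if (nrow(x) < 100) {
    rlang::abort(
      sprintf("Only %d tissue pixels above OD %.3g; need >= 100.", nrow(x), od_threshold),
      class = "stainbench_error_insufficient_tissue"
    )
  }
  v <- t(x) # 3 x n
  w <- unclass(macenko_fit(img,
    od_threshold = od_threshold, i0 = i0,
    max_pixels = max_pixels
  ))
  h <- matrix(0, 2L, ncol(v))
  objective <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    h <- nnls2(crossprod(w), crossprod(w, v) - sparsity)
    for (j in 1:2) {
      hj <- h[j, ]
      nh <- sum(hj^2)
      if (nh < 1e-12) next # unused stain: keep its current direction
      u <- (v %*% hj - w[, 3 - j, drop = FALSE] %*% (h[3 - j, , drop = FALSE] %*% hj)) / nh
      u <- pmax(u[, 1], 0)
      nu <- sqrt(sum(u^2))
      if (nu > 1) u <- u / nu
      if (nu > 1e-10) w[, j] <- u
    }
    r <- v - w %*% h
    objective[it] <- 0.5 * sum(r^2) + sparsity * sum(h)
  }
  # Columns sit on the unit sphere at any optimum; tidy residual slack.
  scale <- sqrt(colSums(w^2))
  w <- sweep(w, 2, scale, "/")
  h <- sweep(h, 1, scale, "*")
  ord <- order(w[1, ] - w[3, ], decreasing = TRUE)
  list(
    stains = stain_matrix(w[, ord, drop = FALSE]),
    concentrations = h[ord, , drop = FALSE],
    objective = objective
  )
}
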