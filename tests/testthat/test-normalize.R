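test_that("histogram matching reproduces the reference distribution", {
  p <- small_panel()
  ref <- p$images[[1]]
  # identity: matching an image to itself is the identity mapping
  expect_equal(histogram_match(ref, ref)$image, ref)

  # constant source channel collapses to a single quantile
  src <- random_image(5, 32, 32)
  src[, , 2] <- 100
  out <- histogram_match(src, ref)$image
  expect_length(unique(as.vector(out[, , 2])), 1L)

  # two-valued source matched to two-valued reference: hand-derived mapping
  s <- array(rep(c(0, 255), each = 32), dim = c(8, 8, 3))
  r <- array(rep(c(10, 200), each = 32), dim = c(8, 8, 3))
  expect_setequal(unique(as.vector(histogram_match(s, r)$image)), c(10, 200))

  # degenerate reference names the constant channel
  bad <- random_image(6, 16, 16)
  bad[, , 2] <- 42
  expect_error(histogram_match(src, bad),
    class = "stainbench_error_degenerate_reference", regexp = "G"
  )
})

test_that("histogram matching tracks the reference CDF at quantization scale", {
  # continuous-tone pairs: every level carries ~1/256 mass, so the empirical
  # CDFs must agree to ~2/256 after the 256-level quantile mapping
  for (s in 1:3) {
    src <- random_image(100 + s, 96, 96)
    ref <- random_image(200 + s, 96, 96)
    out <- histogram_match(src, ref)$image
    expect_lt(max(ks_per_channel(out, ref)), 2 / 256)
  }
})

test_that("reinhard matches reference channel moments exactly pre-clamp", {
  p <- small_panel()
  ref <- p$images[[1]]
  lr <- rgb_to_lab(ref)
  ref_mean <- vapply(lr[c("l", "alpha", "beta")], mean, numeric(1))
  ref_sd <- vapply(lr[c("l", "alpha", "beta")], function(x) sd(as.vector(x)), numeric(1))
  for (i in 2:4) {
    res <- reinhard(p$images[[i]], ref)
    expect_equal(unname(res$diagnostics$preclamp_mean), unname(ref_mean),
      tolerance = 1e-9
    )
    expect_equal(unname(res$diagnostics$preclamp_sd), unname(ref_sd),
      tolerance = 1e-9
    )
  }
  # self-normalization is the identity up to rounding
  expect_lte(max(abs(reinhard(ref, ref)$image - ref)), 1)
})

test_that("reinhard undoes a pure luminance shift", {
  ref <- small_panel()$images[[2]]
  lab <- rgb_to_lab(ref)
  shifted <- lab_to_rgb(list(
    l = lab$l - 0.05, alpha = lab$alpha, beta = lab$beta
  ))
  out <- reinhard(shifted, ref)$image
  # affine moment matching inverts the shift; residual is quantization only
  expect_lte(quantile(abs(out - ref), 0.99), 2)
})

test_that("reinhard rejects constant channels unless the fallback is on", {
  flat <- flat_image(c(100, 100, 100), 16, 16)
  ref <- small_panel()$images[[1]]
  expect_error(reinhard(flat, ref), class = "stainbench_error_degenerate_source")
  expect_silent(res <- reinhard(flat, ref, zero_std_fallback = TRUE))
  expect_equal(dim(res$image), dim(flat))
})

test_that("macenko fit recovers ground-truth stain vectors on clean slides", {
  p <- clean_panel()
  for (i in 2:4) {
    w <- macenko_fit(p$images[[i]])
    expect_lt(max_stain_angle(w, p$labs[[i]]$stains), 5)
    expect_equal(unname(sqrt(colSums(unclass(w)^2))), c(1, 1), tolerance = 1e-9)
    expect_true(all(unclass(w) >= 0))
  }
})

test_that("macenko fit is order-invariant and rejects degenerate input", {
  img <- clean_panel()$images[[2]]
  d <- dim(img)
  perm <- withr::with_seed(9, sample(d[1] * d[2]))
  shuffled <- array(matrix(img, ncol = 3)[perm, ], dim = d)
  expect_equal(
    unclass(macenko_fit(img, max_pixels = Inf)),
    unclass(macenko_fit(shuffled, max_pixels = Inf)),
    tolerance = 1e-9
  )
  expect_error(macenko_fit(flat_image(c(255, 255, 255), 64, 64)),
    class = "stainbench_error_insufficient_tissue"
  )
  # single-stain image: rank-deficient OD cloud
  single <- od_to_rgb(array(
    outer(withr::with_seed(4, runif(64 * 64, 0.2, 1.2)), c(0.65, 0.70, 0.29)),
    dim = c(64, 64, 3)
  ))
  expect_error(macenko_fit(single), class = "stainbench_error_degenerate_stain")
})

test_that("stain concentrations solve the linear model", {
  w <- stain_matrix(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)))
  conc <- array(runif(2 * 12 * 12, 0, 1.5), dim = c(12, 12, 2))
  od <- array(matrix(conc, ncol = 2) %*% t(unclass(w)), dim = c(12, 12, 3))
  expect_equal(stain_concentrations(od, w), conc, tolerance = 1e-6)
  expect_equal(
    stain_concentrations(array(0, dim = c(4, 4, 3)), w),
    array(0, dim = c(4, 4, 2))
  )

  # off-plane component: least squares leaves exactly the orthogonal residual
  wm <- unclass(w)
  normal <- c(
    wm[2, 1] * wm[3, 2] - wm[3, 1] * wm[2, 2],
    wm[3, 1] * wm[1, 2] - wm[1, 1] * wm[3, 2],
    wm[1, 1] * wm[2, 2] - wm[2, 1] * wm[1, 2]
  )
  normal <- normal / sqrt(sum(normal^2))
  v <- as.vector(wm %*% c(0.4, 0.7)) + 0.1 * normal
  od1 <- array(v, dim = c(1, 1, 3))
  c1 <- stain_concentrations(od1, w)
  # independent oracle: explicit normal-equations solve
  oracle <- solve(crossprod(wm), crossprod(wm, v))
  expect_equal(as.vector(c1), as.vector(oracle), tolerance = 1e-9)
  resid <- v - as.vector(wm %*% as.vector(c1))
  expect_equal(sqrt(sum(resid^2)), 0.1, tolerance = 1e-9)
})

test_that("macenko normalization transfers the reference stain basis", {
  p <- clean_panel()
  ref <- p$images[[1]]
  src <- p$images[[3]]
  res <- macenko_normalize(src, ref)
  expect_equal(dim(res$image), dim(src))
  # re-fitting the output recovers the reference's stain matrix
  w_out <- macenko_fit(res$image)
  expect_lt(max_stain_angle(w_out, res$diagnostics$reference_stains), 5)
  # self-normalization is near-identity
  self <- macenko_normalize(ref, ref)
  expect_lte(quantile(abs(self$image - ref), 0.99), 3)
})

test_that("macenko output is invariant to global concentration scale", {
  p <- clean_panel()
  t2 <- p$tissue
  t2$h_density <- 1.5 * t2$h_density
  t2$e_density <- 1.5 * t2$e_density
  img1 <- p$images[[3]]
  img2 <- render_slide(t2, p$labs[[3]])
  ref <- p$images[[1]]
  out1 <- macenko_normalize(img1, ref)$image
  out2 <- macenko_normalize(img2, ref)$image
  # percentile rescaling cancels the global factor; residual is quantization
  expect_lte(median(abs(out1 - out2)), 2)
})

test_that("vahadane fit recovers stains with a monotone objective", {
  p <- clean_panel()
  for (i in 2:4) {
    fit <- vahadane_fit(p$images[[i]])
    expect_lt(max_stain_angle(fit$stains, p$labs[[i]]$stains), 10)
    expect_true(all(diff(fit$objective) <= 1e-8 * max(fit$objective[1], 1)))
    w <- unclass(fit$stains)
    expect_equal(unname(sqrt(colSums(w^2))), c(1, 1), tolerance = 1e-9)
    expect_true(all(w >= 0))
    expect_true(all(fit$concentrations >= 0))
  }
  expect_error(vahadane_fit(flat_image(c(250, 250, 250), 64, 64)),
    class = "stainbench_error_insufficient_tissue"
  )
})

test_that("vahadane normalization is stable and keeps background white", {
  p <- clean_panel()
  ref <- p$images[[1]]
  self <- vahadane_normalize(ref, ref)
  w_out <- vahadane_fit(self$image)$stains
  expect_lt(max_stain_angle(w_out, self$diagnostics$reference_stains), 5)

  src <- p$images[[4]]
  out <- vahadane_normalize(src, ref)$image
  # ground-truth unstained pixels must stay white (no pink background)
  bg <- p$tissue$h_density == 0 & p$tissue$e_density == 0
  bg_err <- apply(abs(out - 255), c(1, 2), max)[bg]
  expect_lte(max(bg_err), 3)

  # global concentration rescale cancels
  t2 <- p$tissue
  t2$h_density <- 1.5 * t2$h_density
  t2$e_density <- 1.5 * t2$e_density
  out2 <- vahadane_normalize(render_slide(t2, p$labs[[4]]), ref)$image
  expect_lte(median(abs(out - out2)), 2)
})

test_that("all methods are deterministic and size-preserving", {
  p <- small_panel()
  src <- p$images[[2]]
  ref <- p$images[[1]]
  for (m in c("histmatch", "reinhard", "macenko", "vahadane")) {
    a <- normalize_stains(src, ref, m)
    b <- normalize_stains(src, ref, m)
    expect_identical(a$image, b$image)
    expect_equal(dim(a$image), dim(src))
  }
  expect_error(normalize_stains(src, ref, "nope"),
    class = "stainbench_error_invalid_argument"
  )
})

test_that("normalization results have tidy and glance methods", {
  p <- small_panel()
  res <- reinhard(p$images[[2]], p$images[[1]])
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("quantity", "channel", "value"))
  expect_true("preclamp_mean" %in% td$quantity)
  gl <- glance(res)
  expect_equal(gl$method, "reinhard")
})
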