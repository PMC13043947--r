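test_that("histogram intersection follows the min-sum definition", {
  a <- hist_set(c(0.5, 0.5))
  b <- hist_set(c(0.25, 0.75))
  expect_equal(hist_intersection(a, a), 1)
  expect_equal(hist_intersection(a, b), 0.75) # sum(min) by hand
  disjoint <- hist_set(c(1, 0, 0, 0))
  other <- hist_set(c(0, 0, 0.5, 0.5))
  expect_equal(hist_intersection(disjoint, other), 0)
  expect_error(hist_intersection(a, hist_set(c(1, 0, 0))),
    class = "stainbench_error_invalid_argument"
  )
})

test_that("histogram PCC handles degenerate and anti-symmetric cases", {
  a <- hist_set(c(0.9, 0.1, 0, 0))
  expect_equal(hist_pcc(a, a), 1)
  # two-bin anti-symmetric pair correlates exactly -1
  expect_equal(hist_pcc(hist_set(c(0.9, 0.1)), hist_set(c(0.1, 0.9))), -1)
  uni <- hist_set(rep(0.25, 4))
  expect_error(hist_pcc(uni, uni),
    class = "stainbench_error_undefined_correlation"
  )
})

test_that("histogram euclidean distance is a metric", {
  a <- hist_set(c(1, 0))
  b <- hist_set(c(0, 1))
  expect_equal(hist_euclidean(a, a), 0)
  expect_equal(hist_euclidean(a, b), sqrt(2))
  # triangle inequality on random triples
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- hist_set(prop.table(runif(8)))
      q <- hist_set(prop.table(runif(8)))
      r <- hist_set(prop.table(runif(8)))
      expect_lte(
        hist_euclidean(p, r),
        hist_euclidean(p, q) + hist_euclidean(q, r) + 1e-12
      )
    }
  })
})

test_that("JS divergence is bounded, symmetric, and base-2", {
  a <- hist_set(c(0.3, 0.7, 0, 0))
  b <- hist_set(c(0, 0, 0.6, 0.4))
  expect_equal(js_divergence(a, a), 0)
  expect_equal(js_divergence(a, b), 1) # disjoint supports, base-2 maximum
  withr::with_seed(32, {
    for (i in 1:10) {
      p <- hist_set(prop.table(runif(8)))
      q <- hist_set(prop.table(runif(8)))
      expect_equal(js_divergence(p, q), js_divergence(q, p))
      expect_gte(js_divergence(p, q), 0)
      expect_lte(js_divergence(p, q), 1)
    }
  })
})

test_that("ssim matches the constant-image closed form and is symmetric", {
  x <- random_image(41, 48, 48)
  expect_equal(ssim(x, x), 1)
  y <- random_image(42, 48, 48)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_lte(ssim(x, y), 1)
  # constant images: variances vanish, closed form (2ab+C1)/(a^2+b^2+C1)
  a <- 100
  b <- 120
  c1 <- (0.01 * 255)^2
  expect_equal(
    ssim(flat_image(c(a, a, a), 32, 32), flat_image(c(b, b, b), 32, 32)),
    (2 * a * b + c1) / (a^2 + b^2 + c1),
    tolerance = 1e-9
  )
  expect_error(ssim(x, random_image(1, 32, 32)),
    class = "stainbench_error_invalid_argument"
  )
})

test_that("feature extraction is deterministic with one row per tile", {
  img <- small_panel()$images[[2]]
  fc <- extract_features(img, tile = 64)
  expect_equal(nrow(fc$vectors), 4) # 128^2 image, 64 px tiles
  expect_identical(fc$vectors, extract_features(img, tile = 64)$vectors)
  expect_identical(
    extract_features(img, tile = 64)$vectors,
    extract_features(img, tile = 64, seed = 423)$vectors
  )
  # different extractor seeds give different, incomparable features
  fc2 <- extract_features(img, tile = 64, seed = 99)
  expect_false(identical(fc$vectors, fc2$vectors))
  expect_error(frechet_distance(fc, fc2),
    class = "stainbench_error_invalid_comparison"
  )
})

test_that("frechet distance matches the univariate Gaussian closed form", {
  a <- feature_cloud(matrix(withr::with_seed(51, rnorm(2000, 0, 1))), "g")
  b <- feature_cloud(matrix(withr::with_seed(52, rnorm(2000, 3, 1))), "g")
  expect_lt(frechet_distance(a, a), 1e-6)
  expect_equal(frechet_distance(a, b), frechet_distance(b, a))
  # closed form from the sample moments: (mu1-mu2)^2 + (sd1-sd2)^2
  m1 <- mean(a$vectors)
  m2 <- mean(b$vectors)
  s1 <- sd(a$vectors)
  s2 <- sd(b$vectors)
  expect_equal(frechet_distance(a, b), (m1 - m2)^2 + (s1 - s2)^2,
    tolerance = 0.02
  )
  expect_error(
    frechet_distance(feature_cloud(matrix(1, 1, 1), "g"), a),
    class = "stainbench_error_invalid_argument"
  )
})

test_that("frechet distance agrees with the diagonal-Gaussian closed form in 3-D", {
  mu1 <- c(0, 1, -1)
  mu2 <- c(2, 0, 1)
  s1 <- c(1, 0.5, 2)
  s2 <- c(0.8, 1.5, 1)
  x <- withr::with_seed(61, sweep(matrix(rnorm(6000), 2000) %*% diag(s1), 2, mu1, "+"))
  y <- withr::with_seed(62, sweep(matrix(rnorm(6000), 2000) %*% diag(s2), 2, mu2, "+"))
  got <- frechet_distance(feature_cloud(x, "g"), feature_cloud(y, "g"))
  # oracle from sample moments, diagonal-covariance closed form per axis
  expected <- sum((colMeans(x) - colMeans(y))^2) +
    sum(diag(cov(x))) + sum(diag(cov(y))) -
    2 * sum(sqrt(diag(cov(x)) * diag(cov(y))))
  # sample covariances have small off-diagonal terms the closed form ignores
  expect_equal(got, expected, tolerance = 0.02)
})

test_that("evaluate_sample composes the individual metrics", {
  p <- small_panel()
  ref <- p$images[[1]]
  rec <- evaluate_sample(ref, ref, ref, sample_id = "x", method = "id", tile = 64)
  expect_equal(rec$intersection, 1)
  expect_equal(rec$js, 0)
  expect_equal(rec$euclidean, 0)
  expect_equal(rec$ssim, 1)
  expect_lt(rec$fid, 1e-6)

  norm <- histogram_match(p$images[[2]], ref)$image
  rec2 <- evaluate_sample(p$images[[2]], norm, ref, tile = 64)
  ranges <- lab_ranges(list(p$images[[2]], norm, ref))
  hn <- lab_histograms(norm, 256, ranges)
  hr <- lab_histograms(ref, 256, ranges)
  expect_equal(rec2$intersection, hist_intersection(hn, hr))
  expect_equal(rec2$js, js_divergence(hn, hr))
  expect_equal(rec2$ssim, ssim(p$images[[2]], norm))
  # documented bounds
  expect_true(rec2$intersection >= 0 && rec2$intersection <= 1)
  expect_true(rec2$js >= 0 && rec2$js <= 1)
  expect_true(rec2$pcc >= -1 && rec2$pcc <= 1)
  expect_gte(rec2$euclidean, 0)
  expect_gte(rec2$fid, 0)
})

test_that("growing colour shifts degrade histogram similarity monotonically", {
  base <- small_panel()$images[[2]]
  ranges <- list(l = c(0, 7.3), alpha = c(-1, 1), beta = c(-1, 1))
  h0 <- lab_histograms(base, 128, ranges)
  inter <- c()
  js <- c()
  for (shift in c(5, 10, 15, 20, 25)) {
    shifted <- pmin(pmax(base + shift, 0), 255)
    hs <- lab_histograms(shifted, 128, ranges)
    inter <- c(inter, hist_intersection(h0, hs))
    js <- c(js, js_divergence(h0, hs))
  }
  expect_true(all(diff(inter) < 0))
  expect_true(all(diff(js) > 0))
})
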