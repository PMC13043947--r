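test_that("rb_ratio is the quotient of channel means", {
  expect_equal(rb_ratio(flat_image(c(128, 128, 128))), 1)
  img <- flat_image(c(100, 50, 200))
  expect_equal(rb_ratio(img), 0.5)
  rnd <- random_image(21, 24, 24)
  expect_equal(rb_ratio(rnd), mean(rnd[, , 1]) / mean(rnd[, , 3])) # brute force
  expect_error(rb_ratio(flat_image(c(10, 10, 0))),
    class = "stainbench_error_degenerate_image"
  )
})

test_that("select_reference picks the ratio closest to one with first-index ties", {
  mk <- function(r, b) flat_image(c(r, 100, b))
  panel <- list(a = mk(80, 100), b = mk(95, 100), c = mk(130, 100))
  sel <- select_reference(panel)
  expect_equal(sel$index, 2)
  expect_equal(sel$ratios$sample_id, c("a", "b", "c"))
  expect_equal(sel$ratios$ratio, c(0.8, 0.95, 1.3))

  expect_equal(select_reference(list(mk(120, 100)))$index, 1)
  # tie |0.9 - 1| == |1.1 - 1| -> first sample
  expect_equal(select_reference(list(mk(90, 100), mk(110, 100)))$index, 1)
  expect_error(select_reference(list()), class = "stainbench_error_invalid_argument")
})

test_that("select_reference is permutation-equivariant", {
  panel <- purrr::map(1:6, function(i) random_image(400 + i, 24, 24))
  sel <- select_reference(panel)
  # brute-force oracle over all samples
  ratios <- vapply(panel, function(x) mean(x[, , 1]) / mean(x[, , 3]), numeric(1))
  expect_equal(sel$index, which.min(abs(ratios - 1)))
  perm <- c(4, 1, 6, 2, 5, 3)
  sel_p <- select_reference(panel[perm])
  expect_equal(perm[sel_p$index], sel$index)
})

test_that("histogram features are normalized per channel block", {
  img <- small_panel()$images[[2]]
  f <- histogram_features(img, bins = 32)
  expect_length(f, 96)
  expect_equal(sum(f[1:32]), 1, tolerance = 1e-9)
  expect_equal(sum(f[33:64]), 1, tolerance = 1e-9)
  expect_equal(sum(f[65:96]), 1, tolerance = 1e-9)
  expect_identical(f, histogram_features(img, bins = 32))
  # constant image: one occupied bin per channel
  fc <- histogram_features(flat_image(c(120, 60, 200)), bins = 32)
  expect_equal(sum(fc > 0), 3)
  expect_error(histogram_features(img, bins = 1),
    class = "stainbench_error_invalid_argument"
  )
})

test_that("panel features share global ranges and feed clustering", {
  p <- small_panel()
  ft <- panel_features(p$images, bins = 16)
  expect_equal(nrow(ft), 5)
  expect_true(all(vapply(ft$feature, length, integer(1)) == 48))
})

test_that("representatives are the members nearest their centroids", {
  # three well-separated blobs in feature space
  blob <- function(center, n, seed) {
    withr::with_seed(seed, {
      matrix(rep(center, each = n), n) + matrix(rnorm(n * 4, 0, 0.05), n)
    })
  }
  x <- rbind(
    blob(c(0, 0, 0, 0), 7, 1),
    blob(c(10, 0, 5, 0), 7, 2),
    blob(c(0, 10, 0, 5), 7, 3)
  )
  rownames(x) <- sprintf("s%02d", 1:21)
  rs <- select_representatives(x, k = 3, seed = 5)
  expect_equal(sort(unique(rs$assignments$cluster)), 1:3)
  # brute force: within every cluster, the representative minimizes the
  # distance to the cluster's PCA-coordinate centroid
  coords <- cbind(rs$assignments$pc1, rs$assignments$pc2)
  for (cl in 1:3) {
    members <- which(rs$assignments$cluster == cl)
    cen <- colMeans(coords[members, , drop = FALSE])
    d2 <- rowSums((coords[members, , drop = FALSE] -
      matrix(cen, length(members), 2, byrow = TRUE))^2)
    best <- rs$assignments$sample_id[members[which.min(d2)]]
    rep_id <- rs$representatives$sample_id[rs$representatives$cluster == cl]
    expect_equal(rep_id, best)
  }
})

test_that("representative selection is deterministic and handles n = k", {
  x <- matrix(withr::with_seed(8, rnorm(40)), 10, 4)
  rownames(x) <- sprintf("s%02d", 1:10)
  a <- select_representatives(x, k = 4, seed = 99)
  b <- select_representatives(x, k = 4, seed = 99)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$representatives, b$representatives)

  full <- select_representatives(x, k = 10, seed = 1)
  expect_setequal(full$representatives$sample_id, rownames(x))
  expect_error(select_representatives(x, k = 11),
    class = "stainbench_error_invalid_argument"
  )
})

test_that("the WCSS elbow curve is non-increasing in k", {
  p <- small_panel()
  rs <- select_representatives(panel_features(p$images, bins = 16), k = 3, seed = 7)
  expect_true(all(diff(rs$wcss$wcss) <= 1e-9))
  td <- tidy(rs)
  expect_true(all(td$sample_id[td$representative] %in% rs$representatives$sample_id))
  expect_s3_class(autoplot(rs), "ggplot")
})
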