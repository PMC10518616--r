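test_that("gray histogram matches the per-pixel binning oracle", {
  expect_equal(gray_histogram(matrix(0, 4, 4))$counts,
               c(16, rep(0, 255)))
  set.seed(10)
  x <- matrix(runif(256), 16, 16)
  h <- gray_histogram(x)
  expect_equal(h$total, 256)
  expect_equal(sum(h$counts), 256)
  expect_equal(h$counts, naive_histogram(x, 256))
})

test_that("between-class variance: perfect two-point separation and the
           variance decomposition", {
  counts <- numeric(256); counts[1] <- 100; counts[256] <- 100
  h <- gray_histogram_from_counts(counts)
  total_var <- 127.5^2
  expect_equal(between_class_variance(h, 128), total_var)
  expect_equal(within_class_variance(h, 128), 0)

  set.seed(11)
  for (i in 1:25) {
    cnt <- rpois(256, 5) + rbinom(256, 1, 0.05) * rpois(256, 200)
    if (sum(cnt) == 0) cnt[7] <- 3
    h <- gray_histogram_from_counts(cnt)
    k <- sample(1:4, 1)
    tv <- sort(sample(1:255, k))
    st_total <- {
      p <- cnt / sum(cnt); lev <- 0:255; mu <- sum(p * lev)
      sum(p * (lev - mu)^2)
    }
    b <- between_class_variance(h, tv)
    w <- within_class_variance(h, tv)
    expect_lt(abs(b + w - st_total), 1e-9)
    expect_gte(b, 0)
    expect_lte(b, st_total + 1e-9)
  }
})

test_that("threshold vector validation rejects malformed inputs", {
  h <- gray_histogram_from_counts(rep(1, 256))
  expect_error(between_class_variance(h, c(10, 10)), "strictly increasing")
  expect_error(between_class_variance(h, 0), "\\[1, L-1\\]")
  expect_error(between_class_variance(h, 256), "\\[1, L-1\\]")
})

test_that("exhaustive Otsu: tie rule, tri-modal placement, and the
           independent single-threshold scan", {
  counts <- numeric(256); counts[1] <- 100; counts[256] <- 100
  h <- gray_histogram_from_counts(counts)
  expect_equal(exhaustive_otsu(h, 1)$thresholds, 1L)  # smallest tied t

  # tri-modal: thresholds fall strictly between adjacent modes
  set.seed(12)
  lev <- 0:255
  cnt <- round(400 * exp(-(lev - 40)^2 / 50) +
                 500 * exp(-(lev - 120)^2 / 80) +
                 300 * exp(-(lev - 220)^2 / 60))
  h3 <- gray_histogram_from_counts(cnt)
  tv <- exhaustive_otsu(h3, 2)$thresholds
  expect_gt(tv[1], 40); expect_lt(tv[1], 120)
  expect_gt(tv[2], 120); expect_lt(tv[2], 220)

  for (i in 1:5) {
    cnt <- rpois(256, runif(1, 1, 20))
    if (sum(cnt) == 0) cnt[100] <- 5
    h <- gray_histogram_from_counts(cnt)
    ours <- exhaustive_otsu(h, 1)
    ref <- naive_otsu1(cnt)
    expect_equal(ours$thresholds, ref$t)
    expect_equal(ours$fitness, ref$f, tolerance = 1e-10)
  }

  expect_error(exhaustive_otsu(h3, 5), "refused")
  # small-L exhaustive works for any k
  h16 <- gray_histogram_from_counts(rpois(16, 10) + 1)
  r <- exhaustive_otsu(h16, 4)
  expect_length(r$thresholds, 4)
})

test_that("Levy steps are reproducible, heavy-tailed, and validated", {
  s1 <- withr::with_seed(33, levy_step(5, 2))
  s2 <- withr::with_seed(33, levy_step(5, 2))
  expect_identical(s1, s2)
  expect_length(levy_step(3, 2.5), 3)
  expect_error(levy_step(3, 1), "delta")
  expect_error(levy_step(3, 3.5), "delta")

  set.seed(34)
  steps <- abs(levy_step(1e5, 2))
  normal <- abs(rnorm(1e5))
  expect_gt(quantile(steps, 0.999), quantile(normal, 0.999))
})

test_that("cuckoo search keeps elitism and a non-decreasing best trace", {
  set.seed(13)
  cnt <- rpois(256, 10)
  h <- gray_histogram_from_counts(cnt)
  opt <- exhaustive_otsu(h, 2)
  res <- csa_optimize(h, csa_config(m = 10, N = 30, k = 2, seed = 5))
  expect_true(all(diff(res$trace$best_fitness) >= 0))
  expect_lte(res$fitness, opt$fitness + 1e-9)

  # same seed, same result
  res2 <- csa_optimize(h, csa_config(m = 10, N = 30, k = 2, seed = 5))
  expect_identical(res$thresholds, res2$thresholds)
  expect_identical(res$trace, res2$trace)
})

test_that("apply_thresholds follows the half-open upper-class rule and the
           per-pixel oracle", {
  img <- matrix(c(0.4, 0.6, 0.5, 0.1), 2, 2)
  lab <- apply_thresholds(img, 128)
  expect_equal(lab[1, 1], 0L)  # level 102
  expect_equal(lab[2, 1], 1L)  # level 153
  expect_equal(lab[1, 2], 1L)  # level 128, exactly at threshold -> upper
  expect_equal(lab[2, 2], 0L)

  set.seed(14)
  r <- matrix(runif(100), 10, 10)
  tv <- c(50L, 180L)
  lab <- apply_thresholds(r, tv)
  for (i in 1:10) for (j in 1:10) {
    lev <- min(floor(r[i, j] * 256), 255)
    expect_equal(lab[i, j], sum(lev >= tv))
  }
})

test_that("pixel-order permutation leaves histogram and mask volume alone", {
  set.seed(15)
  p <- make_phantom(phantom_spec(seed = 20))
  x <- p$image$pixels
  perm <- sample(length(x))
  xp <- matrix(as.vector(x)[perm], nrow(x), ncol(x))
  expect_equal(gray_histogram(x)$counts, gray_histogram(xp)$counts)
  tv <- exhaustive_otsu(gray_histogram(x), 2)$thresholds
  expect_equal(sum(apply_thresholds(x, tv) == 2),
               sum(apply_thresholds(xp, tv) == 2))
})

test_that("nodule mask extraction: exact recovery, min_area, salt removal", {
  p <- make_phantom(phantom_spec(noise_sigma = 0, seed = 6))
  h <- gray_histogram(p$image)
  tv <- exhaustive_otsu(h, 2)$thresholds
  mask <- nodule_mask_from_labels(apply_thresholds(p$image$pixels, tv))
  expect_identical(mask$pixels, p$mask$pixels)

  # min_area larger than every component empties the mask
  mask2 <- nodule_mask_from_labels(apply_thresholds(p$image$pixels, tv),
                                   min_area = 1e6)
  expect_equal(sum(mask2$pixels), 0)

  # single-pixel salt survives thresholding but not the area filter
  img <- p$image$pixels
  lung_px <- which(img == 0.10, arr.ind = TRUE)
  img[lung_px[1, 1], lung_px[1, 2]] <- 0.95
  mask3 <- nodule_mask_from_labels(apply_thresholds(img, tv), min_area = 4)
  expect_identical(mask3$pixels, p$mask$pixels)
})

test_that("8-connectivity labelling joins diagonal pixels", {
  m <- matrix(0L, 5, 5)
  m[1, 1] <- 1L; m[2, 2] <- 1L; m[3, 3] <- 1L  # diagonal chain, area 3
  mask <- nodule_mask_from_labels(m * 2L, min_area = 3)
  expect_equal(sum(mask$pixels), 3)
  mask4 <- nodule_mask_from_labels(m * 2L, min_area = 4)
  expect_equal(sum(mask4$pixels), 0)
})
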