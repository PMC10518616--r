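test_that("min-max normalization matches the elementwise definition", {
  x <- matrix(c(0, 128, 255, 64), 2, 2)
  out <- minmax_normalize(image_grid(x, "uint8"))
  expect_equal(sort(unique(as.vector(out$pixels))),
               c(0, 64 / 255, 128 / 255, 1))

  # idempotence on an already-normalized image with explicit params
  u <- image_grid(matrix(runif(16), 4, 4))
  out2 <- minmax_normalize(u, params = list(mu_min = 0, mu_max = 1))
  expect_equal(out2$pixels, u$pixels)

  # brute-force elementwise oracle on a random raster
  set.seed(4)
  r <- matrix(rnorm(16 * 16, 50, 20), 16, 16)
  expect_equal(minmax_normalize(r)$pixels, naive_minmax(r))

  expect_error(minmax_normalize(matrix(3, 4, 4)), "degenerate")
})

test_that("bilinear resize is identity-safe, range-bounded, and exact", {
  x <- matrix(runif(128 * 128), 128, 128)
  expect_equal(resize_to(x, 128, 128)$pixels, x)

  expect_equal(resize_to(matrix(0.3, 10, 10), 17, 13)$pixels,
               matrix(0.3, 17, 13))

  set.seed(5)
  r <- matrix(runif(20 * 20), 20, 20)
  out <- resize_to(r, 33, 9)$pixels
  expect_gte(min(out), min(r))
  expect_lte(max(out), max(r))

  # hand-evaluated bilinear interpolation of a 2x2 checkerboard onto 4x4:
  # source coords (pixel centres, clamped) are 0, 0.25, 0.75, 1, so the
  # interior weights are (0.75, 0.25) and (0.25, 0.75)
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- resize_to(cb, 4, 4)$pixels
  w <- c(0, 0.25, 0.75, 1)
  expected <- outer(seq_along(w), seq_along(w), function(i, j) {
    a <- w[i]; b <- w[j]
    (1 - a) * (1 - b) * cb[1, 1] + (1 - a) * b * cb[1, 2] +
      a * (1 - b) * cb[2, 1] + a * b * cb[2, 2]
  })
  expect_equal(up, expected)
})

test_that("edge filter has unit DC gain, kernel impulse response, and
           matches the brute-force correlation", {
  expect_equal(edge_filter(matrix(0.7, 6, 6))$pixels, matrix(0.7, 6, 6))

  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  resp <- edge_filter(imp)$pixels
  k <- edge_kernel()
  for (di in -1:1) for (dj in -1:1)
    expect_equal(resp[5 + di, 5 + dj], k[2 + di, 2 + dj])

  set.seed(6)
  r <- matrix(runif(64), 8, 8)
  expect_equal(edge_filter(r)$pixels, naive_correlate3(r, edge_kernel()))

  # kernel invariants
  expect_equal(sum(edge_kernel()), 1)
  expect_equal(edge_kernel(), edge_kernel()[3:1, 3:1])
})

test_that("edge filter is linear on interior pixels", {
  set.seed(7)
  a <- matrix(runif(100), 10, 10)
  b <- matrix(runif(100), 10, 10)
  lhs <- edge_filter(2 * a + 3 * b)$pixels
  rhs <- 2 * edge_filter(a)$pixels + 3 * edge_filter(b)$pixels
  expect_equal(lhs, rhs)
})

test_that("YUV conversion: gray maps to pure luma and round trips", {
  g <- array(0.42, c(6, 6, 3))
  yuv <- rgb_to_yuv(g)
  expect_equal(yuv$y, matrix(0.42, 6, 6))
  expect_equal(max(abs(yuv$u)), 0)
  expect_equal(max(abs(yuv$v)), 0)

  set.seed(8)
  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  back <- yuv_to_rgb(rgb_to_yuv(rgb))
  expect_lt(max(abs(back - rgb)), 1e-6)

  # 2x chroma downsampling on a smooth gradient stays within 0.02
  h <- 16; w <- 16
  grad <- array(0, c(h, w, 3))
  grad[, , 1] <- outer(seq_len(h), seq_len(w), function(i, j) i / (4 * h))
  grad[, , 2] <- outer(seq_len(h), seq_len(w), function(i, j) j / (4 * w))
  grad[, , 3] <- 0.5
  back2 <- yuv_to_rgb(rgb_to_yuv(grad, downsample_chroma = TRUE))
  expect_lt(max(abs(back2 - grad)), 0.02)

  expect_error(rgb_to_yuv(array(2, c(4, 4, 3))), "\\[0, 1\\]")
})

test_that("histogram equalization follows the CDF and preserves order", {
  # two-valued image under classical equalization: CDF(0.2) = 0.5,
  # CDF(0.8) = 1
  x <- matrix(c(rep(0.2, 8), rep(0.8, 8)), 4, 4)
  out <- equalize_hist(x, weight_clip = Inf)$pixels
  expect_equal(sort(unique(as.vector(out))), c(0.5, 1.0))

  expect_equal(equalize_hist(matrix(0.3, 5, 5))$pixels, matrix(0.3, 5, 5))

  set.seed(9)
  r <- matrix(runif(400), 20, 20)
  eq <- equalize_hist(r, weight_clip = 3)$pixels
  o <- order(as.vector(r))
  expect_true(all(diff(as.vector(eq)[o]) >= -1e-12))
})

test_that("preprocess pipeline respects stage toggles and the contract", {
  cfg_off <- default_config()
  cfg_off$preprocess[c("normalize", "resize", "equalize", "edge")] <-
    list(FALSE, FALSE, FALSE, FALSE)
  img <- make_phantom(phantom_spec(seed = 2))$image
  expect_equal(preprocess_pipeline(img, cfg_off)$pixels, img$pixels)

  out <- preprocess_pipeline(make_phantom(tiny_phantom_spec(0.02))$image)
  expect_equal(dim(out$pixels), c(128L, 128L))
  expect_gte(min(out$pixels), 0)
  expect_lte(max(out$pixels), 1)

  # HU input goes through windowing first
  hu <- image_grid(matrix(seq(-1200, 600, length.out = 64), 8, 8),
                   value_range = "hu")
  outh <- preprocess_pipeline(hu)
  expect_equal(dim(outh$pixels), c(128L, 128L))
})
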