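test_that("ELU matches its closed form, limits, and derivative identity", {
  expect_equal(elu(0), 0)
  expect_equal(elu(2.5), 2.5)
  expect_equal(elu(-50, beta = 1.7), -1.7, tolerance = 1e-12)
  expect_lt(abs(elu(1e-12) - elu(-1e-12)), 1e-10)  # continuity at 0

  set.seed(23)
  i <- -runif(50, 0.1, 5)
  beta <- 1.3
  expect_equal(elu_grad(i, beta), elu(i, beta) + beta, tolerance = 1e-12)
  eps <- 1e-6
  num <- (elu(i + eps, beta) - elu(i - eps, beta)) / (2 * eps)
  expect_equal(elu_grad(i, beta), num, tolerance = 1e-6)
  expect_error(elu(1, beta = 0), "beta")
})

test_that("max pooling records row-major argmax indices with first-wins
           ties", {
  w <- matrix(c(1, 3, 2, 4), 2, 2)  # rows: (1,2) / (3,4)
  r <- maxpool_with_indices(w)
  expect_equal(r$y[1, 1], 4)
  expect_equal(r$idx[1, 1], 3L)

  req <- maxpool_with_indices(matrix(0.6, 2, 2))
  expect_equal(req$idx[1, 1], 0L)

  set.seed(24)
  x <- matrix(runif(64), 8, 8)
  ours <- maxpool_with_indices(x)
  ref <- naive_maxpool(x)
  expect_equal(ours$y, ref$y)
  expect_equal(ours$idx, ref$idx)

  expect_error(maxpool_with_indices(matrix(0, 3, 4)), "even")
})

test_that("unpooling inverts pooling on its support and conserves sums", {
  set.seed(25)
  for (i in 1:10) {
    y <- matrix(runif(16, 0.1, 1), 4, 4)      # positive values
    idx <- matrix(sample(0:3, 16, TRUE), 4, 4)
    up <- unpool(y, idx)
    expect_equal(dim(up), c(8L, 8L))
    expect_equal(sum(up), sum(y))
    back <- maxpool_with_indices(up)
    expect_equal(back$y, y)
    expect_equal(back$idx, idx)
  }
  expect_equal(unpool(matrix(0, 2, 2), matrix(0L, 2, 2)),
               matrix(0, 4, 4))
  expect_error(unpool(matrix(1, 2, 2), matrix(7L, 2, 2)), "index")
})

test_that("softmax is normalized, shift-invariant, and overflow-safe", {
  z <- array(0, c(2, 2, 2, 1))
  p <- softmax_probs(z)
  expect_equal(p[1, 1, , 1], c(0.5, 0.5))

  z[,, 1, ] <- 1000; z[,, 2, ] <- 1000
  expect_equal(softmax_probs(z)[1, 1, , 1], c(0.5, 0.5))

  set.seed(26)
  z <- array(rnorm(2 * 2 * 3 * 2), c(2, 2, 3, 2))
  p <- softmax_probs(z)
  naive <- exp(z[1, 2, , 2]) / sum(exp(z[1, 2, , 2]))
  expect_equal(p[1, 2, , 2], naive, tolerance = 1e-12)
  expect_equal(apply(p, c(1, 2, 4), sum),
               array(1, c(2, 2, 2)), tolerance = 1e-12)
  expect_equal(softmax_probs(z + 5), p, tolerance = 1e-12)
})

test_that("the loss is zero for perfect prediction, ln 2 for uniform, and
           adds the exact weight penalty", {
  t <- array(0, c(2, 2, 2, 1)); t[, , 1, ] <- 1
  perfect <- t
  expect_equal(deepnet_loss(perfect, t), 0)

  uniform <- array(0.5, c(2, 2, 2, 1))
  expect_equal(deepnet_loss(uniform, t), log(2))

  set.seed(27)
  w <- list(array(rnorm(12), c(3, 1, 4)), array(rnorm(8), c(2, 4)))
  chi <- 0.3
  expect_equal(deepnet_loss(uniform, t, w, chi),
               log(2) + 0.5 * chi * (sum(w[[1]]^2) + sum(w[[2]]^2)))
  expect_equal(deepnet_loss(uniform, t, list(array(0, c(2, 2))), chi),
               log(2))

  bad <- array(0, c(2, 2, 2, 1)); bad[, , 2, ] <- 1
  expect_warning(l <- deepnet_loss(bad, t), "clamped")
  expect_true(is.finite(l))
})

test_that("network construction: shapes, seeding, and input validation", {
  cfg <- net_config("tiny", input_size = c(32L, 32L), seed = 3)
  net <- build_network(cfg)
  fw <- net_forward(net, matrix(runif(32 * 32), 32, 32), train = FALSE)
  expect_equal(dim(fw$probs), c(32L, 32L, 2L, 1L))
  expect_equal(apply(fw$probs, c(1, 2, 4), sum),
               array(1, c(32, 32, 1)), tolerance = 1e-12)

  net2 <- build_network(cfg)
  expect_identical(net$params, net2$params)

  expect_error(net_config("tiny", input_size = c(30L, 32L)), "divisible")
  expect_error(net_config("tiny", dropout_rho = 1), "dropout")
})

test_that("the VGG-19 preset mirrors 16 conv layers with 16 deconv layers
           and segments a 128x128 slice into two channels", {
  cfg <- net_config("vgg19", input_size = c(128L, 128L), seed = 1)
  net <- build_network(cfg)
  kinds <- vapply(net$ops, `[[`, character(1), "kind")
  convs <- which(kinds == "conv")
  n_pool <- sum(kinds == "pool")
  first_unpool <- which(kinds == "unpool")[1]
  expect_equal(n_pool, 5L)                       # five 2x2 pooling stages
  expect_equal(sum(kinds == "unpool"), 5L)
  expect_equal(sum(convs < first_unpool), 16L)   # encoder convs
  expect_equal(sum(convs > first_unpool &
                     vapply(net$ops[convs], `[[`, integer(1), "k") == 3L),
               16L)                              # decoder deconvs

  x <- as.matrix(make_phantom(phantom_spec(seed = 2))$image)
  fw <- net_forward(net, x, train = FALSE)
  expect_equal(dim(fw$probs), c(128L, 128L, 2L, 1L))
})

test_that("inference applies the argmax rule with background ties", {
  cfg <- net_config("tiny", input_size = c(16L, 16L), seed = 4)
  net <- build_network(cfg)
  head_i <- length(net$ops)
  # zero head -> logits 0 -> probs 0.5/0.5 -> tie -> empty mask
  net$params[[head_i]]$W[] <- 0
  net$params[[head_i]]$b[] <- 0
  m <- infer_deepnet(net, matrix(runif(256), 16, 16))
  expect_equal(sum(m$pixels), 0)
  # certain background
  net$params[[head_i]]$b <- c(10, -10)
  m2 <- infer_deepnet(net, matrix(runif(256), 16, 16))
  expect_equal(sum(m2$pixels), 0)
  # certain foreground
  net$params[[head_i]]$b <- c(-10, 10)
  m3 <- infer_deepnet(net, matrix(runif(256), 16, 16))
  expect_equal(sum(m3$pixels), 256)

  expect_error(infer_deepnet(net, matrix(0.5, 8, 8)), "does not match")
})

test_that("training reduces the loss and checkpoints round-trip", {
  sp <- tiny_phantom_spec(noise = 0)
  ds <- make_dataset(sp, 4, seed = 41)
  cfg <- net_config("tiny", input_size = c(32L, 32L), seed = 5)
  net <- build_network(cfg)
  fit <- train_deepnet(net, ds, epochs = 20, batch = 4, seed = 6)
  expect_lt(fit$loss[20], fit$loss[1])
  expect_true(all(is.finite(fit$loss)))

  f <- withr::local_tempfile(fileext = ".ckpt")
  save_deepnet(fit$net, f)
  net2 <- load_deepnet(f)
  m1 <- infer_deepnet(fit$net, ds[[1]]$image)
  m2 <- infer_deepnet(net2, ds[[1]]$image)
  expect_identical(m1$pixels, m2$pixels)
})
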