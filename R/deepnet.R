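#' ELU activation and its derivative
#'
#' `f(i) = i` for `i > 0` and `beta * (exp(i) - 1)` otherwise: continuous at
#' zero, saturating at `-beta` as `i -> -Inf`. The derivative on the
#' negative branch satisfies the identity `f'(i) = f(i) + beta`.
#'
#' @param i pre-activation values (any numeric array).
#' @param beta saturation hyper-parameter, `> 0`.
#' @return array of the same shape.
#' @export
elu <- function(i, beta = 1) {
  if (beta <= 0) stop_input("beta must be > 0")
  ifelse(i > 0, i, beta * (exp(pmin(i, 0)) - 1))
}

#' @rdname elu
#' @export
elu_grad <- function(i, beta = 1) {
  if (beta <= 0) stop_input("beta must be > 0")
  ifelse(i > 0, 1, elu(i, beta) + beta)
}

#' 2x2 stride-2 max pooling with argmax indices
#'
#' Every output cell is the maximum of its 2x2 input window; `idx` records
#' the 0-based window-local argmax in row-major window order
#' (`(0,0)=0, (0,1)=1, (1,0)=2, (1,1)=3`), ties resolved to the first
#' position. The indices are what the decoder reuses for unpooling.
#'
#' @param x numeric matrix or `H x W x C x B` array with even spatial dims.
#' @return list with `y` (pooled values) and `idx` (argmax indices), each
#'   shaped like the pooled output.
#' @export
maxpool_with_indices <- function(x) {
  a <- as_tensor4(x)
  if (dim(a)[1] %% 2L != 0L || dim(a)[2] %% 2L != 0L)
    stop_input("max pooling requires even spatial dimensions")
  r <- .cpp_maxpool2_fwd(a, dim(a))
  if (is.matrix(x)) {
    list(y = matrix(r$y, dim(r$y)[1], dim(r$y)[2]),
         idx = matrix(r$idx, dim(r$idx)[1], dim(r$idx)[2]))
  } else r
}

#' Index unpooling
#'
#' Places each pooled value back at its recorded argmax position (zeros
#' elsewhere), doubling both spatial dimensions; the exact inverse of
#' [maxpool_with_indices] on the pooled support, and sum-preserving.
#'
#' @param y pooled values (matrix or 4-D array).
#' @param idx matching argmax indices.
#' @return the unpooled array (or matrix for matrix input).
#' @export
unpool <- function(y, idx) {
  a <- as_tensor4(y)
  ia <- as_tensor4(idx)
  if (!all(dim(a) == dim(ia))) stop_input("y and idx shapes must match")
  storage.mode(ia) <- "integer"
  if (any(ia < 0L) || any(ia > 3L)) stop_input("pooling index out of range")
  r <- .cpp_unpool2(a, ia, dim(a))
  if (is.matrix(y)) matrix(r, dim(r)[1], dim(r)[2]) else r
}

as_tensor4 <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 4L) x
  else stop_input("expected a matrix or H x W x C x B array")
}

#' Pixel-wise softmax over the class channel
#'
#' Log-sum-exp stabilized: invariant to adding a constant to all logits,
#' safe for large magnitudes.
#'
#' @param logits `H x W x M x B` array (or `H x W x M`).
#' @return probabilities of the same shape, summing to 1 over channel `M`.
#' @export
softmax_probs <- function(logits) {
  orig3 <- length(dim(logits)) == 3L
  a <- if (orig3) array(logits, c(dim(logits), 1L)) else logits
  d <- dim(a)
  M <- d[3]
  m2 <- matrix(aperm(a, c(1, 2, 4, 3)), ncol = M)   # pixels x classes
  zmax <- do.call(pmax, lapply(seq_len(M), function(m) m2[, m]))
  e <- exp(m2 - zmax)
  e <- e / rowSums(e)
  out <- aperm(array(e, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  if (orig3) array(out, dim(logits)) else out
}

#' Penalized cross-entropy segmentation loss
#'
#' Mean per-pixel cross-entropy `-sum o log s` between predicted class
#' probabilities and one-hot targets, plus the weight penalty
#' `chi/2 * sum(psi^2)` over the convolution weights. With `chi = 0` the
#' penalty vanishes. Probabilities at a target class are clamped at 1e-12
#' (with a warning) to keep the loss finite.
#'
#' @param probs `H x W x M x B` probabilities.
#' @param target one-hot array of the same shape.
#' @param weights optional list/vector of weight arrays entering the penalty.
#' @param chi penalty coefficient, `>= 0`.
#' @return scalar loss (>= 0).
#' @export
deepnet_loss <- function(probs, target, weights = NULL, chi = 0) {
  p <- as.numeric(probs)[as.logical(target)]
  if (any(p < 1e-12)) {
    warning("probabilities clamped at 1e-12 in loss", call. = FALSE)
    p <- pmax(p, 1e-12)
  }
  ce <- -mean(log(p))
  pen <- 0
  if (chi > 0 && !is.null(weights))
    pen <- 0.5 * chi * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  ce + pen
}

## ------------------------------------------------------- architecture -----

#' Network configuration
#'
#' `depth_preset = "vgg19"` uses the full VGG-19 convolutional layout (16
#' conv layers, 5 pooling stages) mirrored by a 16-layer deconvolution
#' decoder; `"tiny"` is a 2-block test-scale variant of the same design.
#' Dropout is applied after the deepest encoder stage and the deepest
#' decoder stage, at training time only.
#'
#' @param depth_preset `"tiny"` or `"vgg19"`.
#' @param channels optional list of per-block channel vectors overriding
#'   the preset.
#' @param beta ELU saturation parameter (> 0).
#' @param dropout_rho dropout probability in `[0, 1)`, default 0.5.
#' @param weight_penalty_chi weight penalty coefficient, `>= 0`.
#' @param num_classes output channels `M` (default 2: front/background).
#' @param input_size `c(H, W)`; must be divisible by `2^(number of blocks)`.
#' @param seed seed for parameter initialization.
#' @return validated `net_config`.
#' @export
net_config <- function(depth_preset = c("tiny", "vgg19"), channels = NULL,
                       beta = 1, dropout_rho = 0.5, weight_penalty_chi = 1e-4,
                       num_classes = 2L, input_size = c(32L, 32L), seed = 1L) {
  depth_preset <- match.arg(depth_preset)
  if (is.null(channels)) {
    channels <- switch(depth_preset,
      tiny = list(8L, 16L),
      vgg19 = list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L, 256L),
                   c(512L, 512L, 512L, 512L), c(512L, 512L, 512L, 512L)))
  }
  if (beta <= 0) stop_input("beta must be > 0")
  if (dropout_rho < 0 || dropout_rho >= 1)
    stop_input("dropout_rho must lie in [0, 1)")
  if (weight_penalty_chi < 0) stop_input("weight_penalty_chi must be >= 0")
  if (num_classes < 2) stop_input("num_classes must be >= 2")
  pools <- length(channels)
  if (any(input_size %% 2^pools != 0))
    stop_input("input_size must be divisible by 2^", pools,
               " (one 2x2 pooling per block)")
  structure(list(depth_preset = depth_preset, channels = channels,
                 beta = beta, dropout_rho = dropout_rho,
                 weight_penalty_chi = weight_penalty_chi,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Build the encoder-decoder network
#'
#' Encoder: per block, 3x3 conv + batch norm + ELU layers followed by 2x2
#' stride-2 max pooling with stored indices. Decoder: mirror image - index
#' unpooling followed by 3x3 deconvolution + batch norm + ELU, the last
#' layer of each stage reducing to the channel width of the next shallower
#' stage. A 1x1 convolution maps to `num_classes` channels; softmax yields
#' the front/background probability maps. Initialization is seeded and
#' reproducible.
#'
#' @param cfg a [net_config].
#' @return a `deepnet` object (ops, parameters, batch-norm state).
#' @export
build_network <- function(cfg) {
  blocks <- cfg$channels
  nb <- length(blocks)
  ops <- list()
  add <- function(op) ops[[length(ops) + 1L]] <<- op
  in_ch <- 1L
  for (bi in seq_len(nb)) {
    for (ch in blocks[[bi]]) {
      add(list(kind = "conv", k = 3L, cin = in_ch, cout = ch))
      add(list(kind = "bn", channels = ch))
      add(list(kind = "elu", beta = cfg$beta))
      in_ch <- ch
    }
    add(list(kind = "pool", slot = bi))
  }
  add(list(kind = "dropout", rho = cfg$dropout_rho))
  for (bi in rev(seq_len(nb))) {
    add(list(kind = "unpool", slot = bi))
    ncv <- length(blocks[[bi]])
    out_final <- if (bi > 1L) blocks[[bi - 1L]][length(blocks[[bi - 1L]])]
    else blocks[[1L]][1L]
    for (j in seq_len(ncv)) {
      out_ch <- if (j == ncv) out_final else in_ch
      add(list(kind = "conv", k = 3L, cin = in_ch, cout = out_ch))
      add(list(kind = "bn", channels = out_ch))
      add(list(kind = "elu", beta = cfg$beta))
      in_ch <- out_ch
    }
    if (bi == nb) add(list(kind = "dropout", rho = cfg$dropout_rho))
  }
  add(list(kind = "conv", k = 1L, cin = in_ch, cout = cfg$num_classes))
  params <- vector("list", length(ops))
  bn <- vector("list", length(ops))
  with_seed(cfg$seed, {
    for (i in seq_along(ops)) {
      op <- ops[[i]]
      if (op$kind == "conv") {
        fan_in <- op$k * op$k * op$cin
        sdv <- if (op$k == 1L) 0.01 else sqrt(2 / fan_in)
        params[[i]] <- list(
          W = array(rnorm(op$k * op$k * op$cin * op$cout, 0, sdv),
                    c(op$k, op$k, op$cin, op$cout)),
          b = numeric(op$cout))
      } else if (op$kind == "bn") {
        params[[i]] <- list(gamma = rep(1, op$channels),
                            beta = rep(0, op$channels))
        bn[[i]] <- list(mean = rep(0, op$channels),
                        var = rep(1, op$channels))
      }
    }
  })
  n_par <- sum(vapply(params, function(p)
    if (is.null(p)) 0L else sum(vapply(p, length, integer(1))), integer(1)))
  structure(list(cfg = cfg, ops = ops, params = params, bn = bn,
                 npools = nb, n_parameters = n_par),
            class = "deepnet")
}

#' @export
print.deepnet <- function(x, ...) {
  cat(sprintf("<deepnet '%s': %d ops, %s parameters, input %dx%d>\n",
              x$cfg$depth_preset, length(x$ops),
              format(x$n_parameters, big.mark = ","),
              x$cfg$input_size[1], x$cfg$input_size[2]))
  invisible(x)
}

# channel-wise moments helpers: view (H,W,C,B) with channel last
chan_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
unchan_mat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Forward pass
#'
#' @param net a `deepnet`.
#' @param x input `H x W x 1 x B` array (or `H x W` matrix for one image).
#' @param train use batch statistics, apply dropout, and return caches for
#'   backpropagation; `FALSE` uses batch-norm running averages and no
#'   dropout (deterministic inference).
#' @return list with `probs` (`H x W x M x B`), `logits`, `caches`, and
#'   `bn` (updated running statistics when training).
#' @export
net_forward <- function(net, x, train = TRUE) {
  x <- as_tensor4(x)
  caches <- vector("list", length(net$ops))
  pool_idx <- vector("list", net$npools)
  bn_new <- net$bn
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    if (op$kind == "conv") {
      caches[[i]] <- list(x = x)
      x <- .cpp_conv2d_fwd(x, net$params[[i]]$W, net$params[[i]]$b,
                           dim(x), dim(net$params[[i]]$W))
    } else if (op$kind == "bn") {
      g <- net$params[[i]]$gamma
      b <- net$params[[i]]$beta
      xm <- chan_mat(x)
      if (train) {
        mu <- colMeans(xm)
        va <- colMeans(xm^2) - mu^2
        bn_new[[i]] <- list(
          mean = BN_MOMENTUM * net$bn[[i]]$mean + (1 - BN_MOMENTUM) * mu,
          var = BN_MOMENTUM * net$bn[[i]]$var + (1 - BN_MOMENTUM) * va)
      } else {
        mu <- net$bn[[i]]$mean
        va <- net$bn[[i]]$var
      }
      invstd <- 1 / sqrt(va + BN_EPS)
      xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
      ym <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
      caches[[i]] <- list(xhat = xhat, invstd = invstd, dims = dim(x),
                          train = train)
      x <- unchan_mat(ym, dim(x))
    } else if (op$kind == "elu") {
      caches[[i]] <- list(grad = elu_grad(x, op$beta))
      x <- elu(x, op$beta)
    } else if (op$kind == "pool") {
      if (dim(x)[1] %% 2L != 0L || dim(x)[2] %% 2L != 0L)
        stop_input("odd spatial dimension reached a pooling layer")
      r <- .cpp_maxpool2_fwd(x, dim(x))
      pool_idx[[op$slot]] <- r$idx
      caches[[i]] <- list(idx = r$idx)
      x <- r$y
    } else if (op$kind == "unpool") {
      idx <- pool_idx[[op$slot]]
      if (!all(dim(idx) == dim(x)))
        stop_input("unpool indices inconsistent with activation shape")
      caches[[i]] <- list(idx = idx)
      x <- .cpp_unpool2(x, idx, dim(x))
    } else if (op$kind == "dropout") {
      if (train && op$rho > 0) {
        mask <- array((runif(length(x)) >= op$rho) / (1 - op$rho), dim(x))
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      }
    }
  }
  list(probs = softmax_probs(x), logits = x, caches = caches, bn = bn_new)
}

# Backpropagate from d(loss)/d(logits); returns per-op parameter gradients.
net_backward <- function(net, caches, glogits) {
  grads <- vector("list", length(net$ops))
  gx <- glogits
  for (i in rev(seq_along(net$ops))) {
    op <- net$ops[[i]]
    if (op$kind == "conv") {
      r <- .cpp_conv2d_bwd(caches[[i]]$x, net$params[[i]]$W, gx,
                           dim(caches[[i]]$x), dim(net$params[[i]]$W))
      grads[[i]] <- list(W = r$gw, b = r$gb)
      gx <- r$gx
    } else if (op$kind == "bn") {
      cc <- caches[[i]]
      g <- net$params[[i]]$gamma
      gym <- chan_mat(gx)
      gbeta <- colSums(gym)
      ggamma <- colSums(gym * cc$xhat)
      gxhat <- sweep(gym, 2, g, `*`)
      if (cc$train) {
        n <- nrow(gxhat)
        gxm <- sweep(gxhat -
                       matrix(colMeans(gxhat), n, ncol(gxhat), byrow = TRUE) -
                       cc$xhat * matrix(colMeans(gxhat * cc$xhat), n,
                                        ncol(gxhat), byrow = TRUE),
                     2, cc$invstd, `*`)
      } else {
        gxm <- sweep(gxhat, 2, cc$invstd, `*`)
      }
      grads[[i]] <- list(gamma = ggamma, beta = gbeta)
      gx <- unchan_mat(gxm, cc$dims)
    } else if (op$kind == "elu") {
      gx <- gx * caches[[i]]$grad
    } else if (op$kind == "pool") {
      gx <- .cpp_unpool2(gx, caches[[i]]$idx, dim(gx))
    } else if (op$kind == "unpool") {
      d <- dim(gx)
      gx <- .cpp_pool_gather(gx, caches[[i]]$idx,
                             c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4]))
    } else if (op$kind == "dropout") {
      if (!is.null(caches[[i]]$mask)) gx <- gx * caches[[i]]$mask
    }
  }
  grads
}

conv_weights <- function(net) {
  keep <- vapply(net$ops, function(o) o$kind == "conv", logical(1))
  lapply(net$params[keep], `[[`, "W")
}

onehot_targets <- function(masks, num_classes = 2L) {
  # masks: list of seg_mask/binary matrices -> H x W x M x B, channel 1 =
  # background, channel 2 = front (nodule)
  B <- length(masks)
  m1 <- as_mask_pixels(masks[[1]])
  t <- array(0, c(nrow(m1), ncol(m1), num_classes, B))
  for (b in seq_len(B)) {
    mk <- as_mask_pixels(masks[[b]])
    t[, , 1, b] <- 1 - mk
    t[, , 2, b] <- mk
  }
  t
}

batch_input <- function(imgs) {
  B <- length(imgs)
  p1 <- as_pixels(imgs[[1]])
  x <- array(0, c(nrow(p1), ncol(p1), 1L, B))
  for (b in seq_len(B)) x[, , 1, b] <- as_pixels(imgs[[b]])
  x
}

#' Train the network on (image, mask) pairs
#'
#' Minimizes the penalized cross-entropy by Adam (adaptive stochastic
#' gradient descent; lr 1e-3, batch 4 by default). Fully seeded: identical
#' seeds reproduce the loss trace bit-for-bit. The parameter set with the
#' lowest epoch loss is kept as the checkpoint.
#'
#' @param net a `deepnet` from [build_network].
#' @param dataset list of items with `$image` ([image_grid]) and `$mask`
#'   ([seg_mask]); shapes must match `cfg$input_size`.
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param batch mini-batch size.
#' @param seed RNG seed for shuffling, dropout and Adam.
#' @param verbose print per-epoch loss.
#' @return list with the trained `net`, `loss` trace (per epoch), `best`
#'   checkpoint parameters and `best_epoch`.
#' @export
train_deepnet <- function(net, dataset, epochs = 50L, lr = 1e-3, batch = 4L,
                          seed = 1L, verbose = FALSE) {
  if (length(dataset) < 1L) stop_input("dataset must be nonempty")
  chi <- net$cfg$weight_penalty_chi
  mstate <- rapply(net$params, function(a) a * 0, how = "replace")
  vstate <- mstate
  t_step <- 0L
  losses <- numeric(epochs)
  best_loss <- Inf
  best_params <- net$params
  best_bn <- net$bn
  best_epoch <- 0L
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(length(dataset))
      bl <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = batch)) {
        idx <- ord[start:min(start + batch - 1L, length(ord))]
        x <- batch_input(lapply(dataset[idx], `[[`, "image"))
        tg <- onehot_targets(lapply(dataset[idx], `[[`, "mask"),
                             net$cfg$num_classes)
        fw <- net_forward(net, x, train = TRUE)
        net$bn <- fw$bn
        loss <- deepnet_loss(fw$probs, tg, conv_weights(net), chi)
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", e,
               " (reduce lr or check inputs)", call. = FALSE)
        npx <- prod(dim(x)[c(1, 2, 4)])
        glog <- (fw$probs - tg) / npx
        grads <- net_backward(net, fw$caches, glog)
        t_step <- t_step + 1L
        for (i in seq_along(net$params)) {
          if (is.null(net$params[[i]])) next
          for (nm in names(net$params[[i]])) {
            gr <- grads[[i]][[nm]]
            if (chi > 0 && nm == "W" && net$ops[[i]]$kind == "conv")
              gr <- gr + chi * net$params[[i]][[nm]]
            mstate[[i]][[nm]] <- 0.9 * mstate[[i]][[nm]] + 0.1 * gr
            vstate[[i]][[nm]] <- 0.999 * vstate[[i]][[nm]] + 0.001 * gr^2
            mhat <- mstate[[i]][[nm]] / (1 - 0.9^t_step)
            vhat <- vstate[[i]][[nm]] / (1 - 0.999^t_step)
            net$params[[i]][[nm]] <- net$params[[i]][[nm]] -
              lr * mhat / (sqrt(vhat) + 1e-8)
          }
        }
        bl <- bl + loss
        nb <- nb + 1L
      }
      losses[e] <- bl / nb
      if (losses[e] < best_loss) {
        best_loss <- losses[e]
        best_params <- net$params
        best_bn <- net$bn
        best_epoch <- e
      }
      if (verbose) message(sprintf("epoch %d: loss %.6f", e, losses[e]))
    }
  })
  net$params <- best_params
  net$bn <- best_bn
  list(net = net, loss = losses, best_epoch = best_epoch,
       final_loss = losses[epochs])
}

#' Segment an image with a trained network
#'
#' Deterministic inference (running batch-norm statistics, no dropout):
#' per-pixel argmax of the front vs background probability; ties go to
#' background, so a maximally uncertain network predicts an empty mask.
#'
#' @param net trained `deepnet`.
#' @param img [image_grid] or matrix matching `cfg$input_size`.
#' @return a [seg_mask] (role `"prediction"`).
#' @export
infer_deepnet <- function(net, img) {
  x <- as_pixels(img)
  if (!all(dim(x) == net$cfg$input_size))
    stop_input("image shape ", nrow(x), "x", ncol(x),
               " does not match network input ",
               net$cfg$input_size[1], "x", net$cfg$input_size[2])
  fw <- net_forward(net, x, train = FALSE)
  front <- fw$probs[, , 2, 1]
  back <- fw$probs[, , 1, 1]
  seg_mask(front > back, role = "prediction")
}

#' Save / load a network checkpoint
#'
#' Single-file serialized parameters + configuration + batch-norm state.
#'
#' @param net a `deepnet`. @param path file path.
#' @return `save_deepnet`: `path` invisibly; `load_deepnet`: the `deepnet`.
#' @export
save_deepnet <- function(net, path) {
  saveRDS(list(version = 1L, cfg = net$cfg, params = net$params,
               bn = net$bn), path)
  invisible(path)
}

#' @rdname save_deepnet
#' @export
load_deepnet <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L)
    stop_input("unrecognized checkpoint version")
  net <- build_network(ck$cfg)
  net$params <- ck$params
  net$bn <- ck$bn
  net
}

#' Central-difference gradient check
#'
#' Compares analytic backpropagation gradients against central finite
#' differences of the loss for a random subset of parameters. Dropout must
#' be disabled (`dropout_rho = 0`) so the forward pass is deterministic.
#'
#' @param net a `deepnet` with `dropout_rho = 0`.
#' @param x input tensor. @param target one-hot target tensor.
#' @param n_checks number of parameter entries to probe.
#' @param eps finite-difference step.
#' @param seed seed for the parameter subset.
#' @return data.frame with analytic/numeric gradients and relative error.
#' @export
gradient_check <- function(net, x, target, n_checks = 20L, eps = 1e-4,
                           seed = 1L) {
  if (net$cfg$dropout_rho > 0)
    stop_input("gradient check requires dropout_rho = 0")
  chi <- net$cfg$weight_penalty_chi
  loss_at <- function(net) {
    fw <- net_forward(net, x, train = TRUE)
    deepnet_loss(fw$probs, target, conv_weights(net), chi)
  }
  fw <- net_forward(net, x, train = TRUE)
  npx <- prod(dim(as_tensor4(x))[c(1, 2, 4)])
  glog <- (fw$probs - target) / npx
  grads <- net_backward(net, fw$caches, glog)
  slots <- list()
  for (i in seq_along(net$params)) {
    if (is.null(net$params[[i]])) next
    for (nm in names(net$params[[i]]))
      slots[[length(slots) + 1L]] <- list(i = i, nm = nm,
                                          len = length(net$params[[i]][[nm]]))
  }
  rows <- with_seed(seed, {
    lapply(seq_len(n_checks), function(ch) {
      s <- slots[[sample.int(length(slots), 1L)]]
      j <- sample.int(s$len, 1L)
      ana <- grads[[s$i]][[s$nm]][j]
      if (chi > 0 && s$nm == "W" && net$ops[[s$i]]$kind == "conv")
        ana <- ana + chi * net$params[[s$i]][[s$nm]][j]
      np <- net
      np$params[[s$i]][[s$nm]][j] <- np$params[[s$i]][[s$nm]][j] + eps
      lp <- loss_at(np)
      np$params[[s$i]][[s$nm]][j] <- np$params[[s$i]][[s$nm]][j] - 2 * eps
      lm <- loss_at(np)
      num <- (lp - lm) / (2 * eps)
      data.frame(op = s$i, param = s$nm, index = j,
                 analytic = ana, numeric = num,
                 rel_err = abs(ana - num) / max(abs(ana), abs(num), 1e-8))
    })
  })
  do.call(rbind, rows)
}
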