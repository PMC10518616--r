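#' Gray-level histogram
#'
#' Uniform binning of a unit-range image into `L` gray levels
#' (`level = floor(x * L)`, clipped to `L - 1`).
#'
#' @param img unit-range [image_grid] or matrix.
#' @param L number of levels (>= 2), default 256.
#' @return object of class `gray_histogram` with `counts` (length `L`),
#'   `L` and `total`.
#' @export
gray_histogram <- function(img, L = 256L) {
  x <- as_pixels(img)
  if (!all(is.finite(x))) stop_input("image must be finite")
  if (L < 2) stop_input("L must be >= 2")
  if (min(x) < 0 || max(x) > 1)
    stop_input("gray_histogram expects a [0, 1] image")
  lev <- pmin(floor(x * L), L - 1L)
  counts <- tabulate(lev + 1L, nbins = L)
  gray_histogram_from_counts(counts)
}

#' @rdname gray_histogram
#' @param counts non-negative counts per level (sum > 0).
#' @export
gray_histogram_from_counts <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0)
    stop_input("histogram counts must be non-negative with positive total")
  structure(list(counts = as.numeric(counts), L = length(counts),
                 total = sum(counts)),
            class = "gray_histogram")
}

# Prefix-sum statistics reused by every fitness evaluation: cp[t] = P(level
# < t), cm[t] = E[level; level < t] for t = 1..L (index t covers levels
# 0..t-1), global mean mu and total variance.
hist_stats <- function(hist) {
  p <- hist$counts / hist$total
  lev <- seq_len(hist$L) - 1
  cp <- cumsum(p)
  cm <- cumsum(p * lev)
  mu <- cm[hist$L]
  list(cp = cp, cm = cm, mu = mu, L = hist$L,
       total_var = sum(p * (lev - mu)^2))
}

# Between-class variance for thresholds tv (strictly increasing integers in
# [1, L-1]); classes are the half-open level ranges [t_c, t_{c+1}) with
# t_0 = 0, t_{k+1} = L. Zero-mass classes contribute 0.
bcv_eval <- function(st, tv) {
  b <- c(0L, tv, st$L)
  cp0 <- c(0, st$cp)
  cm0 <- c(0, st$cm)
  w <- cp0[b[-1] + 1L] - cp0[b[-length(b)] + 1L]
  m <- cm0[b[-1] + 1L] - cm0[b[-length(b)] + 1L]
  ok <- w > 0
  sum(w[ok] * (m[ok] / w[ok] - st$mu)^2)
}

validate_tv <- function(tv, L) {
  if (length(tv) < 1L || any(tv != round(tv)) || any(tv < 1) || any(tv > L - 1))
    stop_input("thresholds must be integers in [1, L-1]")
  if (is.unsorted(tv, strictly = TRUE))
    stop_input("thresholds must be strictly increasing")
  as.integer(tv)
}

#' Between-class variance (multilevel Otsu criterion)
#'
#' The fitness maximized by the threshold optimizer: the variance of the
#' class means, `sum_c w_c (mu_c - mu)^2`, over the intensity classes
#' induced by the thresholds. Larger values indicate a wider gap between
#' the regions; it never exceeds the total gray-level variance, and the two
#' add up with the pooled within-class variance.
#'
#' @param hist a [gray_histogram].
#' @param tv integer thresholds, strictly increasing in `[1, L-1]`.
#' @return non-negative fitness value (gray-level-squared units).
#' @export
between_class_variance <- function(hist, tv) {
  tv <- validate_tv(tv, hist$L)
  bcv_eval(hist_stats(hist), tv)
}

#' Pooled within-class variance (complement of [between_class_variance])
#' @inheritParams between_class_variance
#' @return non-negative value; `between + within = total` variance.
#' @export
within_class_variance <- function(hist, tv) {
  tv <- validate_tv(tv, hist$L)
  st <- hist_stats(hist)
  p <- hist$counts / hist$total
  lev <- seq_len(hist$L) - 1
  cls <- findInterval(lev, tv)
  tot <- 0
  for (c_ in unique(cls)) {
    sel <- cls == c_
    w <- sum(p[sel])
    if (w > 0) {
      m <- sum(p[sel] * lev[sel]) / w
      tot <- tot + sum(p[sel] * (lev[sel] - m)^2)
    }
  }
  tot
}

#' Exhaustive multilevel Otsu search (reference oracle)
#'
#' Finds the global maximizer of [between_class_variance] by full
#' enumeration. Tractable for `k = 1` or `k = 2` at any `L`, and for any
#' `k` when `L <= 16`; other combinations are refused. Ties are broken by
#' the lexicographically smallest threshold vector.
#'
#' @param hist a [gray_histogram].
#' @param k number of thresholds.
#' @return list with `thresholds` and `fitness`.
#' @export
exhaustive_otsu <- function(hist, k) {
  L <- hist$L
  st <- hist_stats(hist)
  if (k == 1L) {
    cand <- seq_len(L - 1L)
    w <- st$cp[cand]
    m <- st$cm[cand]
    f <- ifelse(w <= 0 | w >= 1, 0, (st$mu * w - m)^2 / (w * (1 - w)))
    best <- which.max(f)  # first maximum = smallest t under ties
    # report the fitness through the same evaluator the optimizer uses, so
    # optimum comparisons are free of formula-level rounding differences
    return(list(thresholds = best, fitness = bcv_eval(st, best)))
  }
  if (k == 2L) {
    cp0 <- c(0, st$cp); cm0 <- c(0, st$cm)
    best_f <- -Inf; best_tv <- NULL
    for (t1 in seq_len(L - 2L)) {
      t2 <- (t1 + 1L):(L - 1L)
      w1 <- cp0[t1 + 1L]; m1 <- cm0[t1 + 1L]
      w2 <- cp0[t2 + 1L] - w1; m2 <- cm0[t2 + 1L] - m1
      w3 <- 1 - cp0[t2 + 1L]; m3 <- st$mu - cm0[t2 + 1L]
      f <- numeric(length(t2))
      if (w1 > 0) f <- f + w1 * (m1 / w1 - st$mu)^2
      ok <- w2 > 0; f[ok] <- f[ok] + w2[ok] * (m2[ok] / w2[ok] - st$mu)^2
      ok <- w3 > 0; f[ok] <- f[ok] + w3[ok] * (m3[ok] / w3[ok] - st$mu)^2
      i <- which.max(f)
      if (f[i] > best_f) {
        best_f <- f[i]
        best_tv <- c(t1, t2[i])
      }
    }
    return(list(thresholds = best_tv, fitness = bcv_eval(st, best_tv)))
  }
  if (L <= 16L) {
    combos <- utils::combn(L - 1L, k)
    best_f <- -Inf; best_tv <- NULL
    for (j in seq_len(ncol(combos))) {
      f <- bcv_eval(st, combos[, j])
      if (f > best_f) {  # combn enumerates in lexicographic order
        best_f <- f
        best_tv <- combos[, j]
      }
    }
    return(list(thresholds = as.integer(best_tv), fitness = best_f))
  }
  stop_input("exhaustive enumeration refused for k = ", k, " at L = ", L,
             " (supported: k <= 2 any L, or L <= 16)")
}

#' Cuckoo-search configuration
#'
#' @param m number of host nests (>= 2).
#' @param Q alien-egg discovery probability in (0, 1): the fraction of worst
#'   nests abandoned and rebuilt each generation.
#' @param N maximum number of generations.
#' @param sigma Levy step-size scale in gray levels.
#' @param delta Levy exponent, `1 < delta <= 3`; steps are drawn by
#'   Mantegna's method with stability index `delta - 1`.
#' @param k number of thresholds.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param patience generations without improvement before early stop.
#' @return validated `csa_config` list.
#' @export
csa_config <- function(m = 25L, Q = 0.25, N = 100L, sigma = 10, delta = 2.5,
                       k = 2L, seed = NULL, patience = 25L) {
  if (m < 2) stop_input("m must be >= 2")
  if (Q <= 0 || Q >= 1) stop_input("Q must lie in (0, 1)")
  if (N < 1) stop_input("N must be >= 1")
  if (sigma <= 0) stop_input("sigma must be > 0")
  if (delta <= 1 || delta > 3) stop_input("delta must satisfy 1 < delta <= 3")
  if (k < 1) stop_input("k must be >= 1")
  structure(list(m = as.integer(m), Q = Q, N = as.integer(N), sigma = sigma,
                 delta = delta, k = as.integer(k), seed = seed,
                 patience = as.integer(patience)),
            class = "csa_config")
}

#' Levy-flight step vector
#'
#' Heavy-tailed random steps via Mantegna's method: with stability index
#' `alpha = delta - 1`, `step = u / |v|^(1/alpha)` where
#' `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)`. `delta = 3` (`alpha = 2`) is the
#' Gaussian limit and is handled exactly.
#'
#' @param dim number of components.
#' @param delta Levy exponent, `1 < delta <= 3`.
#' @return numeric vector of `dim` heavy-tailed steps (unit scale).
#' @export
levy_step <- function(dim, delta) {
  if (!is.numeric(delta) || delta <= 1 || delta > 3)
    stop_input("delta must satisfy 1 < delta <= 3")
  alpha <- delta - 1
  if (alpha >= 2) return(rnorm(dim))
  sigma_u <- (gamma(1 + alpha) * sin(pi * alpha / 2) /
                (gamma((1 + alpha) / 2) * alpha * 2^((alpha - 1) / 2)))^(1 / alpha)
  u <- rnorm(dim, 0, sigma_u)
  v <- rnorm(dim)
  u / abs(v)^(1 / alpha)
}

# Repair a real-valued proposal into a valid threshold vector: round, clip
# to [1, L-1], sort, then nudge duplicates upward (and re-clip from the top)
# so the result is strictly increasing.
repair_tv <- function(v, L, k) {
  r <- sort(pmin(pmax(round(v), 1), L - 1))
  if (k > 1L) {
    for (i in 2:k) if (r[i] <= r[i - 1]) r[i] <- r[i - 1] + 1
    for (i in k:1) {
      cap <- L - 1 - (k - i)
      if (r[i] > cap) r[i] <- cap
    }
    for (i in 2:k) if (r[i] <= r[i - 1]) r[i] <- r[i - 1] + 1
  }
  as.integer(r)
}

random_tv <- function(L, k) sort(sample.int(L - 1L, k))

#' Cuckoo-search threshold optimization
#'
#' Population metaheuristic over threshold vectors ("nests"). Each
#' generation: (a) every nest proposes a Levy-flight perturbation
#' `m' = m + sigma (*) Levy(delta)` (entry-wise), repaired to a valid sorted
#' integer vector; (b) the proposal replaces a randomly chosen nest when its
#' between-class variance is higher; (c) the worst `ceiling(Q * m)` nests
#' are abandoned and re-initialized uniformly at random; (d) the best-ever
#' solution is retained (elitism), so the best-fitness trace is
#' non-decreasing. Stops after `N` generations or `patience` generations
#' without improvement.
#'
#' @param hist a [gray_histogram].
#' @param cfg a [csa_config].
#' @return list with `thresholds` (best-ever vector), `fitness`, `trace`
#'   (data.frame iteration/best_fitness), and `evaluations`.
#' @export
csa_optimize <- function(hist, cfg = csa_config()) {
  if (!inherits(cfg, "csa_config")) stop_input("cfg must be a csa_config")
  run <- function() {
    st <- hist_stats(hist)
    L <- st$L; k <- cfg$k; m <- cfg$m
    if (k > L - 1L) stop_input("k must be < L")
    nests <- matrix(0L, m, k)
    for (i in seq_len(m)) nests[i, ] <- random_tv(L, k)
    fit <- apply(nests, 1L, bcv_eval, st = st)
    evals <- m
    bi <- which.max(fit)
    best_f <- fit[bi]; best_tv <- nests[bi, ]
    trace_f <- numeric(cfg$N)
    stall <- 0L
    n_aband <- ceiling(cfg$Q * m)
    iter <- 0L
    for (s in seq_len(cfg$N)) {
      iter <- s
      improved <- FALSE
      for (j in seq_len(m)) {
        prop <- repair_tv(nests[j, ] + cfg$sigma * levy_step(k, cfg$delta),
                          L, k)
        fp <- bcv_eval(st, prop)
        evals <- evals + 1L
        if (fp > best_f ||
            (fp == best_f && !lex_ge(prop, best_tv))) {
          if (fp > best_f) improved <- TRUE
          best_f <- fp; best_tv <- prop
        }
        i <- sample.int(m, 1L)
        if (fp > fit[i]) {
          nests[i, ] <- prop
          fit[i] <- fp
        }
      }
      worst <- order(fit)[seq_len(n_aband)]
      for (i in worst) {
        nests[i, ] <- random_tv(L, k)
        fit[i] <- bcv_eval(st, nests[i, ])
        evals <- evals + 1L
        if (fit[i] > best_f) {
          improved <- TRUE
          best_f <- fit[i]; best_tv <- nests[i, ]
        }
      }
      trace_f[s] <- best_f
      stall <- if (improved) 0L else stall + 1L
      if (stall >= cfg$patience) break
    }
    list(thresholds = as.integer(best_tv), fitness = best_f,
         trace = data.frame(iteration = seq_len(iter),
                            best_fitness = trace_f[seq_len(iter)]),
         evaluations = evals)
  }
  if (is.null(cfg$seed)) run() else with_seed(cfg$seed, run())
}

# TRUE when a >= b lexicographically (used for deterministic tie-breaking
# toward the smallest threshold vector).
lex_ge <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  if (length(nz) == 0L) TRUE else d[nz[1]] > 0
}

#' Apply thresholds to an image
#'
#' Assigns each pixel the class `c` with `t_c <= level < t_{c+1}`
#' (half-open, `t_0 = 0`, `t_{k+1} = L`); a pixel exactly at a threshold
#' level falls in the upper class.
#'
#' @param img unit-range [image_grid] or matrix.
#' @param tv strictly increasing integer thresholds in `[1, L-1]`.
#' @param L number of gray levels.
#' @return integer matrix of class labels `0..k`.
#' @export
apply_thresholds <- function(img, tv, L = 256L) {
  x <- as_pixels(img)
  tv <- validate_tv(tv, L)
  lev <- pmin(floor(x * L), L - 1L)
  matrix(findInterval(lev, tv), nrow(x), ncol(x))
}

#' Extract the nodule mask from a threshold label map
#'
#' Default policy: keep the highest-intensity class, then remove connected
#' components (8-connectivity) smaller than `min_area` pixels.
#'
#' @param labels label map from [apply_thresholds].
#' @param min_area minimum component area in pixels.
#' @return a [seg_mask] (role `"prediction"`); empty when nothing survives.
#' @export
nodule_mask_from_labels <- function(labels, min_area = 4L) {
  sel <- matrix(as.integer(labels == max(labels)), nrow(labels), ncol(labels))
  if (max(labels) == 0L)  # single class: nothing to separate
    return(seg_mask(matrix(0L, nrow(labels), ncol(labels)), "prediction"))
  lab <- .cpp_label8(sel)
  if (max(lab) > 0L && min_area > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area)
    sel <- matrix(as.integer(lab %in% keep), nrow(lab), ncol(lab))
  }
  seg_mask(sel, role = "prediction")
}

#' End-to-end cuckoo-search segmentation of one image
#'
#' Convenience wrapper: histogram, CSA threshold optimization, threshold
#' application, and nodule-mask extraction.
#'
#' @param img unit-range [image_grid] or matrix.
#' @param cfg a [csa_config].
#' @param L gray levels.
#' @param min_area minimum component area.
#' @return list with `mask` ([seg_mask]), `thresholds`, `fitness`, `trace`.
#' @export
segment_csa <- function(img, cfg = csa_config(), L = 256L, min_area = 4L) {
  hist <- gray_histogram(img, L)
  opt <- csa_optimize(hist, cfg)
  labels <- apply_thresholds(img, opt$thresholds, L)
  mask <- nodule_mask_from_labels(labels, min_area)
  list(mask = mask, thresholds = opt$thresholds, fitness = opt$fitness,
       trace = opt$trace)
}
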