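#' Min-max normalization
#'
#' Rescales intensities to \[0,1\] with the affine map
#' `(x - mu_min) / (mu_max - mu_min)`, the standard min-max scalar used to
#' bring heterogeneous CT intensities onto a common scale before
#' segmentation.
#'
#' @param img [image_grid] or numeric matrix.
#' @param params optional `list(mu_min=, mu_max=)`; taken from the data when
#'   omitted. `mu_max` must exceed `mu_min`.
#' @return unit-range [image_grid].
#' @export
minmax_normalize <- function(img, params = NULL) {
  x <- as_pixels(img)
  if (is.null(params)) params <- list(mu_min = min(x), mu_max = max(x))
  if (!is.numeric(params$mu_min) || !is.numeric(params$mu_max))
    stop_input("params must provide numeric mu_min and mu_max")
  if (params$mu_max <= params$mu_min)
    stop_input("degenerate input: mu_max must exceed mu_min ",
               "(constant image cannot be min-max normalized)")
  y <- (x - params$mu_min) / (params$mu_max - params$mu_min)
  image_grid(pmin(pmax(y, 0), 1), value_range = "unit")
}

#' Window a Hounsfield-unit image and normalize to \[0,1\]
#'
#' Standard lung windowing: clip HU to `window` then min-max normalize.
#'
#' @param img [image_grid] in HU.
#' @param window `c(low, high)` HU window, default `c(-1000, 400)`.
#' @return unit-range [image_grid].
#' @export
hu_window <- function(img, window = c(-1000, 400)) {
  x <- as_pixels(img)
  x <- pmin(pmax(x, window[1]), window[2])
  image_grid((x - window[1]) / (window[2] - window[1]), value_range = "unit",
             spacing = if (inherits(img, "image_grid")) img$spacing)
}

# Interpolation weight matrix mapping n_in samples onto n_out, with sample
# positions at pixel centres ((i + 0.5) * scale - 0.5) and edge clamping.
bilinear_weights <- function(n_out, n_in) {
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale - 0.5        # 0-based source coord
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  frac <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  w <- matrix(0, n_out, n_in)
  w[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
  w[cbind(seq_len(n_out), hi + 1)] <-
    w[cbind(seq_len(n_out), hi + 1)] + frac
  w
}

#' Bilinear resize
#'
#' Resamples to `height x width` by separable bilinear interpolation with
#' pixel-centre alignment; the output range never exceeds the input range.
#' The pipeline default brings every slice to the 128 x 128 working
#' resolution.
#'
#' @param img [image_grid] or matrix.
#' @param height,width target size (>= 8).
#' @return resized [image_grid] (value_range preserved).
#' @export
resize_to <- function(img, height, width) {
  if (height < 1 || width < 1)
    stop_input("resize target must be at least 1 x 1")
  x <- as_pixels(img)
  if (nrow(x) == height && ncol(x) == width) {
    y <- x
  } else {
    y <- bilinear_weights(height, nrow(x)) %*% x %*%
      t(bilinear_weights(width, ncol(x)))
  }
  # bare matrices (e.g. chroma planes) carry no domain guarantee, and
  # interpolation breaks integer domains: declare both unconstrained
  vr <- if (inherits(img, "image_grid")) img$value_range else "hu"
  if (vr %in% c("uint8", "uint16")) vr <- "hu"
  image_grid(y, value_range = vr)
}

#' Edge-enhancement filter
#'
#' Correlates the image with the fixed 3x3 kernel
#' `[[-1, 0, -1], [0, 5, 0], [-1, 0, -1]]` (weights sum to 1, so constant
#' regions pass through unchanged) using reflect padding at the borders.
#' The kernel is symmetric under 180-degree rotation, so correlation and
#' convolution coincide.
#'
#' @param img [image_grid] or matrix (normalized input expected).
#' @param clip clip the response to \[0,1\] (default FALSE; the pipeline
#'   clips after this stage).
#' @return filtered [image_grid]-compatible matrix wrapped as `"hu"` range
#'   when unclipped (responses may leave \[0,1\]), `"unit"` when clipped.
#' @export
edge_filter <- function(img, clip = FALSE) {
  x <- as_pixels(img)
  h <- nrow(x); w <- ncol(x)
  # reflect padding by one pixel (edge rows/cols mirrored without repeat of
  # the border? classical 'reflect' duplicates the border sample: use
  # symmetric padding x[1], x[1..h], x[h])
  p <- x[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  ctr <- p[2:(h + 1), 2:(w + 1)]
  y <- 5 * ctr -
    p[1:h, 1:w] - p[1:h, 3:(w + 2)] -
    p[3:(h + 2), 1:w] - p[3:(h + 2), 3:(w + 2)]
  if (clip) image_grid(pmin(pmax(y, 0), 1), value_range = "unit")
  else image_grid(y, value_range = "hu")
}

#' Fixed edge-enhancement kernel
#' @return the 3x3 kernel matrix (rows are kernel rows).
#' @export
edge_kernel <- function() {
  matrix(c(-1, 0, -1,
           0, 5, 0,
           -1, 0, -1), 3, 3, byrow = TRUE)
}

#' RGB to YUV (BT.601) and back
#'
#' Luma/chroma conversion with optional 2x chroma (U, V) downsampling; the
#' luma channel is always kept at full resolution. Used for completeness on
#' color inputs; the grayscale CT path does not need it.
#'
#' @param rgb `H x W x 3` array with channels in \[0,1\].
#' @param downsample_chroma halve the U/V resolution by 2x2 block averaging
#'   (requires even dimensions).
#' @return `rgb_to_yuv`: list with full-resolution `y` and (possibly
#'   half-resolution) `u`, `v` matrices; `yuv_to_rgb`: the `H x W x 3` array.
#' @export
rgb_to_yuv <- function(rgb, downsample_chroma = FALSE) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop_input("rgb must be an H x W x 3 array")
  if (min(rgb) < 0 || max(rgb) > 1)
    stop_input("rgb channels must lie in [0, 1]")
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  u <- 0.492 * (b - y)
  v <- 0.877 * (r - y)
  if (downsample_chroma) {
    if (nrow(y) %% 2L != 0L || ncol(y) %% 2L != 0L)
      stop_input("chroma downsampling requires even image dimensions")
    u <- block_mean2(u)
    v <- block_mean2(v)
  }
  list(y = y, u = u, v = v, downsampled = downsample_chroma)
}

block_mean2 <- function(m) {
  h <- nrow(m) %/% 2L; w <- ncol(m) %/% 2L
  0.25 * (m[2 * seq_len(h) - 1, 2 * seq_len(w) - 1] +
            m[2 * seq_len(h) - 1, 2 * seq_len(w)] +
            m[2 * seq_len(h), 2 * seq_len(w) - 1] +
            m[2 * seq_len(h), 2 * seq_len(w)])
}

#' @rdname rgb_to_yuv
#' @param yuv result of [rgb_to_yuv].
#' @export
yuv_to_rgb <- function(yuv) {
  y <- yuv$y
  u <- yuv$u; v <- yuv$v
  if (isTRUE(yuv$downsampled)) {
    u <- as.matrix(resize_to(u, nrow(y), ncol(y)))
    v <- as.matrix(resize_to(v, nrow(y), ncol(y)))
  }
  r <- y + v / 0.877
  b <- y + u / 0.492
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(nrow(y), ncol(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  pmin(pmax(out, 0), 1)
}

#' Weighted histogram equalization
#'
#' CDF-based intensity remapping on 256 gray levels with the histogram
#' counts clipped at `weight_clip` times the uniform bin count before the
#' CDF is formed ("clip-weighted" equalization). Clipping tempers the noise
#' amplification of classical equalization; `weight_clip = Inf` recovers the
#' classical method. The mapping is monotone in the input value; constant
#' images are returned unchanged.
#'
#' @param img unit-range [image_grid] or matrix.
#' @param weight_clip clip factor (> 0), default 3.
#' @param levels number of gray levels, default 256.
#' @return equalized unit-range [image_grid].
#' @export
equalize_hist <- function(img, weight_clip = 3, levels = 256L) {
  x <- as_pixels(img)
  if (min(x) < 0 || max(x) > 1)
    stop_input("equalize_hist expects a [0, 1] image")
  if (max(x) == min(x))
    return(image_grid(x, value_range = "unit"))
  bin <- pmin(floor(x * levels), levels - 1L) + 1L
  counts <- tabulate(bin, nbins = levels)
  if (is.finite(weight_clip))
    counts <- pmin(counts, weight_clip * length(x) / levels)
  cdf <- cumsum(counts) / sum(counts)
  image_grid(matrix(cdf[bin], nrow(x), ncol(x)), value_range = "unit")
}

#' Full preprocessing pipeline
#'
#' Applies, in order: HU windowing (HU inputs only), min-max normalization,
#' bilinear resize to the working resolution, weighted histogram
#' equalization, and edge enhancement (clipped back to \[0,1\]). Each stage
#' can be toggled in `cfg$preprocess`.
#'
#' @param img [image_grid] (unit, uint8 or HU).
#' @param cfg a `run_config` (see [default_config]).
#' @return preprocessed unit-range [image_grid].
#' @export
preprocess_pipeline <- function(img, cfg = default_config()) {
  pc <- cfg$preprocess
  x <- if (inherits(img, "image_grid")) img else image_grid(img, "unit")
  if (x$value_range == "hu") x <- hu_window(x, pc$hu_window)
  if (x$value_range == "uint8")
    x <- image_grid(x$pixels / 255, value_range = "unit")
  if (isTRUE(pc$normalize) && max(x$pixels) > min(x$pixels))
    x <- minmax_normalize(x)
  if (isTRUE(pc$resize)) x <- resize_to(x, pc$size[1], pc$size[2])
  if (isTRUE(pc$equalize)) x <- equalize_hist(x, pc$equalize_clip)
  if (isTRUE(pc$edge)) x <- edge_filter(x, clip = TRUE)
  x
}
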