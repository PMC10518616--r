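#' LBP configuration
#'
#' @param n number of neighbors on the sampling circle (4, 8 or 16).
#' @param radius circle radius in pixels (>= 1).
#' @param grid cells per axis for histogram pooling (default 1 = whole
#'   image as one cell).
#' @param normalize normalize each cell histogram to sum 1 (default FALSE,
#'   which keeps the coded-pixel count — and hence region size — in the
#'   descriptor).
#' @return validated `lbp_config` list.
#' @export
lbp_config <- function(n = 8L, radius = 1L, grid = 1L, normalize = FALSE) {
  if (!n %in% c(4L, 8L, 16L)) stop_input("n must be 4, 8 or 16")
  if (radius < 1) stop_input("radius must be >= 1")
  if (grid < 1 || grid != round(grid)) stop_input("grid must be a positive integer")
  structure(list(n = as.integer(n), radius = radius, grid = as.integer(grid),
                 normalize = isTRUE(normalize)),
            class = "lbp_config")
}

# Neighbor offsets (drow, dcol) for angle t: t = 0 points east, proceeding
# counter-clockwise in image coordinates (row axis points down, hence the
# minus sign on the sine).
lbp_offsets <- function(cfg) {
  t <- seq_len(cfg$n) - 1L
  theta <- 2 * pi * t / cfg$n
  cbind(drow = -cfg$radius * sin(theta), dcol = cfg$radius * cos(theta))
}

bilinear_sample <- function(x, r, c_) {
  # r, c_ real-valued 1-based coordinates strictly inside the raster
  r0 <- floor(r); c0 <- floor(c_)
  fr <- r - r0; fc <- c_ - c0
  r1 <- pmin(r0 + 1, nrow(x)); c1 <- pmin(c0 + 1, ncol(x))
  x[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    x[cbind(r1, c0)] * fr * (1 - fc) +
    x[cbind(r0, c1)] * (1 - fr) * fc +
    x[cbind(r1, c1)] * fr * fc
}

#' Local binary pattern code at one pixel
#'
#' The code `sum_t s(q_t - q_d) 2^t` where `q_d` is the center gray value,
#' `q_t` the value of the t-th circle neighbor (bilinearly interpolated when
#' off-grid), and the sign function `s(v)` is 1 for `v >= 0`, 0 otherwise —
#' ties count as 1, so a perfectly flat neighborhood codes to `2^n - 1`.
#'
#' @param img [image_grid] or matrix.
#' @param row,col 1-based pixel position, at least `ceiling(radius)` away
#'   from every border.
#' @param cfg an [lbp_config].
#' @return integer code in `[0, 2^n - 1]`.
#' @export
lbp_code <- function(img, row, col, cfg = lbp_config()) {
  x <- as_pixels(img)
  m <- ceiling(cfg$radius)
  if (row <= m || row > nrow(x) - m || col <= m || col > ncol(x) - m)
    stop_input("pixel too close to the border for radius ", cfg$radius)
  off <- lbp_offsets(cfg)
  qd <- x[row, col]
  qt <- bilinear_sample(x, row + off[, "drow"], col + off[, "dcol"])
  sum((qt - qd >= 0) * 2^(seq_len(cfg$n) - 1))
}

#' LBP code raster
#'
#' Codes every interior pixel (border margin `ceiling(radius)` is `NA`).
#' Neighbor sampling reuses one bilinear stencil per angle, so the map is
#' exactly [lbp_code] applied everywhere.
#'
#' @inheritParams lbp_code
#' @return numeric matrix of codes with `NA` borders.
#' @export
lbp_map <- function(img, cfg = lbp_config()) {
  x <- as_pixels(img)
  h <- nrow(x); w <- ncol(x)
  m <- ceiling(cfg$radius)
  if (h <= 2 * m || w <= 2 * m)
    stop_input("image too small for LBP radius ", cfg$radius)
  rows <- (m + 1):(h - m)
  cols <- (m + 1):(w - m)
  ctr <- x[rows, cols]
  codes <- matrix(0, length(rows), length(cols))
  off <- lbp_offsets(cfg)
  for (t in seq_len(cfg$n)) {
    dr <- off[t, "drow"]; dc <- off[t, "dcol"]
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    # constant fractional offset: blend four shifted blocks
    blk <- function(sr, sc) x[rows + sr, cols + sc, drop = FALSE]
    qt <- blk(r0, c0) * (1 - fr) * (1 - fc)
    if (fr > 0) qt <- qt + blk(r0 + 1, c0) * fr * (1 - fc)
    if (fc > 0) qt <- qt + blk(r0, c0 + 1) * (1 - fr) * fc
    if (fr > 0 && fc > 0) qt <- qt + blk(r0 + 1, c0 + 1) * fr * fc
    codes <- codes + (qt - ctr >= 0) * 2^(t - 1)
  }
  out <- matrix(NA_real_, h, w)
  out[rows, cols] <- codes
  out
}

#' LBP histogram descriptor
#'
#' Pools LBP codes into per-cell histograms (`grid x grid` cells over the
#' full image extent) of `2^n` bins each, concatenated cell by cell
#' (row-major cells). An optional mask restricts pooling to the segmented
#' region. Unnormalized histograms sum to the number of coded pixels.
#'
#' @param codes code raster from [lbp_map].
#' @param mask optional [seg_mask] or binary matrix restricting the pixels.
#' @param cfg an [lbp_config].
#' @return object of class `lbp_descriptor` with `histogram` (length
#'   `grid^2 * 2^n`), `cfg` and `coded` (pixels pooled).
#' @export
lbp_histogram <- function(codes, mask = NULL, cfg = lbp_config()) {
  nb <- 2L^cfg$n
  h <- nrow(codes); w <- ncol(codes)
  keep <- !is.na(codes)
  if (!is.null(mask)) {
    mk <- as_mask_pixels(mask)
    if (!all(dim(mk) == dim(codes)))
      stop_input("mask shape must match the code raster")
    keep <- keep & mk == 1L
  }
  if (!any(keep))
    warning("empty masked region: zero LBP descriptor", call. = FALSE)
  g <- cfg$grid
  cell_r <- pmin(ceiling(row(codes) / (h / g)), g)
  cell_c <- pmin(ceiling(col(codes) / (w / g)), g)
  cell <- (cell_r - 1L) * g + cell_c
  hist <- numeric(g * g * nb)
  for (ci in seq_len(g * g)) {
    sel <- keep & cell == ci
    if (any(sel)) {
      counts <- tabulate(codes[sel] + 1L, nbins = nb)
      if (cfg$normalize) counts <- counts / sum(counts)
      hist[((ci - 1L) * nb + 1L):(ci * nb)] <- counts
    }
  }
  structure(list(histogram = hist, cfg = cfg, coded = sum(keep)),
            class = "lbp_descriptor")
}

#' Extract an LBP descriptor from an image region
#'
#' Composition of [lbp_map] and [lbp_histogram] restricted to `mask`;
#' deterministic in its inputs.
#'
#' @param img [image_grid] or matrix.
#' @param mask optional [seg_mask]/binary matrix (e.g. a segmentation).
#' @param cfg an [lbp_config].
#' @return an `lbp_descriptor`.
#' @export
extract_features <- function(img, mask = NULL, cfg = lbp_config()) {
  lbp_histogram(lbp_map(img, cfg), mask = mask, cfg = cfg)
}
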