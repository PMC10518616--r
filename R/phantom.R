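#' Specify a CT-like lung phantom
#'
#' Defines the synthetic study material used throughout the package: a
#' tri-modal slice with a bright "body" background, two dark elliptical lung
#' fields and zero or more bright circular nodules placed fully inside a lung
#' field, plus additive Gaussian noise. The exact nodule mask and a
#' benign/malignant proxy label are returned with every image, so every
#' pipeline stage can be validated against known truth.
#'
#' @param height,width image size in pixels (>= 32).
#' @param lung_ellipses list of two lung-field ellipses, each
#'   `list(center = c(row, col), semi = c(a_row, a_col))` in pixel units.
#'   Default: two ellipses centred at 30%/70% of the width, spanning 64% of
#'   the height, mimicking axial lung fields.
#' @param intensity_means named means on \[0,1\] for `background` (body
#'   tissue), `lung` (air-filled lung field) and `nodule`; must satisfy
#'   `lung < background < nodule` so the histogram is tri-modal and
#'   thresholding is well-posed.
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   \[0,1\] scale; the image is clipped back to \[0,1\].
#' @param nodule_count_range integer interval for the number of nodules
#'   (0 allowed); the count is drawn uniformly.
#' @param nodule_radius_range radius interval in pixels; radii are drawn
#'   uniformly (continuous).
#' @param label_rule `list(type = "radius", threshold = 6)` labels a phantom
#'   1 ("malignant" proxy) when any nodule radius reaches the threshold;
#'   `list(type = "presence")` labels 1 whenever at least one nodule exists.
#' @param seed integer; the same spec and seed reproduce the phantom
#'   bit-identically.
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         lung_ellipses = NULL,
                         intensity_means = c(background = 0.50, lung = 0.10,
                                             nodule = 0.95),
                         noise_sigma = 0.03,
                         nodule_count_range = c(1L, 1L),
                         nodule_radius_range = c(3, 9),
                         label_rule = list(type = "radius", threshold = 6),
                         seed = 1L) {
  if (is.null(lung_ellipses)) {
    lung_ellipses <- list(
      list(center = c(height / 2, 0.30 * width),
           semi = c(0.32 * height, 0.17 * width)),
      list(center = c(height / 2, 0.70 * width),
           semi = c(0.32 * height, 0.17 * width)))
  }
  spec <- list(height = as.integer(height), width = as.integer(width),
               lung_ellipses = lung_ellipses,
               intensity_means = intensity_means,
               noise_sigma = noise_sigma,
               nodule_count_range = as.integer(round(nodule_count_range)),
               nodule_radius_range = nodule_radius_range,
               label_rule = label_rule, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$height < 32L || spec$width < 32L)
    stop_input("phantom spec invalid: height and width must be >= 32")
  im <- spec$intensity_means
  need <- c("background", "lung", "nodule")
  if (!all(need %in% names(im)))
    stop_input("phantom spec invalid: intensity_means must name ",
               "background, lung and nodule")
  if (!(im[["lung"]] < im[["background"]] && im[["background"]] < im[["nodule"]]))
    stop_input("phantom spec invalid: intensity_means must be ordered ",
               "lung < background < nodule")
  if (any(im < 0) || any(im > 1))
    stop_input("phantom spec invalid: intensity_means must lie in [0, 1]")
  if (spec$noise_sigma < 0)
    stop_input("phantom spec invalid: noise_sigma must be >= 0")
  ncr <- spec$nodule_count_range
  if (length(ncr) != 2L || ncr[1] > ncr[2] || ncr[1] < 0)
    stop_input("phantom spec invalid: nodule_count_range must be a ",
               "non-empty non-negative integer interval")
  nrr <- spec$nodule_radius_range
  if (length(nrr) != 2L || nrr[1] > nrr[2] || nrr[1] <= 0)
    stop_input("phantom spec invalid: nodule_radius_range must be a ",
               "non-empty positive interval")
  if (length(spec$lung_ellipses) != 2L)
    stop_input("phantom spec invalid: lung_ellipses must list two ellipses")
  for (e in spec$lung_ellipses) {
    if (!all(c("center", "semi") %in% names(e)) ||
        length(e$center) != 2L || length(e$semi) != 2L || any(e$semi <= 0))
      stop_input("phantom spec invalid: each lung ellipse needs ",
                 "center = c(row, col) and positive semi = c(a_row, a_col)")
    lo <- e$center - e$semi
    hi <- e$center + e$semi
    if (lo[1] < 1 || lo[2] < 1 || hi[1] > spec$height || hi[2] > spec$width)
      stop_input("phantom spec invalid: lung_ellipses extend outside the frame")
  }
  if (!spec$label_rule$type %in% c("radius", "presence"))
    stop_input("phantom spec invalid: label_rule type must be ",
               "'radius' or 'presence'")
  if (spec$label_rule$type == "radius" &&
      !(is.numeric(spec$label_rule$threshold) && spec$label_rule$threshold > 0))
    stop_input("phantom spec invalid: label_rule radius threshold must be > 0")
  invisible(spec)
}

ellipse_mask <- function(h, w, center, semi) {
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c_ - center[2]) / semi[2])^2 <= 1
}

disk_pixels <- function(h, w, center, radius) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(h, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(w, ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
  g[keep, , drop = FALSE]
}

#' Generate one phantom
#'
#' Deterministic given `spec` (including its seed): the image, mask, label
#' and nodule table are bit-identical across calls. Nodules are rejected and
#' re-sampled until their full pixel disk lies inside a lung field, so the
#' ground-truth mask is always a subset of the lung pixels.
#'
#' @param spec a [phantom_spec].
#' @return list with `image` ([image_grid], \[0,1\]), `mask` ([seg_mask],
#'   role `"truth"`), `label` (0/1) and `nodules` (data.frame of
#'   row/col/radius).
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    lung <- ellipse_mask(h, w, spec$lung_ellipses[[1]]$center,
                         spec$lung_ellipses[[1]]$semi) |
      ellipse_mask(h, w, spec$lung_ellipses[[2]]$center,
                   spec$lung_ellipses[[2]]$semi)
    img <- matrix(spec$intensity_means[["background"]], h, w)
    img[lung] <- spec$intensity_means[["lung"]]
    mask <- matrix(FALSE, h, w)
    ncr <- spec$nodule_count_range
    count <- if (ncr[1] == ncr[2]) ncr[1] else sample(ncr[1]:ncr[2], 1L)
    nodules <- data.frame(row = numeric(0), col = numeric(0),
                          radius = numeric(0))
    lung_idx <- which(lung)
    for (i in seq_len(count)) {
      placed <- FALSE
      # radius drawn once (keeps the radius distribution uniform); only the
      # position is re-sampled on placement rejection
      radius <- runif(1, spec$nodule_radius_range[1],
                      spec$nodule_radius_range[2])
      for (try in 1:200) {
        at <- lung_idx[sample.int(length(lung_idx), 1L)]
        center <- c((at - 1L) %% h + 1L, (at - 1L) %/% h + 1L)
        px <- disk_pixels(h, w, center, radius)
        inside <- center[1] - radius >= 1 && center[1] + radius <= h &&
          center[2] - radius >= 1 && center[2] + radius <= w &&
          all(lung[cbind(px$row, px$col)])
        if (inside) {
          mask[cbind(px$row, px$col)] <- TRUE
          nodules <- rbind(nodules,
                           data.frame(row = center[1], col = center[2],
                                      radius = radius))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_input("phantom spec invalid: nodule_radius_range too large for ",
                   "the lung_ellipses (no admissible placement found)")
    }
    img[mask] <- spec$intensity_means[["nodule"]]
    if (spec$noise_sigma > 0) {
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
      img <- pmin(pmax(img, 0), 1)
    }
    label <- switch(spec$label_rule$type,
      presence = as.integer(nrow(nodules) > 0L),
      radius = as.integer(nrow(nodules) > 0L &&
                            any(nodules$radius >= spec$label_rule$threshold)))
    list(image = image_grid(img, value_range = "unit"),
         mask = seg_mask(mask, role = "truth"),
         label = label, nodules = nodules)
  })
}

#' Generate a reproducible phantom dataset
#'
#' Per-item seeds are derived from the master seed, so the whole set is
#' reproducible while items stay mutually independent.
#'
#' @param spec a [phantom_spec]; its own `seed` field is ignored here.
#' @param n number of phantoms (>= 1).
#' @param seed master seed for the dataset.
#' @return list of `n` results of [make_phantom].
#' @export
make_dataset <- function(spec, n, seed = spec$seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_input("n must be a positive integer")
  item_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- item_seeds[i]
    make_phantom(s)
  })
}

#' Write a phantom dataset to disk
#'
#' Emits `img_####.png` (16-bit grayscale), `mask_####.png` (8-bit, 0/255),
#' `labels.csv` and a YAML copy of the generating spec.
#'
#' @param spec a [phantom_spec]; @param n items; @param dir output directory;
#' @param seed master seed.
#' @return invisible data.frame of filenames and labels.
#' @export
write_phantom_dataset <- function(spec, n, dir, seed = spec$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  items <- make_dataset(spec, n, seed)
  rows <- lapply(seq_along(items), function(i) {
    fi <- sprintf("img_%04d.png", i)
    fm <- sprintf("mask_%04d.png", i)
    write_png(items[[i]]$image, file.path(dir, fi))
    write_mask_png(items[[i]]$mask, file.path(dir, fm))
    data.frame(filename = fi, mask = fm, label = items[[i]]$label)
  })
  labels <- do.call(rbind, rows)
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(list(height = spec$height, width = spec$width,
                        intensity_means = as.list(spec$intensity_means),
                        noise_sigma = spec$noise_sigma,
                        nodule_count_range = spec$nodule_count_range,
                        nodule_radius_range = spec$nodule_radius_range,
                        label_rule = spec$label_rule,
                        seed = as.integer(seed)),
                   file.path(dir, "spec.yaml"))
  invisible(labels)
}
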