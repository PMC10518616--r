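#' Construct an image grid
#'
#' The universal pixel carrier of the package: a real-valued `H x W` matrix
#' (row-major pixel semantics, 0-based `(row, col)` coordinates in the docs,
#' 1-based in R indexing) together with a declared value domain and optional
#' physical pixel spacing.
#'
#' @param pixels numeric matrix, all values finite.
#' @param value_range declared domain: `"unit"` (values in \[0,1\]),
#'   `"uint8"` (integers in \[0,255\]), `"uint16"` (integers in \[0,65535\])
#'   or `"hu"` (Hounsfield units, unrestricted).
#' @param spacing optional numeric length-2, mm per pixel `(row, col)`.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(pixels, value_range = c("unit", "uint8", "uint16", "hu"),
                       spacing = NULL) {
  value_range <- match.arg(value_range)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_input("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_input("pixels must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop_input("pixels must be finite")
  if (value_range == "unit" && (min(pixels) < 0 || max(pixels) > 1))
    stop_input("value_range 'unit' requires pixels in [0, 1]")
  if (value_range == "uint8" && (min(pixels) < 0 || max(pixels) > 255))
    stop_input("value_range 'uint8' requires pixels in [0, 255]")
  if (!is.null(spacing)) {
    if (!is.numeric(spacing) || length(spacing) != 2L || any(spacing <= 0))
      stop_input("spacing must be two positive numbers (mm per pixel)")
  }
  structure(list(pixels = unname(pixels), value_range = value_range,
                 spacing = spacing),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d, %s, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$value_range,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.image_grid <- function(x, ...) x$pixels

# Accept either an image_grid or a bare matrix in internal code paths.
as_pixels <- function(img) {
  if (inherits(img, "image_grid")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else stop_input("expected an image_grid or numeric matrix")
}

#' Construct a binary segmentation mask
#'
#' @param pixels matrix with values in `{0, 1}` (logical accepted).
#' @param role `"prediction"` (a segmentation S) or `"truth"` (gold mask G).
#' @return object of class `seg_mask`; pixels stored as an integer matrix.
#' @export
seg_mask <- function(pixels, role = c("prediction", "truth")) {
  role <- match.arg(role)
  if (is.logical(pixels)) pixels <- pixels + 0L
  if (!is.matrix(pixels) || !all(pixels %in% c(0, 1)))
    stop_input("mask pixels must be a matrix with values in {0, 1}")
  m <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  structure(list(pixels = m, role = role), class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask %d x %d (%s), %d positive>\n",
              nrow(x$pixels), ncol(x$pixels), x$role, sum(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.seg_mask <- function(x, ...) x$pixels

as_mask_pixels <- function(m) {
  if (inherits(m, "seg_mask")) return(m$pixels)
  if (is.logical(m)) m <- m + 0L
  if (is.matrix(m) && all(m %in% c(0, 1)))
    return(matrix(as.integer(m), nrow(m), ncol(m)))
  stop_input("expected a seg_mask or binary matrix")
}

## ---------------------------------------------------------------- PNG -----

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- .cpp_crc32(body)
  c(writeBin(length(data), raw(), size = 4L, endian = "big"),
    body,
    u32_be(crc))
}

u32_be <- function(x) {
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

# memCompress(type = "gzip") emits a zlib-framed stream (0x78 header +
# deflate + Adler-32), which is exactly the IDAT payload PNG requires.
# Verified against the stream's own Adler-32 as a guard.
zlib_compress <- function(data) {
  z <- memCompress(data, type = "gzip")
  stopifnot(as.integer(z[1]) == 0x78,
            identical(tail(z, 4L), u32_be(.cpp_adler32(data))))
  z
}

#' Write a grayscale PNG
#'
#' `"unit"` images are quantized to 16-bit depth (`round(v * 65535)`), so the
#' worst-case round-trip error is `1/(2*65535)`; `"uint8"` images are written
#' at 8-bit depth and round-trip bit-exactly.
#'
#' @param img an [image_grid] with `value_range` `"unit"` or `"uint8"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (!inherits(img, "image_grid"))
    stop_input("write_png expects an image_grid; see write_mask_png for masks")
  px <- img$pixels
  if (img$value_range == "unit") {
    q <- round(px * 65535)
    depth <- 16L
    samp <- rbind(as.raw(q %/% 256), as.raw(q %% 256))  # big-endian pairs
  } else if (img$value_range == "uint8") {
    q <- round(px)
    depth <- 8L
    samp <- matrix(as.raw(q), nrow = 1L)
  } else {
    stop_input("write_png supports value_range 'unit' or 'uint8' only; ",
               "window/normalize HU images first")
  }
  h <- nrow(px); w <- ncol(px)
  # samp columns follow R's column-major order over (row, col); regroup into
  # scanlines: scanline r = pixels (r, 1..w).
  bytes_per_px <- depth %/% 8L
  sm <- matrix(samp, nrow = bytes_per_px)          # one column per pixel
  pix_index <- as.vector(outer(seq_len(w), seq_len(h),
                               function(cc, rr) (cc - 1L) * h + rr))
  sm <- sm[, pix_index, drop = FALSE]              # row-major pixel order
  scan <- matrix(as.vector(sm), nrow = w * bytes_per_px)  # one col per line
  lines <- rbind(matrix(as.raw(0L), 1L, h), scan)  # filter byte 0
  ihdr <- c(writeBin(w, raw(), size = 4L, endian = "big"),
            writeBin(h, raw(), size = 4L, endian = "big"),
            as.raw(c(depth, 0L, 0L, 0L, 0L)))      # grayscale, no interlace
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_compress(as.vector(lines))),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a grayscale PNG
#'
#' @param path PNG file; must be single-channel (8- or 16-bit). RGB input is
#'   rejected: convert explicitly (e.g. via [rgb_to_yuv]) rather than relying
#'   on silent channel averaging.
#' @param value_range domain to decode into: `"unit"` keeps the \[0,1\]
#'   scale `png::readPNG` produces; `"uint8"` rescales an 8-bit file back to
#'   integer \[0,255\].
#' @return an [image_grid].
#' @export
read_png <- function(path, value_range = c("unit", "uint8")) {
  value_range <- match.arg(value_range)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 2L) a <- a[, , 1L]            # grayscale + alpha
    else stop_input("RGB PNG where grayscale expected: convert explicitly")
  }
  if (value_range == "uint8") {
    image_grid(round(a * 255), value_range = "uint8")
  } else {
    image_grid(a, value_range = "unit")
  }
}

#' Write/read a binary mask PNG (`{0,1}` in memory, `{0,255}` on disk)
#' @param mask a [seg_mask] or binary matrix.
#' @param path PNG path.
#' @return `write_mask_png`: `path` invisibly; `read_mask_png`: a [seg_mask].
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_pixels(mask)
  write_png(image_grid(m * 255, value_range = "uint8"), path)
}

#' @rdname write_mask_png
#' @param role role of the mask being read.
#' @export
read_mask_png <- function(path, role = c("truth", "prediction")) {
  role <- match.arg(role)
  img <- read_png(path, value_range = "uint8")
  px <- img$pixels
  if (!all(px %in% c(0, 255)))
    stop_input("mask PNG must contain only values 0 and 255")
  seg_mask(px == 255, role = role)
}

## -------------------------------------------------------------- DICOM -----

read_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}
read_u32 <- function(bytes, pos) {
  read_u16(bytes, pos) + 65536 * read_u16(bytes, pos + 2L)
}

#' Read a single-frame grayscale DICOM slice
#'
#' Minimal reader for explicit-VR little-endian, single-frame, monochrome
#' DICOM, the storage format of CT slice archives. Stored values are mapped
#' through the rescale slope/intercept tags to Hounsfield units; pixel
#' spacing is propagated when present.
#'
#' @param path DICOM file.
#' @return an [image_grid] with `value_range = "hu"`.
#' @export
read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop_input("DICOM parse error: missing DICM magic in ", path)
  tags <- list()
  pos <- 133L
  pixel_raw <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(bytes)) {
    group <- read_u16(bytes, pos)
    elem <- read_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_input("DICOM parse error: implicit VR or corrupt element at ",
                 "offset ", pos - 1L, " (only explicit-VR little-endian ",
                 "is supported)")
    if (vr %in% long_vrs) {
      len <- read_u32(bytes, pos + 8L)
      vpos <- pos + 12L
    } else {
      len <- read_u16(bytes, pos + 6L)
      vpos <- pos + 8L
    }
    if (len == 4294967295)
      stop_input("unsupported DICOM: undefined-length element ",
                 sprintf("(%04x,%04x)", group, elem))
    key <- sprintf("%04x,%04x", group, elem)
    if (group == 0x7fe0L && elem == 0x0010L) {
      pixel_raw <- bytes[vpos:(vpos + len - 1L)]
      break
    }
    if (len > 0L && vr %in% c("US", "UL", "DS", "IS", "CS", "UI", "LO")) {
      val <- bytes[vpos:(vpos + len - 1L)]
      tags[[key]] <- if (vr == "US") read_u16(val, 1L)
      else if (vr == "UL") read_u32(val, 1L)
      else trimws(rawToChar(val[val != as.raw(0)]))
    }
    pos <- vpos + len
  }
  ts <- tags[["0002,0010"]]
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop_input("unsupported DICOM transfer syntax: ", ts,
               " (only explicit-VR little-endian is supported)")
  if (is.null(pixel_raw))
    stop_input("DICOM parse error: no PixelData element in ", path)
  nframes <- suppressWarnings(as.integer(tags[["0028,0008"]] %||% "1"))
  if (!is.na(nframes) && nframes > 1L)
    stop_input("unsupported DICOM: multi-frame object (", nframes, " frames)")
  spp <- tags[["0028,0002"]] %||% 1L
  photo <- tags[["0028,0004"]] %||% "MONOCHROME2"
  if (spp != 1L || !startsWith(photo, "MONOCHROME"))
    stop_input("unsupported DICOM: color transfer (SamplesPerPixel=", spp,
               ", PhotometricInterpretation=", photo, ")")
  rows <- tags[["0028,0010"]]
  cols <- tags[["0028,0011"]]
  if (is.null(rows) || is.null(cols))
    stop_input("DICOM parse error: missing Rows/Columns")
  bits <- tags[["0028,0100"]] %||% 16L
  signed <- (tags[["0028,0103"]] %||% 0L) == 1L
  n <- rows * cols
  stored <- if (bits == 16L) {
    readBin(pixel_raw, "integer", n = n, size = 2L, endian = "little",
            signed = signed)
  } else if (bits == 8L) {
    readBin(pixel_raw, "integer", n = n, size = 1L, signed = signed)
  } else stop_input("unsupported DICOM: BitsAllocated=", bits)
  if (length(stored) < n)
    stop_input("DICOM parse error: PixelData shorter than Rows*Columns")
  slope <- as.numeric(tags[["0028,1053"]] %||% "1")
  intercept <- as.numeric(tags[["0028,1052"]] %||% "0")
  hu <- slope * stored + intercept
  spacing <- NULL
  if (!is.null(tags[["0028,0030"]])) {
    sp <- as.numeric(strsplit(tags[["0028,0030"]], "\\\\")[[1]])
    if (length(sp) == 2L && all(is.finite(sp))) spacing <- sp
  }
  image_grid(matrix(hu, nrow = rows, ncol = cols, byrow = TRUE),
             value_range = "hu", spacing = spacing)
}

## ------------------------------------------------------------- config -----

#' Default run configuration
#'
#' Nested settings consumed by the pipeline stages. Notable defaults: network
#' dropout 0.5, 2x2 stride-2 pooling, 10 cross-validation folds, 128x128
#' working resolution, Hounsfield window \[-1000, 400\].
#'
#' @return a named nested list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = ".",
    preprocess = list(
      normalize = TRUE, resize = TRUE, equalize = TRUE, edge = TRUE,
      size = c(128L, 128L), equalize_clip = 3, hu_window = c(-1000, 400)),
    thresholdseg = list(
      k = 2L, nests = 25L, iters = 100L, discovery_q = 0.25, sigma = 10,
      delta = 2.5, min_area = 4L, levels = 256L),
    lbp = list(n = 8L, radius = 1L, grid = 1L, normalize = FALSE),
    deepnet = list(
      depth = "tiny", beta = 1, dropout = 0.5, chi = 1e-4, classes = 2L,
      input_size = c(128L, 128L), pool_window = 2L,
      lr = 1e-3, batch = 4L, epochs = 50L),
    metrics = list(folds = 10L)
  ), class = "run_config")
}

config_checks <- list(
  "seed" = function(v) is.numeric(v) && length(v) == 1 && v == round(v),
  "out_dir" = function(v) is.character(v) && length(v) == 1,
  "preprocess.normalize" = function(v) isTRUE(v) || isFALSE(v),
  "preprocess.resize" = function(v) isTRUE(v) || isFALSE(v),
  "preprocess.equalize" = function(v) isTRUE(v) || isFALSE(v),
  "preprocess.edge" = function(v) isTRUE(v) || isFALSE(v),
  "preprocess.size" = function(v) is.numeric(v) && length(v) == 2 &&
    all(v >= 8) && all(v == round(v)),
  "preprocess.equalize_clip" = function(v) is.numeric(v) && length(v) == 1 &&
    v > 0,
  "preprocess.hu_window" = function(v) is.numeric(v) && length(v) == 2 &&
    v[2] > v[1],
  "thresholdseg.k" = function(v) is.numeric(v) && v >= 1 && v == round(v),
  "thresholdseg.nests" = function(v) is.numeric(v) && v >= 2 && v == round(v),
  "thresholdseg.iters" = function(v) is.numeric(v) && v >= 1 && v == round(v),
  "thresholdseg.discovery_q" = function(v) is.numeric(v) && v > 0 && v < 1,
  "thresholdseg.sigma" = function(v) is.numeric(v) && v > 0,
  "thresholdseg.delta" = function(v) is.numeric(v) && v > 1 && v <= 3,
  "thresholdseg.min_area" = function(v) is.numeric(v) && v >= 0 &&
    v == round(v),
  "thresholdseg.levels" = function(v) is.numeric(v) && v >= 2 && v == round(v),
  "lbp.n" = function(v) v %in% c(4, 8, 16),
  "lbp.radius" = function(v) is.numeric(v) && v >= 1,
  "lbp.grid" = function(v) is.numeric(v) && v >= 1 && v == round(v),
  "lbp.normalize" = function(v) isTRUE(v) || isFALSE(v),
  "deepnet.depth" = function(v) v %in% c("tiny", "vgg19"),
  "deepnet.beta" = function(v) is.numeric(v) && v > 0,
  "deepnet.dropout" = function(v) is.numeric(v) && v >= 0 && v < 1,
  "deepnet.chi" = function(v) is.numeric(v) && v >= 0,
  "deepnet.classes" = function(v) is.numeric(v) && v >= 2 && v == round(v),
  "deepnet.input_size" = function(v) is.numeric(v) && length(v) == 2 &&
    all(v >= 8),
  "deepnet.pool_window" = function(v) identical(as.numeric(v), 2),
  "deepnet.lr" = function(v) is.numeric(v) && v > 0,
  "deepnet.batch" = function(v) is.numeric(v) && v >= 1 && v == round(v),
  "deepnet.epochs" = function(v) is.numeric(v) && v >= 1 && v == round(v),
  "metrics.folds" = function(v) is.numeric(v) && v >= 2 && v == round(v)
)

merge_validate <- function(defaults, user, prefix = NULL) {
  for (key in names(user)) {
    path <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(defaults))
      stop_input("unknown configuration key: ", path)
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop_input("configuration key ", path, " must be a section")
      defaults[[key]] <- merge_validate(defaults[[key]], user[[key]], path)
    } else {
      chk <- config_checks[[path]]
      if (!is.null(chk) && !isTRUE(chk(user[[key]])))
        stop_input("invalid value for configuration key ", path)
      v <- user[[key]]
      if (is.numeric(defaults[[key]]) && is.numeric(v)) {
        storage.mode(v) <- storage.mode(defaults[[key]])
      }
      defaults[[key]] <- v
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' Missing keys take the documented defaults; unknown keys are rejected;
#' every value is checked against its constraint before any computation.
#'
#' @param path YAML file. An empty file yields [default_config()].
#' @return validated `run_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop_input("configuration must be a YAML mapping")
  structure(merge_validate(unclass(default_config()), user),
            class = "run_config")
}

#' Serialize a run configuration back to YAML
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
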