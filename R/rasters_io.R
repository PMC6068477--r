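#' Single-band guidance image
#'
#' A guidance image is the one-band representation of a hyperspectral cube
#' (typically its first principal component) that steers the neighbor
#' search. Values are expected in `[0, 1]`; use [normalize_guidance()] to
#' rescale an arbitrary band.
#'
#' @param values Numeric matrix, one value per pixel (`rows x cols`).
#' @return An object of class `guidance_image` with fields `rows`, `cols`
#'   and `values`.
#' @seealso [normalize_guidance()], [read_raster()]
#' @export
guidance_image <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("guidance image requires a non-empty numeric matrix")
  if (any(!is.finite(values)))
    stop("guidance image contains non-finite values")
  structure(
    list(rows = nrow(values), cols = ncol(values), values = values),
    class = "guidance_image"
  )
}

#' Per-class probability map stack
#'
#' Holds one posterior probability raster per class, as produced by a
#' pixel-wise classifier. Per pixel the class probabilities must lie in
#' `[0, 1]` and sum to 1 within `tolerance`; external classifiers carry
#' rounding, so a `renormalize` flag rescales near-simplex rows instead of
#' failing.
#'
#' @param values Numeric array `rows x cols x n_classes`.
#' @param tolerance Allowed absolute deviation of each per-pixel sum from 1.
#' @param renormalize If `TRUE`, divide each pixel's probabilities by their
#'   sum instead of raising an error when the sum deviates by more than
#'   `tolerance` (sums must still be positive).
#' @return An object of class `probability_maps` with fields `rows`, `cols`,
#'   `n_classes` and `values`.
#' @export
probability_maps <- function(values, tolerance = 1e-6, renormalize = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("probability maps require a rows x cols x n_classes array")
  d <- dim(values)
  if (d[3] < 2L) stop("probability maps require at least 2 classes")
  if (any(!is.finite(values)))
    stop("probability maps contain non-finite values")
  if (any(values < 0 | values > 1))
    stop("probability values must lie in [0, 1]")
  slab <- matrix(values, d[1] * d[2], d[3])
  sums <- rowSums(slab)
  bad <- which(abs(sums - 1) > tolerance)
  if (length(bad) > 0L) {
    if (renormalize) {
      if (any(sums <= 0)) stop("cannot renormalize: zero probability sum")
      slab <- slab / sums
      values <- array(slab, d)
    } else {
      i <- bad[1L]
      stop(sprintf(
        "probabilities at pixel (row %d, col %d) sum to %.8g, not 1 (tolerance %g)",
        (i - 1L) %% d[1], (i - 1L) %/% d[1], sums[i], tolerance
      ))
    }
  }
  structure(
    list(rows = d[1], cols = d[2], n_classes = d[3], values = values),
    class = "probability_maps"
  )
}

default_class_names <- function(n_classes) {
  base <- c("tumor", "normal", "hypervascularized", "background")
  if (n_classes <= length(base)) base[seq_len(n_classes)]
  else c(base, paste0("class", seq(length(base), n_classes - 1L)))
}

default_palette <- function(n_classes) {
  base <- c("red", "green", "blue", "black")
  if (n_classes <= length(base)) base[seq_len(n_classes)]
  else c(base, grDevices::rainbow(n_classes - length(base)))
}

#' Per-pixel class label map
#'
#' Integer labels are 0-based class indices. The default vocabulary is the
#' four intraoperative tissue classes -- tumor, normal, hypervascularized,
#' background -- rendered red, green, blue and black.
#'
#' @param labels Integer matrix of class labels in `[0, n_classes)`.
#' @param class_names Ordered class names; their order defines the label
#'   encoding (class 0 first).
#' @param palette Ordered colors used by [render_classmap()], one per class.
#' @param n_classes Number of classes; defaults to `length(class_names)`.
#' @return An object of class `class_map`.
#' @export
class_map <- function(labels, class_names = NULL, palette = NULL,
                      n_classes = NULL) {
  labels <- as.matrix(labels)
  if (any(!is.finite(labels)) || any(labels != round(labels)))
    stop("labels must be integers")
  storage.mode(labels) <- "integer"
  if (is.null(n_classes)) {
    n_classes <- if (!is.null(class_names)) length(class_names)
                 else max(4L, max(labels) + 1L)
  }
  if (is.null(class_names)) class_names <- default_class_names(n_classes)
  if (is.null(palette)) palette <- default_palette(n_classes)
  class_names <- as.character(class_names)
  if (length(class_names) != n_classes)
    stop("class_names must have length n_classes")
  if (length(palette) != n_classes)
    stop("palette must have length n_classes")
  if (any(labels < 0L) || any(labels >= n_classes))
    stop("labels must lie in [0, n_classes)")
  structure(
    list(rows = nrow(labels), cols = ncol(labels), labels = labels,
         n_classes = n_classes, class_names = class_names, palette = palette),
    class = "class_map"
  )
}

#' Min-max normalize a guidance band to [0, 1]
#'
#' Affine rescale of a raw one-band image so that the minimum maps to 0 and
#' the maximum to 1. A constant image carries no guidance information and is
#' mapped to all zeros rather than dividing by zero. The operation is
#' idempotent.
#'
#' @param raw Numeric matrix (or a `guidance_image`).
#' @return A [guidance_image()] with values in `[0, 1]`.
#' @export
normalize_guidance <- function(raw) {
  if (inherits(raw, "guidance_image")) raw <- raw$values
  raw <- as.matrix(raw)
  if (any(!is.finite(raw)))
    stop("guidance image contains NaN or infinite values")
  rng <- range(raw)
  span <- rng[2] - rng[1]
  vals <- if (span == 0) array(0, dim(raw)) else (raw - rng[1]) / span
  guidance_image(matrix(vals, nrow(raw), ncol(raw)))
}

# ---- ENVI-style header + flat binary dialect --------------------------------
# Text header `<path>.hdr` (samples, lines, bands, data type, interleave bsq,
# byte order 0) next to a flat little-endian binary: float32 (data type 4)
# for guidance/probabilities, int32 (data type 3) for class maps. Bands are
# band-sequential, row-major within each band.

envi_paths <- function(path) {
  if (grepl("\\.hdr$", path)) {
    list(hdr = path, dat = sub("\\.hdr$", "", path))
  } else {
    list(hdr = paste0(path, ".hdr"), dat = path)
  }
}

write_envi_header <- function(hdr, rows, cols, bands, data_type) {
  writeLines(c(
    "ENVI",
    paste0("samples = ", cols),
    paste0("lines = ", rows),
    paste0("bands = ", bands),
    paste0("data type = ", data_type),
    "interleave = bsq",
    "byte order = 0"
  ), hdr)
}

read_envi_header <- function(hdr) {
  if (!file.exists(hdr)) stop("missing ENVI header: ", hdr)
  lines <- readLines(hdr, warn = FALSE)
  kv <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- tolower(trimws(sub("=.*$", "", kv)))
  vals <- trimws(sub("^[^=]*=", "", kv))
  get <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("ENVI header missing field '", key, "' in ", hdr)
    vals[i]
  }
  h <- list(
    cols = as.integer(get("samples")),
    rows = as.integer(get("lines")),
    bands = as.integer(get("bands")),
    data_type = as.integer(get("data type")),
    interleave = tolower(get("interleave")),
    byte_order = as.integer(get("byte order"))
  )
  if (anyNA(unlist(h[c("cols", "rows", "bands", "data_type", "byte_order")])))
    stop("unparseable ENVI header field in ", hdr)
  if (h$interleave != "bsq") stop("only bsq interleave is supported")
  if (h$byte_order != 0L) stop("only little-endian (byte order 0) is supported")
  if (!h$data_type %in% c(3L, 4L)) stop("unsupported ENVI data type ", h$data_type)
  h
}

read_envi_bands <- function(path) {
  p <- envi_paths(path)
  h <- read_envi_header(p$hdr)
  n <- h$rows * h$cols * h$bands
  size <- 4L
  expected <- n * size
  actual <- file.info(p$dat)$size
  if (is.na(actual) || actual != expected)
    stop(sprintf("data file %s has %s bytes, header implies %d", p$dat,
                 ifelse(is.na(actual), "no", as.character(actual)), expected))
  what <- if (h$data_type == 4L) "numeric" else "integer"
  raw <- readBin(p$dat, what = what, n = n, size = size, endian = "little")
  # bsq, row-major within band -> array [rows, cols, bands]
  arr <- array(NA_real_, c(h$rows, h$cols, h$bands))
  per <- h$rows * h$cols
  for (b in seq_len(h$bands)) {
    band <- raw[((b - 1L) * per + 1L):(b * per)]
    arr[, , b] <- matrix(band, h$rows, h$cols, byrow = TRUE)
  }
  list(header = h, values = arr)
}

write_envi_bands <- function(values, path, data_type) {
  p <- envi_paths(path)
  d <- dim(values)
  write_envi_header(p$hdr, d[1], d[2], d[3], data_type)
  con <- file(p$dat, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    band <- as.vector(t(values[, , b, drop = TRUE]))
    if (data_type == 4L) {
      writeBin(as.numeric(band), con, size = 4L, endian = "little")
    } else {
      writeBin(as.integer(band), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

# ---- delimited-text dialect for small fixtures ------------------------------
# Plain comma-separated matrix; multi-band stacks carry a one-line comment
# header "# rows cols bands" and band-sequential row blocks.

is_text_path <- function(path) grepl("\\.(csv|txt)$", path, ignore.case = TRUE)

read_text_bands <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^#", first)) {
    dims <- as.integer(strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]])
    if (length(dims) != 3L || anyNA(dims))
      stop("malformed text raster header in ", path)
    m <- as.matrix(read.table(path, sep = ",", header = FALSE, skip = 1L))
    if (nrow(m) != dims[1] * dims[3] || ncol(m) != dims[2])
      stop("text raster body does not match its header in ", path)
    arr <- array(NA_real_, dims)
    for (b in seq_len(dims[3]))
      arr[, , b] <- m[((b - 1L) * dims[1] + 1L):(b * dims[1]), , drop = FALSE]
    arr
  } else {
    m <- as.matrix(read.table(path, sep = ",", header = FALSE))
    array(m, c(nrow(m), ncol(m), 1L))
  }
}

write_text_bands <- function(values, path, multi_band_header) {
  d <- dim(values)
  stacked <- do.call(rbind, lapply(seq_len(d[3]), function(b)
    values[, , b, drop = TRUE]))
  if (multi_band_header || d[3] > 1L) {
    writeLines(sprintf("# %d %d %d", d[1], d[2], d[3]), path)
    suppressWarnings(write.table(
      stacked, path, sep = ",", row.names = FALSE, col.names = FALSE,
      append = TRUE
    ))
  } else {
    write.table(stacked, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a raster from disk
#'
#' Reads either the ENVI-style dialect (text `<path>.hdr` header plus flat
#' little-endian binary, band-sequential) or, for paths ending in `.csv` /
#' `.txt`, a comma-delimited matrix (multi-band stacks carry a `# rows cols
#' bands` comment line). Type invariants are validated on load:
#' probabilities must form a per-pixel simplex, class labels must be
#' in-range integers.
#'
#' @param path Path to the data file (or its `.hdr` header).
#' @param kind One of `"guidance"`, `"probabilities"`, `"classmap"`.
#' @param tolerance,renormalize Passed to [probability_maps()] when
#'   `kind = "probabilities"`.
#' @param class_names,palette Passed to [class_map()] when
#'   `kind = "classmap"`.
#' @return A [guidance_image()], [probability_maps()] or [class_map()].
#' @export
read_raster <- function(path, kind = c("guidance", "probabilities", "classmap"),
                        tolerance = 1e-6, renormalize = FALSE,
                        class_names = NULL, palette = NULL) {
  kind <- match.arg(kind)
  arr <- if (is_text_path(path)) read_text_bands(path) else read_envi_bands(path)$values
  bands <- dim(arr)[3]
  if (kind == "guidance") {
    if (bands != 1L) stop("guidance raster must have exactly 1 band, found ", bands)
    guidance_image(arr[, , 1L])
  } else if (kind == "probabilities") {
    if (bands < 2L) stop("probability raster must have at least 2 bands")
    probability_maps(arr, tolerance = tolerance, renormalize = renormalize)
  } else {
    if (bands != 1L) stop("classification raster must have exactly 1 band")
    labels <- arr[, , 1L]
    args <- list(labels = labels)
    if (!is.null(class_names)) {
      args$class_names <- class_names
      args$n_classes <- length(class_names)
    }
    if (!is.null(palette)) args$palette <- palette
    do.call(class_map, args)
  }
}

#' Write a raster to disk
#'
#' Inverse of [read_raster()]. Paths ending in `.csv` / `.txt` select the
#' delimited-text dialect; anything else writes the ENVI-style header +
#' binary pair. Binary values are stored as 32-bit floats (guidance,
#' probabilities) or 32-bit integers (class maps); doubles are quantized to
#' float32 precision on write, after which the round trip is bit-exact.
#'
#' @param obj A [guidance_image()], [probability_maps()] or [class_map()].
#' @param path Output data-file path (the `.hdr` is placed alongside).
#' @return `path`, invisibly.
#' @export
write_raster <- function(obj, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write raster: no such directory ", dir)
  if (inherits(obj, "guidance_image")) {
    arr <- array(obj$values, c(obj$rows, obj$cols, 1L))
    if (is_text_path(path)) write_text_bands(arr, path, FALSE)
    else write_envi_bands(arr, path, 4L)
  } else if (inherits(obj, c("probability_maps", "optimized_probabilities"))) {
    if (is_text_path(path)) write_text_bands(obj$values, path, TRUE)
    else write_envi_bands(obj$values, path, 4L)
  } else if (inherits(obj, "class_map")) {
    arr <- array(obj$labels, c(obj$rows, obj$cols, 1L))
    if (is_text_path(path)) write_text_bands(arr, path, FALSE)
    else write_envi_bands(arr, path, 3L)
  } else {
    stop("unsupported raster object of class ", paste(class(obj), collapse = "/"))
  }
  invisible(path)
}

#' Render a classification map to a color image
#'
#' Writes a PNG in which every pixel takes its class color from the map's
#' palette (default: tumor red, normal green, hypervascularized blue,
#' background black).
#'
#' @param map A [class_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_classmap <- function(map, path) {
  stopifnot(inherits(map, "class_map"))
  if (length(map$palette) == 0L) stop("class map has an empty palette")
  if (max(map$labels) >= length(map$palette))
    stop("label outside palette range")
  rgb <- grDevices::col2rgb(map$palette) / 255
  img <- array(0, c(map$rows, map$cols, 3L))
  for (ch in 1:3)
    img[, , ch] <- matrix(rgb[ch, map$labels + 1L], map$rows, map$cols)
  png::writePNG(img, path)
  invisible(path)
}
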