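#' Filtering parameters
#'
#' Bundles the tunables of the KNN guided filter. `lambda_weight = 1` and
#' `k_neighbors = 40` are the defaults reported as a good compromise for
#' intraoperative tissue mapping; `wsize = 14` rows is the reference search
#' window that reproduces whole-image results.
#'
#' @param lambda_weight Non-negative spatial balance weight. 0 ignores the
#'   pixel coordinates entirely; larger values favour the local
#'   neighborhood.
#' @param k_neighbors Number of nearest neighbors averaged per pixel.
#' @param metric `"euclidean"` (2-norm) or `"manhattan"` (1-norm) distance
#'   in feature space.
#' @param coordinate_mode `"raw"` uses the integer row/column offsets in the
#'   spatial features (the default; with `lambda_weight = 1` the spatial
#'   terms dominate beyond a few pixels, which is what makes a narrow row
#'   band sufficient); `"normalized"` divides the 0-based row by
#'   `rows - 1` and the column by `cols - 1` first.
#' @param wsize Search-window height in image rows: an even integer `>= 2`,
#'   or `"full"` for a whole-image search.
#' @param include_self If `TRUE` the query pixel itself may be selected as
#'   one of its own neighbors; by default it is excluded, so a full-image
#'   search evaluates `n_pixels - 1` distances per pixel.
#' @param strategy Neighbor selection strategy: `"bounded_insert"` keeps a
#'   K-slot ascending array initialised with `+Inf` sentinels and inserts
#'   any candidate whose distance does not exceed the current last slot;
#'   `"full_sort"` sorts all candidate distances (canonical
#'   distance-then-index order) and takes the first K. Both yield the same
#'   neighbor sets on tie-free data.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(lambda_weight = 1, k_neighbors = 40L,
                          metric = c("euclidean", "manhattan"),
                          coordinate_mode = c("raw", "normalized"),
                          wsize = 14L, include_self = FALSE,
                          strategy = c("bounded_insert", "full_sort")) {
  metric <- match.arg(metric)
  coordinate_mode <- match.arg(coordinate_mode)
  strategy <- match.arg(strategy)
  if (!is.numeric(lambda_weight) || length(lambda_weight) != 1L ||
      !is.finite(lambda_weight) || lambda_weight < 0)
    stop("lambda_weight must be a single non-negative number")
  if (!is.numeric(k_neighbors) || length(k_neighbors) != 1L ||
      k_neighbors < 1 || k_neighbors != round(k_neighbors))
    stop("k_neighbors must be a positive integer")
  validate_wsize(wsize)
  structure(
    list(lambda_weight = lambda_weight, k_neighbors = as.integer(k_neighbors),
         metric = metric, coordinate_mode = coordinate_mode, wsize = wsize,
         include_self = isTRUE(include_self), strategy = strategy),
    class = "filter_params"
  )
}

validate_wsize <- function(wsize) {
  if (identical(wsize, "full")) return(invisible(wsize))
  if (!is.numeric(wsize) || length(wsize) != 1L || !is.finite(wsize) ||
      wsize != round(wsize) || wsize < 2 || wsize %% 2 != 0)
    stop("wsize must be \"full\" or an even integer >= 2")
  invisible(wsize)
}

#' Build the feature vector of one pixel
#'
#' The neighbor search measures distances between triples
#' `(I(q), lambda * l(q), lambda * h(q))`: the guidance intensity of the
#' pixel plus its spatially weighted row and column coordinates. Coordinates
#' are 0-based; in `"normalized"` mode they are divided by `rows - 1` /
#' `cols - 1` before scaling by `lambda_weight`.
#'
#' @param img A [guidance_image()].
#' @param row,col 0-based pixel coordinates.
#' @param params A [filter_params()].
#' @return A named numeric vector of class `feature_vector` with elements
#'   `intensity`, `row_feature`, `col_feature`.
#' @export
build_feature <- function(img, row, col, params = filter_params()) {
  stopifnot(inherits(img, "guidance_image"), inherits(params, "filter_params"))
  if (row < 0 || row >= img$rows || col < 0 || col >= img$cols)
    stop(sprintf("pixel (%d, %d) outside %d x %d image", row, col,
                 img$rows, img$cols))
  lam <- params$lambda_weight
  if (params$coordinate_mode == "normalized") {
    rf <- lam * if (img$rows > 1L) row / (img$rows - 1L) else 0
    cf <- lam * if (img$cols > 1L) col / (img$cols - 1L) else 0
  } else {
    rf <- lam * row
    cf <- lam * col
  }
  structure(c(intensity = img$values[row + 1L, col + 1L],
              row_feature = rf, col_feature = cf),
            class = "feature_vector")
}

#' Distance between two pixel feature vectors
#'
#' Euclidean: `sqrt(dI^2 + dr^2 + dc^2)`; Manhattan: `|dI| + |dr| + |dc|`,
#' where `dI` is the intensity difference and `dr`, `dc` the (lambda-scaled)
#' coordinate feature differences. The 1-norm always dominates the 2-norm,
#' and with `lambda_weight = 0` both collapse to `|dI|`.
#'
#' @param a,b Feature vectors from [build_feature()] (built under the same
#'   image and parameters).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return A single non-negative number.
#' @export
feature_distance <- function(a, b, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  d <- unclass(a) - unclass(b)
  if (metric == "euclidean") sqrt(sum(d^2)) else sum(abs(d))
}
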