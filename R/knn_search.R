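#' Row-band search-window bounds for one pixel
#'
#' The windowed search restricts each pixel's candidate neighbors to a band
#' of `wsize` image rows, half above and half below the query pixel: the
#' inclusive row interval `[row - wsize/2, row + wsize/2 - 1]`, clamped to
#' the image. At the first row the band holds `wsize/2` rows and grows with
#' each further row until the steady state of `wsize` rows is reached; an
#' analogous shrink happens at the bottom border. Rows (not columns) are
#' banded so that candidate pixels are contiguous in row-major storage.
#'
#' @param row 0-based row of the query pixel.
#' @param rows Total number of image rows.
#' @param wsize Even window height in rows, or `"full"`.
#' @param cols Optional column count; when given, the candidate pixel count
#'   `n_rows * cols` is included.
#' @return An object of class `window_spec` with fields `row_lo`, `row_hi`
#'   (inclusive, 0-based), `n_rows` and (if `cols` is supplied)
#'   `n_candidates`.
#' @examples
#' # steady-state and first-row windows of a 479 x 552 scene
#' window_bounds(239, 479, 14, cols = 552)$n_candidates  # 7728
#' window_bounds(0, 479, 14, cols = 552)$n_candidates    # 3864
#' @export
window_bounds <- function(row, rows, wsize, cols = NULL) {
  row <- as.integer(row)
  rows <- as.integer(rows)
  if (row < 0L || row >= rows) stop("row outside [0, rows)")
  if (identical(wsize, "full")) {
    lo <- 0L
    hi <- rows - 1L
  } else {
    validate_wsize(wsize)
    half <- as.integer(wsize) %/% 2L
    lo <- max(0L, row - half)
    hi <- min(rows - 1L, row + half - 1L)
  }
  out <- list(row_lo = lo, row_hi = hi, n_rows = hi - lo + 1L)
  if (!is.null(cols)) out$n_candidates <- out$n_rows * as.integer(cols)
  structure(out, class = "window_spec")
}

#' Initialize an empty bounded neighbor list
#'
#' A K-slot ascending array of (distance, pixel index) pairs, initialised
#' with `+Inf` sentinel distances so the first K insertions are always
#' accepted.
#'
#' @param k Number of neighbors to keep.
#' @return An object of class `neighbor_list` with `distances` and
#'   `indices` vectors of length `k`.
#' @export
neighbor_list <- function(k) {
  stopifnot(k >= 1)
  structure(list(distances = rep(Inf, k), indices = rep(NA_integer_, k)),
            class = "neighbor_list")
}

#' Insert a candidate into a bounded neighbor list
#'
#' The bounded-insert selection step: if the new distance is smaller than or
#' equal to the last (largest) element, it replaces that element and the
#' list is re-sorted ascending with index tracking; otherwise the list is
#' unchanged. Applied over a row-major scan of a pixel's window this yields
#' its K nearest neighbors without sorting the full candidate set.
#'
#' @param list A [neighbor_list()].
#' @param d Candidate distance (non-negative).
#' @param idx Candidate 0-based row-major linear pixel index.
#' @return The updated `neighbor_list`.
#' @export
bounded_insert <- function(list, d, idx) {
  stopifnot(inherits(list, "neighbor_list"))
  k <- length(list$distances)
  if (d <= list$distances[k]) {
    list$distances[k] <- d
    list$indices[k] <- as.integer(idx)
    ord <- order(list$distances)  # stable: ties keep earlier entries first
    list$distances <- list$distances[ord]
    list$indices <- list$indices[ord]
  }
  list
}

knn_result <- function(res, img, params, mode) {
  structure(
    list(distances = res$distances, indices = res$indices,
         k = params$k_neighbors, rows = img$rows, cols = img$cols,
         n_distances = res$n_distances, params = params, mode = mode),
    class = "neighbor_lists"
  )
}

# cheap structural assertions run after every search
validate_neighbor_lists <- function(nl) {
  d <- nl$distances
  idx <- nl$indices
  if (any(!is.finite(d)) || any(d < 0))
    stop("neighbor distances must be finite and non-negative")
  if (nrow(d) != nl$k) stop("neighbor lists must have exactly k entries")
  if (nrow(d) > 1L && any(d[-1L, , drop = FALSE] < d[-nrow(d), , drop = FALSE]))
    stop("neighbor distances must be ascending")
  n <- ncol(idx)
  self <- seq_len(n) - 1L
  if (!nl$params$include_self && any(idx == rep(self, each = nrow(idx))))
    stop("self pixel present in its own neighbor list")
  if (any(matrixStats_anyDup(idx))) stop("duplicate neighbor indices")
  invisible(nl)
}

# column-wise duplicate check without apply() overhead: sort rows per column
# is overkill for k ~ 40, a simple loop over columns is fine at test scales
matrixStats_anyDup <- function(idx) {
  vapply(seq_len(ncol(idx)), function(j) anyDuplicated(idx[, j]) > 0L,
         logical(1))
}

run_knn <- function(img, params, wsize, strategy) {
  stopifnot(inherits(img, "guidance_image"), inherits(params, "filter_params"))
  w <- if (identical(wsize, "full")) 0L else as.integer(wsize)
  res <- .knn_search_impl(
    img$values, params$lambda_weight, params$k_neighbors, w,
    match(params$metric, c("euclidean", "manhattan")) - 1L,
    params$coordinate_mode == "normalized", params$include_self,
    match(strategy, c("bounded_insert", "full_sort")) - 1L
  )
  out <- knn_result(res, img, params,
                    if (w == 0L) "full" else sprintf("wsize%d", w))
  validate_neighbor_lists(out)
  out
}

#' Windowed K-nearest-neighbor search
#'
#' Finds, for every pixel, its `k_neighbors` nearest neighbors in feature
#' space among the pixels of its row-band search window (see
#' [window_bounds()]), scanning candidates row-major and keeping the query
#' pixel itself out of its own list unless `include_self` is set. With the
#' defaults (`lambda_weight = 1`, `k_neighbors = 40`, raw coordinates,
#' `wsize = 14`) the result is identical to a whole-image search: the 40
#' nearest candidates lie within a Chebyshev radius of 3 pixels (48
#' candidates at feature distance below 7), while every pixel outside the
#' 14-row band is at spatial distance at least 7.
#'
#' @param img A [guidance_image()].
#' @param params A [filter_params()]; `params$wsize` may be an even integer
#'   or `"full"`.
#' @return An object of class `neighbor_lists`: `distances` and `indices`
#'   are `k x n_pixels` matrices whose column `q` holds pixel `q`'s
#'   neighbors ascending by distance (columns ordered by 0-based row-major
#'   pixel index, as are the index entries); `n_distances` counts the
#'   distance evaluations performed.
#' @export
knn_windowed <- function(img, params = filter_params()) {
  run_knn(img, params, params$wsize, params$strategy)
}

#' Whole-image K-nearest-neighbor reference search
#'
#' Exhaustive reference: computes the distance from each pixel to every
#' other pixel of the image (`n_pixels - 1` distances per pixel), selects
#' the first `k_neighbors` in ascending (distance, linear index) order --
#' the order a stable merge sort of the row-major candidate scan produces.
#' Quadratic in the pixel count; meant for validation at small scales.
#'
#' @inheritParams knn_windowed
#' @return A `neighbor_lists` object, as for [knn_windowed()].
#' @export
knn_full_oracle <- function(img, params = filter_params()) {
  n <- img$rows * img$cols
  if (n - 1L < params$k_neighbors)
    stop("image has only ", n - 1L, " candidate neighbors per pixel but k = ",
         params$k_neighbors)
  run_knn(img, params, "full", "full_sort")
}
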