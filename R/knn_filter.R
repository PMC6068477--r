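#' Filtered per-class probabilities from neighbor averaging
#'
#' For every pixel `q` and class, the optimized probability is the sum of
#' the class probabilities of `q`'s K nearest neighbors divided by K --
#' i.e. the neighborhood mean posterior. Averaging simplex rows preserves
#' the simplex, so per-pixel sums remain 1 whenever the input maps sum to 1.
#'
#' @param P A [probability_maps()] with the same dimensions as the searched
#'   image.
#' @param neighbors A `neighbor_lists` object from [knn_windowed()] or
#'   [knn_full_oracle()].
#' @param k Divisor of the neighbor sum; defaults to the K of the search.
#' @return An object of class `optimized_probabilities` with fields `rows`,
#'   `cols`, `n_classes`, `values` (array `rows x cols x n_classes`).
#' @export
optimized_probability <- function(P, neighbors, k = neighbors$k) {
  stopifnot(inherits(P, "probability_maps"),
            inherits(neighbors, "neighbor_lists"))
  if (P$rows != neighbors$rows || P$cols != neighbors$cols)
    stop("probability maps and neighbor lists have mismatched dimensions")
  rows <- P$rows
  cols <- P$cols
  idx <- neighbors$indices  # 0-based row-major linear pixel indices
  # convert to 1-based positions into a column-major rows x cols slab
  pos <- (idx %/% cols) + rows * (idx %% cols) + 1L
  kk <- nrow(idx)
  vals <- array(NA_real_, c(rows, cols, P$n_classes))
  for (cl in seq_len(P$n_classes)) {
    slab <- as.vector(P$values[, , cl])
    sums <- colSums(matrix(slab[pos], kk, ncol(idx)))
    # neighbor columns are row-major ordered; reshape accordingly
    vals[, , cl] <- matrix(sums / k, rows, cols, byrow = TRUE)
  }
  structure(
    list(rows = rows, cols = cols, n_classes = P$n_classes, values = vals),
    class = "optimized_probabilities"
  )
}

#' Assign the label with the highest optimized probability
#'
#' Per pixel, the label is the smallest class index achieving the maximum
#' optimized probability (a first-strictly-greater update over the classes,
#' so exact ties go to the lowest index -- with the default vocabulary,
#' conservative toward tumor).
#'
#' @param O An `optimized_probabilities` object (a [probability_maps()] is
#'   also accepted, giving the plain argmax labeling).
#' @param class_names,palette Optional vocabulary for the resulting map.
#' @return A [class_map()].
#' @export
assign_labels <- function(O, class_names = NULL, palette = NULL) {
  stopifnot(inherits(O, c("optimized_probabilities", "probability_maps")))
  m <- matrix(O$values, O$rows * O$cols, O$n_classes)
  lab <- max.col(m, ties.method = "first") - 1L
  class_map(matrix(lab, O$rows, O$cols),
            class_names = class_names, palette = palette,
            n_classes = O$n_classes)
}

#' KNN guided filtering of a classification probability map
#'
#' End-to-end spatial-spectral refinement: normalize the guidance band,
#' search each pixel's K nearest neighbors in feature space (within the
#' row-band window of `params$wsize`, or the whole image for
#' `wsize = "full"`), average the neighbors' class probabilities, and label
#' each pixel with its highest filtered probability. Deterministic given
#' inputs and parameters; every pixel's output depends only on probability
#' values inside its own window.
#'
#' @param img A [guidance_image()] (re-normalized internally; the
#'   normalization is idempotent).
#' @param P A [probability_maps()] of the same spatial dimensions.
#' @param params A [filter_params()].
#' @return A [class_map()] of filtered labels.
#' @export
filter_classification <- function(img, P, params = filter_params()) {
  stopifnot(inherits(img, "guidance_image"), inherits(P, "probability_maps"))
  if (img$rows != P$rows || img$cols != P$cols)
    stop("guidance image and probability maps have mismatched dimensions")
  img <- normalize_guidance(img$values)
  nb <- knn_windowed(img, params)
  O <- optimized_probability(P, nb)
  assign_labels(O)
}
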