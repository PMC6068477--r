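# Independent brute-force KNN oracle built on base R dist(): assembles the
# full feature matrix in row-major pixel order, takes the all-pairs distance
# matrix, and selects the first k candidates in ascending (distance, index)
# order. Quadratic in memory and time -- only for tiny images.

feature_matrix <- function(img, params) {
  rows <- img$rows
  cols <- img$cols
  r <- rep(seq_len(rows) - 1L, each = cols)
  cl <- rep(seq_len(cols) - 1L, times = rows)
  lam <- params$lambda_weight
  if (params$coordinate_mode == "normalized") {
    rf <- lam * if (rows > 1L) r / (rows - 1L) else rep(0, length(r))
    cf <- lam * if (cols > 1L) cl / (cols - 1L) else rep(0, length(cl))
  } else {
    rf <- lam * r
    cf <- lam * cl
  }
  cbind(as.vector(t(img$values)), rf, cf)
}

brute_force_knn <- function(img, params, window_rows = NULL) {
  fm <- feature_matrix(img, params)
  n <- nrow(fm)
  k <- params$k_neighbors
  method <- if (params$metric == "euclidean") "euclidean" else "manhattan"
  D <- as.matrix(stats::dist(fm, method = method))
  dd <- matrix(NA_real_, k, n)
  idx <- matrix(NA_integer_, k, n)
  cols <- img$cols
  for (q in seq_len(n)) {
    cand <- seq_len(n)
    if (!is.null(window_rows)) {
      wb <- window_bounds((q - 1L) %/% cols, img$rows, window_rows)
      pix_row <- (cand - 1L) %/% cols
      cand <- cand[pix_row >= wb$row_lo & pix_row <= wb$row_hi]
    }
    if (!params$include_self) cand <- setdiff(cand, q)
    ord <- cand[order(D[cand, q], cand)]
    sel <- ord[seq_len(k)]
    dd[, q] <- D[sel, q]
    idx[, q] <- sel - 1L
  }
  list(distances = dd, indices = idx)
}

# tie-free random guidance image under a fixed seed
random_guidance <- function(rows, cols, seed) {
  set.seed(seed)
  guidance_image(matrix(runif(rows * cols), rows, cols))
}

# small random simplex probability stack
random_probs <- function(rows, cols, n_classes, seed) {
  set.seed(seed)
  m <- matrix(rexp(rows * cols * n_classes), rows * cols, n_classes)
  m <- m / rowSums(m)
  probability_maps(array(m, c(rows, cols, n_classes)))
}
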