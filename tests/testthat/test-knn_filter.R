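# hand-built neighbor lists for a 1 x 3 image (pixels 0, 1, 2 row-major)
manual_neighbors <- function(indices, k, rows, cols) {
  structure(
    list(distances = matrix(0, k, rows * cols), indices = indices, k = k,
         rows = rows, cols = cols,
         params = filter_params(k_neighbors = k)),
    class = "neighbor_lists"
  )
}

test_that("optimized probability is the neighbor mean of each class map", {
  # 1x3 image, 2 classes; every pixel's neighbors are the other two pixels
  P <- probability_maps(array(c(0.4, 0.6, 0.1,    # class 0 by pixel 0,1,2
                                0.6, 0.4, 0.9),   # class 1
                              c(1, 3, 2)))
  nb <- manual_neighbors(matrix(c(1L, 2L, 0L, 2L, 0L, 1L), 2, 3), 2, 1, 3)
  O <- optimized_probability(P, nb)
  # pixel 0 averages pixels 1 and 2: class 0 -> (0.6 + 0.1)/2
  expect_equal(O$values[1, 1, 1], 0.35)
  expect_equal(O$values[1, 1, 2], 0.65)
  expect_equal(O$values[1, 2, 1], 0.25)  # pixel 1: (0.4 + 0.1)/2
  expect_equal(O$values[1, 3, 1], 0.50)  # pixel 2: (0.4 + 0.6)/2

  # identical probability rows everywhere: the mean is idempotent
  Pc <- probability_maps(array(rep(c(0.1, 0.2, 0.3, 0.4), each = 12),
                               c(3, 4, 4)))
  nbc <- knn_windowed(random_guidance(3, 4, seed = 1),
                      filter_params(k_neighbors = 5L, wsize = "full"))
  Oc <- optimized_probability(Pc, nbc)
  expect_equal(Oc$values, Pc$values, tolerance = 1e-12)
})

test_that("optimized probabilities preserve the per-pixel simplex", {
  img <- random_guidance(8, 8, seed = 77)
  P <- random_probs(8, 8, 4, seed = 78)
  nb <- knn_windowed(img, filter_params(k_neighbors = 10L, wsize = 6L))
  O <- optimized_probability(P, nb)
  sums <- rowSums(matrix(O$values, 64, 4))
  expect_true(all(abs(sums - 1) <= 1e-6))
  expect_true(all(O$values >= 0 & O$values <= 1))
})

test_that("labels take the first class attaining the maximum", {
  O <- structure(list(rows = 1L, cols = 3L, n_classes = 4L,
                      values = array(c(0.1, 0.4, 0.25,
                                       0.6, 0.4, 0.25,
                                       0.2, 0.1, 0.25,
                                       0.1, 0.1, 0.25), c(1, 3, 4))),
                 class = "optimized_probabilities")
  cm <- assign_labels(O)
  expect_identical(as.vector(cm$labels), c(1L, 0L, 0L))
})

test_that("uniform probabilities give all-first-class labels", {
  img <- random_guidance(10, 10, seed = 5)
  P <- probability_maps(array(0.25, c(10, 10, 4)))
  cm <- filter_classification(img, P, filter_params(k_neighbors = 8L,
                                                    wsize = 6L))
  expect_true(all(cm$labels == 0L))
})

test_that("one-hot maps constant across windows pass through unchanged", {
  # two one-hot bands of rows, far enough apart that no window spans both
  rows <- 24; cols <- 10
  lab <- matrix(ifelse(row(matrix(0, rows, cols)) <= 12, 0L, 2L), rows, cols)
  arr <- array(0, c(rows, cols, 4))
  for (cl in 0:3) arr[, , cl + 1][lab == cl] <- 1
  P <- probability_maps(arr)
  img <- random_guidance(rows, cols, seed = 6)
  p <- filter_params(k_neighbors = 10L, wsize = 4L)
  cm <- filter_classification(img, P, p)
  # pixels whose windows stay inside one band keep their label
  keep <- row(lab) <= 10 | row(lab) >= 15
  expect_true(all(cm$labels[keep] == lab[keep]))
})

test_that("windowed and whole-image searches give identical labels", {
  sc <- generate_scene(scene_spec(rows = 40, cols = 30, seed = 9))
  m14 <- filter_classification(sc$guidance, sc$probabilities,
                               filter_params(wsize = 14L))
  mfull <- filter_classification(sc$guidance, sc$probabilities,
                                 filter_params(wsize = "full"))
  expect_identical(m14$labels, mfull$labels)
})

test_that("class permutation of the input maps permutes the output labels", {
  img <- random_guidance(12, 12, seed = 31)
  P <- random_probs(12, 12, 4, seed = 32)
  p <- filter_params(k_neighbors = 6L, wsize = 6L)
  base <- filter_classification(img, P, p)
  perm <- c(3L, 1L, 4L, 2L)  # new order of old classes (1-based)
  Pp <- probability_maps(P$values[, , perm])
  permuted <- filter_classification(img, Pp, p)
  # label in permuted map = position of old label within perm (0-based)
  expect_identical(permuted$labels,
                   matrix(match(base$labels + 1L, perm) - 1L, 12, 12))
})

test_that("a pixel's label depends only on probabilities in its window", {
  img <- random_guidance(30, 10, seed = 41)
  P <- random_probs(30, 10, 4, seed = 42)
  p <- filter_params(k_neighbors = 8L, wsize = 6L)
  base <- filter_classification(img, P, p)
  # perturb probabilities only in rows 20..29; windows of rows 0..10
  # (row interval [r-3, r+2]) never reach them
  m <- matrix(P$values, 300, 4)
  far <- as.vector(row(matrix(0, 30, 10)) >= 21)  # 1-based rows 21..30
  set.seed(43)
  repl <- matrix(rexp(sum(far) * 4), ncol = 4)
  m[far, ] <- repl / rowSums(repl)
  P2 <- probability_maps(array(m, c(30, 10, 4)))
  changed <- filter_classification(img, P2, p)
  expect_identical(changed$labels[1:11, ], base$labels[1:11, ])
})

test_that("dimension mismatches are rejected", {
  img <- random_guidance(5, 5, seed = 51)
  P <- random_probs(6, 5, 4, seed = 52)
  expect_error(filter_classification(img, P, filter_params(k_neighbors = 3L,
                                                           wsize = 4L)),
               "mismatched")
  nb <- knn_windowed(img, filter_params(k_neighbors = 3L, wsize = 4L))
  expect_error(optimized_probability(P, nb), "mismatched")
})
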