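test_that("window_bounds reproduces the published candidate-count arithmetic", {
  # 552-column scene, 14-row window: 7728 at steady state, 3864 at row 0
  steady <- window_bounds(239, 479, 14, cols = 552)
  expect_identical(steady$n_rows, 14L)
  expect_identical(steady$n_candidates, 7728L)
  first <- window_bounds(0, 479, 14, cols = 552)
  expect_identical(first$n_rows, 7L)
  expect_identical(first$n_candidates, 3864L)
  expect_identical(first$row_lo, 0L)
  expect_identical(first$row_hi, 6L)

  # 329-column scene: 4606 and 2303
  expect_identical(window_bounds(150, 379, 14, cols = 329)$n_candidates, 4606L)
  expect_identical(window_bounds(0, 379, 14, cols = 329)$n_candidates, 2303L)

  # interval is [row - wsize/2, row + wsize/2 - 1]
  w <- window_bounds(100, 479, 14)
  expect_identical(c(w$row_lo, w$row_hi), c(93L, 106L))
})

test_that("window_bounds clamps at borders and validates input", {
  # wsize >= 2*rows spans the whole image from any row
  for (r in c(0, 5, 9)) {
    w <- window_bounds(r, 10, 20)
    expect_identical(c(w$row_lo, w$row_hi), c(0L, 9L))
  }
  full <- window_bounds(3, 10, "full", cols = 5)
  expect_identical(full$n_candidates, 50L)
  # bottom border: the band shrinks symmetrically to wsize/2 + 1 rows
  bottom <- window_bounds(478, 479, 14)
  expect_identical(bottom$n_rows, 8L)
  expect_identical(bottom$row_hi, 478L)
  expect_error(window_bounds(0, 10, 7), "even")
  expect_error(window_bounds(10, 10, 4), "outside")
})

test_that("bounded_insert reproduces the worked insertion example", {
  # ascending 40-slot array whose last element (position 39) is 98;
  # a new distance of 61 evicts it and lands at its sorted position
  nl <- neighbor_list(40)
  dists <- c(sort(runif(39, 0, 90)), 98)
  for (i in seq_along(dists)) nl <- bounded_insert(nl, dists[i], i - 1L)
  expect_equal(nl$distances[40], 98)

  nl2 <- bounded_insert(nl, 61, 555L)
  expect_equal(length(nl2$distances), 40L)
  expect_false(98 %in% nl2$distances)       # 98 evicted
  expect_true(555L %in% nl2$indices)        # 61 present, index tracked
  expect_false(is.unsorted(nl2$distances))  # re-sorted ascending
  pos <- which(nl2$indices == 555L)
  expect_equal(nl2$distances[pos], 61)

  # a distance greater than the last element leaves the list unchanged
  nl3 <- bounded_insert(nl2, nl2$distances[40] + 1, 999L)
  expect_identical(nl3, nl2)
})

test_that("bounded_insert always accepts into sentinel slots", {
  # the first k insertions are always accepted: sentinels are +Inf
  nl <- neighbor_list(3)
  expect_true(all(is.infinite(nl$distances)))
  nl <- bounded_insert(nl, 50, 0L)
  nl <- bounded_insert(nl, 10, 1L)
  nl <- bounded_insert(nl, 30, 2L)
  expect_equal(nl$distances, c(10, 30, 50))
  expect_equal(nl$indices, c(1L, 2L, 0L))
})

test_that("windowed search matches the independent brute-force oracle", {
  img <- random_guidance(16, 12, seed = 101)
  for (metric in c("euclidean", "manhattan")) {
    for (mode in c("raw", "normalized")) {
      p <- filter_params(k_neighbors = 10L, metric = metric,
                         coordinate_mode = mode, wsize = 6L)
      got <- knn_windowed(img, p)
      want <- brute_force_knn(img, p, window_rows = 6L)
      expect_identical(got$indices, want$indices)
      expect_equal(got$distances, want$distances, tolerance = 1e-12)
    }
  }
})

test_that("full-image oracle matches the independent brute force", {
  img <- random_guidance(9, 8, seed = 202)
  for (metric in c("euclidean", "manhattan")) {
    p <- filter_params(k_neighbors = 12L, metric = metric)
    got <- knn_full_oracle(img, p)
    want <- brute_force_knn(img, p)
    expect_identical(got$indices, want$indices)
    expect_equal(got$distances, want$distances, tolerance = 1e-12)
  }
  # on a 3x3 image with k = 8 the neighbor set is all other pixels
  img3 <- random_guidance(3, 3, seed = 203)
  got <- knn_full_oracle(img3, filter_params(k_neighbors = 8L))
  for (q in 1:9)
    expect_setequal(got$indices[, q], setdiff(0:8, q - 1L))
})

test_that("each pixel of a two-pixel image has the other as sole neighbor", {
  img <- guidance_image(matrix(c(0.2, 0.9), 1, 2))
  p <- filter_params(k_neighbors = 1L, wsize = "full")
  got <- knn_windowed(img, p)
  expect_identical(as.vector(got$indices), c(1L, 0L))
})

test_that("bounded-insert and full-sort strategies agree on tie-free data", {
  img <- random_guidance(20, 15, seed = 303)
  for (metric in c("euclidean", "manhattan")) {
    p1 <- filter_params(k_neighbors = 8L, metric = metric, wsize = 8L,
                        strategy = "bounded_insert")
    p2 <- filter_params(k_neighbors = 8L, metric = metric, wsize = 8L,
                        strategy = "full_sort")
    a <- knn_windowed(img, p1)
    b <- knn_windowed(img, p2)
    expect_identical(a$indices, b$indices)
    expect_equal(a$distances, b$distances, tolerance = 1e-12)
  }
})

test_that("neighbor lists are sorted, unique, self-free and length k", {
  for (seed in c(11, 12, 13)) {
    img <- random_guidance(14, 10, seed = seed)
    nb <- knn_windowed(img, filter_params(k_neighbors = 7L, wsize = 6L))
    expect_identical(dim(nb$indices), c(7L, 140L))
    for (q in seq_len(ncol(nb$indices))) {
      expect_false(is.unsorted(nb$distances[, q]))
      expect_identical(anyDuplicated(nb$indices[, q]), 0L)
      expect_false((q - 1L) %in% nb$indices[, q])
    }
  }
})

test_that("neighbor lists are unchanged by widening the window beyond 14", {
  img <- random_guidance(40, 20, seed = 404)
  base <- knn_windowed(img, filter_params(wsize = 14L))
  for (w in list(16L, 20L, "full")) {
    expect_identical(knn_windowed(img, filter_params(wsize = w))$indices,
                     base$indices)
  }
})

test_that("too-small windows are rejected with guidance to fix them", {
  img <- random_guidance(10, 3, seed = 505)
  # first-row window of wsize 2 holds 1 row x 3 cols = 2 candidates < k
  expect_error(knn_windowed(img, filter_params(k_neighbors = 5L, wsize = 2L)),
               "increase wsize or decrease k")
  expect_error(knn_full_oracle(guidance_image(matrix(runif(4), 2, 2)),
                               filter_params(k_neighbors = 10L)),
               "k = 10")
})

test_that("the distance-evaluation counter matches the search space size", {
  img <- random_guidance(8, 6, seed = 606)
  n <- 48
  full <- knn_full_oracle(img, filter_params(k_neighbors = 5L))
  expect_equal(full$n_distances, n * (n - 1))
  win <- knn_windowed(img, filter_params(k_neighbors = 5L, wsize = 4L))
  expected <- sum(vapply(0:7, function(r)
    window_bounds(r, 8, 4, cols = 6)$n_candidates - 1L, integer(1)) * 6L)
  expect_equal(win$n_distances, expected)
})
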