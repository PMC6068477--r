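#' Specification of a synthetic scene
#'
#' Describes a seeded synthetic stand-in for the filter's upstream inputs:
#' a ground-truth label map built from contiguous class blobs on a
#' background, a PCA-like one-band guidance image (per-class mean intensity
#' plus Gaussian noise, min-max normalized), and SVM-like posterior maps (a
#' softmax over sharpness-scaled class affinities with unit-variance logit
#' noise). Blob-shaped truth, not i.i.d. labels, because spatial coherence
#' is the premise the filter exploits; the default radii keep K = 40
#' neighborhoods class-dominated.
#'
#' @param rows,cols Scene dimensions (default 128 x 128: wide enough for
#'   steady-state 14-row windows, small enough for the quadratic
#'   whole-image reference search).
#' @param n_classes Number of classes; the last one is the background on
#'   which the other classes' blobs are deposited.
#' @param n_blobs Blobs deposited per non-background class.
#' @param blob_radius Length-2 range of blob radii in pixels.
#' @param class_means Per-class guidance intensity means in `[0, 1]`; must
#'   be distinct.
#' @param noise_sd Standard deviation of the Gaussian intensity noise.
#' @param sharpness Scale of the true-class affinity in the posterior
#'   logits; larger values push the maps toward one-hot ground truth.
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(rows = 128L, cols = 128L, n_classes = 4L,
                       n_blobs = 3L, blob_radius = c(8, 16),
                       class_means = c(0.85, 0.55, 0.25, 0.05),
                       noise_sd = 0.05, sharpness = 3, seed = 1L) {
  if (rows < 1L || cols < 1L) stop("rows and cols must be positive")
  if (n_classes < 2L) stop("at least 2 classes required")
  if (length(class_means) != n_classes)
    stop("class_means must have one entry per class")
  if (anyDuplicated(class_means)) stop("class mean intensities must be distinct")
  if (any(class_means < 0 | class_means > 1))
    stop("class mean intensities must lie in [0, 1]")
  if (length(blob_radius) != 2L || blob_radius[1] > blob_radius[2] ||
      blob_radius[1] <= 0)
    stop("blob_radius must be a positive (min, max) pair")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (sharpness <= 0) stop("sharpness must be positive")
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         n_classes = as.integer(n_classes), n_blobs = as.integer(n_blobs),
         blob_radius = as.numeric(blob_radius),
         class_means = as.numeric(class_means),
         noise_sd = as.numeric(noise_sd), sharpness = as.numeric(sharpness),
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

with_scene_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a seeded synthetic scene
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `guidance` ([guidance_image()]),
#'   `probabilities` ([probability_maps()]), `truth` ([class_map()]) and
#'   the echoed `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_seed(spec$seed, {
    rows <- spec$rows
    cols <- spec$cols
    bg <- spec$n_classes - 1L
    labels <- matrix(bg, rows, cols)
    rr <- matrix(seq_len(rows) - 1L, rows, cols)
    cc <- matrix(rep(seq_len(cols) - 1L, each = rows), rows, cols)
    for (cl in seq_len(spec$n_classes - 1L) - 1L) {
      for (b in seq_len(spec$n_blobs)) {
        radius <- runif(1, spec$blob_radius[1], spec$blob_radius[2])
        cr <- runif(1, 0, rows - 1)
        ccol <- runif(1, 0, cols - 1)
        labels[(rr - cr)^2 + (cc - ccol)^2 <= radius^2] <- cl
      }
    }
    raw <- matrix(spec$class_means[labels + 1L], rows, cols) +
      rnorm(rows * cols, sd = spec$noise_sd)
    guidance <- normalize_guidance(raw)
    logits <- array(rnorm(rows * cols * spec$n_classes),
                    c(rows, cols, spec$n_classes))
    for (cl in seq_len(spec$n_classes) - 1L)
      logits[, , cl + 1L] <- logits[, , cl + 1L] +
        spec$sharpness * (labels == cl)
    m <- matrix(logits, rows * cols, spec$n_classes)
    m <- exp(m - apply(m, 1L, max))
    m <- m / rowSums(m)
    probs <- probability_maps(array(m, c(rows, cols, spec$n_classes)))
    list(guidance = guidance, probabilities = probs,
         truth = class_map(labels,
                           class_names = default_class_names(spec$n_classes),
                           n_classes = spec$n_classes),
         spec = spec)
  })
}

#' Inject label noise into probability maps
#'
#' Selects pixels independently with probability `flip_rate` and swaps
#' their two largest class probabilities, creating salt-and-pepper label
#' noise for the filter to clean while preserving the per-pixel simplex.
#'
#' @param P A [probability_maps()].
#' @param flip_rate Per-pixel swap probability in `[0, 1]`.
#' @param seed Integer seed for the pixel selection.
#' @return A new [probability_maps()] object.
#' @export
degrade_probabilities <- function(P, flip_rate, seed = 1L) {
  stopifnot(inherits(P, "probability_maps"))
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must lie in [0, 1]")
  with_scene_seed(seed, {
    n <- P$rows * P$cols
    m <- matrix(P$values, n, P$n_classes)
    hit <- which(runif(n) < flip_rate)
    for (i in hit) {
      ord <- order(m[i, ], decreasing = TRUE)
      m[i, ord[1:2]] <- m[i, ord[2:1]]
    }
    probability_maps(array(m, c(P$rows, P$cols, P$n_classes)))
  })
}
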