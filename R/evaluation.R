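#' Binary difference map between two classification maps
#'
#' Marks every pixel whose labels differ between the two maps -- the binary
#' maps used to compare each window-size configuration against the
#' reference one. Symmetric in its arguments.
#'
#' @param a,b [class_map()] objects of equal dimensions.
#' @return An object of class `diff_map` with fields `mask` (0/1 integer
#'   matrix), `n_pixels`, `n_different` and `pct_different` (percent of all
#'   pixels).
#' @export
diff_map <- function(a, b) {
  stopifnot(inherits(a, "class_map"), inherits(b, "class_map"))
  if (a$rows != b$rows || a$cols != b$cols)
    stop("classification maps have mismatched dimensions")
  mask <- matrix(as.integer(a$labels != b$labels), a$rows, a$cols)
  n <- a$rows * a$cols
  nd <- sum(mask)
  structure(
    list(mask = mask, n_pixels = n, n_different = nd,
         pct_different = 100 * nd / n),
    class = "diff_map"
  )
}

#' Class-pair breakdown of classification differences
#'
#' Assigns every differing pixel to exactly one unordered label-pair
#' category. Pairs involving the first class of the vocabulary (tumor, by
#' default) are reported separately -- a swap between tumor and normal
#' tissue matters far more to the surgical application than one between,
#' say, blood vessels and background -- and all remaining pairs are pooled
#' as `"others"`. Percents are relative to the total number of differing
#' pixels; with no differences all counts and percents are 0 and
#' `no_differences` is set.
#'
#' @param a A [class_map()] to evaluate.
#' @param ref The reference [class_map()]; must share the class vocabulary.
#' @return An object of class `pair_breakdown`: a list with `table` (a
#'   data.frame of `category`, `count`, `percent`), `n_different` and
#'   `no_differences`.
#' @export
pair_breakdown <- function(a, ref) {
  stopifnot(inherits(a, "class_map"), inherits(ref, "class_map"))
  if (!identical(a$class_names, ref$class_names))
    stop("classification maps use different class vocabularies")
  if (a$rows != ref$rows || a$cols != ref$cols)
    stop("classification maps have mismatched dimensions")
  cn <- a$class_names
  nc <- a$n_classes
  diff <- a$labels != ref$labels
  la <- a$labels[diff]
  lr <- ref$labels[diff]
  nd <- length(la)
  categories <- c(paste0(cn[1], "_vs_", cn[-1]), "others")
  counts <- integer(length(categories))
  names(counts) <- categories
  if (nd > 0L) {
    involves_first <- la == 0L | lr == 0L
    other_class <- ifelse(la == 0L, lr, la)  # partner of the first class
    for (j in seq_len(nc - 1L)) {
      counts[j] <- sum(involves_first & other_class == j)
    }
    counts[length(counts)] <- sum(!involves_first)
  }
  percent <- if (nd > 0L) 100 * counts / nd else rep(0, length(counts))
  structure(
    list(table = data.frame(category = categories, count = as.integer(counts),
                            percent = as.numeric(percent),
                            row.names = NULL),
         n_different = nd, no_differences = nd == 0L),
    class = "pair_breakdown"
  )
}

#' Figure of merit for a time/accuracy trade-off
#'
#' `FoM = 1 / (t * err)`: strictly decreasing in both the execution time
#' `t` (seconds) and the disagreement `err` with the reference
#' configuration. `err` is taken as the percent of differing pixels, the
#' quantity tabulated alongside the timings; the fraction-scale value is
#' simply 100 times larger. Perfect agreement (`err = 0`) is reported as
#' `Inf` with attribute `perfect_agreement`, not as an arithmetic fault.
#'
#' @param time_s Positive execution time in seconds.
#' @param err_pct Non-negative disagreement, in percent of pixels.
#' @return A single number (possibly `Inf`).
#' @export
fom_compute <- function(time_s, err_pct) {
  if (!is.numeric(time_s) || time_s <= 0) stop("time_s must be positive")
  if (!is.numeric(err_pct) || err_pct < 0) stop("err_pct must be non-negative")
  if (err_pct == 0) return(structure(Inf, perfect_agreement = TRUE))
  1 / (time_s * err_pct)
}

#' Evaluate one classification map against a reference
#'
#' Combines [diff_map()], [pair_breakdown()] and [fom_compute()] into the
#' record kept per configuration of a sweep.
#'
#' @param map,ref [class_map()] objects sharing dimensions and vocabulary.
#' @param time_s Optional wall-clock seconds spent producing `map`
#'   (environment-dependent; reported, never comparable across machines).
#' @return An object of class `evaluation_result` with fields `n_pixels`,
#'   `n_different`, `pct_different`, `pair_breakdown`, `time_s`, `err_pct`,
#'   `fom` (percent-scale err) and `fom_fraction` (fraction-scale err).
#' @export
evaluate_against_reference <- function(map, ref, time_s = NA_real_) {
  dm <- diff_map(map, ref)
  pb <- pair_breakdown(map, ref)
  err <- dm$pct_different
  fom <- if (is.finite(time_s) && time_s > 0) fom_compute(time_s, err) else NA_real_
  fom_frac <- if (is.finite(time_s) && time_s > 0) fom_compute(time_s, err / 100)
              else NA_real_
  structure(
    list(n_pixels = dm$n_pixels, n_different = dm$n_different,
         pct_different = dm$pct_different, pair_breakdown = pb,
         time_s = time_s, err_pct = err, fom = as.numeric(fom),
         fom_fraction = as.numeric(fom_frac)),
    class = "evaluation_result"
  )
}

#' Sweep window sizes and metrics over one scene
#'
#' Runs the guided filter for every combination of `wsizes` and `metrics`,
#' then evaluates each configuration against a designated reference
#' configuration (by default the 14-row Euclidean window): difference
#' counts, class-pair breakdown, wall-clock timing and figure of merit.
#' Timings use this machine's clock and are not reproducible across
#' environments; the difference counts are deterministic.
#'
#' @param img A [guidance_image()].
#' @param P A [probability_maps()].
#' @param wsizes Vector of window sizes (even integers and/or `"full"`).
#' @param metrics Character vector drawn from `"euclidean"`, `"manhattan"`.
#' @param reference List with elements `wsize` and `metric` naming the
#'   reference configuration; it must appear in the grid.
#' @param params Base [filter_params()] supplying lambda, K and the other
#'   settings shared across the grid.
#' @param out_dir Optional directory; when given, `report.json` and
#'   `report.csv` are written there.
#' @return A data.frame with one row per configuration: `wsize`, `metric`,
#'   `time_s`, `n_different`, `pct_different`, `fom`, `fom_fraction`, one
#'   count column per pair category, and an `is_reference` flag. The full
#'   per-configuration [evaluate_against_reference()] records are attached
#'   as attribute `"evaluations"`, the label maps as `"maps"`.
#' @export
sweep_report <- function(img, P, wsizes = c("full", 14, 12, 10, 8, 6, 4, 2),
                         metrics = c("euclidean", "manhattan"),
                         reference = list(wsize = 14, metric = "euclidean"),
                         params = filter_params(), out_dir = NULL) {
  wlab <- vapply(wsizes, function(w) if (identical(w, "full")) "full"
                 else as.character(as.integer(w)), character(1))
  grid <- expand.grid(wsize = wlab, metric = metrics,
                      stringsAsFactors = FALSE)
  ref_lab <- if (identical(reference$wsize, "full")) "full"
             else as.character(as.integer(reference$wsize))
  ref_row <- which(grid$wsize == ref_lab & grid$metric == reference$metric)
  if (length(ref_row) != 1L)
    stop("reference configuration (wsize ", ref_lab, ", ", reference$metric,
         ") is not in the sweep grid")

  run_one <- function(wsize, metric) {
    p <- params
    p$wsize <- if (identical(wsize, "full")) "full" else as.integer(wsize)
    p$metric <- metric
    t0 <- proc.time()[["elapsed"]]
    map <- filter_classification(img, P, p)
    list(map = map, time_s = proc.time()[["elapsed"]] - t0)
  }
  runs <- Map(run_one, grid$wsize, grid$metric)
  ref_map <- runs[[ref_row]]$map

  evals <- lapply(runs, function(r)
    evaluate_against_reference(r$map, ref_map, time_s = r$time_s))
  pair_names <- evals[[1]]$pair_breakdown$table$category
  pair_cols <- t(vapply(evals, function(e) e$pair_breakdown$table$count,
                        integer(length(pair_names))))
  colnames(pair_cols) <- pair_names
  report <- cbind(
    data.frame(
      wsize = grid$wsize, metric = grid$metric,
      time_s = vapply(evals, `[[`, numeric(1), "time_s"),
      n_different = vapply(evals, `[[`, numeric(1), "n_different"),
      pct_different = vapply(evals, `[[`, numeric(1), "pct_different"),
      fom = vapply(evals, `[[`, numeric(1), "fom"),
      fom_fraction = vapply(evals, `[[`, numeric(1), "fom_fraction"),
      stringsAsFactors = FALSE
    ),
    as.data.frame(pair_cols)
  )
  report$is_reference <- seq_len(nrow(report)) == ref_row

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(report, file.path(out_dir, "report.csv"), sep = ",",
                row.names = FALSE)
    jsonlite::write_json(
      list(reference = list(wsize = ref_lab, metric = reference$metric),
           configurations = report),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  attr(report, "evaluations") <- evals
  attr(report, "maps") <- lapply(runs, `[[`, "map")
  report
}
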