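# Chance-level baselines: Monte Carlo null distributions of the dispersion
# measures over randomly generated inventories.

#' Generate a chance-level null distribution
#'
#' Draws `n_inventories` inventories of `inventory_size` points uniformly
#' on the unit-square pad and computes one dispersion statistic per
#' inventory. `"pairwise"` is [mean_pairwise_distance()], `"center_dist"`
#' [mean_distance_from_center()]; `"mode_brightness"` maps the points
#' through [xy_to_rgb()] for the given condition and averages the brightest
#' channel. The uniform sampling law is the maximum-entropy reading of
#' "by chance" over the pad.
#'
#' @param measure one of `"pairwise"`, `"center_dist"`, `"mode_brightness"`.
#' @param inventory_size points per inventory (at least 2 for `"pairwise"`).
#' @param n_inventories number of inventories.
#' @param condition used by `"mode_brightness"` only.
#' @param seed integer seed; with the same seed the result is
#'   bitwise-reproducible. The caller's RNG state is left untouched.
#' @return An object of class `null_distribution`: list with `measure`,
#'   `inventory_size`, `n_inventories`, `condition`, `seed`, `samples`,
#'   `mean`, `se` (Monte Carlo standard error of the mean).
#' @export
generate_null <- function(measure = c("pairwise", "center_dist",
                                      "mode_brightness"),
                          inventory_size, n_inventories, condition = "outer_edge",
                          seed = 1L) {
  measure <- match.arg(measure)
  assert_condition(condition)
  if (n_inventories < 1L) stop("n_inventories must be >= 1", call. = FALSE)
  if (measure == "pairwise" && inventory_size < 2L) {
    stop("pairwise measure needs inventory_size >= 2", call. = FALSE)
  }
  if (inventory_size < 1L) stop("inventory_size must be >= 1", call. = FALSE)
  samples <- local_seed(seed, {
    X <- matrix(stats::runif(n_inventories * inventory_size),
                nrow = n_inventories)
    Y <- matrix(stats::runif(n_inventories * inventory_size),
                nrow = n_inventories)
    switch(measure,
      pairwise = {
        pairs <- utils::combn(inventory_size, 2L)
        acc <- numeric(n_inventories)
        for (p in seq_len(ncol(pairs))) {
          i <- pairs[1L, p]; j <- pairs[2L, p]
          acc <- acc + sqrt((X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2)
        }
        acc / ncol(pairs)
      },
      center_dist = rowMeans(sqrt((X - 0.5)^2 + (Y - 0.5)^2)),
      mode_brightness = {
        rgb <- xy_to_rgb(as.vector(X), as.vector(Y), condition)
        bright <- matrix(pmax(rgb$r, rgb$g, rgb$b), nrow = n_inventories)
        rowMeans(bright)
      })
  })
  structure(list(measure = measure, inventory_size = as.integer(inventory_size),
                 n_inventories = as.integer(n_inventories),
                 condition = condition, seed = as.integer(seed),
                 samples = samples, mean = mean(samples),
                 se = stats::sd(samples) / sqrt(n_inventories)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %s, size %d, n %d, %s: mean %.5f (MC se %.2g), seed %d\n",
    x$measure, x$inventory_size, x$n_inventories, x$condition,
    x$mean, x$se, x$seed))
  invisible(x)
}

#' Empirical p-value against a null distribution
#'
#' Add-one estimator: for the upper tail,
#' `(1 + #\{samples >= observed\}) / (n + 1)`; mirrored for the lower tail.
#'
#' @param observed observed statistic.
#' @param null a [generate_null()] result.
#' @param tail `"upper"` or `"lower"`.
#' @return Probability in `(0, 1]`.
#' @export
empirical_p <- function(observed, null, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(inherits(null, "null_distribution"))
  s <- null$samples
  k <- if (tail == "upper") sum(s >= observed) else sum(s <= observed)
  (1 + k) / (length(s) + 1)
}
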