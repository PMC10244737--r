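# Color-phoneme identification: pool a dyad's colors per referent and merge
# statistically indistinguishable groups using the Pillai-Bartlett trace.

#' Pillai-Bartlett trace for two exemplar groups
#'
#' One-way two-group MANOVA on the 2-D pad coordinates: with H the
#' between-group and E the pooled within-group SSCP matrices, the statistic
#' is `trace(H (H + E)^-1)`, which for two groups lies in `[0, 1]`. Low
#' values mean the groups are not separated. The statistic is invariant
#' under rotation and translation of the plane.
#'
#' @param a,b two-column matrices (or data frames) of points, at least 3
#'   rows each.
#' @param ridge regularization added to the diagonal of `H + E` (scaled by
#'   its mean diagonal) when it is singular; if the system is degenerate
#'   even then, `NA` is returned.
#' @return The trace statistic, clamped to `[0, 1]`, or `NA`.
#' @export
pillai_score <- function(a, b, ridge = 1e-8) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 3L || nrow(b) < 3L) {
    stop("each group needs at least 3 points", call. = FALSE)
  }
  ma <- colMeans(a); mb <- colMeans(b)
  gm <- (nrow(a) * ma + nrow(b) * mb) / (nrow(a) + nrow(b))
  H <- nrow(a) * tcrossprod(ma - gm) + nrow(b) * tcrossprod(mb - gm)
  E <- crossprod(sweep(a, 2, ma)) + crossprod(sweep(b, 2, mb))
  total <- H + E
  inv <- tryCatch(solve(total), error = function(e) NULL)
  if (is.null(inv)) {
    total <- total + diag(ridge * mean(diag(total)) + ridge, nrow(total))
    inv <- tryCatch(solve(total), error = function(e) NULL)
    if (is.null(inv)) return(NA_real_)
  }
  min(max(sum(diag(H %*% inv)), 0), 1)
}

#' Identify color phonemes for a dyad
#'
#' Pools the dyad's color tokens (both players) per referent, then
#' iteratively merges the pair of groups with the lowest Pillai score while
#' that score is below `merge_threshold`. Ties break on the lowest
#' (smallest id, smallest id) pair, so the procedure is deterministic.
#' Groups with fewer than 3 exemplars cannot be scored and are left as
#' their own phonemes. The merge criterion is a reconstruction: a fixed
#' threshold on the trace, configurable.
#'
#' @param log a [game_log()].
#' @param merge_threshold merge while the lowest pairwise Pillai score is
#'   below this value (default 0.3).
#' @param successful_only use only successful trials' tokens (default
#'   `FALSE`: all tokens, as the inventories pool all colors used).
#' @return An object of class `inventory`: list with `phonemes` (list of
#'   data frames with columns `x`, `y`, `r`, `g`, `b`, `referent_id`),
#'   `labels` (the referent ids pooled into each phoneme), `trace` (data
#'   frame of merge events: `step`, `group_a`, `group_b`, `score`), and
#'   `merge_threshold`.
#' @export
identify_phonemes <- function(log, merge_threshold = 0.3,
                              successful_only = FALSE) {
  stopifnot(inherits(log, "game_log"))
  tk <- log$tokens
  if (successful_only) tk <- tk[tk$correct, , drop = FALSE]
  if (nrow(tk) == 0L) stop("no tokens to pool", call. = FALSE)
  cols <- c("x", "y", "r", "g", "b", "referent_id")
  groups <- lapply(split(tk[, cols], tk$referent_id), function(g) {
    rownames(g) <- NULL
    g
  })
  labels <- lapply(as.integer(names(groups)), identity)
  names(groups) <- NULL
  trace <- data.frame(step = integer(), group_a = character(),
                      group_b = character(), score = numeric())
  step <- 0L
  repeat {
    k <- length(groups)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (nrow(groups[[i]]) < 3L || nrow(groups[[j]]) < 3L) next
        sc <- pillai_score(groups[[i]][, c("x", "y")],
                           groups[[j]][, c("x", "y")])
        if (is.na(sc)) next
        key <- c(min(labels[[i]]), min(labels[[j]]))
        if (is.null(best) || sc < best$score - 1e-12 ||
            (abs(sc - best$score) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, score = sc, key = key)
        }
      }
    }
    if (is.null(best) || best$score >= merge_threshold) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step,
      group_a = paste(sort(labels[[best$i]]), collapse = "+"),
      group_b = paste(sort(labels[[best$j]]), collapse = "+"),
      score = best$score))
    groups[[best$i]] <- rbind(groups[[best$i]], groups[[best$j]])
    labels[[best$i]] <- sort(c(labels[[best$i]], labels[[best$j]]))
    groups[[best$j]] <- NULL
    labels[[best$j]] <- NULL
  }
  structure(list(phonemes = groups, labels = labels, trace = trace,
                 merge_threshold = merge_threshold),
            class = "inventory")
}

#' @export
print.inventory <- function(x, ...) {
  cat(sprintf("<inventory> %d phoneme(s) (threshold %.2f, %d merge(s))\n",
              length(x$phonemes), x$merge_threshold, nrow(x$trace)))
  for (i in seq_along(x$phonemes)) {
    cat(sprintf("  phoneme %d: referents {%s}, %d exemplars\n", i,
                paste(x$labels[[i]], collapse = ","), nrow(x$phonemes[[i]])))
  }
  invisible(x)
}

#' Phoneme centroids of an inventory
#'
#' @param inventory an [identify_phonemes()] result.
#' @return Data frame of per-phoneme mean `x`, `y`.
#' @export
phoneme_centroids <- function(inventory) {
  stopifnot(inherits(inventory, "inventory"))
  do.call(rbind, lapply(seq_along(inventory$phonemes), function(i) {
    g <- inventory$phonemes[[i]]
    data.frame(phoneme = i, x = mean(g$x), y = mean(g$y))
  }))
}
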