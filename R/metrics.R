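# Per-log statistics: success index, dispersion measures, extremeness,
# auto-/partner distance, rolling dispersion, and PCA-ellipse signal areas.

#' Success index of a game
#'
#' The per-round count of established referents `s` (see
#' [mastery_trajectory()]) is summed over rounds and normalized by
#' `12 * n_rounds`, the maximum possible cumulative count.
#'
#' @param log a [game_log()], or a mastery trajectory data frame.
#' @return A fraction in `[0, 1]`.
#' @export
success_index <- function(log) {
  traj <- if (inherits(log, "game_log")) log_mastery(log) else log
  if (nrow(traj) == 0L) stop("empty log", call. = FALSE)
  sum(traj$s) / (12 * nrow(traj))
}

#' Mean pairwise distance between points
#'
#' @param x,y coordinates of at least two points.
#' @return Mean Euclidean distance over all unordered pairs.
#' @examples
#' mean_pairwise_distance(c(0, 1), c(0, 1))  # the pad diagonal, 1.41
#' @export
mean_pairwise_distance <- function(x, y) {
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  mean(stats::dist(cbind(x, y)))
}

#' Mean distance from the pad center
#'
#' @param x,y coordinates of at least one point.
#' @return Mean of [distance_from_center()].
#' @export
mean_distance_from_center <- function(x, y) {
  if (length(x) < 1L) stop("need at least 1 point", call. = FALSE)
  mean(distance_from_center(x, y))
}

#' Extremeness index
#'
#' Distance from the pad center is normalized by the center-to-corner
#' distance (`norm_dist`, in `[0, 1]`); the index is
#' `|norm_dist - 0.5| / 0.5`. It equals 1 at the absolute center and at the
#' corners of the space and 0 on the ring exactly halfway between center
#' and corner.
#'
#' @inheritParams distance_from_center
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' extremeness_index(c(0.5, 1, 0.75), c(0.5, 1, 0.75))
#' @export
extremeness_index <- function(x, y) {
  norm_dist <- distance_from_center(x, y) / pad_max_radius
  abs(norm_dist - 0.5) / 0.5
}

#' Mode brightness of an inventory
#'
#' For each phoneme, the mean over its exemplars of the brightest RGB
#' channel; returned is the mean over phonemes. A perceptual analog of mean
#' distance from center.
#'
#' @param inventory an inventory as returned by [identify_phonemes()], or a
#'   list of data frames with columns `r`, `g`, `b`.
#' @return Intensity in `[0, 1]`.
#' @export
mode_brightness <- function(inventory) {
  groups <- if (inherits(inventory, "inventory")) inventory$phonemes else inventory
  if (length(groups) == 0L) stop("empty inventory", call. = FALSE)
  per_phoneme <- vapply(groups, function(g) {
    if (nrow(g) == 0L) stop("empty phoneme group", call. = FALSE)
    mean(pmax(g$r, g$g, g$b))
  }, numeric(1))
  mean(per_phoneme)
}

#' Auto- and partner distance for every trial
#'
#' Auto-distance is the Euclidean distance between a trial's first-color
#' pad point and the same player's most recent previous point for the same
#' referent; partner distance conditions on the other player instead. Both
#' are `NA` when no previous trial exists.
#'
#' @param log a [game_log()].
#' @return Data frame with one row per trial: `turn`, `auto_distance`,
#'   `partner_distance`, `prev_outcome_own`, `prev_outcome_partner`,
#'   `prev_outcome_any` (outcome of the most recent previous trial for the
#'   same referent by, respectively, the same player, the other player, and
#'   either player; `NA` when none exists).
#' @export
turn_distances <- function(log) {
  fc <- first_colors(log)
  n <- nrow(fc)
  auto <- partner <- rep(NA_real_, n)
  p_own <- p_partner <- p_any <- rep(NA, n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    same_ref <- prev[fc$referent_id[prev] == fc$referent_id[i]]
    if (!length(same_ref)) next
    own <- same_ref[fc$sender_id[same_ref] == fc$sender_id[i]]
    oth <- same_ref[fc$sender_id[same_ref] != fc$sender_id[i]]
    d_to <- function(j) sqrt((fc$x[i] - fc$x[j])^2 + (fc$y[i] - fc$y[j])^2)
    if (length(own)) {
      j <- max(own); auto[i] <- d_to(j); p_own[i] <- fc$correct[j]
    }
    if (length(oth)) {
      j <- max(oth); partner[i] <- d_to(j); p_partner[i] <- fc$correct[j]
    }
    p_any[i] <- fc$correct[max(same_ref)]
  }
  data.frame(turn = fc$turn, auto_distance = auto, partner_distance = partner,
             prev_outcome_own = p_own, prev_outcome_partner = p_partner,
             prev_outcome_any = p_any)
}

#' Rolling dispersion over the course of a game
#'
#' At every turn, collect for each referent the first-color point of its
#' most recent successful signal at or before that turn; rolling dispersion
#' is the mean pairwise distance over that set, `NA` while fewer than two
#' referents have a successful signal.
#'
#' @param log a [game_log()].
#' @return Data frame with one row per trial: `turn`, `dispersion`,
#'   `n_referents` (size of the most-recent-success set).
#' @export
rolling_dispersion <- function(log) {
  fc <- first_colors(log)
  n <- nrow(fc)
  last_x <- last_y <- rep(NA_real_, 12L)
  disp <- rep(NA_real_, n)
  n_ref <- integer(n)
  for (i in seq_len(n)) {
    if (fc$correct[i]) {
      last_x[fc$referent_id[i] + 1L] <- fc$x[i]
      last_y[fc$referent_id[i] + 1L] <- fc$y[i]
    }
    have <- !is.na(last_x)
    n_ref[i] <- sum(have)
    if (n_ref[i] >= 2L) {
      disp[i] <- mean_pairwise_distance(last_x[have], last_y[have])
    }
  }
  data.frame(turn = fc$turn, dispersion = disp, n_referents = n_ref)
}

#' PCA-ellipse area of a coordinate cloud
#'
#' Points whose Euclidean distance from the cloud centroid exceeds the mean
#' of those distances plus two standard deviations are removed (once, not
#' iterated). The remaining points are centered and projected onto their
#' first two principal components; the area is that of an ellipse whose
#' diameters are the coordinate ranges along the two components,
#' `pi * (width/2) * (height/2)`. Degenerate clouds (one surviving point,
#' identical or collinear points) have area 0. The measure is invariant
#' under rotation and translation of the cloud.
#'
#' @param x,y coordinates of a non-empty cloud, in pad units (the total
#'   space has area 1).
#' @return Non-negative area.
#' @export
signal_area <- function(x, y) {
  if (length(x) == 0L) stop("empty cloud", call. = FALSE)
  pts <- cbind(x, y)
  if (nrow(pts) >= 2L) {
    ctr <- colMeans(pts)
    d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    keep <- d <= mean(d) + 2 * stats::sd(d)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) <= 1L) return(0)
  cc <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  scores <- cc %*% ev$vectors
  width <- diff(range(scores[, 1]))
  height <- diff(range(scores[, 2]))
  pi * (width / 2) * (height / 2)
}

# Quintile sizes: earlier quintiles absorb the remainder, so sizes differ
# by at most one and are non-increasing.
quintile_sizes <- function(n, k = 5L) {
  base <- n %/% k
  base + (seq_len(k) <= n %% k)
}

#' Assign turns to quintiles
#'
#' @param n number of turns.
#' @param k number of sections.
#' @return Integer vector of length `n`, the section index of each turn.
#' @export
quintile_of <- function(n, k = 5L) {
  rep(seq_len(k), times = quintile_sizes(n, k))
}

#' Signal areas by quintile and referent
#'
#' The series of turns is divided into five contiguous sections of equal
#' size (earlier sections absorb any remainder). Within each section, the
#' coordinate cloud of a referent is the set of first-color points of the
#' successful signals for that referent; its area is [signal_area()].
#' Referents with no successful signal in a section contribute no cloud.
#'
#' @param log a [game_log()].
#' @param k number of sections (default 5, quintiles).
#' @return List with `clouds` (data frame: `referent_id`, `quintile`,
#'   `n_points`, `area`) and `quintile_means` (data frame: `quintile`,
#'   `mean_area`, `n_clouds`).
#' @export
quintile_areas <- function(log, k = 5L) {
  fc <- first_colors(log)
  if (nrow(fc) < k) stop("log must have at least ", k, " turns", call. = FALSE)
  fc$quintile <- quintile_of(nrow(fc), k)
  ok <- fc[fc$correct, , drop = FALSE]
  clouds <- do.call(rbind, lapply(split(ok, list(ok$quintile, ok$referent_id),
                                        drop = TRUE), function(g) {
    data.frame(referent_id = g$referent_id[1], quintile = g$quintile[1],
               n_points = nrow(g), area = signal_area(g$x, g$y))
  }))
  if (is.null(clouds)) {
    clouds <- data.frame(referent_id = integer(), quintile = integer(),
                         n_points = integer(), area = numeric())
  }
  clouds <- clouds[order(clouds$quintile, clouds$referent_id), ]
  rownames(clouds) <- NULL
  means <- do.call(rbind, lapply(split(clouds, clouds$quintile), function(g) {
    data.frame(quintile = g$quintile[1], mean_area = mean(g$area),
               n_clouds = nrow(g))
  }))
  if (is.null(means)) {
    means <- data.frame(quintile = integer(), mean_area = numeric(),
                        n_clouds = integer())
  }
  rownames(means) <- NULL
  list(clouds = clouds, quintile_means = means)
}

#' Descriptive end-of-game counts
#'
#' @param log a [game_log()].
#' @param merge_threshold Pillai threshold passed to [identify_phonemes()].
#' @return Data frame with one row: `final_s` (established referents at the
#'   final round), `final_n_active`, `mean_word_length` (mean color tokens
#'   per signal), `n_phonemes`, `success_index`.
#' @export
descriptive_counts <- function(log, merge_threshold = 0.3) {
  traj <- log_mastery(log)
  fc <- first_colors(log)
  inv <- identify_phonemes(log, merge_threshold = merge_threshold,
                           successful_only = TRUE)
  data.frame(final_s = traj$s[nrow(traj)],
             final_n_active = traj$n_active[nrow(traj)],
             mean_word_length = mean(fc$n_tokens),
             n_phonemes = length(inv$phonemes),
             success_index = success_index(traj))
}
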