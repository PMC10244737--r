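# Core domain: the unit-square signal pad, the pad->color mappings for the
# two experimental conditions, and the game-log container.

#' Pad geometry constants
#'
#' The signal space is the unit square with origin at the bottom left. Its
#' center is (0.5, 0.5) and the center-to-corner distance is sqrt(0.5).
#'
#' @format `pad_center` is a length-2 numeric; `pad_max_radius` a scalar.
#' @keywords internal
pad_center <- c(0.5, 0.5)

#' @rdname pad_center
#' @keywords internal
pad_max_radius <- sqrt(0.5)

#' Legal condition labels
#'
#' In the outer-edge condition colors get brighter and more distinct with
#' distance from the pad center; in the inner-edge condition brightness
#' peaks on a ridge short of the edge and falls off again toward the
#' corners.
#'
#' @export
conditions <- function() c("outer_edge", "inner_edge")

assert_condition <- function(condition) {
  if (!(is.character(condition) && length(condition) == 1L &&
        condition %in% conditions())) {
    stop("`condition` must be one of ", paste(conditions(), collapse = ", "),
         call. = FALSE)
  }
  condition
}

assert_pad_xy <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  bad <- which(!is.finite(x) | !is.finite(y) | x < 0 | x > 1 | y < 0 | y > 1)
  if (length(bad)) {
    stop("pad coordinates outside [0,1] at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Euclidean distance from the pad center
#'
#' @param x,y numeric vectors of pad coordinates in `[0, 1]`.
#' @return Numeric vector of distances to (0.5, 0.5), in `[0, sqrt(0.5)]`.
#' @examples
#' distance_from_center(c(0.5, 0, 1), c(0.5, 0, 0.5))
#' @export
distance_from_center <- function(x, y) {
  assert_pad_xy(x, y)
  sqrt((x - 0.5)^2 + (y - 0.5)^2)
}

# Continuous HSV -> RGB in [0,1]^3. Implemented here rather than through
# grDevices because col2rgb() quantizes channels to 8 bits, which would
# break the exact brightness contract max(r,g,b) == v.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- numeric(length(h6)); g <- r; b <- r
  idx <- function(k) i == k
  r[idx(0)] <- v[idx(0)]; g[idx(0)] <- t[idx(0)]; b[idx(0)] <- p[idx(0)]
  r[idx(1)] <- q[idx(1)]; g[idx(1)] <- v[idx(1)]; b[idx(1)] <- p[idx(1)]
  r[idx(2)] <- p[idx(2)]; g[idx(2)] <- v[idx(2)]; b[idx(2)] <- t[idx(2)]
  r[idx(3)] <- p[idx(3)]; g[idx(3)] <- q[idx(3)]; b[idx(3)] <- v[idx(3)]
  r[idx(4)] <- t[idx(4)]; g[idx(4)] <- p[idx(4)]; b[idx(4)] <- v[idx(4)]
  r[idx(5)] <- v[idx(5)]; g[idx(5)] <- p[idx(5)]; b[idx(5)] <- q[idx(5)]
  cbind(r = r, g = g, b = b)
}

#' Brightness (HSV value) of the color at a pad point
#'
#' Brightness is the maximum RGB channel of the mapped color. Under
#' `outer_edge` it increases linearly with radial distance from the pad
#' center; under `inner_edge` it rises to a ridge at `ridge_frac` of the
#' center-to-corner distance and falls back to `b_min` at the corners.
#'
#' @inheritParams distance_from_center
#' @param condition `"outer_edge"` or `"inner_edge"`.
#' @param b_min,b_max brightness at radius 0 (and, for `inner_edge`, at the
#'   corners) and at the brightest point of the space.
#' @param ridge_frac location of the inner-edge brightness ridge as a
#'   fraction of the center-to-corner distance.
#' @return Numeric vector of brightness values in `[b_min, b_max]`.
#' @export
pad_brightness <- function(x, y, condition, b_min = 0.15, b_max = 1,
                           ridge_frac = 0.8) {
  assert_condition(condition)
  rn <- distance_from_center(x, y) / pad_max_radius
  if (condition == "outer_edge") {
    b_min + (b_max - b_min) * rn
  } else {
    up <- rn <= ridge_frac
    v <- numeric(length(rn))
    v[up] <- b_min + (b_max - b_min) * rn[up] / ridge_frac
    v[!up] <- b_max - (b_max - b_min) * (rn[!up] - ridge_frac) / (1 - ridge_frac)
    v
  }
}

#' Map pad coordinates to RGB colors
#'
#' The mapping is polar about the pad center: hue varies with the angle,
#' brightness with the radius following the condition's profile (see
#' [pad_brightness()]). Saturation is fixed at 1, so brightness equals the
#' maximum RGB channel exactly. The mapping is deterministic.
#'
#' @inheritParams pad_brightness
#' @return A data frame with columns `r`, `g`, `b`, all in `[0, 1]`.
#' @examples
#' xy_to_rgb(c(0.5, 1), c(0.5, 1), "outer_edge")
#' @export
xy_to_rgb <- function(x, y, condition, b_min = 0.15, b_max = 1,
                      ridge_frac = 0.8) {
  assert_pad_xy(x, y)
  angle <- atan2(y - 0.5, x - 0.5)
  hue <- (angle %% (2 * pi)) / (2 * pi)
  hue[distance_from_center(x, y) == 0] <- 0  # hue undefined at the center
  v <- pad_brightness(x, y, condition, b_min = b_min, b_max = b_max,
                      ridge_frac = ridge_frac)
  as.data.frame(hsv_to_rgb(hue, rep(1, length(hue)), v))
}

token_columns <- function() {
  c("turn", "sender_id", "referent_id", "token_index",
    "x", "y", "r", "g", "b", "guess_id", "correct")
}

#' Construct a game log
#'
#' A game log holds the full record of one dyad's game: one row per color
#' token, in turn order, with the sender, referent, pad and RGB coordinates,
#' and the receiver's guess and its correctness.
#'
#' @param tokens data frame with columns `turn`, `sender_id`, `referent_id`,
#'   `token_index`, `x`, `y`, `r`, `g`, `b`, `guess_id`, `correct`.
#' @param pair_id identifier for the dyad.
#' @param condition `"outer_edge"` or `"inner_edge"`.
#' @param validate run [validate_tokens()] on construction.
#' @return An object of class `game_log`.
#' @export
game_log <- function(tokens, pair_id, condition, validate = TRUE) {
  assert_condition(condition)
  tokens <- as.data.frame(tokens)
  if (validate) validate_tokens(tokens)
  structure(list(pair_id = pair_id, condition = condition, tokens = tokens),
            class = "game_log")
}

#' @export
print.game_log <- function(x, ...) {
  fc <- first_colors(x)
  cat(sprintf("<game_log> pair %s, %s, %d turns, %d tokens, %.0f%% correct\n",
              x$pair_id, x$condition, nrow(fc), nrow(x$tokens),
              100 * mean(fc$correct)))
  invisible(x)
}

#' Validate the token table of a game log
#'
#' Checks the structural invariants of the log: required columns; pad and
#' RGB coordinates in range; referent and guess ids in `0..11`; `correct`
#' equal to `guess_id == referent_id` (a missing guess is incorrect); turn
#' numbers strictly increasing across trials with tokens numbered `1..k`
#' within a trial; and the sender alternating between consecutive trials.
#' Violations raise errors that name the offending row.
#'
#' @param tokens data frame of tokens (see [game_log()]).
#' @param alternation require strict sender alternation.
#' @return Invisibly `TRUE`; errors describe the first violations found.
#' @export
validate_tokens <- function(tokens, alternation = TRUE) {
  missing_cols <- setdiff(token_columns(), names(tokens))
  if (length(missing_cols)) {
    stop("tokens missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tokens) == 0L) stop("empty token table", call. = FALSE)
  fail <- function(rows, what) {
    stop(sprintf("%s at row(s) %s", what,
                 paste(utils::head(rows, 5L), collapse = ", ")), call. = FALSE)
  }
  rng <- function(v, lo, hi) which(!is.finite(v) | v < lo | v > hi)
  bad <- unique(c(rng(tokens$x, 0, 1), rng(tokens$y, 0, 1)))
  if (length(bad)) fail(bad, "pad coordinate outside [0,1]")
  bad <- unique(c(rng(tokens$r, 0, 1), rng(tokens$g, 0, 1), rng(tokens$b, 0, 1)))
  if (length(bad)) fail(bad, "RGB channel outside [0,1]")
  bad <- rng(tokens$referent_id, 0, 11)
  if (length(bad)) fail(bad, "referent_id outside 0..11")
  bad <- which(!is.na(tokens$guess_id) &
                 (tokens$guess_id < 0 | tokens$guess_id > 11))
  if (length(bad)) fail(bad, "guess_id outside 0..11")
  bad <- which(!tokens$sender_id %in% c(0L, 1L))
  if (length(bad)) fail(bad, "sender_id not in {0,1}")
  implied <- !is.na(tokens$guess_id) & tokens$guess_id == tokens$referent_id
  bad <- which(tokens$correct != implied)
  if (length(bad)) fail(bad, "correct flag contradicts guess/referent equality")
  # per-trial structure
  turns <- unique(tokens$turn)
  if (any(diff(turns) <= 0)) {
    fail(which(c(FALSE, diff(tokens$turn) < 0)),
         "turn numbers not non-decreasing")
  }
  per_trial <- split(seq_len(nrow(tokens)), tokens$turn)
  for (rows in per_trial) {
    if (!identical(as.integer(tokens$token_index[rows]),
                   seq_along(rows))) {
      fail(rows[1], "token_index not 1..k within trial")
    }
    if (length(unique(tokens$sender_id[rows])) != 1L ||
        length(unique(tokens$referent_id[rows])) != 1L) {
      fail(rows[1], "sender or referent varies within trial")
    }
  }
  if (alternation && length(turns) > 1L) {
    senders <- tokens$sender_id[match(turns, tokens$turn)]
    bad <- which(diff(senders) == 0)
    if (length(bad)) {
      fail(match(turns[bad + 1L], tokens$turn), "sender does not alternate")
    }
  }
  invisible(TRUE)
}

#' First color of every signal
#'
#' The trend analyses operate on the first color of each signal only, since
#' signals overwhelmingly repeat a single color. Returns one row per trial.
#'
#' @param log a [game_log()].
#' @return Data frame with one row per trial: `turn`, `sender_id`,
#'   `referent_id`, `x`, `y`, `r`, `g`, `b`, `guess_id`, `correct`,
#'   `n_tokens`.
#' @export
first_colors <- function(log) {
  stopifnot(inherits(log, "game_log"))
  tk <- log$tokens
  first <- tk$token_index == 1L
  out <- tk[first, c("turn", "sender_id", "referent_id", "x", "y",
                     "r", "g", "b", "guess_id", "correct")]
  out$n_tokens <- as.integer(table(factor(tk$turn, levels = out$turn)))
  rownames(out) <- NULL
  out
}

#' First token of a single signal
#'
#' @param signal data frame of the tokens of one trial, in token order.
#' @return Its first row.
#' @export
first_color <- function(signal) {
  if (is.null(nrow(signal)) || nrow(signal) == 0L) {
    stop("empty signal", call. = FALSE)
  }
  signal[1L, , drop = FALSE]
}
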