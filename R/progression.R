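# Referent establishment and unlocking: the mastery rules that grow the
# active referent set 4 -> 8 -> 12 over the course of a game.

#' Is a referent's signal established?
#'
#' A referent counts as established when it has been communicated
#' successfully in at least three of the last four rounds in which it
#' occurred. With fewer than four occurrences, at least three successes are
#' still required, so a referent needs at least three occurrences to
#' qualify.
#'
#' @param outcomes logical vector of outcomes for one referent, ordered
#'   oldest to newest, one entry per occurrence.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_established(c(TRUE, TRUE, FALSE, TRUE))  # 3 of last 4
#' is_established(c(TRUE, TRUE))               # too few occurrences
#' @export
is_established <- function(outcomes) {
  n <- length(outcomes)
  if (n < 3L) return(FALSE)
  k <- min(4L, n)
  sum(outcomes[(n - k + 1L):n]) >= 3L
}

#' Mastery trajectory of a game
#'
#' Replays the unlocking rule over a sequence of rounds. The game starts
#' with `n_initial` active referents; at the end of any round in which every
#' active referent is established (see [is_established()]), a block of
#' `block` new referents is added, up to `max_referents`. Referents are
#' never removed and establishment is evaluated at dyad level (both
#' senders' outcomes pooled).
#'
#' @param referent_ids integer vector, the referent communicated each round
#'   (ids `0..max_referents-1`).
#' @param correct logical vector of round outcomes.
#' @param n_initial,block,max_referents referent-set schedule.
#' @return Data frame with one row per round: `turn`, `referent_id`,
#'   `correct`, `s` (number of established referents at round end, before
#'   any unlock), `n_active` (active-set size after any unlock), `unlock`
#'   (did this round trigger an unlock), `turns_since_new` (rounds since the
#'   last unlock event, 0 on the first round after an unlock and at game
#'   start).
#' @export
mastery_trajectory <- function(referent_ids, correct, n_initial = 4L,
                               block = 4L, max_referents = 12L) {
  n <- length(referent_ids)
  stopifnot(n == length(correct), n >= 1L)
  active <- seq_len(n_initial) - 1L
  history <- vector("list", max_referents)
  established <- rep(FALSE, max_referents)
  s <- integer(n); n_active <- integer(n); unlock <- logical(n)
  tsn <- integer(n)
  last_unlock <- 0L
  for (i in seq_len(n)) {
    r <- referent_ids[i]
    if (!(r %in% active)) {
      stop(sprintf("round %d communicates referent %d, not in the active set",
                   i, r), call. = FALSE)
    }
    history[[r + 1L]] <- c(history[[r + 1L]], correct[i])
    established[r + 1L] <- is_established(history[[r + 1L]])
    s[i] <- sum(established[active + 1L])
    tsn[i] <- i - last_unlock - 1L
    if (all(established[active + 1L]) && length(active) < max_referents) {
      new_ids <- seq(length(active), length.out = block)
      active <- c(active, new_ids)
      unlock[i] <- TRUE
      last_unlock <- i
    }
    n_active[i] <- length(active)
  }
  data.frame(turn = seq_len(n), referent_id = referent_ids,
             correct = correct, s = s, n_active = n_active,
             unlock = unlock, turns_since_new = tsn)
}

#' @rdname mastery_trajectory
#' @param log a [game_log()]; rounds are its trials in turn order.
#' @export
log_mastery <- function(log) {
  fc <- first_colors(log)
  mastery_trajectory(fc$referent_id, fc$correct)
}

#' Active referents at every round
#'
#' @param trajectory output of [mastery_trajectory()].
#' @return List of integer vectors, the active referent set at each round
#'   (before that round's unlock takes effect).
#' @keywords internal
active_sets <- function(trajectory) {
  n_before <- c(4L, utils::head(trajectory$n_active, -1L))
  lapply(n_before, function(k) seq_len(k) - 1L)
}
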