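# Agent-based dyad simulator. Two agents alternate as sender and receiver
# over a growing referent set; the sender selects pad points under comfort,
# consistency and distinctiveness pressures, the receiver classifies the
# observed color against remembered exemplars. Emitted logs carry the
# statistical structure the trend analyses assume: a comfort-biased start,
# increasing motor precision, outcome-contingent convergence, and
# above-chance dispersion through repulsion from established signals.

#' Agent behavioral parameters
#'
#' @param comfort_correlation target Pearson correlation of the x and y
#'   coordinates of initial exploratory points (the comfortable region runs
#'   diagonally from lower left to upper right).
#' @param comfort_exclusion fraction of the bottom of the pad excluded from
#'   initial sampling (the hard-to-reach strip).
#' @param motor_sd0 motor noise standard deviation (pad units) at the start
#'   of the game.
#' @param motor_sd_min asymptotic motor noise standard deviation.
#' @param motor_decay per-turn multiplicative decay rate of the motor noise
#'   toward `motor_sd_min`.
#' @param stay_prob_success probability of reusing the previous point (plus
#'   motor noise) after a success, rather than exploring.
#' @param repel_weight strength of the distinctiveness pressure pushing new
#'   candidate points away from currently established signals; 0 disables
#'   it.
#' @param perceptual_sd receiver noise standard deviation per RGB channel.
#' @param n_candidates candidate points scored when exploring.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(comfort_correlation = 0.4, comfort_exclusion = 0.25,
                         motor_sd0 = 0.08, motor_sd_min = 0.015,
                         motor_decay = 0.015, stay_prob_success = 0.95,
                         repel_weight = 1, perceptual_sd = 0.05,
                         n_candidates = 25L) {
  stopifnot(comfort_correlation >= -1, comfort_correlation <= 1,
            comfort_exclusion >= 0, comfort_exclusion < 1,
            motor_sd0 >= 0, motor_sd_min >= 0, motor_decay >= 0,
            motor_decay <= 1, stay_prob_success >= 0, stay_prob_success <= 1,
            repel_weight >= 0, perceptual_sd >= 0, n_candidates >= 1)
  structure(list(comfort_correlation = comfort_correlation,
                 comfort_exclusion = comfort_exclusion,
                 motor_sd0 = motor_sd0, motor_sd_min = motor_sd_min,
                 motor_decay = motor_decay,
                 stay_prob_success = stay_prob_success,
                 repel_weight = repel_weight, perceptual_sd = perceptual_sd,
                 n_candidates = as.integer(n_candidates)),
            class = "agent_params")
}

#' Motor noise schedule
#'
#' `motor_sd_min + (motor_sd0 - motor_sd_min) * (1 - motor_decay)^t`.
#'
#' @param params an [agent_params()] list.
#' @param t turn number (0 at the start of the game).
#' @return Standard deviation in pad units.
#' @export
motor_sd <- function(params, t) {
  params$motor_sd_min +
    (params$motor_sd0 - params$motor_sd_min) * (1 - params$motor_decay)^t
}

#' Sample initial exploratory pad points
#'
#' Draws from a diagonal-band distribution: a Gaussian copula with positive
#' dependence gives uniform margins with correlated ranks; y is then
#' rescaled into `[comfort_exclusion, 1]`, excluding the hard-to-reach
#' bottom strip. The copula correlation is chosen so the Pearson
#' correlation of the uniforms matches `comfort_correlation`.
#'
#' @param n number of points.
#' @param params an [agent_params()] list.
#' @return Data frame with columns `x`, `y`. Uses the current RNG stream.
#' @export
sample_initial_point <- function(n = 1L, params = agent_params()) {
  # Pearson corr of copula uniforms is (6/pi) asin(rho/2); invert.
  rho <- 2 * sin(pi * params$comfort_correlation / 6)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  x <- stats::pnorm(z1)
  y <- params$comfort_exclusion + (1 - params$comfort_exclusion) * stats::pnorm(z2)
  data.frame(x = x, y = y)
}

clamp01 <- function(v) pmin(pmax(v, 0), 1)

#' Sender policy: choose a pad point for a referent
#'
#' When the referent's most recent signal (by either player) was
#' successful, the sender stays close to what worked: it reuses that point
#' plus Gaussian motor noise (with probability `stay_prob_success`).
#' Otherwise it tries something new: `n_candidates` points are drawn from
#' the comfort-band distribution and the candidate maximizing
#' `repel_weight * (minimum distance to currently established points)` is
#' chosen (with `repel_weight = 0` or no established points, the first
#' candidate, i.e., a random comfort-band draw). Reusing the partner's
#' successful points is what produces outcome-contingent convergence
#' between the players.
#'
#' @param prev_point the referent's most recent signal point by either
#'   player (data frame row or list with `x`, `y`), or `NULL`.
#' @param prev_correct was that most recent trial successful?
#' @param established two-column matrix of the most recent successful point
#'   per established referent (may have 0 rows).
#' @param t turn number, for the motor-noise schedule.
#' @param params an [agent_params()] list.
#' @return Data frame with one row, columns `x`, `y`. Uses the current RNG
#'   stream.
#' @export
sender_policy <- function(prev_point, prev_correct, established, t,
                          params = agent_params()) {
  if (!is.null(prev_point) && isTRUE(prev_correct) &&
      stats::runif(1) < params$stay_prob_success) {
    sd_t <- motor_sd(params, t)
    return(data.frame(x = clamp01(prev_point$x + stats::rnorm(1, 0, sd_t)),
                      y = clamp01(prev_point$y + stats::rnorm(1, 0, sd_t))))
  }
  cand <- sample_initial_point(params$n_candidates, params)
  if (params$repel_weight > 0 && NROW(established) > 0) {
    min_dist <- vapply(seq_len(nrow(cand)), function(i) {
      min(sqrt((established[, 1] - cand$x[i])^2 +
               (established[, 2] - cand$y[i])^2))
    }, numeric(1))
    pick <- which.max(params$repel_weight * min_dist)
  } else {
    pick <- 1L
  }
  cand[pick, , drop = FALSE]
}

#' Receiver policy: classify an observed color
#'
#' The observation is perturbed by Gaussian perceptual noise per RGB
#' channel and matched to the nearest remembered exemplar in RGB Euclidean
#' distance; ties break on the lowest referent id. With no exemplars in
#' memory, the guess is uniform over the active referents.
#'
#' @param observed numeric length-3 RGB vector.
#' @param memory named list mapping referent id (as character) to an RGB
#'   exemplar vector; may be empty.
#' @param active integer vector of active referent ids.
#' @param params an [agent_params()] list.
#' @return List with `guess` (referent id) and `perceived` (the noisy RGB
#'   vector, for memory updating). Uses the current RNG stream.
#' @export
receiver_policy <- function(observed, memory, active,
                            params = agent_params()) {
  perceived <- clamp01(observed + stats::rnorm(3, 0, params$perceptual_sd))
  if (length(memory) == 0L) {
    return(list(guess = active[sample.int(length(active), 1L)],
                perceived = perceived))
  }
  ids <- as.integer(names(memory))
  d <- vapply(memory, function(ex) sqrt(sum((perceived - ex)^2)), numeric(1))
  best <- ids[d == min(d)]
  list(guess = min(best), perceived = perceived)
}

#' Simulate one dyad playing the game
#'
#' Two agents alternate as sender and receiver. Each turn a referent is
#' drawn uniformly from the active set, the sender selects a pad point (see
#' [sender_policy()]), the color under the condition's mapping is sent, the
#' receiver classifies it ([receiver_policy()]), and both players get
#' outcome feedback: the receiver stores the perceived color as the
#' exemplar for the true referent, and the mastery state is updated, which
#' may unlock a new block of referents ([mastery_trajectory()]). One color
#' is sent per turn.
#'
#' @param condition `"outer_edge"` or `"inner_edge"`.
#' @param n_turns number of turns (rounds).
#' @param seed integer seed; the whole simulation is reproducible from it
#'   and the caller's RNG state is preserved.
#' @param params an [agent_params()] list, shared by both players, or a
#'   list of two such lists (one per player).
#' @param pair_id identifier recorded in the log.
#' @return A validated [game_log()] with attributes `seed` and `params`.
#' @examples
#' log <- simulate_dyad("outer_edge", n_turns = 50, seed = 1)
#' success_index(log)
#' @export
simulate_dyad <- function(condition = "outer_edge", n_turns = 250L, seed = 1L,
                          params = agent_params(), pair_id = "sim") {
  assert_condition(condition)
  stopifnot(n_turns >= 1L)
  if (inherits(params, "agent_params")) params <- list(params, params)
  stopifnot(length(params) == 2L)

  local_seed(seed, {
    active <- 0:3
    history <- vector("list", 12L)        # per-referent outcome history
    established <- rep(FALSE, 12L)
    est_x <- est_y <- rep(NA_real_, 12L)  # last successful point per referent
    last_point <- rep(list(NULL), 12L)    # last point per referent (either player)
    last_correct <- rep(NA, 12L)
    memory <- list(list(), list())        # receiver exemplars per player
    rows <- vector("list", n_turns)

    for (t in seq_len(n_turns)) {
      sender <- (t - 1L) %% 2L
      receiver <- 1L - sender
      referent <- active[sample.int(length(active), 1L)]
      slot <- referent + 1L

      est_have <- established & !is.na(est_x)
      est_pts <- cbind(est_x[est_have], est_y[est_have])
      pt <- sender_policy(last_point[[slot]], last_correct[slot],
                          est_pts, t - 1L, params[[sender + 1L]])
      rgb <- xy_to_rgb(pt$x, pt$y, condition)
      resp <- receiver_policy(c(rgb$r, rgb$g, rgb$b),
                              memory[[receiver + 1L]], active,
                              params[[receiver + 1L]])
      correct <- resp$guess == referent

      # feedback: receiver learns the true referent's color as perceived
      memory[[receiver + 1L]][[as.character(referent)]] <- resp$perceived
      last_point[[slot]] <- pt
      last_correct[slot] <- correct
      if (correct) {
        est_x[referent + 1L] <- pt$x
        est_y[referent + 1L] <- pt$y
      }
      history[[referent + 1L]] <- c(history[[referent + 1L]], correct)
      established[referent + 1L] <- is_established(history[[referent + 1L]])
      if (all(established[active + 1L]) && length(active) < 12L) {
        active <- c(active, seq(length(active), length.out = 4L))
      }

      rows[[t]] <- data.frame(turn = t, sender_id = sender,
                              referent_id = referent, token_index = 1L,
                              x = pt$x, y = pt$y,
                              r = rgb$r, g = rgb$g, b = rgb$b,
                              guess_id = resp$guess, correct = correct)
    }
    log <- game_log(do.call(rbind, rows), pair_id = pair_id,
                    condition = condition)
    attr(log, "seed") <- as.integer(seed)
    attr(log, "params") <- params
    log
  })
}

#' Simulate a set of dyads
#'
#' @param n_pairs dyads per condition.
#' @param conditions_used conditions to simulate.
#' @param n_turns turns per game.
#' @param seed base seed; dyad k in condition j uses `seed + 1000*j + k`.
#' @param params an [agent_params()] list.
#' @return List of [game_log()]s with pair ids `"<condition>_<k>"`.
#' @export
simulate_study <- function(n_pairs = 10L, conditions_used = conditions(),
                           n_turns = 250L, seed = 1L,
                           params = agent_params()) {
  logs <- list()
  for (j in seq_along(conditions_used)) {
    for (k in seq_len(n_pairs)) {
      id <- sprintf("%s_%02d", conditions_used[j], k)
      logs[[id]] <- simulate_dyad(conditions_used[j], n_turns = n_turns,
                                  seed = seed + 1000L * j + k,
                                  params = params, pair_id = id)
    }
  }
  logs
}
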