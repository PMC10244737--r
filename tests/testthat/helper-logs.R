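# Toy-log constructors shared across tests. All fixtures are built in code.

# A minimal valid log from coordinate/outcome vectors; senders alternate,
# one token per trial, RGB from the condition's mapping.
toy_log <- function(x, y, referent, correct,
                    sender = rep_len(c(0L, 1L), length(x)),
                    condition = "outer_edge", pair_id = "toy") {
  n <- length(x)
  guess <- ifelse(correct, referent, (referent + 1L) %% 12L)
  rgb <- xy_to_rgb(x, y, condition)
  tokens <- data.frame(turn = seq_len(n), sender_id = sender,
                       referent_id = referent, token_index = 1L,
                       x = x, y = y, r = rgb$r, g = rgb$g, b = rgb$b,
                       guess_id = guess, correct = correct)
  game_log(tokens, pair_id, condition)
}

# An always-successful log whose referent schedule respects the unlocking
# rule (round-robin over the active set) and whose signals form one tight
# cluster per referent, spread around a circle. `shared` collapses
# referents 0 and 1 onto the same cluster.
mastered_log <- function(n_turns = 280, jitter = 0.01, seed = 1,
                         shared = FALSE, condition = "outer_edge") {
  withr::with_seed(seed, {
    ang <- seq(0, 2 * pi, length.out = 13)[1:12]
    cx <- 0.5 + 0.42 * cos(ang)
    cy <- 0.5 + 0.42 * sin(ang)
    if (shared) {
      cx[2] <- cx[1]
      cy[2] <- cy[1]
    }
    active <- 0:3
    hist <- vector("list", 12)
    est <- rep(FALSE, 12)
    rows <- vector("list", n_turns)
    for (t in seq_len(n_turns)) {
      r <- active[(t - 1) %% length(active) + 1]
      x <- min(max(cx[r + 1] + stats::rnorm(1, 0, jitter), 0), 1)
      y <- min(max(cy[r + 1] + stats::rnorm(1, 0, jitter), 0), 1)
      rgb <- xy_to_rgb(x, y, condition)
      rows[[t]] <- data.frame(turn = t, sender_id = (t - 1) %% 2,
                              referent_id = r, token_index = 1L,
                              x = x, y = y, r = rgb$r, g = rgb$g, b = rgb$b,
                              guess_id = r, correct = TRUE)
      hist[[r + 1]] <- c(hist[[r + 1]], TRUE)
      est[r + 1] <- is_established(hist[[r + 1]])
      if (all(est[active + 1]) && length(active) < 12) {
        active <- c(active, length(active):(length(active) + 3))
      }
    }
    game_log(do.call(rbind, rows), "mastered", condition)
  })
}
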