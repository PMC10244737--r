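test_that("simulation is reproducible from its seed and preserves the RNG", {
  withr::with_seed(3, before <- runif(1))
  withr::with_seed(3, {
    a <- simulate_dyad("outer_edge", 60, seed = 5)
    after <- runif(1)
  })
  b <- simulate_dyad("outer_edge", 60, seed = 5)
  expect_identical(a$tokens, b$tokens)
  expect_identical(before, after)
  expect_false(identical(a$tokens, simulate_dyad("outer_edge", 60, seed = 6)$tokens))
})

test_that("emitted logs satisfy the structural and progression invariants", {
  for (cond in conditions()) {
    log <- simulate_dyad(cond, 150, seed = 13)
    expect_silent(validate_tokens(log$tokens))
    traj <- log_mastery(log)  # errors if a referent precedes its unlock
    expect_true(all(traj$n_active %in% c(4L, 8L, 12L)))
    # colors match the condition mapping
    fc <- first_colors(log)
    rgb <- xy_to_rgb(fc$x, fc$y, cond)
    expect_equal(fc$r, rgb$r, tolerance = 1e-12)
  }
})

test_that("initial points stay in the comfort band with correlated coordinates", {
  pts <- withr::with_seed(2, sample_initial_point(10000))
  expect_true(all(pts$y >= 0.25 & pts$y <= 1))
  expect_true(all(pts$x >= 0 & pts$x <= 1))
  expect_gt(cor(pts$x, pts$y), 0.2)
  pts0 <- withr::with_seed(2, sample_initial_point(
    5000, agent_params(comfort_correlation = 0)))
  expect_lt(abs(cor(pts0$x, pts0$y)), 0.05)
})

test_that("motor noise decays along the closed-form schedule", {
  p <- agent_params()
  expect_equal(motor_sd(p, 0), p$motor_sd0)
  tvals <- c(1, 10, 200)
  expect_equal(motor_sd(p, tvals),
               p$motor_sd_min + (p$motor_sd0 - p$motor_sd_min) *
                 (1 - p$motor_decay)^tvals)
  expect_equal(motor_sd(agent_params(motor_decay = 0), 500), p$motor_sd0)
})

test_that("a successful sender repeats exactly in the zero-noise limit", {
  p <- agent_params(motor_sd0 = 0, motor_sd_min = 0, stay_prob_success = 1)
  pt <- withr::with_seed(1, sender_policy(list(x = 0.31, y = 0.62), TRUE,
                                          matrix(numeric(), 0, 2), t = 5,
                                          params = p))
  expect_equal(c(pt$x, pt$y), c(0.31, 0.62))
})

test_that("exploration is repelled from established signals", {
  est <- cbind(c(0.1, 0.9, 0.1, 0.9), c(0.3, 0.3, 0.9, 0.9))
  d_min <- function(pt) min(sqrt((est[, 1] - pt$x)^2 + (est[, 2] - pt$y)^2))
  withr::with_seed(8, {
    repelled <- replicate(200, d_min(
      sender_policy(NULL, FALSE, est, 1, agent_params())))
    random <- replicate(200, d_min(
      sender_policy(NULL, FALSE, est, 1, agent_params(repel_weight = 0))))
  })
  expect_gt(mean(repelled), mean(random))
})

test_that("the receiver classifies by nearest remembered exemplar", {
  p0 <- agent_params(perceptual_sd = 0)
  mem <- list(`3` = c(1, 0, 0), `7` = c(0, 0, 1))
  expect_equal(receiver_policy(c(1, 0, 0), mem, 0:11, p0)$guess, 3L)
  expect_equal(receiver_policy(c(0, 0.1, 0.9), mem, 0:11, p0)$guess, 7L)
  # equidistant exemplars: lowest referent id wins
  expect_equal(receiver_policy(c(0.5, 0, 0.5), mem, 0:11, p0)$guess, 3L)
  g <- withr::with_seed(4, replicate(200, receiver_policy(
    c(0.5, 0.5, 0.5), list(), 0:3, p0)$guess))
  expect_setequal(unique(g), 0:3)  # empty memory: uniform over active
})

test_that("success-contingent persistence: smaller moves after success than failure", {
  tt <- build_turn_table(lapply(1:4, function(s)
    simulate_dyad("outer_edge", 200, seed = 300 + s, pair_id = paste0("p", s))))
  ok <- !is.na(tt$auto_distance) & !is.na(tt$prev_outcome_own)
  m_auto <- tapply(tt$auto_distance[ok], tt$prev_outcome_own[ok], mean)
  expect_lt(m_auto[["TRUE"]], m_auto[["FALSE"]])
  ok <- !is.na(tt$partner_distance) & !is.na(tt$prev_outcome_any)
  m_partner <- tapply(tt$partner_distance[ok], tt$prev_outcome_any[ok], mean)
  expect_lt(m_partner[["TRUE"]], m_partner[["FALSE"]])
})

test_that("distinctiveness pressure raises final dispersion (dose-response)", {
  d <- vapply(1:6, function(s) {
    l0 <- simulate_dyad("outer_edge", 250, seed = 400 + s,
                        params = agent_params(repel_weight = 0))
    l1 <- simulate_dyad("outer_edge", 250, seed = 400 + s)
    c(tail(rolling_dispersion(l0)$dispersion, 1),
      tail(rolling_dispersion(l1)$dispersion, 1))
  }, numeric(2))
  expect_lt(mean(d[1, ]), mean(d[2, ]))
})

test_that("noise-free dyads master the full referent set in long games", {
  p0 <- agent_params(motor_sd0 = 0, motor_sd_min = 0, perceptual_sd = 0,
                     stay_prob_success = 1)
  res <- vapply(1:6, function(s) {
    traj <- log_mastery(simulate_dyad("outer_edge", 1200, seed = s, params = p0))
    c(traj$s[nrow(traj)], success_index(traj))
  }, numeric(2))
  expect_true(all(res[1, ] >= 11))
  expect_gte(sum(res[1, ] == 12), 5)
  expect_gt(mean(res[2, ]), 0.55)
})

test_that("simulate_study labels pairs by condition and seeds them apart", {
  logs <- simulate_study(n_pairs = 2, n_turns = 30, seed = 50)
  expect_length(logs, 4L)
  expect_equal(vapply(logs, function(l) l$condition, character(1)),
               c(outer_edge_01 = "outer_edge", outer_edge_02 = "outer_edge",
                 inner_edge_01 = "inner_edge", inner_edge_02 = "inner_edge"))
  expect_false(identical(logs[[1]]$tokens$x, logs[[2]]$tokens$x))
})
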