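test_that("mean pairwise distance over unordered pairs", {
  expect_equal(mean_pairwise_distance(c(0, 1), c(0, 1)), sqrt(2))
  expect_equal(round(mean_pairwise_distance(c(0, 1), c(0, 1)), 2), 1.41)
  expect_equal(mean_pairwise_distance(c(0.3, 0.3), c(0.7, 0.7)), 0)
  # 4 corners: four sides of length 1 and two diagonals of length sqrt(2)
  expect_equal(mean_pairwise_distance(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               (4 + 2 * sqrt(2)) / 6)
  expect_error(mean_pairwise_distance(0.5, 0.5), "at least 2")
})

test_that("mean distance from center", {
  expect_equal(mean_distance_from_center(0.5, 0.5), 0)
  expect_equal(mean_distance_from_center(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               sqrt(0.5))
  expect_equal(mean_distance_from_center(c(1, 0.5), c(0.5, 1)), 0.5)
})

test_that("extremeness is 1 at center and corners, 0 on the half-radius ring", {
  expect_equal(extremeness_index(0.5, 0.5), 1)
  expect_equal(extremeness_index(1, 1), 1)
  expect_equal(extremeness_index(0.75, 0.75), 0)  # halfway to the corner
  g <- expand.grid(x = seq(0, 1, 0.05), y = seq(0, 1, 0.05))
  e <- extremeness_index(g$x, g$y)
  expect_true(all(e >= 0 & e <= 1))
  ones <- which(abs(e - 1) < 1e-12)
  corners <- (g$x %in% c(0, 1) & g$y %in% c(0, 1))
  center <- (g$x == 0.5 & g$y == 0.5)
  expect_true(all(corners[ones] | center[ones]))
})

test_that("mode brightness averages the brightest channel within then across phonemes", {
  ph1 <- data.frame(r = c(0.2, 0.4), g = 0, b = 0)
  expect_equal(mode_brightness(list(ph1)), 0.3)
  ph2 <- data.frame(r = 1, g = 0, b = 0)
  expect_equal(mode_brightness(list(ph2, ph2)), 1.0)
  expect_equal(mode_brightness(list(data.frame(r = 0.2, g = 0, b = 0),
                                    data.frame(r = 0, g = 0.8, b = 0))), 0.5)
  expect_error(mode_brightness(list()), "empty")
})

test_that("auto- and partner distance condition on the right player's history", {
  # referent 0 throughout; senders alternate 0,1,0,1
  log <- toy_log(x = c(0.2, 0.0, 0.5, 0.6),
                 y = c(0.2, 0.0, 0.6, 0.8),
                 referent = rep(0L, 4), correct = rep(TRUE, 4))
  td <- turn_distances(log)
  expect_true(is.na(td$auto_distance[1]) && is.na(td$partner_distance[1]))
  expect_true(is.na(td$auto_distance[2]))          # player 1's first trial
  expect_equal(td$partner_distance[2], sqrt(0.08)) # vs (0.2, 0.2)
  expect_equal(td$auto_distance[3], 0.5)           # (0.2,0.2) -> (0.5,0.6)
  expect_equal(td$partner_distance[3], sqrt(0.25 + 0.36))
  expect_equal(td$partner_distance[4], sqrt(0.01 + 0.04))
  expect_equal(td$auto_distance[4], 1.0)           # (0,0) -> (0.6,0.8), 3-4-5
})

test_that("swapping player labels swaps auto and partner distances", {
  log <- toy_log(x = c(0.2, 0.0, 0.5, 0.6), y = c(0.2, 0.0, 0.6, 0.8),
                 referent = rep(0L, 4), correct = rep(TRUE, 4))
  mirrored <- log
  mirrored$tokens$sender_id <- 1L - mirrored$tokens$sender_id
  expect_equal(turn_distances(mirrored)$auto_distance,
               turn_distances(log)$auto_distance)
  expect_equal(turn_distances(mirrored)$partner_distance,
               turn_distances(log)$partner_distance)
})

test_that("rolling dispersion tracks the most recent successful signal per referent", {
  log <- toy_log(x = c(0, 1, 0.5, 0.2), y = c(0, 1, 0.5, 0.2),
                 referent = c(0L, 1L, 2L, 3L),
                 correct = c(TRUE, TRUE, TRUE, FALSE))
  rd <- rolling_dispersion(log)
  expect_true(is.na(rd$dispersion[1]))  # one successful referent only
  expect_equal(rd$dispersion[2], sqrt(2))
  expect_equal(rd$dispersion[3], (sqrt(2) + sqrt(0.5) + sqrt(0.5)) / 3)
  expect_equal(rd$dispersion[4], rd$dispersion[3])  # failures change nothing
})

test_that("final rolling dispersion equals the pairwise mean of the final set", {
  log <- simulate_dyad("outer_edge", 120, seed = 42)
  rd <- rolling_dispersion(log)
  fc <- first_colors(log)
  finals <- do.call(rbind, lapply(split(fc[fc$correct, ], fc$referent_id[fc$correct]),
                                  function(g) g[nrow(g), c("x", "y")]))
  expect_equal(rd$dispersion[nrow(rd)],
               mean_pairwise_distance(finals$x, finals$y))
})

test_that("signal area handles degenerate clouds and removes radial outliers", {
  expect_equal(signal_area(rep(0.4, 5), rep(0.4, 5)), 0)
  expect_equal(signal_area(seq(0, 1, 0.1), seq(0, 1, 0.1)), 0)  # collinear
  expect_error(signal_area(numeric(), numeric()), "empty")
  # a tight ring plus one far outlier: the outlier is dropped, so the area
  # is close to the ring's own area
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  x <- 0.3 + 0.05 * cos(theta)
  y <- 0.3 + 0.05 * sin(theta)
  with_out <- signal_area(c(x, 0.95), c(y, 0.95))
  expect_equal(with_out, signal_area(x, y), tolerance = 1e-12)
})

test_that("signal area is invariant under rotation and translation", {
  withr::with_seed(7, {
    x <- rnorm(30, 0.5, 0.08)
    y <- rnorm(30, 0.5, 0.03)
  })
  base <- signal_area(x, y)
  for (theta in c(0.3, 1.1, 2.6)) {
    xr <- 0.45 + cos(theta) * (x - 0.5) - sin(theta) * (y - 0.5)
    yr <- 0.55 + sin(theta) * (x - 0.5) + cos(theta) * (y - 0.5)
    expect_equal(signal_area(xr, yr), base, tolerance = 1e-9)
  }
})

test_that("turn sections are contiguous, near-equal, with the remainder leading", {
  expect_equal(quintile_of(10), rep(1:5, each = 2))
  expect_equal(quintile_of(12), rep(1:5, times = c(3, 3, 2, 2, 2)))
  for (n in c(5, 7, 23, 101)) {
    q <- quintile_of(n)
    expect_equal(length(q), n)
    expect_true(all(diff(q) >= 0))
    sizes <- as.integer(table(q))
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("quintile clouds are emitted only for referents with successes", {
  # referent 1 succeeds only in the first half
  log <- toy_log(x = c(0.1, 0.9, 0.2, 0.8, 0.15, 0.85, 0.2, 0.8, 0.2, 0.8),
                 y = c(0.1, 0.9, 0.2, 0.8, 0.15, 0.85, 0.2, 0.8, 0.2, 0.8),
                 referent = rep(c(0L, 1L), 5),
                 correct = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                             FALSE, TRUE, FALSE, TRUE, FALSE))
  qa <- quintile_areas(log)
  expect_false(any(qa$clouds$referent_id == 1L & qa$clouds$quintile >= 4L))
  expect_true(all(qa$clouds$area >= 0))
  expect_error(quintile_areas(toy_log(0.5, 0.5, 0L, TRUE)), "at least 5")
})

test_that("descriptive counts summarize the end state of a mastered game", {
  log <- mastered_log(n_turns = 300)
  d <- descriptive_counts(log)
  expect_equal(d$final_s, 12L)
  expect_equal(d$mean_word_length, 1.0)
  expect_equal(d$n_phonemes, 12L)
  expect_gt(d$success_index, 0.8)
})
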