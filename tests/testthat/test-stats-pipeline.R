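test_that("the turn table has one row per trial with explicit missings", {
  empty <- build_turn_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("pair_id", "condition", "turn", "auto_distance",
                    "partner_distance", "rolling_dispersion", "extremeness",
                    "turns_since_new", "quintile", "referent_set")
                  %in% names(empty)))

  log <- toy_log(x = seq(0.1, 1, 0.1), y = seq(0.1, 1, 0.1),
                 referent = rep(c(0L, 0L, 1L, 1L), length.out = 10),
                 correct = rep(TRUE, 10))
  tt <- build_turn_table(log)
  expect_equal(nrow(tt), 10L)
  # trials 1-4 are each referent's first occurrence for that player
  expect_true(all(is.na(tt$auto_distance[1:4])))
  expect_true(all(!is.na(tt$auto_distance[5:10])))
  expect_equal(levels(tt$condition), c("outer_edge", "inner_edge"))
  expect_equal(tt$referent_set, rep(1L, 10L))
})

test_that("turns_since_new resets at the unlock event", {
  tt <- build_turn_table(mastered_log(n_turns = 40))
  u <- which(tt$unlock)[1]
  expect_equal(tt$turns_since_new[u], u - 1L)
  expect_equal(tt$turns_since_new[u + 1L], 0L)
})

make_grouped_table <- function(slope, n_groups = 20, n_per = 50, sd = 0.1,
                               seed = 1) {
  withr::with_seed(seed, {
    g <- rep(seq_len(n_groups), each = n_per)
    x <- runif(n_groups * n_per)
    y <- rnorm(n_groups, 0, 0.3)[g] + slope * x + rnorm(n_groups * n_per, 0, sd)
    data.frame(pair_id = paste0("g", g), y = y, x = x)
  })
}

test_that("an injected fixed-effect slope is recovered", {
  tab <- make_grouped_table(-0.2)
  fit <- fit_trend(tab, "y", fixed = "x", random_intercepts = "pair_id")
  co <- fit$coefficients
  b <- co[co$term == "x", ]
  expect_gt(b$estimate, -0.3)
  expect_lt(b$estimate, -0.1)
  expect_lt(b$p, 0.01)
  expect_true(fit$converged)
})

test_that("a dependent equal to a fixed effect recovers a unit slope", {
  tab <- make_grouped_table(0, sd = 1e-5, seed = 2)
  tab$y <- tab$x + rnorm(nrow(tab), 0, 1e-5)
  fit <- fit_trend(tab, "y", fixed = "x", random_intercepts = "pair_id")
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "x"], 1, tolerance = 1e-2)
  expect_lt(stats::sigma(fit$model), 1e-3)
})

test_that("a permuted dependent rarely shows a significant slope", {
  tab <- make_grouped_table(-0.2, n_groups = 10, n_per = 20, seed = 3)
  tstats <- withr::with_seed(4, replicate(100, {
    tab$y <- sample(tab$y)
    fit <- fit_trend(tab, "y", fixed = "x", random_intercepts = "pair_id")
    abs(fit$coefficients$t[fit$coefficients$term == "x"])
  }))
  expect_gte(mean(tstats < 2), 0.9)
})

test_that("slope reduction is deterministic and drops pair slopes first", {
  # tiny per-group samples make the maximal model singular, forcing reduction
  tab <- make_grouped_table(-0.2, n_groups = 6, n_per = 8, sd = 0.3, seed = 5)
  tab$referent_id <- rep_len(0:3, nrow(tab))
  slopes <- list(pair_id = "x", referent_id = "x")
  f1 <- fit_trend(tab, "y", fixed = "x",
                  random_intercepts = c("pair_id", "referent_id"),
                  random_slopes = slopes)
  f2 <- fit_trend(tab, "y", fixed = "x",
                  random_intercepts = c("pair_id", "referent_id"),
                  random_slopes = slopes)
  expect_identical(f1$dropped_slopes, f2$dropped_slopes)
  expect_identical(f1$coefficients, f2$coefficients)
  if (f1$reduced && length(f1$dropped_slopes) > 0) {
    expect_equal(f1$dropped_slopes[1], "x|pair_id")
  }
})

test_that("unfittable requests return an explicit failure", {
  tab <- data.frame(pair_id = "only_one", y = rnorm(10), x = runif(10))
  fit <- fit_trend(tab, "y", fixed = "x", random_intercepts = "pair_id")
  expect_s3_class(fit, "trend_fit_failure")
  expect_match(fit$error, "grouping factor")
  expect_error(fit_trend(tab, "z", fixed = "x"), "lacks column")
})

test_that("comfort-band first signals show the x-y coupling, uniform ones do not", {
  logs <- lapply(1:12, function(s)
    simulate_dyad("outer_edge", 20, seed = 500 + s, pair_id = paste0("p", s)))
  fs <- first_signal_analysis(logs)
  co <- fs$fit$coefficients
  expect_gt(co$estimate[co$term == "x"], 0)
  expect_lt(co$p[co$term == "x"], 0.05)
  expect_true(all(c("condition", "mean_dist_center", "n") %in%
                    names(fs$condition_means)))

  # null behavior: independent coordinates give few significant slopes
  sig <- withr::with_seed(6, replicate(50, {
    pts <- sample_initial_point(30, agent_params(comfort_correlation = 0))
    tab <- data.frame(x = pts$x, y = pts$y, referent_id = rep_len(0:3, 30))
    fit <- fit_trend(tab, "y", fixed = "x", random_intercepts = "referent_id")
    fit$coefficients$p[fit$coefficients$term == "x"] < 0.05
  }))
  expect_gte(mean(!sig), 0.9)
})

test_that("the report battery is complete, deterministic, and detects dispersion", {
  logs <- simulate_study(n_pairs = 3, n_turns = 150, seed = 77)
  rep1 <- report(logs, null_n = 2000, seed = 9)
  expected <- c("turn_table", "first_signal", "first_signal_initial_referents",
                "first_signal_successful", "dist_center_trend",
                "extremeness_trend", "auto_distance_trend",
                "partner_distance_trend", "partner_by_last_outcome",
                "auto_by_last_outcome", "new_referent_destabilization",
                "quintile_areas", "area_quintile_trend", "area_by_set_trend",
                "per_set_mean_areas", "auto_partner_correlation",
                "partner_by_success", "dispersion_null", "descriptives",
                "density_summary")
  expect_true(all(expected %in% names(rep1)))
  rep2 <- report(logs, null_n = 2000, seed = 9)
  expect_identical(rep1$dispersion_null, rep2$dispersion_null)
  expect_identical(rep1$auto_distance_trend$coefficients,
                   rep2$auto_distance_trend$coefficients)
  cs <- rep1$dispersion_null$condition_summary
  outer <- cs[cs$condition == "outer_edge", ]
  expect_gt(outer$mean_final_dispersion, outer$mean_null)
})
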