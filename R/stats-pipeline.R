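# Trend-analysis battery: derived-variable tables and linear mixed-effects
# fits with a deterministic random-slope reduction protocol.

#' Assemble the per-turn analysis table
#'
#' One row per trial across all logs, with every derived variable the trend
#' analyses use. Missing values (e.g., auto-distance on a referent's first
#' occurrence for a player) are explicit `NA`s.
#'
#' @param logs a list of [game_log()]s (or a single log).
#' @return Data frame with columns `pair_id`, `condition` (factor,
#'   `outer_edge` reference level), `turn`, `sender_id`, `sender` (pair x
#'   player grouping id), `referent_id`, `correct`, `x`, `y`, `brightness`,
#'   `dist_center`, `extremeness`, `auto_distance`, `partner_distance`,
#'   `prev_outcome_own`, `prev_outcome_partner`, `prev_outcome_any`,
#'   `rolling_dispersion`, `s`, `n_active`, `unlock`, `turns_since_new`,
#'   `quintile`, `referent_set`.
#' @export
build_turn_table <- function(logs) {
  if (inherits(logs, "game_log")) logs <- list(logs)
  header <- data.frame(pair_id = character(), condition = character(),
                       turn = integer(), sender_id = integer(),
                       sender = character(), referent_id = integer(),
                       correct = logical(), x = numeric(), y = numeric(),
                       brightness = numeric(), dist_center = numeric(),
                       extremeness = numeric(), auto_distance = numeric(),
                       partner_distance = numeric(),
                       prev_outcome_own = logical(),
                       prev_outcome_partner = logical(),
                       prev_outcome_any = logical(),
                       rolling_dispersion = numeric(), s = integer(),
                       n_active = integer(), unlock = logical(),
                       turns_since_new = integer(), quintile = integer(),
                       referent_set = integer())
  pieces <- lapply(logs, function(log) {
    fc <- first_colors(log)
    traj <- log_mastery(log)
    td <- turn_distances(log)
    rd <- rolling_dispersion(log)
    data.frame(pair_id = log$pair_id, condition = log$condition,
               turn = fc$turn, sender_id = fc$sender_id,
               sender = paste0(log$pair_id, ":", fc$sender_id),
               referent_id = fc$referent_id, correct = fc$correct,
               x = fc$x, y = fc$y,
               brightness = pmax(fc$r, fc$g, fc$b),
               dist_center = distance_from_center(fc$x, fc$y),
               extremeness = extremeness_index(fc$x, fc$y),
               auto_distance = td$auto_distance,
               partner_distance = td$partner_distance,
               prev_outcome_own = td$prev_outcome_own,
               prev_outcome_partner = td$prev_outcome_partner,
               prev_outcome_any = td$prev_outcome_any,
               rolling_dispersion = rd$dispersion,
               s = traj$s, n_active = traj$n_active, unlock = traj$unlock,
               turns_since_new = traj$turns_since_new,
               quintile = quintile_of(nrow(fc)),
               referent_set = fc$referent_id %/% 4L + 1L)
  })
  out <- if (length(pieces)) do.call(rbind, pieces) else header
  out$condition <- factor(out$condition, levels = conditions())
  rownames(out) <- NULL
  out
}

# Ordered random-slope entries for the reduction protocol: pair-level
# slopes are dropped before referent-level slopes, and interaction slopes
# before main-effect slopes within a group.
slope_entries <- function(random_slopes) {
  groups <- names(random_slopes)
  groups <- c(intersect("pair_id", groups), setdiff(groups, "pair_id"))
  out <- list()
  for (g in groups) {
    terms <- random_slopes[[g]]
    terms <- c(grep(":", terms, value = TRUE),
               grep(":", terms, value = TRUE, invert = TRUE))
    for (tm in terms) out[[length(out) + 1L]] <- c(group = g, term = tm)
  }
  out
}

build_formula <- function(dependent, fixed, interactions, intercept_groups,
                          slopes) {
  rhs <- c(fixed, interactions)
  if (!length(rhs)) rhs <- "1"
  re <- character()
  for (g in intercept_groups) {
    tms <- vapply(slopes, function(s) if (s[["group"]] == g) s[["term"]]
                  else NA_character_, character(1))
    tms <- tms[!is.na(tms)]
    re <- c(re, sprintf("(1 %s| %s)",
                        if (length(tms)) paste("+", paste(tms, collapse = " + "), "") else "",
                        g))
  }
  stats::as.formula(paste(dependent, "~", paste(c(rhs, re), collapse = " + ")))
}

fit_ok <- function(m) {
  msgs <- m@optinfo$conv$lme4$messages
  conv_ok <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  conv_ok && !lme4::isSingular(m, tol = 1e-4)
}

tidy_lmer <- function(m) {
  co <- summary(m)$coefficients
  data.frame(term = rownames(co), estimate = co[, "Estimate"],
             se = co[, "Std. Error"], df = co[, "df"],
             t = co[, "t value"], p = co[, "Pr(>|t|)"],
             row.names = NULL)
}

#' Fit a trend model with deterministic random-slope reduction
#'
#' Fits a linear mixed-effects model by REML with Satterthwaite
#' denominator degrees of freedom. If the maximal requested structure
#' fails to converge or is singular, random slopes are removed one at a
#' time in a fixed priority order — pair-level slopes before
#' referent-level slopes, interaction slopes before main-effect slopes —
#' until a converged, non-singular fit is found; the final structure and
#' the dropped terms are recorded. Grouping factors with fewer than two
#' levels are dropped up front. If no random intercept group survives, the
#' result is an explicit failure, never a silent fallback.
#'
#' @param table data frame (see [build_turn_table()]).
#' @param dependent name of the dependent variable.
#' @param fixed character vector of fixed-effect terms.
#' @param interactions character vector of interaction terms
#'   (`"a:b"` form).
#' @param random_intercepts character vector of grouping factors.
#' @param random_slopes named list: for each grouping factor, the terms
#'   given random slopes.
#' @return An object of class `trend_fit`: list with `coefficients` (tidy
#'   data frame: `term`, `estimate`, `se`, `df`, `t`, `p`), `formula`,
#'   `dropped_slopes`, `reduced`, `converged`, `singular`, `n_obs`,
#'   `n_groups`, and `model` (the fitted `lmerModLmerTest`). On failure,
#'   class `trend_fit_failure` with an `error` message.
#' @export
fit_trend <- function(table, dependent, fixed = character(),
                      interactions = character(),
                      random_intercepts = c("pair_id", "referent_id"),
                      random_slopes = list()) {
  base_vars <- unique(unlist(c(dependent, fixed,
                               strsplit(interactions, ":", fixed = TRUE),
                               random_intercepts,
                               lapply(random_slopes, function(v)
                                 unlist(strsplit(v, ":", fixed = TRUE))))))
  missing_cols <- setdiff(base_vars, names(table))
  if (length(missing_cols)) {
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- stats::na.omit(table[, base_vars, drop = FALSE])
  usable <- random_intercepts[vapply(random_intercepts, function(g)
    length(unique(dat[[g]])) >= 2L, logical(1))]
  if (!length(usable)) {
    return(structure(list(error = "no grouping factor with >= 2 levels",
                          dependent = dependent, n_obs = nrow(dat)),
                     class = c("trend_fit_failure", "trend_fit")))
  }
  random_slopes <- random_slopes[names(random_slopes) %in% usable]
  entries <- slope_entries(random_slopes)
  # drop order is from highest priority (first entry) onward
  attempts <- lapply(0:length(entries), function(k) {
    if (k == 0) entries else entries[-seq_len(k)]
  })
  last <- NULL
  for (k in seq_along(attempts)) {
    slopes <- attempts[[k]]
    fml <- build_formula(dependent, fixed, interactions, usable, slopes)
    m <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(fml, data = dat, REML = TRUE))),
      error = function(e) e)
    if (inherits(m, "error")) { last <- m; next }
    last <- m
    if (fit_ok(m)) {
      dropped <- vapply(utils::head(entries, k - 1L), function(s)
        paste0(s[["term"]], "|", s[["group"]]), character(1))
      return(structure(list(coefficients = tidy_lmer(m),
                            formula = fml, dropped_slopes = dropped,
                            reduced = k > 1L, converged = TRUE,
                            singular = FALSE, n_obs = nrow(dat),
                            n_groups = vapply(usable, function(g)
                              length(unique(dat[[g]])), integer(1)),
                            model = m),
                       class = "trend_fit"))
    }
  }
  # fully reduced structure still not clean: report it, flagged
  if (inherits(last, "error")) {
    return(structure(list(error = conditionMessage(last),
                          dependent = dependent, n_obs = nrow(dat)),
                     class = c("trend_fit_failure", "trend_fit")))
  }
  structure(list(coefficients = tidy_lmer(last),
                 formula = build_formula(dependent, fixed, interactions,
                                         usable, list()),
                 dropped_slopes = vapply(entries, function(s)
                   paste0(s[["term"]], "|", s[["group"]]), character(1)),
                 reduced = length(entries) > 0L, converged = FALSE,
                 singular = lme4::isSingular(last, tol = 1e-4),
                 n_obs = nrow(dat),
                 n_groups = vapply(usable, function(g)
                   length(unique(dat[[g]])), integer(1)),
                 model = last),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  if (inherits(x, "trend_fit_failure")) {
    cat("<trend_fit> FAILED:", x$error, "\n")
    return(invisible(x))
  }
  cat("<trend_fit>", deparse(x$formula), "\n")
  if (x$reduced) {
    cat("  reduced; dropped slopes:",
        paste(x$dropped_slopes, collapse = ", "), "\n")
  }
  print(x$coefficients, digits = 3)
  invisible(x)
}

first_trial_table <- function(logs, scope = c("first", "initial_referents",
                                              "first_successful")) {
  scope <- match.arg(scope)
  if (inherits(logs, "game_log")) logs <- list(logs)
  do.call(rbind, lapply(logs, function(log) {
    fc <- first_colors(log)
    rows <- switch(scope,
      first = {
        # each player's very first signal
        idx <- vapply(c(0L, 1L), function(p)
          which(fc$sender_id == p)[1], integer(1))
        idx[!is.na(idx)]
      },
      initial_referents = {
        # each player's first signal for each of the initial four referents
        idx <- integer()
        for (p in c(0L, 1L)) for (r in 0:3) {
          i <- which(fc$sender_id == p & fc$referent_id == r)[1]
          if (!is.na(i)) idx <- c(idx, i)
        }
        idx
      },
      first_successful = {
        # the first successful signal per referent in the pair
        idx <- integer()
        for (r in sort(unique(fc$referent_id))) {
          i <- which(fc$referent_id == r & fc$correct)[1]
          if (!is.na(i)) idx <- c(idx, i)
        }
        idx
      })
    if (!length(rows)) return(NULL)
    out <- fc[rows, , drop = FALSE]
    out$pair_id <- log$pair_id
    out$condition <- log$condition
    out
  }))
}

#' Initial-behavior analysis of first signals
#'
#' Fits a mixed model predicting the `y` from the `x` coordinate of first
#' signals, with random intercepts for referents (a positive slope is the
#' signature of comfort-band exploration), and reports per-condition mean
#' distance from center of those signals.
#'
#' @param logs list of [game_log()]s.
#' @param scope `"first"` (each player's very first signal),
#'   `"initial_referents"` (first signal for each of the initial four
#'   referents), or `"first_successful"` (first successful signal per
#'   referent).
#' @return List with `fit` (a [fit_trend()] result for `y ~ x +
#'   (1|referent_id)`), `condition_means` (data frame of mean
#'   distance-from-center by condition), and `table`.
#' @export
first_signal_analysis <- function(logs, scope = "first") {
  tab <- first_trial_table(logs, scope)
  if (is.null(tab) || nrow(tab) == 0L) stop("no first signals", call. = FALSE)
  tab$dist_center <- distance_from_center(tab$x, tab$y)
  fit <- fit_trend(tab, "y", fixed = "x",
                   random_intercepts = "referent_id")
  means <- do.call(rbind, lapply(split(tab, tab$condition), function(g) {
    data.frame(condition = g$condition[1],
               mean_dist_center = mean(g$dist_center), n = nrow(g))
  }))
  rownames(means) <- NULL
  list(fit = fit, condition_means = means, table = tab)
}

with_condition <- function(tt, fixed, interactions = character()) {
  # drop condition terms when the table has a single condition
  if (length(unique(tt$condition[!is.na(tt$condition)])) >= 2L) {
    list(fixed = fixed, interactions = interactions)
  } else {
    keep <- function(v) v[!grepl("condition", v)]
    list(fixed = keep(fixed), interactions = keep(interactions))
  }
}

pair_areas <- function(logs) {
  do.call(rbind, lapply(logs, function(log) {
    qa <- quintile_areas(log)$clouds
    if (nrow(qa) == 0L) return(NULL)
    qa$pair_id <- log$pair_id
    qa$condition <- log$condition
    qa$referent_set <- qa$referent_id %/% 4L + 1L
    qa
  }))
}

#' Run the full analysis battery over a set of game logs
#'
#' Reproduces the exploratory-analysis battery on whatever logs are
#' supplied (simulated or read from disk): initial behavior, the
#' distance-from-center, extremeness, auto-distance and partner-distance
#' trends, quintile signal-area models, outcome-contingent convergence,
#' destabilization by new referents, the auto-/partner-distance
#' correlation across pairs, dispersion against the matched-size
#' chance-level null, per-referent-set mean areas, descriptive counts, and
#' a grid density summary of final successful signals. Individual analyses
#' that cannot be fit on the supplied logs are reported as failures rather
#' than aborting the battery. Deterministic given `logs` and `seed`.
#'
#' @param logs list of [game_log()]s.
#' @param out_dir if non-`NULL`, results are written as CSV/JSON via
#'   [write_results()].
#' @param null_n inventories per Monte Carlo null.
#' @param seed seed for the null generation.
#' @param merge_threshold Pillai threshold for phoneme counts.
#' @return Named list of analysis results (see Details); names are stable
#'   and an entry is present for every analysis in the battery.
#' @export
report <- function(logs, out_dir = NULL, null_n = 10000L, seed = 1L,
                   merge_threshold = 0.3) {
  if (inherits(logs, "game_log")) logs <- list(logs)
  stopifnot(length(logs) >= 1L)
  tt <- build_turn_table(logs)
  safe <- function(expr) {
    tryCatch(expr, error = function(e)
      structure(list(error = conditionMessage(e)), class = "battery_failure"))
  }
  out <- list(turn_table = tt)

  out$first_signal <- safe(first_signal_analysis(logs, "first"))
  out$first_signal_initial_referents <-
    safe(first_signal_analysis(logs, "initial_referents"))
  out$first_signal_successful <-
    safe(first_signal_analysis(logs, "first_successful"))

  trend <- function(dep, fixed, inter, slopes = list()) {
    tm <- with_condition(tt, fixed, inter)
    safe(fit_trend(tt, dep, fixed = tm$fixed, interactions = tm$interactions,
                   random_intercepts = c("pair_id", "referent_id"),
                   random_slopes = slopes))
  }
  out$dist_center_trend <- trend("dist_center", c("turn", "condition"),
                                 "turn:condition")
  out$extremeness_trend <- trend("extremeness", c("turn", "condition"),
                                 "turn:condition")
  out$auto_distance_trend <- trend("auto_distance", c("turn", "condition"),
                                   "turn:condition",
                                   slopes = list(referent_id = "condition"))
  out$partner_distance_trend <- trend("partner_distance",
                                      c("turn", "condition"),
                                      "turn:condition",
                                      slopes = list(referent_id = "condition"))
  out$partner_by_last_outcome <- trend(
    "partner_distance", c("prev_outcome_any", "turn", "condition"),
    c("prev_outcome_any:condition", "turn:condition"),
    slopes = list(referent_id = "prev_outcome_any"))
  out$auto_by_last_outcome <- trend(
    "auto_distance", c("prev_outcome_any", "turn", "condition"),
    c("prev_outcome_any:condition", "turn:condition"))
  out$new_referent_destabilization <- safe({
    tm <- with_condition(tt, c("turns_since_new", "turn", "condition"),
                         c("turns_since_new:condition", "turn:condition",
                           "turns_since_new:turn:condition"))
    fit_trend(tt, "auto_distance", fixed = tm$fixed,
              interactions = tm$interactions,
              random_intercepts = c("pair_id", "referent_id", "sender"))
  })

  areas <- pair_areas(logs)
  out$quintile_areas <- areas
  out$area_quintile_trend <- safe({
    pm <- do.call(rbind, lapply(
      split(areas, list(areas$pair_id, areas$quintile), drop = TRUE),
      function(g) data.frame(pair_id = g$pair_id[1],
                             condition = g$condition[1],
                             quintile = g$quintile[1],
                             log_mean_area = log(mean(g$area) + 1e-6))))
    pm$condition <- factor(pm$condition, levels = conditions())
    tm <- with_condition(pm, c("quintile", "condition"),
                         "quintile:condition")
    fit_trend(pm, "log_mean_area", fixed = tm$fixed,
              interactions = tm$interactions,
              random_intercepts = "pair_id")
  })
  out$area_by_set_trend <- safe({
    a2 <- areas
    a2$condition <- factor(a2$condition, levels = conditions())
    tm <- with_condition(a2, c("referent_set", "quintile", "condition"),
                         c("referent_set:condition", "quintile:condition"))
    fit_trend(a2, "area", fixed = tm$fixed, interactions = tm$interactions,
              random_intercepts = c("pair_id", "referent_id"))
  })
  out$per_set_mean_areas <- safe({
    ms <- do.call(rbind, lapply(split(areas, areas$referent_set), function(g)
      data.frame(referent_set = g$referent_set[1],
                 mean_area = mean(g$area), n_clouds = nrow(g))))
    rownames(ms) <- NULL
    ms
  })

  out$auto_partner_correlation <- safe({
    pm <- do.call(rbind, lapply(split(tt, tt$pair_id), function(g)
      data.frame(pair_id = g$pair_id[1], condition = g$condition[1],
                 mean_auto = mean(g$auto_distance, na.rm = TRUE),
                 mean_partner = mean(g$partner_distance, na.rm = TRUE),
                 success_index = sum(g$s) / (12 * nrow(g)))))
    ct <- stats::cor.test(pm$mean_auto, pm$mean_partner)
    list(r = unname(ct$estimate), df = unname(ct$parameter),
         p = ct$p.value, pair_means = pm)
  })
  out$partner_by_success <- safe({
    if (inherits(out$auto_partner_correlation, "battery_failure")) {
      stop("pair means unavailable")
    }
    tt2 <- tt
    si <- out$auto_partner_correlation$pair_means
    tt2$success_index <- si$success_index[match(tt2$pair_id, si$pair_id)]
    tm <- with_condition(tt2, c("success_index", "condition"),
                         "success_index:condition")
    fit_trend(tt2, "partner_distance", fixed = tm$fixed,
              interactions = tm$interactions,
              random_intercepts = c("pair_id", "referent_id"),
              random_slopes = list(referent_id = "condition"))
  })

  out$dispersion_null <- safe({
    per_pair <- do.call(rbind, lapply(seq_along(logs), function(i) {
      log <- logs[[i]]
      rd <- rolling_dispersion(log)
      final <- rd[nrow(rd), ]
      size <- max(2L, final$n_referents)
      null <- generate_null("pairwise", inventory_size = size,
                            n_inventories = null_n, seed = seed + i)
      data.frame(pair_id = log$pair_id, condition = log$condition,
                 mean_dispersion = mean(rd$dispersion, na.rm = TRUE),
                 final_dispersion = final$dispersion,
                 final_set_size = final$n_referents,
                 null_mean = null$mean,
                 p_above_chance = empirical_p(final$dispersion, null, "upper"))
    }))
    cond <- do.call(rbind, lapply(split(per_pair, per_pair$condition),
                                  function(g)
      data.frame(condition = g$condition[1],
                 mean_dispersion = mean(g$mean_dispersion),
                 mean_final_dispersion = mean(g$final_dispersion),
                 mean_null = mean(g$null_mean), n_pairs = nrow(g))))
    rownames(cond) <- NULL
    list(per_pair = per_pair, condition_summary = cond)
  })

  out$descriptives <- safe({
    d <- do.call(rbind, lapply(logs, function(log) {
      dc <- descriptive_counts(log, merge_threshold = merge_threshold)
      cbind(data.frame(pair_id = log$pair_id, condition = log$condition), dc)
    }))
    rownames(d) <- NULL
    d
  })

  out$density_summary <- safe({
    # grid counts of final successful signals, the heat-map analog
    do.call(rbind, lapply(split(tt, tt$condition), function(g) {
      pts <- do.call(rbind, lapply(split(g, g$pair_id), function(p) {
        ok <- p[p$correct, , drop = FALSE]
        do.call(rbind, lapply(split(ok, ok$referent_id), function(r)
          r[nrow(r), c("x", "y")]))
      }))
      if (is.null(pts)) return(NULL)
      gx <- pmin(floor(pts$x * 10) + 1L, 10L)
      gy <- pmin(floor(pts$y * 10) + 1L, 10L)
      counts <- as.data.frame(table(cell_x = factor(gx, levels = 1:10),
                                    cell_y = factor(gy, levels = 1:10)))
      counts$condition <- g$condition[1]
      counts
    }))
  })

  if (!is.null(out_dir)) {
    write_results(out, out_dir, seed = seed,
                  config = list(null_n = null_n,
                                merge_threshold = merge_threshold))
  }
  out
}
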