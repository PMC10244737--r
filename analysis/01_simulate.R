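#!/usr/bin/env Rscript
# Simulate the study: 10 dyads per condition playing 250-turn games, and
# write their logs as CSV for the downstream analysis scripts.

suppressPackageStartupMessages(library(dispersim))

seed <- 20260921L
logs <- simulate_study(n_pairs = 10, n_turns = 250, seed = seed)

dir.create("results/logs", recursive = TRUE, showWarnings = FALSE)
for (id in names(logs)) {
  write_game_log(logs[[id]], file.path("results/logs", paste0(id, ".csv")))
}

si <- vapply(logs, success_index, numeric(1))
na <- vapply(logs, function(l) log_mastery(l)$n_active[250], integer(1))
cond <- vapply(logs, function(l) l$condition, character(1))
cat(sprintf("Simulated %d dyads (seed %d) into results/logs/\n",
            length(logs), seed))
for (cn in conditions()) {
  cat(sprintf("  %s: mean success index %.3f, mean final referent set %.1f\n",
              cn, mean(si[cond == cn]), mean(na[cond == cn])))
}
cat("The conditions differ in where bright, distinct colors live: at the\n")
cat("pad's rim (outer edge) or on an interior ridge (inner edge). The\n")
cat("contrast surfaces downstream as more extreme, more dispersed signal\n")
cat("placement in the outer-edge condition (see 03 and 04).\n")
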