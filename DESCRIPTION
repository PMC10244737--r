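Package: dispersim
Title: Dispersion Dynamics in a Color-Signaling Communication Game
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analyzing dyadic color-signaling
    communication games in which pairs of players establish signals for a
    growing set of referents by selecting points on a continuous signal pad.
    Provides the game's referent-unlocking (mastery) rules, per-turn
    dispersion and convergence metrics (mean pairwise distance, distance
    from center, extremeness index, auto- and partner distance, rolling
    dispersion, PCA-ellipse signal areas), Monte Carlo chance-level null
    distributions for inventory dispersion, Pillai-trace identification of
    color phonemes, an agent-based dyad simulator, and a linear
    mixed-effects trend-analysis battery with a deterministic
    random-slope reduction protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
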