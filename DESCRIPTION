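Package: gdprofiler
Title: Individual Soccer Player Effort Profiles from Goal Difference and
    Pre-Game Expectations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models a soccer player's cumulative energy expenditure (J/kg,
    from GPS-derived 5-minute interval records) as a function of the
    in-game goal difference, the pre-game expectation (favorite versus
    non-favorite, from betting odds), and an exponential endurance decay.
    Player-specific power levels and the endurance coefficient are
    estimated by bounded derivative-free optimization (Nelder-Mead and
    particle swarm), compared against mean- and median-power baselines
    with standard regression metrics, and post-processed into an
    influence matrix that profiles how score context shifts a player's
    effort.  Includes a synthetic match and trace generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
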