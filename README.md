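# gdprofiler

Individual soccer player effort profiles from goal difference and
pre-game expectations.

## What it does

GPS wearables report a player's external load as energy expenditure
(J/kg) in 5-minute intervals.  `gdprofiler` models a player's cumulative
energy over a stint as

    dE/dτ = P(d(t), e) · exp(−α τ),    α = −ln(η90)/90,    E(0) = 0

where `d(t)` is the in-game goal difference (clipped to −2…+2, changing
exactly at goal minutes), `e` marks whether the team entered as the
betting favorite (odds ratio `p_win/p_lose ≥ 2`) or not, `τ` is the
player's own playing clock, and `η90 ∈ [0.5, 1]` is the endurance
coefficient — the fraction of initial power left after 90 minutes on
the pitch.  The eleven player-specific parameters (ten powers
`P(d, e) ∈ [200, 800]` J/kg/min plus `η90`) are estimated from a season
of interval records by bounded Nelder–Mead and particle swarm
optimization (best of 10 restarts each; their agreement is a confidence
check), compared against mean-power (B1) and median-power (B2)
baselines with MAE/RMSE/MSE, and summarized as a dimensionless
influence matrix `g(e, d) = P(d, e) / r(d)` — how far each score
context pushes a player above or below their minutes-weighted reference
effort at that GD.

The package includes a synthetic season generator with known ground
truth (odds and goal times driven by the same Poisson scoring rates,
substitutions, discarded warm-up/halftime records, additive sensor
noise), so the whole pipeline is testable without any proprietary
tracking data.  It is aimed at sports scientists and analysts who want
per-player, context-aware load profiles rather than squad-level
averages.

## Worked example

Fit one synthetic player whose scripted schedule visits every
(GD, expectation) state, with realistic sensor noise (σ = 150 J/kg per
record):

```r
library(gdprofiler)

cfg <- synthetic_config(n_players = 1, n_games = 8, games_per_player = 8,
                        p_sub = 0, noise_sd = 150,
                        scripted_games = coverage_schedule(), seed = 42)
ds    <- generate_dataset(cfg)
games <- dataset_player_games(ds, "athlete01")

pair <- run_player_fit(games, fit_config(seed = 1))
pair
#> NM cost 47314.2 | PSO cost 47314.2 | relative gap 2.06e-09% | agree

pair$NM$parameters
#> Player model parameters (J/kg per minute):
#>     expectation
#> gd        f     nf
#>   -2 687.11 544.09
#>   -1 706.24 612.10
#>   0  363.60 316.36
#>   1  655.30 503.89
#>   2  540.90 594.65
#> eta90 = 0.8593  (alpha = 0.001685 / min)
```

Both optimizers land on the same cost (the agreement flag would warn if
they disagreed by more than 5%), and the estimates sit close to the
generator's truth (e.g. true `P(0, f)` = 393.1 vs fitted 363.6, true
`η90` = 0.835 vs fitted 0.859 from noisy data).  The influence matrix
and the baseline comparison:

```r
labeled <- do.call(rbind, lapply(games, `[[`, "intervals"))
influence_matrix(pair$NM$parameters, minutes_ledger(labeled))
#> Influence matrix g (power relative to GD reference r):
#>     expectation
#> gd       f    nf
#>   -2 1.116 0.884
#>   -1 1.071 0.929
#>   0  1.069 0.931
#>   1  1.131 0.869
#>   2  0.953 1.047

score_player(games, list(model_NM = pair$NM$parameters,
                         B1 = baseline_powers(labeled, "mean"),
                         B2 = baseline_powers(labeled, "median")),
             player_id = "athlete01")
#>   player_id   method   mae  rmse   mse   n
#> 1 athlete01 model_NM 112.4 144.6 20900 128
#> 2 athlete01       B1 239.2 293.9 86374 128
#> 3 athlete01       B2 237.5 296.7 88028 128
```

Reading the profile: `g(f, 1) = 1.13` says this player works about 13%
above their GD+1 reference effort when the team is the favorite, and
`g(nf, 1) = 0.87` that they drop well below it otherwise; the model
halves the baselines' MAE because neither baseline can represent the
expectation split or the endurance decay.  `run_pipeline()` runs the
same steps for every player and writes `labeled.csv`,
`fit_results.json`, `metrics.csv`, per-player profile JSONs and a
manifest that reproduces the run byte-for-byte;
`inst/scripts/profiler.R` is a command-line wrapper around it.

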