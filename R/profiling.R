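#' Minutes played per goal difference and expectation
#'
#' Sums labeled interval lengths into the 5 x 2 ledger of minutes spent
#' at each (GD, expectation) state, the data-density companion to a
#' player's power profile.
#'
#' @param labeled Data frame of labeled intervals ([label_intervals()]),
#'   pooled over a player's games; zero rows give an all-zero ledger.
#' @return A 5 x 2 matrix of class `"minutes_ledger"` (rows GD `-2..2`,
#'   columns `f`/`nf`); row sums are the minutes per GD.
#' @export
minutes_ledger <- function(labeled) {
  m <- matrix(0, 5, 2, dimnames = list(gd = .GD_LEVELS, expectation = .EXP_LEVELS))
  if (!is.null(labeled) && nrow(labeled) > 0L) {
    len <- labeled$end_min - labeled$start_min
    for (i in seq_len(nrow(labeled))) {
      m[as.character(labeled$gd[i]), labeled$expectation[i]] <-
        m[as.character(labeled$gd[i]), labeled$expectation[i]] + len[i]
    }
  }
  structure(m, class = c("minutes_ledger", "matrix"))
}

#' Influence matrix of goal difference and expectation on effort
#'
#' For each GD level `d`, the reference power `r[d]` is the
#' minutes-weighted mean of the fitted powers over the two expectation
#' classes, and the influence `g[d, e] = P[d, e] / r[d]` expresses a
#' state's power relative to that reference: values above 1 mean
#' elevated effort in that state, below 1 reduced effort.  Cells with no
#' observed minutes are undefined (`NA`), and a GD with minutes in only
#' one class has `g = 1` there by construction.  The minutes-weighted
#' mean of `g` over expectations is exactly 1 at every defined GD.
#'
#' @param params A [player_parameters()] fit.
#' @param ledger A [minutes_ledger()].
#' @return Object of class `"influence_matrix"`: list with `r` (named
#'   reference power per GD, `NA` where unobserved), `g` (5 x 2 matrix)
#'   and `defined` (logical 5 x 2 mask).
#' @examples
#' p <- player_parameters(cbind(rep(600, 5), rep(400, 5)), eta90 = 1)
#' led <- minutes_ledger(data.frame(start_min = c(10, 20), end_min = c(15, 25),
#'                                  energy = 3000, playing_flag = TRUE,
#'                                  gd = 0, expectation = c("f", "nf"),
#'                                  tau_start = c(10, 20)))
#' influence_matrix(p, led)$g["0", ]  # 1.2 (f) and 0.8 (nf)
#' @export
influence_matrix <- function(params, ledger) {
  stopifnot(inherits(params, "player_parameters"),
            inherits(ledger, "minutes_ledger"))
  t_d <- rowSums(ledger)
  if (all(t_d == 0)) stop("ledger has zero minutes at every GD")
  P <- params$P
  r <- ifelse(t_d > 0,
              (P[, "f"] * ledger[, "f"] + P[, "nf"] * ledger[, "nf"]) / t_d,
              NA_real_)
  g <- P / r  # recycles r down both columns
  g[unclass(ledger) == 0] <- NA_real_
  structure(list(r = stats::setNames(r, .GD_LEVELS),
                 g = g,
                 defined = unclass(ledger) > 0),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat("Influence matrix g (power relative to GD reference r):\n")
  print(round(x$g, 3))
  cat("Reference powers r (J/kg per minute):\n")
  print(round(x$r, 1))
  out_of_range <- x$g[x$defined]
  if (any(out_of_range < 0.5 | out_of_range > 1.5)) {
    cat("note: influence values outside the typical 0.5-1.5 range\n")
  }
  invisible(x)
}

#' Per-game overlay of measured and modeled cumulative energy
#'
#' Builds the comparison curve behind a per-game fit plot: the simulated
#' cumulative trace at 1-minute resolution and the measured cumulative
#' energy at the kept interval boundaries (rebased per gap-free block,
#' matching the fitting cost).
#'
#' @param params A [player_parameters()] object.
#' @param game One game entry (`list(intervals, timeline, stint,
#'   expectation)`).
#' @param dt Euler step.
#' @return Data frame with `game_min`, `gd`, `predicted_cum` and
#'   `measured_cum` (`NA` off the measured knots).
#' @export
game_overlay <- function(params, game, dt = 1) {
  tr <- simulate_energy(params, game$timeline, game$stint, game$expectation,
                        dt = dt)
  df <- data.frame(game_min = tr$game_min, gd = tr$gd,
                   predicted_cum = tr$cumulative,
                   measured_cum = NA_real_)
  iv <- game$intervals
  if (nrow(iv) > 0L) {
    iv <- iv[order(iv$start_min), , drop = FALSE]
    new_block <- c(TRUE, abs(iv$start_min[-1L] - iv$end_min[-nrow(iv)]) > 1e-9)
    bid <- cumsum(new_block)
    for (rows in split(seq_len(nrow(iv)), bid)) {
      knots <- c(iv$start_min[rows[1L]], iv$end_min[rows])
      base_idx <- which(abs(df$game_min - knots[1L]) < 1e-8)
      cum <- c(0, cumsum(iv$energy[rows])) + df$predicted_cum[base_idx]
      for (k in seq_along(knots)) {
        j <- which(abs(df$game_min - knots[k]) < 1e-8)
        if (length(j)) df$measured_cum[j] <- cum[k]
      }
    }
  }
  df
}

#' Assemble a player's profile report
#'
#' Collects everything a practitioner-facing profile needs: fitted
#' powers for both methods, endurance, the influence matrix, the minutes
#' ledger, identifiability flags and per-game fit summaries.  Serialize
#' with [write_profile()]; the JSON round-trips losslessly through
#' [read_profile()].
#'
#' @param player_id Player identifier.
#' @param fits A [run_player_fit()] result (or a list with `NM`/`PSO`
#'   `player_fit` entries).
#' @param influence An [influence_matrix()].
#' @param ledger A [minutes_ledger()].
#' @param game_fits Optional named list of per-game summaries (e.g. cost
#'   contributions or [game_overlay()] digests).
#' @return List of class `"profile_report"`.
#' @export
profile_report <- function(player_id, fits, influence, ledger,
                           game_fits = NULL) {
  stopifnot(inherits(influence, "influence_matrix"),
            inherits(ledger, "minutes_ledger"))
  methods <- list()
  for (m in intersect(c("NM", "PSO"), names(fits))) {
    ft <- fits[[m]]
    methods[[m]] <- list(x_hat = as.list(ft$x_hat),
                         cost = ft$cost,
                         n_evaluations = ft$n_evaluations,
                         restart_costs = ft$restart_costs)
  }
  structure(list(
    player_id = player_id,
    methods = methods,
    eta90 = fits$NM$parameters$eta90,
    alpha = fits$NM$parameters$alpha,
    influence = list(r = as.list(influence$r),
                     g = .matrix_to_list(influence$g),
                     defined = .matrix_to_list(influence$defined * 1)),
    minutes = .matrix_to_list(unclass(ledger)),
    identifiable = if (!is.null(fits$identifiable)) as.list(fits$identifiable) else NULL,
    agreement = fits$agreement,
    cost_gap = fits$cost_gap,
    game_fits = game_fits
  ), class = "profile_report")
}

.matrix_to_list <- function(m) {
  out <- lapply(seq_len(ncol(m)), function(j) as.list(stats::setNames(m[, j], rownames(m))))
  stats::setNames(out, colnames(m))
}

#' Write a profile report to JSON
#' @param report A [profile_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a profile report back from JSON
#' @param path File written by [write_profile()].
#' @return The report as a list (class `"profile_report"`).
#' @export
read_profile <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "profile_report")
}
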