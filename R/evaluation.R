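#' Baseline power levels per goal difference
#'
#' The two reference predictors ignore expectation and endurance: B1
#' uses the mean, B2 the median, of the observed power (interval energy
#' divided by interval length) per GD, with the endurance coefficient
#' fixed at 1.  A GD level with no labeled records falls back to the
#' all-data statistic and is flagged.
#'
#' @param labeled Data frame of labeled intervals ([label_intervals()]),
#'   possibly pooled across games; needs columns `gd`, `energy`,
#'   `start_min`, `end_min`.
#' @param method `"mean"` (B1) or `"median"` (B2).
#' @return Object of class `"baseline_parameters"`: list with `method`,
#'   `P` (named power per GD, J/kg per minute), `fallback` (logical per
#'   GD) and `eta90 = 1`.
#' @export
baseline_powers <- function(labeled, method = c("mean", "median")) {
  method <- match.arg(method)
  if (is.null(labeled) || nrow(labeled) == 0L) {
    stop("no labeled intervals to build a baseline from")
  }
  stat <- if (method == "mean") mean else stats::median
  rate <- labeled$energy / (labeled$end_min - labeled$start_min)
  P <- numeric(5)
  fallback <- logical(5)
  overall <- stat(rate)
  for (i in seq_along(.GD_LEVELS)) {
    sel <- labeled$gd == as.integer(.GD_LEVELS[i])
    if (any(sel)) {
      P[i] <- stat(rate[sel])
    } else {
      P[i] <- overall
      fallback[i] <- TRUE
    }
  }
  structure(list(method = method,
                 P = stats::setNames(P, .GD_LEVELS),
                 fallback = stats::setNames(fallback, .GD_LEVELS),
                 eta90 = 1),
            class = "baseline_parameters")
}

#' Predict interval energies from fitted or baseline parameters
#'
#' The shared prediction path used to score the model and the baselines
#' identically.  Fitted [player_parameters()] go through the forward
#' simulation ([simulate_energy()] + [interval_energies()]); baseline
#' parameters predict `P[gd] * length` with no decay.
#'
#' @param params A [player_parameters()] or [baseline_parameters()]
#'   object.
#' @param games Per-player list of games (see [fit_nelder_mead()]).
#' @param dt Euler step for the model path.
#' @return Data frame with one row per labeled interval: `game_id`,
#'   `start_min`, `end_min`, `gd`, `expectation`, `measured` and
#'   `predicted` energies (J/kg).
#' @export
predict_intervals <- function(params, games, dt = 1) {
  .validate_games(games)
  out <- lapply(games, function(g) {
    iv <- g$intervals
    if (nrow(iv) == 0L) return(NULL)
    pred <- if (inherits(params, "player_parameters")) {
      tr <- simulate_energy(params, g$timeline, g$stint, g$expectation, dt = dt)
      interval_energies(tr, iv, g$stint)
    } else if (inherits(params, "baseline_parameters")) {
      params$P[as.character(iv$gd)] * (iv$end_min - iv$start_min)
    } else {
      stop("'params' must be player_parameters or baseline_parameters")
    }
    data.frame(game_id = if (!is.null(g$stint$game_id)) g$stint$game_id else NA,
               start_min = iv$start_min, end_min = iv$end_min,
               gd = iv$gd, expectation = iv$expectation,
               measured = iv$energy, predicted = as.numeric(pred))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Regression metrics between predicted and measured interval energies
#'
#' @param predicted,measured Equal-length numeric vectors (J/kg per
#'   5-minute interval).
#' @return List of class `"metrics"`: `mae`, `rmse`, `mse`, `n`.
#'   `rmse = sqrt(mse)` and `mae <= rmse` always hold.
#' @export
compute_metrics <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    stop("'predicted' and 'measured' must have equal length")
  }
  if (length(predicted) == 0L) stop("need at least one prediction pair")
  r <- predicted - measured
  mse <- mean(r^2)
  structure(list(mae = mean(abs(r)), rmse = sqrt(mse), mse = mse,
                 n = length(r)),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("MAE %.2f | RMSE %.2f | MSE %.2f  (n = %d intervals)\n",
              x$mae, x$rmse, x$mse, x$n))
  invisible(x)
}

#' Score a player's games under several parameter sets
#'
#' Convenience wrapper producing one metrics row per method, the shape
#' written to `metrics.csv` by [run_pipeline()].
#'
#' @param games Per-player list of games.
#' @param params_list Named list of [player_parameters()] /
#'   [baseline_parameters()] objects (e.g. `model_NM`, `model_PSO`,
#'   `B1`, `B2`).
#' @param player_id Identifier copied into the rows.
#' @return Data frame with columns `player_id`, `method`, `mae`, `rmse`,
#'   `mse`, `n`.
#' @export
score_player <- function(games, params_list, player_id = NA) {
  rows <- lapply(names(params_list), function(nm) {
    pr <- predict_intervals(params_list[[nm]], games)
    m <- compute_metrics(pr$predicted, pr$measured)
    data.frame(player_id = player_id, method = nm,
               mae = m$mae, rmse = m$rmse, mse = m$mse, n = m$n)
  })
  do.call(rbind, rows)
}

#' Aggregate per-player metrics across players
#'
#' @param metrics Data frame as returned by [score_player()] (stacked
#'   over players).
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return Data frame with one row per method and columns `method`,
#'   `mae_mean`, `mae_sd`, `rmse_mean`, `rmse_sd`, `mse_mean`, `mse_sd`,
#'   `n_players`; players are weighted equally.
#' @export
aggregate_metrics <- function(metrics, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  sdev <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  rows <- lapply(split(metrics, metrics$method), function(d) {
    data.frame(method = d$method[1L],
               mae_mean = mean(d$mae), mae_sd = sdev(d$mae),
               rmse_mean = mean(d$rmse), rmse_sd = sdev(d$rmse),
               mse_mean = mean(d$mse), mse_sd = sdev(d$mse),
               n_players = nrow(d))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
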