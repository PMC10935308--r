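#' Configuration for player-model fitting
#'
#' Box constraints, restart count, seed and optimizer settings shared by
#' [fit_nelder_mead()] and [fit_pso()].
#'
#' @param lower_power,upper_power Bounds on every power level
#'   (J/kg per minute); default `[200, 800]`.
#' @param eta90_bounds Bounds on the endurance coefficient, default
#'   `c(0.5, 1)`.
#' @param n_restarts Independent optimizer restarts per method; the best
#'   result is kept (default 10).
#' @param seed Integer seed driving start points and the swarm.
#' @param nm Named list overriding Nelder-Mead settings: `maxit` (4000),
#'   `reltol` (1e-12), `abstol` (1e-10), `max_rounds` (12; the simplex
#'   is restarted from its own solution until the per-round improvement
#'   falls below the relative `round_tol`), `round_tol` (1e-10).
#' @param pso Named list overriding particle-swarm settings:
#'   `swarm_size` (25), `inertia` (0.72), `cognitive` and `social`
#'   (1.49), `max_iter` (800), `stagnation` (75 iterations without
#'   improvement), `vmax_frac` (velocity clamp as a fraction of the box
#'   width, 0.5).
#' @param agreement_tol Relative cost gap above which the two methods
#'   are flagged as disagreeing (default 0.05).
#' @param dt Euler/comparison grid step in minutes.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(lower_power = 200, upper_power = 800,
                       eta90_bounds = c(0.5, 1), n_restarts = 10,
                       seed = 1L, nm = list(), pso = list(),
                       agreement_tol = 0.05, dt = 1) {
  stopifnot(n_restarts >= 1, lower_power < upper_power,
            eta90_bounds[1] < eta90_bounds[2])
  nm_def <- list(maxit = 4000, reltol = 1e-12, abstol = 1e-10,
                 max_rounds = 12, round_tol = 1e-10)
  pso_def <- list(swarm_size = 25, inertia = 0.72, cognitive = 1.49,
                  social = 1.49, max_iter = 800, stagnation = 75,
                  vmax_frac = 0.5)
  nm_def[names(nm)] <- nm
  pso_def[names(pso)] <- pso
  structure(list(lower = c(rep(lower_power, 10), eta90_bounds[1]),
                 upper = c(rep(upper_power, 10), eta90_bounds[2]),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 nm = nm_def, pso = pso_def,
                 agreement_tol = agreement_tol, dt = dt),
            class = "fit_config")
}

# Restart start points: box midpoint first (for NM), the rest uniform in
# the box from the seeded generator.
.restart_starts <- function(config) {
  k <- length(config$lower)
  starts <- matrix(stats::runif(config$n_restarts * k, config$lower,
                                config$upper),
                   nrow = config$n_restarts, ncol = k, byrow = TRUE)
  starts[1L, ] <- (config$lower + config$upper) / 2
  starts
}

.new_fit_result <- function(x_hat, cost, method, n_evaluations,
                            total_evaluations, restart_costs, trace) {
  structure(list(parameters = from_param_vector(x_hat, validate = FALSE),
                 x_hat = stats::setNames(x_hat, param_names()),
                 cost = cost, method = method,
                 n_evaluations = n_evaluations,
                 total_evaluations = total_evaluations,
                 restart_costs = restart_costs,
                 convergence_trace = trace),
            class = "player_fit")
}

#' @export
print.player_fit <- function(x, ...) {
  cat(sprintf("%s fit: cost %.6g (J/kg)^2/min, %d evaluations (best restart), %d total\n",
              x$method, x$cost, x$n_evaluations, x$total_evaluations))
  print(x$parameters)
  invisible(x)
}

#' Fit a player's parameters with bounded Nelder-Mead
#'
#' Minimizes [cost_function()] over the 11-dimensional box with the
#' Nelder-Mead simplex (`stats::optim`), bounds enforced by clipping
#' candidate points into the box before evaluation.  The best of
#' `n_restarts` runs (box midpoint plus seeded uniform starts) is kept;
#' each run restarts the simplex once from its own solution to polish.
#'
#' @param games Per-player list of games: each element a
#'   `list(intervals, timeline, stint, expectation)` as produced by
#'   [label_intervals()], [build_gd_timeline()] and
#'   [compute_expectation()] (see [assemble_player_games()]).
#' @param config A [fit_config()].
#' @return Object of class `"player_fit"`: `parameters`
#'   ([player_parameters()]), `x_hat`, `cost`, `n_evaluations` (best
#'   restart), `total_evaluations`, `restart_costs` and
#'   `convergence_trace` (best cost per evaluation of the best restart).
#' @export
fit_nelder_mead <- function(games, config = fit_config()) {
  ctx <- make_cost_context(games, dt = config$dt)
  lower <- config$lower
  upper <- config$upper
  set.seed(config$seed)
  starts <- .restart_starts(config)

  best <- NULL
  restart_costs <- numeric(config$n_restarts)
  total_evals <- 0L
  for (r in seq_len(config$n_restarts)) {
    rec <- new.env(parent = emptyenv())
    rec$costs <- numeric(4096)
    rec$n <- 0L
    fn <- function(x) {
      xc <- pmin(pmax(x, lower), upper)
      v <- cost_eval(xc[1:10], xc[11L], ctx)
      n <- rec$n + 1L
      if (n > length(rec$costs)) rec$costs <- c(rec$costs, numeric(length(rec$costs)))
      rec$costs[n] <- v
      rec$n <- n
      v
    }
    ctrl <- list(maxit = config$nm$maxit, reltol = config$nm$reltol,
                 abstol = config$nm$abstol, parscale = upper - lower)
    # iterated simplex: restart from the solution until a round stalls
    par <- starts[r, ]
    val <- Inf
    for (round in seq_len(config$nm$max_rounds)) {
      res <- stats::optim(par, fn, method = "Nelder-Mead", control = ctrl)
      par <- res$par
      stalled <- val - res$value < config$nm$round_tol * max(1, abs(val))
      val <- res$value
      if (stalled) break
    }
    x_hat <- pmin(pmax(par, lower), upper)
    cost <- cost_eval(x_hat[1:10], x_hat[11L], ctx)
    restart_costs[r] <- cost
    total_evals <- total_evals + rec$n
    if (is.null(best) || cost < best$cost) {
      best <- list(x_hat = x_hat, cost = cost, n_evals = rec$n,
                   trace = cummin(rec$costs[seq_len(rec$n)]))
    }
  }
  .new_fit_result(best$x_hat, best$cost, "NM", best$n_evals, total_evals,
                  restart_costs, best$trace)
}

#' Fit a player's parameters with particle swarm optimization
#'
#' Global-best PSO over the 11-dimensional box: inertia-weighted
#' velocity updates with cognitive and social attraction, velocities
#' clamped to `vmax_frac` of the box width, positions clipped to the
#' bounds with absorbing walls (a clipped coordinate loses its outward
#' velocity, so particles do not stay pinned to a bound).  A run stops
#' after `max_iter` iterations or `stagnation`
#' iterations without improvement of the global best; the best of
#' `n_restarts` seeded runs is returned.
#'
#' @inheritParams fit_nelder_mead
#' @return A `"player_fit"` object (see [fit_nelder_mead()]).
#' @export
fit_pso <- function(games, config = fit_config()) {
  ctx <- make_cost_context(games, dt = config$dt)
  lower <- config$lower
  upper <- config$upper
  k <- length(lower)
  s <- config$pso
  vmax <- s$vmax_frac * (upper - lower)
  set.seed(config$seed)

  best <- NULL
  restart_costs <- numeric(config$n_restarts)
  total_evals <- 0L
  for (r in seq_len(config$n_restarts)) {
    X <- matrix(stats::runif(s$swarm_size * k, lower, upper),
                nrow = s$swarm_size, ncol = k, byrow = TRUE)
    V <- matrix(stats::runif(s$swarm_size * k, -vmax, vmax),
                nrow = s$swarm_size, ncol = k, byrow = TRUE)
    cost_of <- function(M) apply(M, 1L, function(x) cost_eval(x[1:10], x[11L], ctx))
    f <- cost_of(X)
    n_evals <- s$swarm_size
    trace <- cummin(f)
    pbest_x <- X
    pbest_f <- f
    g_idx <- which.min(f)
    gbest_x <- X[g_idx, ]
    gbest_f <- f[g_idx]
    stagnant <- 0L
    # scalar inertia, or c(start, end) for a linear schedule over the run
    w_sched <- if (length(s$inertia) == 2L) {
      seq(s$inertia[1], s$inertia[2], length.out = s$max_iter)
    } else {
      rep(s$inertia, s$max_iter)
    }
    for (it in seq_len(s$max_iter)) {
      R1 <- matrix(stats::runif(s$swarm_size * k), s$swarm_size, k)
      R2 <- matrix(stats::runif(s$swarm_size * k), s$swarm_size, k)
      V <- w_sched[it] * V +
        s$cognitive * R1 * (pbest_x - X) +
        s$social * R2 * sweep(X, 2L, gbest_x, function(x, g) g - x)
      V <- pmin(pmax(V, matrix(-vmax, s$swarm_size, k, byrow = TRUE)),
                matrix(vmax, s$swarm_size, k, byrow = TRUE))
      Xf <- X + V
      X <- pmin(pmax(Xf, matrix(lower, s$swarm_size, k, byrow = TRUE)),
                matrix(upper, s$swarm_size, k, byrow = TRUE))
      # absorbing walls: a clipped coordinate loses its outward velocity
      V[Xf != X] <- 0
      f <- cost_of(X)
      n_evals <- n_evals + s$swarm_size
      trace <- c(trace, cummin(c(gbest_f, f))[-1L])
      imp <- f < pbest_f
      pbest_x[imp, ] <- X[imp, , drop = FALSE]
      pbest_f[imp] <- f[imp]
      new_g <- which.min(pbest_f)
      if (pbest_f[new_g] < gbest_f - 1e-12 * max(1, abs(gbest_f))) {
        gbest_f <- pbest_f[new_g]
        gbest_x <- pbest_x[new_g, ]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= s$stagnation) break
      }
    }
    restart_costs[r] <- gbest_f
    total_evals <- total_evals + n_evals
    if (is.null(best) || gbest_f < best$cost) {
      best <- list(x_hat = gbest_x, cost = gbest_f, n_evals = n_evals,
                   trace = cummin(trace))
    }
  }
  .new_fit_result(best$x_hat, best$cost, "PSO", best$n_evals, total_evals,
                  restart_costs, best$trace)
}

# A power coordinate is unidentifiable when the cost is flat along it
# (no labeled minutes in that (GD, expectation) cell): probe both bounds.
.identifiability <- function(x_hat, ctx, lower, upper, cost_at) {
  flags <- logical(10)
  tol <- 1e-9 * (1 + cost_at)
  for (j in 1:10) {
    lo <- x_hat; lo[j] <- lower[j]
    hi <- x_hat; hi[j] <- upper[j]
    spread <- max(abs(cost_eval(lo[1:10], lo[11L], ctx) - cost_at),
                  abs(cost_eval(hi[1:10], hi[11L], ctx) - cost_at))
    flags[j] <- spread > tol
  }
  stats::setNames(flags, param_names()[1:10])
}

#' Fit a player with both optimizers and compare them
#'
#' Runs [fit_nelder_mead()] and [fit_pso()] (PSO with an offset seed so
#' the two methods are independent), probes parameter identifiability at
#' the Nelder-Mead solution, and flags disagreement when the relative
#' cost gap exceeds `config$agreement_tol`.
#'
#' @inheritParams fit_nelder_mead
#' @return A list of class `"player_fit_pair"`: `NM` and `PSO` fit
#'   results, `identifiable` (named logical over the ten powers, `FALSE`
#'   where the cost is flat because the cell has no labeled minutes),
#'   `cost_gap` (relative), `agreement` (logical) and
#'   `param_max_diff` (largest absolute power difference between the two
#'   methods over identifiable cells).
#' @export
run_player_fit <- function(games, config = fit_config()) {
  nm <- fit_nelder_mead(games, config)
  pso_config <- config
  pso_config$seed <- config$seed + 1L
  pso <- fit_pso(games, pso_config)

  ctx <- make_cost_context(games, dt = config$dt)
  ident <- .identifiability(nm$x_hat, ctx, config$lower, config$upper, nm$cost)
  lo_cost <- min(nm$cost, pso$cost)
  gap <- if (lo_cost < 1e-8) {
    if (max(nm$cost, pso$cost) < 1e-8) 0 else abs(nm$cost - pso$cost)
  } else {
    abs(nm$cost - pso$cost) / lo_cost
  }
  pd <- abs(nm$x_hat[1:10] - pso$x_hat[1:10])
  structure(list(NM = nm, PSO = pso,
                 identifiable = ident,
                 cost_gap = gap,
                 agreement = gap <= config$agreement_tol,
                 param_max_diff = if (any(ident)) max(pd[ident]) else NA_real_),
            class = "player_fit_pair")
}

#' @export
print.player_fit_pair <- function(x, ...) {
  cat(sprintf("NM cost %.6g | PSO cost %.6g | relative gap %.3g%% | %s\n",
              x$NM$cost, x$PSO$cost, 100 * x$cost_gap,
              if (x$agreement) "agree" else "DISAGREE"))
  if (!all(x$identifiable)) {
    cat("Unidentifiable powers (no labeled minutes):",
        paste(names(x$identifiable)[!x$identifiable], collapse = ", "), "\n")
  }
  invisible(x)
}
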