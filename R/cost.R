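# Cost of a candidate parameter vector against measured interval records.
#
# A player's "games" object is a list with one element per game, each a
# list(intervals = labeled data frame, timeline = gd_timeline,
# stint = list(t_s, t_e, ...), expectation = "f"/"nf" or expectation
# object).  The cost compares the Euler-simulated cumulative trace with
# the measured cumulative energy, interpolated from the 5-minute
# boundaries to the 1-minute grid, and normalizes by the total minutes
# played across games.

.validate_games <- function(games) {
  if (!is.list(games) || length(games) == 0L) stop("'games' must be a non-empty list")
  n_iv <- 0L
  for (g in games) {
    if (is.null(g$timeline) || is.null(g$stint) || is.null(g$expectation) ||
        is.null(g$intervals)) {
      stop("each game needs 'intervals', 'timeline', 'stint' and 'expectation'")
    }
    n_iv <- n_iv + nrow(g$intervals)
  }
  if (n_iv == 0L) stop("no labeled intervals across games")
  total <- sum(vapply(games, function(g) g$stint$t_e - g$stint$t_s, 0))
  if (total <= 0) stop("zero total minutes played")
  invisible(total)
}

# Precompute everything that does not depend on the parameter vector:
# per-step state indices (1..10 into the power vector), playing-time
# grid, and per-block measured cumulative energies at the 5-min knots.
#
# Measured cumulative energy only exists over kept intervals; discarded
# records (halftime, warm-up) leave gaps.  Each maximal gap-free block of
# intervals is compared on its own, with both the simulated and the
# measured cumulative rebased to zero at the block start.  With nothing
# discarded this reduces to a single block anchored at stint entry.
# The squared-error integral is discretized at the measured knots, each
# term weighted by the knot spacing; the measured cumulative has no
# defined shape between knots, so comparing there would only add an
# irreducible interpolation artifact.
make_cost_context <- function(games, dt = 1) {
  total_minutes <- .validate_games(games)
  ctx_games <- lapply(games, function(g) {
    # per-game pieces; flattened below so one evaluation is a handful of
    # whole-vector operations instead of a loop over games
    t_s <- g$stint$t_s
    t_e <- g$stint$t_e
    T <- t_e - t_s
    n <- round(T / dt)
    if (abs(n * dt - T) > 1e-8) stop("stint length must be a multiple of dt")
    tau_left <- (seq_len(n) - 1L) * dt
    gd <- gd_at(g$timeline, t_s + tau_left)
    e <- .model_class(g$expectation)
    state_idx <- (gd + 3L) + if (e == "nf") 5L else 0L

    iv <- g$intervals
    blocks <- list()
    if (nrow(iv) > 0L) {
      iv <- iv[order(iv$start_min), , drop = FALSE]
      rel_s <- iv$start_min - t_s
      rel_e <- iv$end_min - t_s
      if (any(rel_s < -1e-9) || any(rel_e > T + 1e-9)) {
        stop("labeled interval outside the player's stint")
      }
      ks <- round(rel_s / dt)
      ke <- round(rel_e / dt)
      if (any(abs(ks * dt - rel_s) > 1e-8) || any(abs(ke * dt - rel_e) > 1e-8)) {
        stop("interval boundaries must lie on the Euler grid")
      }
      new_block <- c(TRUE, ks[-1L] != ke[-length(ke)])
      bid <- cumsum(new_block)
      blocks <- lapply(split(seq_len(nrow(iv)), bid), function(rows) {
        k0 <- ks[rows[1L]]
        kk <- ke[rows]                           # knot grid steps
        list(idx = kk,
             base = k0,                           # 0 means anchored at entry
             w = diff(c(k0, kk)) * dt,            # knot spacing weights
             m = cumsum(iv$energy[rows]))
      })
    }
    list(state_idx = state_idx, tau_left = tau_left, blocks = blocks, T = T)
  })

  # flatten: concatenated Euler steps across games plus global knot,
  # base and weight vectors.  The cumulative sum runs across game
  # boundaries, but every comparison is a within-game difference
  # E[knot] - E[base], so the carried-over constant cancels; blocks
  # anchored at stint entry use the game's starting offset as base.
  state <- integer(0)
  tau <- numeric(0)
  knot_pos <- integer(0)
  base_pos <- integer(0)
  m_all <- numeric(0)
  w_all <- numeric(0)
  off <- 0L
  for (g in ctx_games) {
    for (b in g$blocks) {
      knot_pos <- c(knot_pos, off + b$idx + 1L)       # +1: E[1] == 0 sentinel
      base_pos <- c(base_pos, rep(off + b$base + 1L, length(b$idx)))
      m_all <- c(m_all, b$m)
      w_all <- c(w_all, b$w)
    }
    state <- c(state, g$state_idx)
    tau <- c(tau, g$tau_left)
    off <- off + length(g$state_idx)
  }
  list(state = state, tau = tau, knot_pos = knot_pos, base_pos = base_pos,
       m = m_all, w = w_all, dt = dt, total_minutes = total_minutes,
       games = ctx_games)
}

# Fast evaluation used by the optimizers; p10 is the length-10 power
# vector (favorite block first), eta90 the endurance coefficient.
cost_eval <- function(p10, eta90, ctx) {
  alpha <- -log(eta90) / 90
  E <- c(0, cumsum(p10[ctx$state] * exp(-alpha * ctx$tau) * ctx$dt))
  d <- E[ctx$knot_pos] - E[ctx$base_pos] - ctx$m
  sum(d * d * ctx$w) / ctx$total_minutes
}

#' Fitting cost of a parameter vector (squared trace error per minute)
#'
#' For each game the measured cumulative energy (cumulative sum of kept
#' 5-minute records from stint entry) is compared with the simulated
#' cumulative trace at the record boundaries; each squared difference is
#' weighted by the knot spacing (the discretization of the squared-error
#' integral at the points where the measurement is defined), totalled
#' across games and divided by the total minutes played.  Where
#' discarded records leave gaps, each gap-free block is compared with
#' both curves rebased to the block start (see the methods vignette).
#'
#' @param x A [player_parameters()] object or a length-11 numeric vector
#'   (ten powers, favorite block first, then `eta90`).
#' @param games Per-player list of games (see Details in
#'   [fit_nelder_mead()]).
#' @param dt Comparison grid step in minutes (default 1).
#' @return The cost in (J/kg)^2 per minute played; 0 for a perfect fit.
#' @export
cost_function <- function(x, games, dt = 1) {
  ctx <- make_cost_context(games, dt = dt)
  if (inherits(x, "player_parameters")) {
    x <- as_param_vector(x)
  }
  if (!is.numeric(x) || length(x) != 11L) {
    stop("'x' must be player_parameters or a length-11 numeric vector")
  }
  if (x[11L] <= 0 || x[11L] > 1) stop("'eta90' component must lie in (0, 1]")
  cost_eval(x[1:10], x[11L], ctx)
}
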