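#' Forward-simulate cumulative energy expenditure over a stint
#'
#' Integrates the energy-expenditure model by the explicit Euler method:
#' starting from `E(0) = 0` at the player's entry minute, each step adds
#' `P(d(t_s + tau), e) * eta(tau) * dt`, where `d()` is the clipped GD
#' timeline, `e` the pre-game expectation class and
#' `eta(tau) = exp(-alpha * tau)` the endurance decay on the playing
#' clock.  GD is looked up at the left endpoint of each step, so a goal
#' at a fractional minute takes effect at the next grid point.
#'
#' @param params A [player_parameters()] object.
#' @param timeline A [build_gd_timeline()] object.
#' @param stint List/row with entry and exit minutes `t_s`, `t_e`
#'   (within the game duration).
#' @param expectation [compute_expectation()] object or `"f"`/`"nf"`.
#' @param dt Euler step in minutes (default 1).
#'
#' @return Object of class `"energy_trace"`: list with `tau` (playing
#'   minutes `0..(t_e - t_s)`), `game_min`, `gd`, `eta` and `cumulative`
#'   (E(tau) in J/kg at each grid point), plus `dt` and the inputs'
#'   identifiers.  Convert with [as.data.frame()] for export.
#'
#' @examples
#' tl <- build_gd_timeline(NULL, 90)
#' p <- player_parameters(600, eta90 = 1)
#' tr <- simulate_energy(p, tl, list(t_s = 0, t_e = 90), "f")
#' tail(tr$cumulative, 1)  # 600 * 90 = 54000 J/kg
#' @export
simulate_energy <- function(params, timeline, stint, expectation, dt = 1) {
  stopifnot(inherits(params, "player_parameters"),
            inherits(timeline, "gd_timeline"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("'dt' must be a positive step in minutes")
  }
  t_s <- stint$t_s
  t_e <- stint$t_e
  if (t_s < 0 || t_e <= t_s || t_e > timeline$duration + 1e-9) {
    stop("stint must satisfy 0 <= t_s < t_e <= game duration")
  }
  T <- t_e - t_s
  grid <- seq(0, T, by = dt)
  if (utils::tail(grid, 1) < T - 1e-9) grid <- c(grid, T)  # partial last step
  tau_left <- grid[-length(grid)]
  step <- diff(grid)
  d <- gd_at(timeline, t_s + tau_left)
  e <- .model_class(expectation)
  p <- unname(params$P[as.character(d), e])
  inc <- p * exp(-params$alpha * tau_left) * step
  structure(
    list(tau = grid,
         game_min = t_s + grid,
         gd = gd_at(timeline, pmin(t_s + grid, timeline$duration)),
         eta = exp(-params$alpha * grid),
         cumulative = c(0, cumsum(inc)),
         dt = dt,
         stint = list(t_s = t_s, t_e = t_e),
         expectation = e),
    class = "energy_trace"
  )
}

#' @export
as.data.frame.energy_trace <- function(x, ...) {
  data.frame(tau_min = x$tau,
             game_min = x$game_min,
             gd = x$gd,
             eta = x$eta,
             cumulative_energy_jkg = x$cumulative)
}

# Index of playing-minute tau on the trace grid; errors off-grid.
.grid_index <- function(trace, tau) {
  j <- round(tau / trace$dt) + 1L
  ok <- j >= 1L & j <= length(trace$tau) & abs(trace$tau[pmax(j, 1L)] - tau) < 1e-8
  if (!all(ok)) stop("interval endpoint does not lie on the trace grid")
  j
}

#' Predicted energy per measured interval from a simulated trace
#'
#' Differences the cumulative trace at interval boundaries:
#' `E(end - t_s) - E(start - t_s)`, giving the model's prediction for
#' each 5-minute record.
#'
#' @param trace An [simulate_energy()] trace.
#' @param intervals Data frame with `start_min` and `end_min` columns
#'   (game minutes); endpoints must lie on the trace grid and inside the
#'   stint.
#' @param stint The stint used to build the trace (for the entry offset).
#' @return Numeric vector of predicted interval energies (J/kg).
#' @export
interval_energies <- function(trace, intervals, stint) {
  stopifnot(inherits(trace, "energy_trace"))
  if (nrow(intervals) == 0L) return(numeric(0))
  rel_s <- intervals$start_min - stint$t_s
  rel_e <- intervals$end_min - stint$t_s
  T <- stint$t_e - stint$t_s
  if (any(rel_s < -1e-9) || any(rel_e > T + 1e-9)) {
    stop("interval outside the player's stint")
  }
  trace$cumulative[.grid_index(trace, rel_e)] -
    trace$cumulative[.grid_index(trace, rel_s)]
}
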