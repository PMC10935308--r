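#' Endurance decay rate from the 90-minute coefficient
#'
#' The endurance coefficient `eta90` is the fraction of a player's
#' initial power output still available after 90 minutes of playing
#' time.  The per-minute exponential decay rate is
#' `alpha = -log(eta90) / 90`, so that `exp(-alpha * 90) == eta90`.
#'
#' @param eta90 Endurance coefficient in `(0, 1]` (the model constrains
#'   it to `[0.5, 1]`; 1 means no fatigue, 0.5 a 50% drop at minute 90).
#' @return The decay rate in 1/minute (0 when `eta90 == 1`).
#' @examples
#' alpha_from_eta90(1)    # 0
#' alpha_from_eta90(0.7)  # ~0.00396
#' @export
alpha_from_eta90 <- function(eta90) {
  if (!is.numeric(eta90) || any(is.na(eta90)) || any(eta90 <= 0) ||
      any(eta90 > 1)) {
    stop("'eta90' must lie in (0, 1]")
  }
  -log(eta90) / 90
}

#' Power-efficiency decay at a playing-time minute
#'
#' `eta(tau) = exp(-alpha * tau)`: the multiplicative efficiency applied
#' to a player's state-specific power after `tau` minutes on the pitch.
#' The playing clock `tau` starts when the player enters the field, not
#' at kickoff.
#'
#' @param tau Playing-time minutes (`>= 0`).
#' @param alpha Decay rate from [alpha_from_eta90()].
#' @return Efficiency values in `(0, 1]`.
#' @export
eta_decay <- function(tau, alpha) {
  if (any(tau < 0)) stop("'tau' must be non-negative")
  exp(-alpha * tau)
}

.GD_LEVELS <- c("-2", "-1", "0", "1", "2")
.EXP_LEVELS <- c("f", "nf")

#' Player model parameters
#'
#' The 11-dimensional parameter set of the energy-expenditure model: ten
#' state-specific power levels `P[d, e]` (J/kg per minute) for GD
#' `d in {-2..2}` crossed with expectation `e in {f, nf}`, plus the
#' endurance coefficient `eta90`.  The decay rate `alpha` is derived.
#'
#' @param P Either a 5 x 2 numeric matrix (rows GD `-2..2`, columns
#'   `f`/`nf`), a single number recycled to all ten states, or a named
#'   length-10 vector in the order `P_-2_f ... P_2_f, P_-2_n ... P_2_n`.
#' @param eta90 Endurance coefficient in `[0.5, 1]`.
#' @param validate Check the box constraints `200 <= P <= 800` and
#'   `0.5 <= eta90 <= 1` (default `TRUE`).
#' @return Object of class `"player_parameters"`: list with `P` (5 x 2
#'   matrix), `eta90`, `alpha`.
#' @examples
#' player_parameters(600, eta90 = 0.7)
#' @export
player_parameters <- function(P, eta90, validate = TRUE) {
  if (length(P) == 1L) P <- matrix(P, 5, 2)
  if (is.numeric(P) && is.null(dim(P)) && length(P) == 10L) {
    P <- matrix(P, 5, 2)  # f block first, then nf
  }
  if (!is.matrix(P) || !all(dim(P) == c(5L, 2L))) {
    stop("'P' must be a 5 x 2 matrix (GD -2..2 by expectation f/nf)")
  }
  dimnames(P) <- list(gd = .GD_LEVELS, expectation = .EXP_LEVELS)
  if (!is.numeric(eta90) || length(eta90) != 1L || is.na(eta90)) {
    stop("'eta90' must be a single number")
  }
  if (validate) {
    if (any(P < 200 | P > 800)) {
      stop("power values must lie in [200, 800] J/kg per minute")
    }
    if (eta90 < 0.5 || eta90 > 1) stop("'eta90' must lie in [0.5, 1]")
  }
  structure(list(P = P, eta90 = eta90, alpha = alpha_from_eta90(eta90)),
            class = "player_parameters")
}

#' Names of the optimization vector components
#'
#' Order: the five favorite powers `P_-2_f ... P_2_f`, the five
#' non-favorite powers `P_-2_n ... P_2_n`, then `eta90`.
#' @return Character vector of length 11.
#' @export
param_names <- function() {
  c(paste0("P_", .GD_LEVELS, "_f"), paste0("P_", .GD_LEVELS, "_n"), "eta90")
}

#' Flatten player parameters to the optimization vector
#' @param params A [player_parameters()] object.
#' @return Named numeric vector of length 11 (see [param_names()]).
#' @export
as_param_vector <- function(params) {
  stopifnot(inherits(params, "player_parameters"))
  stats::setNames(c(params$P[, "f"], params$P[, "nf"], params$eta90),
                  param_names())
}

#' Rebuild player parameters from an optimization vector
#' @param x Numeric vector of length 11 (powers then `eta90`).
#' @param validate Passed to [player_parameters()].
#' @return A [player_parameters()] object.
#' @export
from_param_vector <- function(x, validate = TRUE) {
  if (length(x) != 11L) stop("parameter vector must have length 11")
  player_parameters(matrix(x[1:10], 5, 2), eta90 = x[11], validate = validate)
}

#' @export
print.player_parameters <- function(x, ...) {
  cat("Player model parameters (J/kg per minute):\n")
  print(round(x$P, 2))
  cat(sprintf("eta90 = %.4f  (alpha = %.6f / min)\n", x$eta90, x$alpha))
  invisible(x)
}
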