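#' Pre-game expectation from betting odds
#'
#' Converts pre-game win/lose probabilities into the expectation ratio
#' `e = p_win / p_lose` and its derived category.  A team with `e >= 2`
#' is the favorite, a team with `e < 0.5` the underdog; anything in
#' between is a closely contested game.  Because underdog games are rare
#' in a typical top-team schedule, the model pools underdog and close
#' games into a single non-favorite class `"nf"`; the three-way category
#' is kept as metadata only.
#'
#' @param p_win Probability of winning the game, in `[0, 1]`.
#' @param p_lose Probability of losing the game, in `[0, 1]`.
#' @param p_draw Optional draw probability, carried through unused.
#'
#' @return An object of class `"expectation"`: a list with elements
#'   `ratio` (`p_win / p_lose`, possibly `Inf`), `category`
#'   (`"favorite"`, `"close"` or `"underdog"`) and `model_class`
#'   (`"f"` or `"nf"`).
#'
#' @details `p_lose = 0` with `p_win > 0` yields an infinite ratio and is
#'   classified as favorite with a warning; both probabilities zero is an
#'   error because the ratio is undefined.  The favorite boundary is
#'   inclusive (`ratio == 2` is a favorite), the underdog boundary
#'   exclusive (`ratio == 0.5` is a close game).
#'
#' @examples
#' compute_expectation(p_win = 0.5, p_lose = 0.25)  # ratio 2 -> favorite
#' compute_expectation(p_win = 0.3, p_lose = 0.3)   # ratio 1 -> close, "nf"
#' @export
compute_expectation <- function(p_win, p_lose, p_draw = NA_real_) {
  if (!is.numeric(p_win) || !is.numeric(p_lose) || length(p_win) != 1L ||
      length(p_lose) != 1L || is.na(p_win) || is.na(p_lose)) {
    stop("'p_win' and 'p_lose' must be single non-missing numbers")
  }
  if (p_win < 0 || p_win > 1 || p_lose < 0 || p_lose > 1) {
    stop("win/lose probabilities must lie in [0, 1]")
  }
  if (p_win == 0 && p_lose == 0) {
    stop("invalid odds: both win and lose probability are zero")
  }
  if (p_lose == 0) {
    warning("p_lose is zero; expectation ratio treated as +Inf (favorite)")
    ratio <- Inf
  } else {
    ratio <- p_win / p_lose
  }
  category <- if (ratio >= 2) "favorite" else if (ratio < 0.5) "underdog" else "close"
  structure(
    list(ratio = ratio,
         category = category,
         model_class = if (category == "favorite") "f" else "nf"),
    class = "expectation"
  )
}

#' @export
print.expectation <- function(x, ...) {
  cat(sprintf("Pre-game expectation: e = %.4g (%s, model class '%s')\n",
              x$ratio, x$category, x$model_class))
  invisible(x)
}

# Accept either an "expectation" object or a bare "f"/"nf" string.
.model_class <- function(x) {
  if (inherits(x, "expectation")) return(x$model_class)
  if (is.character(x) && length(x) == 1L && x %in% c("f", "nf")) return(x)
  stop("expectation must be an 'expectation' object or one of \"f\", \"nf\"")
}
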