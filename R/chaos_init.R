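# Chaotic population initialization and elite opposition-based learning.
#
# The optimizer does not start from a plain uniform draw: a cubic chaotic
# map spreads candidates ergodically over the box, an "opposite" population
# is reflected through the bounds, and the best N of the union seed the
# search.

#' Box-bounded search space
#'
#' @param lower Numeric vector of lower bounds (or scalar, recycled).
#' @param upper Numeric vector of upper bounds (or scalar, recycled).
#' @param dim Dimension; defaults to the longer of the two bound vectors.
#' @return An object of class `search_space` with vectors `lower`, `upper`
#'   and integer `dim`.
#' @export
#' @examples
#' search_space(-3, 3, dim = 94)
search_space <- function(lower, upper, dim = max(length(lower), length(upper))) {
  dim <- as.integer(dim)
  if (dim < 1L) stop("dim must be >= 1", call. = FALSE)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound",
         call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, dim = dim),
            class = "search_space")
}

#' Cubic chaotic map parameters
#'
#' The recurrence `C[i+1] = mu * C[i] * (1 - C[i]^2)` is ergodic on (0, 1)
#' at the default `c0 = 0.3`, `mu = 2.595`.
#'
#' @param c0 Initial value, in (0, 1). Default 0.3.
#' @param mu Map coefficient, positive. Default 2.595.
#' @return An object of class `chaos_params`.
#' @export
chaos_params <- function(c0 = 0.3, mu = 2.595) {
  stop_if_not_scalar_number(c0, "c0")
  stop_if_not_scalar_number(mu, "mu")
  if (c0 <= 0 || c0 >= 1) stop("c0 must lie strictly in (0, 1)", call. = FALSE)
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  structure(list(c0 = c0, mu = mu), class = "chaos_params")
}

#' Cubic chaotic sequence
#'
#' Iterates `C[i+1] = mu * C[i] * (1 - C[i]^2)` from `c0`, returning
#' `C[1], ..., C[length]` (the starting value itself is not emitted).
#'
#' @param params A [chaos_params()].
#' @param length Number of values to produce (>= 1).
#' @return Numeric vector of length `length`, in `[0, 1]` for the default
#'   parameters.
#' @export
#' @examples
#' cubic_map_sequence(chaos_params(), 5)
cubic_map_sequence <- function(params, length) {
  stopifnot(inherits(params, "chaos_params"))
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  out <- numeric(length)
  c_cur <- params$c0
  for (i in seq_len(length)) {
    c_cur <- params$mu * c_cur * (1 - c_cur^2)
    out[i] <- c_cur
  }
  out
}

# Internal population constructor (positions always checked against bounds).
population <- function(positions, fitness = rep(NA_real_, nrow(positions))) {
  structure(list(positions = positions, fitness = fitness),
            class = "population")
}

#' Chaos-based population initialization
#'
#' Places candidate `i`, coordinate `j`, at
#' `C[(i-1)*dim + j] * (upper[j] - lower[j]) + lower[j]` where the `C` values
#' are consecutive draws from a single cubic chaotic sequence consumed in
#' row-major order (individual-major, coordinate-minor).
#'
#' @param space A [search_space()].
#' @param n_pop Population size N (>= 2).
#' @param params A [chaos_params()].
#' @return A `population` (list with `positions` N x dim matrix and
#'   unevaluated `fitness`).
#' @export
chaos_initialize <- function(space, n_pop, params = chaos_params()) {
  stopifnot(inherits(space, "search_space"))
  n_pop <- as.integer(n_pop)
  if (n_pop < 2L) stop("population size must be >= 2", call. = FALSE)
  cvals <- cubic_map_sequence(params, n_pop * space$dim)
  cmat <- matrix(cvals, nrow = n_pop, ncol = space$dim, byrow = TRUE)
  pos <- sweep(cmat, 2, space$upper - space$lower, `*`)
  pos <- sweep(pos, 2, space$lower, `+`)
  pos <- clip(pos, rep(space$lower, each = n_pop), rep(space$upper, each = n_pop))
  population(pos)
}

#' Chaotic opposite population
#'
#' Reflects each position through the bounds: coordinate `(i, j)` of the
#' opposite population is `C[i,j] * (lower[j] + upper[j]) - x[i,j]`, clipped
#' into the box. By default the `C` values continue the chaotic sequence
#' where [chaos_initialize()] stopped (a fresh block of `N * dim` draws);
#' a matrix `C` may be supplied explicitly.
#'
#' @param pop A `population` from [chaos_initialize()].
#' @param space The [search_space()].
#' @param params A [chaos_params()].
#' @param C Optional N x dim matrix of chaotic multipliers overriding the
#'   continued sequence.
#' @return The opposite `population` (fitness unevaluated).
#' @export
opposite_population <- function(pop, space, params = chaos_params(), C = NULL) {
  stopifnot(inherits(pop, "population"), inherits(space, "search_space"))
  n_pop <- nrow(pop$positions)
  if (is.null(C)) {
    len <- n_pop * space$dim
    cvals <- cubic_map_sequence(params, 2L * len)[(len + 1L):(2L * len)]
    C <- matrix(cvals, nrow = n_pop, ncol = space$dim, byrow = TRUE)
  }
  C <- matrix(C, nrow = n_pop, ncol = space$dim)
  opp <- sweep(C, 2, space$lower + space$upper, `*`) - pop$positions
  opp <- clip(opp, rep(space$lower, each = n_pop), rep(space$upper, each = n_pop))
  population(opp)
}

#' Elite selection from a population and its opposite
#'
#' Evaluates the objective on all `2N` candidates and keeps, for every
#' index `i`, the better of candidate `i` and its opposite (ties go to the
#' original), so an opposite identical to the population returns the
#' population unchanged. The objective is minimized throughout the package
#' (it is a classification error rate in the hybrid trainer).
#'
#' @param pop Original `population`.
#' @param opposite Opposite `population` (same size).
#' @param objective Function mapping a numeric position vector to a single
#'   finite number.
#' @return A `population` of `N` rows with evaluated `fitness`.
#' @export
elite_select <- function(pop, opposite, objective) {
  stopifnot(inherits(pop, "population"), inherits(opposite, "population"))
  n <- nrow(pop$positions)
  if (n != nrow(opposite$positions)) {
    stop("populations must have the same size", call. = FALSE)
  }
  fit_pop <- evaluate_positions(pop$positions, objective)
  fit_opp <- evaluate_positions(opposite$positions, objective)
  take_opp <- fit_opp < fit_pop
  out_pos <- pop$positions
  out_pos[take_opp, ] <- opposite$positions[take_opp, ]
  population(out_pos, ifelse(take_opp, fit_opp, fit_pop))
}

# Evaluate an objective on every row, insisting on finite values.
evaluate_positions <- function(positions, objective) {
  fit <- vapply(seq_len(nrow(positions)), function(i) {
    v <- objective(positions[i, ])
    if (!is.numeric(v) || length(v) != 1L) {
      stop(sprintf("objective must return a single number (candidate %d)", i),
           call. = FALSE)
    }
    v
  }, numeric(1))
  if (any(!is.finite(fit))) {
    stop(sprintf("evaluation error: objective returned a non-finite value for candidate %d",
                 which(!is.finite(fit))[1L]), call. = FALSE)
  }
  fit
}
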