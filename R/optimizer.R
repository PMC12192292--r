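# Reptile Search Algorithm (RSA) baseline and its improved variant (IRSA)
# as general box-constrained minimizers.
#
# The crocodile metaphor gives four phases over the iteration budget T:
#   [1, T/4]        high walking        (global exploration)
#   (T/4, T/2]      belly walking       (global exploration)
#   (T/2, 3T/4]     hunting coordination (local exploitation)
#   (3T/4, T]       hunting cooperation  (local exploitation)
# IRSA replaces uniform initialization by chaos + elite opposition, blends
# the encirclement update with the golden-section constant, damps the
# coordination step by a nonlinear decreasing factor, and stabilizes the
# reduction function's denominator with a sigmoid of the iteration ratio.

#' Optimizer configuration
#'
#' Control parameters for [rsa_optimize()]. Defaults follow the reference
#' setting used throughout the package for network training: population 10,
#' 8 iterations, box `[-3, 3]`, exploration constants `alpha = beta = 0.1`.
#'
#' @param n_pop Population size N (>= 2). Default 10.
#' @param max_iter Iteration budget T (>= 1). Default 8.
#' @param alpha Hunting-precision constant in the percent-difference term.
#'   Default 0.1.
#' @param beta Exploration-precision constant in the high-walking step.
#'   Default 0.1.
#' @param epsilon Small denominator guard for the baseline reduction
#'   function (also the multiplier in the cooperation step). Default 1e-10.
#' @param xi Scale of the sigmoid stabilizer in the improved reduction
#'   function. Default 1e-6.
#' @param golden_ratio Golden-section constant blending the best solution
#'   into encirclement updates; must lie in (0, 1).
#'   Default `(sqrt(5) - 1) / 2`.
#' @param seed Integer seed; runs are bit-reproducible given the config.
#' @param tolerance Stop as soon as the best fitness is `<= tolerance`.
#'   Default 0 (effectively disabled unless 0 is attainable).
#' @param chaos A [chaos_params()] for the IRSA initialization.
#' @return An object of class `irsa_config`.
#' @export
irsa_config <- function(n_pop = 10, max_iter = 8, alpha = 0.1, beta = 0.1,
                        epsilon = 1e-10, xi = 1e-6,
                        golden_ratio = (sqrt(5) - 1) / 2,
                        seed = 1, tolerance = 0, chaos = chaos_params()) {
  n_pop <- as.integer(n_pop); max_iter <- as.integer(max_iter)
  if (n_pop < 2L) stop("n_pop must be >= 2", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (xi <= 0) stop("xi must be > 0", call. = FALSE)
  if (golden_ratio <= 0 || golden_ratio >= 1) {
    stop("golden_ratio must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(n_pop = n_pop, max_iter = max_iter, alpha = alpha,
                 beta = beta, epsilon = epsilon, xi = xi,
                 golden_ratio = golden_ratio, seed = as.integer(seed),
                 tolerance = tolerance, chaos = chaos),
            class = "irsa_config")
}

#' Evolution factor ES(t)
#'
#' The stochastic ratio `2 * r3 * (1 - t / max_iter)` modulating
#' belly-walking steps; `r3` is an integer drawn uniformly from
#' \{-1, 0, 1\} (from the current RNG stream unless supplied). Always lies
#' in `[-2, 2]`.
#'
#' @param t Current iteration, `0 <= t <= max_iter`.
#' @param max_iter Iteration budget.
#' @param r3 Optional explicit value in \{-1, 0, 1\}.
#' @return A single number in `[-2, 2]`.
#' @export
evolution_factor <- function(t, max_iter, r3 = sample(c(-1L, 0L, 1L), 1L)) {
  stopifnot(t >= 0, t <= max_iter)
  2 * r3 * (1 - t / max_iter)
}

#' Baseline reduction function
#'
#' `(best_j - x_r2_j) / (best_j + epsilon)`: shrinks the search area around
#' the best solution; `epsilon` guards the denominator.
#'
#' @param best_j Best solution's j-th coordinate.
#' @param x_r2_j j-th coordinate of a randomly chosen candidate.
#' @param epsilon Positive denominator guard.
#' @return A single number.
#' @export
reduction_rsa <- function(best_j, x_r2_j, epsilon = 1e-10) {
  (best_j - x_r2_j) / (best_j + epsilon)
}

#' Sigmoid-stabilized reduction function
#'
#' The improved reduction term
#' `(best_j - x_r2_j) / (best_j + xi * sigmoid(t / max_iter))`: the
#' stabilizer grows smoothly from `xi/2` toward `xi * sigmoid(1)` over the
#' run, trading early global search for late local refinement.
#'
#' @param best_j Best solution's j-th coordinate.
#' @param x_r2_j j-th coordinate of a randomly chosen candidate.
#' @param xi Positive stabilizer scale.
#' @param t Current iteration.
#' @param max_iter Iteration budget.
#' @return A single number.
#' @export
reduction_irsa <- function(best_j, x_r2_j, xi = 1e-6, t, max_iter) {
  stopifnot(xi > 0, t >= 0, t <= max_iter)
  (best_j - x_r2_j) / (best_j + xi * sigmoid(t / max_iter))
}

#' Hunting operator
#'
#' `eta = best_j * p_ij`, the hunting mechanism for one coordinate.
#'
#' @param best_j Best solution's j-th coordinate.
#' @param p_ij Percent-difference term from [percent_diff()].
#' @return A single number.
#' @export
hunting_operator <- function(best_j, p_ij) best_j * p_ij

#' Percent difference from the best solution
#'
#' `P = alpha + (x_ij - mean_i) / (best_j * (ub_j - lb_j) + epsilon)` where
#' `mean_i` is the mean coordinate of candidate i.
#'
#' @param x_ij Current coordinate.
#' @param mean_i Mean position of candidate i across dimensions.
#' @param best_j Best solution's j-th coordinate.
#' @param ub_j,lb_j Bounds of dimension j (`ub_j > lb_j`).
#' @param alpha Hunting-precision constant. Default 0.1.
#' @param epsilon Denominator guard. Default 1e-10.
#' @return A single number.
#' @export
percent_diff <- function(x_ij, mean_i, best_j, ub_j, lb_j,
                         alpha = 0.1, epsilon = 1e-10) {
  stopifnot(ub_j > lb_j)
  alpha + (x_ij - mean_i) / (best_j * (ub_j - lb_j) + epsilon)
}

#' Nonlinear adjustment factor A
#'
#' `A = arctan(exp(-(iter / max_iter)^3))`, strictly decreasing from
#' `pi/4` at iteration 0 to `arctan(exp(-1))` at the final iteration; damps
#' the hunting-coordination step more and more as the search matures.
#'
#' @param iter Current iteration, `0 <= iter <= max_iter`.
#' @param max_iter Iteration budget (>= 1).
#' @return A single number in `(arctan(exp(-1)), pi/4]`.
#' @export
nonlinear_factor <- function(iter, max_iter) {
  stopifnot(max_iter >= 1, iter >= 0, iter <= max_iter)
  atan(exp(-(iter / max_iter)^3))
}

#' Scalar position-update steps
#'
#' The four phase updates applied coordinate-wise by [rsa_optimize()],
#' exposed as scalar functions so single steps can be evaluated by hand.
#' With `golden_ratio = NULL` (and `factor_a = NULL`) they reduce to the
#' baseline RSA forms; with the defaults they are the improved forms, which
#' blend the best coordinate by the golden-section constant `a`
#' (high walking: `a*best - (1-a)*eta*beta - R*rand`; belly walking:
#' `a*best*x_r1*ES*rand`) and damp coordination by the nonlinear factor `A`
#' (`best * A * P * rand`).
#'
#' @param best_j Best solution's j-th coordinate.
#' @param eta Hunting operator value for this coordinate.
#' @param reduction Reduction-function value for this coordinate.
#' @param rand Uniform (0,1) draw.
#' @param beta Exploration-precision constant.
#' @param golden_ratio Golden-section constant, or `NULL` for the baseline
#'   form.
#' @param x_r1_j Coordinate of a randomly selected candidate.
#' @param es Evolution factor ES(t).
#' @param p_ij Percent-difference value.
#' @param factor_a Nonlinear adjustment factor, or `NULL` for the baseline.
#' @param epsilon Cooperation-step multiplier (small positive).
#' @return A single (unclipped) number.
#' @name update-steps
NULL

#' @rdname update-steps
#' @export
encircle_high_walk <- function(best_j, eta, reduction, rand, beta = 0.1,
                               golden_ratio = (sqrt(5) - 1) / 2) {
  if (is.null(golden_ratio)) {
    best_j - eta * beta - reduction * rand
  } else {
    golden_ratio * best_j - (1 - golden_ratio) * eta * beta - reduction * rand
  }
}

#' @rdname update-steps
#' @export
encircle_belly_walk <- function(best_j, x_r1_j, es, rand,
                                golden_ratio = (sqrt(5) - 1) / 2) {
  a <- if (is.null(golden_ratio)) 1 else golden_ratio
  a * best_j * x_r1_j * es * rand
}

#' @rdname update-steps
#' @export
hunt_coordination <- function(best_j, p_ij, rand, factor_a = NULL) {
  a <- if (is.null(factor_a)) 1 else factor_a
  best_j * a * p_ij * rand
}

#' @rdname update-steps
#' @export
hunt_cooperation <- function(best_j, eta, reduction, rand, epsilon = 1e-10) {
  best_j - eta * epsilon - reduction * rand
}

#' Minimize an objective with RSA or IRSA
#'
#' Runs the four-phase reptile search over a box. Iteration 1 is the
#' initial evaluation (chaos + elite-opposition initialization for
#' `variant = "irsa"`, uniform random for `variant = "rsa"`); iterations
#' `2..max_iter` update every coordinate of every candidate in the phase
#' dictated by the iteration index, clip into the box, re-evaluate, and
#' update the best-so-far solution greedily. Stops early once the best
#' fitness is `<= cfg$tolerance`. Random index and uniform draws are
#' consumed in a fixed iteration-major, individual-major, coordinate-minor
#' order, and neighbor lookups use a snapshot of the population taken at
#' the start of the iteration, so runs are bit-reproducible given
#' `cfg$seed`.
#'
#' @param objective Function from a numeric vector of length `space$dim` to
#'   a single finite number (minimized).
#' @param space A [search_space()].
#' @param cfg An [irsa_config()].
#' @param variant `"irsa"` (default) or `"rsa"`.
#' @return An object of class `optimizer_state`: list with `population`,
#'   `best_position`, `best_fitness`, `t` (iterations performed), `history`
#'   (best fitness per iteration, non-increasing), and `variant`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' st <- rsa_optimize(sphere, search_space(-3, 3, dim = 2),
#'                    irsa_config(n_pop = 10, max_iter = 50, seed = 1))
#' st$best_fitness
rsa_optimize <- function(objective, space, cfg = irsa_config(),
                         variant = c("irsa", "rsa")) {
  variant <- match.arg(variant)
  stopifnot(inherits(space, "search_space"), inherits(cfg, "irsa_config"))
  N <- cfg$n_pop; T_max <- cfg$max_iter
  lb <- space$lower; ub <- space$upper; dim <- space$dim
  improved <- variant == "irsa"

  with_seed(cfg$seed, {
    if (improved) {
      pop <- chaos_initialize(space, N, cfg$chaos)
      opp <- opposite_population(pop, space, cfg$chaos)
      pop <- elite_select(pop, opp, objective)
    } else {
      pos <- matrix(stats::runif(N * dim), nrow = N)
      pos <- sweep(pos, 2, ub - lb, `*`)
      pos <- sweep(pos, 2, lb, `+`)
      pop <- population(pos, evaluate_positions(pos, objective))
    }
    best_i <- which.min(pop$fitness)
    best_fitness <- pop$fitness[best_i]
    best_position <- pop$positions[best_i, ]

    history <- numeric(T_max)
    history[1L] <- best_fitness
    t_done <- 1L

    if (best_fitness > cfg$tolerance && T_max > 1L) {
      for (t in 2:T_max) {
        snapshot <- pop$positions
        es <- evolution_factor(t, T_max)          # one r3 draw per iteration
        A <- if (improved) nonlinear_factor(t, T_max) else NULL
        new_pos <- snapshot
        for (i in seq_len(N)) {
          mean_i <- mean(snapshot[i, ])
          for (j in seq_len(dim)) {
            bj <- best_position[j]
            if (t <= T_max / 4) {                 # high walking
              r2 <- sample.int(N, 1L); rand <- stats::runif(1)
              P <- percent_diff(snapshot[i, j], mean_i, bj, ub[j], lb[j],
                                cfg$alpha, cfg$epsilon)
              eta <- hunting_operator(bj, P)
              R <- if (improved) {
                reduction_irsa(bj, snapshot[r2, j], cfg$xi, t, T_max)
              } else {
                reduction_rsa(bj, snapshot[r2, j], cfg$epsilon)
              }
              val <- encircle_high_walk(bj, eta, R, rand, cfg$beta,
                                        if (improved) cfg$golden_ratio else NULL)
            } else if (t <= T_max / 2) {          # belly walking
              r1 <- sample.int(N, 1L); rand <- stats::runif(1)
              val <- encircle_belly_walk(bj, snapshot[r1, j], es, rand,
                                         if (improved) cfg$golden_ratio else NULL)
            } else if (t <= 3 * T_max / 4) {      # hunting coordination
              rand <- stats::runif(1)
              P <- percent_diff(snapshot[i, j], mean_i, bj, ub[j], lb[j],
                                cfg$alpha, cfg$epsilon)
              val <- hunt_coordination(bj, P, rand, A)
            } else {                              # hunting cooperation
              r2 <- sample.int(N, 1L); rand <- stats::runif(1)
              P <- percent_diff(snapshot[i, j], mean_i, bj, ub[j], lb[j],
                                cfg$alpha, cfg$epsilon)
              eta <- hunting_operator(bj, P)
              R <- if (improved) {
                reduction_irsa(bj, snapshot[r2, j], cfg$xi, t, T_max)
              } else {
                reduction_rsa(bj, snapshot[r2, j], cfg$epsilon)
              }
              val <- hunt_cooperation(bj, eta, R, rand, cfg$epsilon)
            }
            new_pos[i, j] <- clip(val, lb[j], ub[j])
          }
        }
        fit <- evaluate_positions(new_pos, objective)
        pop <- population(new_pos, fit)
        it_best <- which.min(fit)
        if (fit[it_best] < best_fitness) {
          best_fitness <- fit[it_best]
          best_position <- new_pos[it_best, ]
        }
        history[t] <- best_fitness
        t_done <- t
        if (best_fitness <= cfg$tolerance) break
      }
    }
    structure(list(population = pop,
                   best_position = best_position,
                   best_fitness = best_fitness,
                   t = t_done,
                   history = history[seq_len(t_done)],
                   variant = variant),
              class = "optimizer_state")
  })
}

#' @export
print.optimizer_state <- function(x, ...) {
  cat(sprintf("<optimizer_state> variant=%s, iterations=%d, best fitness=%.6g\n",
              x$variant, x$t, x$best_fitness))
  invisible(x)
}
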