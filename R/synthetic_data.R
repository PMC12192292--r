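# Pima-style synthetic data generator. Every downstream stage (preprocessing,
# optimization, training, evaluation) is exercised on tables from this module,
# so its defaults define the package's reference study conditions.
#
# Labels are independent of the features except through the class-conditional
# shift of Glucose and BMI, so effect_size alone tunes difficulty and the
# Bayes rule is a closed-form two-Gaussian threshold on the shifted columns.

#' Specification for a synthetic clinical table
#'
#' Describes a Pima-like cohort: eight positive-valued clinical features with
#' heterogeneous scales, zero-coded missingness in Blood Pressure / Skin
#' Thickness / Insulin, class imbalance, and a label driven mainly by
#' Glucose, BMI and Age.
#'
#' @param n_rows Number of observations (>= 10).
#' @param prevalence Target positive-label fraction, in (0, 1); both classes
#'   must be expected to contain at least 2 rows.
#' @param effect_size Upward shift applied to Glucose and BMI in positive
#'   rows, in within-class standard-deviation units (>= 0). 0 removes all
#'   label signal.
#' @param zero_inflation Length-3 numeric vector of probabilities in `[0, 1)`
#'   that a Blood Pressure / Skin Thickness / Insulin entry is set to 0
#'   (zero-coded missingness).
#' @param seed Integer seed; identical specs yield identical tables.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_rows = 100, prevalence = 0.35, effect_size = 2,
#'                        seed = 1)
#' tab <- generate_table(spec)
synthetic_spec <- function(n_rows = 769, prevalence = 0.35, effect_size = 1.5,
                           zero_inflation = c(0.05, 0.30, 0.49), seed = 1) {
  stop_if_not_scalar_number(n_rows, "n_rows")
  stop_if_not_scalar_number(prevalence, "prevalence")
  stop_if_not_scalar_number(effect_size, "effect_size")
  stop_if_not_scalar_number(seed, "seed")
  n_rows <- as.integer(n_rows)
  if (n_rows < 10L) stop("n_rows must be >= 10", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  if (prevalence * n_rows < 2 || (1 - prevalence) * n_rows < 2) {
    stop("each class must be expected to hold at least 2 rows: require prevalence*n_rows >= 2 and (1-prevalence)*n_rows >= 2",
         call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (length(zero_inflation) != 3L || !is.numeric(zero_inflation) ||
      any(!is.finite(zero_inflation)) ||
      any(zero_inflation < 0) || any(zero_inflation >= 1)) {
    stop("zero_inflation must be three probabilities in [0, 1)", call. = FALSE)
  }
  structure(list(n_rows = n_rows, prevalence = prevalence,
                 effect_size = effect_size,
                 zero_inflation = as.numeric(zero_inflation),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic clinical feature table
#'
#' Draws eight clinical marginals (Poisson pregnancies; clipped Gaussian
#' glucose, blood pressure, skin thickness and BMI; log-normal insulin;
#' gamma pedigree; shifted-exponential age with Age >= 21), assigns labels by
#' thresholding a unit-Gaussian latent score at the (1 - prevalence)
#' quantile (so class counts hit the target prevalence up to rounding and
#' carry no feature information on their own), shifts Glucose and BMI
#' upward in the positive class by `effect_size` within-class standard
#' deviations, and finally zeroes entries of the three missingness-prone
#' columns with the configured probabilities.
#'
#' @param spec A [synthetic_spec()].
#' @return A [feature_table()] with `spec$n_rows` rows.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_rows
    pregnancies <- pmin(stats::rpois(n, lambda = 3), 15)
    glucose  <- clip(stats::rnorm(n, 110, 30), 40, 250)
    bp       <- clip(stats::rnorm(n, 70, 12), 30, 130)
    skin     <- clip(stats::rnorm(n, 29, 10), 5, 80)
    insulin  <- clip(stats::rlnorm(n, log(100), 0.6), 10, 900)
    bmi      <- clip(stats::rnorm(n, 32, 7), 15, 60)
    pedigree <- stats::rgamma(n, shape = 2, scale = 0.25)
    age      <- clip(21 + stats::rexp(n, rate = 1 / 12), 21, 85)

    # Labels threshold a pure-noise latent at the (1 - prevalence) quantile:
    # class counts match the target prevalence up to integer rounding, and at
    # effect_size = 0 the features carry no label information at all.
    score <- stats::rnorm(n)
    thr <- stats::quantile(score, probs = 1 - spec$prevalence, names = FALSE)
    labels <- as.integer(score >= thr)

    if (spec$effect_size > 0 && any(labels == 1L)) {
      pos <- labels == 1L
      # within-class spread measured before the shift; shifted values are not
      # re-clipped, so the configured separation is preserved exactly
      glucose[pos] <- glucose[pos] + spec$effect_size * stats::sd(glucose[pos])
      bmi[pos]     <- bmi[pos]     + spec$effect_size * stats::sd(bmi[pos])
    }

    zi <- spec$zero_inflation
    bp[stats::runif(n) < zi[1L]]      <- 0
    skin[stats::runif(n) < zi[2L]]    <- 0
    insulin[stats::runif(n) < zi[3L]] <- 0

    feature_table(cbind(pregnancies, glucose, bp, skin, insulin, bmi,
                        pedigree, age),
                  labels)
  })
}
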