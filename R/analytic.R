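#' Parameter bundle for the analytic model
#'
#' Collects the parameters of the analytic model of mutation accumulation:
#' effective population size, extrinsic adult mortality rate, fecundity
#' pleiotropy of mutants, age at first reproduction, and the grain of the
#' age dependence of mutational effects.
#'
#' @param Ne Effective population size (dimensionless, `> 1`). The drift
#'   barrier is the selection threshold `-1/Ne`.
#' @param mu Extrinsic adult mortality rate, per unit age (`> 0`).
#' @param alpha Fecundity multiplier of mutants (`>= 0`). `alpha = 1` means
#'   no pleiotropy; `alpha > 1` a fecundity benefit; `alpha < 1` a cost.
#' @param x_min Age at first reproduction, in age units (`>= 0`).
#' @param delta Grain of the age dependence of mutational effects, in age
#'   units (`>= 0`; `0` encodes continuous ages).
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(Ne = 1000, mu = 0.2)
#' critical_age(Inf, p)  # ln(Ne)/mu
#' @export
model_params <- function(Ne, mu, alpha = 1, x_min = 0, delta = 0) {
  stop_unless(is_scalar_num(Ne) && Ne > 1, "Ne must be a number > 1")
  stop_unless(is_scalar_num(mu) && mu > 0, "mu must be a number > 0")
  stop_unless(is_scalar_num(alpha) && alpha >= 0, "alpha must be a number >= 0")
  stop_unless(is_scalar_num(x_min) && x_min >= 0, "x_min must be a number >= 0")
  stop_unless(is_scalar_num(delta) && delta >= 0, "delta must be a number >= 0")
  structure(list(Ne = Ne, mu = mu, alpha = alpha, x_min = x_min, delta = delta),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Analytic model parameters\n")
  cat(sprintf("  Ne = %g, mu = %g, alpha = %g, x_min = %g, delta = %g\n",
              x$Ne, x$mu, x$alpha, x$x_min, x$delta))
  invisible(x)
}

#' Fecundity of a stationary life history
#'
#' In a stationary (density-regulated) population the lifetime reproductive
#' success equals one, which pins the age-independent fecundity to
#' `F = mu / (exp(-mu * x_min) - exp(-mu * X))`. For `X = Inf` this reduces
#' to `F = mu * exp(mu * x_min)` (`F = mu` when `x_min = 0`). Fecundity is
#' higher the earlier the maximum age at death, because recruitment must
#' compensate the extra deaths caused by the fixed lethal mutation.
#'
#' @param mu Extrinsic mortality rate (`> 0`).
#' @param X Maximum age at death (`> x_min`), possibly `Inf`.
#' @param x_min Age at first reproduction (default 0).
#' @return The stationary fecundity (offspring per unit age).
#' @export
stationary_fecundity <- function(mu, X, x_min = 0) {
  stop_unless(is_scalar_num(mu) && mu > 0, "mu must be a number > 0")
  stop_unless(is_scalar_num(X, allow_inf = TRUE) && X > x_min,
              "X must be > x_min (possibly Inf)")
  stop_unless(is_scalar_num(x_min) && x_min >= 0, "x_min must be >= 0")
  e_X <- if (is.infinite(X)) 0 else exp(-mu * X)
  mu / (exp(-mu * x_min) - e_X)
}

#' Stationary life history
#'
#' A life history with age-independent extrinsic mortality `mu`, a hard
#' maximum age at death `X` (set by the earliest fixed lethal mutation), and
#' the fecundity that makes the population stationary (LRS = 1).
#'
#' @inheritParams stationary_fecundity
#' @return An object of class `life_history` with fields `X`, `F`, `mu`,
#'   `x_min`.
#' @export
life_history <- function(mu, X, x_min = 0) {
  Fec <- stationary_fecundity(mu, X, x_min)
  structure(list(X = X, F = Fec, mu = mu, x_min = x_min),
            class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat(sprintf("Stationary life history: X = %g, F = %g, mu = %g, x_min = %g\n",
              x$X, x$F, x$mu, x$x_min))
  invisible(x)
}

#' Age-specific reproductive success
#'
#' The chance that an individual chosen at birth reproduces at age `t`:
#' `k(t) = F * exp(-mu * t)` for `t <= X`, and 0 after death (`t > X`).
#'
#' @param t Age(s), `>= 0`. Vectorized.
#' @param lh A [life_history()].
#' @return `k(t)`, same length as `t`.
#' @export
reproductive_success <- function(t, lh) {
  stop_unless(inherits(lh, "life_history"), "lh must be a life_history")
  stop_unless(is.numeric(t) && all(t >= 0), "ages must be >= 0")
  ifelse(t > lh$X, 0, lh$F * exp(-lh$mu * t))
}

#' Lifetime reproductive success of a mutant lethal at age x
#'
#' Integrates the mutant's reproductive output, `alpha * k(t)`, from the age
#' at first reproduction to its age of death `x`. Computed in closed form,
#' `alpha * F * (exp(-mu * x_min) - exp(-mu * x)) / mu`; equals 1 when
#' `alpha = 1` and `x = X` (the stationarity condition).
#'
#' @param lh A [life_history()].
#' @param alpha Fecundity multiplier of the mutant (`>= 0`).
#' @param x Age at which the mutant's lethal effect occurs
#'   (`x_min <= x <= X`).
#' @return The mutant's lifetime reproductive success.
#' @export
lifetime_reproductive_success <- function(lh, alpha, x) {
  stop_unless(inherits(lh, "life_history"), "lh must be a life_history")
  stop_unless(is_scalar_num(alpha) && alpha >= 0, "alpha must be >= 0")
  stop_unless(is_scalar_num(x, allow_inf = TRUE) && x >= lh$x_min && x <= lh$X,
              "x must lie in [x_min, X]")
  e_x <- if (is.infinite(x)) 0 else exp(-lh$mu * x)
  alpha * lh$F * (exp(-lh$mu * lh$x_min) - e_x) / lh$mu
}

#' Selection coefficient on a mutation lethal at age x
#'
#' Difference in lifetime reproductive success between a mutant whose lethal
#' effect occurs at age `x` (with fecundity multiplier `alpha`) and the
#' stationary wild type (LRS = 1):
#' `s(x) = alpha * (exp(-mu*x_min) - exp(-mu*x)) /
#'   (exp(-mu*x_min) - exp(-mu*X)) - 1`.
#' `s` increases strictly with `x`, from `-1` at `x = x_min` (death before
#' any reproduction) to `alpha - 1` at `x = X`.
#'
#' @param x Age(s) of the lethal effect, in `[x_min, X]`. Vectorized.
#' @param X Current maximum age at death (`> x_min`), possibly `Inf`.
#' @param params A [model_params()].
#' @return `s(x)`, same length as `x`.
#' @export
selection_coefficient <- function(x, X, params) {
  stop_unless(inherits(params, "model_params"), "params must be model_params")
  mu <- params$mu; x_min <- params$x_min
  stop_unless(is_scalar_num(X, allow_inf = TRUE) && X > x_min,
              "X must be > x_min (possibly Inf)")
  stop_unless(is.numeric(x) && all(x >= x_min) && all(x <= X),
              "x must lie in [x_min, X]")
  e_min <- exp(-mu * x_min)
  e_X <- if (is.infinite(X)) 0 else exp(-mu * X)
  e_x <- ifelse(is.infinite(x), 0, exp(-mu * x))
  params$alpha * (e_min - e_x) / (e_min - e_X) - 1
}

#' Critical age above which a lethal mutation can invade
#'
#' Solves `s(x) = threshold` for the unique age at which the selection
#' coefficient crosses the invasion threshold. With the default threshold
#' `-1/Ne` (the drift barrier) this is the critical age: any mutation whose
#' lethal effect occurs later can spread by genetic drift. With
#' `threshold = 0` it is the age above which a fecundity-enhancing
#' (`alpha > 1`) mutation invades by selection. For `x_min = 0` the closed
#' form is
#' `(1/mu) * log(alpha * Ne / (Ne*(alpha-1) + 1 + exp(-mu*X)*(Ne-1)))`,
#' which tends to `log(Ne)/mu` as `X -> Inf` (no pleiotropy) and to 0 as
#' `X -> 0+`. The returned age always satisfies `x_min <= x < X`; a fixed
#' lethal mutation therefore always opens the door to an earlier one.
#'
#' @param X Current maximum age at death (`> x_min`), possibly `Inf`.
#' @param params A [model_params()].
#' @param threshold Invasion threshold on `s` (`> -1`); default `-1/Ne`.
#' @return The critical age, or `NA_real_` when no age can invade
#'   (`s(X) <= threshold`, i.e. the mutation reduces fecundity too strongly
#'   to invade whatever the age at which it is lethal).
#' @export
critical_age <- function(X, params, threshold = -1 / params$Ne) {
  stop_unless(inherits(params, "model_params"), "params must be model_params")
  mu <- params$mu; x_min <- params$x_min; alpha <- params$alpha
  stop_unless(is_scalar_num(X, allow_inf = TRUE) && X > x_min,
              "X must be > x_min (possibly Inf)")
  stop_unless(is_scalar_num(threshold) && threshold > -1,
              "threshold must be > -1")
  s_X <- alpha - 1                      # s at x = X
  if (s_X <= threshold) return(NA_real_)
  e_min <- exp(-mu * x_min)
  e_X <- if (is.infinite(X)) 0 else exp(-mu * X)
  # grouped to avoid cancellation when threshold is close to alpha - 1
  arg <- (e_min * (alpha - 1 - threshold) + (1 + threshold) * e_X) / alpha
  x <- -log(arg) / mu
  max(x, x_min)  # guard roundoff just above x_min
}
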