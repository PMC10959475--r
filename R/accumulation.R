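#' Sequential fixation of lethal mutations at the critical age
#'
#' Iterates the sequential-fixation map `X[n+1] = critical_age(X[n]) + offset`
#' under the simplifying assumption that each invading mutation is expressed
#' exactly at the current critical age (optionally an `offset` above it).
#' Because the critical age always lies strictly below the current maximum
#' age at death, the trajectory decreases monotonically; without pleiotropy
#' it converges to the age at first reproduction, i.e. the population
#' evolves towards semelparity.
#'
#' @param params A [model_params()].
#' @param X0 Initial maximum age at death (`> x_min`), possibly `Inf`.
#' @param max_steps Maximum number of fixations to iterate (`>= 1`).
#' @param stop_tol Stop once `X - x_min < stop_tol` (age units, `> 0`).
#' @param offset Non-negative age added to the critical age at each step
#'   ("lethal slightly above the critical age" semantics); default 0.
#' @return An object of class `accum_trajectory`: a list with `params`,
#'   `steps` (data.frame with columns `step`, `X`) and `terminated_reason`
#'   (one of `"reached_x_min"`, `"no_invadable_age"`, `"max_steps"`).
#' @examples
#' tr <- iterate_accumulation(model_params(Ne = 10, mu = 0.46), X0 = Inf,
#'                            max_steps = 50)
#' head(tr$steps)
#' @export
iterate_accumulation <- function(params, X0 = Inf, max_steps = 100000L,
                                 stop_tol = 1e-6, offset = 0) {
  stop_unless(inherits(params, "model_params"), "params must be model_params")
  stop_unless(is_scalar_num(X0, allow_inf = TRUE) && X0 > params$x_min,
              "X0 must be > x_min (possibly Inf)")
  stop_unless(is_scalar_num(max_steps) && max_steps >= 1,
              "max_steps must be >= 1")
  stop_unless(is_scalar_num(stop_tol) && stop_tol > 0, "stop_tol must be > 0")
  stop_unless(is_scalar_num(offset) && offset >= 0, "offset must be >= 0")
  X <- numeric(max_steps + 1L)
  X[1L] <- X0
  reason <- "max_steps"
  n <- 1L
  while (n <= max_steps) {
    if (X[n] - params$x_min < stop_tol) {
      reason <- "reached_x_min"
      break
    }
    xc <- critical_age(X[n], params)
    if (is.na(xc)) {
      reason <- "no_invadable_age"
      break
    }
    nxt <- xc + offset
    if (nxt >= X[n]) {  # offset pushed past the current maximum: nothing new fixes
      reason <- "no_invadable_age"
      break
    }
    X[n + 1L] <- nxt
    n <- n + 1L
  }
  steps <- data.frame(step = seq_len(n) - 1L, X = X[seq_len(n)])
  structure(list(params = params, steps = steps, terminated_reason = reason),
            class = "accum_trajectory")
}

#' @export
print.accum_trajectory <- function(x, ...) {
  n <- nrow(x$steps)
  cat(sprintf(
    "Mutation-accumulation trajectory: %d step(s), X %g -> %g (%s)\n",
    n - 1L, x$steps$X[1L], x$steps$X[n], x$terminated_reason))
  invisible(x)
}

#' Equilibrium interval for the maximum age at death under grained ages
#'
#' When the deleterious effects of mutations can occur only at ages
#' separated by a grain `delta`, the catastrophic accumulation halts: the
#' last mutation able to invade is lethal within `[X' - delta, X']` where
#' `X'` solves `X - critical_age(X) = delta`. For `x_min = 0` both
#' endpoints have closed forms:
#' `upper = (1/mu) * log((Ne*(alpha*exp(mu*delta) - 1) + 1) /
#'   (Ne*(alpha-1) + 1))` and `lower = upper - delta`. For `x_min > 0` the
#' root is found numerically. The interval collapses to `[x_min, x_min]` as
#' `delta -> 0`.
#'
#' @param params A [model_params()] with `delta > 0` and
#'   `alpha > (Ne - 1)/Ne` (otherwise no mutation can invade at any age).
#' @return An object of class `equilibrium_interval` with fields `lower`,
#'   `upper`, `delta`.
#' @export
equilibrium_interval <- function(params) {
  stop_unless(inherits(params, "model_params"), "params must be model_params")
  stop_unless(params$delta > 0, "delta must be > 0")
  Ne <- params$Ne; mu <- params$mu; alpha <- params$alpha
  delta <- params$delta; x_min <- params$x_min
  stop_unless(alpha > (Ne - 1) / Ne,
              "alpha too small: no mutation can invade at any age")
  if (x_min == 0) {
    den <- Ne * (alpha - 1) + 1
    upper <- log((Ne * (alpha * exp(mu * delta) - 1) + 1) / den) / mu
    lower <- log((alpha * Ne - exp(-mu * delta) * (Ne - 1)) / den) / mu
  } else {
    g <- function(X) X - critical_age(X, params) - delta
    hi <- x_min + delta
    while (g(hi) < 0) hi <- x_min + 2 * (hi - x_min)
    upper <- uniroot(g, lower = x_min + delta / 2, upper = hi,
                     tol = 1e-12)$root
    lower <- critical_age(upper, params)
  }
  structure(list(lower = lower, upper = upper, delta = delta, params = params),
            class = "equilibrium_interval")
}

#' @export
print.equilibrium_interval <- function(x, ...) {
  cat(sprintf(
    "Equilibrium maximum age at death in [%g, %g] (grain delta = %g)\n",
    x$lower, x$upper, x$delta))
  invisible(x)
}

#' Sequential fixation when lethal effects occur on an age grid
#'
#' As [iterate_accumulation()], but mutational effects can occur only at
#' ages `anchor + j * delta` (`j = 1, 2, ...`). At each step the next
#' maximum age at death is the smallest grid age strictly greater than the
#' current critical age and strictly smaller than the current maximum age at
#' death (the earliest lethal age that can still invade by drift). The
#' iteration halts as soon as no such grid age exists; the final age then
#' lies inside [equilibrium_interval()].
#'
#' @inheritParams iterate_accumulation
#' @param anchor Grid anchor age; defaults to `x_min` (grid ages
#'   `x_min + j*delta`).
#' @return An `accum_trajectory` (see [iterate_accumulation()]).
#' @export
grained_accumulation <- function(params, X0 = Inf, max_steps = 100000L,
                                 anchor = params$x_min) {
  stop_unless(inherits(params, "model_params"), "params must be model_params")
  stop_unless(params$delta > 0, "delta must be > 0")
  stop_unless(is_scalar_num(X0, allow_inf = TRUE) && X0 > params$x_min,
              "X0 must be > x_min (possibly Inf)")
  stop_unless(is_scalar_num(max_steps) && max_steps >= 1,
              "max_steps must be >= 1")
  stop_unless(is_scalar_num(anchor) && anchor >= 0, "anchor must be >= 0")
  delta <- params$delta
  X <- numeric(max_steps + 1L)
  X[1L] <- X0
  reason <- "max_steps"
  n <- 1L
  while (n <= max_steps) {
    xc <- critical_age(X[n], params)
    if (is.na(xc)) {
      reason <- "no_invadable_age"
      break
    }
    # smallest grid age strictly above xc
    j <- floor((xc - anchor) / delta) + 1
    if (j < 1) j <- 1
    cand <- anchor + j * delta
    if (cand <= xc) cand <- cand + delta
    if (cand >= X[n]) {  # no grid age inside (xc, X): accumulation halts
      reason <- "no_invadable_age"
      break
    }
    X[n + 1L] <- cand
    n <- n + 1L
  }
  steps <- data.frame(step = seq_len(n) - 1L, X = X[seq_len(n)])
  structure(list(params = params, steps = steps, terminated_reason = reason),
            class = "accum_trajectory")
}
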