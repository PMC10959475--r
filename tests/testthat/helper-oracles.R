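# Independent oracles: numerical quadrature for lifetime reproductive
# success and selection coefficients, and a grid search over s(x) for the
# critical age. These deliberately avoid the closed forms they check.

# LRS of the (possibly pleiotropic) life history by quadrature of
# alpha * F * exp(-mu t) over [x_min, x]
lrs_quadrature <- function(mu, X, x = X, x_min = 0, alpha = 1) {
  Fec <- mu / (exp(-mu * x_min) - if (is.infinite(X)) 0 else exp(-mu * X))
  stats::integrate(function(t) alpha * Fec * exp(-mu * t),
                   lower = x_min, upper = x,
                   rel.tol = 1e-13, abs.tol = 1e-13)$value
}

# s(x) via quadrature (difference of lifetime reproductive successes)
selection_quadrature <- function(x, X, Ne, mu, alpha = 1, x_min = 0) {
  lrs_quadrature(mu, X, x = x, x_min = x_min, alpha = alpha) - 1
}

# Smallest age on the grid {x_min + k*h} at which s exceeds the threshold.
# Integer bisection over grid indices: equivalent to an exhaustive scan
# because s is strictly increasing in x.
critical_age_grid_oracle <- function(X, params, threshold = -1 / params$Ne,
                                     h = 1e-6) {
  s_at <- function(x) selection_coefficient(x, X, params)
  if (s_at(X) <= threshold) return(NA_real_)
  hi_age <- if (is.finite(X)) X else {
    b <- params$x_min + 1 / params$mu
    while (s_at(b) <= threshold) b <- params$x_min + 2 * (b - params$x_min)
    b
  }
  lo <- 0L
  hi <- as.integer(ceiling((hi_age - params$x_min) / h))
  grid_age <- function(k) min(params$x_min + k * h, X)
  # invariant: s(grid_age(hi)) > threshold >= s(grid_age(lo))
  if (s_at(grid_age(lo)) > threshold) return(grid_age(lo))
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (s_at(grid_age(mid)) > threshold) hi <- mid else lo <- mid
  }
  grid_age(hi)
}

# Root of X - critical_age(X) = delta by bisection, independent of the
# closed-form interval
equilibrium_upper_root_oracle <- function(params) {
  g <- function(X) X - critical_age(X, params) - params$delta
  hi <- params$x_min + params$delta
  while (g(hi) < 0) hi <- params$x_min + 2 * (hi - params$x_min)
  stats::uniroot(g, lower = params$x_min + params$delta / 4, upper = hi,
                 tol = 1e-12)$root
}

# random parameter draws for property tests
draw_params <- function(n, seed) {
  set.seed(seed)
  data.frame(Ne = 10^runif(n, 0.01, 6),
             mu = runif(n, 0.01, 2),
             alpha = runif(n, 0.5, 2),
             X = runif(n, 0.05, 50))
}
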