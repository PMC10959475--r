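#' Sweep specification for parameter grids
#'
#' Describes a battery of model runs: one row of `grid` per cell, an
#' operation applied to every cell, and (for stochastic cells) a replicate
#' count and base seed. Replicate `i` of a cell runs with seed
#' `seed + (cell - 1) * replicates + (i - 1)`, so outputs are pure
#' functions of the spec.
#'
#' @param grid A data.frame of parameter combinations. For analytic
#'   operations, columns among `Ne`, `mu`, `alpha`, `x_min`, `delta`, `X0`;
#'   for IBM cells, any [sim_config()] argument.
#' @param op One of `"trajectory"`, `"equilibrium"`, `"ibm"`.
#' @param replicates Replicates per cell (IBM cells).
#' @param seed Base seed for the replicate policy.
#' @param ... Extra arguments stored with the spec and passed to the
#'   per-cell operation (e.g. `max_steps`, `stop_tol`).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(grid, op = c("trajectory", "equilibrium", "ibm"),
                       replicates = 1L, seed = 1L, ...) {
  op <- match.arg(op)
  stop_unless(is.data.frame(grid) && nrow(grid) > 0, "grid must be non-empty")
  stop_unless(is_scalar_num(replicates) && replicates >= 1,
              "replicates must be >= 1")
  stop_unless(is_scalar_num(seed), "seed must be a number")
  structure(list(grid = grid, op = op, replicates = as.integer(replicates),
                 seed = as.integer(seed), extra = list(...)),
            class = "sweep_spec")
}

default_cell <- function(row, name, default) {
  if (name %in% names(row) && !is.na(row[[name]])) row[[name]] else default
}

cell_params <- function(row) {
  model_params(Ne = default_cell(row, "Ne", 1000),
               mu = default_cell(row, "mu", 0.2),
               alpha = default_cell(row, "alpha", 1),
               x_min = default_cell(row, "x_min", 0),
               delta = default_cell(row, "delta", 0))
}

#' Trajectory sweep: decline of the maximum age at death
#'
#' Runs [iterate_accumulation()] (or [grained_accumulation()] when a cell
#' has `delta > 0`) for every cell of the grid and returns a long-format
#' table of the declining maximum age at death. At every shared step index,
#' curves with lower `Ne`, higher `mu`, or higher `alpha` lie at or below
#' the baseline curve.
#'
#' @param spec A [sweep_spec()] with `op = "trajectory"`.
#' @return A data.frame with columns `Ne`, `mu`, `alpha`, `x_min`, `delta`,
#'   `step`, `X`, `terminated_reason`.
#' @export
trajectory_sweep_table <- function(spec) {
  stop_unless(inherits(spec, "sweep_spec"), "spec must be a sweep_spec")
  stop_unless(spec$op == "trajectory", "spec op must be 'trajectory'")
  extra <- spec$extra
  out <- lapply(seq_len(nrow(spec$grid)), function(i) {
    row <- spec$grid[i, , drop = FALSE]
    p <- cell_params(row)
    X0 <- default_cell(row, "X0", Inf)
    tr <- if (p$delta > 0) {
      grained_accumulation(p, X0 = X0,
                           max_steps = default_cell(extra, "max_steps", 1e5))
    } else {
      iterate_accumulation(p, X0 = X0,
                           max_steps = default_cell(extra, "max_steps", 1e5),
                           stop_tol = default_cell(extra, "stop_tol", 1e-6))
    }
    data.frame(Ne = p$Ne, mu = p$mu, alpha = p$alpha, x_min = p$x_min,
               delta = p$delta, step = tr$steps$step, X = tr$steps$X,
               terminated_reason = tr$terminated_reason)
  })
  do.call(rbind, out)
}

#' Equilibrium sweep: grained equilibrium interval across parameters
#'
#' Evaluates [equilibrium_interval()] for every cell (requires
#' `delta > 0`). At fixed other parameters the upper bound increases with
#' the grain `delta`: coarser age dependence of mutational effects halts
#' the accumulation at a higher maximum age at death.
#'
#' @param spec A [sweep_spec()] with `op = "equilibrium"`.
#' @return A data.frame with columns `Ne`, `mu`, `alpha`, `x_min`, `delta`,
#'   `lower`, `upper`.
#' @export
equilibrium_sweep_table <- function(spec) {
  stop_unless(inherits(spec, "sweep_spec"), "spec must be a sweep_spec")
  stop_unless(spec$op == "equilibrium", "spec op must be 'equilibrium'")
  out <- lapply(seq_len(nrow(spec$grid)), function(i) {
    row <- spec$grid[i, , drop = FALSE]
    p <- cell_params(row)
    eq <- equilibrium_interval(p)
    data.frame(Ne = p$Ne, mu = p$mu, alpha = p$alpha, x_min = p$x_min,
               delta = p$delta, lower = eq$lower, upper = eq$upper)
  })
  do.call(rbind, out)
}

# summary of one replicate set of IBM runs
summarize_replicates <- function(recs) {
  finals <- vapply(recs, function(r) {
    w <- r$series$max_age_at_death
    w[length(w)]
  }, numeric(1))
  slopes <- vapply(recs, function(r) {
    s <- r$series
    ok <- is.finite(s$max_age_at_death)
    if (sum(ok) < 2) return(NA_real_)
    unname(coef(lm(s$max_age_at_death[ok] ~ s$time[ok]))[2])
  }, numeric(1))
  plateaus <- vapply(recs, function(r) {
    s <- r$series
    k <- nrow(s)
    tail_idx <- seq.int(max(1, k - 9), k)   # last 10 records
    w <- s$max_age_at_death[tail_idx]
    if (all(is.finite(w)) && length(unique(w)) == 1L) w[1] else NA_real_
  }, numeric(1))
  ext <- vapply(recs, function(r) r$extinction_time, numeric(1))
  data.frame(
    median_final_max_age = median(finals),
    mean_decline_slope = mean(slopes, na.rm = TRUE),
    plateau_age = if (all(is.na(plateaus))) NA_real_
                  else median(plateaus, na.rm = TRUE),
    extinction_fraction = mean(!is.na(ext)),
    median_extinction_time = if (all(is.na(ext))) NA_real_
                             else median(ext, na.rm = TRUE))
}

#' IBM replicate battery
#'
#' Runs the individual-based model for every cell of the grid, `replicates`
#' times per cell with deterministic derived seeds, and summarizes each
#' cell: decline slope of the earliest fixed lethal age, plateau age when
#' the decline halted, extinction fraction and median extinction time.
#'
#' @param spec A [sweep_spec()] with `op = "ibm"`. Grid columns are
#'   [sim_config()] arguments.
#' @param keep_runs If `TRUE`, attach the individual `sim_record`s as
#'   attribute `"runs"`.
#' @return A data.frame, one row per cell, with the cell parameters and the
#'   replicate summaries.
#' @export
ibm_battery <- function(spec, keep_runs = FALSE) {
  stop_unless(inherits(spec, "sweep_spec"), "spec must be a sweep_spec")
  stop_unless(spec$op == "ibm", "spec op must be 'ibm'")
  all_runs <- list()
  out <- lapply(seq_len(nrow(spec$grid)), function(i) {
    row <- as.list(spec$grid[i, , drop = FALSE])
    row <- row[!vapply(row, function(v) is.na(v), logical(1))]
    recs <- lapply(seq_len(spec$replicates), function(r) {
      args <- modifyList(row, list(
        seed = spec$seed + (i - 1L) * spec$replicates + (r - 1L)))
      do.call(run_ibm, list(config = do.call(sim_config, args)))
    })
    if (keep_runs) all_runs[[i]] <<- recs
    cbind(as.data.frame(spec$grid[i, , drop = FALSE], row.names = NULL),
          summarize_replicates(recs))
  })
  res <- do.call(rbind, out)
  if (keep_runs) attr(res, "runs") <- all_runs
  res
}
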