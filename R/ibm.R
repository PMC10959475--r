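#' Configuration for the individual-based simulator
#'
#' Builds and validates the configuration of the diploid individual-based
#' model (IBM). The population is held at a target census `N` by
#' density-dependent recruitment: each step, extrinsic deaths (probability
#' `1 - exp(-mu * dt)`) and lethal-mutation expression deaths open
#' vacancies, which are refilled by offspring of randomly mated parents
#' (sampled with weight equal to the product of the fecundity multipliers
#' of the mutations they carry). Recruitment can be capped at
#' `F_max * alive * dt` recruits per step, in which case deaths may go
#' uncompensated and the census declines.
#'
#' @param N Target census size (integer `>= 2`).
#' @param mu Extrinsic adult mortality rate per unit age (`>= 0`); the
#'   per-step death probability is `1 - exp(-mu * dt)`.
#' @param dt Step length in age units (`> 0`).
#' @param U Probability that an offspring acquires one new mutation.
#' @param age_grid_delta Grain of the expression-age grid: new mutations are
#'   expressed at ages `j * age_grid_delta` (or stages `j` in somatic mode).
#' @param max_expr_age Upper bound for newly drawn expression ages (stages
#'   in somatic mode).
#' @param reverse_rate Per-allele probability, at gamete formation, that an
#'   inherited mutant allele reverts to wild type.
#' @param F_max Per-capita recruitment cap, offspring per parent per unit
#'   age (`Inf` = unlimited; recruitment then exactly refills vacancies).
#' @param X0 Initial maximum age at death (age units; `Inf` = nonsenescent
#'   founding population). Represents lethal mutations already fixed before
#'   the simulation starts.
#' @param effect_d Effect of new mutations: `0` for dominant lethals
#'   (death on reaching the expression trigger); a value in `(0, 1]` for
#'   nonlethal mutations adding `d` to the step death probability.
#' @param increment_mode For nonlethal mutations, whether the increment
#'   applies `"onward"` from the trigger (default) or `"at_age"` only at the
#'   step in which the trigger is reached.
#' @param new_pleiotropy Fecundity multiplier attached to new mutations
#'   (`>= 0`; 1 = no pleiotropy).
#' @param somatic_mode If `TRUE`, expression triggers are somatic stage
#'   indices rather than ages; stages advance stochastically.
#' @param stage_advance_prob Per-step probability that an individual's
#'   somatic stage increments (somatic mode).
#' @param init_ages Initial age distribution: `"stationary"` (exponential
#'   with rate `mu`, truncated at `X0`) or `"uniform"` (on `[0, X0]`, or
#'   `[0, 3/mu]` when `X0 = Inf`).
#' @param T_max Horizon, in steps.
#' @param record_every Record the time series every this many steps.
#' @param seed RNG seed (integer).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N = 300, mu = 0.46, dt = 1, U = 0.02,
                       age_grid_delta = dt, max_expr_age = 40,
                       reverse_rate = 0, F_max = Inf, X0 = Inf,
                       effect_d = 0, increment_mode = c("onward", "at_age"),
                       new_pleiotropy = 1, somatic_mode = FALSE,
                       stage_advance_prob = 1, init_ages = c("stationary", "uniform"),
                       T_max = 1000L, record_every = 10L, seed = 1L) {
  increment_mode <- match.arg(increment_mode)
  init_ages <- match.arg(init_ages)
  stop_unless(is_scalar_num(N) && N >= 2 && N == round(N),
              "N must be an integer >= 2")
  stop_unless(is_scalar_num(mu) && mu >= 0, "mu must be >= 0")
  stop_unless(is_scalar_num(dt) && dt > 0, "dt must be > 0")
  stop_unless(is_scalar_num(U) && U >= 0 && U <= 1, "U must be in [0, 1]")
  stop_unless(is_scalar_num(age_grid_delta) && age_grid_delta > 0,
              "age_grid_delta must be > 0")
  stop_unless(is_scalar_num(max_expr_age) && max_expr_age >= age_grid_delta,
              "max_expr_age must be >= age_grid_delta")
  stop_unless(is_scalar_num(reverse_rate) && reverse_rate >= 0 && reverse_rate <= 1,
              "reverse_rate must be in [0, 1]")
  stop_unless(is_scalar_num(F_max, allow_inf = TRUE) && F_max > 0,
              "F_max must be > 0 (possibly Inf)")
  stop_unless(is_scalar_num(X0, allow_inf = TRUE) && X0 > 0,
              "X0 must be > 0 (possibly Inf)")
  stop_unless(is_scalar_num(effect_d) && effect_d >= 0 && effect_d <= 1,
              "effect_d must be in [0, 1]")
  stop_unless(is_scalar_num(new_pleiotropy) && new_pleiotropy >= 0,
              "new_pleiotropy must be >= 0")
  stop_unless(isTRUE(somatic_mode) || isFALSE(somatic_mode),
              "somatic_mode must be TRUE/FALSE")
  stop_unless(is_scalar_num(stage_advance_prob) &&
                stage_advance_prob >= 0 && stage_advance_prob <= 1,
              "stage_advance_prob must be in [0, 1]")
  stop_unless(is_scalar_num(T_max) && T_max >= 1, "T_max must be >= 1")
  stop_unless(is_scalar_num(record_every) && record_every >= 1,
              "record_every must be >= 1")
  stop_unless(is_scalar_num(seed), "seed must be a number")
  structure(list(
    N = as.integer(N), mu = mu, dt = dt, mu_step = 1 - exp(-mu * dt), U = U,
    age_grid_delta = age_grid_delta, max_expr_age = max_expr_age,
    reverse_rate = reverse_rate, F_max = F_max, X0 = X0,
    effect_d = effect_d, increment_mode = increment_mode,
    new_pleiotropy = new_pleiotropy, somatic_mode = somatic_mode,
    stage_advance_prob = stage_advance_prob, init_ages = init_ages,
    T_max = as.integer(T_max), record_every = as.integer(record_every),
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "IBM config: N = %d, mu = %g, dt = %g, U = %g, grid = %g, X0 = %g\n",
    x$N, x$mu, x$dt, x$U, x$age_grid_delta, x$X0))
  cat(sprintf(
    "  reverse_rate = %g, F_max = %g, somatic = %s, T_max = %d, seed = %d\n",
    x$reverse_rate, x$F_max, x$somatic_mode, x$T_max, x$seed))
  invisible(x)
}

# config list handed to the C++ core
cpp_config <- function(config) {
  grid <- if (config$somatic_mode) 1 else config$age_grid_delta
  n_grid <- max(1L, as.integer(floor(config$max_expr_age / grid + 1e-9)))
  list(N = config$N, mu_step = config$mu_step, dt = config$dt, U = config$U,
       reverse_rate = config$reverse_rate, F_max = config$F_max,
       somatic_mode = config$somatic_mode,
       stage_advance_prob = config$stage_advance_prob,
       grid_step = grid, n_grid = n_grid,
       increment_onward = identical(config$increment_mode, "onward"),
       effect_d = config$effect_d, new_pleiotropy = config$new_pleiotropy,
       stop_when_idle = isTRUE(config$stop_when_idle))
}

empty_loci <- function() {
  list(id = integer(0), trigger = numeric(0), effect = integer(0),
       d = numeric(0), pleiotropy = numeric(0), was_fixed = integer(0))
}

#' Initialize a population
#'
#' Creates `N` mutation-free individuals with ages drawn from the stationary
#' exponential age distribution truncated at `X0` (or uniform ages), seeds
#' the RNG from `config$seed`, and optionally plants initial segregating
#' loci (used for controlled drift experiments).
#'
#' @param config A [sim_config()].
#' @param init_loci Optional data.frame with columns `trigger`, `effect`
#'   (`0` lethal, `1` increment), `d`, `pleiotropy`, `count` (initial number
#'   of carrier copies, placed as heterozygotes in distinct individuals).
#' @return An object of class `population_state`.
#' @export
init_population <- function(config, init_loci = NULL) {
  stop_unless(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$N
  u <- runif(n)
  if (config$init_ages == "stationary") {
    if (config$mu <= 0) {
      ages <- rep(0, n)  # no mortality: degenerate newborn cohort
    } else if (is.finite(config$X0)) {
      ages <- -log(1 - u * (1 - exp(-config$mu * config$X0))) / config$mu
    } else {
      ages <- -log(1 - u) / config$mu
    }
  } else {
    hi <- if (is.finite(config$X0)) config$X0 else 3 / max(config$mu, 1e-6)
    ages <- u * hi
  }
  loci <- empty_loci()
  geno <- matrix(0L, nrow = n, ncol = 0L)
  if (!is.null(init_loci) && nrow(init_loci) > 0) {
    L <- nrow(init_loci)
    loci <- list(id = seq_len(L), trigger = as.numeric(init_loci$trigger),
                 effect = as.integer(init_loci$effect),
                 d = as.numeric(init_loci$d),
                 pleiotropy = as.numeric(init_loci$pleiotropy),
                 was_fixed = integer(L))
    geno <- matrix(0L, nrow = n, ncol = L)
    for (l in seq_len(L)) {
      cnt <- as.integer(init_loci$count[l])
      stop_unless(cnt >= 1 && cnt <= n, "initial count must be in [1, N]")
      geno[sample.int(n, cnt), l] <- 1L
    }
  }
  structure(list(
    age = ages, stage = integer(n), geno = geno, loci = loci,
    wall = config$X0, folded_incr_trigger = numeric(0),
    folded_incr_d = numeric(0), time = 0L,
    next_locus_id = length(loci$id) + 1L, extinct = FALSE,
    extinction_time = NA_integer_, n_lost = 0L,
    config = config), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "Population state at t = %g: census %d, %d tracked locus(i), wall = %g%s\n",
    x$time * x$config$dt, length(x$age), length(x$loci$id), x$wall,
    if (x$extinct) " [extinct]" else ""))
  invisible(x)
}

# advance a population_state by n_steps (C++ core); records accumulate
advance_state <- function(state, config, n_steps, record_every = config$record_every) {
  out <- .ibm_steps_cpp(unclass(state), cpp_config(config),
                        as.integer(n_steps), as.integer(record_every))
  st <- structure(list(
    age = out$age, stage = out$stage, geno = out$geno, loci = out$loci,
    wall = out$wall, folded_incr_trigger = out$folded_incr_trigger,
    folded_incr_d = out$folded_incr_d, time = out$time,
    next_locus_id = out$next_locus_id, extinct = out$extinct,
    extinction_time = if (is.na(out$extinction_time)) NA_integer_ else out$extinction_time,
    n_lost = out$n_lost, config = config), class = "population_state")
  attr(st, "records") <- as.data.frame(out$records)
  attr(st, "fixations") <- as.data.frame(out$fixations)
  st
}

#' Advance a population by one step
#'
#' Applies, in order: extrinsic deaths; lethal-mutation expression deaths
#' (and mortality increments added to this step's death probability);
#' somatic stage advance; recruitment refilling vacancies (capped when
#' `F_max` is finite); aging. Errors on an extinct input state.
#'
#' @param state A `population_state`.
#' @param config The [sim_config()] used to create it.
#' @return The updated `population_state`.
#' @export
step_population <- function(state, config = state$config) {
  stop_unless(inherits(state, "population_state"), "state must be a population_state")
  stop_unless(!state$extinct, "population is extinct")
  advance_state(state, config, 1L, record_every = 1L)
}

#' Earliest fixed lethal expression age (the "wall of death")
#'
#' The maximum age at death realized in the population: the minimum
#' expression trigger among lethal loci fixed in every living individual
#' (including those folded into population-level state), or `Inf` when no
#' lethal mutation is fixed.
#'
#' @param state A `population_state`.
#' @return Age (or stage, in somatic mode), possibly `Inf`.
#' @export
fixed_lethal_max_age <- function(state) {
  stop_unless(inherits(state, "population_state"), "state must be a population_state")
  w <- state$wall
  n <- length(state$age)
  if (length(state$loci$id) > 0 && n > 0) {
    counts <- colSums(state$geno)
    fixed <- state$loci$effect == 0L & counts == 2L * n
    if (any(fixed)) w <- min(w, min(state$loci$trigger[fixed]))
  }
  w
}

#' Advance somatic stages
#'
#' Each living individual's somatic stage increments with probability
#' `stage_advance_prob`. Only meaningful (and only allowed) in somatic mode,
#' where mutation expression is keyed to stage attainment rather than
#' chronological age.
#'
#' @inheritParams step_population
#' @return The updated `population_state`.
#' @export
somatic_advance <- function(state, config = state$config) {
  stop_unless(inherits(state, "population_state"), "state must be a population_state")
  stop_unless(isTRUE(config$somatic_mode), "somatic_advance requires somatic_mode")
  n <- length(state$age)
  state$stage <- state$stage + rbinom(n, 1L, config$stage_advance_prob)
  state
}

#' Run the individual-based simulation
#'
#' Iterates [step_population()] to the horizon or extinction and records the
#' time series of census size, segregating locus count, earliest fixed
#' lethal expression age, and mean fecundity weight, plus every fixation
#' event. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param init_loci Optional initial loci (see [init_population()]).
#' @param stop_when_idle If `TRUE` and `U = 0`, stop as soon as no tracked
#'   locus remains (all initial loci lost or fixed) — useful for
#'   fixation-probability experiments.
#' @return An object of class `sim_record`: list with `series` (data.frame:
#'   `time`, `census`, `segregating`, `max_age_at_death`,
#'   `mean_fecundity_weight`), `fixations` (data.frame: `id`, `time`,
#'   `trigger`, `effect`), `extinction_time` (age units, or `NA`),
#'   `final_state`, and `config`.
#' @examples
#' rec <- run_ibm(sim_config(N = 50, T_max = 100, seed = 7))
#' tail(rec$series)
#' @export
run_ibm <- function(config, init_loci = NULL, stop_when_idle = FALSE) {
  stop_unless(inherits(config, "sim_config"), "config must be a sim_config")
  state <- init_population(config, init_loci = init_loci)
  config$stop_when_idle <- stop_when_idle
  st <- advance_state(state, config, config$T_max)
  ext <- if (is.na(st$extinction_time)) NA_real_ else st$extinction_time * config$dt
  structure(list(
    series = attr(st, "records"), fixations = attr(st, "fixations"),
    extinction_time = ext, final_state = st, config = config),
    class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf(
    "IBM run: %g time units, final census %d, wall %g, %d fixation(s)%s\n",
    x$series$time[n], as.integer(x$series$census[n]),
    x$series$max_age_at_death[n], nrow(x$fixations),
    if (!is.na(x$extinction_time))
      sprintf(", extinct at t = %g", x$extinction_time) else ""))
  invisible(x)
}
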