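test_that("seeded runs are reproducible and configs validate", {
  cfg <- sim_config(N = 100, T_max = 150, seed = 1)
  s1 <- init_population(cfg)
  s2 <- init_population(cfg)
  expect_identical(s1$age, s2$age)
  r1 <- run_ibm(cfg)
  r2 <- run_ibm(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$fixations, r2$fixations)
  # minimal viable population
  expect_s3_class(run_ibm(sim_config(N = 2, T_max = 20, seed = 3)),
                  "sim_record")
  expect_error(sim_config(N = 1), class = "senaccum_domain_error")
  expect_error(sim_config(U = 1.5), class = "senaccum_domain_error")
  expect_error(sim_config(dt = 0), class = "senaccum_domain_error")
})

test_that("initial ages follow the truncated stationary exponential", {
  cfg <- sim_config(N = 1e5, mu = 0.46, X0 = 6, seed = 8)
  st <- init_population(cfg)
  cdf <- function(t) (1 - exp(-0.46 * t)) / (1 - exp(-0.46 * 6))
  ks <- suppressWarnings(stats::ks.test(st$age, cdf))
  expect_gt(ks$p.value, 0.001)
  expect_true(all(st$age < 6))
  # nonsenescent founders: plain exponential
  st2 <- init_population(sim_config(N = 1e5, mu = 0.46, seed = 9))
  ks2 <- suppressWarnings(stats::ks.test(st2$age, stats::pexp, rate = 0.46))
  expect_gt(ks2$p.value, 0.001)
})

test_that("unlimited recruitment holds the census exactly at N", {
  rec <- run_ibm(sim_config(N = 100, mu = 0.46, U = 0, T_max = 300,
                            record_every = 1, seed = 5))
  expect_true(all(rec$series$census == 100))
  # with mutations segregating the census is still pinned at N
  rec2 <- run_ibm(sim_config(N = 100, mu = 0.46, U = 0.05, T_max = 300,
                             record_every = 1, seed = 6))
  expect_true(all(rec2$series$census == 100))
})

test_that("the fixed-lethal wall is the minimum fixed expression age", {
  cfg <- sim_config(N = 10, seed = 1)
  st <- init_population(cfg)
  expect_identical(fixed_lethal_max_age(st), Inf)
  # fixture: two lethal loci fixed (allele count 2 in everyone), ages 4 and 7
  st$loci <- list(id = 1:2, trigger = c(7, 4), effect = c(0L, 0L),
                  d = c(0, 0), pleiotropy = c(1, 1), was_fixed = c(0L, 0L))
  st$geno <- matrix(2L, nrow = 10, ncol = 2)
  expect_identical(fixed_lethal_max_age(st), 4)
  # a segregating locus does not set the wall
  st$geno[1, 2] <- 1L
  expect_identical(fixed_lethal_max_age(st), 7)
  # forcing fixation through inheritance: all founders carry one copy
  cfg2 <- sim_config(N = 20, mu = 0.46, U = 0, X0 = 30, T_max = 400,
                     record_every = 400, seed = 12)
  rec <- run_ibm(cfg2, init_loci = data.frame(trigger = 25, effect = 0L,
                                              d = 0, pleiotropy = 1,
                                              count = 20),
                 stop_when_idle = TRUE)
  if (nrow(rec$fixations) > 0) {
    expect_identical(rec$fixations$trigger, 25)
    expect_identical(fixed_lethal_max_age(rec$final_state), 25)
  }
})

test_that("without reverse mutation the wall never rises", {
  rec <- run_ibm(sim_config(N = 80, mu = 0.46, U = 0.1, age_grid_delta = 1,
                            max_expr_age = 20, T_max = 2000,
                            record_every = 10, seed = 33))
  w <- rec$series$max_age_at_death
  expect_true(all(w[-1] <= w[-length(w)]))  # Inf-safe monotonicity
  expect_lt(w[length(w)], Inf)   # something fixed over this horizon
})

test_that("step order and extinction bookkeeping behave", {
  cfg <- sim_config(N = 50, mu = 0.46, U = 0, T_max = 10, seed = 2)
  st <- init_population(cfg)
  st1 <- step_population(st, cfg)
  expect_identical(length(st1$age), 50L)
  expect_identical(st1$time, 1L)
  # extinction: wall below every initial age kills everyone at once
  cfg2 <- sim_config(N = 30, mu = 0.46, U = 0, X0 = 0.5, F_max = 1e-9,
                     T_max = 50, seed = 4)
  rec <- run_ibm(cfg2)
  expect_false(is.na(rec$extinction_time))
  expect_lt(tail(rec$series$census, 1), 2)
  expect_error(step_population(rec$final_state, cfg2),
               class = "senaccum_domain_error")
})

test_that("capped recruitment lets deaths go uncompensated", {
  # F_max below the stationary requirement at the current wall: decline
  rec <- run_ibm(sim_config(N = 300, mu = 0.46, U = 0, X0 = 6, F_max = 0.62,
                            T_max = 60, record_every = 5, seed = 17))
  cen <- rec$series$census
  expect_lt(cen[length(cen)], 300)
  expect_lt(mean(diff(cen)), 0)
  # the same cap sustains a nonsenescent population
  rec2 <- run_ibm(sim_config(N = 300, mu = 0.46, U = 0, X0 = Inf,
                             F_max = 0.62, T_max = 60, record_every = 5,
                             seed = 18))
  expect_identical(tail(rec2$series$census, 1), 300)
})

test_that("somatic stages advance binomially and gate expression", {
  # stage_advance_prob = 1 reduces to the age-triggered model
  cfg <- sim_config(N = 200, mu = 0, U = 0, somatic_mode = TRUE,
                    stage_advance_prob = 1, T_max = 25, seed = 21)
  st <- init_population(cfg)
  cfg$stop_when_idle <- FALSE
  out <- run_ibm(cfg)
  expect_true(all(out$final_state$stage == 25L))
  # stage_advance_prob = 0: staged lethals never express, census constant
  cfg0 <- sim_config(N = 100, mu = 0.46, U = 0, somatic_mode = TRUE,
                     stage_advance_prob = 0, T_max = 100, record_every = 1,
                     seed = 22)
  rec0 <- run_ibm(cfg0, init_loci = data.frame(trigger = 1, effect = 0L,
                                               d = 0, pleiotropy = 1,
                                               count = 50))
  expect_true(all(rec0$series$census == 100))
  expect_identical(nrow(rec0$fixations), 0L)
  # stage_advance_prob = 0.5: mean stage ~ t/2 over 1e4 individuals
  cfg5 <- sim_config(N = 1e4, mu = 0, U = 0, somatic_mode = TRUE,
                     stage_advance_prob = 0.5, T_max = 50, seed = 23)
  out5 <- run_ibm(cfg5)
  expect_equal(mean(out5$final_state$stage), 25, tolerance = 0.02)
  # somatic_advance is refused outside somatic mode
  plain <- init_population(sim_config(N = 10, seed = 1))
  expect_error(somatic_advance(plain), class = "senaccum_domain_error")
  som <- init_population(cfg5)
  som2 <- somatic_advance(som, cfg5)
  expect_true(all((som2$stage - som$stage) %in% c(0L, 1L)))
})

test_that("reverse mutation at rate one strips inherited alleles", {
  cfg <- sim_config(N = 40, mu = 0.46, U = 0, reverse_rate = 1, T_max = 60,
                    record_every = 1, seed = 31)
  rec <- run_ibm(cfg, init_loci = data.frame(trigger = 1e9, effect = 0L,
                                             d = 0, pleiotropy = 1,
                                             count = 40))
  # no transmission succeeds, so the allele can only dwindle with its carriers
  expect_identical(nrow(rec$fixations), 0L)
  expect_identical(tail(rec$series$segregating, 1), 0)
})

test_that("mortality-increment mutations raise the death rate when expressed", {
  # with no extrinsic mortality and an increment of d = 1 from age 3 onward,
  # deaths come only from the mutation: no carrier survives past the trigger
  cfg <- sim_config(N = 200, mu = 0, dt = 1, U = 0, T_max = 40,
                    record_every = 1, seed = 41)
  rec <- run_ibm(cfg, init_loci = data.frame(trigger = 3, effect = 1L,
                                             d = 1, pleiotropy = 1,
                                             count = 100))
  st <- rec$final_state
  carriers <- if (ncol(st$geno) > 0) rowSums(st$geno) > 0 else logical(0)
  expect_true(all(st$age[carriers] <= 3))
  expect_true(any(st$age > 3))            # non-carriers age past the trigger
  expect_true(all(rec$series$census == 200))
})

test_that("pleiotropy weights parent sampling", {
  # a locus with a large fecundity benefit and harmless expression age
  # spreads far faster than drift alone
  cfg <- sim_config(N = 100, mu = 0.46, U = 0, T_max = 600,
                    record_every = 600, seed = 51)
  nfix <- 0
  for (s in 1:10) {
    cfg$seed <- 50 + s
    rec <- run_ibm(cfg, init_loci = data.frame(trigger = 1e9, effect = 0L,
                                               d = 0, pleiotropy = 8,
                                               count = 1),
                   stop_when_idle = TRUE)
    nfix <- nfix + (nrow(rec$fixations) > 0)
  }
  # neutral expectation would be ~10 * 1/(2N) = 0.05 fixations
  expect_gte(nfix, 3)
})
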