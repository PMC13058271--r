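## synthetic person-period frame with a known first-stage structure
mk_iv_pp <- function(n, slope = 3, seed = 1) {
  set.seed(seed)
  z <- runif(n, 0.1, 0.9)
  age10 <- rnorm(n, 0, 0.5)
  p <- plogis(-1.5 + slope * z + 0.3 * age10)
  data.frame(resident_id = sprintf("R%05d", seq_len(n)),
             home_id = sprintf("H%02d", sample(1:20, n, TRUE)),
             period_index = 0L, z = z, age10 = age10,
             exposed = rbinom(n, 1, p))
}

test_that("the instrument is the home's prior-year transfer proportion", {
  co <- mk_cohort(mk_quiet_resident("R1", 8, home = "HA"),
                  mk_quiet_resident("R2", 8, home = "HA"),
                  rbind(mk_row("R3", 0, home = "HA", transfer = 1),
                        mk_row("R3", 1, home = "HA"),
                        mk_row("R3", 2, home = "HA"),
                        mk_row("R3", 3, home = "HA"),
                        mk_row("R3", 4, home = "HA", died = 1)),
                  mk_quiet_resident("R4", 8, home = "HB"))
  hist <- data.frame(home_id = c("HA", "HB"),
                     n_residents_prior_year = c(10, 0),
                     n_transferred_prior_year = c(3, 0))
  iv <- compute_instrument(co, hist)

  ## year 1 comes from the burn-in history
  expect_equal(iv$z[iv$home_id == "HA" & iv$year == 1], 0.3)
  expect_true(is.na(iv$z[iv$home_id == "HB" & iv$year == 1]))

  ## year 2 counts the observed year-1 residents: 3 in HA, 1 transferred
  expect_equal(iv$n_residents_prior_year[iv$home_id == "HA" & iv$year == 2],
               3)
  expect_equal(iv$z[iv$home_id == "HA" & iv$year == 2], 1 / 3)

  pp <- build_person_periods(co, "mortality", n_periods_max = 8)
  expect_warning(ppz <- attach_instrument(pp, iv), "missing instrument")
  expect_false(any(ppz$home_id == "HB" & ppz$period_index < 4))
  expect_false(anyNA(ppz$z))
})

test_that("the computed instrument tracks the latent home propensity", {
  cfg <- sim_scenario("strong_instrument", n_homes = 20,
                      residents_per_home = 60, seed = 15)
  sim <- simulate_cohort(cfg)
  iv <- compute_instrument(sim$cohort, sim$home_history)
  z1 <- iv$z[iv$year == 1]
  expect_gt(cor(z1, sim$homes$theta), 0.6)
})

test_that("the first stage recovers a planted instrument effect", {
  pp <- mk_iv_pp(10000, slope = 3, seed = 33)
  fs <- first_stage(pp, covariates = "age10")
  expect_lt(abs(fs$instrument_coef - 3), 3 * fs$instrument_se)
  expect_gt(fs$relevance, 2)
  expect_false(fs$weak)
})

test_that("a constant instrument triggers the weak-instrument warning", {
  pp <- mk_iv_pp(2000, slope = 0, seed = 3)
  pp$z <- 0.4
  expect_warning(fs <- first_stage(pp, covariates = "age10"), "weak")
  expect_equal(fs$relevance, 0)
})

test_that("a deterministic exposure threshold is flagged as separation", {
  pp <- mk_iv_pp(800, seed = 5)
  pp$exposed <- as.integer(pp$z > 0.5)
  w <- capture_warnings(first_stage(pp, covariates = "age10"))
  expect_true(any(grepl("separation", w)))
})

test_that("without unmeasured confounding the residual adds nothing", {
  ## measured confounding only: the control-function coefficient is null
  ## and the IV estimate agrees with the covariate-adjusted Cox
  cfg <- sim_scenario("measured_confounding", n_homes = 30,
                      residents_per_home = 150, seed = 41)
  sim <- simulate_cohort(cfg)
  el <- apply_eligibility(sim$cohort, "mortality")
  pp <- build_person_periods(el$table, "mortality")
  inst <- compute_instrument(sim$cohort, sim$home_history)
  ppz <- attach_instrument(pp, inst)
  iv <- control_function_cox(ppz, ci = "robust")
  expect_lt(abs(iv$details$residual_coef), 3 * iv$details$residual_se)
  ext <- fit_extended_cox(pp)
  expect_lt(abs(iv$log_hr - ext$log_hr),
            3 * sqrt(iv$robust_se^2 + ext$robust_se^2))
})

test_that("the control function unmasks a protective effect hidden by illness", {
  cfg <- sim_scenario("strong_instrument", n_homes = 40,
                      residents_per_home = 150, seed = 51)
  sim <- simulate_cohort(cfg)
  el <- apply_eligibility(sim$cohort, "mortality")
  pp <- build_person_periods(el$table, "mortality")
  inst <- compute_instrument(sim$cohort, sim$home_history)
  ppz <- attach_instrument(pp, inst)
  iv <- control_function_cox(ppz, ci = "robust")
  crude <- fit_crude_cox(pp)
  ## truth: log-HR -0.5; the crude estimate is confounded far upward
  expect_gt(crude$log_hr, 0)
  expect_lt(iv$log_hr, 0)
  expect_lt(abs(iv$log_hr + 0.5), 3 * iv$robust_se)
})

test_that("the cluster bootstrap yields an interval and counts failures", {
  cfg <- sim_scenario("strong_instrument", n_homes = 20,
                      residents_per_home = 60, seed = 61)
  sim <- simulate_cohort(cfg)
  el <- apply_eligibility(sim$cohort, "mortality")
  pp <- build_person_periods(el$table, "mortality")
  inst <- compute_instrument(sim$cohort, sim$home_history)
  ppz <- attach_instrument(pp, inst)
  iv <- control_function_cox(ppz, ci = "bootstrap", n_boot = 40, seed = 2)
  expect_lt(iv$ci_low, iv$ci_high)
  expect_equal(iv$details$n_boot, 40)
  expect_lte(iv$details$boot_failures, 40)
  expect_gt(iv$details$boot_se, 0)
  ## seeded: same call reproduces the interval
  iv2 <- control_function_cox(ppz, ci = "bootstrap", n_boot = 40, seed = 2)
  expect_identical(c(iv$ci_low, iv$ci_high), c(iv2$ci_low, iv2$ci_high))
})

test_that("bootstrap uncertainty shrinks with the number of homes", {
  ses <- vapply(c(10, 40), function(nh) {
    cfg <- sim_scenario("strong_instrument", n_homes = nh,
                        residents_per_home = 80, seed = 71)
    sim <- simulate_cohort(cfg)
    el <- apply_eligibility(sim$cohort, "mortality")
    pp <- build_person_periods(el$table, "mortality")
    inst <- compute_instrument(sim$cohort, sim$home_history)
    ppz <- attach_instrument(pp, inst)
    control_function_cox(ppz, ci = "bootstrap", n_boot = 60,
                         seed = 3)$details$boot_se
  }, numeric(1))
  ## 4x the homes: expect roughly a halving, allow wide slack
  expect_gt(ses[1] / ses[2], 1.3)
})

test_that("instrument diagnostics check relevance, balance and quintiles", {
  cfg <- sim_scenario("strong_instrument", n_homes = 40,
                      residents_per_home = 250, seed = 6)
  sim <- simulate_cohort(cfg)
  inst <- compute_instrument(sim$cohort, sim$home_history)
  el <- apply_eligibility(sim$cohort, "mortality")
  pp <- build_person_periods(el$table, "mortality")
  d <- instrument_diagnostics(sim$cohort, inst,
                              pp_list = list(mortality = pp))
  expect_gt(d$relevance$wald_z, 2)
  ## propensity is assigned independently of resident characteristics
  expect_true(all(d$balance$smd < 0.1))
  expect_false(d$quintiles_collapsed)
  qi <- d$quintile_incidence
  expect_equal(sort(unique(qi$quintile)), 1:5)

  single <- sim$cohort[sim$cohort$home_id == sim$cohort$home_id[1], ]
  expect_error(instrument_diagnostics(single, inst), "2 homes")
})

test_that("a degenerate propensity range yields no relevance", {
  cfg <- sim_scenario("strong_instrument", n_homes = 10,
                      residents_per_home = 80, seed = 81,
                      theta_range = c(0.1, 0.1))
  sim <- simulate_cohort(cfg)
  inst <- compute_instrument(sim$cohort, sim$home_history)
  el <- apply_eligibility(sim$cohort, "mortality")
  pp <- build_person_periods(el$table, "mortality")
  ppz <- attach_instrument(pp, inst)
  expect_warning(fs <- first_stage(ppz), "weak")
  expect_lt(abs(fs$relevance), 2)
  d <- instrument_diagnostics(sim$cohort, inst)
  expect_lt(abs(d$relevance$wald_z), 2)
})

test_that("widening the propensity range strengthens the first stage", {
  rel <- vapply(c(0.02, 0.25), function(hi) {
    mean(vapply(1:3, function(s) {
      cfg <- sim_scenario("strong_instrument", n_homes = 20,
                          residents_per_home = 80, seed = 90 + s,
                          theta_range = c(0.01, hi))
      sim <- simulate_cohort(cfg)
      el <- apply_eligibility(sim$cohort, "mortality")
      pp <- build_person_periods(el$table, "mortality")
      inst <- compute_instrument(sim$cohort, sim$home_history)
      ppz <- suppressWarnings(attach_instrument(pp, inst))
      abs(suppressWarnings(first_stage(ppz))$relevance)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(rel[2], rel[1])
})
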