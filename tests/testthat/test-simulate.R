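test_that("configuration validation rejects malformed inputs", {
  expect_error(ltc_sim_config(theta_range = c(0.6, 0.1)), "reversed")
  expect_error(ltc_sim_config(theta_range = c(0, 0.5)), "inside")
  expect_error(ltc_sim_config(theta_range = c(0.1, 1)), "inside")
  expect_error(ltc_sim_config(n_periods_max = 0), "n_periods_max")
  expect_error(ltc_sim_config(p_illness = 1.2), "\\[0, 1\\]")
  expect_error(ltc_sim_config(baseline_hazards = c(physical = 0.01,
                                                   cognitive = 0.01,
                                                   death = 1.5,
                                                   discharge = 0.01)),
               "death")
})

test_that("home propensities span the requested range and are deterministic", {
  one <- simulate_homes(ltc_sim_config(n_homes = 1,
                                       theta_range = c(0.5, 0.5)))
  expect_equal(one$theta, 0.5)

  h1 <- simulate_homes(ltc_sim_config(n_homes = 5, seed = 7))
  h2 <- simulate_homes(ltc_sim_config(n_homes = 5, seed = 7))
  expect_identical(h1$theta, h2$theta)

  many <- simulate_homes(ltc_sim_config(n_homes = 50,
                                        theta_range = c(0.1, 0.6)))
  expect_true(all(many$theta > 0.1 & many$theta < 0.6))
  expect_lt(min(many$theta) - 0.1, 0.02)
  expect_lt(0.6 - max(many$theta), 0.02)
  expect_false(any(duplicated(many$home_id)))
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- ltc_sim_config(n_homes = 4, residents_per_home = 30, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  expect_identical(a$home_history, b$home_history)
})

test_that("null hazards produce no events and full administrative follow-up", {
  cfg <- sim_scenario("randomized", n_homes = 3, residents_per_home = 20,
                      seed = 2,
                      baseline_hazards = c(physical = 0, cognitive = 0,
                                           death = 0, discharge = 0))
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$cohort$died_in_period), 0)
  expect_equal(sum(sim$cohort$discharged_in_period), 0)
  n_per <- table(sim$cohort$resident_id)
  expect_true(all(n_per == 20))
})

test_that("an out-of-range per-period probability names the offending hazard", {
  cfg <- ltc_sim_config(n_homes = 2, residents_per_home = 20, seed = 1,
                        gamma_illness_outcomes = c(physical = 1.5,
                                                   cognitive = 1.3,
                                                   death = 9),
                        p_illness = 0.5)
  expect_error(simulate_cohort(cfg), "death")
})

test_that("the analysis-facing table conceals the latent illness process", {
  sim <- simulate_cohort(ltc_sim_config(n_homes = 2,
                                        residents_per_home = 15, seed = 3))
  expect_false("acute_illness" %in% names(sim$cohort))
  expect_true(all(c("acute_illness", "frailty") %in% names(sim$truth)))
  expect_s3_class(attr(sim$truth, "config"), "ltc_sim_config")
})

test_that("scales stay in range and impairment states are absorbing", {
  sim <- simulate_cohort(ltc_sim_config(n_homes = 5,
                                        residents_per_home = 80, seed = 11))
  co <- sim$cohort
  expect_true(all(co$adl_hierarchy %in% 0:6))
  expect_true(all(co$cps %in% 0:6))
  expect_true(all(co$chess %in% 0:5))
  ## once ADL = 6 (resp. CPS >= 5) appears it never improves
  absorbing <- function(v, thr) {
    i <- which(v >= thr)
    length(i) == 0 || all(v[min(i):length(v)] >= thr)
  }
  expect_true(all(tapply(co$adl_hierarchy, co$resident_id, absorbing, 6)))
  expect_true(all(tapply(co$cps, co$resident_id, absorbing, 5)))
})

test_that("home propensity is independent of resident-level baselines", {
  sim <- simulate_cohort(ltc_sim_config(n_homes = 40,
                                        residents_per_home = 50, seed = 19))
  base <- sim$cohort[sim$cohort$period_index == 0, ]
  theta <- sim$homes$theta[match(base$home_id, sim$homes$home_id)]
  for (v in c("age_at_admission", "sex", "adl_hierarchy", "cps", "chess")) {
    expect_lt(abs(cor(theta, base[[v]])), 0.05)
  }
})

test_that("without confounding the crude mortality rate ratio is null", {
  ## no illness pathway, no covariate effects, null true effects; the
  ## person-time contrast (exposed vs unexposed periods) is the rate-scale
  ## quantity that converges to the true effect
  ## sized so that the 0.1 tolerance is a 3-standard-error bound on the
  ## log rate ratio
  cfg <- sim_scenario("randomized", n_homes = 25, residents_per_home = 1000,
                      seed = 5,
                      baseline_hazards = c(physical = 0.01, cognitive = 0.012,
                                           death = 0.03, discharge = 0.008))
  sim <- simulate_cohort(cfg)
  el <- apply_eligibility(sim$cohort, "mortality")
  pp <- build_person_periods(el$table, "mortality")
  inc <- cohort_incidence(pp, by = "period")
  expect_lt(abs(log(inc$irr$ratio)), 0.1)
})

test_that("latent-illness coupling inflates the crude rate ratio above the true effect", {
  ## true effect is protective (log-HR -0.4) yet the confounded ever/never
  ## contrast, counted directly from events and person-time, exceeds 2
  cfg <- ltc_sim_config(n_homes = 20, residents_per_home = 250, seed = 4,
                        beta_transfer = c(physical = 0, cognitive = 0,
                                          death = -0.4))
  sim <- simulate_cohort(cfg)
  el <- apply_eligibility(sim$cohort, "mortality")
  pp <- build_person_periods(el$table, "mortality")
  ever <- tapply(el$table$transfer, el$table$resident_id, max)
  is_ever <- ever[pp$resident_id] == 1
  irr_direct <- (sum(pp$event[is_ever]) / sum(is_ever * 92)) /
    (sum(pp$event[!is_ever]) / sum((!is_ever) * 92))
  expect_gt(irr_direct, 2)
  inc <- cohort_incidence(pp, cohort = el$table)
  expect_equal(inc$irr$ratio, irr_direct, tolerance = 1e-10)
})

test_that("assessment tables round-trip through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")

  empty <- simulate_cohort(ltc_sim_config(n_homes = 1,
                                          residents_per_home = 1,
                                          seed = 1))$cohort[0, ]
  write_cohort(empty, tmp)
  expect_equal(nrow(read_cohort(tmp)), 0)
  expect_identical(names(read_cohort(tmp)), names(empty))

  small <- mk_cohort(mk_row("R1", 0), mk_row("R1", 1, transfer = 1),
                     mk_row("R2", 0, died = 1))
  write_cohort(small, tmp)
  bytes1 <- readBin(tmp, "raw", file.size(tmp))
  write_cohort(small, tmp)
  bytes2 <- readBin(tmp, "raw", file.size(tmp))
  expect_identical(bytes1, bytes2)
  back <- read_cohort(tmp)
  rownames(small) <- NULL
  expect_equal(back, small)

  big <- simulate_cohort(ltc_sim_config(n_homes = 5,
                                        residents_per_home = 60,
                                        seed = 9))$cohort
  write_cohort(big, tmp)
  expect_equal(read_cohort(tmp), big)
})

test_that("cohort IO flags malformed input and unknown columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  small <- mk_cohort(mk_row("R1", 0))
  small$extra <- 1
  expect_warning(write_cohort(small, tmp), "unknown")

  lines <- readLines(tmp)
  lines[2] <- sub("^R1,H1,0", "R1,H1,zero", lines[2])
  writeLines(lines, tmp)
  expect_error(read_cohort(tmp), "period_index")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "no such file")
})
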