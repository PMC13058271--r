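#' Configuration for the synthetic long-term-care cohort simulator
#'
#' Builds a validated configuration object for [simulate_cohort()]. The
#' generator produces quarterly (92-day) assessment data with the statistical
#' structure the downstream causal analyses assume: between-home heterogeneity
#' in transfer propensity (the preference-based instrument), a latent
#' acute-illness process that raises both the probability of hospital transfer
#' and the hazards of impairment and death (the unmeasured confounder),
#' measured time-varying covariates, and known true causal transfer effects.
#'
#' All hazards are discrete-time per-period (92-day) event probabilities with
#' log-linear covariate effects; transfer is drawn from a logistic model. The
#' defaults describe the reference scenario of severe unmeasured confounding:
#' transfers are predominantly markers of an acute illness that is itself
#' strongly lethal, the true causal effect of transfer on death is modestly
#' protective, and the true effects on permanent physical and cognitive
#' impairment are null. Under these defaults roughly two thirds of residents
#' are ever transferred, the crude mortality rate ratio between ever- and
#' never-transferred residents is far above 1, and confounder-adjusted
#' estimators that cannot see the illness remain strongly biased upward —
#' the structure an instrumental-variable analysis is designed to resolve.
#' See [sim_scenario()] for the other named study conditions.
#'
#' @param n_homes number of long-term-care homes.
#' @param residents_per_home residents admitted per home.
#' @param n_periods_max administrative follow-up horizon in 92-day periods
#'   (20 periods = 5 years).
#' @param seed integer seed; identical config + seed gives identical output.
#' @param theta_range length-2 numeric in (0, 1): the range of per-period
#'   baseline transfer probabilities across homes (home "transfer
#'   propensity"). Equal endpoints give a degenerate (single-propensity)
#'   system, which removes the instrument's variation.
#' @param beta_transfer named vector `c(physical=, cognitive=, death=)` of
#'   true causal log-hazard effects of transfer on each outcome. Effects act
#'   on the outcome ascertained in the window after the exposure window, the
#'   same alignment the analysis uses: the death hazard of period t carries
#'   the transfer indicator of period t-1, and an impairment event generated
#'   in period t (which carries the period-t transfer) becomes visible at the
#'   assessment of period t+1.
#' @param gamma_illness_transfer log-odds effect of acute illness on transfer.
#' @param gamma_illness_outcomes named vector of log-hazard effects of acute
#'   illness on each outcome.
#' @param baseline_hazards named vector of per-period event probabilities at
#'   covariate zero: `physical`, `cognitive`, `death`, `discharge`.
#' @param covariate_effects list of named coefficient vectors (`transfer`,
#'   `physical`, `cognitive`, `death`) over assessment columns; `age10` is the
#'   derived column (age - 85)/10.
#' @param p_illness per-period baseline probability of a new acute-illness
#'   episode (modified on the logit scale by a resident frailty term).
#' @param p_illness_persist probability that an ongoing illness episode
#'   continues into the next 92-day period. Persistence is what makes the
#'   acute event a confounder of the analysis's exposure/outcome windowing:
#'   the illness that triggers a transfer in window k is often still present
#'   in window k+1, where the outcome is ascertained.
#' @param frailty_sd standard deviation of the resident-level normal frailty
#'   entering the illness model on the log-odds scale.
#' @param p_illness_chess_shift probability that an acute-illness episode
#'   bumps the CHESS health-instability score by one point (so the measured
#'   scales partially reflect the latent illness, as in real assessment data).
#'
#' @return an object of class `ltc_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- ltc_sim_config(n_homes = 4, residents_per_home = 25, seed = 1)
#' sim <- simulate_cohort(cfg)
#' head(sim$cohort)
ltc_sim_config <- function(n_homes = 20,
                           residents_per_home = 100,
                           n_periods_max = 20,
                           seed = 1,
                           theta_range = c(0.005, 0.06),
                           beta_transfer = c(physical = 0, cognitive = 0,
                                             death = -0.5),
                           gamma_illness_transfer = 6.5,
                           gamma_illness_outcomes = c(physical = 1.5,
                                                      cognitive = 1.3,
                                                      death = 4.6),
                           baseline_hazards = c(physical = 0.008,
                                                cognitive = 0.010,
                                                death = 0.003,
                                                discharge = 0.008),
                           covariate_effects = list(
                             transfer = c(chess = 0.12, fell_30d = 0.10,
                                          adl_hierarchy = 0.04),
                             physical = c(adl_hierarchy = 0.25, chess = 0.10),
                             cognitive = c(cps = 0.25, chess = 0.10),
                             death = c(age10 = 0.15, chess = 0.08)),
                           p_illness = 0.05,
                           p_illness_persist = 0.65,
                           frailty_sd = 1.3,
                           p_illness_chess_shift = 0.3) {
  cfg <- list(n_homes = n_homes, residents_per_home = residents_per_home,
              n_periods_max = n_periods_max, seed = seed,
              theta_range = theta_range, beta_transfer = beta_transfer,
              gamma_illness_transfer = gamma_illness_transfer,
              gamma_illness_outcomes = gamma_illness_outcomes,
              baseline_hazards = baseline_hazards,
              covariate_effects = covariate_effects,
              p_illness = p_illness, p_illness_persist = p_illness_persist,
              frailty_sd = frailty_sd,
              p_illness_chess_shift = p_illness_chess_shift)
  validate_sim_config(cfg)
  class(cfg) <- "ltc_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!.is_count(cfg$n_homes)) .stopf("n_homes must be a positive integer")
  if (!.is_count(cfg$residents_per_home)) {
    .stopf("residents_per_home must be a positive integer")
  }
  if (!.is_count(cfg$n_periods_max)) {
    .stopf("n_periods_max must be an integer >= 1")
  }
  tr <- cfg$theta_range
  if (length(tr) != 2 || any(!is.finite(tr)) || any(tr <= 0) || any(tr >= 1)) {
    .stopf("theta_range must be two values strictly inside (0, 1)")
  }
  if (tr[1] > tr[2]) .stopf("theta_range is reversed (lower bound > upper)")
  for (nm in c("physical", "cognitive", "death")) {
    if (is.na(cfg$beta_transfer[nm])) {
      .stopf("beta_transfer must name '%s'", nm)
    }
    if (is.na(cfg$gamma_illness_outcomes[nm])) {
      .stopf("gamma_illness_outcomes must name '%s'", nm)
    }
  }
  bh <- cfg$baseline_hazards
  for (nm in c("physical", "cognitive", "death", "discharge")) {
    if (is.na(bh[nm]) || bh[nm] < 0 || bh[nm] > 1) {
      .stopf("baseline_hazards['%s'] must be a probability in [0, 1]", nm)
    }
  }
  for (p in c(cfg$p_illness, cfg$p_illness_persist,
              cfg$p_illness_chess_shift)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      .stopf("illness probabilities must lie in [0, 1]")
    }
  }
  if (!is.finite(cfg$frailty_sd) || cfg$frailty_sd < 0) {
    .stopf("frailty_sd must be nonnegative")
  }
  invisible(cfg)
}

#' @export
print.ltc_sim_config <- function(x, ...) {
  cat("Synthetic LTC cohort configuration\n")
  cat(sprintf("  homes: %d x %d residents, %d periods (92 d), seed %d\n",
              x$n_homes, x$residents_per_home, x$n_periods_max, x$seed))
  cat(sprintf("  theta range: [%.3f, %.3f]\n",
              x$theta_range[1], x$theta_range[2]))
  cat(sprintf("  true transfer log-HRs: physical %.2f, cognitive %.2f, death %.2f\n",
              x$beta_transfer["physical"], x$beta_transfer["cognitive"],
              x$beta_transfer["death"]))
  cat(sprintf("  illness -> transfer %.2f; illness -> death %.2f (log scale)\n",
              x$gamma_illness_transfer, x$gamma_illness_outcomes["death"]))
  invisible(x)
}

#' Home transfer-propensity profiles
#'
#' Lays the `n_homes` latent per-period transfer propensities out as equally
#' spaced interior points of `theta_range` (the i-th home gets
#' `lo + i/(n+1) * (hi - lo)`), so the propensities span the range, stay
#' strictly inside it, and are reproducible without consuming random numbers.
#' A single home receives the midpoint.
#'
#' @param config an [ltc_sim_config()] object.
#' @return data.frame with columns `home_id`, `theta`, `n_residents`.
#' @export
simulate_homes <- function(config) {
  validate_sim_config(config)
  n <- config$n_homes
  lo <- config$theta_range[1]
  hi <- config$theta_range[2]
  theta <- lo + seq_len(n) / (n + 1) * (hi - lo)
  data.frame(home_id = sprintf("H%03d", seq_len(n)),
             theta = theta,
             n_residents = rep(config$residents_per_home, n),
             stringsAsFactors = FALSE)
}

## per-period event probability on the log-linear scale, with the validity
## check the discrete-time grid requires
.event_prob <- function(h0, lp, what) {
  p <- h0 * exp(lp)
  if (any(p > 1 + 1e-12)) {
    .stopf(paste0("per-period probability for '%s' exceeds 1 ",
                  "(max %.3f); reduce baseline_hazards['%s'] or its ",
                  "log-linear effects"), what, max(p), what)
  }
  pmin(p, 1)
}

#' Simulate a longitudinal LTC cohort on the 92-day assessment grid
#'
#' Draws one quarterly assessment row per resident per period until death,
#' discharge or the administrative five-year horizon. Within each period the
#' causal ordering is: acute illness (a persistent episode process), covariate
#' evolution, transfer (logistic in home propensity, illness and covariates),
#' then death, impairment onsets and discharge (death precedes impairment
#' evaluation within a period; an impairment onset in period t becomes
#' visible at the assessment of period t+1 and is absorbing thereafter). True
#' causal transfer effects act on the outcome of the window after the
#' exposure window — the death hazard of period t carries the previous
#' period's transfer, and an impairment event of period t surfaces at the
#' next assessment — matching the exposure/outcome alignment of the
#' person-period analysis. The analysis-facing table never contains the
#' latent illness indicator; it is emitted only to the truth table.
#'
#' All randomness flows from a single `set.seed(config$seed)` call with a
#' fixed draw order (home burn-in history, resident baselines, then one
#' vectorised block per period), so identical configurations reproduce
#' identical tables.
#'
#' @param config an [ltc_sim_config()].
#' @param homes optional data.frame from [simulate_homes()]; computed from
#'   `config` when missing.
#' @return list of class `ltc_cohort_sim` with elements `cohort` (assessment
#'   table), `truth` (per resident-period latent illness + frailty, with the
#'   generating config attached as an attribute), `homes`, and `home_history`
#'   (per-home prior-year transfer counts used to seed the instrument).
#' @export
simulate_cohort <- function(config, homes = NULL) {
  validate_sim_config(config)
  if (is.null(homes)) homes <- simulate_homes(config)
  if (nrow(homes) == 0L) .stopf("homes must be nonempty")
  set.seed(config$seed)

  ## --- burn-in year: ever-transferred counts per home in the year before
  ## the cohort opens (feeds the instrument's first follow-up year)
  p_ill <- config$p_illness
  g_it <- config$gamma_illness_transfer
  ## stationary illness prevalence of the persistent episode process
  pi_ill <- p_ill / (1 - config$p_illness_persist * (1 - p_ill))
  p_period <- (1 - pi_ill) * stats::plogis(stats::qlogis(homes$theta)) +
    pi_ill * stats::plogis(stats::qlogis(homes$theta) + g_it)
  p_ever_year <- 1 - (1 - p_period)^4
  home_history <- data.frame(
    home_id = homes$home_id,
    n_residents_prior_year = homes$n_residents,
    n_transferred_prior_year = stats::rbinom(nrow(homes), homes$n_residents,
                                             p_ever_year),
    stringsAsFactors = FALSE)

  ## --- resident baselines
  n <- sum(homes$n_residents)
  home_id <- rep(homes$home_id, homes$n_residents)
  theta <- rep(homes$theta, homes$n_residents)
  resident_id <- sprintf("R%06d", seq_len(n))
  age <- round(.clamp(stats::rnorm(n, 84.6, 7.9), 58, 105), 2)
  sex <- stats::rbinom(n, 1, 0.66)  # 1 = female
  adl <- sample(0:6, n, replace = TRUE,
                prob = c(0.03, 0.06, 0.17, 0.30, 0.24, 0.17, 0.03))
  cps <- sample(0:6, n, replace = TRUE,
                prob = c(0.15, 0.11, 0.23, 0.34, 0.08, 0.07, 0.02))
  chess <- sample(0:5, n, replace = TRUE,
                  prob = c(0.46, 0.34, 0.14, 0.04, 0.013, 0.007))
  comorbidity <- stats::rpois(n, 2)
  frailty <- stats::rnorm(n, 0, config$frailty_sd)
  wt_flag <- stats::rbinom(n, 1, .clamp(0.08 + 0.02 * chess, 0, 1))
  fell <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.12) + 0.1 * adl))

  phys_imp <- adl == 6   # absorbing impairment states
  cog_imp <- cps >= 5

  alive <- rep(TRUE, n)
  prev_transfer <- rep(0L, n)
  prev_ill <- rep(0L, n)
  bh <- config$baseline_hazards
  ce <- config$covariate_effects
  bt <- config$beta_transfer
  gi <- config$gamma_illness_outcomes

  rows <- vector("list", config$n_periods_max)
  truth_rows <- vector("list", config$n_periods_max)

  for (t in seq_len(config$n_periods_max) - 1L) {
    idx <- which(alive)
    if (length(idx) == 0L) break
    m <- length(idx)

    ## latent acute illness: new episodes start with frailty-modified
    ## probability; ongoing episodes persist into the next period
    p_new <- stats::plogis(stats::qlogis(p_ill) + frailty[idx])
    p_cur <- ifelse(prev_ill[idx] == 1,
                    config$p_illness_persist + (1 - config$p_illness_persist) *
                      p_new,
                    p_new)
    ill <- stats::rbinom(m, 1, p_cur)

    ## covariate evolution (period 0 keeps the admission values)
    if (t > 0L) {
      walk <- function(x, up, dn, lo, hi, frozen = rep(FALSE, length(x))) {
        u <- stats::runif(length(x))
        nx <- x + (u < up) - (u > 1 - dn)
        ifelse(frozen, x, .clamp(nx, lo, hi))
      }
      adl[idx] <- walk(adl[idx], 0.08, 0.04, 0, 5, phys_imp[idx])
      cps[idx] <- walk(cps[idx], 0.08, 0.04, 0, 4, cog_imp[idx])
      chess[idx] <- walk(chess[idx], 0.15, 0.15, 0, 5)
      bump <- ill == 1 & stats::runif(m) < config$p_illness_chess_shift
      chess[idx] <- .clamp(chess[idx] + bump, 0, 5)
      wt_flag[idx] <- stats::rbinom(m, 1, .clamp(0.08 + 0.02 * chess[idx],
                                                 0, 1))
      fell[idx] <- stats::rbinom(m, 1, stats::plogis(stats::qlogis(0.12) +
                                                       0.1 * adl[idx]))
    }

    cur <- data.frame(age10 = (age[idx] - 85) / 10, sex = sex[idx],
                      adl_hierarchy = adl[idx], cps = cps[idx],
                      chess = chess[idx],
                      comorbidity_burden = comorbidity[idx],
                      weight_change_flag = wt_flag[idx], fell_30d = fell[idx])

    ## transfer (exposure)
    lp_t <- stats::qlogis(theta[idx]) + g_it * ill + .lp(ce$transfer, cur)
    transfer <- stats::rbinom(m, 1, stats::plogis(lp_t))

    ## death first (competing risk: the dead accrue no impairment onset);
    ## the causal transfer effect is lagged one period so that it acts on
    ## the window in which the analysis ascertains the outcome
    p_death <- .event_prob(bh[["death"]],
                           bt[["death"]] * prev_transfer[idx] +
                             gi[["death"]] * ill +
                             .lp(ce$death, cur), "death")
    died <- stats::rbinom(m, 1, p_death)

    surv <- died == 0
    new_phys <- rep(0L, m)
    can_phys <- surv & !phys_imp[idx]
    if (any(can_phys)) {
      p_phys <- .event_prob(bh[["physical"]],
                            bt[["physical"]] * transfer[can_phys] +
                              gi[["physical"]] * ill[can_phys] +
                              .lp(ce$physical, cur[can_phys, , drop = FALSE]),
                            "physical")
      new_phys[can_phys] <- stats::rbinom(sum(can_phys), 1, p_phys)
    }
    new_cog <- rep(0L, m)
    can_cog <- surv & !cog_imp[idx]
    if (any(can_cog)) {
      p_cog <- .event_prob(bh[["cognitive"]],
                           bt[["cognitive"]] * transfer[can_cog] +
                             gi[["cognitive"]] * ill[can_cog] +
                             .lp(ce$cognitive, cur[can_cog, , drop = FALSE]),
                           "cognitive")
      new_cog[can_cog] <- stats::rbinom(sum(can_cog), 1, p_cog)
    }
    discharged <- ifelse(surv, stats::rbinom(m, 1, bh[["discharge"]]), 0L)

    rows[[t + 1L]] <- data.frame(
      resident_id = resident_id[idx], home_id = home_id[idx],
      period_index = t, age_at_admission = age[idx], sex = sex[idx],
      adl_hierarchy = adl[idx], cps = cps[idx], chess = chess[idx],
      comorbidity_burden = comorbidity[idx],
      weight_change_flag = wt_flag[idx], fell_30d = fell[idx],
      transfer = transfer, died_in_period = died,
      discharged_in_period = as.integer(discharged),
      stringsAsFactors = FALSE)
    truth_rows[[t + 1L]] <- data.frame(
      resident_id = resident_id[idx], period_index = t,
      acute_illness = ill, frailty = frailty[idx],
      stringsAsFactors = FALSE)

    ## state updates: impairment onsets manifest at the next assessment
    onset_p <- idx[new_phys == 1]
    adl[onset_p] <- 6; phys_imp[onset_p] <- TRUE
    onset_c <- idx[new_cog == 1]
    cps[onset_c] <- 5; cog_imp[onset_c] <- TRUE
    alive[idx] <- surv & discharged == 0
    prev_transfer[idx] <- transfer
    prev_ill[idx] <- ill
  }

  cohort <- do.call(rbind, rows)
  cohort <- cohort[order(cohort$resident_id, cohort$period_index), ]
  rownames(cohort) <- NULL
  truth <- do.call(rbind, truth_rows)
  truth <- truth[order(truth$resident_id, truth$period_index), ]
  rownames(truth) <- NULL
  attr(truth, "config") <- config
  attr(truth, "true_log_hr") <- config$beta_transfer

  structure(list(cohort = cohort, truth = truth, homes = homes,
                 home_history = home_history, config = config),
            class = "ltc_cohort_sim")
}

#' @export
print.ltc_cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic LTC cohort: %d residents in %d homes, %d rows\n",
              length(unique(x$cohort$resident_id)), nrow(x$homes),
              nrow(x$cohort)))
  cat(sprintf("  deaths %d, discharges %d, ever transferred %.1f%%\n",
              sum(x$cohort$died_in_period),
              sum(x$cohort$discharged_in_period),
              100 * mean(tapply(x$cohort$transfer, x$cohort$resident_id,
                                max))))
  invisible(x)
}

.cohort_columns <- c("resident_id", "home_id", "period_index",
                     "age_at_admission", "sex", "adl_hierarchy", "cps",
                     "chess", "comorbidity_burden", "weight_change_flag",
                     "fell_30d", "transfer", "died_in_period",
                     "discharged_in_period")

#' Read and write assessment tables
#'
#' Comma-separated, header row, UTF-8, one row per resident-period, fixed
#' column order, empty fields for missing values. `read_cohort(write_cohort(x))`
#' is the identity on all fields.
#'
#' @param table an assessment table (as from [simulate_cohort()]).
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the table.
#' @export
write_cohort <- function(table, path) {
  missing_cols <- setdiff(.cohort_columns, names(table))
  if (length(missing_cols)) {
    .stopf("assessment table lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(table), .cohort_columns)
  if (length(extra)) {
    .warnf("dropping unknown column(s): %s", paste(extra, collapse = ", "))
  }
  utils::write.csv(table[, .cohort_columns, drop = FALSE], path,
                   row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  classes <- c(resident_id = "character", home_id = "character",
               period_index = "integer", age_at_admission = "numeric",
               sex = "integer", adl_hierarchy = "integer", cps = "integer",
               chess = "integer", comorbidity_burden = "integer",
               weight_change_flag = "integer", fell_30d = "integer",
               transfer = "integer", died_in_period = "integer",
               discharged_in_period = "integer")
  tab <- tryCatch(
    utils::read.csv(path, colClasses = NA, na.strings = "",
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE),
    error = function(e) .stopf("cannot parse %s: %s", path, conditionMessage(e)))
  extra <- setdiff(names(tab), .cohort_columns)
  if (length(extra)) {
    .warnf("ignoring unknown column(s): %s", paste(extra, collapse = ", "))
    tab <- tab[, setdiff(names(tab), extra), drop = FALSE]
  }
  missing_cols <- setdiff(.cohort_columns, names(tab))
  if (length(missing_cols)) {
    .stopf("file lacks required column(s): %s",
           paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab)) {
    for (nm in names(classes)) {
      bad <- if (classes[[nm]] == "character") integer(0) else {
        suppressWarnings(v <- as.numeric(tab[[nm]]))
        which(is.na(v) & !is.na(tab[[nm]]))
      }
      if (length(bad)) {
        .stopf("malformed value in column '%s' at data line %d", nm, bad[1])
      }
      tab[[nm]] <- switch(classes[[nm]],
                          character = as.character(tab[[nm]]),
                          integer = as.integer(tab[[nm]]),
                          numeric = as.numeric(tab[[nm]]))
    }
  } else {
    for (nm in names(classes)) {
      tab[[nm]] <- vector(mode = switch(classes[[nm]],
                                        character = "character",
                                        integer = "integer",
                                        numeric = "numeric"), 0L)
    }
  }
  tab[, .cohort_columns, drop = FALSE]
}
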