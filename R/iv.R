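#' Construct the preference-based instrument
#'
#' The instrument for a resident-period in follow-up year y is the
#' proportion of that LTC home's residents transferred to hospital during
#' year y - 1 (years are blocks of four 92-day periods). The first follow-up
#' year uses the home's burn-in (prior-year) history supplied by the
#' simulator; later years use the observed cohort: the denominator is the
#' number of residents assessed in the home in the prior year, the numerator
#' those among them with at least one transfer. Homes with no prior-year
#' residents get a missing `z` for that year.
#'
#' @param cohort assessment table.
#' @param home_history data.frame with `home_id`, `n_residents_prior_year`,
#'   `n_transferred_prior_year` (as emitted by [simulate_cohort()]).
#' @param periods_per_year periods per instrument-update block (default 4).
#' @return data.frame of class `instrument_table`: `home_id`, `year`,
#'   `n_residents_prior_year`, `n_transferred_prior_year`, `z`.
#' @export
compute_instrument <- function(cohort, home_history,
                               periods_per_year = 4) {
  if (nrow(cohort) == 0L) .stopf("empty cohort")
  need <- c("home_id", "n_residents_prior_year", "n_transferred_prior_year")
  if (!all(need %in% names(home_history))) {
    .stopf("home_history needs columns: %s", paste(need, collapse = ", "))
  }
  homes <- sort(unique(cohort$home_id))
  years <- seq_len(max(cohort$period_index) %/% periods_per_year + 1L)
  cohort$year <- cohort$period_index %/% periods_per_year + 1L

  out <- expand.grid(home_id = homes, year = years, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$home_id, out$year), ]
  out$n_residents_prior_year <- 0L
  out$n_transferred_prior_year <- 0L

  hh <- home_history[match(homes, home_history$home_id), ]
  y1 <- out$year == 1L
  out$n_residents_prior_year[y1] <-
    hh$n_residents_prior_year[match(out$home_id[y1], hh$home_id)]
  out$n_transferred_prior_year[y1] <-
    hh$n_transferred_prior_year[match(out$home_id[y1], hh$home_id)]

  if (length(years) > 1L) {
    key <- paste(cohort$home_id, cohort$year)
    n_res <- tapply(cohort$resident_id, key, function(x) length(unique(x)))
    ever <- tapply(cohort$transfer, paste(key, cohort$resident_id), max)
    ever_key <- sub(" [^ ]+$", "", names(ever))
    n_tr <- tapply(ever, ever_key, sum)
    for (y in years[-1]) {
      rows <- which(out$year == y)
      k <- paste(out$home_id[rows], y - 1L)
      out$n_residents_prior_year[rows] <-
        as.integer(ifelse(is.na(n_res[k]), 0L, n_res[k]))
      out$n_transferred_prior_year[rows] <-
        as.integer(ifelse(is.na(n_tr[k]), 0L, n_tr[k]))
    }
  }
  out$z <- ifelse(out$n_residents_prior_year > 0,
                  out$n_transferred_prior_year / out$n_residents_prior_year,
                  NA_real_)
  rownames(out) <- NULL
  class(out) <- c("instrument_table", "data.frame")
  out
}

#' Attach the instrument to a person-period table
#'
#' Joins each row to its home's current-year `z`; rows with a missing
#' instrument are excluded with a warning reporting the count.
#'
#' @param pp person-period table.
#' @param instrument an [compute_instrument()] table.
#' @param periods_per_year periods per block (must match the instrument).
#' @return `pp` with column `z`, missing-`z` rows removed.
#' @export
attach_instrument <- function(pp, instrument, periods_per_year = 4) {
  key_pp <- paste(pp$home_id, pp$period_index %/% periods_per_year + 1L)
  key_iv <- paste(instrument$home_id, instrument$year)
  pp$z <- instrument$z[match(key_pp, key_iv)]
  n_miss <- sum(is.na(pp$z))
  if (n_miss > 0) {
    .warnf("%d person-period row(s) excluded for missing instrument", n_miss)
    pp <- pp[!is.na(pp$z), , drop = FALSE]
  }
  pp
}

#' First-stage exposure model of the IV analysis
#'
#' Logistic regression of the binary exposure on the instrument plus baseline
#' covariates; the control-function residual is the response residual
#' `r = T - p_hat`, or its Pearson-standardized form
#' `r / sqrt(p_hat (1 - p_hat))` (the default used by the Cox stage, which
#' keeps the control function on a scale commensurate with the log-odds
#' confounding it absorbs when the exposure is rare). The instrument's Wald
#' statistic is reported as the relevance diagnostic, with a weak-instrument
#' warning when `|z| < 2` (the fit is still returned).
#'
#' @param pp person-period table with instrument column `z` (see
#'   [attach_instrument()]).
#' @param covariates baseline adjustment set.
#' @param residual_type `"pearson"` (default) or `"response"`.
#' @return list of class `ltc_first_stage`: `model`, `residuals`,
#'   `instrument_coef`, `instrument_se`, `relevance` (Wald z), `weak`.
#' @export
first_stage <- function(pp, covariates = .baseline_covs,
                        residual_type = c("pearson", "response")) {
  residual_type <- match.arg(residual_type)
  if (!"z" %in% names(pp)) .stopf("attach the instrument first (column 'z')")
  if (anyNA(pp$z)) .stopf("instrument contains missing values")
  if (!all(pp$exposed %in% c(0L, 1L))) .stopf("exposure must be binary")
  f <- stats::as.formula(paste("exposed ~ z +",
                               paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = pp,
                                     family = stats::binomial()))
  sm <- summary(fit)$coefficients
  b <- if ("z" %in% rownames(sm)) sm["z", 1] else NA_real_
  se <- if ("z" %in% rownames(sm)) sm["z", 2] else NA_real_
  relevance <- if (is.na(b) || se == 0) 0 else b / se
  if (is.na(b)) relevance <- 0
  weak <- abs(relevance) < 2
  if (weak) .warnf("weak instrument: first-stage Wald z = %.2f", relevance)
  separated <- any(abs(stats::coef(fit)) > 10, na.rm = TRUE)
  if (separated) .warnf("possible separation in the first stage")
  ph <- stats::fitted(fit)
  r <- pp$exposed - ph
  if (residual_type == "pearson") r <- r / sqrt(ph * (1 - ph))
  structure(list(model = fit,
                 residuals = r, residual_type = residual_type,
                 instrument_coef = b, instrument_se = se,
                 relevance = relevance, weak = weak, separated = separated,
                 covariates = covariates),
            class = "ltc_first_stage")
}

#' @export
print.ltc_first_stage <- function(x, ...) {
  cat(sprintf("First stage: instrument coef %.3f (SE %.3f), Wald z = %.2f%s\n",
              x$instrument_coef, x$instrument_se, x$relevance,
              if (x$weak) " [WEAK]" else ""))
  invisible(x)
}

## single 2SRI point fit: first stage + Cox with the residual entered
.tsri_point <- function(pp, covariates, conf_level, fs = NULL,
                        residual_type = "pearson") {
  if (is.null(fs)) fs <- first_stage(pp, covariates, residual_type)
  pp$cf_resid <- fs$residuals
  cs <- cox_spec(c("exposed", "cf_resid", covariates),
                 cluster_col = "home_id")
  fit <- fit_cox(pp, cs)
  list(fs = fs, fit = fit)
}

#' Control-function (two-stage residual inclusion) Cox estimator
#'
#' Stage 1 models exposure on the instrument and baseline covariates; stage 2
#' is a cause-specific Cox model of the outcome on exposure, the stage-1
#' residual (the control function, absorbing unmeasured confounding shared by
#' exposure and outcome) and the baseline covariates. The exposure
#' coefficient estimates the causal log hazard ratio among residents whose
#' transfer is sensitive to the home's propensity. The confidence interval is
#' a nonparametric cluster bootstrap resampling homes (percentile method),
#' or the cheaper home-clustered robust interval with `ci = "robust"`.
#'
#' @param pp person-period table with instrument column `z`.
#' @param covariates baseline adjustment set.
#' @param ci `"bootstrap"` (default) or `"robust"`.
#' @param n_boot bootstrap resamples (default 500).
#' @param seed seed for the bootstrap.
#' @param residual_type control-function residual form; see [first_stage()].
#' @param conf_level confidence level.
#' @return `ltc_hazard` (estimator `"iv"`); `details` carries the residual
#'   coefficient, first-stage relevance, and bootstrap failure count.
#' @export
control_function_cox <- function(pp, covariates = .baseline_covs,
                                 ci = c("bootstrap", "robust"),
                                 n_boot = 500, seed = 1,
                                 residual_type = c("pearson", "response"),
                                 conf_level = 0.95) {
  ci <- match.arg(ci)
  residual_type <- match.arg(residual_type)
  point <- .tsri_point(pp, covariates, conf_level,
                       residual_type = residual_type)
  fit <- point$fit
  b <- fit$coefficients[["exposed"]]
  z <- .crit(fit, conf_level)

  boot_fail <- 0L
  if (ci == "bootstrap") {
    homes <- unique(pp$home_id)
    if (length(homes) < 2) .stopf("cluster bootstrap needs >= 2 homes")
    set.seed(seed)
    rows_by_home <- split(seq_len(nrow(pp)), pp$home_id)
    est <- rep(NA_real_, n_boot)
    for (bi in seq_len(n_boot)) {
      take <- sample(homes, length(homes), replace = TRUE)
      idx_list <- rows_by_home[take]
      bp <- pp[unlist(idx_list, use.names = FALSE), , drop = FALSE]
      ## resampled copies of a home are distinct clusters
      bp$home_id <- rep(paste0(take, "#", seq_along(take)),
                        vapply(idx_list, length, 1L))
      est[bi] <- tryCatch(
        suppressWarnings(
          .tsri_point(bp, covariates, conf_level,
                      residual_type = residual_type
                      )$fit$coefficients[["exposed"]]),
        error = function(e) NA_real_)
    }
    boot_fail <- sum(is.na(est))
    if (boot_fail > n_boot / 2) {
      .stopf("cluster bootstrap failed in %d of %d resamples", boot_fail,
             n_boot)
    }
    qs <- stats::quantile(est, c((1 - conf_level) / 2,
                                 1 - (1 - conf_level) / 2),
                          na.rm = TRUE, names = FALSE)
    ci_lo <- exp(qs[1]); ci_hi <- exp(qs[2])
    boot_se <- stats::sd(est, na.rm = TRUE)
  } else {
    se_use <- fit$robust_se[["exposed"]]
    ci_lo <- exp(b - z * se_use); ci_hi <- exp(b + z * se_use)
    boot_se <- NA_real_
  }

  hazard_estimate("iv", attr(pp, "outcome") %||% "outcome", b,
                  fit$model_se[["exposed"]], fit$robust_se[["exposed"]],
                  ci_lo, ci_hi, conf_level, fit$n_events,
                  details = list(
                    residual_coef = fit$coefficients[["cf_resid"]],
                    residual_se = fit$robust_se[["cf_resid"]],
                    first_stage = point$fs,
                    relevance = point$fs$relevance,
                    weak_instrument = point$fs$weak,
                    ci_method = ci, n_boot = if (ci == "bootstrap") n_boot
                    else NA_integer_,
                    boot_failures = boot_fail, boot_se = boot_se,
                    fit = fit))
}

#' Instrument assumption diagnostics
#'
#' Produces (a) relevance: the association of `z` with individual transfer
#' (first-stage Wald z and the resident-level correlation); (b) an
#' exogeneity proxy: SMDs of baseline covariates between the extreme
#' resident-weighted quintiles of `z`; and (c) the incidence of each
#' requested outcome across instrument quintiles. With fewer than 5 distinct
#' `z` values the quintiles collapse and the collapse is reported, not fatal.
#'
#' @param cohort assessment table.
#' @param instrument an [compute_instrument()] table.
#' @param pp_list optional named list of person-period tables (per outcome)
#'   for the quintile incidence panel.
#' @return list of class `iv_diagnostics`: `relevance`, `balance` (SMD
#'   data.frame), `quintile_incidence`, `quintiles_collapsed`.
#' @export
instrument_diagnostics <- function(cohort, instrument, pp_list = NULL) {
  if (length(unique(cohort$home_id)) < 2) {
    .stopf("instrument diagnostics need at least 2 homes")
  }
  base <- cohort[cohort$period_index == 0L, ]
  z1 <- instrument$z[instrument$year == 1L]
  names(z1) <- instrument$home_id[instrument$year == 1L]
  base$z <- z1[base$home_id]
  base <- base[!is.na(base$z), ]

  ever <- tapply(cohort$transfer, cohort$resident_id, max)
  base$ever <- as.numeric(ever[base$resident_id])
  relevance_cor <- suppressWarnings(stats::cor(base$z, base$ever))

  ## resident-weighted quintiles of z, ties broken by home id
  ord <- order(base$z, base$home_id)
  qgrp <- integer(nrow(base))
  qgrp[ord] <- ceiling(seq_along(ord) / (length(ord) / 5))
  qgrp <- .clamp(qgrp, 1, 5)
  n_distinct <- length(unique(base$z))
  collapsed <- n_distinct < 5
  base$quintile <- qgrp

  vars_cont <- c("age_at_admission", "adl_hierarchy", "cps", "chess",
                 "comorbidity_burden")
  vars_prop <- c("sex", "weight_change_flag", "fell_30d")
  lo <- base[base$quintile == 1, ]
  hi <- base[base$quintile == 5, ]
  balance <- do.call(rbind, lapply(c(vars_cont, vars_prop), function(v) {
    kind <- if (v %in% vars_cont) "continuous" else "proportion"
    s <- if (kind == "continuous") {
      standardized_mean_difference(
        c(mean = mean(hi[[v]]), sd = stats::sd(hi[[v]])),
        c(mean = mean(lo[[v]]), sd = stats::sd(lo[[v]])), kind, v)
    } else {
      standardized_mean_difference(mean(hi[[v]]), mean(lo[[v]]), kind, v)
    }
    data.frame(variable = v, kind = kind, smd = s$smd,
               stringsAsFactors = FALSE)
  }))

  quintile_incidence <- NULL
  if (!is.null(pp_list)) {
    qi <- lapply(names(pp_list), function(oc) {
      pp <- pp_list[[oc]]
      pp$quintile <- base$quintile[match(pp$resident_id, base$resident_id)]
      pp <- pp[!is.na(pp$quintile), ]
      do.call(rbind, lapply(split(pp, pp$quintile), function(d) {
        r <- incidence_rate(sum(d$event),
                            sum(d$stop - d$start) / 365.25)
        data.frame(outcome = oc, quintile = d$quintile[1],
                   events = r$events, person_years = r$person_years,
                   rate_per_100py = r$rate_per_100py,
                   stringsAsFactors = FALSE)
      }))
    })
    quintile_incidence <- do.call(rbind, qi)
    rownames(quintile_incidence) <- NULL
  }

  fs_rel <- tryCatch({
    ppz <- base
    ppz$exposed <- as.integer(ppz$ever)
    f <- suppressWarnings(stats::glm(exposed ~ z, data = ppz,
                                     family = stats::binomial()))
    sm <- summary(f)$coefficients
    if ("z" %in% rownames(sm)) sm["z", 1] / sm["z", 2] else 0
  }, error = function(e) 0)

  structure(list(relevance = list(correlation = relevance_cor,
                                  wald_z = fs_rel),
                 balance = balance,
                 quintile_incidence = quintile_incidence,
                 quintiles_collapsed = collapsed,
                 n_distinct_z = n_distinct),
            class = "iv_diagnostics")
}

#' @export
print.iv_diagnostics <- function(x, ...) {
  cat(sprintf("Instrument diagnostics: relevance cor = %.3f, Wald z = %.2f\n",
              x$relevance$correlation, x$relevance$wald_z))
  if (x$quintiles_collapsed) {
    cat(sprintf("  quintiles collapsed (%d distinct z values)\n",
                x$n_distinct_z))
  }
  cat(sprintf("  max baseline SMD across extreme quintiles: %.3f\n",
              max(x$balance$smd)))
  invisible(x)
}
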