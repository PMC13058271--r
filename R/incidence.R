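#' Incidence rate per 100 person-years
#'
#' Point estimate `100 * events / person_years` with a log-rate normal
#' confidence interval `rate * exp(+/- z / sqrt(events))`; for fewer than 5
#' events the exact Poisson (chi-square) interval is used, with a zero lower
#' bound at zero events.
#'
#' @param events nonnegative event count.
#' @param person_years person-time at risk in years; must be positive.
#' @param conf_level confidence level (default 0.95).
#' @param group optional label (`"ever_transferred"` / `"never_transferred"`).
#' @return object of class `incidence_result`.
#' @export
#' @examples
#' incidence_rate(10, 100)   # 10 per 100 person-years
incidence_rate <- function(events, person_years, conf_level = 0.95,
                           group = NA_character_) {
  if (!is.finite(person_years) || person_years <= 0) {
    .stopf("person_years must be positive")
  }
  if (!is.finite(events) || events < 0) .stopf("events must be nonnegative")
  rate <- 100 * events / person_years
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (events >= 5) {
    ci <- rate * exp(c(-1, 1) * z / sqrt(events))
  } else {
    a <- 1 - conf_level
    lo <- if (events == 0) 0 else stats::qchisq(a / 2, 2 * events) / 2
    hi <- stats::qchisq(1 - a / 2, 2 * events + 2) / 2
    ci <- 100 * c(lo, hi) / person_years
  }
  structure(list(group = group, events = events, person_years = person_years,
                 rate_per_100py = rate, ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level),
            class = "incidence_result")
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf("%s%.1f per 100 person-years (%d%% CI %.1f-%.1f; %g events / %.1f PY)\n",
              if (is.na(x$group)) "" else paste0(x$group, ": "),
              x$rate_per_100py, round(100 * x$conf_level), x$ci_low,
              x$ci_high, x$events, x$person_years))
  invisible(x)
}

#' Incidence rate ratio
#'
#' Ratio of two incidence rates. When both arguments are full
#' [incidence_rate()] results the CI is formed on the log scale with standard
#' error `sqrt(1/e1 + 1/e2)`; bare numeric rates (e.g. rates transcribed from
#' a published table) give the point ratio only.
#'
#' @param numerator,denominator `incidence_result` objects or bare rates.
#' @param conf_level confidence level when counts are available.
#' @return object of class `rate_ratio` with `ratio`, and `ci_low`/`ci_high`
#'   when computable.
#' @export
#' @examples
#' rate_ratio(13.2, 4.4)   # 3.0
rate_ratio <- function(numerator, denominator, conf_level = 0.95) {
  get_rate <- function(x) if (inherits(x, "incidence_result"))
    x$rate_per_100py else as.numeric(x)
  r1 <- get_rate(numerator)
  r0 <- get_rate(denominator)
  if (!is.finite(r0) || r0 <= 0) .stopf("denominator rate must be positive")
  ratio <- r1 / r0
  ci <- c(NA_real_, NA_real_)
  if (inherits(numerator, "incidence_result") &&
      inherits(denominator, "incidence_result") &&
      numerator$events > 0 && denominator$events > 0) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / numerator$events + 1 / denominator$events)
    ci <- ratio * exp(c(-1, 1) * z * se)
  }
  structure(list(ratio = ratio, ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level),
            class = "rate_ratio")
}

#' @export
print.rate_ratio <- function(x, ...) {
  if (is.na(x$ci_low)) {
    cat(sprintf("IRR %.2f\n", x$ratio))
  } else {
    cat(sprintf("IRR %.2f (%d%% CI %.2f-%.2f)\n", x$ratio,
                round(100 * x$conf_level), x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Standardized mean difference
#'
#' Balance metric for baseline tables. Continuous variables use the pooled-SD
#' (Cohen's d style) form `|m_a - m_b| / sqrt((s_a^2 + s_b^2)/2)`; proportions
#' use `|p_a - p_b| / sqrt((p_a(1-p_a) + p_b(1-p_b))/2)`. Reported as an
#' absolute value, so it is symmetric in the two groups.
#'
#' @param summary_a,summary_b for `kind = "continuous"`, named vectors
#'   `c(mean=, sd=)`; for `kind = "proportion"`, single proportions in
#'   `[0, 1]`.
#' @param kind `"continuous"` or `"proportion"`.
#' @param variable optional variable label.
#' @return object of class `smd_result` with element `smd`.
#' @export
#' @examples
#' standardized_mean_difference(c(mean = 84.62, sd = 7.95),
#'                              c(mean = 84.14, sd = 7.52), "continuous")
standardized_mean_difference <- function(summary_a, summary_b,
                                         kind = c("continuous", "proportion"),
                                         variable = NA_character_) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    for (s in list(summary_a, summary_b)) {
      if (any(is.na(s[c("mean", "sd")]))) {
        .stopf("continuous summaries need 'mean' and 'sd'")
      }
      if (s[["sd"]] <= 0) .stopf("dispersions must be positive")
    }
    smd <- abs(summary_a[["mean"]] - summary_b[["mean"]]) /
      sqrt((summary_a[["sd"]]^2 + summary_b[["sd"]]^2) / 2)
  } else {
    p_a <- as.numeric(summary_a)[1]
    p_b <- as.numeric(summary_b)[1]
    if (any(!is.finite(c(p_a, p_b))) || any(c(p_a, p_b) < 0) ||
        any(c(p_a, p_b) > 1)) {
      .stopf("proportions must lie in [0, 1]")
    }
    denom <- sqrt((p_a * (1 - p_a) + p_b * (1 - p_b)) / 2)
    smd <- if (denom == 0) 0 else abs(p_a - p_b) / denom
  }
  structure(list(variable = variable, kind = kind, group_a = summary_a,
                 group_b = summary_b, smd = as.numeric(smd)),
            class = "smd_result")
}

#' @export
print.smd_result <- function(x, ...) {
  cat(sprintf("SMD%s = %.3f (%s)\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$smd, x$kind))
  invisible(x)
}

#' Incidence by ever/never-transferred status
#'
#' Classifies residents (not periods) by whether they were ever transferred
#' during follow-up, sums events and 92-day person-time within each group,
#' and returns the two rates with their ratio. Transfer status is read from
#' the full assessment table when `cohort` is supplied — a transfer in the
#' resident's final (event) period counts — otherwise from the person-period
#' rows. Person-time before a transferred resident's first transfer is
#' counted in the ever-transferred group, matching the resident-level
#' framing of a transfer-status table (this carries the usual immortal-time
#' caveat for descriptive rates).
#'
#' @param pp person-period table from [build_person_periods()].
#' @param cohort optional assessment table used to determine ever/never
#'   transfer status over full follow-up.
#' @param by `"resident"` (default) contrasts ever- vs never-transferred
#'   residents, the framing of a transfer-status table; `"period"` contrasts
#'   exposed vs unexposed person-time, which is free of immortal-time
#'   artefacts and converges to the true rate-scale effect in the absence of
#'   confounding.
#' @param conf_level confidence level.
#' @return list of class `incidence_table` with `ever`, `never`
#'   (`incidence_result`) and `irr` (`rate_ratio`).
#' @export
cohort_incidence <- function(pp, cohort = NULL,
                             by = c("resident", "period"),
                             conf_level = 0.95) {
  by <- match.arg(by)
  if (nrow(pp) == 0L) .stopf("empty person-period table")
  if (by == "resident") {
    src <- if (is.null(cohort)) pp else cohort
    flag <- if (is.null(cohort)) src$exposed else src$transfer
    ever_id <- tapply(flag, src$resident_id, max)
    is_ever <- ever_id[pp$resident_id] == 1
    labels <- c("ever_transferred", "never_transferred")
  } else {
    is_ever <- pp$exposed == 1
    labels <- c("exposed_periods", "unexposed_periods")
  }
  mk <- function(rows, label) {
    incidence_rate(sum(pp$event[rows]),
                   sum(pp$stop[rows] - pp$start[rows]) / 365.25,
                   conf_level, group = label)
  }
  ever <- mk(which(is_ever), labels[1])
  never <- mk(which(!is_ever), labels[2])
  irr <- if (never$rate_per_100py > 0) {
    rate_ratio(ever, never, conf_level)
  } else {
    ## comparison group without events: the ratio is undefined
    structure(list(ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   conf_level = conf_level), class = "rate_ratio")
  }
  structure(list(ever = ever, never = never, irr = irr,
                 outcome = attr(pp, "outcome")),
            class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("Incidence (%s)\n", x$outcome %||% "outcome"))
  print(x$ever); print(x$never); print(x$irr)
  invisible(x)
}

#' Baseline characteristics by transfer status with SMDs
#'
#' Summarises admission (period 0) covariates for ever- vs never-transferred
#' residents and computes the standardized mean difference for each.
#'
#' @param cohort assessment table.
#' @return data.frame with one row per covariate: group summaries and `smd`.
#' @export
baseline_table <- function(cohort) {
  if (nrow(cohort) == 0L) .stopf("empty cohort")
  ever <- tapply(cohort$transfer, cohort$resident_id, max)
  base <- cohort[cohort$period_index == 0L, ]
  base$ever <- ever[base$resident_id] == 1
  cont <- c("age_at_admission", "adl_hierarchy", "cps", "chess",
            "comorbidity_burden")
  prop <- c("sex", "weight_change_flag", "fell_30d")
  out <- lapply(c(cont, prop), function(v) {
    kind <- if (v %in% cont) "continuous" else "proportion"
    a <- base[[v]][base$ever]
    b <- base[[v]][!base$ever]
    if (kind == "continuous") {
      sa <- c(mean = mean(a), sd = stats::sd(a))
      sb <- c(mean = mean(b), sd = stats::sd(b))
      s <- standardized_mean_difference(sa, sb, kind, variable = v)
      data.frame(variable = v, kind = kind, ever = sa[["mean"]],
                 ever_sd = sa[["sd"]], never = sb[["mean"]],
                 never_sd = sb[["sd"]], smd = s$smd,
                 stringsAsFactors = FALSE)
    } else {
      s <- standardized_mean_difference(mean(a), mean(b), kind, variable = v)
      data.frame(variable = v, kind = kind, ever = mean(a), ever_sd = NA_real_,
                 never = mean(b), never_sd = NA_real_, smd = s$smd,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
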