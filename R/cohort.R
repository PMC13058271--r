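#' Apply eligibility rules to an assessment table
#'
#' Removes residents under 65 at admission, then — for the impairment
#' outcomes — residents already past the permanence threshold at the
#' admission assessment (ADL hierarchy = 6 for the physical outcome,
#' CPS >= 5 for the cognitive outcome). The mortality analysis applies no
#' impairment-based exclusion. The report tallies every exclusion and the
#' at-risk counts for both impairment outcomes regardless of the outcome
#' requested, so the cohort accounting can be audited from a single pass.
#'
#' @param table assessment table (see [simulate_cohort()] for the schema).
#' @param outcome one of `"physical"`, `"cognitive"`, `"mortality"`.
#' @return list with `table` (the filtered assessment rows) and `report`
#'   (class `eligibility_report`).
#' @export
apply_eligibility <- function(table,
                              outcome = c("physical", "cognitive",
                                          "mortality")) {
  outcome <- match.arg(outcome)
  if (nrow(table) == 0L) {
    rep0 <- eligibility_report(0L, 0L, 0L, 0L)
    return(list(table = table, report = rep0))
  }
  has0 <- tapply(table$period_index, table$resident_id, min)
  no_admission <- names(has0)[has0 != 0]
  if (length(no_admission)) {
    .stopf("resident(s) missing the admission (period 0) assessment: %s",
           paste(utils::head(no_admission, 5), collapse = ", "))
  }
  base <- table[table$period_index == 0L, ]
  n_input <- nrow(base)
  under65 <- base$resident_id[base$age_at_admission < 65]
  base_aged <- base[!(base$resident_id %in% under65), ]
  phys_imp <- base_aged$resident_id[base_aged$adl_hierarchy == 6]
  cog_imp <- base_aged$resident_id[base_aged$cps >= 5]
  report <- eligibility_report(n_input, length(under65),
                               length(phys_imp), length(cog_imp))
  drop <- switch(outcome,
                 physical = c(under65, phys_imp),
                 cognitive = c(under65, cog_imp),
                 mortality = under65)
  list(table = table[!(table$resident_id %in% drop), , drop = FALSE],
       report = report)
}

#' Eligibility accounting
#'
#' The at-risk counts follow by subtraction from the input count after the
#' age filter: `n_at_risk_physical = (n_input - n_excluded_age) -
#' n_excluded_prior_impairment_physical`, and likewise for the cognitive
#' outcome.
#'
#' @param n_input residents in the input table.
#' @param n_excluded_age residents under 65 at admission.
#' @param n_excluded_prior_impairment_physical residents with ADL = 6 at
#'   admission (among the age-eligible).
#' @param n_excluded_prior_impairment_cognitive residents with CPS >= 5 at
#'   admission (among the age-eligible).
#' @return object of class `eligibility_report`.
#' @export
eligibility_report <- function(n_input, n_excluded_age,
                               n_excluded_prior_impairment_physical,
                               n_excluded_prior_impairment_cognitive) {
  counts <- c(n_input, n_excluded_age, n_excluded_prior_impairment_physical,
              n_excluded_prior_impairment_cognitive)
  if (any(counts < 0)) .stopf("eligibility counts must be nonnegative")
  n_aged <- n_input - n_excluded_age
  structure(list(
    n_input = n_input,
    n_excluded_age = n_excluded_age,
    n_excluded_prior_impairment_physical =
      n_excluded_prior_impairment_physical,
    n_excluded_prior_impairment_cognitive =
      n_excluded_prior_impairment_cognitive,
    n_at_risk_physical = n_aged - n_excluded_prior_impairment_physical,
    n_at_risk_cognitive = n_aged - n_excluded_prior_impairment_cognitive),
    class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Eligibility report\n")
  cat(sprintf("  input residents:            %d\n", x$n_input))
  cat(sprintf("  excluded, age < 65:         %d\n", x$n_excluded_age))
  cat(sprintf("  baseline ADL = 6:           %d  (at risk physical: %d)\n",
              x$n_excluded_prior_impairment_physical, x$n_at_risk_physical))
  cat(sprintf("  baseline CPS >= 5:          %d  (at risk cognitive: %d)\n",
              x$n_excluded_prior_impairment_cognitive, x$n_at_risk_cognitive))
  invisible(x)
}

#' Detect permanent impairment onset in a scale sequence
#'
#' An onset is the first assessment at which the scale is at or above the
#' permanence threshold (ADL hierarchy = 6, or CPS >= 5) with no later
#' observed value falling below it. A crossing reversed by a subsequent
#' improvement does not count, but a later re-crossing with no subsequent
#' improvement does. When the crossing is the final observation it counts as
#' permanent unless `require_confirmation = TRUE`, which demands at least one
#' further assessment still at or above the threshold.
#'
#' @param values integer vector of quarterly scale values (ADL 0-6 or CPS 0-6).
#' @param rule `"adl_eq_6"` or `"cps_ge_5"`.
#' @param require_confirmation stricter variant; see above.
#' @return list with `onset_index` (1-based position, `NA` when none) and
#'   `permanent` (logical).
#' @export
#' @examples
#' detect_permanent_impairment(c(4, 5, 6, 6, 6), "adl_eq_6")  # onset at 3
#' detect_permanent_impairment(c(4, 6, 5, 6, 6), "adl_eq_6")  # onset at 4
detect_permanent_impairment <- function(values,
                                        rule = c("adl_eq_6", "cps_ge_5"),
                                        require_confirmation = FALSE) {
  rule <- match.arg(rule)
  if (length(values) == 0L) .stopf("scale sequence is empty")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 6)) {
    .stopf("scale values must lie in 0..6")
  }
  thr <- if (rule == "adl_eq_6") 6 else 5
  bad <- values >= thr
  n <- length(bad)
  if (!bad[n]) return(list(onset_index = NA_integer_, permanent = FALSE))
  last_good <- if (all(bad)) 0L else max(which(!bad))
  onset <- last_good + 1L
  if (require_confirmation && onset == n) {
    return(list(onset_index = NA_integer_, permanent = FALSE))
  }
  list(onset_index = onset, permanent = TRUE)
}

## vectorised onset period per resident: the period index (0-based) of the
## first threshold crossing never followed by improvement; NA when none
.onset_periods <- function(table, scale_col, thr) {
  bad <- table[[scale_col]] >= thr
  id <- table$resident_id
  last_bad <- tapply(bad, id, function(b) b[length(b)])
  last_good_period <- tapply(seq_along(bad), id, function(i) {
    g <- i[!bad[i]]
    if (length(g)) table$period_index[max(g)] else -1L
  })
  onset <- ifelse(last_bad, last_good_period + 1L, NA_integer_)
  onset
}

#' Build the person-period (counting-process) dataset for one outcome
#'
#' Converts quarterly assessment rows into counting-process rows
#' `[92k, 92(k+1))` with the binary exposure of period k (any transfer within
#' the period) and the event ascertained in the immediately subsequent 92-day
#' window: the row for period k carries the outcome observed in window k+1,
#' so a death in days 92-183 is the event of the k = 0 row. Follow-up ends at
#' the outcome onset, death (a competing event for the impairment outcomes),
#' discharge without readmission (censored at the discharge period's end), or
#' the administrative horizon. The mortality dataset keeps the impairment
#' path as covariates and truncates only at death or censoring.
#'
#' @param table assessment table, eligibility already applied.
#' @param outcome `"physical"`, `"cognitive"` or `"mortality"`.
#' @param n_periods_max administrative horizon in periods (default 20).
#' @param impairment_precedence when an impairment onset and death fall in
#'   the same outcome window, attribute the impairment (default); set
#'   `FALSE` for the death-first variant.
#' @param require_confirmation passed to the permanence rule.
#' @return data.frame of class `ltc_person_periods`: one row per
#'   resident-period with `start`, `stop`, `exposed`, `event` (0/1 for the
#'   requested outcome), `event_code`, `censor_reason`, time-varying and
#'   baseline covariates, and exposure history (`prev_exposed`, `cum_prev`).
#' @export
build_person_periods <- function(table,
                                 outcome = c("physical", "cognitive",
                                             "mortality"),
                                 n_periods_max = 20,
                                 impairment_precedence = TRUE,
                                 require_confirmation = FALSE) {
  outcome <- match.arg(outcome)
  if (nrow(table) == 0L) return(.empty_pp(outcome))
  table <- table[order(table$resident_id, table$period_index), ]

  ## contiguity: per resident, periods must run 0,1,2,... without gaps
  contiguous <- tapply(table$period_index, table$resident_id, function(p) {
    identical(as.integer(p), seq_along(p) - 1L)
  })
  if (!all(contiguous)) {
    .stopf("non-contiguous period indices for resident(s): %s",
           paste(utils::head(names(contiguous)[!contiguous], 5),
                 collapse = ", "))
  }

  ids <- unique(table$resident_id)
  K <- tapply(table$period_index, table$resident_id, max)[ids]
  died_p <- tapply(ifelse(table$died_in_period == 1, table$period_index, NA),
                   table$resident_id, function(x) {
                     x <- x[!is.na(x)]
                     if (length(x)) min(x) else NA_integer_
                   })[ids]
  disc_p <- tapply(ifelse(table$discharged_in_period == 1,
                          table$period_index, NA),
                   table$resident_id, function(x) {
                     x <- x[!is.na(x)]
                     if (length(x)) min(x) else NA_integer_
                   })[ids]

  onset_p <- rep(NA_integer_, length(ids))
  names(onset_p) <- ids
  if (outcome != "mortality") {
    scale_col <- if (outcome == "physical") "adl_hierarchy" else "cps"
    thr <- if (outcome == "physical") 6 else 5
    o <- .onset_periods(table, scale_col, thr)[ids]
    if (require_confirmation) {
      o <- ifelse(!is.na(o) & o == K, NA_integer_, o)
    }
    onset_p <- o
  }

  inf_na <- function(x) ifelse(is.na(x), Inf, x)
  w_onset <- inf_na(onset_p)
  w_death <- inf_na(died_p)

  n_rows <- integer(length(ids))
  terminal <- character(length(ids))
  reason <- rep(NA_character_, length(ids))
  outcome_code <- switch(outcome, physical = "physical_impairment",
                         cognitive = "cognitive_impairment",
                         mortality = "death")
  for (i in seq_along(ids)) {
    wo <- if (outcome == "mortality") Inf else w_onset[i]
    wd <- w_death[i]
    if (is.finite(wo) || is.finite(wd)) {
      w <- min(wo, wd)
      code <- if (wo < wd) outcome_code
      else if (wd < wo) "death"
      else if (impairment_precedence) outcome_code else "death"
      n_rows[i] <- w                      # rows 0 .. w-1; row w-1 holds event
      terminal[i] <- code
    } else if (is.finite(disc_p[i])) {
      n_rows[i] <- disc_p[i] + 1L         # censored at discharge period end
      terminal[i] <- "censored"
      reason[i] <- "discharge"
    } else {
      n_rows[i] <- K[i] + 1L              # administrative censoring
      terminal[i] <- "censored"
      reason[i] <- "administrative"
    }
  }

  keep_n <- n_rows[match(table$resident_id, ids)]
  pp <- table[table$period_index < keep_n, , drop = FALSE]
  if (nrow(pp) == 0L) return(.empty_pp(outcome))

  ids_kept <- ids[n_rows > 0]
  last_row <- !duplicated(pp$resident_id, fromLast = TRUE)
  pp$event_code <- "none"
  pp$event_code[last_row] <- terminal[match(pp$resident_id[last_row], ids)]
  pp$censor_reason <- NA_character_
  pp$censor_reason[last_row] <- reason[match(pp$resident_id[last_row], ids)]
  pp$event <- as.integer(pp$event_code == outcome_code)
  pp$cens <- as.integer(pp$event_code == "censored" &
                          !is.na(pp$censor_reason) &
                          pp$censor_reason == "discharge")

  pp$start <- 92L * pp$period_index
  pp$stop <- pp$start + 92L
  pp$exposed <- as.integer(pp$transfer > 0)
  pp$prev_exposed <- stats::ave(pp$exposed, pp$resident_id,
                                FUN = function(x) c(0L, utils::head(x, -1)))
  pp$cum_prev <- stats::ave(pp$exposed, pp$resident_id,
                            FUN = function(x) c(0L, utils::head(cumsum(x),
                                                                -1)))
  pp$age10 <- (pp$age_at_admission - 85) / 10
  pp$period <- pp$period_index

  base <- pp[pp$period_index == 0L,
             c("resident_id", "adl_hierarchy", "cps", "chess")]
  names(base) <- c("resident_id", "baseline_adl", "baseline_cps",
                   "baseline_chess")
  pp <- merge(pp, base, by = "resident_id", sort = FALSE)
  pp <- pp[order(pp$resident_id, pp$period_index), ]
  rownames(pp) <- NULL
  attr(pp, "outcome") <- outcome
  class(pp) <- c("ltc_person_periods", "data.frame")
  pp
}

.empty_pp <- function(outcome) {
  pp <- data.frame(resident_id = character(0), home_id = character(0),
                   period_index = integer(0), age_at_admission = numeric(0),
                   sex = integer(0), adl_hierarchy = integer(0),
                   cps = integer(0), chess = integer(0),
                   comorbidity_burden = integer(0),
                   weight_change_flag = integer(0), fell_30d = integer(0),
                   transfer = integer(0), died_in_period = integer(0),
                   discharged_in_period = integer(0),
                   event_code = character(0), censor_reason = character(0),
                   event = integer(0), cens = integer(0), start = integer(0),
                   stop = integer(0), exposed = integer(0),
                   prev_exposed = integer(0), cum_prev = integer(0),
                   age10 = numeric(0), period = integer(0),
                   baseline_adl = integer(0), baseline_cps = integer(0),
                   baseline_chess = integer(0))
  attr(pp, "outcome") <- outcome
  class(pp) <- c("ltc_person_periods", "data.frame")
  pp
}

#' Total person-years in a person-period table
#'
#' Each 92-day row contributes 92/365.25 years.
#'
#' @param pp person-period table from [build_person_periods()].
#' @return numeric scalar.
#' @export
person_years <- function(pp) sum(pp$stop - pp$start) / 365.25
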