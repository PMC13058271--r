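#' Analysis configuration for the full pipeline
#'
#' @param sim an [ltc_sim_config()] used to simulate the cohort, or `NULL`
#'   when `cohort_path` is given.
#' @param cohort_path path to an assessment CSV (read with [read_cohort()]).
#' @param home_history_path path to a home burn-in history CSV (needed for
#'   the IV estimator when reading a cohort from disk).
#' @param outcomes subset of `c("physical", "cognitive", "mortality")`.
#' @param estimators subset of `c("crude", "extended_cox", "msm", "iv")`.
#' @param truncation stabilized-weight truncation percentiles or `NULL`.
#' @param iv_ci `"bootstrap"` or `"robust"`.
#' @param n_boot bootstrap resamples for the IV interval.
#' @param n_periods_max administrative horizon in periods.
#' @param seed master seed (simulation and bootstrap).
#' @return object of class `ltc_analysis_config`.
#' @export
analysis_config <- function(sim = ltc_sim_config(),
                            cohort_path = NULL,
                            home_history_path = NULL,
                            outcomes = c("physical", "cognitive",
                                         "mortality"),
                            estimators = c("crude", "extended_cox", "msm",
                                           "iv"),
                            truncation = c(0.01, 0.99),
                            iv_ci = c("bootstrap", "robust"),
                            n_boot = 500,
                            n_periods_max = 20,
                            seed = 1) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  estimators <- match.arg(estimators, several.ok = TRUE)
  iv_ci <- match.arg(iv_ci)
  if (is.null(sim) && is.null(cohort_path)) {
    .stopf("either a simulation config or a cohort path is required")
  }
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    .stopf("missing input file: %s", cohort_path)
  }
  if (!is.null(sim)) sim$seed <- seed
  structure(list(sim = sim, cohort_path = cohort_path,
                 home_history_path = home_history_path,
                 outcomes = outcomes, estimators = estimators,
                 truncation = truncation, iv_ci = iv_ci, n_boot = n_boot,
                 n_periods_max = n_periods_max, seed = seed),
            class = "ltc_analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [analysis_config()]; the `sim` key
#' holds [ltc_sim_config()] arguments.
#'
#' @param path YAML file.
#' @return `ltc_analysis_config`.
#' @export
analysis_config_from_yaml <- function(path) {
  if (!file.exists(path)) .stopf("missing input file: %s", path)
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(ltc_sim_config, y$sim) else
    if (is.null(y$cohort_path)) ltc_sim_config() else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(analysis_config, c(list(sim = sim), args))
}

.load_inputs <- function(config) {
  if (!is.null(config$cohort_path)) {
    cohort <- read_cohort(config$cohort_path)
    hh <- NULL
    if (!is.null(config$home_history_path)) {
      if (!file.exists(config$home_history_path)) {
        .stopf("missing input file: %s", config$home_history_path)
      }
      hh <- utils::read.csv(config$home_history_path,
                            stringsAsFactors = FALSE)
    }
    list(cohort = cohort, home_history = hh)
  } else {
    sim <- simulate_cohort(config$sim)
    list(cohort = sim$cohort, home_history = sim$home_history)
  }
}

## one outcome x estimator cell; failures are isolated, not fatal
.run_cell <- function(estimator, pp, ppz, config) {
  tryCatch(switch(estimator,
                  crude = fit_crude_cox(pp),
                  extended_cox = fit_extended_cox(pp),
                  msm = fit_msm(pp, weight_model_spec(
                    truncation = config$truncation)),
                  iv = {
                    if (is.null(ppz)) .stopf("no instrument available")
                    control_function_cox(ppz, ci = config$iv_ci,
                                         n_boot = config$n_boot,
                                         seed = config$seed)
                  }),
           error = function(e) {
             structure(list(estimator = estimator, failed = TRUE,
                            reason = conditionMessage(e)),
                       class = "ltc_failed_cell")
           })
}

#' Run the full transfer-effect analysis pipeline
#'
#' Simulates (or reads) the cohort, applies eligibility per outcome, builds
#' the person-period datasets, computes incidence tables, and fits every
#' requested outcome-by-estimator cell, isolating failures per cell. The
#' result is deterministic given the configuration and seed.
#'
#' @param config an [analysis_config()].
#' @param verbose log row counts per stage to the console.
#' @return object of class `ltc_results`: `estimates` (nested list,
#'   outcome then estimator), `incidence`, `eligibility`, `baseline`,
#'   `diagnostics`, `provenance`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ltc_analysis_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  inputs <- .load_inputs(config)
  cohort <- inputs$cohort
  say("input: %d assessment rows, %d residents", nrow(cohort),
      length(unique(cohort$resident_id)))

  instrument <- NULL
  if ("iv" %in% config$estimators && !is.null(inputs$home_history)) {
    instrument <- compute_instrument(cohort, inputs$home_history)
  }

  estimates <- list()
  incidence <- list()
  eligibility <- NULL
  pp_list <- list()
  for (oc in config$outcomes) {
    el <- apply_eligibility(cohort, oc)
    eligibility <- el$report
    say("%s: %d residents eligible", oc,
        length(unique(el$table$resident_id)))
    pp <- build_person_periods(el$table, oc,
                               n_periods_max = config$n_periods_max)
    say("%s: %d person-periods, %d events", oc, nrow(pp), sum(pp$event))
    pp_list[[oc]] <- pp
    incidence[[oc]] <- tryCatch(cohort_incidence(pp, cohort = el$table),
                                error = function(e) NULL)
    ppz <- if (!is.null(instrument)) {
      suppressWarnings(attach_instrument(pp, instrument))
    } else NULL
    estimates[[oc]] <- lapply(stats::setNames(config$estimators,
                                              config$estimators),
                              .run_cell, pp = pp, ppz = ppz, config = config)
  }

  diagnostics <- NULL
  if (!is.null(instrument)) {
    diagnostics <- tryCatch(
      instrument_diagnostics(cohort, instrument, pp_list),
      error = function(e) NULL)
  }

  structure(list(estimates = estimates, incidence = incidence,
                 eligibility = eligibility,
                 baseline = baseline_table(cohort),
                 diagnostics = diagnostics,
                 provenance = list(
                   config_hash = .config_hash(unclass(config)),
                   seed = config$seed,
                   version = as.character(utils::packageVersion(
                     "ltctransfer")))),
            class = "ltc_results")
}

#' @export
print.ltc_results <- function(x, ...) {
  cat("LTC transfer-effect analysis\n")
  for (oc in names(x$estimates)) {
    cat(sprintf("  %s:\n", oc))
    for (es in names(x$estimates[[oc]])) {
      cell <- x$estimates[[oc]][[es]]
      if (inherits(cell, "ltc_failed_cell")) {
        cat(sprintf("    %-13s FAILED: %s\n", es, cell$reason))
      } else {
        cat(sprintf("    %-13s HR %6.3f (%.3f-%.3f)\n", es, cell$hr,
                    cell$ci_low, cell$ci_high))
      }
    }
  }
  invisible(x)
}

#' Forest-plot data from a results bundle
#'
#' @param bundle an `ltc_results`.
#' @return data.frame `outcome`, `estimator`, `hr`, `ci_low`, `ci_high`.
#' @export
forest_data <- function(bundle) {
  rows <- list()
  for (oc in names(bundle$estimates)) {
    for (es in names(bundle$estimates[[oc]])) {
      cell <- bundle$estimates[[oc]][[es]]
      if (inherits(cell, "ltc_failed_cell")) next
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, estimator = es, hr = cell$hr, ci_low = cell$ci_low,
        ci_high = cell$ci_high, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(outcome = character(0),
                                       estimator = character(0),
                                       hr = numeric(0), ci_low = numeric(0),
                                       ci_high = numeric(0)))
  do.call(rbind, rows)
}

#' @export
plot.ltc_results <- function(x, ...) {
  fd <- forest_data(x)
  if (nrow(fd) == 0L) .stopf("nothing to plot")
  fd$label <- paste(fd$outcome, fd$estimator, sep = " / ")
  n <- nrow(fd)
  old <- graphics::par(mar = c(4, 12, 2, 2))
  on.exit(graphics::par(old))
  xlim <- range(c(fd$ci_low, fd$ci_high, 1), na.rm = TRUE)
  plot(fd$hr, seq_len(n), log = "x", xlim = xlim, pch = 15,
       yaxt = "n", ylab = "", xlab = "Hazard ratio (log scale)",
       main = "Transfer-effect estimates", ...)
  graphics::segments(fd$ci_low, seq_len(n), fd$ci_high, seq_len(n))
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = seq_len(n), labels = fd$label, las = 1,
                 cex.axis = 0.7)
  invisible(fd)
}

#' Subgroup (stratified) analysis
#'
#' Re-runs the full estimator set inside strata defined at admission:
#' baseline physical function (ADL <= 2, 2 < ADL <= 4, ADL = 5), baseline
#' cognitive function (CPS <= 2, 2 < CPS <= 4, CPS = 5), or age (< 80,
#' 80-89, >= 90). Strata with fewer than 10 events for an outcome are
#' flagged and skipped, not fatal.
#'
#' @param config an [analysis_config()].
#' @param stratifier `"adl"`, `"cps"` or `"age"`.
#' @return named list of per-stratum `ltc_results` (or skip markers),
#'   class `ltc_subgroups`.
#' @export
subgroup_analysis <- function(config, stratifier = c("adl", "cps", "age")) {
  stratifier <- match.arg(stratifier)
  inputs <- .load_inputs(config)
  cohort <- inputs$cohort
  base <- cohort[cohort$period_index == 0L, ]
  strata <- switch(stratifier,
    adl = list("ADL<=2" = base$resident_id[base$adl_hierarchy <= 2],
               "2<ADL<=4" = base$resident_id[base$adl_hierarchy > 2 &
                                               base$adl_hierarchy <= 4],
               "ADL=5" = base$resident_id[base$adl_hierarchy == 5]),
    cps = list("CPS<=2" = base$resident_id[base$cps <= 2],
               "2<CPS<=4" = base$resident_id[base$cps > 2 & base$cps <= 4],
               "CPS=5" = base$resident_id[base$cps == 5]),
    age = list("<80" = base$resident_id[base$age_at_admission < 80],
               "80-89" = base$resident_id[base$age_at_admission >= 80 &
                                            base$age_at_admission < 90],
               ">=90" = base$resident_id[base$age_at_admission >= 90]))

  out <- lapply(names(strata), function(nm) {
    ids <- strata[[nm]]
    if (length(ids) == 0L) {
      return(structure(list(stratum = nm, skipped = TRUE,
                            reason = "empty stratum"),
                       class = "ltc_skipped_stratum"))
    }
    sub <- cohort[cohort$resident_id %in% ids, , drop = FALSE]
    ## require 10+ events of each requested outcome before fitting
    enough <- vapply(config$outcomes, function(oc) {
      el <- apply_eligibility(sub, oc)
      pp <- build_person_periods(el$table, oc,
                                 n_periods_max = config$n_periods_max)
      sum(pp$event) >= 10
    }, logical(1))
    if (!all(enough)) {
      return(structure(list(stratum = nm, skipped = TRUE,
                            reason = sprintf("fewer than 10 events (%s)",
                                             paste(config$outcomes[!enough],
                                                   collapse = ", "))),
                       class = "ltc_skipped_stratum"))
    }
    cfg <- config
    cfg$sim <- NULL
    cfg$cohort_path <- NULL
    res <- run_pipeline_on(sub, inputs$home_history, cfg)
    res$stratum <- nm
    res
  })
  names(out) <- names(strata)
  class(out) <- "ltc_subgroups"
  out
}

## run the estimator grid on an in-memory cohort (used by subgroups)
run_pipeline_on <- function(cohort, home_history, config) {
  tmp_cfg <- config
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_cohort(cohort, f)
  tmp_cfg$cohort_path <- f
  tmp_cfg$sim <- NULL
  if (!is.null(home_history)) {
    fh <- tempfile(fileext = ".csv")
    on.exit(unlink(fh), add = TRUE)
    utils::write.csv(home_history, fh, row.names = FALSE)
    tmp_cfg$home_history_path <- fh
  }
  run_pipeline(tmp_cfg)
}

#' @export
print.ltc_subgroups <- function(x, ...) {
  for (nm in names(x)) {
    if (inherits(x[[nm]], "ltc_skipped_stratum")) {
      cat(sprintf("stratum %s: skipped (%s)\n", nm, x[[nm]]$reason))
    } else {
      cat(sprintf("stratum %s:\n", nm))
      print(x[[nm]])
    }
  }
  invisible(x)
}

.write_with_header <- function(df, path, provenance) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# ltctransfer config_hash=%s seed=%d version=%s",
                     provenance$config_hash, provenance$seed,
                     provenance$version), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

#' Write the table-shaped outputs of a results bundle
#'
#' Emits `table1.csv` (baseline characteristics with SMDs), `table2.csv`
#' (incidence by transfer status with IRRs), `table3.csv` (hazard-ratio
#' estimates per outcome and estimator) and `forest.csv` (forest-plot data).
#' Every file carries a provenance header comment with the configuration
#' hash and seed; re-running with the same configuration reproduces the
#' files byte for byte.
#'
#' @param bundle an `ltc_results`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
emit_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- bundle$provenance
  paths <- character(0)

  p1 <- file.path(dir, "table1.csv")
  .write_with_header(bundle$baseline, p1, pv)
  paths <- c(paths, p1)

  t2 <- do.call(rbind, lapply(names(bundle$incidence), function(oc) {
    it <- bundle$incidence[[oc]]
    if (is.null(it)) return(NULL)
    data.frame(outcome = oc,
               ever_rate = it$ever$rate_per_100py,
               ever_ci_low = it$ever$ci_low, ever_ci_high = it$ever$ci_high,
               never_rate = it$never$rate_per_100py,
               never_ci_low = it$never$ci_low,
               never_ci_high = it$never$ci_high,
               irr = it$irr$ratio, irr_ci_low = it$irr$ci_low,
               irr_ci_high = it$irr$ci_high, stringsAsFactors = FALSE)
  }))
  p2 <- file.path(dir, "table2.csv")
  .write_with_header(t2, p2, pv)
  paths <- c(paths, p2)

  fd <- forest_data(bundle)
  p3 <- file.path(dir, "table3.csv")
  .write_with_header(fd, p3, pv)
  p4 <- file.path(dir, "forest.csv")
  .write_with_header(fd, p4, pv)
  paths <- c(paths, p3, p4)
  invisible(paths)
}
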