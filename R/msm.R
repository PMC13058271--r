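## default covariate sets for the weight and outcome models; the denominator
## conditions on the full time-varying confounder list, the numerator only on
## baseline terms (plus the follow-up clock and exposure history in both)
.tv_confounders <- c("adl_hierarchy", "cps", "chess", "weight_change_flag",
                     "fell_30d")
.baseline_covs <- c("age10", "sex", "comorbidity_burden", "baseline_adl",
                    "baseline_cps", "baseline_chess")
.history_terms <- c("prev_exposed", "cum_prev")
.clock_terms <- c("period", "period2")

#' Specification of the stabilized-weight models
#'
#' @param denominator covariates of the denominator (fully
#'   confounder-conditional) pooled logistic treatment model.
#' @param numerator covariates of the numerator (baseline-conditional) model;
#'   must not contain time-varying confounders beyond the clock and exposure
#'   history, or the weights lose their stabilizing interpretation.
#' @param cens_denominator,cens_numerator analogous covariate sets for the
#'   discharge-censoring models.
#' @param truncation percentiles `c(lo, hi)` in (0, 1) at which the
#'   cumulative stabilized weight is truncated, or `NULL` for none
#'   (default `c(0.01, 0.99)`).
#' @param clip probabilities are clipped to `[clip, 1 - clip]` before ratio
#'   formation.
#' @return object of class `weight_model_spec`.
#' @export
weight_model_spec <- function(denominator = c(.clock_terms, .history_terms,
                                              .baseline_covs,
                                              .tv_confounders),
                              numerator = c(.clock_terms, .history_terms,
                                            .baseline_covs),
                              cens_denominator = denominator,
                              cens_numerator = numerator,
                              truncation = c(0.01, 0.99),
                              clip = 1e-6) {
  if (!is.null(truncation)) {
    if (length(truncation) != 2 || any(truncation <= 0) ||
        any(truncation >= 1) || truncation[1] >= truncation[2]) {
      .stopf("truncation must be increasing percentiles inside (0, 1)")
    }
  }
  if (clip <= 0 || clip >= 0.5) .stopf("clip must lie in (0, 0.5)")
  structure(list(denominator = denominator, numerator = numerator,
                 cens_denominator = cens_denominator,
                 cens_numerator = cens_numerator,
                 truncation = truncation, clip = clip),
            class = "weight_model_spec")
}

.pooled_logit <- function(pp, response, covs, label) {
  f <- stats::as.formula(paste(response, "~",
                               paste(covs, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = pp, family = stats::binomial()))
  if (!fit$converged) .stopf("weight model '%s' did not converge", label)
  fit
}

#' Fit the sequential treatment and censoring probability models
#'
#' Pooled logistic regressions over person-periods: the denominator treatment
#' model conditions on the time-varying confounders and exposure history, the
#' numerator on baseline covariates and exposure history only; an analogous
#' pair models discharge censoring. Predicted probabilities of the
#' *observed* exposure (`p` if transferred, `1 - p` otherwise) and of
#' remaining uncensored are attached per row and clipped away from {0, 1}.
#'
#' @param pp person-period table from [build_person_periods()].
#' @param spec a [weight_model_spec()].
#' @return `pp` with columns `p_num_treat`, `p_den_treat`, `p_num_cens`,
#'   `p_den_cens`; the fitted models are attached as attribute
#'   `weight_models`.
#' @export
fit_treatment_models <- function(pp, spec = weight_model_spec()) {
  stopifnot(inherits(spec, "weight_model_spec"))
  if (!all(pp$exposed %in% c(0L, 1L))) .stopf("exposure must be binary")
  pp$period2 <- pp$period^2
  covs_all <- unique(c(spec$denominator, spec$numerator,
                       spec$cens_denominator, spec$cens_numerator))
  miss <- setdiff(covs_all, names(pp))
  if (length(miss)) .stopf("missing covariate column(s): %s",
                           paste(miss, collapse = ", "))
  if (anyNA(pp[, covs_all])) .stopf("covariates must be complete")

  m_den <- .pooled_logit(pp, "exposed", spec$denominator,
                         "treatment denominator")
  m_num <- .pooled_logit(pp, "exposed", spec$numerator,
                         "treatment numerator")
  any_cens <- sum(pp$cens) > 0
  if (any_cens) {
    c_den <- .pooled_logit(pp, "cens", spec$cens_denominator,
                           "censoring denominator")
    c_num <- .pooled_logit(pp, "cens", spec$cens_numerator,
                           "censoring numerator")
  }

  clip <- spec$clip
  obs_prob <- function(p) .clamp(ifelse(pp$exposed == 1, p, 1 - p),
                                 clip, 1 - clip)
  pp$p_den_treat <- obs_prob(stats::predict(m_den, type = "response"))
  pp$p_num_treat <- obs_prob(stats::predict(m_num, type = "response"))
  if (any_cens) {
    ## probability of remaining uncensored through the current period
    pp$p_den_cens <- .clamp(1 - stats::predict(c_den, type = "response"),
                            clip, 1 - clip)
    pp$p_num_cens <- .clamp(1 - stats::predict(c_num, type = "response"),
                            clip, 1 - clip)
  } else {
    pp$p_den_cens <- 1
    pp$p_num_cens <- 1
  }
  degenerate <- pp$p_den_treat <= clip | pp$p_den_treat >= 1 - clip
  if (mean(degenerate) > 0.05) {
    .stopf("more than 5%% of treatment probabilities are degenerate after clipping")
  }
  attr(pp, "weight_models") <- list(
    treatment_denominator = m_den, treatment_numerator = m_num,
    censoring = any_cens, spec = spec)
  pp
}

#' Compute cumulative stabilized weights
#'
#' Per-period stabilized weight
#' `sw = (p_num_treat / p_den_treat) * (p_num_cens / p_den_cens)` using the
#' probability of the observed exposure and of remaining uncensored, carried
#' forward as a running product within resident (`sw_cum`) so the weight at
#' period k reflects the entire exposure, confounder and censoring history.
#' Optional truncation caps `sw_cum` at configured percentiles of its
#' distribution.
#'
#' @param pp output of [fit_treatment_models()].
#' @param truncation percentiles `c(lo, hi)` or `NULL`; defaults to the
#'   spec used when fitting the models.
#' @return `pp` with columns `sw_period`, `sw_cum`, `truncated`.
#' @export
compute_stabilized_weights <- function(pp, truncation = NULL) {
  need <- c("p_num_treat", "p_den_treat", "p_num_cens", "p_den_cens")
  miss <- setdiff(need, names(pp))
  if (length(miss)) .stopf("run fit_treatment_models() first (missing %s)",
                           paste(miss, collapse = ", "))
  probs <- as.matrix(pp[, need])
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs > 1)) {
    .stopf("all probabilities must lie in (0, 1]")
  }
  if (is.null(truncation)) {
    wm <- attr(pp, "weight_models")
    truncation <- if (!is.null(wm)) wm$spec$truncation else NULL
  }
  pp$sw_period <- (pp$p_num_treat / pp$p_den_treat) *
    (pp$p_num_cens / pp$p_den_cens)
  pp$sw_cum <- stats::ave(pp$sw_period, pp$resident_id, FUN = cumprod)
  pp$truncated <- FALSE
  if (!is.null(truncation)) {
    bounds <- stats::quantile(pp$sw_cum, truncation, names = FALSE)
    pp$truncated <- pp$sw_cum < bounds[1] | pp$sw_cum > bounds[2]
    pp$sw_cum <- .clamp(pp$sw_cum, bounds[1], bounds[2])
    attr(pp, "truncation_bounds") <- bounds
  }
  pp
}

#' Per-period weight diagnostics
#'
#' @param pp table with `sw_cum` from [compute_stabilized_weights()].
#' @return data.frame with mean, SD, min and max of the cumulative
#'   stabilized weight at each period.
#' @export
weight_diagnostics <- function(pp) {
  if (!"sw_cum" %in% names(pp)) .stopf("no sw_cum column")
  out <- do.call(rbind, lapply(split(pp$sw_cum, pp$period), function(w) {
    data.frame(n = length(w), mean = mean(w), sd = stats::sd(w),
               min = min(w), max = max(w))
  }))
  out$period <- as.integer(rownames(out))
  rownames(out) <- NULL
  out[, c("period", "n", "mean", "sd", "min", "max")]
}

#' Marginal structural Cox model for the transfer effect
#'
#' Weighted cause-specific extended Cox model: the person-periods are
#' weighted by the cumulative stabilized weight and the model contains the
#' exposure plus baseline covariates only (the numerator set), with the
#' cluster-robust sandwich variance at the home level.
#'
#' @param pp person-period table carrying `sw_cum` (see
#'   [compute_stabilized_weights()]); if the weight columns are absent the
#'   full weight pipeline is run with `spec`.
#' @param spec a [weight_model_spec()] used when weights must be computed.
#' @param conf_level confidence level.
#' @return an [hazard_estimate()] of class `ltc_hazard` (estimator `"msm"`).
#' @export
fit_msm <- function(pp, spec = weight_model_spec(), conf_level = 0.95) {
  if (!"sw_cum" %in% names(pp)) {
    pp <- compute_stabilized_weights(fit_treatment_models(pp, spec))
  }
  cs <- cox_spec(c("exposed", .baseline_covs), weight_col = "sw_cum",
                 cluster_col = "home_id")
  fit <- fit_cox(pp, cs)
  est <- .hazard_from_cox(fit, "msm", attr(pp, "outcome") %||% "outcome",
                          conf_level = conf_level)
  est$details$weight_diagnostics <- weight_diagnostics(pp)
  est
}

#' Covariate-adjusted extended Cox model
#'
#' Adjusts directly for the time-varying confounders (unweighted), with the
#' cluster-robust sandwich at the home level.
#'
#' @param pp person-period table.
#' @param conf_level confidence level.
#' @return `ltc_hazard` (estimator `"extended_cox"`).
#' @export
fit_extended_cox <- function(pp, conf_level = 0.95) {
  cs <- cox_spec(c("exposed", "age10", "sex", "comorbidity_burden",
                   .tv_confounders), cluster_col = "home_id")
  fit <- fit_cox(pp, cs)
  .hazard_from_cox(fit, "extended_cox", attr(pp, "outcome") %||% "outcome",
                   conf_level = conf_level)
}

#' Crude (exposure-only) Cox model
#'
#' @param pp person-period table.
#' @param conf_level confidence level.
#' @return `ltc_hazard` (estimator `"crude"`).
#' @export
fit_crude_cox <- function(pp, conf_level = 0.95) {
  cs <- cox_spec("exposed", cluster_col = "home_id")
  fit <- fit_cox(pp, cs)
  .hazard_from_cox(fit, "crude", attr(pp, "outcome") %||% "outcome",
                   conf_level = conf_level)
}
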