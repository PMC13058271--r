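#' Specification for a counting-process Cox fit
#'
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default; better under the heavy ties a 92-day grid
#'   produces) or `"breslow"`.
#' @param weight_col optional column of positive observation weights.
#' @param cluster_col optional column defining clusters (e.g. `home_id`) for
#'   the robust sandwich variance.
#' @param tolerance convergence tolerance passed to the optimiser.
#' @param max_iterations Newton iteration cap.
#' @return object of class `cox_spec`.
#' @export
cox_spec <- function(covariates, ties = c("efron", "breslow"),
                     weight_col = NULL, cluster_col = NULL,
                     tolerance = 1e-9, max_iterations = 50) {
  ties <- match.arg(ties)
  if (length(covariates) == 0L) .stopf("at least one covariate is required")
  if (!is.numeric(tolerance) || tolerance <= 0) {
    .stopf("tolerance must be positive")
  }
  structure(list(covariates = covariates, ties = ties,
                 weight_col = weight_col, cluster_col = cluster_col,
                 tolerance = tolerance, max_iterations = max_iterations),
            class = "cox_spec")
}

#' Fit a weighted counting-process Cox model
#'
#' Maximises the (weighted) Cox partial likelihood on `(start, stop, event)`
#' rows with time-varying covariates, via [survival::coxph()]. With a cluster
#' column the sandwich (robust) variance is computed at that level — with the
#' CR1 small-sample factor G/(G-1) and t(G-1) critical values for intervals,
#' since home counts are often modest — and drives the confidence intervals;
#' otherwise the model-based variance is used.
#' Coefficients with `|beta| > 10` are flagged as probable complete
#' separation. Non-convergence returns the fit with `converged = FALSE` and
#' a warning rather than an error.
#'
#' @param pp person-period table (needs `start`, `stop` and an event column).
#' @param spec a [cox_spec()].
#' @param event_col event indicator column (default `"event"`).
#' @return object of class `ltc_cox` with elements `coefficients`,
#'   `model_se`, `robust_se`, `loglik`, `n_events`, `converged`,
#'   `n_iterations`, and the underlying `survival::coxph` fit in `$fit`.
#' @export
fit_cox <- function(pp, spec, event_col = "event") {
  stopifnot(inherits(spec, "cox_spec"))
  need <- c("start", "stop", event_col, spec$covariates,
            spec$weight_col, spec$cluster_col)
  miss <- setdiff(need, names(pp))
  if (length(miss)) .stopf("person-period table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  ev <- pp[[event_col]]
  if (sum(ev) < 1) .stopf("no events: cannot fit a Cox model")
  covs <- pp[, spec$covariates, drop = FALSE]
  if (anyNA(covs)) .stopf("missing values in covariates")
  w <- if (is.null(spec$weight_col)) rep(1, nrow(pp)) else pp[[spec$weight_col]]
  if (anyNA(w) || any(w <= 0)) .stopf("weights must be positive and complete")

  dat <- cbind(data.frame(.start = pp$start, .stop = pp$stop, .event = ev,
                          .w = w), covs)
  f <- stats::as.formula(paste("survival::Surv(.start, .stop, .event) ~",
                               paste(spec$covariates, collapse = " + ")))
  cl <- if (!is.null(spec$cluster_col)) pp[[spec$cluster_col]] else NULL

  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(f, data = dat, weights = .w, ties = spec$ties,
                    cluster = cl, robust = !is.null(cl),
                    control = survival::coxph.control(
                      eps = spec$tolerance, iter.max = spec$max_iterations),
                    model = FALSE, x = FALSE),
    warning = function(w_) {
      msg <- conditionMessage(w_)
      if (grepl("Ran out of iterations|did not converge", msg)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })

  beta <- stats::coef(fit)
  model_se <- sqrt(diag(fit$naive.var %||% fit$var))
  n_clusters <- if (!is.null(cl)) length(unique(cl)) else NA_integer_
  ## CR1 small-sample correction G/(G-1) on the sandwich
  robust_se <- if (!is.null(cl)) {
    sqrt(diag(fit$var)) * sqrt(n_clusters / (n_clusters - 1))
  } else rep(NA_real_, length(beta))
  names(model_se) <- names(beta)
  names(robust_se) <- names(beta)
  separated <- abs(beta) > 10
  if (any(separated)) {
    .warnf("possible complete separation: |beta| > 10 for %s",
           paste(names(beta)[separated], collapse = ", "))
  }
  if (!converged) .warnf("Cox fit did not converge in %d iterations",
                         spec$max_iterations)
  structure(list(coefficients = beta, model_se = model_se,
                 robust_se = robust_se, loglik = fit$loglik[2],
                 n_events = sum(ev), converged = converged,
                 n_iterations = fit$iter, separated = separated,
                 spec = spec, fit = fit,
                 cluster = cl, n_clusters = n_clusters),
            class = "ltc_cox")
}

#' @export
coef.ltc_cox <- function(object, ...) object$coefficients

#' @export
print.ltc_cox <- function(x, ...) {
  se <- if (all(is.na(x$robust_se))) x$model_se else x$robust_se
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$model_se, robust_se = x$robust_se,
                    z = x$coefficients / se, check.names = FALSE)
  cat(sprintf("Counting-process Cox fit (%s ties), %d events, loglik %.3f%s\n",
              x$spec$ties, x$n_events, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(tab, 4))
  invisible(x)
}

## critical value: normal, or t(G-1) when a cluster structure is present
.crit <- function(fit, level) {
  a <- 1 - (1 - level) / 2
  if (!is.null(fit$n_clusters) && !is.na(fit$n_clusters)) {
    stats::qt(a, df = fit$n_clusters - 1)
  } else {
    stats::qnorm(a)
  }
}

#' @export
confint.ltc_cox <- function(object, parm, level = 0.95, ...) {
  se <- if (all(is.na(object$robust_se))) object$model_se else object$robust_se
  z <- .crit(object, level)
  out <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Cluster-robust sandwich standard errors for a Cox fit
#'
#' Computes `A^{-1} B A^{-1}` where `A` is the observed information and `B`
#' sums, over clusters, the outer products of cluster-summed score residuals;
#' equivalently, the cross-product of dfbeta residuals collapsed by cluster,
#' scaled by the CR1 factor G/(G-1). With every row its own cluster this
#' reduces to the standard (Lin-Wei) sandwich.
#'
#' @param fit an `ltc_cox` object.
#' @param cluster vector of cluster labels, one per person-period row of the
#'   original fit.
#' @return named vector of robust standard errors.
#' @export
robust_sandwich <- function(fit, cluster) {
  stopifnot(inherits(fit, "ltc_cox"))
  if (!fit$converged) .stopf("fit did not converge; sandwich not computed")
  if (length(unique(cluster)) < 2) {
    .stopf("fewer than 2 clusters: robust variance undefined")
  }
  D <- stats::residuals(fit$fit, type = "dfbeta", collapse = cluster,
                        weighted = TRUE)
  D <- as.matrix(D)
  g <- length(unique(cluster))
  V <- crossprod(D) * g / (g - 1)
  out <- sqrt(diag(V))
  names(out) <- names(fit$coefficients)
  out
}

#' Hazard-ratio estimate with its provenance
#'
#' Common container returned by every estimator in the package (crude Cox,
#' covariate-adjusted extended Cox, marginal structural model, instrumental
#' variable), so results can be printed, compared and forest-plotted
#' uniformly.
#'
#' @param estimator label: `"crude"`, `"extended_cox"`, `"msm"` or `"iv"`.
#' @param outcome outcome label.
#' @param log_hr exposure log hazard ratio.
#' @param se model-based standard error.
#' @param robust_se cluster-robust standard error (may be `NA`).
#' @param ci_low,ci_high confidence limits on the hazard-ratio scale.
#' @param conf_level confidence level of `ci_low`/`ci_high`.
#' @param n_events number of events used.
#' @param details list of estimator-specific extras.
#' @return object of class `ltc_hazard`.
#' @export
hazard_estimate <- function(estimator, outcome, log_hr, se,
                            robust_se = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, conf_level = 0.95,
                            n_events = NA_integer_, details = list()) {
  structure(list(estimator = estimator, outcome = outcome, log_hr = log_hr,
                 se = se, robust_se = robust_se, hr = exp(log_hr),
                 ci_low = ci_low, ci_high = ci_high,
                 conf_level = conf_level, n_events = n_events,
                 details = details),
            class = "ltc_hazard")
}

## build an ltc_hazard from an ltc_cox fit's exposure coefficient
.hazard_from_cox <- function(fit, estimator, outcome, term = "exposed",
                             conf_level = 0.95) {
  b <- fit$coefficients[[term]]
  se_use <- if (is.na(fit$robust_se[[term]])) fit$model_se[[term]] else
    fit$robust_se[[term]]
  z <- .crit(fit, conf_level)
  hazard_estimate(estimator, outcome, b, fit$model_se[[term]],
                  fit$robust_se[[term]],
                  exp(b - z * se_use), exp(b + z * se_use), conf_level,
                  fit$n_events, details = list(fit = fit))
}

#' @export
print.ltc_hazard <- function(x, ...) {
  cat(sprintf("%s [%s]: HR %.3f (%d%% CI %.3f-%.3f), log-HR %.4f, %s events\n",
              x$estimator, x$outcome, x$hr, round(100 * x$conf_level),
              x$ci_low, x$ci_high, x$log_hr,
              ifelse(is.na(x$n_events), "?", as.character(x$n_events))))
  invisible(x)
}

#' @export
coef.ltc_hazard <- function(object, ...) c(log_hr = object$log_hr)

#' @export
confint.ltc_hazard <- function(object, parm, level, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("hr", c("lower", "upper")))
}

#' @export
summary.ltc_hazard <- function(object, ...) {
  out <- data.frame(estimator = object$estimator, outcome = object$outcome,
                    hr = object$hr, ci_low = object$ci_low,
                    ci_high = object$ci_high, log_hr = object$log_hr,
                    se = object$se, robust_se = object$robust_se,
                    n_events = object$n_events, stringsAsFactors = FALSE)
  class(out) <- c("summary.ltc_hazard", "data.frame")
  out
}
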