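## shared fixtures and independent oracles

## one handcrafted assessment row with sensible defaults
mk_row <- function(id, period, home = "H1", age = 80, sex = 1, adl = 3,
                   cps = 2, chess = 1, comorb = 2, wt = 0, fell = 0,
                   transfer = 0, died = 0, disch = 0) {
  data.frame(resident_id = id, home_id = home, period_index = period,
             age_at_admission = age, sex = sex, adl_hierarchy = adl,
             cps = cps, chess = chess, comorbidity_burden = comorb,
             weight_change_flag = wt, fell_30d = fell, transfer = transfer,
             died_in_period = died, discharged_in_period = disch,
             stringsAsFactors = FALSE)
}

mk_cohort <- function(...) do.call(rbind, list(...))

## a resident followed to administrative censoring with no events
mk_quiet_resident <- function(id, n_periods = 20, ...) {
  do.call(rbind, lapply(seq_len(n_periods) - 1L,
                        function(k) mk_row(id, k, ...)))
}

## independent day-by-day oracle for person-period construction: walks each
## resident's assessment rows one period at a time and applies the windowing,
## permanence, competing-risk and censoring rules literally
oracle_person_periods <- function(cohort, outcome) {
  out <- list()
  for (id in unique(cohort$resident_id)) {
    rows <- cohort[cohort$resident_id == id, ]
    rows <- rows[order(rows$period_index), ]
    K <- nrow(rows) - 1L
    died <- which(rows$died_in_period == 1)
    d <- if (length(died)) rows$period_index[min(died)] else NA
    disc <- which(rows$discharged_in_period == 1)
    s <- if (length(disc)) rows$period_index[min(disc)] else NA
    onset <- NA
    if (outcome != "mortality") {
      v <- if (outcome == "physical") rows$adl_hierarchy else rows$cps
      thr <- if (outcome == "physical") 6 else 5
      # first crossing never followed by an observed improvement
      for (i in seq_along(v)) {
        if (v[i] >= thr && all(v[i:length(v)] >= thr)) {
          onset <- rows$period_index[i]
          break
        }
      }
    }
    cand <- c(onset = ifelse(is.na(onset), Inf, onset),
              death = ifelse(is.na(d), Inf, d))
    if (any(is.finite(cand))) {
      w <- min(cand)
      code <- if (cand["onset"] <= cand["death"]) {
        switch(outcome, physical = "physical_impairment",
               cognitive = "cognitive_impairment", mortality = "death")
      } else "death"
      if (outcome == "mortality") code <- "death"
      n_rows <- w
    } else if (!is.na(s)) {
      n_rows <- s + 1
      code <- "censored"
    } else {
      n_rows <- K + 1
      code <- "censored"
    }
    if (n_rows > 0) {
      out[[id]] <- data.frame(resident_id = id, n_rows = n_rows,
                              terminal = code,
                              exposure = paste(rows$transfer[seq_len(n_rows)],
                                               collapse = ""),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, unname(out))
}

## brute-force Cox partial likelihood (counting process, no ties, one
## covariate); independent of the fitting path
oracle_partial_loglik <- function(beta, start, stop, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    t_i <- stop[i]
    risk <- which(start < t_i & stop >= t_i)
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

## summarise a pp table per resident for oracle comparison
pp_signature <- function(pp) {
  sig <- do.call(rbind, lapply(split(pp, pp$resident_id), function(d) {
    d <- d[order(d$period_index), ]
    data.frame(resident_id = d$resident_id[1], n_rows = nrow(d),
               terminal = d$event_code[nrow(d)],
               exposure = paste(d$exposed, collapse = ""),
               stringsAsFactors = FALSE)
  }))
  sig[order(sig$resident_id), ]
}
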