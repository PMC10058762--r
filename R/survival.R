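## Person-year mortality rates and Cox proportional-hazards models.

#' Person-year mortality rates with Poisson confidence intervals
#'
#' For each group, the rate is `1000 * events / person_years`. The default
#' 95% CI uses the normal approximation on the log rate,
#' `exp(log r +/- 1.96 / sqrt(events))`; with `exact = TRUE` (recommended
#' when events < 10) the Garwood chi-square interval for a Poisson count is
#' used instead. Groups with zero events get rate 0 with a one-sided upper
#' bound and are flagged.
#'
#' @param records data frame with columns `followup_years` (> 0) and
#'   `event` (0/1), plus the grouping column.
#' @param group_by name of the grouping column (default `"class"`); use
#'   `NULL` for a single overall rate.
#' @param level confidence level (default 0.95).
#' @param exact logical; use the exact Poisson (Garwood) interval.
#' @return data frame `group, n_events, person_years, rate, lo, hi, flag`.
#' @export
person_year_rates <- function(records, group_by = "class", level = 0.95,
                              exact = FALSE) {
  stopifnot(all(c("followup_years", "event") %in% names(records)))
  if (any(records$followup_years <= 0))
    stop("all follow-up times must be positive")
  if (!all(records$event %in% c(0, 1)))
    stop("'event' must be a 0/1 indicator")
  grp <- if (is.null(group_by)) rep("all", nrow(records)) else
    records[[group_by]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- do.call(rbind, lapply(split(records, grp), function(d) {
    ev <- sum(d$event); py <- sum(d$followup_years)
    if (py <= 0) stop("zero person-years in group ", unique(grp))
    rate <- 1000 * ev / py
    if (ev == 0) {
      ## one-sided upper bound from the exact Poisson relation
      hi <- 1000 * stats::qgamma(level, 1) / py
      data.frame(n_events = ev, person_years = py, rate = 0,
                 lo = 0, hi = hi, flag = "zero events")
    } else if (exact) {
      lo <- 1000 * stats::qchisq((1 - level) / 2, 2 * ev) / (2 * py)
      hi <- 1000 * stats::qchisq(1 - (1 - level) / 2, 2 * (ev + 1)) / (2 * py)
      data.frame(n_events = ev, person_years = py, rate = rate,
                 lo = lo, hi = hi, flag = "")
    } else {
      se <- 1 / sqrt(ev)
      data.frame(n_events = ev, person_years = py, rate = rate,
                 lo = rate * exp(-z * se), hi = rate * exp(z * se),
                 flag = if (ev < 10) "few events" else "")
    }
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper around [survival::coxph()] on time-on-study
#' (`followup_years`, `event`), returning coefficients, hazard ratios and
#' Wald confidence intervals in a tidy table. Efron tie handling is the
#' default.
#'
#' @param records data frame with `followup_years`, `event` and the
#'   covariate columns.
#' @param covariates character vector of covariate column names (terms are
#'   used verbatim, so factors expand as usual).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param level confidence level for the Wald intervals.
#' @return object of class `cox_fit`: list with `table` (term, coef, se,
#'   HR, lo, hi, p), `loglik` (partial log-likelihood at the solution),
#'   `loglik_null`, `n`, `n_events`, `ties`, and the underlying `model`.
#' @export
fit_cox <- function(records, covariates, ties = c("efron", "breslow"),
                    level = 0.95) {
  ties <- match.arg(ties)
  miss <- setdiff(c("followup_years", "event", covariates), names(records))
  if (length(miss))
    stop("survival records are missing column(s): ", paste(miss, collapse = ", "))
  if (sum(records$event) < 1) stop("need at least one event")
  fml <- stats::as.formula(paste(
    "survival::Surv(followup_years, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = ties)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear or inestimable covariate term(s): ",
         paste(bad, collapse = ", "))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(term = names(co), coef = unname(co), se = unname(se),
                    HR = exp(unname(co)),
                    lo = exp(unname(co) - z * se), hi = exp(unname(co) + z * se),
                    p = 2 * stats::pnorm(-abs(unname(co) / se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[2L],
                 loglik_null = fit$loglik[1L], n = fit$n,
                 n_events = fit$nevent, ties = ties, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): ", x$n,
      " records, ", x$n_events, " events\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

## covariate blocks of the sequentially adjusted model ladder
cox_model_blocks <- function() {
  list(
    "Model 1" = character(0),
    "Model 2" = c("age_entry", "sex", "region"),
    "Model 3" = c("chronic_disease", "medicine", "smoker",
                  "physical_activity", "energy_kcal", "bmi"),
    "Model 4" = c("drinker", "income", "education"))
}

#' Sequentially adjusted Cox models for trajectory classes
#'
#' Fits the four-model ladder relating trajectory class (class 1 =
#' reference) to all-cause mortality: Model 1 unadjusted; Model 2 adds age
#' at entry, sex and region; Model 3 adds chronic disease history, medicine
#' use, current smoking, physical activity, energy intake and BMI; Model 4
#' adds current drinking, income and education. Covariate blocks accumulate.
#'
#' @param records data frame with `followup_years`, `event`, `class`, and
#'   the ladder covariates (`age_entry`, `sex`, `region`,
#'   `chronic_disease`, `medicine`, `smoker`, `physical_activity`,
#'   `energy_kcal`, `bmi`, `drinker`, `income`, `education`).
#' @param ties passed to [fit_cox()].
#' @return list with `table`: data frame of one row per model per non-
#'   reference class (model, class, HR, lo, hi, p) and `fits`: the four
#'   `cox_fit` objects.
#' @export
sequential_models <- function(records, ties = "efron") {
  blocks <- cox_model_blocks()
  needed <- unique(unlist(blocks))
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    req <- vapply(names(blocks), function(m) paste(
      unlist(blocks[seq_len(match(m, names(blocks)))]), collapse = ", "),
      "")
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         ". Cumulative requirements: ",
         paste(names(blocks), "=", ifelse(req == "", "(none)", req),
               collapse = "; "))
  }
  records$class <- factor(records$class)
  fits <- list(); rows <- list()
  for (k in seq_along(blocks)) {
    covs <- c("class", unlist(blocks[seq_len(k)], use.names = FALSE))
    f <- fit_cox(records, covs, ties = ties)
    fits[[names(blocks)[k]]] <- f
    cl <- f$table[grepl("^class", f$table$term), , drop = FALSE]
    rows[[k]] <- data.frame(model = names(blocks)[k],
                            class = sub("^class", "", cl$term),
                            HR = cl$HR, lo = cl$lo, hi = cl$hi, p = cl$p,
                            stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), fits = fits)
}
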