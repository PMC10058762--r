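## Synthetic longitudinal dietary cohort with known ground truth.
##
## The generator emulates a CHNS-like analysis sample: middle-aged entry
## cohort, 4 dietary survey rounds at 2-3 year spacing, three latent
## trajectory classes of the non-adherence score, exponential death times
## with class-specific rates, loss to follow-up, and administrative
## censoring at the study end. Intake vectors are constructed so that
## re-scoring them against the guideline reproduces the intended score
## exactly (round-trip identity).

#' Configuration of a synthetic cohort
#'
#' Defaults describe the study conditions the package is calibrated to:
#' 4533 subjects entering at ages 30-60 (mean 43.3, SD 8.3), surveyed in
#' 2004/2006/2009/2011 with mortality follow-up to 2015; three latent
#' classes with proportions 378/3522/633, mean scores 3.3/4.8/5.9 at the
#' mean entry age, age slopes -0.020/0/+0.008 per year, and all-cause
#' mortality rates 11.8/28.8/44.5 per 1000 person-years. The within-class
#' score variance is split into a between-subject SD of 0.65 and a
#' round-to-round residual SD of 0.62, giving the observable within-class
#' SD of about 0.9 that the study conditions describe (intraclass
#' correlation about 0.5, typical of repeated short-term dietary
#' assessment). A loss-to-follow-up hazard of 0.072/year combines
#' with administrative censoring to give a median follow-up near 6.9
#' years. The `frac_*` fields plant rule violations for exercising the
#' eligibility filter and default to 0.
#'
#' @param n_subjects number of subjects.
#' @param survey_years ascending calendar years of the dietary rounds.
#' @param censor_year administrative end of mortality follow-up.
#' @param entry_age_mean,entry_age_sd,entry_age_range truncated-normal
#'   entry-age model.
#' @param class_prop class proportions (normalized internally).
#' @param class_mean mean score per class at the mean entry age.
#' @param class_slope score change per year of age, per class.
#' @param subject_sd between-subject SD of the random intercept.
#' @param residual_sd within-subject residual SD.
#' @param class_rate mortality rate per 1000 person-years, per class.
#' @param dropout_rate loss-to-follow-up hazard per year.
#' @param covariate_log_hr named numeric vector of log hazard ratios for
#'   survival-table covariates (e.g. `c(smoker = 0.7)`), applied on top of
#'   the class rate; default none, so class rates hold marginally.
#' @param frac_underage,frac_overage,frac_few_rounds,frac_low_energy,
#'   frac_high_energy,frac_missing_food,frac_missing_covariate,
#'   frac_cancer,frac_pregnant fractions of subjects planted with each
#'   eligibility violation (disjoint subject sets).
#' @param seed integer seed; every draw of [generate_cohort()] is a
#'   deterministic function of the config including this seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 4533L,
                          survey_years = c(2004L, 2006L, 2009L, 2011L),
                          censor_year = 2015L,
                          entry_age_mean = 43.3, entry_age_sd = 8.3,
                          entry_age_range = c(30, 60),
                          class_prop = c(378, 3522, 633) / 4533,
                          class_mean = c(3.3, 4.8, 5.9),
                          class_slope = c(-0.020, 0.000, 0.008),
                          subject_sd = 0.65, residual_sd = 0.62,
                          class_rate = c(11.8, 28.8, 44.5),
                          dropout_rate = 0.072,
                          covariate_log_hr = numeric(0),
                          frac_underage = 0, frac_overage = 0,
                          frac_few_rounds = 0, frac_low_energy = 0,
                          frac_high_energy = 0, frac_missing_food = 0,
                          frac_missing_covariate = 0, frac_cancer = 0,
                          frac_pregnant = 0, seed = 1L) {
  cfg <- as.list(environment())
  if (is.unsorted(cfg$survey_years, strictly = TRUE))
    stop("survey_years must be strictly ascending")
  if (any(cfg$class_prop <= 0)) stop("class proportions must be positive")
  cfg$class_prop <- cfg$class_prop / sum(cfg$class_prop)
  G <- length(cfg$class_prop)
  if (length(cfg$class_mean) != G || length(cfg$class_slope) != G ||
      length(cfg$class_rate) != G)
    stop("class_prop, class_mean, class_slope, class_rate must share length")
  if (any(cfg$class_rate <= 0)) stop("class rates must be positive")
  if (cfg$subject_sd <= 0 || cfg$residual_sd <= 0)
    stop("subject_sd and residual_sd must be positive")
  if (cfg$censor_year <= max(cfg$survey_years))
    stop("censor_year must fall after the last survey round")
  class(cfg) <- "cohort_config"
  cfg
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

## internal: find a nonnegative normalized intake at Euclidean distance
## `score` from the all-ones reference, near direction u, by alternating
## projection between the sphere and the nonnegative orthant.
invert_score <- function(score, u) {
  if (score <= 0) return(rep(1, length(u)))
  project <- function(u) {
    d <- u * score
    for (it in 1:100) {
      x <- pmax(1 + d, 0)
      dd <- x - 1
      len <- sqrt(sum(dd^2))
      if (len < 1e-14) { dd <- abs(u); len <- sqrt(sum(dd^2)) }
      d <- dd * (score / len)
      if (all(1 + d >= -1e-15)) break
    }
    pmax(1 + d, 0)
  }
  x <- project(u)
  ## a mostly-negative direction cannot reach a large score inside the
  ## orthant (each clipped coordinate contributes at most 1); flip the
  ## largest coordinates positive until the target is reachable
  ord <- order(abs(u), decreasing = TRUE)
  k <- 0L
  while (abs(sqrt(sum((x - 1)^2)) - score) > 1e-10 && k < length(u)) {
    k <- k + 1L
    u[ord[seq_len(k)]] <- abs(u[ord[seq_len(k)]])
    x <- project(u)
  }
  if (abs(sqrt(sum((x - 1)^2)) - score) > 1e-9)
    stop("could not invert score ", signif(score, 4),
         " to a nonnegative intake vector")
  x
}

#' Generate a synthetic longitudinal dietary cohort
#'
#' Draws latent classes, subject random intercepts and per-round scores
#' from the trajectory model in [cohort_config()], inverts each score into
#' a food-group intake vector consistent with `guideline` (so that
#' [score_panel()] recovers the intended score to machine precision),
#' draws class-linked baseline covariates, and simulates exponential death
#' times with loss to follow-up and administrative censoring.
#'
#' @param config a [cohort_config()].
#' @param guideline a [guideline_spec()]; default [default_guideline()].
#' @return list of class `dnas_cohort` with elements `panel` (long intake
#'   panel: `subject_id, round, age_years, energy_kcal, <groups>`),
#'   `survival` (one row per subject: follow-up, event, covariates,
#'   `baseline_dnas`), and `truth` (per-subject `class`, `intercept`,
#'   `death_time`, plus `scores`: the intended per-round score panel).
#' @export
generate_cohort <- function(config = cohort_config(),
                            guideline = default_guideline()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  N <- cfg$n_subjects
  G <- length(cfg$class_prop)
  R <- length(cfg$survey_years)
  ngrp <- nrow(guideline)
  ids <- sprintf("S%05d", seq_len(N))

  cls <- sample.int(G, N, replace = TRUE, prob = cfg$class_prop)
  age0 <- rtruncnorm1(N, cfg$entry_age_mean, cfg$entry_age_sd,
                      cfg$entry_age_range[1L], cfg$entry_age_range[2L])
  b <- stats::rnorm(N, 0, cfg$subject_sd)

  ## eligibility-violation fixtures on disjoint subject sets
  fr <- c(underage = cfg$frac_underage, overage = cfg$frac_overage,
          few_rounds = cfg$frac_few_rounds, low_energy = cfg$frac_low_energy,
          high_energy = cfg$frac_high_energy,
          missing_food = cfg$frac_missing_food,
          missing_covariate = cfg$frac_missing_covariate,
          cancer = cfg$frac_cancer, pregnant = cfg$frac_pregnant)
  n_fl <- round(fr * N)
  if (sum(n_fl) > N) stop("planted-violation fractions exceed the cohort")
  pool <- sample.int(N)
  planted <- list(); ptr <- 0L
  for (nm in names(n_fl)) {
    planted[[nm]] <- pool[seq_len(n_fl[[nm]]) + ptr]
    ptr <- ptr + n_fl[[nm]]
  }
  age0[planted$underage] <- stats::runif(length(planted$underage), 20, 29.5)
  age0[planted$overage] <- stats::runif(length(planted$overage), 60.5, 75)

  ## per-round ages and intended scores
  offs <- cfg$survey_years - cfg$survey_years[1L]
  age <- outer(age0, offs, "+")                       # N x R
  mu <- cfg$class_mean[cls] +
    outer(cfg$class_slope[cls], rep(1, R)) * (age - cfg$entry_age_mean) + b
  score <- mu + matrix(stats::rnorm(N * R, 0, cfg$residual_sd), N, R)
  score <- pmax(score, 0.05)                          # scores are distances

  ## invert scores into nonnegative intakes (ratio scale), then to grams
  u <- matrix(stats::rnorm(N * R * ngrp), N * R, ngrp)
  u <- u / sqrt(rowSums(u^2))
  xnorm <- matrix(0, N * R, ngrp)
  sv <- as.vector(score)                              # subject-major
  for (i in seq_len(N * R)) xnorm[i, ] <- invert_score(sv[i], u[i, ])
  grams <- sweep(xnorm, 2L, guideline$reference, "*")
  colnames(grams) <- guideline$group

  energy <- matrix(rtruncnorm1(N * R, 2224, 503, 600, 7500), N, R)
  panel <- data.frame(subject_id = rep(ids, R),
                      round = rep(cfg$survey_years, each = N),
                      age_years = as.vector(age),
                      energy_kcal = as.vector(energy),
                      grams, check.names = FALSE,
                      stringsAsFactors = FALSE)

  ## survival: exponential death times with class rates (+ optional
  ## covariate effects), loss to follow-up, administrative censoring
  smoker_p <- c(0.296, 0.431, 0.487)[pmin(cls, 3L)]
  medicine_p <- c(0.241, 0.192, 0.164)[pmin(cls, 3L)]
  pa_mean <- c(1518, 3158, 3714)[pmin(cls, 3L)]
  pa_sd <- c(1652, 2856, 2959)[pmin(cls, 3L)]
  inc_mean <- c(18393, 10933, 6307)[pmin(cls, 3L)]
  sexv <- stats::rbinom(N, 1L, 0.495)
  surv <- data.frame(
    subject_id = ids,
    age_entry = age0,
    sex = factor(ifelse(sexv == 1L, "male", "female")),
    region = factor(sample(c("north", "central", "south"), N, TRUE)),
    chronic_disease = stats::rbinom(N, 1L, 0.32),
    medicine = stats::rbinom(N, 1L, medicine_p),
    smoker = stats::rbinom(N, 1L, smoker_p),
    physical_activity = pmax(stats::rnorm(N, pa_mean, pa_sd), 0),
    energy_kcal = energy[, 1L],
    bmi = stats::rnorm(N, 23.3, 3.2),
    drinker = stats::rbinom(N, 1L, 0.525),
    income = stats::rlnorm(N, log(inc_mean) - 0.5, 1),
    education = factor(sample(c("primary", "secondary", "tertiary"), N,
                              TRUE, prob = c(0.4, 0.45, 0.15)),
                       levels = c("primary", "secondary", "tertiary")),
    cancer = FALSE, pregnant_lactating = FALSE,
    stringsAsFactors = FALSE)

  lp <- rep(0, N)
  for (nm in names(cfg$covariate_log_hr)) {
    v <- surv[[nm]]
    if (is.null(v)) stop("covariate_log_hr names a missing covariate: ", nm)
    lp <- lp + cfg$covariate_log_hr[[nm]] * as.numeric(v)
  }
  lambda <- cfg$class_rate[cls] / 1000 * exp(lp)
  t_death <- stats::rexp(N, lambda)
  t_drop <- if (cfg$dropout_rate > 0) stats::rexp(N, cfg$dropout_rate) else
    rep(Inf, N)
  t_admin <- cfg$censor_year - cfg$survey_years[1L]
  followup <- pmin(t_death, t_drop, t_admin)
  surv$followup_years <- pmax(followup, 1e-3)
  surv$event <- as.integer(t_death <= pmin(t_drop, t_admin))

  ## plant remaining violations
  surv$cancer[planted$cancer] <- TRUE
  surv$pregnant_lactating[planted$pregnant] <- TRUE
  surv$income[planted$missing_covariate] <- NA_real_
  drop_rows <- panel$subject_id %in% ids[planted$few_rounds] &
    panel$round > cfg$survey_years[2L]
  panel <- panel[!drop_rows, , drop = FALSE]
  i1 <- match(ids[planted$low_energy], panel$subject_id)
  panel$energy_kcal[i1] <- stats::runif(length(i1), 100, 450)
  i2 <- match(ids[planted$high_energy], panel$subject_id)
  panel$energy_kcal[i2] <- stats::runif(length(i2), 8500, 12000)
  i3 <- match(ids[planted$missing_food], panel$subject_id)
  panel[i3, guideline$group[1L]] <- NA_real_

  truth_scores <- data.frame(subject_id = rep(ids, R),
                             round = rep(cfg$survey_years, each = N),
                             score = sv, stringsAsFactors = FALSE)
  truth_scores <- truth_scores[paste(truth_scores$subject_id,
                                     truth_scores$round) %in%
                                 paste(panel$subject_id, panel$round), ]
  surv$baseline_dnas <- score[, 1L]

  panel <- panel[order(panel$subject_id, panel$round), , drop = FALSE]
  rownames(panel) <- NULL
  truth_scores <- truth_scores[order(truth_scores$subject_id,
                                     truth_scores$round), , drop = FALSE]
  rownames(truth_scores) <- NULL
  structure(list(panel = panel, survival = surv,
                 truth = list(class = cls, intercept = b,
                              death_time = t_death, scores = truth_scores),
                 config = cfg),
            class = "dnas_cohort")
}

#' @export
print.dnas_cohort <- function(x, ...) {
  cat("Synthetic dietary cohort:", nrow(x$survival), "subjects,",
      nrow(x$panel), "intake records,",
      sum(x$survival$event), "deaths\n")
  invisible(x)
}
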