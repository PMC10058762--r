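cfg_small <- function(...) cohort_config(n_subjects = 150, seed = 11, ...)

test_that("generation is a deterministic function of the config seed", {
  g <- toy_guideline()
  a <- generate_cohort(cfg_small(), g)
  b <- generate_cohort(cfg_small(), g)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_subjects = 150, seed = 12), g)
  expect_false(identical(a$panel, c$panel))
})

test_that("generated intakes re-score to the intended DNAS values", {
  g <- toy_guideline()
  co <- generate_cohort(cfg_small(), g)
  d <- score_panel(co$panel, g)
  expect_equal(nrow(d), nrow(co$truth$scores))
  expect_equal(d$score, co$truth$scores$score, tolerance = 1e-9)
  # intakes are all nonnegative and aligned to the guideline
  expect_true(all(as.matrix(co$panel[, g$group]) >= 0))
})

test_that("entry ages and class shares follow the configured distributions", {
  co <- generate_cohort(cohort_config(n_subjects = 4000, seed = 2),
                        toy_guideline())
  age <- co$survival$age_entry
  expect_true(all(age >= 30 & age <= 60))
  # moments of normal(43.3, 8.3) truncated to [30, 60], computed from the
  # closed-form truncated-normal expressions
  a <- (30 - 43.3) / 8.3; b <- (60 - 43.3) / 8.3
  Z <- pnorm(b) - pnorm(a)
  tmean <- 43.3 + 8.3 * (dnorm(a) - dnorm(b)) / Z
  tsd <- 8.3 * sqrt(1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                      ((dnorm(a) - dnorm(b)) / Z)^2)
  expect_lt(abs(mean(age) - tmean), 0.4)
  expect_lt(abs(sd(age) - tsd), 0.4)
  shares <- tabulate(co$truth$class, 3) / 4000
  truth <- c(378, 3522, 633) / 4533
  expect_true(all(abs(shares - truth) < 3 * sqrt(truth * (1 - truth) / 4000)))
})

test_that("class-wise event rates converge to the configured rates", {
  g <- toy_guideline()
  ev <- py <- matrix(0, 6, 3)
  for (s in 1:6) {
    co <- generate_cohort(cohort_config(n_subjects = 3000, seed = 400 + s), g)
    for (k in 1:3) {
      sel <- co$truth$class == k
      ev[s, k] <- sum(co$survival$event[sel])
      py[s, k] <- sum(co$survival$followup_years[sel])
    }
  }
  est <- 1000 * colSums(ev) / colSums(py)
  expect_equal(est, c(11.8, 28.8, 44.5), tolerance = 0.10)
})

test_that("follow-up length matches the censoring design", {
  co <- generate_cohort(cohort_config(n_subjects = 3000, seed = 9),
                        toy_guideline())
  fu <- co$survival$followup_years
  expect_true(all(fu > 0 & fu <= 11))
  # dropout hazard targets a median follow-up near 6.9 years
  expect_lt(abs(median(fu) - 6.9), 1.0)
})

test_that("planted eligibility violations are excluded with exact counts", {
  g <- toy_guideline()
  cfg <- cohort_config(n_subjects = 400, seed = 5,
                       frac_underage = 0.02, frac_overage = 0.02,
                       frac_few_rounds = 0.03, frac_low_energy = 0.02,
                       frac_high_energy = 0.01, frac_missing_food = 0.02,
                       frac_missing_covariate = 0.02, frac_cancer = 0.03,
                       frac_pregnant = 0.01)
  co <- generate_cohort(cfg, g)
  ex <- apply_exclusions(co$panel, co$survival)
  lg <- setNames(ex$log$n_excluded, ex$log$criterion)
  expect_equal(lg[["age"]], round(0.04 * 400))
  expect_equal(lg[["few_rounds"]], round(0.03 * 400))
  expect_equal(lg[["energy"]], round(0.03 * 400))
  expect_equal(lg[["missing_food"]], round(0.02 * 400))
  expect_equal(lg[["missing_covariate"]], round(0.02 * 400))
  expect_equal(lg[["cancer"]], round(0.03 * 400))
  expect_equal(lg[["pregnant_lactating"]], round(0.01 * 400))
  expect_equal(ex$n_before - ex$n_after, sum(lg))

  # boundary: exactly 3 rounds is retained, exactly 2 is excluded
  p <- co$panel[co$panel$subject_id %in% ex$panel$subject_id, ]
  keep3 <- unique(p$subject_id)[1]
  p3 <- p[p$subject_id == keep3, ][1:3, ]
  s3 <- co$survival[co$survival$subject_id == keep3, ]
  expect_equal(apply_exclusions(p3, s3)$n_after, 1)
  expect_equal(apply_exclusions(p3[1:2, ], s3)$n_after, 0)
})

test_that("the exclusion filter is idempotent", {
  g <- toy_guideline()
  co <- generate_cohort(cohort_config(n_subjects = 300, seed = 6,
                                      frac_low_energy = 0.05,
                                      frac_cancer = 0.05), g)
  once <- apply_exclusions(co$panel, co$survival)
  twice <- apply_exclusions(once$panel, once$survival)
  expect_identical(once$panel, twice$panel)
  expect_identical(once$survival, twice$survival)
  expect_equal(sum(twice$log$n_excluded), 0)
})

test_that("energy thresholds are enforced at the stated boundaries", {
  g <- toy_guideline()
  co <- generate_cohort(cfg_small(), g)
  p <- co$panel; s <- co$survival
  p$energy_kcal[1] <- 499.9
  ex <- apply_exclusions(p, s)
  expect_equal(ex$n_before - ex$n_after, 1)
  p$energy_kcal[1] <- 500
  expect_equal(apply_exclusions(p, s)$n_after, ex$n_before)
  p$energy_kcal[1] <- 8000.5
  expect_equal(apply_exclusions(p, s)$n_before -
                 apply_exclusions(p, s)$n_after, 1)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(class_prop = c(-1, 1, 1)), "positive")
  expect_error(cohort_config(survey_years = c(2004, 2004, 2009, 2011)),
               "ascending")
  expect_error(cohort_config(censor_year = 2010), "after")
  expect_error(cohort_config(subject_sd = 0), "positive")
  expect_error(generate_cohort(cohort_config(n_subjects = 100,
                                             frac_cancer = 0.9,
                                             frac_few_rounds = 0.9)),
               "exceed")
})
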