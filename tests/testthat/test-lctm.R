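test_that("marginal log-likelihood matches direct mixture-density evaluation", {
  beta <- rbind(c(3.2, -0.02), c(5.1, 0.01))
  pan <- mixture_panel(5, 3, beta, pi = c(0.4, 0.6), tau2 = 0.5,
                       sigma2 = 0.3, seed = 21)
  center <- mean(pan$age_years)
  for (k in 1:5) {
    set.seed(k)
    b <- beta + matrix(rnorm(4, 0, 0.3), 2)
    p1 <- runif(1, 0.2, 0.8)
    t2 <- runif(1, 0.1, 1); s2 <- runif(1, 0.1, 1)
    expect_equal(lctm_loglik(pan, b, c(p1, 1 - p1), t2, s2, center = center),
                 oracle_mixture_loglik(pan, b, c(p1, 1 - p1), t2, s2, center),
                 tolerance = 1e-10)
  }
})

test_that("degenerate structures reduce to known closed forms", {
  # G = 1: plain linear-mixed-model likelihood
  pan <- mixture_panel(4, 2, rbind(c(4, 0.01)), pi = 1, tau2 = 0.4,
                       sigma2 = 0.2, seed = 3)
  center <- mean(pan$age_years)
  expect_equal(lctm_loglik(pan, rbind(c(4, 0.01)), 1, 0.4, 0.2,
                           center = center),
               oracle_mixture_loglik(pan, rbind(c(4, 0.01)), 1, 0.4, 0.2,
                                     center),
               tolerance = 1e-10)
  # tau2 = 0, one observation per subject: G-component univariate mixture
  pan1 <- mixture_panel(6, 1, rbind(c(3, 0), c(6, 0)), pi = c(0.5, 0.5),
                        tau2 = 0, sigma2 = 0.5, seed = 4)
  center <- mean(pan1$age_years)
  got <- lctm_loglik(pan1, rbind(c(3, 0), c(6, 0)), c(0.3, 0.7), 0, 0.5,
                     center = center)
  want <- sum(log(0.3 * dnorm(pan1$score, 3, sqrt(0.5)) +
                  0.7 * dnorm(pan1$score, 6, sqrt(0.5))))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("single-class fit matches an independent linear mixed model", {
  pan <- mixture_panel(80, 4, rbind(c(4.5, -0.015)), pi = 1, tau2 = 0.5,
                       sigma2 = 0.3, seed = 8)
  fit <- fit_lctm(pan, G = 1, tol = 1e-12)
  pan$xc <- pan$age_years - fit$age_center
  ref <- lme4::lmer(score ~ xc + (1 | subject_id), data = pan, REML = FALSE)
  expect_equal(unname(fit$beta[1, ]), unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$tau2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
})

test_that("EM log-likelihood trace is monotone and posteriors normalize", {
  beta <- rbind(c(3.3, -0.02), c(4.8, 0), c(5.9, 0.008))
  pan <- mixture_panel(150, 4, beta, pi = c(0.2, 0.5, 0.3), tau2 = 0.4,
                       sigma2 = 0.4, seed = 12)
  fit <- fit_lctm(pan, G = 3, n_starts = 3, seed = 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(rowSums(fit$posterior), rep(1, 150), tolerance = 1e-10)
  expect_equal(fit$modal_class, max.col(fit$posterior))
  expect_equal(fit$BIC, -2 * fit$loglik + fit$n_params * log(150))
  # canonical ordering: class means ascend
  expect_false(is.unsorted(fit$beta[, 1]))
})

test_that("relabelling classes leaves the likelihood unchanged", {
  beta <- rbind(c(3.5, -0.01), c(5.5, 0.01))
  pan <- mixture_panel(30, 3, beta, pi = c(0.5, 0.5), tau2 = 0.3,
                       sigma2 = 0.3, seed = 5)
  center <- mean(pan$age_years)
  ll <- lctm_loglik(pan, beta, c(0.35, 0.65), 0.3, 0.3, center = center)
  ll_perm <- lctm_loglik(pan, beta[2:1, ], c(0.65, 0.35), 0.3, 0.3,
                         center = center)
  expect_equal(ll, ll_perm, tolerance = 1e-12)
})

test_that("classification limits behave as expected", {
  beta <- rbind(c(2, 0), c(8, 0))
  # subject sitting exactly on class 1's line, far from class 2
  pan <- data.frame(subject_id = "A",
                    age_years = c(40, 44, 48),
                    score = c(2, 2, 2))
  fit <- structure(list(beta = beta, pi = c(0.5, 0.5), tau2 = 0.2,
                        sigma2 = 0.2, age_center = 44, G = 2),
                   class = "lctm_fit")
  cl <- classify(fit, pan)
  expect_gt(cl$prob_class1, 0.99)
  expect_equal(cl$modal_class, 1L)
  # identical classes: posterior equals the prior
  fit$beta <- rbind(c(5, 0), c(5, 0)); fit$pi <- c(0.3, 0.7)
  cl2 <- classify(fit, pan)
  expect_equal(c(cl2$prob_class1, cl2$prob_class2), c(0.3, 0.7),
               tolerance = 1e-12)
})

test_that("G_max = 1 selection is trivial and the table is complete", {
  pan <- mixture_panel(40, 3, rbind(c(4, 0)), pi = 1, tau2 = 0.3,
                       sigma2 = 0.3, seed = 2)
  sel <- select_n_classes(pan, G_max = 1)
  expect_equal(sel$G, 1L)
  expect_equal(nrow(sel$table), 1)
  expect_named(sel$table, c("G", "loglik", "n_params", "BIC", "converged"))
})

test_that("invalid panels and parameters are rejected", {
  pan <- mixture_panel(5, 2, rbind(c(4, 0)), pi = 1, tau2 = 0.3,
                       sigma2 = 0.3, seed = 1)
  expect_error(fit_lctm(pan[0, ], G = 1), "empty")
  bad <- pan; bad$score[1] <- NA
  expect_error(fit_lctm(bad, G = 1), "non-finite")
  expect_error(lctm_loglik(pan, rbind(c(4, 0)), 1, -0.1, 0.3), "tau2")
  expect_error(lctm_loglik(pan, rbind(c(4, 0)), c(0.5, 0.5), 0.3, 0.3),
               "length")
})
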