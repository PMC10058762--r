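## Latent-class linear mixed trajectory model
##
## Model, for subject i in latent class g with observations j = 1..m_i:
##   y_ij = beta0_g + beta1_g * (age_ij - center) + b_i + e_ij
##   b_i ~ N(0, tau2)   (subject-level random intercept, shared across classes)
##   e_ij ~ N(0, sigma2)
##   P(class = g) = pi_g  (intercept-only membership model)
## Marginally y_i | g ~ MVN(X_i beta_g, V_i), V_i = sigma2 I + tau2 J, so the
## mixture log-likelihood has a closed form and no numeric integration is
## needed. With this covariance structure every likelihood and EM quantity
## depends on the data only through per-subject sufficient statistics
## (m, sum x, sum x^2, sum y, sum y^2, sum xy), which keeps each EM
## iteration O(N * G). Fitting is EM (latent class + latent intercept both
## treated as missing data, giving closed-form monotone updates) followed
## by a quasi-Newton polish of the exact marginal log-likelihood.

## internal: validate/condense a trajectory panel into sufficient statistics
lctm_data <- function(panel, center = NULL) {
  need <- c("subject_id", "age_years", "score")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("trajectory panel is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(panel) == 0L) stop("trajectory panel is empty")
  if (any(!is.finite(panel$age_years)) || any(!is.finite(panel$score)))
    stop("trajectory panel contains non-finite age or score values")
  panel <- panel[order(panel$subject_id, panel$age_years), , drop = FALSE]
  id <- factor(panel$subject_id, levels = unique(panel$subject_id))
  if (is.null(center)) center <- mean(panel$age_years)
  x <- panel$age_years - center
  y <- panel$score
  idx <- as.integer(id)
  n <- nlevels(id)
  agg <- function(v) {
    out <- numeric(n)
    tmp <- rowsum(v, idx)
    out[as.integer(rownames(tmp))] <- tmp
    out
  }
  list(m = agg(rep(1, length(y))), sx = agg(x), sxx = agg(x * x),
       sy = agg(y), syy = agg(y * y), sxy = agg(x * y),
       ids = levels(id), center = center,
       n_obs = nrow(panel), n_subj = n)
}

## internal: per-subject residual sums S1 = sum(y - Xb), S2 = sum((y - Xb)^2)
lctm_ressums <- function(dat, b0, b1) {
  list(S1 = dat$sy - b0 * dat$m - b1 * dat$sx,
       S2 = dat$syy - 2 * b0 * dat$sy - 2 * b1 * dat$sxy +
         b0^2 * dat$m + 2 * b0 * b1 * dat$sx + b1^2 * dat$sxx)
}

## internal: per-subject, per-class marginal log-density matrix (N x G).
## Random-intercept structure gives
##   -2 loglik_ig = m log(2 pi sigma2) + log(1 + m tau2/sigma2)
##                  + (S2 - c S1^2)/sigma2,  c = tau2/(sigma2 + m tau2).
lctm_logdens <- function(dat, beta, tau2, sigma2) {
  G <- nrow(beta)
  cc <- tau2 / (sigma2 + dat$m * tau2)
  const <- dat$m * log(2 * pi * sigma2) + log1p(dat$m * tau2 / sigma2)
  ll <- matrix(0, dat$n_subj, G)
  for (g in seq_len(G)) {
    rs <- lctm_ressums(dat, beta[g, 1L], beta[g, 2L])
    ll[, g] <- -0.5 * (const + (rs$S2 - cc * rs$S1^2) / sigma2)
  }
  ll
}

#' Marginal log-likelihood of a latent-class trajectory model
#'
#' Evaluates \eqn{\sum_i \log \sum_g \pi_g \phi(y_i; X_i\beta_g, V_i)} where
#' \eqn{y_i} is subject i's score vector, \eqn{X_i = [1, age - center]} and
#' \eqn{V_i = \sigma^2 I + \tau^2 J} is the random-intercept marginal
#' covariance. This is the exact mixture-of-multivariate-normals likelihood;
#' no numeric integration is involved.
#'
#' @param panel data frame with columns `subject_id`, `age_years`, `score`.
#' @param beta numeric G x 2 matrix of class-specific (intercept, age slope),
#'   intercepts expressed at `center`.
#' @param pi numeric vector of G mixing proportions (positive, sum 1).
#' @param tau2 random-intercept variance (>= 0).
#' @param sigma2 residual variance (> 0).
#' @param center age origin for the intercepts (default: mean observed age).
#' @return The scalar marginal log-likelihood.
#' @export
lctm_loglik <- function(panel, beta, pi, tau2, sigma2, center = NULL) {
  beta <- matrix(as.numeric(beta), ncol = 2L)
  if (length(pi) != nrow(beta)) stop("length(pi) must equal nrow(beta)")
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("mixing proportions must be positive and sum to 1")
  if (tau2 < 0 || sigma2 <= 0) stop("need tau2 >= 0 and sigma2 > 0")
  dat <- lctm_data(panel, center)
  lctm_estep(dat, beta, pi, tau2, sigma2)$loglik
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## internal: one evaluation of loglik + posterior for given parameters
lctm_estep <- function(dat, beta, pi, tau2, sigma2) {
  ll <- lctm_logdens(dat, beta, tau2, sigma2)
  lw <- sweep(ll, 2L, log(pi), "+")
  lse <- logsumexp_rows(lw)
  list(loglik = sum(lse), post = exp(lw - lse))
}

## internal: initial partition-based parameters from subject mean scores
lctm_init <- function(dat, G, perturb = 0) {
  ybar <- dat$sy / dat$m
  if (G == 1L) {
    cls <- rep(1L, dat$n_subj)
  } else {
    km <- try(stats::kmeans(ybar, centers = G, nstart = 5L), silent = TRUE)
    cls <- if (inherits(km, "try-error"))
      sample.int(G, dat$n_subj, replace = TRUE) else
      order(order(km$centers))[km$cluster]     # labels ascending in mean
    if (perturb > 0) {
      flip <- which(stats::runif(dat$n_subj) < perturb)
      cls[flip] <- sample.int(G, length(flip), replace = TRUE)
    }
  }
  beta <- matrix(0, G, 2L)
  for (g in seq_len(G)) {
    in_g <- cls == g
    A <- matrix(c(sum(dat$m[in_g]), sum(dat$sx[in_g]),
                  sum(dat$sx[in_g]), sum(dat$sxx[in_g])), 2L)
    rhs <- c(sum(dat$sy[in_g]), sum(dat$sxy[in_g]))
    bg <- try(solve(A, rhs), silent = TRUE)
    beta[g, ] <- if (inherits(bg, "try-error") || any(!is.finite(bg)))
      c(mean(ybar), 0) else bg
  }
  tot <- stats::var(rep(ybar, dat$m))
  shares <- pmax(tabulate(cls, G), 1)
  list(beta = beta, pi = shares / sum(shares),
       tau2 = max(tot * 0.4, 1e-4), sigma2 = max(tot * 0.4, 1e-4))
}

## internal: constrained maximizer of sum(n * log(pi)) over the simplex
## with pi >= eps (water-filling KKT solution)
clip_simplex <- function(n, eps) {
  G <- length(n)
  if (eps <= 0) return(n / sum(n))
  ord <- order(n)
  for (k in 0:(G - 1L)) {
    clip <- ord[seq_len(k)]
    free <- setdiff(seq_len(G), clip)
    lam <- sum(n[free]) / (1 - k * eps)
    pi <- numeric(G)
    pi[clip] <- eps
    pi[free] <- n[free] / lam
    if (all(pi[free] >= eps - 1e-12)) return(pi)
  }
  rep(1 / G, G)
}

## internal: EM from given parameters; returns parameters + loglik trace
lctm_em <- function(dat, init, tol, max_iter, eps = 0) {
  beta <- init$beta; pi <- init$pi; tau2 <- init$tau2; sigma2 <- init$sigma2
  G <- nrow(beta)
  trace <- numeric(max_iter)
  converged <- FALSE
  m <- dat$m
  for (it in seq_len(max_iter)) {
    es <- lctm_estep(dat, beta, pi, tau2, sigma2)
    trace[it] <- es$loglik
    w <- es$post                               # N x G
    cc <- tau2 / (sigma2 + m * tau2)           # per subject
    v <- sigma2 * cc                           # posterior var of b_i
    bhat <- matrix(0, dat$n_subj, G)
    for (g in seq_len(G))
      bhat[, g] <- cc * lctm_ressums(dat, beta[g, 1L], beta[g, 2L])$S1
    ## M-step: beta_g by WLS of (y - bhat_ig) on [1, x], weights w_ig
    beta_new <- beta
    for (g in seq_len(G)) {
      wg <- w[, g]
      A <- matrix(c(sum(wg * m), sum(wg * dat$sx),
                    sum(wg * dat$sx), sum(wg * dat$sxx)), 2L)
      rhs <- c(sum(wg * (dat$sy - m * bhat[, g])),
               sum(wg * (dat$sxy - dat$sx * bhat[, g])))
      beta_new[g, ] <- solve(A, rhs)
    }
    tau2_new <- sum(w * (bhat^2 + v)) / dat$n_subj
    sse <- 0
    for (g in seq_len(G)) {
      rs <- lctm_ressums(dat, beta_new[g, 1L], beta_new[g, 2L])
      sse <- sse + sum(w[, g] *
                         (rs$S2 - 2 * bhat[, g] * rs$S1 +
                            m * bhat[, g]^2 + m * v))
    }
    sigma2_new <- sse / dat$n_obs
    pi_new <- clip_simplex(pmax(colSums(w), 1e-12), eps)
    beta <- beta_new; tau2 <- max(tau2_new, 1e-12)
    sigma2 <- max(sigma2_new, 1e-12); pi <- pi_new
    if (it > 1L) {
      rel <- (trace[it] - trace[it - 1L]) / (abs(trace[it - 1L]) + 1e-12)
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
  }
  n_iter <- if (converged) it else max_iter
  list(beta = beta, pi = pi, tau2 = tau2, sigma2 = sigma2,
       loglik = trace[n_iter], trace = trace[seq_len(n_iter)],
       n_iter = n_iter, converged = converged)
}

## internal: quasi-Newton polish of the exact marginal loglik
lctm_polish <- function(dat, par) {
  G <- nrow(par$beta)
  pack <- function(p) c(as.vector(p$beta), log(max(p$tau2, 1e-12)),
                        log(p$sigma2), if (G > 1L) log(p$pi[-1L] / p$pi[1L]))
  unpack <- function(th) {
    beta <- matrix(th[seq_len(2 * G)], G, 2L)
    tau2 <- exp(th[2 * G + 1L]); sigma2 <- exp(th[2 * G + 2L])
    pi <- if (G > 1L) {
      a <- c(0, th[(2 * G + 3L):length(th)]); exp(a) / sum(exp(a))
    } else 1
    list(beta = beta, pi = pi, tau2 = tau2, sigma2 = sigma2)
  }
  nll <- function(th) {
    p <- unpack(th)
    -lctm_estep(dat, p$beta, p$pi, p$tau2, p$sigma2)$loglik
  }
  opt <- try(stats::optim(pack(par), nll, method = "BFGS",
                          control = list(maxit = 300, reltol = 1e-14)),
             silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$value)) return(par)
  p <- unpack(opt$par)
  if (-opt$value <= par$loglik) return(par)   # keep EM answer if no gain
  p$loglik <- -opt$value
  p$trace <- par$trace; p$n_iter <- par$n_iter
  p$converged <- par$converged || opt$convergence == 0L
  p
}

#' Fit a latent-class linear mixed trajectory model
#'
#' Fits a G-class mixture of linear mixed models of score on age: each class
#' has its own intercept and age slope, subjects carry a shared-variance
#' random intercept, and class membership follows intercept-only multinomial
#' probabilities. Estimation maximizes the exact marginal likelihood by EM
#' (both the class label and the random intercept are treated as missing
#' data, giving closed-form monotone updates). Initialization uses a
#' short-run multistart strategy: `n_starts` perturbed k-means partitions of
#' subject mean scores each get a short EM run, the best by log-likelihood
#' is run to convergence and then refined by a BFGS polish of the exact
#' marginal log-likelihood. Classes are relabelled in ascending order of
#' fitted mean score at the centering age, so class 1 is the lowest-score
#' ("best adherence") class.
#'
#' @param panel data frame with columns `subject_id`, `age_years`, `score`.
#' @param G number of latent classes (>= 1).
#' @param n_starts number of random initializations (ignored for G = 1).
#' @param seed optional integer seed controlling the initializations.
#' @param tol relative log-likelihood convergence tolerance of the EM phase.
#' @param max_iter maximum EM iterations for the final run (short runs use
#'   `min(50, max_iter)`).
#' @param center_age age origin for the intercepts; default the sample mean
#'   observed age.
#' @param polish logical; refine the EM solution by direct quasi-Newton
#'   maximization of the marginal log-likelihood (default TRUE). The
#'   refinement is kept only when it respects the class-share constraint.
#' @param min_share smallest admissible mixing proportion per class
#'   (default 0.05). Maximum-likelihood mixtures at modest separation are
#'   prone to spurious near-empty classes; the constraint (enforced
#'   exactly in the EM M-step, making the estimate a constrained MLE)
#'   follows the applied trajectory-modelling convention that every class
#'   should hold a non-trivial share of subjects. Set to 0 for the
#'   unconstrained MLE.
#' @return An object of class `lctm_fit` with elements `beta` (G x 2 matrix
#'   of intercept/slope), `se` (approximate Wald standard errors), `pi`,
#'   `tau2`, `sigma2`, `loglik`, `n_params`, `BIC` (computed with N =
#'   number of subjects), `posterior` (N x G), `modal_class`, `subject_id`,
#'   `age_center`, `converged`, `n_iter`, `loglik_trace`, `G`.
#' @seealso [select_n_classes()], [classify()], [lctm_loglik()]
#' @export
fit_lctm <- function(panel, G, n_starts = 5L, seed = NULL, tol = 1e-8,
                     max_iter = 500L, center_age = NULL, polish = TRUE,
                     min_share = 0.05) {
  if (G < 1L) stop("G must be >= 1")
  dat <- lctm_data(panel, center_age)
  if (!is.null(seed)) set.seed(seed)
  starts <- if (G == 1L) 1L else max(1L, as.integer(n_starts))
  short <- min(50L, max_iter)
  eps <- min(min_share, 0.5 / G)   # keep the constraint feasible
  best <- NULL
  for (s in seq_len(starts)) {
    init <- lctm_init(dat, G, perturb = if (s == 1L) 0 else 0.2)
    init$pi <- clip_simplex(init$pi, eps)
    fit <- lctm_em(dat, init, tol, short, eps)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best <- lctm_em(dat, best, tol, max_iter, eps)
  if (polish) {
    cand <- lctm_polish(dat, best)
    if (all(cand$pi >= eps - 1e-9)) best <- cand   # keep only admissible
  }
  ## canonical order: ascending mean score at the centering age
  ord <- order(best$beta[, 1L])
  best$beta <- best$beta[ord, , drop = FALSE]
  best$pi <- best$pi[ord]
  es <- lctm_estep(dat, best$beta, best$pi, best$tau2, best$sigma2)
  ## approximate Wald SEs from the posterior-weighted GLS information
  se <- matrix(NA_real_, G, 2L)
  m <- dat$m
  cc <- best$tau2 / (best$sigma2 + m * best$tau2)
  for (g in seq_len(G)) {
    w <- es$post[, g]
    ## X_i' V_i^{-1} X_i accumulated over subjects, weighted by posterior
    i11 <- sum(w * (m - cc * m^2)) / best$sigma2
    i12 <- sum(w * (dat$sx - cc * m * dat$sx)) / best$sigma2
    i22 <- sum(w * (dat$sxx - cc * dat$sx^2)) / best$sigma2
    v <- try(solve(matrix(c(i11, i12, i12, i22), 2L)), silent = TRUE)
    if (!inherits(v, "try-error")) se[g, ] <- sqrt(pmax(diag(v), 0))
  }
  n_params <- 2L * G + (G - 1L) + 2L
  empty <- best$pi < 0.5 / dat$n_subj
  structure(list(
    beta = best$beta, se = se, pi = best$pi, tau2 = best$tau2,
    sigma2 = best$sigma2, loglik = es$loglik, n_params = n_params,
    BIC = -2 * es$loglik + n_params * log(dat$n_subj),
    posterior = es$post, modal_class = max.col(es$post),
    subject_id = dat$ids, age_center = dat$center,
    converged = best$converged, n_iter = best$n_iter,
    loglik_trace = best$trace, G = G, empty_class = any(empty)),
    class = "lctm_fit")
}

#' @export
print.lctm_fit <- function(x, ...) {
  cat("Latent-class trajectory model:", x$G, "class(es),",
      length(x$subject_id), "subjects\n")
  tab <- data.frame(class = seq_len(x$G),
                    intercept = x$beta[, 1L], slope = x$beta[, 2L],
                    slope_se = x$se[, 2L],
                    p_slope = 2 * stats::pnorm(-abs(x$beta[, 2L] / x$se[, 2L])),
                    pi = x$pi)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("tau2 = %.4f  sigma2 = %.4f  logLik = %.2f  BIC = %.2f\n",
              x$tau2, x$sigma2, x$loglik, x$BIC))
  if (!x$converged) cat("warning: fit did not meet its convergence tolerance\n")
  invisible(x)
}

#' Select the number of latent classes by BIC
#'
#' Fits models with 1..`G_max` classes and returns the class count with the
#' lowest BIC (N = number of subjects) together with the full comparison
#' table. Non-converged fits stay in the table, flagged.
#'
#' @inheritParams fit_lctm
#' @param G_max largest number of classes to try.
#' @return list with `G` (chosen), `table` (data frame G, loglik, n_params,
#'   BIC, converged), and `fits` (list of `lctm_fit` objects).
#' @export
select_n_classes <- function(panel, G_max, n_starts = 5L, seed = NULL,
                             tol = 1e-8, max_iter = 500L, min_share = 0.05) {
  if (G_max < 1L) stop("G_max must be >= 1")
  fits <- vector("list", G_max)
  for (g in seq_len(G_max)) {
    fits[[g]] <- fit_lctm(panel, g, n_starts = n_starts,
                          seed = if (is.null(seed)) NULL else seed + g,
                          tol = tol, max_iter = max_iter,
                          min_share = min_share)
  }
  tab <- data.frame(G = seq_len(G_max),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    n_params = vapply(fits, `[[`, 0L, "n_params"),
                    BIC = vapply(fits, `[[`, 0, "BIC"),
                    converged = vapply(fits, `[[`, TRUE, "converged"))
  list(G = tab$G[which.min(tab$BIC)], table = tab, fits = fits)
}

#' Posterior class probabilities and modal assignment
#'
#' Computes, for each subject in `panel`, the posterior probability of each
#' latent class under a fitted model, and the modal (highest-posterior)
#' class. When `panel` is omitted the training-sample posteriors stored in
#' the fit are returned.
#'
#' @param fit an `lctm_fit`.
#' @param panel optional trajectory panel; defaults to the training data
#'   stored in the fit (`NULL` returns stored posteriors).
#' @return data frame `subject_id`, `prob_class1..G`, `modal_class`.
#' @export
classify <- function(fit, panel = NULL) {
  if (is.null(panel)) {
    post <- fit$posterior
    ids <- fit$subject_id
  } else {
    dat <- lctm_data(panel, fit$age_center)
    es <- lctm_estep(dat, fit$beta, fit$pi, fit$tau2, fit$sigma2)
    post <- es$post
    ids <- dat$ids
  }
  out <- data.frame(subject_id = ids, post, max.col(post),
                    stringsAsFactors = FALSE)
  names(out) <- c("subject_id", paste0("prob_class", seq_len(ncol(post))),
                  "modal_class")
  out
}
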