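# Shared fixtures and independent oracles used across test files.

# simple 10-group guideline with distinct references
toy_guideline <- function(n = 10L) {
  guideline_spec(paste0("g", seq_len(n)),
                 low = seq_len(n) * 10,
                 high = seq_len(n) * 30,
                 reference = seq_len(n) * 20)
}

# brute-force distance oracle: explicit loop over coordinates
oracle_distance <- function(x, y, metric = "euclidean") {
  acc <- 0
  for (i in seq_along(x)) {
    if (metric == "euclidean") acc <- acc + (x[i] - y[i])^2
    else acc <- acc + abs(x[i] - y[i])
  }
  if (metric == "euclidean") sqrt(acc) else acc
}

# random intake panel on a guideline
random_panel <- function(n_subj, rounds, guideline, seed = 1) {
  set.seed(seed)
  n <- n_subj * length(rounds)
  grams <- sapply(guideline$reference, function(r) stats::runif(n, 0, 3 * r))
  colnames(grams) <- guideline$group
  data.frame(subject_id = rep(sprintf("P%03d", seq_len(n_subj)),
                              each = length(rounds)),
             round = rep(rounds, n_subj),
             age_years = 40 + rep(rounds - min(rounds), n_subj) +
               rep(stats::runif(n_subj, -5, 5), each = length(rounds)),
             energy_kcal = stats::runif(n, 1500, 3000),
             grams, check.names = FALSE, stringsAsFactors = FALSE)
}

# small trajectory panel drawn from an explicit mixture of linear mixed
# models; used to feed the likelihood oracle
mixture_panel <- function(n_subj, m_per, beta, pi, tau2, sigma2, seed = 1) {
  set.seed(seed)
  G <- nrow(beta)
  cls <- sample.int(G, n_subj, replace = TRUE, prob = pi)
  rows <- list()
  for (i in seq_len(n_subj)) {
    x <- sort(stats::runif(m_per, -5, 5))
    b <- stats::rnorm(1, 0, sqrt(tau2))
    y <- beta[cls[i], 1] + beta[cls[i], 2] * x + b +
      stats::rnorm(m_per, 0, sqrt(sigma2))
    rows[[i]] <- data.frame(subject_id = sprintf("M%03d", i),
                            age_years = 50 + x, score = y)
  }
  do.call(rbind, rows)
}

# direct mixture-of-multivariate-normal-densities log-likelihood oracle:
# builds each V_i explicitly and evaluates the densities with full
# matrix algebra, independently of the package's sufficient-statistic path
oracle_mixture_loglik <- function(panel, beta, prob, tau2, sigma2, center) {
  panel <- panel[order(panel$subject_id, panel$age_years), ]
  total <- 0
  for (id in unique(panel$subject_id)) {
    d <- panel[panel$subject_id == id, ]
    x <- d$age_years - center
    y <- d$score
    m <- length(y)
    V <- diag(sigma2, m) + matrix(tau2, m, m)
    dens <- 0
    for (g in seq_len(nrow(beta))) {
      mu <- beta[g, 1] + beta[g, 2] * x
      r <- y - mu
      q <- drop(t(r) %*% solve(V) %*% r)
      logdet <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
      dens <- dens + prob[g] * exp(-0.5 * (m * log(2 * base::pi) +
                                             logdet + q))
    }
    total <- total + log(dens)
  }
  total
}

# hand-written Cox partial likelihood for one covariate, no ties (Breslow
# and Efron coincide); maximized by golden-section search
oracle_cox_coef <- function(time, event, z) {
  stopifnot(!anyDuplicated(time[event == 1]))
  plik <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + beta * z[i] - log(sum(exp(beta * z[risk])))
    }
    s
  }
  stats::optimize(plik, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# textbook restricted cubic spline (truncated power basis with linear
# tail constraints), written with explicit scalar loops
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in 1:(k - 2)) {
    for (i in seq_along(x)) {
      p3 <- function(u) if (u > 0) u^3 else 0
      out[i, j + 1] <- (p3(x[i] - knots[j]) -
        p3(x[i] - knots[k - 1]) * (knots[k] - knots[j]) /
          (knots[k] - knots[k - 1]) +
        p3(x[i] - knots[k]) * (knots[k - 1] - knots[j]) /
          (knots[k] - knots[k - 1])) / (knots[k] - knots[1])^2
    }
  }
  out
}

# two-group exponential survival data with known hazard ratio
exp_surv_data <- function(n, hr, base_rate = 0.05, admin = 15, seed = 1) {
  set.seed(seed)
  grp <- rep(0:1, length.out = n)
  t <- stats::rexp(n, base_rate * hr^grp)
  data.frame(followup_years = pmin(t, admin),
             event = as.integer(t <= admin),
             group = grp)
}
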