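## Restricted cubic splines and the spline Cox dose-response curve.

#' Restricted cubic spline basis
#'
#' Builds the restricted (natural) cubic spline basis with k knots
#' `t_1 < ... < t_k`: the function space is cubic between knots, has
#' continuous value, first and second derivative everywhere, and is linear
#' beyond the boundary knots. The basis has `k - 1` columns: the linear
#' term `x` followed by `k - 2` nonlinear terms
#' \deqn{C_j(x) = [ (x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1}) ] / (t_k-t_1)^2}
#' for j = 1..k-2 (the usual scaling that keeps all columns on the scale
#' of x).
#'
#' @param x numeric vector of evaluation points.
#' @param knots numeric vector of at least 3 strictly increasing knots.
#' @return numeric matrix, `length(x)` rows and `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) stop("need at least 3 knots")
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing (no duplicates)")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1L]
  norm <- (knots[k] - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                        pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                        pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("lin", if (k > 2L) paste0("nl", seq_len(k - 2L)))
  out
}

## Harrell's default quantiles for knot placement
rcs_knot_quantiles <- function(k) {
  switch(as.character(k),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         seq(0.05, 0.95, length.out = k))
}

## Royston-Sauerbrei R^2_D for a Cox model: regress survival on the
## rankit-transformed prognostic index scaled by kappa = sqrt(8/pi);
## R2_D = (D^2/kappa^2) / (pi^2/6 + D^2/kappa^2).
royston_r2 <- function(records, pindex, ties = "efron") {
  kappa <- sqrt(8 / pi)
  n <- length(pindex)
  rk <- rank(pindex, ties.method = "first")
  z <- stats::qnorm((rk - 3 / 8) / (n + 1 / 4)) / kappa
  d <- data.frame(followup_years = records$followup_years,
                  event = records$event, z = z)
  f <- survival::coxph(survival::Surv(followup_years, event) ~ z,
                       data = d, ties = ties)
  D <- unname(stats::coef(f))
  (D^2 / kappa^2) / (pi^2 / 6 + D^2 / kappa^2)
}

## Nagelkerke-style R^2 from the partial-likelihood ratio
nagelkerke_r2 <- function(fit) {
  n <- fit$n
  lr <- 2 * (fit$loglik - fit$loglik_null)
  (1 - exp(-lr / n)) / (1 - exp(2 * fit$loglik_null / n))
}

#' Restricted-cubic-spline Cox dose-response curve
#'
#' Fits Cox models of all-cause mortality on a restricted-cubic-spline
#' expansion of a continuous exposure (baseline score by default), with the
#' full covariate ladder as adjustment, for each candidate number of knots;
#' knots are placed at Harrell's quantiles of the exposure. The knot count
#' with the largest coefficient of determination is selected and the fitted
#' hazard-ratio curve is returned, anchored so that HR equals 1 exactly at
#' the reference exposure.
#'
#' @param records data frame with `followup_years`, `event`, the exposure
#'   column, and (when `adjust` is TRUE) the ladder covariates of
#'   [sequential_models()].
#' @param exposure name of the exposure column (default `"baseline_dnas"`).
#' @param candidate_knots integer vector of knot counts to try.
#' @param reference `"auto"` (exposure value minimizing the fitted log-HR
#'   over the observed range) or a number.
#' @param adjust logical; include the Model-4 covariate ladder (default
#'   TRUE; set FALSE for unadjusted curves, e.g. in simulations without
#'   covariates).
#' @param r2 `"royston"` (default, Royston-Sauerbrei D-based measure) or
#'   `"nagelkerke"` for the likelihood-ratio-based measure.
#' @param grid_n number of grid points for the returned curve.
#' @param level confidence level of the pointwise band.
#' @return object of class `dnas_spline`: list with `knots`, `n_knots`,
#'   `coef` (spline coefficients), `reference`, `r2` (named vector over
#'   candidates), `curve` (data frame `x`, `loghr`, `HR`, `lo`, `hi`), and
#'   the selected `fit` (`cox_fit`).
#' @export
fit_rcs_cox <- function(records, exposure = "baseline_dnas",
                        candidate_knots = c(3L, 4L, 5L),
                        reference = "auto", adjust = TRUE,
                        r2 = c("royston", "nagelkerke"),
                        grid_n = 200L, level = 0.95) {
  r2 <- match.arg(r2)
  if (!exposure %in% names(records))
    stop("exposure column '", exposure, "' not found")
  x <- records[[exposure]]
  if (length(unique(x)) < 10L)
    stop("exposure needs at least 10 distinct values")
  adj <- if (adjust) unique(unlist(cox_model_blocks())) else character(0)
  fits <- list(); r2s <- numeric(0); knot_list <- list()
  for (k in candidate_knots) {
    kn <- unique(stats::quantile(x, rcs_knot_quantiles(k), names = FALSE))
    if (length(kn) < 3L) next
    B <- rcs_basis(x, kn)
    d <- cbind(records, as.data.frame(B))
    f <- try(fit_cox(d, c(colnames(B), adj)), silent = TRUE)
    if (inherits(f, "try-error")) next
    key <- as.character(k)
    fits[[key]] <- f; knot_list[[key]] <- kn
    pidx <- drop(B %*% f$table$coef[match(colnames(B), f$table$term)])
    r2s[key] <- if (r2 == "royston") royston_r2(records, pidx) else
      nagelkerke_r2(f)
  }
  if (!length(fits)) stop("no candidate spline Cox model converged")
  best <- names(r2s)[which.max(r2s)]
  fit <- fits[[best]]; kn <- knot_list[[best]]
  bnames <- colnames(rcs_basis(0, kn))
  beta <- fit$table$coef[match(bnames, fit$table$term)]
  idx <- match(bnames, fit$table$term)
  V <- stats::vcov(fit$model)[idx, idx, drop = FALSE]
  grid <- seq(min(x), max(x), length.out = grid_n)
  Bg <- rcs_basis(grid, kn)
  lhr_raw <- drop(Bg %*% beta)
  ref <- if (identical(reference, "auto")) grid[which.min(lhr_raw)] else
    as.numeric(reference)
  Bref <- rcs_basis(ref, kn)
  Bc <- sweep(Bg, 2L, drop(Bref), "-")
  lhr <- drop(Bc %*% beta)
  se <- sqrt(pmax(rowSums((Bc %*% V) * Bc), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    knots = kn, n_knots = length(kn), coef = stats::setNames(beta, bnames),
    reference = ref, r2 = r2s, r2_measure = r2,
    curve = data.frame(x = grid, loghr = lhr, HR = exp(lhr),
                       lo = exp(lhr - z * se), hi = exp(lhr + z * se)),
    fit = fit), class = "dnas_spline")
}

#' @export
print.dnas_spline <- function(x, ...) {
  cat("Restricted-cubic-spline Cox dose-response:", x$n_knots,
      "knots at", paste(signif(x$knots, 4), collapse = ", "), "\n")
  cat("reference exposure (HR = 1):", signif(x$reference, 4), "\n")
  cat("R^2 (", x$r2_measure, ") by knot count: ",
      paste(names(x$r2), "=", signif(x$r2, 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.dnas_spline <- function(x, xlab = "baseline DNAS",
                             ylab = "hazard ratio", ...) {
  cv <- x$curve
  plot(cv$x, cv$HR, type = "l", log = "y", xlab = xlab, ylab = ylab, ...)
  graphics::lines(cv$x, cv$lo, lty = 2)
  graphics::lines(cv$x, cv$hi, lty = 2)
  graphics::abline(h = 1, col = "grey60")
  graphics::rug(x$knots)
  invisible(x)
}
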