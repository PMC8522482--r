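## Model-fitting engines behind the inequality and determinants analyses.
## Both are written out explicitly (closed-form least squares; IRLS for the
## offset Poisson) so tests can cross-check them against independent
## maximisers of the same likelihoods.

new_glm_fit <- function(coefficients, standard_errors, log_likelihood,
                        aic, converged, n_iterations, family, nobs,
                        deviance = NA_real_, dispersion = NA_real_,
                        fitted = NULL) {
  stopifnot(length(coefficients) == length(standard_errors))
  structure(
    list(coefficients = coefficients, standard_errors = standard_errors,
         log_likelihood = log_likelihood, aic = aic, converged = converged,
         n_iterations = n_iterations, family = family, nobs = nobs,
         deviance = deviance, dispersion = dispersion, fitted = fitted),
    class = "glm_fit"
  )
}

#' Simple linear regression by closed-form least squares
#'
#' Intercept and slope from the normal equations, with classical
#' standard errors. Used for the distance arm of the Relative Index of
#' Inequality, where the outcome is regressed on the deprivation score
#' alone.
#'
#' @param x,y numeric vectors, `length(x) == length(y)`, `n >= 3`; `x` must
#'   not be constant.
#' @return an object of class `glm_fit` with named coefficients
#'   `(intercept, slope)`. `log_likelihood` is the Gaussian ML
#'   log-likelihood and `aic = 2k - 2 logLik` with k = 3 (two coefficients
#'   plus the error variance).
#' @export
fit_ols <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (isTRUE(all.equal(var(x), 0)) || var(x) == 0) {
    stop("`x` is constant: slope (and hence RII) undefined", call. = FALSE)
  }
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  s2 <- rss / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_intercept <- sqrt(s2 * (1 / n + xbar^2 / sxx))
  sigma2_ml <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  new_glm_fit(
    coefficients = c(intercept = intercept, slope = slope),
    standard_errors = c(intercept = se_intercept, slope = se_slope),
    log_likelihood = ll, aic = 2 * 3 - 2 * ll,
    converged = TRUE, n_iterations = 0L, family = "gaussian", nobs = n,
    deviance = rss, fitted = intercept + slope * x
  )
}

#' Offset-Poisson regression by iteratively reweighted least squares
#'
#' Maximises the Poisson log-likelihood with log link and a fixed offset
#' (here, log population, turning counts into rates). Standard errors come
#' from the inverse Fisher information at the maximum. Convergence is
#' declared when the relative change in deviance falls below `tol`;
#' non-convergence (including the divergent all-zero-counts case) is
#' flagged on the returned object, never silently dropped.
#'
#' @param design numeric model matrix including the intercept column.
#' @param y nonnegative integer counts.
#' @param offset per-observation log-exposure (default 0).
#' @param tol relative deviance-change tolerance (default 1e-8).
#' @param max_iter IRLS iteration cap (default 100).
#' @return an object of class `glm_fit`; `dispersion` holds the Pearson
#'   dispersion estimate (chi-squared / residual df), used by the
#'   quasi-Poisson sensitivity analysis.
#' @export
fit_poisson_glm <- function(design, y, offset = 0, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(design)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must be nonnegative integer counts", call. = FALSE)
  }
  offset <- rep_len(offset, n)
  if (any(!is.finite(offset))) stop("offsets must be finite", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("design matrix is rank deficient", call. = FALSE)
  }

  ## IRLS: working response z = eta - offset + (y - mu)/mu, weights mu.
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  dev <- poisson_deviance(y, mu)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu
    z <- eta - offset + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) break
    eta <- drop(X %*% beta_new) + offset
    mu <- exp(pmin(eta, 700))
    if (any(mu == 0) || any(!is.finite(mu))) { beta <- beta_new; break }
    dev_new <- poisson_deviance(y, mu)
    beta <- beta_new
    if (is.finite(dev_new) && abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }

  ## a likelihood maximised at infinity (e.g. all counts zero with nonzero
  ## offsets: intercept -> -Inf) stabilises numerically but is no MLE
  if (sum(y) == 0 || max(abs(beta)) > 1e2) converged <- FALSE

  info <- crossprod(X * sqrt(mu))
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  ll <- sum(dpois(y, pmax(mu, 1e-300), log = TRUE))
  pearson <- sum((y - mu)^2 / pmax(mu, 1e-300))
  disp <- if (n > p) pearson / (n - p) else NA_real_
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("b", seq_len(p) - 1L)
  new_glm_fit(
    coefficients = setNames(as.numeric(beta), nm),
    standard_errors = setNames(as.numeric(se), nm),
    log_likelihood = ll, aic = 2 * p - 2 * ll,
    converged = converged, n_iterations = iter, family = "poisson",
    nobs = n, deviance = dev, dispersion = disp, fitted = mu
  )
}

poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu) - (y - mu), mu)
  2 * sum(term)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> family:", x$family,
      "| n =", x$nobs,
      "| logLik =", format(x$log_likelihood, digits = 6),
      "| AIC =", format(x$aic, digits = 6),
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param x a `glm_fit`.
#' @param ... unused.
#' @return one row per model term: `term`, `estimate`, `std.error`,
#'   `statistic` (Wald z), `p.value`.
#' @export
tidy.glm_fit <- function(x, ...) {
  z <- x$coefficients / x$standard_errors
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients),
    std.error = as.numeric(x$standard_errors),
    statistic = as.numeric(z),
    p.value = 2 * pnorm(-abs(as.numeric(z)))
  )
}

#' Glance at a fitted model
#'
#' @param x a `glm_fit`.
#' @param ... unused.
#' @return one-row tibble: `logLik`, `AIC`, `deviance`, `dispersion`,
#'   `nobs`, `converged`, `n_iterations`.
#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood, AIC = x$aic, deviance = x$deviance,
    dispersion = x$dispersion, nobs = x$nobs, converged = x$converged,
    n_iterations = x$n_iterations
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
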