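# Maximum-likelihood Gaussian and Bernoulli regressions plus the association
# statistics built on them. The Gaussian log-likelihood uses the ML variance
# RSS/n (not RSS/(n - p)) so that chained factorizations of a joint Gaussian
# likelihood add exactly; unbiased variance enters only the Wald SEs.

# internal: build a model frame from a named list/data.frame of terms,
# dummy-coding character/factor terms against the alphabetically first level
# and dropping single-level terms (e.g. a constant study site).
build_design <- function(design_terms, n) {
  if (is.null(design_terms) || length(design_terms) == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  design_terms <- as.list(design_terms)
  cols <- list()
  for (nm in names(design_terms)) {
    v <- design_terms[[nm]]
    if (length(v) != n) stop("term '", nm, "' has length ", length(v),
                             ", expected ", n)
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) < 2L) next
      for (l in lev[-1L]) {
        cols[[paste0(nm, l)]] <- as.numeric(as.character(v) == l)
      }
    } else {
      if (length(unique(v)) < 2L) next  # constant numeric carries no signal
      cols[[nm]] <- as.numeric(v)
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow = n, ncol = 0))
  do.call(cbind, cols)
}

# internal: X with intercept, rank check with offender names
design_with_intercept <- function(design_terms, n) {
  X <- cbind(`(Intercept)` = rep(1, n), build_design(design_terms, n))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  X
}

#' Fit a Gaussian linear model by maximum likelihood
#'
#' Ordinary least squares with the exact ML log-likelihood: `sigma2_ml =
#' RSS/n` enters the likelihood, while Wald standard errors use the unbiased
#' variance `RSS/(n - p)`.
#'
#' @param y Numeric outcome.
#' @param design_terms Named list or data.frame of predictors; character or
#'   factor terms are dummy-coded against the alphabetically first level.
#'   An intercept is always included. NULL fits the intercept-only model.
#' @return A `pleio_fit` list: `family`, `coefficients`, `standard_errors`,
#'   `loglik`, `sigma2_ml`, `n_used`, `converged`, `pvalues`.
#' @export
fit_linear <- function(y, design_terms = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y contains NA; subset to complete cases first")
  X <- design_with_intercept(design_terms, n)
  p <- ncol(X)
  if (n <= p) stop("need n > number of design columns (", p, ")")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  if (rss <= 1e-12 * max(1, sum(y^2))) {
    stop("degenerate fit: residual sum of squares is zero")
  }
  sigma2_ml <- rss / n
  loglik <- -(n / 2) * (log(2 * pi * sigma2_ml) + 1)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv) * rss / (n - p))
  coefs <- fit$coefficients
  names(se) <- names(coefs)
  structure(list(family = "gaussian", coefficients = coefs,
                 standard_errors = se, loglik = loglik,
                 sigma2_ml = sigma2_ml, n_used = n, converged = TRUE,
                 pvalues = wald_p(coefs, se)),
            class = "pleio_fit")
}

#' Fit a Bernoulli logistic model by maximum likelihood
#'
#' IRLS (via [stats::glm.fit()]) with convergence to machine-level score
#' tolerance; Wald standard errors from the observed information. Complete
#' or quasi-complete separation is detected and raised as an error.
#'
#' @param y Binary 0/1 outcome.
#' @inheritParams fit_linear
#' @return A `pleio_fit` list (no `sigma2_ml`).
#' @export
fit_logistic <- function(y, design_terms = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y contains NA; subset to complete cases first")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y is constant; cannot fit")
  X <- design_with_intercept(design_terms, n)
  p <- ncol(X)
  if (n <= p) stop("need n > number of design columns (", p, ")")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 50))
  )
  mu <- fit$fitted.values
  sep <- (mu < 1e-10 & y == 0) | (mu > 1 - 1e-10 & y == 1)
  if (mean(sep) > 0 && any(abs(fit$coefficients) > 15)) {
    stop("complete or quasi-complete separation detected")
  }
  if (!fit$converged) {
    stop("logistic fit did not converge in 50 iterations (deviance ",
         format(fit$deviance), ")")
  }
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  W <- mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  se <- sqrt(diag(chol2inv(chol(info))))
  coefs <- fit$coefficients
  names(se) <- names(coefs)
  structure(list(family = "bernoulli", coefficients = coefs,
                 standard_errors = se, loglik = loglik, n_used = n,
                 converged = TRUE, pvalues = wald_p(coefs, se)),
            class = "pleio_fit")
}

#' @export
print.pleio_fit <- function(x, ...) {
  cat(sprintf("<pleio_fit: %s, n = %d, logLik = %.4f>\n",
              x$family, x$n_used, x$loglik))
  print(data.frame(coef = x$coefficients, se = x$standard_errors,
                   p = x$pvalues))
  invisible(x)
}

#' Two-sided Wald p-value
#'
#' @param coefficient Estimate(s).
#' @param se Standard error(s), > 0.
#' @return Two-sided normal-approximation p-value(s).
#' @export
wald_p <- function(coefficient, se) {
  if (any(se <= 0)) stop("se must be > 0")
  2 * stats::pnorm(-abs(coefficient / se))
}

#' Partial correlation of two variables given covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the covariates; confidence interval and p-value from the
#' Fisher z transform with effective degrees of freedom `n - k - 3`, where
#' `k` is the number of covariate columns after dummy coding.
#'
#' @param x,y Numeric vectors.
#' @param covariate_terms Named list/data.frame of covariates (may be NULL,
#'   giving the plain Pearson correlation).
#' @param conf_level Confidence level (default 0.95).
#' @return A data.frame row: estimate, ci_low, ci_high, pvalue, n_used,
#'   adjustment_terms.
#' @export
partial_correlation <- function(x, y, covariate_terms = NULL,
                                conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  Z <- build_design(covariate_terms, n)
  k <- ncol(Z)
  if (n <= k + 2L) stop("need n > number of covariate columns + 2")
  rx <- stats::lm.fit(cbind(1, Z), x)$residuals
  ry <- stats::lm.fit(cbind(1, Z), y)$residuals
  if (stats::sd(rx) < 1e-12 * (abs(mean(x)) + 1) ||
      stats::sd(ry) < 1e-12 * (abs(mean(y)) + 1)) {
    stop("zero-variance residuals; partial correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df_eff <- n - k - 3
  if (df_eff < 1) stop("not enough observations for a Fisher-z interval")
  if (abs(r) >= 1 - 1e-12) {
    warning("degenerate |r| = 1; confidence interval collapsed")
    return(assoc_row(r, r, r, 0, n, names_of(covariate_terms)))
  }
  z <- atanh(r)
  se_z <- 1 / sqrt(df_eff)
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(z / se_z))
  assoc_row(r, tanh(z - crit * se_z), tanh(z + crit * se_z), p, n,
            names_of(covariate_terms))
}

names_of <- function(terms) {
  if (is.null(terms) || !length(terms)) "(none)"
  else paste(names(terms), collapse = "+")
}

assoc_row <- function(est, lo, hi, p, n, adj) {
  data.frame(estimate = est, ci_low = lo, ci_high = hi, pvalue = p,
             n_used = n, adjustment_terms = adj, stringsAsFactors = FALSE)
}

#' Covariate-adjusted group means
#'
#' Cell-means coding: the outcome is regressed on one indicator per group
#' (no overall intercept) plus covariates centered at their sample means, so
#' each group coefficient is that group's mean adjusted to the average
#' covariate profile.
#'
#' @param y Numeric outcome.
#' @param group Group labels (character/factor).
#' @param covariate_terms Named list/data.frame of covariates or NULL.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame, one row per group: group, estimate, ci_low, ci_high,
#'   pvalue, n_used, adjustment_terms.
#' @export
adjusted_group_means <- function(y, group, covariate_terms = NULL,
                                 conf_level = 0.95) {
  y <- as.numeric(y)
  group <- as.character(group)
  n <- length(y)
  if (length(group) != n) stop("y and group must have equal length")
  lev <- sort(unique(group))
  if (length(lev) < 2L) stop("need at least 2 groups")
  counts <- table(group)
  if (any(counts < 2L)) {
    stop("every group needs >= 2 observations; too small: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  G <- vapply(lev, function(l) as.numeric(group == l), numeric(n))
  Z <- build_design(covariate_terms, n)
  if (ncol(Z)) Z <- scale(Z, center = TRUE, scale = FALSE)
  X <- cbind(G, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient adjusted-means design")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv) * rss / (n - ncol(X)))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- fit$coefficients[seq_along(lev)]
  se_g <- se[seq_along(lev)]
  out <- assoc_row(est, est - crit * se_g, est + crit * se_g,
                   wald_p(est, se_g), n, names_of(covariate_terms))
  cbind(data.frame(group = lev, stringsAsFactors = FALSE), out,
        row.names = NULL)
}

#' Ordinal trend test
#'
#' Linear regression of the outcome on the integer-coded ordinal group
#' (treated as a continuous variable) plus covariates; the estimate is the
#' slope per one-category step, with a two-sided Wald p-value.
#'
#' @param y Numeric outcome.
#' @param ordinal_group Integer codes 1..K.
#' @param covariate_terms Named list/data.frame of covariates or NULL.
#' @param conf_level Confidence level (default 0.95).
#' @return Single-row data frame: estimate, ci_low, ci_high, pvalue, n_used,
#'   adjustment_terms.
#' @export
trend_test <- function(y, ordinal_group, covariate_terms = NULL,
                       conf_level = 0.95) {
  ordinal_group <- as.numeric(ordinal_group)
  if (length(unique(ordinal_group)) < 2L) {
    stop("only one ordinal category represented")
  }
  terms <- c(list(.trend = ordinal_group), as.list(covariate_terms))
  fit <- fit_linear(y, terms)
  est <- fit$coefficients[[".trend"]]
  se <- fit$standard_errors[[".trend"]]
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  assoc_row(est, est - crit * se, est + crit * se, wald_p(est, se),
            fit$n_used, names_of(covariate_terms))
}
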