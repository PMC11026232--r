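# Logistic regression engine shared by the association and effector-score
# modules: maximum likelihood by iteratively reweighted least squares.
# Deliberately self-contained so that the model fitted is exactly the one
# documented (no dispersion, no penalisation); stats::glm serves as an
# independent cross-check in the test suite, not as the implementation.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Plain Newton/IRLS maximum likelihood for a binary outcome. Convergence
#' is declared when the log-likelihood improves by less than `tol`
#' (default 1e-10) between iterations; complete or quasi-complete
#' separation is detected through a diverging coefficient norm and
#' reported via `separation = TRUE`, in which case the Wald quantities
#' are meaningless and set to `NA`.
#'
#' @param X numeric design matrix (including the intercept column).
#' @param y binary 0/1 outcome vector.
#' @param max_iter maximum IRLS iterations (default 50).
#' @param tol log-likelihood convergence tolerance (default 1e-10).
#' @return List with `coef`, `vcov`, `se`, `loglik`, `iter`, `converged`,
#'   `separation`, `fitted`, `n`.
#' @export
logit_irls <- function(X, y, max_iter = 50L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("outcome is constant: all individuals have the same usage group")
  }
  if (qr(X)$rank < ncol(X)) {
    stop("singular design matrix: a predictor is constant or collinear")
  }
  p <- ncol(X)
  beta <- rep(0, p)
  ll_old <- -Inf
  separation <- FALSE
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(y * eta - log1pexp(eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      drop(solve(XtW %*% X, XtW %*% z)),
      error = function(e) NULL
    )
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      separation <- TRUE
      break
    }
    if (max(abs(beta_new)) > 30) {
      # fitted log-odds running away: (quasi-)complete separation
      separation <- TRUE
      beta <- beta_new
      break
    }
    beta <- beta_new
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged && !separation && max(abs(beta)) > 10) {
    # ran out of iterations while the coefficients were still drifting
    # outward: treat as (quasi-)separation rather than report a fit
    separation <- TRUE
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(y * eta - log1pexp(eta))
  if (!separation && all(mu < 1e-6 | mu > 1 - 1e-6)) {
    # every fitted probability pinned to 0/1: the likelihood plateaued
    # on a perfectly separating configuration
    separation <- TRUE
    converged <- FALSE
  }
  if (separation) {
    vcov <- matrix(NA_real_, p, p)
  } else {
    w <- pmax(mu * (1 - mu), 1e-12)
    vcov <- solve(t(X * w) %*% X)
  }
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(X)
  list(coef = beta, vcov = vcov, se = se, loglik = ll, iter = iter,
       converged = converged && !separation, separation = separation,
       fitted = mu, n = length(y))
}

# Wald z tests and 95% intervals for an IRLS fit.
wald_table <- function(fit, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coef
  se <- fit$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  cbind(estimate = est, se = se, z = z, p = p,
        lo = est - zq * se, hi = est + zq * se)
}

# Likelihood-ratio test between two nested IRLS fits.
lr_test <- function(fit_full, fit_null, df) {
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
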