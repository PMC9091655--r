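#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an explicit convergence contract:
#' iterate IRLS (with step-halving so the log-likelihood never decreases)
#' until the relative log-likelihood change falls below `tol` or `maxit`
#' iterations are reached.  Used for the reclassification machinery, where
#' the per-patient predicted probabilities and the exact log-likelihood are
#' first-class outputs.
#'
#' @param design numeric matrix or data frame of covariates (no intercept
#'   column; one is added internally).  Column names become coefficient
#'   names.
#' @param outcome 0/1 vector, same length as `nrow(design)`.
#' @param tol relative log-likelihood convergence tolerance (default 1e-10).
#' @param maxit maximum IRLS iterations (default 100).
#' @return Object of class `logit_fit`: list with `coefficients` (named,
#'   intercept first), `vcov`, `log_likelihood`, `ll_trace` (per-iteration
#'   log-likelihood), `n`, `k` (number of estimated parameters including
#'   the intercept), `fitted` (predicted probabilities), `outcome`,
#'   `covariates` (names).
#' @export
fit_logistic <- function(design, outcome, tol = 1e-10, maxit = 100L) {
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(outcome)
  n <- length(y)
  if (nrow(X) != n) stop("fit_logistic: design and outcome sizes differ")
  if (!all(y %in% c(0, 1))) stop("fit_logistic: outcome must be 0/1")
  if (!any(y == 0) || !any(y == 1))
    stop("fit_logistic: outcome must contain both classes")
  X <- cbind(`(Intercept)` = 1, X)
  k <- ncol(X)
  if (n <= k) stop("fit_logistic: need more observations than parameters")

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  beta <- c(stats::qlogis(mean(y)), rep(0, k - 1))
  ll <- loglik(beta)
  trace <- ll
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    w <- pmax(w, 1e-12)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new)))
      stop("fit_logistic: singular design (collinear covariates)")
    ll_new <- loglik(beta_new)
    step <- 1
    while (ll_new < ll && step > 1e-8) {  # step-halving keeps the trace monotone
      step <- step / 2
      beta_new <- beta + step * (fit$coefficients - beta)
      ll_new <- loglik(beta_new)
    }
    beta <- beta_new
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  p <- stats::plogis(drop(X %*% beta))
  if (max(abs(beta)) > 30 || any(p < 1e-10) || any(p > 1 - 1e-10))
    stop("fit_logistic: perfect (or quasi-perfect) separation detected")
  info <- crossprod(X * sqrt(p * (1 - p)))
  structure(list(coefficients = beta,
                 vcov = solve(info),
                 log_likelihood = ll,
                 ll_trace = trace,
                 n = n, k = k,
                 fitted = p,
                 outcome = y,
                 covariates = colnames(X)[-1]),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic fit:", x$n, "patients,", sum(x$outcome), "events\n")
  se <- sqrt(diag(x$vcov))
  tab <- cbind(estimate = x$coefficients, se = se,
               z = x$coefficients / se,
               p = 2 * stats::pnorm(-abs(x$coefficients / se)))
  print(round(tab, 4))
  cat("log-likelihood:", format(x$log_likelihood), "\n")
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
predict.logit_fit <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    return(stats::qlogis(object$fitted))
  }
  X <- cbind(1, as.matrix(newdata)[, object$covariates, drop = FALSE])
  eta <- drop(X %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}
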