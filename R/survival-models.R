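#' Fit a Cox proportional-hazards model
#'
#' Thin structured wrapper around [survival::coxph()] that returns the
#' quantities the reporting pipeline needs: hazard ratios with Wald 95%
#' confidence intervals `exp(beta +/- 1.96 SE)`, per-covariate Wald p-values,
#' the partial log-likelihood and Harrell's concordance.
#'
#' @param design numeric matrix or data frame of covariates.
#' @param times follow-up times (> 0).
#' @param events 0/1 event indicators (at least one event).
#' @param ties tie handling, `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: list with `coefficients`,
#'   `hazard_ratios`, `ci95` (2-column matrix), `se`, `p`,
#'   `partial_log_likelihood`, `concordance`, `n`, `n_events` and the
#'   underlying `model`.
#' @export
fit_cox <- function(design, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(times) | times <= 0))
    stop("fit_cox: follow-up times must be positive")
  if (!any(events == 1)) stop("fit_cox: no events")
  df <- data.frame(.time = as.numeric(times), .event = as.numeric(events))
  df <- cbind(df, as.data.frame(X))
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", colnames(X)),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  if (any(!is.finite(fit$coefficients)))
    stop("fit_cox: did not converge (non-finite coefficients); iterations: ",
         fit$iter)
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  se <- sqrt(diag(fit$var))
  names(se) <- colnames(X)
  structure(list(coefficients = beta,
                 hazard_ratios = exp(beta),
                 ci95 = cbind(lower = exp(beta - 1.96 * se),
                              upper = exp(beta + 1.96 * se)),
                 se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 partial_log_likelihood = fit$loglik[2],
                 concordance = unname(fit$concordance["concordance"]),
                 n = fit$n, n_events = fit$nevent,
                 model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit:", x$n, "patients,", x$n_events, "events, concordance",
      sprintf("%.3f", x$concordance), "\n")
  tab <- cbind(HR = x$hazard_ratios, x$ci95, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Kaplan-Meier curves with a log-rank comparison
#'
#' Product-limit survival estimates per group and the k-sample log-rank
#' test (df = k - 1), via [survival::survfit()] and [survival::survdiff()].
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param groups group labels (>= 2 non-empty groups).
#' @return Object of class `km_logrank`: list with `curves` (per-group data
#'   frames with `time`, `n_risk`, `n_event`, `surv`), `chisq`, `df`,
#'   `p_value`, `n`, `n_events`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("km_logrank: need >= 2 groups")
  if (any(table(groups) == 0L)) stop("km_logrank: empty group")
  df <- data.frame(time = times, event = events, group = groups)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- lapply(stats::setNames(nm = levels(groups)), function(g) {
    sel <- strata == paste0("group=", g)
    data.frame(time = sf$time[sel], n_risk = sf$n.risk[sel],
               n_event = sf$n.event[sel], surv = sf$surv[sel])
  })
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(groups)
  structure(list(curves = curves, chisq = sd$chisq, df = k - 1L,
                 p_value = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE),
                 n = nrow(df), n_events = sum(df$event)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("Log-rank over", length(x$curves), "groups: chi-square =",
      sprintf("%.3f", x$chisq), "df =", x$df,
      "p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.km_logrank <- function(x, col = seq_along(x$curves), ...) {
  graphics::plot(NULL, xlim = c(0, max(unlist(lapply(x$curves, `[[`, "time")))),
                 ylim = c(0, 1), xlab = "time (months)",
                 ylab = "MACE-free survival", ...)
  for (i in seq_along(x$curves)) {
    cv <- x$curves[[i]]
    graphics::lines(c(0, cv$time), c(1, cv$surv), type = "s", col = col[i])
  }
  graphics::legend("bottomleft", legend = names(x$curves), col = col, lty = 1)
  invisible(x)
}
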