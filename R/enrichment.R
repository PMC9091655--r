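#' Likelihood-ratio test between nested logistic fits
#'
#' `chi2 = 2 * (ll_full - ll_reduced)`, df = difference in parameter count,
#' p from the chi-square distribution.  The reduced model's covariates must
#' be a subset of the full model's, fitted on the same patients and outcome.
#'
#' @param full,reduced [fit_logistic()] objects.
#' @return Object of class `lrt_result`: list with `chi2`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "logit_fit"), inherits(reduced, "logit_fit"))
  if (full$n != reduced$n || !isTRUE(all.equal(full$outcome, reduced$outcome)))
    stop("likelihood_ratio_test: models fitted on different patients/outcome")
  if (!all(reduced$covariates %in% full$covariates))
    stop("likelihood_ratio_test: models are not nested")
  chi2 <- 2 * (full$log_likelihood - reduced$log_likelihood)
  chi2 <- max(chi2, 0)  # guard numerical jitter for identical fits
  df <- full$k - reduced$k
  p <- if (df == 0) as.numeric(chi2 <= 0) * 1 else
    stats::pchisq(chi2, df, lower.tail = FALSE)
  if (df == 0 && chi2 <= 0) p <- 1
  structure(list(chi2 = chi2, df = df, p_value = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi-square = %.3f, %d df, p = %s\n",
              x$chi2, x$df, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Small-sample corrected AIC table with Akaike weights
#'
#' For each candidate model: `AICc = -2 ll + 2k + 2k(k+1)/(n-k-1)`,
#' `delta = AICc - min(AICc)`, relative likelihood `exp(-delta/2)` and the
#' Akaike weight (relative likelihoods normalised to sum to one) -- the
#' probability weight of each model being the best in the candidate set.
#'
#' @param models list of [fit_logistic()] objects fitted on the same
#'   patients.
#' @param labels model labels (defaults to covariate formulas).
#' @return Object of class `aicc_table`: a data frame sorted by ascending
#'   AICc with columns `label`, `k`, `log_likelihood`, `aicc`, `delta`,
#'   `rel_likelihood`, `weight`.
#' @export
aicc_table <- function(models, labels = NULL) {
  if (!length(models)) stop("aicc_table: no models")
  ns <- vapply(models, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("aicc_table: models fitted on different numbers of patients")
  if (is.null(labels))
    labels <- vapply(models, function(m)
      paste(m$covariates, collapse = " + "), character(1))
  n <- ns[1]
  k <- vapply(models, `[[`, numeric(1), "k")
  if (any(n - k - 1 <= 0)) stop("aicc_table: n - k - 1 must be positive")
  ll <- vapply(models, `[[`, numeric(1), "log_likelihood")
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  delta <- aicc - min(aicc)
  rel <- exp(-delta / 2)
  out <- data.frame(label = labels, k = k, log_likelihood = ll, aicc = aicc,
                    delta = delta, rel_likelihood = rel,
                    weight = rel / sum(rel), stringsAsFactors = FALSE)
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  class(out) <- c("aicc_table", "data.frame")
  out
}

nri_se_component <- function(up, down, n) {
  sqrt((up + down) / n^2 - (up - down)^2 / n^3)
}

#' Continuous NRI from reclassification counts
#'
#' Category-free net reclassification improvement computed directly from
#' the movement counts: among events, `nri_e = (up_e - down_e) / n_e` (a net
#' upward move in predicted risk is correct for an event); among non-events,
#' `nri_ne = (down_ne - up_ne) / n_ne`; the total NRI is their sum.  The
#' standard error of each component is the asymptotic binomial form
#' `sqrt((up + down)/n^2 - (up - down)^2/n^3)`; the two are combined in
#' quadrature and a two-sided z-test is reported.
#'
#' @param up_e,down_e events moved to a higher / lower predicted risk.
#' @param n_e number of events.
#' @param up_ne,down_ne non-events moved up / down.
#' @param n_ne number of non-events.
#' @return Object of class `reclass_nri`: list with the counts, `tie_e`,
#'   `tie_ne`, the components `nri_e`, `nri_ne`, the total `nri`, `se`,
#'   `z`, `p_value` and a `degenerate` flag (all ties).
#' @export
nri_from_counts <- function(up_e, down_e, n_e, up_ne, down_ne, n_ne) {
  cnt <- c(up_e, down_e, n_e, up_ne, down_ne, n_ne)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("nri_from_counts: counts must be non-negative integers")
  if (up_e + down_e > n_e || up_ne + down_ne > n_ne)
    stop("nri_from_counts: up + down exceeds class size")
  nri_e <- (up_e - down_e) / n_e
  nri_ne <- (down_ne - up_ne) / n_ne
  nri <- nri_e + nri_ne
  se <- sqrt(nri_se_component(up_e, down_e, n_e)^2 +
             nri_se_component(up_ne, down_ne, n_ne)^2)
  degenerate <- (up_e + down_e + up_ne + down_ne) == 0
  z <- if (degenerate) NA_real_ else nri / se
  structure(list(up_e = up_e, down_e = down_e, tie_e = n_e - up_e - down_e,
                 n_e = n_e,
                 up_ne = up_ne, down_ne = down_ne,
                 tie_ne = n_ne - up_ne - down_ne, n_ne = n_ne,
                 nri_e = nri_e, nri_ne = nri_ne, nri = nri,
                 se = se, z = z,
                 p_value = if (degenerate) NA_real_ else
                   2 * stats::pnorm(-abs(z)),
                 degenerate = degenerate),
            class = "reclass_nri")
}

#' Continuous NRI from predicted probabilities
#'
#' Counts risk movements between a base and an updated model (any increase
#' is "up", any decrease "down", exact ties count as no movement but stay
#' in the denominators) and delegates to [nri_from_counts()].
#'
#' @param p_old,p_new predicted event probabilities from the base and the
#'   updated model.
#' @param outcome 0/1 event indicator.
#' @return A `reclass_nri`, see [nri_from_counts()].
#' @export
continuous_nri <- function(p_old, p_new, outcome) {
  stopifnot(length(p_old) == length(p_new),
            length(p_old) == length(outcome))
  y <- as.numeric(outcome)
  if (!any(y == 1) || !any(y == 0))
    stop("continuous_nri: both classes must be present")
  e <- y == 1
  nri_from_counts(sum(p_new[e] > p_old[e]), sum(p_new[e] < p_old[e]), sum(e),
                  sum(p_new[!e] > p_old[!e]), sum(p_new[!e] < p_old[!e]),
                  sum(!e))
}

#' @export
print.reclass_nri <- function(x, ...) {
  cat("Continuous NRI\n")
  cat(sprintf("  events     (n=%d): up %d, down %d, tie %d -> NRIe  = %.3f\n",
              x$n_e, x$up_e, x$down_e, x$tie_e, x$nri_e))
  cat(sprintf("  non-events (n=%d): up %d, down %d, tie %d -> NRIne = %.3f\n",
              x$n_ne, x$up_ne, x$down_ne, x$tie_ne, x$nri_ne))
  cat(sprintf("  total NRI = %.3f (se %.3f, p = %s)\n", x$nri, x$se,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Integrated discrimination improvement
#'
#' IDI is the gain in discrimination slope between two models: among
#' events, the mean rise in predicted risk (`idi_e`); among non-events, the
#' mean fall (`idi_ne`); the total is their sum, identically equal to
#' `[mean_e(p_new) - mean_ne(p_new)] - [mean_e(p_old) - mean_ne(p_old)]`
#' (both formulations are computed and must agree).  The standard error is
#' `sqrt(var_e(d)/n_e + var_ne(d)/n_ne)` with `d = p_new - p_old`, and a
#' two-sided z-test is reported.
#'
#' @inheritParams continuous_nri
#' @return Object of class `reclass_idi`: list with `idi_e`, `idi_ne`,
#'   `idi`, `se`, `z`, `p_value`, `discrimination_slopes` (old and new)
#'   and a `degenerate` flag.
#' @export
idi <- function(p_old, p_new, outcome) {
  stopifnot(length(p_old) == length(p_new),
            length(p_old) == length(outcome))
  y <- as.numeric(outcome)
  if (!any(y == 1) || !any(y == 0))
    stop("idi: both classes must be present")
  e <- y == 1
  d <- p_new - p_old
  idi_e <- mean(d[e])
  idi_ne <- -mean(d[!e])
  total <- idi_e + idi_ne
  slope_old <- mean(p_old[e]) - mean(p_old[!e])
  slope_new <- mean(p_new[e]) - mean(p_new[!e])
  if (abs((slope_new - slope_old) - total) > 1e-9)
    stop("idi: internal inconsistency between component and slope forms")
  se <- sqrt(stats::var(d[e]) / sum(e) + stats::var(d[!e]) / sum(!e))
  degenerate <- se == 0
  z <- if (degenerate) NA_real_ else total / se
  structure(list(idi_e = idi_e, idi_ne = idi_ne, idi = total,
                 se = se, z = z,
                 p_value = if (degenerate) NA_real_ else
                   2 * stats::pnorm(-abs(z)),
                 discrimination_slopes = c(old = slope_old, new = slope_new),
                 degenerate = degenerate),
            class = "reclass_idi")
}

#' @export
print.reclass_idi <- function(x, ...) {
  cat(sprintf("IDI = %.4f (events %.4f + non-events %.4f), se %.4f, p = %s\n",
              x$idi, x$idi_e, x$idi_ne, x$se,
              format.pval(x$p_value, digits = 3)))
  cat(sprintf("  discrimination slope: %.4f -> %.4f\n",
              x$discrimination_slopes["old"], x$discrimination_slopes["new"]))
  invisible(x)
}

# DeLong placement-value variance of the Mann-Whitney AUC
delong_se <- function(score, outcome) {
  x <- score[outcome == 1]
  y <- score[outcome == 0]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  sqrt(stats::var(v10) / m + stats::var(v01) / n)
}

#' ROC analysis with DeLong standard error and Youden cutoff
#'
#' The AUC is the tie-corrected Mann-Whitney statistic (identical to the
#' trapezoidal area under the empirical ROC).  Its standard error uses the
#' DeLong placement-value decomposition by default (Hanley-McNeil available
#' for comparability), with a Wald 95% CI.  The operating point maximising
#' the Youden index `J = sensitivity + specificity - 1` is reported; ties
#' resolve to the lowest threshold.  When follow-up times are supplied,
#' Harrell's C over comparable pairs is added for the survival view.
#'
#' @param score numeric risk score (higher = higher predicted risk).
#' @param outcome 0/1 event indicator.
#' @param times,events optional follow-up times and event indicators for
#'   Harrell's C.
#' @param se_method `"delong"` (default) or `"hanley"`.
#' @return Object of class `roc_curve`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `auc_se`, `ci95`,
#'   `youden_cutoff`, `youden_j`, `sens_at_cutoff`, `spec_at_cutoff`,
#'   `c_statistic` (or `NA`), `degenerate`.
#' @export
roc_analysis <- function(score, outcome, times = NULL, events = NULL,
                         se_method = c("delong", "hanley")) {
  se_method <- match.arg(se_method)
  y <- as.numeric(outcome)
  if (!any(y == 1) || !any(y == 0))
    stop("roc_analysis: both classes must be present")
  m <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(score)  # midranks handle ties
  auc <- (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n0)
  degenerate <- length(unique(score)) == 1L
  thr <- sort(unique(score))
  sens <- vapply(thr, function(t) mean(score[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(score[y == 0] < t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)  # which.max returns the first (lowest threshold) tie
  auc_se <- if (degenerate) NA_real_
  else if (se_method == "delong") delong_se(score, y)
  else {  # Hanley & McNeil
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    sqrt((auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (m * n0))
  }
  cstat <- NA_real_
  if (!is.null(times)) {
    if (is.null(events)) events <- y
    cf <- survival::concordance(survival::Surv(times, events) ~ score,
                                reverse = TRUE)
    cstat <- unname(cf$concordance)
  }
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_se = auc_se,
                 ci95 = c(lower = max(0, auc - 1.96 * auc_se),
                          upper = min(1, auc + 1.96 * auc_se)),
                 youden_cutoff = thr[best], youden_j = j[best],
                 sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
                 c_statistic = cstat, degenerate = degenerate,
                 se_method = se_method),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("AUC = %.3f (se %.3f, 95%% CI %.3f-%.3f)%s\n", x$auc, x$auc_se,
              x$ci95["lower"], x$ci95["upper"],
              if (x$degenerate) " [degenerate: constant score]" else ""))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%, J = %.3f\n",
              x$youden_cutoff, 100 * x$sens_at_cutoff,
              100 * x$spec_at_cutoff, x$youden_j))
  if (!is.na(x$c_statistic))
    cat(sprintf("  Harrell's C = %.3f\n", x$c_statistic))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  fpr <- c(1, 1 - x$specificity, 0)
  tpr <- c(1, x$sensitivity, 0)
  graphics::plot(fpr, tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("ROC, AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Incremental value of adding a marker to a base risk model
#'
#' The central fitting function of the package.  Fits nested logistic
#' models for a binary outcome -- base score alone versus base score plus
#' one added marker -- and quantifies the increment on every axis used in
#' prognostic-enrichment studies: nested likelihood-ratio test, AICc and
#' Akaike weights, continuous NRI, IDI, and ROC/AUC for both models (plus
#' the marker alone).  When follow-up times are given, Harrell's C from the
#' survival view is attached to each ROC block.
#'
#' @param data data frame (e.g. a `cohort_table`).
#' @param base column name of the base risk score (default
#'   `"grace_score"`).
#' @param added column name of the added marker (e.g. `"dc_ms"` or
#'   `"lf_hf"`).
#' @param outcome column name of the 0/1 outcome (default `"event"`).
#' @param times optional column name of follow-up times for Harrell's C.
#' @return Object of class `model_enrichment`: list with `fits` (base,
#'   full, marker-only), `lrt`, `aicc`, `nri`, `idi`, `roc` (list: base,
#'   marker, full), `base`, `added`, `n`, `n_events`.
#' @examples
#' \donttest{
#' cg <- cohort_gen_params(n_patients = 150, seed = 11)
#' coh <- generate_cohort(cg)
#' enr <- model_enrichment(coh$cohort, base = "grace_score", added = "dc_ms")
#' print(enr)
#' }
#' @export
model_enrichment <- function(data, base = "grace_score", added,
                             outcome = "event", times = "time_months") {
  for (col in c(base, added, outcome))
    if (!col %in% names(data))
      stop("model_enrichment: column ", sQuote(col), " not found")
  keep <- stats::complete.cases(data[, c(base, added, outcome)])
  d <- data[keep, ]
  y <- d[[outcome]]
  tt <- if (!is.null(times) && times %in% names(d)) d[[times]] else NULL
  m_base <- fit_logistic(d[, base, drop = FALSE], y)
  m_full <- fit_logistic(d[, c(base, added)], y)
  m_marker <- fit_logistic(d[, added, drop = FALSE], y)
  roc_of <- function(fit) roc_analysis(fit$fitted, y, times = tt, events = y)
  structure(list(
    fits = list(base = m_base, full = m_full, marker = m_marker),
    lrt = likelihood_ratio_test(m_full, m_base),
    aicc = aicc_table(list(m_base, m_full),
                      labels = c(base, paste(base, "+", added))),
    nri = continuous_nri(m_base$fitted, m_full$fitted, y),
    idi = idi(m_base$fitted, m_full$fitted, y),
    roc = list(base = roc_of(m_base), marker = roc_of(m_marker),
               full = roc_of(m_full)),
    base = base, added = added, n = m_base$n, n_events = sum(y)),
    class = "model_enrichment")
}

#' @export
print.model_enrichment <- function(x, ...) {
  cat("Incremental value of", sQuote(x$added), "over", sQuote(x$base),
      sprintf("(n = %d, events = %d)\n", x$n, x$n_events))
  print(x$lrt)
  cat(sprintf("AUC: %.3f (%s) -> %.3f (+%s)\n", x$roc$base$auc, x$base,
              x$roc$full$auc, x$added))
  print(x$nri)
  print(x$idi)
  invisible(x)
}

#' @export
summary.model_enrichment <- function(object, ...) {
  cat("== Model enrichment summary ==\n")
  print(object)
  cat("\nAICc table:\n")
  print(as.data.frame(object$aicc), digits = 6)
  cat("\nROC blocks:\n")
  for (nm in names(object$roc)) {
    cat("[", nm, "] ", sep = "")
    print(object$roc[[nm]])
  }
  invisible(object)
}
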