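sim_logit_cohort <- function(n, b_base, b_marker, rate = 41 / 323) {
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  a <- uniroot(function(a) mean(plogis(a + b_base * x1 + b_marker * x2)) - rate,
               c(-10, 2))$root
  y <- rbinom(n, 1, plogis(a + b_base * x1 + b_marker * x2))
  data.frame(base = x1, marker = x2, y = y)
}

test_that("the likelihood-ratio test behaves at the boundary and under power", {
  set.seed(70)
  d <- sim_logit_cohort(500, 0.8, 0.7)
  full <- fit_logistic(d[, c("base", "marker")], d$y)
  reduced <- fit_logistic(d[, "base", drop = FALSE], d$y)
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 1L)
  expect_gt(lrt$chi2, 0)

  same <- likelihood_ratio_test(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  # strong effect at large n: decisive
  d2 <- sim_logit_cohort(5000, 0.8, 0.9)
  f2 <- fit_logistic(d2[, c("base", "marker")], d2$y)
  r2 <- fit_logistic(d2[, "base", drop = FALSE], d2$y)
  expect_lt(likelihood_ratio_test(f2, r2)$p_value, 1e-6)

  other <- fit_logistic(d[, "marker", drop = FALSE], d$y)
  expect_error(likelihood_ratio_test(reduced, other), "not nested")
  short <- fit_logistic(d[1:400, c("base", "marker")], d$y[1:400])
  expect_error(likelihood_ratio_test(short, reduced), "different patients")
})

test_that("the LRT null distribution holds its size for a noise marker", {
  set.seed(71)
  R <- 400
  rej <- logical(R)
  for (r in seq_len(R)) {
    d <- sim_logit_cohort(1000, 0.8, 0, rate = 0.2)
    full <- fit_logistic(d[, c("base", "marker")], d$y)
    reduced <- fit_logistic(d[, "base", drop = FALSE], d$y)
    rej[r] <- likelihood_ratio_test(full, reduced)$p_value < 0.05
  }
  band <- 3 * sqrt(0.05 * 0.95 / R)
  expect_gt(mean(rej), 0.05 - band)
  expect_lt(mean(rej), 0.05 + band)
})

test_that("AICc, delta and Akaike weights follow their closed forms", {
  mk <- function(ll, k, n) structure(list(log_likelihood = ll, k = k, n = n),
                                     class = "logit_fit")
  single <- aicc_table(list(mk(-100, 2, 300)), labels = "only")
  expect_equal(single$delta, 0)
  expect_equal(single$weight, 1)

  # two models, equal k, log-likelihood difference 5
  two <- aicc_table(list(mk(-100, 3, 300), mk(-105, 3, 300)),
                    labels = c("good", "bad"))
  expect_equal(two$delta, c(0, 10))
  expect_equal(two$weight[1] / two$weight[2], exp(5), tolerance = 1e-12)

  # three models, hand-computed AICc
  models <- list(mk(-390.72, 2, 323), mk(-390.5535, 3, 323),
                 mk(-386.1065, 3, 323))
  tab <- aicc_table(models, labels = c("m1", "m2", "m3"))
  hand_aicc <- function(ll, k, n) -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(sort(tab$aicc),
               sort(c(hand_aicc(-390.72, 2, 323), hand_aicc(-390.5535, 3, 323),
                      hand_aicc(-386.1065, 3, 323))), tolerance = 1e-9)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$delta[1], 0)
  expect_equal(which.max(tab$weight), 1L)  # sorted ascending by AICc
  expect_true(all(diff(tab$aicc) >= 0))

  expect_error(aicc_table(list(mk(-10, 5, 6))), "n - k - 1")
})

test_that("NRI from counts matches its formulas and degenerates cleanly", {
  r <- nri_from_counts(22, 19, 41, 123, 159, 282)
  expect_equal(r$nri_e, (22 - 19) / 41)
  expect_equal(r$nri_ne, (159 - 123) / 282)
  expect_identical(r$nri, r$nri_e + r$nri_ne)
  expect_equal(r$tie_e, 0)
  expect_equal(r$tie_ne, 0)
  se_e <- sqrt(41 / 41^2 - (22 - 19)^2 / 41^3)
  se_ne <- sqrt(282 / 282^2 - (123 - 159)^2 / 282^3)
  expect_equal(r$se, sqrt(se_e^2 + se_ne^2), tolerance = 1e-12)

  zero <- nri_from_counts(0, 0, 10, 0, 0, 10)
  expect_equal(zero$nri, 0)
  expect_true(zero$degenerate)
  expect_error(nri_from_counts(-1, 0, 10, 0, 0, 10), "non-negative")
  expect_error(nri_from_counts(6, 6, 10, 0, 0, 10), "exceeds")
})

test_that("probability-based NRI equals the count route on its own counts", {
  set.seed(80)
  for (i in 1:20) {
    n <- 120
    y <- rbinom(n, 1, 0.3)
    if (!any(y == 1) || !any(y == 0)) next
    p_old <- runif(n)
    p_new <- p_old
    move <- sample(n, 60)
    p_new[move] <- p_old[move] + runif(60, -0.2, 0.2)
    tie <- sample(n, 20)                  # force exact ties
    p_new[tie] <- p_old[tie]
    r1 <- continuous_nri(p_old, p_new, y)
    r2 <- nri_from_counts(r1$up_e, r1$down_e, r1$n_e,
                          r1$up_ne, r1$down_ne, r1$n_ne)
    expect_identical(r1$nri, r2$nri)
    expect_identical(r1$se, r2$se)
    expect_equal(r1$tie_e + r1$tie_ne, sum(p_new == p_old))
  }
  p <- runif(50)
  y0 <- rep(c(0, 1), 25)
  expect_equal(continuous_nri(p, p, y0)$nri, 0)
})

test_that("IDI matches the hand example and the slope identity", {
  p_old <- c(0.2, 0.4, 0.3, 0.1)
  p_new <- c(0.3, 0.5, 0.2, 0.1)
  y <- c(1, 1, 0, 0)
  r <- idi(p_old, p_new, y)
  expect_equal(r$idi_e, 0.10)
  expect_equal(r$idi_ne, 0.05)
  expect_equal(r$idi, 0.15)
  expect_equal(unname(diff(r$discrimination_slopes)), r$idi, tolerance = 1e-12)

  null <- idi(p_old, p_old, y)
  expect_equal(null$idi, 0)
  expect_true(null$degenerate)

  set.seed(81)
  for (i in 1:10) {
    n <- 200
    yy <- rbinom(n, 1, 0.25)
    po <- runif(n); pn <- plogis(qlogis(po) + rnorm(n, 0, 0.3))
    rr <- idi(po, pn, yy)
    slope_diff <- (mean(pn[yy == 1]) - mean(pn[yy == 0])) -
      (mean(po[yy == 1]) - mean(po[yy == 0]))
    expect_equal(rr$idi, slope_diff, tolerance = 1e-12)
  }
})

test_that("ROC analysis: AUC equals the trapezoid oracle and pROC agrees", {
  set.seed(90)
  n <- 300
  y <- rbinom(n, 1, 0.3)
  score <- round(rnorm(n) + y, 1)       # rounding creates ties
  r <- roc_analysis(score, y)
  expect_equal(r$auc, oracle_trapezoid_auc(score, y), tolerance = 1e-10)

  pr <- pROC::roc(y, score, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  expect_equal(r$auc_se, sqrt(pROC::var(pr)), tolerance = 1e-8)

  # perfect separation
  perf <- roc_analysis(c(rep(0, 10), rep(1, 10)), rep(c(0, 1), each = 10))
  expect_equal(perf$auc, 1)
  expect_equal(perf$youden_j, 1)

  # random score: AUC near 1/2
  y2 <- rbinom(2000, 1, 0.3)
  r2 <- roc_analysis(rnorm(2000), y2)
  expect_lt(abs(r2$auc - 0.5), 0.03)

  # constant score degenerates to 0.5 with a flag
  rc <- roc_analysis(rep(1, 100), rbinom(100, 1, 0.4))
  expect_equal(rc$auc, 0.5)
  expect_true(rc$degenerate)

  # sensitivity is non-increasing in the threshold; J is the printed identity
  expect_true(all(diff(r$sensitivity) <= 1e-12))
  expect_equal(r$youden_j, r$sens_at_cutoff + r$spec_at_cutoff - 1,
               tolerance = 1e-12)
})

test_that("an informative added marker yields positive NRI and IDI", {
  # effects sized to the AUC gain seen when an autonomic marker joins a
  # clinical score (0.71 -> 0.765)
  set.seed(91)
  R <- 40
  pos <- logical(R)
  for (r in seq_len(R)) {
    d <- sim_logit_cohort(323, 0.83, 0.70)
    if (sum(d$y) < 5) next
    e <- model_enrichment(d, base = "base", added = "marker", outcome = "y",
                          times = NULL)
    pos[r] <- e$nri$nri > 0 && e$idi$idi > 0
  }
  expect_gte(mean(pos), 0.9)
})

test_that("model_enrichment assembles a coherent object", {
  set.seed(92)
  sc <- generate_cohort(cohort_gen_params(n_patients = 150, seed = 92,
                                          rr_duration = 400))
  e <- model_enrichment(sc$cohort, base = "grace_score", added = "dc_ms")
  expect_s3_class(e, "model_enrichment")
  expect_equal(e$lrt$chi2,
               2 * (e$fits$full$log_likelihood - e$fits$base$log_likelihood),
               tolerance = 1e-10)
  expect_equal(sum(e$aicc$weight), 1, tolerance = 1e-12)
  expect_equal(e$nri$n_e + e$nri$n_ne, e$n)
  expect_true(is.finite(e$roc$full$c_statistic))
  expect_output(print(e), "Incremental value")
})
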