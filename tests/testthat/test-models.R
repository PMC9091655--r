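test_that("logistic IRLS recovers closed forms and matches glm", {
  set.seed(30)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.3)           # independent of x
  fit <- fit_logistic(cbind(noise = x), y)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients["noise"]) / se["noise"], 3)
  # single binary covariate: saturated closed form is exact
  g0 <- rbinom(n, 1, 0.5)
  fit0 <- fit_logistic(cbind(g = g0), y)
  expect_equal(unname(fit0$coefficients["(Intercept)"]),
               qlogis(mean(y[g0 == 0])), tolerance = 1e-8)

  # single binary covariate: slope equals the 2x2 log odds ratio
  g <- rbinom(n, 1, 0.5)
  y2 <- rbinom(n, 1, ifelse(g == 1, 0.45, 0.2))
  tab <- table(g, y2)
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  fit2 <- fit_logistic(cbind(g = g), y2)
  expect_equal(unname(fit2$coefficients["g"]), lor, tolerance = 1e-8)

  # agreement with the glm oracle on a multi-covariate fit
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y3 <- rbinom(n, 1, plogis(-1 + 0.5 * X[, "a"] - 0.8 * X[, "b"]))
  fit3 <- fit_logistic(X, y3)
  gl <- glm(y3 ~ X, family = binomial)
  expect_equal(unname(fit3$coefficients), unname(coef(gl)), tolerance = 1e-7)
  expect_equal(fit3$log_likelihood, as.numeric(logLik(gl)), tolerance = 1e-9)
})

test_that("logistic log-likelihood trace is monotone and recovery works", {
  set.seed(31)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.7 * x))
  fit <- fit_logistic(cbind(x = x), y)
  expect_true(all(diff(fit$ll_trace) >= -1e-10))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients["(Intercept)"] + 2), 3 * se[1])
  expect_lt(abs(fit$coefficients["x"] - 0.7), 3 * se[2])
})

test_that("perfect separation raises instead of diverging silently", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(cbind(x = x), y), "separation")
  expect_error(fit_logistic(cbind(x = x), rep(1, 40)), "both classes")
})

test_that("Cox fits recover known hazard ratios", {
  set.seed(40)
  n <- 2000
  g <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = 0.05 * 2^g)        # true HR = 2 between groups
  ev <- as.integer(tt <= 36)
  tt <- pmin(tt, 36)
  fit <- fit_cox(cbind(group = g), tt, ev)
  expect_lt(abs(fit$coefficients["group"] - log(2)) / fit$se["group"], 3)
  expect_true(fit$ci95["group", "lower"] < fit$hazard_ratios["group"] &
              fit$hazard_ratios["group"] < fit$ci95["group", "upper"])

  # null covariate: HR ~ 1, CI covers 1
  z <- rnorm(n)
  fit0 <- fit_cox(cbind(z = z), tt, ev)
  expect_true(fit0$ci95["z", "lower"] < 1 & 1 < fit0$ci95["z", "upper"])

  # duplicating the data leaves beta identical and shrinks SE by sqrt(2)
  fit2 <- fit_cox(cbind(group = c(g, g)), c(tt, tt), c(ev, ev))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-3)
  expect_equal(unname(fit$se["group"] / fit2$se["group"]), sqrt(2), tolerance = 0.01)

  expect_error(fit_cox(cbind(z = z), tt, rep(0, n)), "no events")
  expect_error(fit_cox(cbind(z = z), -tt, ev), "positive")
})

test_that("Kaplan-Meier steps match the hand product-limit and log-rank behaves", {
  # 5 patients: event times 2, 4 (censored), 5, 7 (censored), 8
  tt <- c(2, 4, 5, 7, 8)
  ev <- c(1, 0, 1, 0, 1)
  km <- km_logrank(c(tt, tt), c(ev, ev), rep(c("A", "B"), each = 5))
  surv_A <- km$curves$A$surv[km$curves$A$n_event > 0]
  expect_equal(surv_A, c(1 - 1/5, (1 - 1/5) * (1 - 1/3),
                         (1 - 1/5) * (1 - 1/3) * (1 - 1/1)))
  # identical groups: chi-square ~ 0
  expect_lt(km$chisq, 1e-8)
  expect_equal(km$df, 1L)

  # stochastically ordered groups: curves ordered, chi-square > 0
  set.seed(41)
  t1 <- rexp(150, 0.1); t2 <- rexp(150, 0.3)
  km2 <- km_logrank(c(t1, t2), rep(1, 300), rep(c("slow", "fast"), each = 150))
  expect_gt(km2$chisq, 0)
  m1 <- min(km2$curves$slow$surv[km2$curves$slow$time <= 5])
  m2 <- min(km2$curves$fast$surv[km2$curves$fast$time <= 5])
  expect_gt(m1, m2)
  expect_error(km_logrank(t1, rep(1, 150), rep("only", 150)), "2 groups")
})

test_that("categorical tests reproduce closed forms and the brute-force G", {
  # a table equal to its own expectation gives zero for both statistics
  even <- rbind(c(20, 40), c(10, 20))
  expect_lt(pearson_chi2(even)$statistic, 1e-12)
  expect_lt(g_test(even)$statistic, 1e-12)

  set.seed(50)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 30) + 1, nrow = 3)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    g_oracle <- 2 * sum(ifelse(tab == 0, 0, tab * log(tab / E)))
    expect_equal(g_test(tab)$statistic, g_oracle, tolerance = 1e-12)
    chi_oracle <- sum((tab - E)^2 / E)
    expect_equal(pearson_chi2(tab)$statistic, chi_oracle, tolerance = 1e-10)
  }
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(g_test(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("Pearson and G agree asymptotically on well-filled tables", {
  set.seed(51)
  for (i in 1:20) {
    rowp <- c(0.5, 0.5); colp <- c(0.4, 0.3, 0.3)
    tab <- matrix(stats::rmultinom(1, 2000, outer(rowp, colp)), nrow = 2)
    if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 50)) next
    chi <- pearson_chi2(tab)$statistic
    g <- g_test(tab)$statistic
    expect_lt(abs(chi - g), 0.1 * max(chi, g, 1))
  }
})

test_that("group comparisons dispatch correctly and match hand ranks", {
  set.seed(60)
  a <- rnorm(50); b <- rnorm(50, 5)
  r <- group_comparison(c(a, b), rep(c("a", "b"), each = 50), "anova")
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$method, "anova")

  # identical groups sit at the null centre
  same <- rep(1:25, 2)
  r0 <- group_comparison(same, rep(c("x", "y"), each = 25), "kruskal")
  expect_gt(r0$p_value, 0.9)

  # Kruskal-Wallis H from hand-computed midranks on 6 values
  vals <- c(1, 3, 5, 2, 4, 6)
  grp <- rep(c("g1", "g2"), each = 3)
  rk <- rank(vals)
  n <- 6
  H <- 12 / (n * (n + 1)) * sum(tapply(rk, grp, function(v)
    length(v) * (mean(v) - (n + 1) / 2)^2))
  rh <- group_comparison(vals, grp, "kruskal")
  expect_equal(rh$statistic, H, tolerance = 1e-12)

  rw <- group_comparison(c(a, b), rep(c("a", "b"), each = 50), "mann_whitney")
  expect_lt(rw$p_value, 1e-6)
  expect_error(group_comparison(c(a, b, rnorm(10)),
                                c(rep(c("a", "b"), each = 50), rep("c", 10)),
                                "mann_whitney"), "2 groups")
})
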