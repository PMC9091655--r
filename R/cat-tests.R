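# Categorical and group-comparison tests used by the baseline table.

check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table: counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table: zero margin")
  tab
}

test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", sprintf("%.4f", x$statistic),
      if (!is.null(x$df) && !is.na(x$df)) paste0(", df = ", round(x$df, 2)),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic on an r x c table of observed counts, without
#' continuity correction, with df = (r-1)(c-1).
#'
#' @param tab matrix (or table) of non-negative integer counts with positive
#'   margins.
#' @return A `test_result` with fields `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- check_table(tab)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(res$statistic, res$parameter, res$p.value, "pearson_chi2")
}

#' Likelihood-ratio (G) test of independence
#'
#' `G = 2 * sum O * ln(O / E)` over cells, with cells where `O = 0`
#' contributing zero, `E` the usual product-margin expectation and
#' df = (r-1)(c-1).  Reported alongside the Pearson statistic for every
#' categorical baseline row, because the two can differ materially on
#' sparse tables.
#'
#' @inheritParams pearson_chi2
#' @return A `test_result`.
#' @export
g_test <- function(tab) {
  tab <- check_table(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  terms <- ifelse(tab == 0, 0, tab * log(tab / E))
  G <- 2 * sum(terms)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  test_result(G, df, stats::pchisq(G, df, lower.tail = FALSE), "g_test")
}

#' Compare a continuous variable across groups
#'
#' Dispatches to one-way ANOVA, the Kruskal-Wallis test or the
#' Mann-Whitney U test (two groups only).  Ties in the rank tests are
#' handled with midranks by the underlying base R implementations.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param method `"anova"`, `"kruskal"` or `"mann_whitney"`.
#' @return A `test_result`.
#' @export
group_comparison <- function(values, groups,
                             method = c("anova", "kruskal", "mann_whitney")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  keep <- is.finite(values)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L || any(table(groups) == 0L))
    stop("group_comparison: need >= 2 non-empty groups")
  switch(method,
    anova = {
      av <- stats::anova(stats::lm(values ~ groups))
      test_result(av$`F value`[1], av$Df[1], av$`Pr(>F)`[1], "anova")
    },
    kruskal = {
      kt <- stats::kruskal.test(values, groups)
      test_result(kt$statistic, kt$parameter, kt$p.value, "kruskal")
    },
    mann_whitney = {
      if (nlevels(groups) != 2L)
        stop("group_comparison: mann_whitney requires exactly 2 groups")
      wt <- suppressWarnings(stats::wilcox.test(values ~ groups, exact = FALSE))
      test_result(wt$statistic, NA_real_, wt$p.value, "mann_whitney")
    })
}
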