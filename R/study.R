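# Full study pipeline: per-patient signal metrics -> stratification ->
# baseline table -> KM/log-rank -> Cox screen -> model enrichment -> report.

#' Baseline characteristics table by group
#'
#' One row per variable, compared across groups.  Continuous variables pass
#' a per-group Shapiro-Wilk normality gate (alpha = 0.05, all groups must
#' pass): normal variables are summarised as mean (SD) and compared by
#' one-way ANOVA, the rest as median (IQR) and compared by Kruskal-Wallis.
#' Categorical variables are summarised as counts (%) and compared with
#' *both* the Pearson chi-square and the likelihood-ratio G statistic,
#' because the two can disagree materially on sparse tables.
#'
#' @param cohort data frame.
#' @param group column name of the grouping factor (default `"dc_group"`).
#' @param variables columns to tabulate; defaults to every column except
#'   identifiers, outcome bookkeeping and the grouping itself.
#' @return Data frame of class `baseline_table` with one row per variable:
#'   `variable`, `type`, per-group summaries, `test`, `statistic`, `df`,
#'   `p_value`, `statistic_g`, `p_value_g` (categoricals), `degenerate`.
#' @export
baseline_table <- function(cohort, group = "dc_group", variables = NULL) {
  g <- droplevels(as.factor(cohort[[group]]))
  if (nlevels(g) < 2L) stop("baseline_table: need >= 2 non-empty groups")
  if (is.null(variables))
    variables <- setdiff(names(cohort), c("id", group, "event_type",
                                          "time_months"))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    base <- data.frame(variable = v, stringsAsFactors = FALSE)
    is_cat <- is.character(x) || is.factor(x) || is.logical(x) ||
      (is.numeric(x) && length(unique(x[is.finite(x)])) <= 2)
    if (all(is.na(x))) {
      base$type <- "missing"
      base$test <- NA_character_; base$statistic <- NA_real_
      base$df <- NA_real_; base$p_value <- NA_real_
      base$statistic_g <- NA_real_; base$p_value_g <- NA_real_
      base$degenerate <- TRUE
      for (lev in levels(g)) base[[paste0("grp_", lev)]] <- NA_character_
      return(base)
    }
    if (is_cat) {
      xf <- as.factor(x)
      tab <- table(xf, g)
      for (lev in levels(g)) {
        cnt <- tab[, lev]
        base[[paste0("grp_", lev)]] <- paste(
          sprintf("%s:%d(%.1f%%)", rownames(tab), cnt,
                  100 * cnt / sum(cnt)), collapse = " ")
      }
      base$type <- "categorical"
      degen <- nrow(tab) < 2 || any(colSums(tab) == 0) || any(rowSums(tab) == 0)
      if (degen) {
        base$test <- "chi2"; base$statistic <- NA_real_; base$df <- NA_real_
        base$p_value <- NA_real_
        base$statistic_g <- NA_real_; base$p_value_g <- NA_real_
        base$degenerate <- TRUE
      } else {
        pc <- pearson_chi2(tab); gt <- g_test(tab)
        base$test <- "chi2"
        base$statistic <- pc$statistic; base$df <- pc$df
        base$p_value <- pc$p_value
        base$statistic_g <- gt$statistic; base$p_value_g <- gt$p_value
        base$degenerate <- FALSE
      }
    } else {
      xs <- split(x, g)
      constant <- stats::sd(x, na.rm = TRUE) == 0
      normal_ok <- !constant && all(vapply(xs, function(v2) {
        v2 <- v2[is.finite(v2)]
        if (length(v2) < 3 || stats::sd(v2) == 0) return(FALSE)
        if (length(v2) > 5000) v2 <- v2[seq_len(5000)]
        stats::shapiro.test(v2)$p.value > 0.05
      }, logical(1)))
      for (lev in levels(g)) {
        v2 <- xs[[lev]]
        base[[paste0("grp_", lev)]] <- if (normal_ok)
          sprintf("%.2f (%.2f)", mean(v2, na.rm = TRUE), stats::sd(v2, na.rm = TRUE))
        else
          sprintf("%.2f (%.2f, %.2f)", stats::median(v2, na.rm = TRUE),
                  stats::quantile(v2, 0.25, na.rm = TRUE),
                  stats::quantile(v2, 0.75, na.rm = TRUE))
      }
      base$type <- "continuous"
      if (constant) {
        base$test <- NA_character_; base$statistic <- NA_real_
        base$df <- NA_real_; base$p_value <- NA_real_
        base$statistic_g <- NA_real_; base$p_value_g <- NA_real_
        base$degenerate <- TRUE
      } else {
        tr <- group_comparison(x, g, if (normal_ok) "anova" else "kruskal")
        base$test <- tr$method
        base$statistic <- tr$statistic; base$df <- tr$df
        base$p_value <- tr$p_value
        base$statistic_g <- NA_real_; base$p_value_g <- NA_real_
        base$degenerate <- FALSE
      }
    }
    base
  })
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  out <- do.call(rbind, rows)
  class(out) <- c("baseline_table", "data.frame")
  out
}

cox_screen <- function(cohort, covariates, alpha = 0.05, ties = "efron") {
  uni <- do.call(rbind, lapply(covariates, function(v) {
    fit <- tryCatch(fit_cox(cohort[, v, drop = FALSE], cohort$time_months,
                            cohort$event, ties = ties),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(covariate = v, hr = NA, lower = NA, upper = NA,
                        p_value = NA, stringsAsFactors = FALSE))
    data.frame(covariate = v, hr = unname(fit$hazard_ratios),
               lower = unname(fit$ci95[, "lower"]),
               upper = unname(fit$ci95[, "upper"]),
               p_value = unname(fit$p), stringsAsFactors = FALSE)
  }))
  selected <- uni$covariate[!is.na(uni$p_value) & uni$p_value < alpha]
  multi <- NULL
  if (length(selected) >= 1) {
    fit <- fit_cox(cohort[, selected, drop = FALSE], cohort$time_months,
                   cohort$event, ties = ties)
    multi <- data.frame(covariate = selected,
                        hr = unname(fit$hazard_ratios),
                        lower = unname(fit$ci95[, "lower"]),
                        upper = unname(fit$ci95[, "upper"]),
                        p_value = unname(fit$p),
                        concordance = fit$concordance,
                        stringsAsFactors = FALSE)
  }
  list(univariate = uni, selected = selected, multivariate = multi)
}

#' Run the full study pipeline
#'
#' Executes, in order: deceleration capacity and the HRV panel per patient
#' (when RR files are supplied), risk stratification at the 2.5/4.5 ms DC
#' cutpoints, the baseline characteristics table, Kaplan-Meier curves with
#' a log-rank test across DC groups, a univariate Cox screen over the
#' configured covariates followed by a multivariate Cox model on the
#' covariates passing the screen, the model-enrichment comparison of the
#' base score alone versus base score plus each marker, and (when a
#' `presentation` column exists) per-presentation subgroup Cox analyses.
#'
#' @param config named list or path to a YAML file.  Recognised fields:
#'   `cohort_file` (CSV path) or pass `cohort` directly; `rr_dir`
#'   (directory of per-patient `<id>.csv` RR files; optional when the
#'   cohort already carries `dc_ms`/HRV columns); `out_dir` (optional,
#'   written via [write_report()]); `dc_thresholds` (default
#'   `c(2.5, 4.5)`); `nn_bounds`, `nn_max_rel_change`,
#'   `anchor_max_rel_increase`; `screen_alpha` (default 0.05);
#'   `base_score` (default `"grace_score"`); `markers` (default
#'   `c("dc_ms", "lf_hf")`); `covariates` (default: every numeric cohort
#'   column plus the computed markers, except bookkeeping columns).
#' @param cohort optionally, an in-memory cohort data frame (overrides
#'   `config$cohort_file`).
#' @return Object of class `study_report`; see [write_report()] for the
#'   serialised layout.
#' @export
run_study <- function(config = list(), cohort = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    rr_dir = NULL, cohort_file = NULL, out_dir = NULL,
    dc_thresholds = c(2.5, 4.5), nn_bounds = c(300, 2000),
    nn_max_rel_change = 0.2, anchor_max_rel_increase = 0.05,
    screen_alpha = 0.05, base_score = "grace_score",
    markers = c("dc_ms", "lf_hf"), covariates = NULL), config)

  if (is.null(cohort)) {
    if (is.null(cfg$cohort_file)) stop("run_study: no cohort supplied")
    cohort <- read_cohort_table(cfg$cohort_file)
  } else cohort <- as_cohort_table(as.data.frame(cohort))

  if (!is.null(cfg$rr_dir)) {
    pcfg <- prsa_config(max_relative_increase = cfg$anchor_max_rel_increase)
    met <- lapply(cohort$id, function(pid) {
      path <- file.path(cfg$rr_dir, paste0(pid, ".csv"))
      if (!file.exists(path))
        stop("run_study: [signal stage, patient ", pid, "] RR file not found: ",
             path)
      tryCatch({
        rr <- read_rr_file(path, patient_id = pid)
        prof <- deceleration_capacity(rr, cfg = pcfg,
                                      bounds = cfg$nn_bounds,
                                      max_rel_change = cfg$nn_max_rel_change)
        pan <- hrv_panel(rr, bounds = cfg$nn_bounds,
                         max_rel_change = cfg$nn_max_rel_change)
        data.frame(dc_ms = prof$dc_ms, anchor_count = prof$anchor_count,
                   sdnn = pan$time$sdnn, sdann = pan$time$sdann,
                   rmssd = pan$time$rmssd, pnn50 = pan$time$pnn50,
                   mean_hr = pan$time$mean_hr,
                   lf = pan$freq$lf, hf = pan$freq$hf, lf_hf = pan$freq$lf_hf)
      }, error = function(e)
        stop("run_study: [signal stage, patient ", pid, "] ",
             conditionMessage(e), call. = FALSE))
    })
    met <- do.call(rbind, met)
    cohort <- cbind(cohort[setdiff(names(cohort), names(met))], met)
  }
  if (!"dc_ms" %in% names(cohort))
    stop("run_study: cohort has no dc_ms and no rr_dir was given")
  cohort$dc_group <- as.character(
    dc_risk_group(cohort$dc_ms, thresholds = cfg$dc_thresholds))

  baseline <- baseline_table(cohort)
  km <- km_logrank(cohort$time_months, cohort$event,
                   factor(cohort$dc_group,
                          levels = c("low", "intermediate", "high")))

  if (is.null(cfg$covariates)) {
    skip <- c("id", "event", "time_months", "event_type", "dc_group",
              "grace_risk_category", "presentation", "anchor_count")
    cfg$covariates <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    cfg$covariates <- setdiff(cfg$covariates, skip)
  }
  screen <- cox_screen(cohort, cfg$covariates, alpha = cfg$screen_alpha)

  markers <- intersect(cfg$markers, names(cohort))
  enrichment <- lapply(stats::setNames(nm = markers), function(mk)
    tryCatch(model_enrichment(cohort, base = cfg$base_score, added = mk),
             error = function(e)
               stop("run_study: [enrichment stage, marker ", mk, "] ",
                    conditionMessage(e), call. = FALSE)))

  subgroups <- NULL
  if ("presentation" %in% names(cohort)) {
    subgroups <- lapply(stats::setNames(nm = unique(cohort$presentation)),
                        function(lev) {
      sub <- cohort[cohort$presentation == lev, ]
      if (sum(sub$event) < 5)
        return(list(note = "fewer than 5 events; subgroup screen skipped",
                    n = nrow(sub), n_events = sum(sub$event)))
      sc <- cox_screen(sub, cfg$covariates, alpha = cfg$screen_alpha)
      list(n = nrow(sub), n_events = sum(sub$event),
           univariate = sc$univariate, selected = sc$selected,
           multivariate = sc$multivariate)
    })
  }

  report <- structure(list(
    baseline = baseline,
    km = list(chisq = km$chisq, df = km$df, p_value = km$p_value,
              curves = km$curves),
    cox = screen,
    enrichment = enrichment,
    subgroups = subgroups,
    cohort = cohort,
    metadata = list(config = cfg[setdiff(names(cfg), "out_dir")],
                    n = nrow(cohort), n_events = sum(cohort$event),
                    multiple_testing = "none applied",
                    package_version = as.character(
                      utils::packageVersion("dcgrace")))),
    class = "study_report")
  validate_report(report)
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", x$metadata$n, "patients,", x$metadata$n_events,
      "events\n")
  cat(sprintf("Log-rank across DC groups: chi-square = %.3f, df = %d, p = %s\n",
              x$km$chisq, x$km$df, format.pval(x$km$p_value, digits = 3)))
  cat("Univariate Cox screen kept:",
      if (length(x$cox$selected)) paste(x$cox$selected, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$cox$multivariate)) {
    cat("Multivariate Cox:\n")
    print(x$cox$multivariate, digits = 4)
  }
  for (mk in names(x$enrichment)) {
    cat("\n-- enrichment:", mk, "--\n")
    print(x$enrichment[[mk]])
  }
  invisible(x)
}

report_to_list <- function(report) {
  enr <- lapply(report$enrichment, function(e) list(
    base = e$base, added = e$added, n = e$n, n_events = e$n_events,
    lrt = unclass(e$lrt),
    aicc = as.data.frame(e$aicc),
    nri = unclass(e$nri),
    idi = e$idi[c("idi_e", "idi_ne", "idi", "se", "z", "p_value")],
    roc = lapply(e$roc, function(r)
      r[c("auc", "auc_se", "ci95", "youden_cutoff", "youden_j",
          "sens_at_cutoff", "spec_at_cutoff", "c_statistic", "degenerate")])))
  list(baseline = as.data.frame(report$baseline),
       km = report$km,
       cox = report$cox,
       enrichment = enr,
       subgroups = report$subgroups,
       metadata = report$metadata)
}

#' Write a study report to disk
#'
#' Emits `report.json` (the full machine-readable report) together with
#' CSV analogues of the four printed study tables, with fixed column
#' orders: `table1_baseline.csv`, `table5_aicc.csv`,
#' `table6_reclassification.csv` and `table7_roc.csv`.
#'
#' @param report a `study_report` from [run_study()].
#' @param directory output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "study_report"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (file.access(directory, 2) != 0)
    stop("write_report: directory not writable: ", directory)
  files <- character(0)
  jpath <- file.path(directory, "report.json")
  jsonlite::write_json(report_to_list(report), jpath, auto_unbox = TRUE,
                       digits = NA, na = "null")
  files <- c(files, jpath)

  f1 <- file.path(directory, "table1_baseline.csv")
  utils::write.csv(as.data.frame(report$baseline), f1, row.names = FALSE)
  files <- c(files, f1)

  aicc_rows <- do.call(rbind, lapply(names(report$enrichment), function(mk) {
    a <- as.data.frame(report$enrichment[[mk]]$aicc)
    a$marker <- mk
    a[, c("marker", "label", "k", "log_likelihood", "aicc", "delta",
          "rel_likelihood", "weight")]
  }))
  f5 <- file.path(directory, "table5_aicc.csv")
  utils::write.csv(aicc_rows, f5, row.names = FALSE)
  files <- c(files, f5)

  nri_rows <- do.call(rbind, lapply(names(report$enrichment), function(mk) {
    e <- report$enrichment[[mk]]
    data.frame(marker = mk,
               up_e = e$nri$up_e, down_e = e$nri$down_e, tie_e = e$nri$tie_e,
               n_e = e$nri$n_e, up_ne = e$nri$up_ne, down_ne = e$nri$down_ne,
               tie_ne = e$nri$tie_ne, n_ne = e$nri$n_ne,
               nri_e = e$nri$nri_e, nri_ne = e$nri$nri_ne, nri = e$nri$nri,
               nri_p = e$nri$p_value,
               idi_e = e$idi$idi_e, idi_ne = e$idi$idi_ne, idi = e$idi$idi,
               idi_p = e$idi$p_value)
  }))
  f6 <- file.path(directory, "table6_reclassification.csv")
  utils::write.csv(nri_rows, f6, row.names = FALSE)
  files <- c(files, f6)

  roc_rows <- do.call(rbind, lapply(names(report$enrichment), function(mk) {
    e <- report$enrichment[[mk]]
    do.call(rbind, lapply(names(e$roc), function(which) {
      r <- e$roc[[which]]
      data.frame(marker = mk, model = which, auc = r$auc, se = r$auc_se,
                 ci_lower = r$ci95["lower"], ci_upper = r$ci95["upper"],
                 cutoff = r$youden_cutoff, sensitivity = r$sens_at_cutoff,
                 specificity = r$spec_at_cutoff, youden_j = r$youden_j,
                 c_statistic = r$c_statistic)
    }))
  }))
  f7 <- file.path(directory, "table7_roc.csv")
  utils::write.csv(roc_rows, f7, row.names = FALSE)
  files <- c(files, f7)
  invisible(files)
}

#' Read back a serialised study report
#'
#' @param path the `report.json` file (or the directory containing it).
#' @return The report as plain nested lists/data frames.
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Structural validation of a study report
#'
#' Checks that every section required by the report contract is present
#' and has the expected shape; errors with the list of problems otherwise.
#'
#' @param report a `study_report` or the list returned by [read_report()].
#' @return `TRUE`, invisibly.
#' @export
validate_report <- function(report) {
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(all(c("baseline", "km", "cox", "enrichment", "metadata") %in%
             names(report)), "missing top-level section")
  need(all(c("chisq", "df", "p_value") %in% names(report$km)),
       "km block incomplete")
  need(all(c("univariate", "selected") %in% names(report$cox)),
       "cox block incomplete")
  if (length(report$enrichment)) {
    for (mk in names(report$enrichment)) {
      e <- report$enrichment[[mk]]
      need(all(c("lrt", "aicc", "nri", "idi", "roc") %in% names(e)),
           paste0("enrichment block ", mk, " incomplete"))
    }
  }
  need(all(c("n", "n_events") %in% names(report$metadata)),
       "metadata incomplete")
  if (length(problems))
    stop("validate_report: ", paste(problems, collapse = "; "))
  invisible(TRUE)
}
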