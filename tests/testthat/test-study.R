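test_that("the full pipeline runs from files and keeps its bookkeeping straight", {
  dir <- withr::local_tempdir()
  sc <- generate_cohort(cohort_gen_params(n_patients = 40, seed = 14),
                        rr_dir = dir, keep_rr = TRUE)
  cfg <- list(rr_dir = dir, cohort_file = file.path(dir, "cohort.csv"),
              covariates = c("grace_score", "dc_ms", "age", "male", "lf_hf"))
  rep <- run_study(cfg)
  co <- rep$cohort
  expect_s3_class(rep, "study_report")
  expect_silent(validate_report(rep))

  # group sizes sum to cohort size; KM events equal baseline event counts
  expect_equal(sum(table(co$dc_group)), nrow(co))
  expect_equal(sum(vapply(rep$km$curves, function(cv) sum(cv$n_event),
                          numeric(1))),
               sum(co$event))
  # dc_group consistent with the capacity
  expect_identical(co$dc_group, as.character(dc_risk_group(co$dc_ms)))
  # screen invariant: multivariate covariates passed the univariate screen
  kept <- rep$cox$selected
  uni <- rep$cox$univariate
  expect_true(all(uni$p_value[uni$covariate %in% kept] < 0.05, na.rm = TRUE))
  if (!is.null(rep$cox$multivariate))
    expect_true(all(rep$cox$multivariate$covariate %in% kept))
  # per-patient metrics were attached by the signal stage
  expect_true(all(c("dc_ms", "sdnn", "lf_hf") %in% names(co)))
  expect_true(all(is.finite(co$dc_ms)))
})

test_that("run_study accepts an in-memory cohort and a YAML config", {
  sc <- generate_cohort(cohort_gen_params(n_patients = 60, seed = 15,
                                          rr_duration = 400))
  rep <- run_study(cohort = sc$cohort, config = list(markers = "dc_ms"))
  expect_s3_class(rep, "study_report")
  expect_named(rep$enrichment, "dc_ms")

  dir <- withr::local_tempdir()
  write_cohort_table(sc$cohort, file.path(dir, "cohort.csv"))
  cfg_path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(cohort_file = file.path(dir, "cohort.csv"),
                        markers = "dc_ms",
                        out_dir = file.path(dir, "out")), cfg_path)
  rep2 <- run_study(cfg_path)
  expect_true(file.exists(file.path(dir, "out", "report.json")))
  expect_equal(rep2$km$chisq, rep$km$chisq, tolerance = 1e-9)
})

test_that("subgroup analyses appear when a presentation column exists", {
  sc <- generate_cohort(cohort_gen_params(n_patients = 250, seed = 16,
                                          rr_duration = 400))
  rep <- run_study(cohort = sc$cohort,
                   config = list(markers = "dc_ms",
                                 covariates = c("grace_score", "dc_ms")))
  expect_setequal(names(rep$subgroups), c("STEMI", "NSTE-ACS"))
  for (sg in rep$subgroups)
    expect_true(!is.null(sg$note) || !is.null(sg$univariate))
})

test_that("baseline table gates tests by normality and flags degeneracy", {
  set.seed(1)
  n <- 120
  co <- data.frame(
    grp = rep(c("low", "intermediate", "high"), each = n / 3),
    gaussian = rnorm(n, 10, 2),
    skewed = rexp(n),
    yesno = rbinom(n, 1, 0.4),
    constant = rep(7, n))
  tab <- baseline_table(co, group = "grp")
  row <- function(v) tab[tab$variable == v, ]
  expect_equal(row("gaussian")$test, "anova")
  expect_equal(row("skewed")$test, "kruskal")
  expect_equal(row("yesno")$type, "categorical")
  expect_true(is.finite(row("yesno")$statistic_g))
  expect_true(row("constant")$degenerate)

  # identical groups: the comparison sits at the null centre
  same <- data.frame(grp = rep(c("a", "b"), each = 50),
                     v = rep(rnorm(50), 2))
  tsame <- baseline_table(same, group = "grp")
  expect_gt(tsame$p_value[tsame$variable == "v"], 0.9)
})

test_that("dual chi-square reporting differs where tables are sparse", {
  # a sparse outcome row (zero cell): Pearson and G diverge materially
  tab <- rbind(c(0, 3, 6), c(183, 91, 40))
  expect_gt(abs(pearson_chi2(tab)$statistic - g_test(tab)$statistic), 1)
})

test_that("the CLI dispatches, emits JSON, and returns contract exit codes", {
  expect_equal(cli_main(c("dc", "--bogus-flag", "x")), 2L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 2L)
  expect_equal(suppressMessages(cli_main(character(0))), 2L)

  f <- withr::local_tempfile(fileext = ".csv")
  write_rr_file(generate_rr_series(rr_gen_params(duration = 120, seed = 18)), f)
  out <- capture.output(code <- cli_main(c("dc", f)))
  expect_equal(code, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_true(is.numeric(parsed$dc_ms))
  expect_gt(parsed$anchor_count, 0)

  # constant series: stage failure, exit 1
  fconst <- withr::local_tempfile(fileext = ".csv")
  write_rr_file(make_rr(rep(800, 200)), fconst)
  expect_equal(suppressMessages(cli_main(c("dc", fconst))), 1L)

  dir <- withr::local_tempdir()
  code <- suppressMessages(cli_main(c("simulate", "--n", "4", "--seed", "3",
                                      "--rr-duration", "300", "--out", dir)))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
})
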