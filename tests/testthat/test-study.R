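make_separated_cohort <- function() {
  # suboptimal group strictly above optimal on every marker
  data.frame(
    patient_id = sprintf("P%02d", 1:20),
    group = sub_opt_labels(10, 10),
    ca125 = c(rnorm(10, 1000, 10), rnorm(10, 50, 5)),
    fasn = c(rnorm(10, 1.2, 0.02), rnorm(10, 0.2, 0.02)),
    gls = c(rnorm(10, 30, 0.5), rnorm(10, 15, 0.5)))
}

test_that("formula and default interfaces agree and expose model methods", {
  coh <- generate_cohort(default_study_params(), seed = 3)
  f1 <- roc_cutoff(group ~ ca125, data = coh)
  f2 <- roc_cutoff(coh$ca125, coh$group, marker = "ca125")
  expect_equal(coef(f1), coef(f2))
  expect_identical(f1$marker, "ca125")

  k <- coef(f1)
  expect_named(k, c("cutoff", "sensitivity", "specificity", "youden_j", "auc"))
  expect_equal(k[["youden_j"]], k[["sensitivity"]] + k[["specificity"]] - 1)

  # predictions at the fitted cutoff follow the strict-greater rule
  pr <- predict(f1, c(k[["cutoff"]] - 1, k[["cutoff"]], k[["cutoff"]] + 1))
  expect_identical(as.character(pr), c("optimal", "optimal", "suboptimal"))
  expect_identical(predict(f1, k[["cutoff"]] + 1, type = "category"), 2L)
  expect_output(print(f1), "Cutoff model for ca125")
})

test_that("perfectly separated groups yield a perfect six-panel study", {
  set.seed(71)
  rep <- run_study(make_separated_cohort())
  for (f in rep$fits) {
    expect_equal(f$auc, 1.0)
    expect_equal(f$diagnostics$sensitivity, 1.0)
    expect_equal(f$diagnostics$specificity, 1.0)
  }
})

test_that("study conserves patients and honours pinned cutoffs", {
  coh <- generate_cohort(default_study_params(), seed = 42)
  pins <- c(ca125 = 248.55, gls = 22.895)
  rep <- run_study(coh, pinned_cutoffs = pins)
  expect_named(rep$fits, c("ca125", "fasn", "gls", "ca125_fasn", "ca125_gls",
                           "ca125_fasn_gls"))
  for (f in rep$fits) {
    cm <- f$diagnostics$confusion
    expect_identical(cm$tp + cm$fn, 56L)
    expect_identical(cm$tn + cm$fp, 53L)
    # report rates are exactly those of its own confusion matrix
    expect_equal(f$diagnostics$sensitivity, cm$tp / 56)
    # combined values obey the x{1,2} scale bound
    expect_true(f$cutoff >= min(f$curve$threshold) &&
                  f$cutoff <= max(f$curve$threshold))
  }
  expect_equal(rep$cutoffs[["ca125"]], 248.55)
  expect_equal(rep$cutoffs[["gls"]], 22.895)
  expect_equal(rep$panel_specs$ca125_fasn_gls$category_markers,
               c(ca125 = 248.55, gls = 22.895))

  # bit-stable across runs
  expect_identical(run_study(coh, pinned_cutoffs = pins)[c("cutoffs", "fits")],
                   rep[c("cutoffs", "fits")])
  # without pins, the category cutoffs are the stage-1 Youden cutoffs
  rep2 <- run_study(coh)
  expect_equal(rep2$panel_specs$ca125_gls$category_markers[["ca125"]],
               rep2$cutoffs[["ca125"]])
})

test_that("report serialization round-trips through JSON and CSV", {
  coh <- generate_cohort(default_study_params(), seed = 8)
  rep <- run_study(coh)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$n_pos, 56)
  expect_equal(back$panels$ca125$auc, rep$fits$ca125$auc)
  expect_equal(back$panels$ca125_fasn_gls$confusion$tp,
               rep$fits$ca125_fasn_gls$diagnostics$confusion$tp)
  tab <- utils::read.csv(cp)
  expect_identical(names(tab)[1:7],
                   c("variable", "cutoff", "sensitivity_pct", "specificity_pct",
                     "accuracy_pct", "ppv_pct", "npv_pct"))
  expect_identical(nrow(tab), 6L)
})

test_that("published-table verification flags only the known discrepancies", {
  v <- verify_published_table()
  bad <- v$cells[!v$cells$agree, ]
  # truncated (not half-up rounded) printed cells, and nothing else
  expect_identical(paste(bad$panel, bad$cell),
                   c("ca125 acc_pct", "fasn acc_pct",
                     "ca125_gls acc_pct", "ca125_gls ppv_pct"))
  expect_equal(bad$recomputed - bad$printed, rep(0.1, 4), tolerance = 1e-9)

  # a corrupt fixture fails validation
  pub <- published_table2()
  pub$panels$ca125$sens_pct <- 140
  expect_error(verify_published_table(pub), "\\[0, 100\\]")
})
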