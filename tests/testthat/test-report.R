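test_that("record validation reports every field-level problem by name", {
  rec <- tiny_cohort(5, seed = 2)[1, ]
  expect_true(validate_record(rec))
  bad <- rec
  bad$smoking <- "sometimes"
  bad$age <- NA
  err <- tryCatch(validate_record(bad), error = conditionMessage)
  expect_match(err, "smoking")
  expect_match(err, "age")
  bad2 <- rec; bad2$preop_roe <- 150
  expect_error(validate_record(bad2), "preop_roe")
})

test_that("risk tiers follow the configured probability cut points", {
  fit <- manual_fit(intercept = -10)          # probability ~ 0 for anyone
  rec <- tiny_cohort(5, seed = 3)[1, ]
  rep <- predict_patient(rec, fit_class = fit)
  expect_lt(rep$complication_probability, 0.2)
  expect_equal(rep$risk_tier, "low")
  fit_hi <- manual_fit(intercept = 10)
  rep_hi <- predict_patient(rec, fit_class = fit_hi)
  expect_equal(rep_hi$risk_tier, "high")
  # moderate band under custom cuts
  fit_mid <- manual_fit(intercept = 0, coefs = c(0, 0, 0))
  rep_mid <- predict_patient(rec, fit_class = fit_mid, cuts = c(0.4, 0.6))
  expect_equal(rep_mid$risk_tier, "moderate")
  expect_error(predict_patient(rec), "at least one")
})

test_that("a high-risk profile scores strictly above the baseline profile", {
  fit <- manual_fit()
  base <- tiny_cohort(5, seed = 4)[1, ]
  base$nasal_collision_1mo <- factor("no", levels = c("yes", "no"))
  base$folliculitis <- factor("no", levels = c("yes", "no"))
  base$smoking <- factor("no", levels = c("yes", "no"))
  risky <- base
  risky$nasal_collision_1mo <- factor("yes", levels = c("yes", "no"))
  risky$folliculitis <- factor("yes", levels = c("yes", "no"))
  risky$smoking <- factor("yes", levels = c("yes", "no"))
  p0 <- predict_patient(base, fit_class = fit)$complication_probability
  p1 <- predict_patient(risky, fit_class = fit)$complication_probability
  expect_gt(p1, p0)
})

test_that("reports attach top contributors and matching recommendations", {
  fit <- manual_fit()
  bg <- tiny_cohort(40, seed = 5)
  rec <- bg[1, ]
  rec$smoking <- factor("yes", levels = c("yes", "no"))
  rec$nasal_collision_1mo <- factor("yes", levels = c("yes", "no"))
  rep <- predict_patient(rec, fit_class = fit, background = bg, seed = 2)
  expect_lte(nrow(rep$top_contributors), 3)
  expect_true(all(rep$top_contributors$feature %in% fit$selected_features))
  expect_true(any(grepl("smoking cessation", rep$recommendations)))
  expect_true(any(grepl("nasal contact", rep$recommendations)))
  # rule table is well formed editorial data
  rules <- recommendation_rules()
  expect_true(all(c("feature", "risk_value", "recommendation") %in%
                    names(rules)))
  expect_true(all(rules$feature %in% predictor_names()))
})

test_that("the study driver writes a self-describing, reproducible bundle", {
  out1 <- file.path(tempdir(), "study_a")
  out2 <- file.path(tempdir(), "study_b")
  ctl <- mh_control(population_size = 5, max_iterations = 6)
  m1 <- run_study(out1, optimizer = ctl, seed = 42, shap_samples = 4)
  m2 <- run_study(out2, optimizer = ctl, seed = 42, shap_samples = 4)
  expect_setequal(m1$partitions, c("train", "test", "validation"))
  for (f in c("resolved_config.json", "metrics_classification.csv",
              "metrics_regression.csv", "dca_train.csv", "dca_test.csv",
              "dca_validation.csv", "manifest.json", "run.log")) {
    expect_true(file.exists(file.path(out1, f)))
  }
  # fixed seed -> byte-identical metric grids
  expect_identical(readLines(file.path(out1, "metrics_classification.csv")),
                   readLines(file.path(out2, "metrics_classification.csv")))
  expect_identical(readLines(file.path(out1, "metrics_regression.csv")),
                   readLines(file.path(out2, "metrics_regression.csv")))
  # resolved config records the open design choices actually exercised
  cfg <- jsonlite::read_json(file.path(out1, "resolved_config.json"))
  expect_equal(cfg$threshold, 0.5)
  expect_equal(cfg$seed, 42)
  expect_true(!is.null(cfg$data_dictionary_md5))
  # metric grid covers the six models on all three partitions
  grid <- utils::read.csv(file.path(out1, "metrics_classification.csv"))
  expect_setequal(unique(grid$partition), c("train", "test", "validation"))
  expect_equal(length(unique(grid$model)), 6)
  unlink(c(out1, out2), recursive = TRUE)
})
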