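test_that("the data dictionary defines 16 predictors and 2 outcomes", {
  d <- data_dictionary()
  expect_equal(sum(d$role == "predictor"), 16)
  expect_setequal(d$name[d$role == "outcome"], c("complication_1mo", "roe_1yr"))
  expect_true(all(d$type %in% c("continuous", "binary")))
})

test_that("generation is seeded, complete at zero missingness, and typed", {
  cfg <- cohort_config(missing_rate = 0)
  t1 <- generate_cohort(200, cfg, seed = 4)
  t2 <- generate_cohort(200, cfg, seed = 4)
  t3 <- generate_cohort(200, cfg, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1$age, t3$age))
  expect_false(anyNA(t1[, predictor_names()]))
  expect_true(all(t1$roe_1yr >= 0 & t1$roe_1yr <= 100))
  expect_true(is.factor(t1$smoking) && is.factor(t1$complication_1mo))
  # truth surface exported for recovery experiments
  tru <- cohort_truth(t1)
  expect_named(tru$class_coef)
  expect_true(all(c("nasal_collision_1mo", "folliculitis", "smoking") %in%
                    tru$planted_class_drivers))
  expect_length(tru$event_prob, 200)
})

test_that("missingness is injected at the configured rate", {
  cfg <- cohort_config(missing_rate = 0.05)
  tb <- generate_cohort(3000, cfg, seed = 8)
  rate <- mean(is.na(as.matrix(tb[, predictor_names()])))
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
  expect_false(anyNA(tb$complication_1mo))
  expect_false(anyNA(tb$roe_1yr))
})

test_that("large-sample marginals match the configuration within 3 SE", {
  cfg <- cohort_config(missing_rate = 0)
  n <- 1e4
  tb <- generate_cohort(n, cfg, seed = 21)
  m <- cfg$marginals
  # continuous means (preoperative ROE clipping is negligible at these
  # parameters)
  for (v in c("age", "bmi", "preop_roe")) {
    se <- m[[v]][2] / sqrt(n)
    expect_lt(abs(mean(tb[[v]]) - m[[v]][1]), 3 * se)
  }
  # binary proportions, including the coupled education variable whose
  # marginal is preserved by calibration
  dict <- data_dictionary()
  for (v in c("sex", "education", "smoking", "folliculitis",
              "hospital_stay_ge5d", "nasal_collision_1mo")) {
    p <- m[[v]]
    pos <- dict$positive[dict$name == v]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(tb[[v]] == pos) - p), 3 * se)
  }
  # event rate calibration
  p <- m$event_rate
  expect_lt(abs(mean(tb$complication_1mo == "yes") - p),
            3 * sqrt(p * (1 - p) / n))
  # documented coupling: education inversely associated with preop ROE
  expect_lt(mean(tb$preop_roe[tb$education == ">high_school"]),
            mean(tb$preop_roe[tb$education == "<=high_school"]))
})

test_that("imputation fills from training statistics only", {
  tb <- data.frame(
    age = c(5, NA, 7, 100), smoking = factor(c("yes", "yes", "no", NA),
                                             levels = c("yes", "no")),
    .partition = c("train", "train", "train", "test"),
    stringsAsFactors = FALSE)
  out <- impute_cohort(tb)
  expect_equal(out$age[2], 6)          # median of train {5, 7}
  expect_equal(as.character(out$smoking[4]), "yes") # train mode
  vals <- attr(out, "imputation_values")
  expect_equal(vals$age, 6)
  # a complete table passes through unchanged
  cmplt <- generate_cohort(30, cohort_config(missing_rate = 0), seed = 1)
  expect_identical(impute_cohort(cmplt)[, names(cmplt)], cmplt[, names(cmplt)])
  # all-missing training column is an error
  bad <- data.frame(age = c(NA, NA, 3), .partition = c("train", "train", "test"))
  expect_error(impute_cohort(bad), "entirely missing")
})

test_that("ROE strata close their upper boundaries", {
  expect_equal(as.character(roe_stratum(c(0, 25, 25.5, 30, 35, 35.5, 100))),
               c("Low", "Low", "Medium", "Medium", "Medium", "High", "High"))
  expect_error(roe_stratum(101), "\\[0, 100\\]")
  expect_error(roe_stratum(-1), "\\[0, 100\\]")
})

test_that("the stratified split yields 264/66 from 330 with stratum balance", {
  tb <- generate_cohort(330, cohort_config(missing_rate = 0), seed = 6)
  sp <- stratified_split(tb, fraction = 0.8, seed = 6)
  expect_equal(nrow(sp$train), 264)
  expect_equal(nrow(sp$test), 66)
  # partition contract: disjoint, exhaustive
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(sp$table)))
  expect_true(all(sp$table$.partition %in% c("train", "test")))
  # per-stratum training share within one row of 80% (largest remainder)
  strata <- interaction(roe_stratum(tb$preop_roe), tb$complication_1mo,
                        drop = TRUE)
  for (s in levels(strata)) {
    idx <- strata == s
    if (sum(idx) < 2) next
    got <- sum(sp$table$.partition[idx] == "train")
    expect_lte(abs(got - 0.8 * sum(idx)), 1)
  }
  # determinism
  sp2 <- stratified_split(tb, fraction = 0.8, seed = 6)
  expect_identical(sp$table$.partition, sp2$table$.partition)
  expect_error(stratified_split(tb[0, ]), "empty")
})

test_that("SMOTE balances 70/194 to parity with convex synthetics", {
  set.seed(2)
  n_min <- 70; n_maj <- 194
  x <- rbind(cbind(rnorm(n_min, 3), rnorm(n_min, 3)),
             cbind(rnorm(n_maj), rnorm(n_maj)))
  y <- c(rep(1, n_min), rep(0, n_maj))
  out <- apply_smote(x, y, seed = 1)
  expect_equal(as.integer(table(out$y)), c(194L, 194L))
  expect_equal(out$n_synthetic, 124L)
  # balanced input is a no-op
  xb <- x[c(1:50, 71:120), ]; yb <- y[c(1:50, 71:120)]
  outb <- apply_smote(xb, yb, seed = 1)
  expect_identical(outb$x, xb)
  expect_equal(outb$n_synthetic, 0L)
  expect_error(apply_smote(x, rep(1, nrow(x))), "binary")
})

test_that("synthetic points lie on segments between minority parents", {
  # collinear minority class: every convex combination stays on the line
  x <- rbind(cbind(0:4, 0:4), cbind(10 + runif(20), 20 + runif(20)))
  y <- c(rep(1, 5), rep(0, 20))
  out <- apply_smote(x, y, k = 2, seed = 3)
  synth <- out$x[(nrow(x) + 1):nrow(out$x), , drop = FALSE]
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12)
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 4))
  # binary columns are copied, never interpolated
  set.seed(9)
  xb <- cbind(c(rep(0, 4), rep(1, 3), rbinom(20, 1, 0.5)), runif(27))
  yb <- c(rep(1, 7), rep(0, 20))
  outb <- apply_smote(xb, yb, seed = 4)
  sb <- outb$x[(nrow(xb) + 1):nrow(outb$x), 1]
  expect_true(all(sb %in% c(0, 1)))
})

test_that("cohort summaries reproduce printed-style event rows", {
  comp <- factor(c(rep("yes", 70), rep("no", 194)), levels = c("yes", "no"))
  tb <- data.frame(complication_1mo = comp)
  s <- summarize_cohorts(list(training = tb))
  row <- s[s$variable == "Poor prognosis at 1 month", ]
  expect_equal(row$training, "26.52% (70/264)")
  expect_true(is.na(row$p_value)) # single cohort: no comparison
  # identical cohorts compare with p = 1
  tb2 <- generate_cohort(80, cohort_config(missing_rate = 0), seed = 2)
  s2 <- summarize_cohorts(list(a = tb2, b = tb2))
  expect_true(all(s2$p_value[!is.na(s2$p_value)] >= 0.999))
  # different cohorts produce the full Table-1-style grid
  tb3 <- generate_cohort(60, cohort_config("table1_validation",
                                           missing_rate = 0), seed = 3)
  s3 <- summarize_cohorts(list(a = tb2, b = tb3))
  expect_equal(nrow(s3), 18)
  expect_true(all(c("a", "b", "p_value") %in% names(s3)))
})

test_that("configuration validation rejects impossible parameters", {
  expect_error(cohort_config(missing_rate = 1.2), "missing_rate")
  expect_error(cohort_config(reg_noise_sd = 0), "reg_noise_sd")
  cfg <- cohort_config()
  cfg$marginals$smoking <- 1.5
  expect_error(rhinoml:::validate_cohort_config(cfg), "proportions")
})
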