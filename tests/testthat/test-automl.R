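test_that("solution decoding follows the slot-partition rules", {
  cat_ <- model_catalog("classification")
  m <- 16
  raw <- rep(0.4, 1 + m + cat_$n_max)
  raw[1] <- 0.6
  sol <- decode_solution(raw, cat_, m)
  expect_equal(sol$k, 3)                       # 0.6 -> third family
  expect_equal(sol$family, "gboost_depthwise")
  expect_true(sol$k %in% 1:4)
  # mask threshold at exactly 0.5
  raw2 <- rep(0, 1 + m + cat_$n_max)
  raw2[2] <- 0.5; raw2[3] <- 0.49
  sol2 <- decode_solution(raw2, cat_, m)
  expect_equal(sol2$delta[1], 1L)
  expect_equal(sol2$delta[2], 0L)
  # k slot edges
  expect_equal(decode_solution(c(0, raw[-1]), cat_, m)$k, 1)
  expect_equal(decode_solution(c(1, raw[-1]), cat_, m)$k, 4)
  expect_error(decode_solution(raw[-1], cat_, m), "length")
})

test_that("hyperparameter slots map affinely into their bounds", {
  cat_ <- model_catalog("classification")
  cat_$families[[1]]$hypers <- list(rhinoml:::hyper("z", 1, 9, "linear"))
  m <- 16
  raw <- c(0, rep(1, m), 0.5, rep(0, cat_$n_max - 1))
  sol <- decode_solution(raw, cat_, m)
  expect_equal(unname(sol$lambda[["z"]]), 5)   # midpoint of [1, 9]
  # log-scaled slot at the midpoint is the geometric mean
  cat2 <- model_catalog("classification")
  raw2 <- c(0, rep(1, m), 0.5, 0.5, rep(0, cat2$n_max - 2))
  sol2 <- decode_solution(raw2, cat2, m)
  expect_equal(unname(sol2$lambda[["lambda"]]), sqrt(1e-4 * 1),
               tolerance = 1e-12)
  # integer-flagged hyperparameters decode to whole numbers
  raw3 <- c(0.6, rep(1, m), rep(0.37, cat2$n_max))
  sol3 <- decode_solution(raw3, cat2, m)
  expect_equal(sol3$lambda[["max_depth"]], round(sol3$lambda[["max_depth"]]))
})

test_that("an all-zero mask is repaired to the strongest slot", {
  cat_ <- model_catalog("classification")
  m <- 16
  raw <- c(0.1, seq(0.01, 0.16, length.out = m), rep(0.5, cat_$n_max))
  sol <- decode_solution(raw, cat_, m)
  expect_equal(sum(sol$delta), 1)
  expect_equal(which(sol$delta == 1), m)       # highest-valued slot forced on
})

test_that("the weight schedule starts accuracy-dominant and ends balanced", {
  expect_equal(unname(weight_schedule(0, 100)), c(0.80, 0.10, 0.10))
  w <- weight_schedule(100, 100)
  expect_equal(unname(w), c(0.45, 0.45, 0.10))
  expect_equal(w[["w1"]], w[["w2"]])           # terminal balance
  for (t in seq(0, 100, by = 10)) {
    expect_equal(sum(weight_schedule(t, 100)), 1)
  }
  expect_error(weight_schedule(-1, 100), "t")
})

test_that("fitness arithmetic matches hand evaluation and decomposes", {
  # acc 0.8, 8 of 16 features, terminal weights
  f <- fitness_value(0.8, 8, 16, t = 100, Tmax = 100)
  expect_equal(as.numeric(f), 0.45 * 0.8 + 0.45 * 0.5 + 0.10 * exp(-1))
  expect_equal(round(as.numeric(f), 4), 0.6218)
  # decomposition identity from logged components
  comp <- attr(f, "components"); w <- attr(f, "weights")
  expect_equal(as.numeric(f),
               sum(w * comp[c("acc", "sparsity", "decay")]),
               tolerance = 1e-12)
  # full mask zeroes the sparsity term
  f2 <- fitness_value(0.9, 16, 16, t = 0, Tmax = 50)
  expect_equal(as.numeric(f2), 0.80 * 0.9 + 0.10 * 1)
  # removing a feature never decreases the sparsity term
  sp <- sapply(16:1, function(k) attr(fitness_value(0.5, k, 16, 0, 10),
                                      "components")[["sparsity"]])
  expect_false(is.unsorted(sp))
})

test_that("cross-validation uses exactly ten stratified folds", {
  y <- factor(c(rep("yes", 40), rep("no", 120)), levels = c("yes", "no"))
  fold <- rhinoml:::make_folds(y, 10, seed = 1)
  expect_equal(sort(unique(fold)), 1:10)
  per_fold_pos <- tapply(y == "yes", fold, sum)
  expect_true(all(per_fold_pos == 4))          # stratification exact here
  expect_identical(fold, rhinoml:::make_folds(y, 10, seed = 1))
})

test_that("the accuracy term is leakage-safe and bounded", {
  tb <- tiny_cohort(n = 160, seed = 3)
  cat_ <- model_catalog("classification")
  sol <- decode_solution(c(0.05, rep(0.9, 16), rep(0.5, cat_$n_max)),
                         cat_, 16)
  a <- cv_accuracy(sol, tb, "classification", cat_, folds = 10, seed = 2)
  expect_gte(a, 0); expect_lte(a, 1)
  a2 <- cv_accuracy(sol, tb, "classification", cat_, folds = 10, seed = 2,
                    metric = "auc")
  expect_gte(a2, 0); expect_lte(a2, 1)
  # regression term is clipped R2
  solr <- decode_solution(c(0.05, rep(0.9, 16), rep(0.5, cat_$n_max)),
                          model_catalog("regression"), 16)
  ar <- cv_accuracy(solr, tb, "regression", model_catalog("regression"),
                    folds = 10, seed = 2)
  expect_gte(ar, 0); expect_lte(ar, 1)
})

test_that("every learner family fits and predicts within contract", {
  tb <- tiny_cohort(n = 140, seed = 5)
  X <- cohort_matrix(tb)
  yc <- tb$complication_1mo
  yr <- tb$roe_1yr
  for (k in 1:4) {
    cat_ <- model_catalog("classification")
    fam <- cat_$families[[k]]
    lam <- vapply(fam$hypers, function(h) {
      v <- if (h$scale == "log") sqrt(h$lower * h$upper) else
        (h$lower + h$upper) / 2
      if (h$integer) round(v) else v
    }, numeric(1))
    names(lam) <- vapply(fam$hypers, `[[`, character(1), "name")
    mod <- fam$fit(X, yc, lam, "classification")
    p <- mod$predict(X)
    expect_true(all(p >= 0 & p <= 1))
    catr <- model_catalog("regression")
    modr <- catr$families[[k]]$fit(X, yr, lam, "regression")
    expect_true(all(is.finite(modr$predict(X))))
  }
  # a constant-outcome regression fit predicts that constant
  catr <- model_catalog("regression")
  modc <- catr$families[[1]]$fit(X, rep(50, nrow(X)),
                                 c(lambda = 1e-3, alpha = 0), "regression")
  expect_equal(modc$predict(X), rep(50, nrow(X)), tolerance = 1e-6)
})

test_that("a small search returns a valid, reproducible fitted model", {
  tb <- tiny_cohort(n = 150, seed = 7)
  ctl <- mh_control(population_size = 5, max_iterations = 5, seed = 7)
  fit <- automl(tb, "classification", optimizer = ctl, seed = 7)
  expect_s3_class(fit, "automl_fit")
  expect_true(fit$best_solution$k %in% 1:4)
  expect_gte(length(fit$selected_features), 1)
  expect_length(fit$search_trace, 5)
  p <- predict(fit, tb)
  expect_true(all(p >= 0 & p <= 1))
  # determinism: identical configuration, identical fingerprint
  fit2 <- automl(tb, "classification", optimizer = ctl, seed = 7)
  expect_identical(model_fingerprint(fit), model_fingerprint(fit2))
  # regression predictions respect the ROE range
  fitr <- automl(tb, "regression", optimizer = ctl, seed = 7)
  pr <- predict(fitr, tb)
  expect_true(all(pr >= 0 & pr <= 100))
  # a missing selected feature is a named error
  drop <- fit$selected_features[1]
  expect_error(predict(fit, tb[, setdiff(names(tb), drop)]), drop)
})

test_that("input validation guards empty and unimputed data", {
  tb <- tiny_cohort(n = 60, seed = 9)
  expect_error(automl(tb[0, ], "classification"), "training rows|no training")
  tb$age[1] <- NA
  expect_error(automl(tb, "classification"), "missing")
  expect_error(automl(tiny_cohort(40, 1), "classification",
                      optimizer = mh_control(population_size = 4,
                                             max_iterations = 0)),
               "max_iterations")
})
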