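# Clinical front end: single-patient risk reports and the end-to-end
# study driver. Replaces a GUI dashboard with machine-readable output: a
# patient report is a plain list (JSON-serialisable), a study run is a
# self-describing output directory.

#' Load the editable recommendation rule table
#'
#' Clinical wording for modifiable high-risk features ships as a data
#' file (inst/extdata/recommendations.csv) so it can be edited without a
#' code change.
#' @return Data.frame: `feature`, `risk_value`, `recommendation`.
#' @export
recommendation_rules <- function() {
  utils::read.csv(system.file("extdata", "recommendations.csv",
                              package = "rhinoml"),
                  stringsAsFactors = FALSE)
}

#' Validate a patient record against the data dictionary
#'
#' @param record One-row data.frame or named list.
#' @param features Features that must be present and non-missing.
#' @return Invisibly TRUE; otherwise an error listing every violation.
#' @export
validate_record <- function(record, features = predictor_names()) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  dict <- data_dictionary()
  problems <- character()
  for (nm in features) {
    row <- dict[dict$name == nm, ]
    if (nrow(row) == 0) { problems <- c(problems, sprintf("unknown feature `%s`", nm)); next }
    if (!nm %in% names(record) || is.na(record[[nm]][1])) {
      problems <- c(problems, sprintf("missing value for `%s`", nm))
      next
    }
    v <- record[[nm]][1]
    if (row$type == "binary") {
      if (!as.character(v) %in% c(row$positive, row$negative)) {
        problems <- c(problems,
                      sprintf("`%s` must be one of '%s'/'%s' (got '%s')",
                              nm, row$positive, row$negative, v))
      }
    } else if (!is.numeric(v)) {
      problems <- c(problems, sprintf("`%s` must be numeric", nm))
    } else if (nm %in% c("preop_roe", "roe_1yr") && (v < 0 || v > 100)) {
      problems <- c(problems, sprintf("`%s` must lie in [0, 100]", nm))
    }
  }
  if (length(problems)) {
    stop("invalid patient record:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Single-patient prognosis report
#'
#' Predicts from one or both fitted models, assigns a risk tier by
#' configurable probability cut points, attributes the classification
#' prediction to its top contributing features by sampling-based Shapley
#' values against a background cohort, and maps modifiable high-risk
#' features to recommendation strings from the shipped rule table.
#'
#' @param record One-row data.frame (or named list) with the predictors.
#' @param fit_class Optional classification `automl_fit`.
#' @param fit_reg Optional regression `automl_fit`.
#' @param background Cohort rows used as the Shapley background (required
#'   when `fit_class` is given).
#' @param cuts Risk-tier cut points (low < `cuts[1]` <= moderate <
#'   `cuts[2]` <= high); default `c(0.2, 0.5)`.
#' @param top_k Number of Shapley contributors to report; default 3.
#' @param seed Seed for the Shapley sampling estimator.
#' @return List of class `patient_report`.
#' @export
predict_patient <- function(record, fit_class = NULL, fit_reg = NULL,
                            background = NULL, cuts = c(0.2, 0.5),
                            top_k = 3L, seed = 1L) {
  if (is.null(fit_class) && is.null(fit_reg)) {
    stop("supply at least one fitted model")
  }
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  need <- unique(c(if (!is.null(fit_class)) fit_class$selected_features,
                   if (!is.null(fit_reg)) fit_reg$selected_features))
  validate_record(record, need)
  out <- list(record = as.list(record[1, intersect(names(record),
                                                   data_dictionary()$name)]))
  if (!is.null(fit_class)) {
    p <- predict(fit_class, record)
    tier <- if (p < cuts[1]) "low" else if (p < cuts[2]) "moderate" else "high"
    out$complication_probability <- as.numeric(p)
    out$risk_tier <- tier
    if (!is.null(background)) {
      feats <- fit_class$selected_features
      bg <- cohort_matrix(background, feats)
      xs <- cohort_matrix(record, feats)
      sh <- shap_values(function(X) {
        colnames(X) <- feats
        df <- as.data.frame(X)
        # matrix columns are already 0/1-coded; rebuild factors for predict
        dict <- data_dictionary()
        for (nm in feats) {
          row <- dict[dict$name == nm, ]
          if (row$type == "binary") {
            df[[nm]] <- factor(ifelse(X[, nm] >= 0.5, row$positive,
                                      row$negative),
                               levels = c(row$positive, row$negative))
          }
        }
        predict(fit_class, df)
      }, bg, xs,
      method = if (length(feats) <= 12) "exact" else "sampling",
      n_permutations = 500L, seed = seed)
      imp <- data.frame(feature = feats, shap = sh$values[1, ])
      imp <- imp[order(-abs(imp$shap)), ]
      out$top_contributors <- utils::head(imp, top_k)
      rules <- recommendation_rules()
      rec <- character()
      for (i in seq_len(nrow(rules))) {
        nm <- rules$feature[i]
        if (nm %in% names(record) &&
            as.character(record[[nm]][1]) == rules$risk_value[i]) {
          rec <- c(rec, rules$recommendation[i])
        }
      }
      out$recommendations <- rec
    }
  }
  if (!is.null(fit_reg)) {
    out$predicted_roe_1yr <- as.numeric(predict(fit_reg, record))
  }
  structure(out, class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat("Patient prognosis report\n")
  if (!is.null(x$complication_probability)) {
    cat(sprintf("  1-month complication probability: %.3f (%s risk)\n",
                x$complication_probability, x$risk_tier))
  }
  if (!is.null(x$predicted_roe_1yr)) {
    cat(sprintf("  predicted 1-year ROE score: %.1f\n", x$predicted_roe_1yr))
  }
  if (!is.null(x$top_contributors)) {
    cat("  top contributors:\n")
    for (i in seq_len(nrow(x$top_contributors))) {
      cat(sprintf("    %s (%+.4f)\n", x$top_contributors$feature[i],
                  x$top_contributors$shap[i]))
    }
  }
  if (length(x$recommendations)) {
    cat("  recommendations:\n")
    for (r in x$recommendations) cat("    -", r, "\n")
  }
  invisible(x)
}

# AdaBoost (discrete SAMME over shallow rpart trees) — comparison-table
# baseline only; not selectable by the AutoML search.
fit_adaboost <- function(x, y, task, n_trees = 50, depth = 2) {
  df <- data.frame(x)
  if (task == "regression") {
    # simple gradient-style additive stumps for the regression baseline
    pred <- rep(mean(y), length(y))
    trees <- list()
    for (b in seq_len(n_trees)) {
      fit <- rpart::rpart(r ~ ., data = cbind(df, r = y - pred),
                          control = rpart::rpart.control(maxdepth = depth,
                                                         cp = 0, minsplit = 5))
      pred <- pred + 0.5 * stats::predict(fit, df)
      trees[[b]] <- fit
    }
    base <- mean(y)
    return(function(newx) {
      nd <- data.frame(newx)
      out <- rep(base, nrow(nd))
      for (fit in trees) out <- out + 0.5 * stats::predict(fit, nd)
      out
    })
  }
  yy <- ifelse(as_binary01(y) == 1, 1, -1)
  w <- rep(1 / length(yy), length(yy))
  trees <- list(); alphas <- numeric()
  for (b in seq_len(n_trees)) {
    fit <- rpart::rpart(factor(yy) ~ ., data = df, weights = w / mean(w),
                        control = rpart::rpart.control(maxdepth = depth,
                                                       cp = 0, minsplit = 5))
    h <- ifelse(stats::predict(fit, df)[, "1"] >= 0.5, 1, -1)
    err <- sum(w * (h != yy))
    if (err >= 0.5 || err <= 0) break
    a <- 0.5 * log((1 - err) / err)
    w <- w * exp(-a * yy * h)
    w <- w / sum(w)
    trees[[b]] <- fit; alphas[b] <- a
  }
  function(newx) {
    nd <- data.frame(newx)
    s <- rep(0, nrow(nd))
    for (b in seq_along(trees)) {
      s <- s + alphas[b] *
        ifelse(stats::predict(trees[[b]], nd)[, "1"] >= 0.5, 1, -1)
    }
    stats::plogis(2 * s / max(sum(alphas), 1e-12))
  }
}

# fixed-configuration comparison baselines fitted on the (SMOTE-balanced,
# for classification) training matrix
baseline_models <- function(task) {
  cat_ <- model_catalog(task)
  mk <- function(k, lam) {
    fam <- cat_$families[[k]]
    list(name = fam$name,
         fit = function(x, y) fam$fit(x, y, lam, task)$predict)
  }
  list(
    lr = mk(1, c(lambda = 1e-3, alpha = 0)),
    svm = mk(2, c(cost = 1, gamma = 0.06)),
    adaboost = list(name = "adaboost",
                    fit = function(x, y) fit_adaboost(x, y, task)),
    xgboost = mk(3, c(eta = 0.1, max_depth = 4, nrounds = 60,
                      reg_lambda = 1)),
    gbm_leafwise = mk(4, c(eta = 0.1, max_leaves = 31, nrounds = 60,
                           reg_lambda = 1))
  )
}

#' Run the full prognosis study end to end
#'
#' Simulates (or loads) the cohorts, splits the development cohort,
#' imputes from training statistics, fits the AutoML classification and
#' regression models, evaluates them alongside fixed-configuration
#' baselines on every partition, runs decision-curve analysis, exports
#' Shapley attributions, and writes everything to a self-describing
#' output directory (resolved configuration, data-dictionary hash,
#' package version, log).
#'
#' @param out_dir Output directory (created if needed).
#' @param n_development,n_validation Cohort sizes for the simulated
#'   development (split 8:2) and external validation sets.
#' @param optimizer [mh_control()] search budget for both fits.
#' @param metric Classification accuracy term (`"acc"` or `"auc"`).
#' @param seed Master seed for every stage.
#' @param shap_samples Number of test rows to explain; 0 disables the
#'   Shapley export.
#' @return Invisibly, a manifest list of the written artefacts.
#' @export
run_study <- function(out_dir, n_development = 330L, n_validation = 117L,
                      optimizer = mh_control(population_size = 10L,
                                             max_iterations = 30L),
                      metric = "auc", seed = 1L, shap_samples = 20L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    r <- tryCatch(expr, error = function(e) {
      log_line("stage %s: FAILED: %s", name, conditionMessage(e))
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    log_line("stage %s: done", name)
    r
  }

  cfg_dev <- cohort_config("table1_train")
  cfg_val <- cohort_config("table1_validation")
  dev <- stage("simulate", generate_cohort(n_development, cfg_dev, seed))
  val <- stage("simulate_validation",
               generate_cohort(n_validation, cfg_val, seed + 1L))
  sp <- stage("split", stratified_split(dev, seed = seed))
  tbl <- sp$table
  val$.partition <- "validation"
  tbl <- stage("impute", impute_cohort(tbl))
  # validation rows are imputed with the development training statistics
  iv <- attr(tbl, "imputation_values")
  for (nm in names(iv)) val[[nm]][is.na(val[[nm]])] <- iv[[nm]]
  for (nm in predictor_names()) {
    if (anyNA(val[[nm]])) val <- impute_cohort(val)
  }
  log_line("decisions: threshold=0.5, metric=%s, SMOTE fold-level in search / full-train refit, weight schedule w1 0.80->0.45, w3 0.10", metric)

  fit_c <- stage("fit_classification",
                 automl(tbl, "classification", optimizer = optimizer,
                        metric = metric, seed = seed))
  fit_r <- stage("fit_regression",
                 automl(tbl, "regression", optimizer = optimizer,
                        seed = seed))

  parts <- list(train = tbl[tbl$.partition == "train", ],
                test = tbl[tbl$.partition == "test", ],
                validation = val)
  cls_rows <- list(); reg_rows <- list()
  dca_files <- character()
  bl <- baseline_models("classification")
  blr <- baseline_models("regression")
  Xtr <- cohort_matrix(parts$train)
  ytr_c <- parts$train$complication_1mo
  sm <- apply_smote(Xtr, as_binary01(ytr_c), seed = seed)
  bl_fits <- lapply(bl, function(b) b$fit(sm$x, sm$y))
  blr_fits <- lapply(blr, function(b) b$fit(Xtr, parts$train$roe_1yr))
  stage("evaluate", {
    for (pname in names(parts)) {
      pt <- parts[[pname]]
      Xp <- cohort_matrix(pt)
      y_c <- as_binary01(pt$complication_1mo)
      for (bn in names(bl_fits)) {
        pr <- pmin(1, pmax(0, bl_fits[[bn]](Xp)))
        met <- classification_metrics(y_c, pr)$metrics
        cls_rows[[length(cls_rows) + 1L]] <-
          cbind(partition = pname, model = bl[[bn]]$name, met)
      }
      pr <- predict(fit_c, pt)
      met <- classification_metrics(y_c, pr)$metrics
      cls_rows[[length(cls_rows) + 1L]] <-
        cbind(partition = pname, model = "automl", met)
      dc <- decision_curve(y_c, pr)
      f <- file.path(out_dir, sprintf("dca_%s.csv", pname))
      utils::write.csv(dc, f, row.names = FALSE)
      dca_files <- c(dca_files, f)
      for (bn in names(blr_fits)) {
        prr <- pmin(100, pmax(0, blr_fits[[bn]](Xp)))
        reg_rows[[length(reg_rows) + 1L]] <-
          cbind(partition = pname, model = blr[[bn]]$name,
                regression_metrics(pt$roe_1yr, prr))
      }
      prr <- predict(fit_r, pt)
      reg_rows[[length(reg_rows) + 1L]] <-
        cbind(partition = pname, model = "automl",
              regression_metrics(pt$roe_1yr, prr))
    }
  })
  cls_grid <- do.call(rbind, cls_rows)
  reg_grid <- do.call(rbind, reg_rows)
  utils::write.csv(cls_grid, file.path(out_dir, "metrics_classification.csv"),
                   row.names = FALSE)
  utils::write.csv(reg_grid, file.path(out_dir, "metrics_regression.csv"),
                   row.names = FALSE)

  if (shap_samples > 0) {
    stage("shap", {
      feats <- fit_c$selected_features
      te <- utils::head(parts$test, shap_samples)
      bg <- utils::head(parts$train, 50)
      sh <- shap_values(
        function(X) fit_c$model$predict(X),
        cohort_matrix(bg, feats), cohort_matrix(te, feats),
        method = if (length(feats) <= 12) "exact" else "sampling",
        seed = seed)
      utils::write.csv(cbind(as.data.frame(sh$values)),
                       file.path(out_dir, "shap_classification.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(base_value = sh$base_value,
                                features = feats),
                           file.path(out_dir, "shap_classification.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(shap_importance(sh),
                       file.path(out_dir, "shap_importance.csv"),
                       row.names = FALSE)
    })
  }

  dict_hash <- {
    f <- tempfile(); on.exit(unlink(f), add = TRUE)
    utils::write.csv(data_dictionary(), f, row.names = FALSE)
    unname(tools::md5sum(f))
  }
  resolved <- list(
    package_version = as.character(utils::packageVersion("rhinoml")),
    seed = seed, n_development = n_development,
    n_validation = n_validation, metric = metric,
    optimizer = unclass(optimizer)[c("population_size", "max_iterations",
                                     "algorithm", "levy_prob", "levy_scale",
                                     "bernoulli_beta", "levy_beta")],
    threshold = 0.5, data_dictionary_md5 = dict_hash,
    classification = list(solution = unclass(fit_c$best_solution[
      c("k", "family", "delta", "lambda")]),
      features = fit_c$selected_features, cv_score = fit_c$cv_score),
    regression = list(solution = unclass(fit_r$best_solution[
      c("k", "family", "delta", "lambda")]),
      features = fit_r$selected_features, cv_score = fit_r$cv_score)
  )
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    partitions = names(parts),
    files = c("resolved_config.json", "metrics_classification.csv",
              "metrics_regression.csv", basename(dca_files),
              if (shap_samples > 0) c("shap_classification.csv",
                                      "shap_classification.json",
                                      "shap_importance.csv"),
              "run.log"),
    fits = list(classification = fit_c, regression = fit_r)
  )
  jsonlite::write_json(manifest[c("partitions", "files")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  log_line("run complete")
  invisible(manifest)
}
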