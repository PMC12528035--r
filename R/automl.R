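# The AutoML layer: a hybrid solution vector (k | delta | lambda) jointly
# encodes the base-learner choice, a binary feature mask over the 16
# dictionary predictors, and the active family's hyperparameters. The
# population optimizer searches the unit cube; candidates are decoded and
# scored by a dynamically weighted fitness combining cross-validated
# accuracy, feature sparsity and an iteration-decay term.

hyper <- function(name, lower, upper, scale = c("linear", "log"),
                  integer = FALSE) {
  scale <- match.arg(scale)
  list(name = name, lower = lower, upper = upper, scale = scale,
       integer = integer)
}

#' Base-learner catalog
#'
#' The four families selectable through the k slot of the solution
#' vector: 1 = penalised logistic/linear regression (glmnet), 2 = RBF
#' support vector machine, 3 = depth-wise gradient-boosted trees,
#' 4 = leaf-wise histogram gradient boosting (LightGBM-style growth).
#' Each family carries its tunable hyperparameter space (regularisation,
#' tree depth / leaf count, learning rate, boosting rounds).
#'
#' @param task `"classification"` or `"regression"`.
#' @return Object of class `model_catalog`: `families` (list of name,
#'   hypers, fit) and `n_max`, the widest hyperparameter count.
#' @export
model_catalog <- function(task = c("classification", "regression")) {
  task <- match.arg(task)
  fams <- list(
    list(name = if (task == "classification") "logistic_regression"
                else "linear_regression",
         hypers = list(hyper("lambda", 1e-4, 1, "log"),
                       hyper("alpha", 0, 1, "linear")),
         fit = fit_glmnet),
    list(name = "svm_rbf",
         hypers = list(hyper("cost", 0.01, 100, "log"),
                       hyper("gamma", 1e-3, 10, "log")),
         fit = fit_svm),
    list(name = "gboost_depthwise",
         hypers = list(hyper("eta", 0.02, 0.3, "log"),
                       hyper("max_depth", 2, 8, "linear", integer = TRUE),
                       hyper("nrounds", 20, 120, "linear", integer = TRUE),
                       hyper("reg_lambda", 0.01, 10, "log")),
         fit = fit_xgb_depthwise),
    list(name = "gboost_leafwise",
         hypers = list(hyper("eta", 0.02, 0.3, "log"),
                       hyper("max_leaves", 4, 64, "linear", integer = TRUE),
                       hyper("nrounds", 20, 120, "linear", integer = TRUE),
                       hyper("reg_lambda", 0.01, 10, "log")),
         fit = fit_xgb_leafwise)
  )
  structure(list(families = fams, task = task,
                 n_max = max(vapply(fams, function(f) length(f$hypers),
                                    integer(1)))),
            class = "model_catalog")
}

# ---- family fit wrappers: each returns predict(newx) plus a canonical
# numeric representation of the fitted parameters (for fingerprints) ----

fit_glmnet <- function(x, y, params, task) {
  # glmnet needs >= 2 columns; pad single-feature designs with a zero column
  pad <- ncol(x) < 2
  if (pad) x <- cbind(x, .pad = 0)
  fam <- if (task == "classification") "binomial" else "gaussian"
  yy <- if (task == "classification") as_binary01(y) else as.numeric(y)
  if (stats::sd(yy) == 0) {
    # degenerate outcome: the fit is the constant
    const <- if (task == "classification") {
      min(1 - 1e-12, max(1e-12, yy[1]))
    } else yy[1]
    return(list(predict = function(newx) rep(const, nrow(newx)),
                canonical = c(const, rep(0, ncol(x)))))
  }
  fit <- glmnet::glmnet(x, yy, family = fam, alpha = params[["alpha"]],
                        lambda = params[["lambda"]], standardize = TRUE)
  list(
    predict = function(newx) {
      if (pad) newx <- cbind(newx, .pad = 0)
      eta <- as.numeric(glmnet::predict.glmnet(fit, newx,
                                               s = params[["lambda"]],
                                               type = "link"))
      if (task == "classification") stats::plogis(eta) else eta
    },
    canonical = as.numeric(as.matrix(stats::coef(fit, s = params[["lambda"]])))
  )
}

fit_svm <- function(x, y, params, task) {
  yy <- if (task == "classification") {
    factor(as_binary01(y), levels = c(1, 0))
  } else as.numeric(y)
  fit <- e1071::svm(x, yy, type = if (task == "classification")
                      "C-classification" else "eps-regression",
                    kernel = "radial", cost = params[["cost"]],
                    gamma = params[["gamma"]], scale = TRUE)
  sgn <- 1
  if (task == "classification") {
    # orientation of the libsvm decision value relative to the positive
    # class, read off once from the trained model
    dv0 <- attr(stats::predict(fit, x[1, , drop = FALSE],
                               decision.values = TRUE), "decision.values")
    sgn <- if (startsWith(colnames(dv0)[1], "1")) 1 else -1
  }
  list(
    predict = function(newx) {
      if (task == "classification") {
        # deterministic monotone probability via a logistic link on the
        # signed margin (avoids libsvm's internally randomised Platt CV)
        dv <- attr(stats::predict(fit, newx, decision.values = TRUE),
                   "decision.values")[, 1]
        stats::plogis(sgn * dv)
      } else as.numeric(stats::predict(fit, newx))
    },
    canonical = list(sv = unname(fit$SV), coefs = as.numeric(fit$coefs),
                     rho = fit$rho)
  )
}

fit_xgb <- function(x, y, params, task, extra) {
  yy <- if (task == "classification") as_binary01(y) else as.numeric(y)
  obj <- if (task == "classification") "binary:logistic" else "reg:squarederror"
  dtr <- xgboost::xgb.DMatrix(as.matrix(x), label = yy)
  fit <- xgboost::xgb.train(
    params = c(list(objective = obj, eta = params[["eta"]],
                    lambda = params[["reg_lambda"]], nthread = 1), extra),
    data = dtr, nrounds = params[["nrounds"]], verbose = 0
  )
  list(
    predict = function(newx) {
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(newx)))
    },
    canonical = xgboost::xgb.save.raw(fit)
  )
}

fit_xgb_depthwise <- function(x, y, params, task) {
  fit_xgb(x, y, params, task, list(max_depth = params[["max_depth"]]))
}

fit_xgb_leafwise <- function(x, y, params, task) {
  fit_xgb(x, y, params, task,
          list(max_depth = 0, max_leaves = params[["max_leaves"]],
               grow_policy = "lossguide", tree_method = "hist"))
}

#' Decode a raw unit-cube vector into a solution
#'
#' Layout of `raw`: slot 1 selects the learner family
#' (`k = 1 + floor(4 * raw[1])`, clipped to 1..4), the next `m` slots are
#' the binary feature mask (selected iff slot >= 0.5), and the final
#' `n_max` slots map affinely (or log-affinely) into the active family's
#' hyperparameter bounds; surplus slots of narrower families are ignored.
#' Out-of-range entries are clipped. An all-zero mask is repaired by
#' forcing the single highest-valued feature slot on.
#'
#' @param raw Numeric vector of length `1 + m + n_max`.
#' @param catalog A [model_catalog()].
#' @param m Number of candidate features.
#' @return Object of class `solution_vector`: `k`, `family`, `delta`
#'   (0/1 vector of length m), `lambda` (named decoded hyperparameters).
#' @export
decode_solution <- function(raw, catalog, m) {
  n_max <- catalog$n_max
  if (length(raw) != 1 + m + n_max) {
    stop(sprintf("`raw` must have length %d", 1 + m + n_max))
  }
  clipped <- any(raw < 0 | raw > 1)
  raw <- pmin(1, pmax(0, raw))
  k <- min(1L + as.integer(floor(raw[1] * length(catalog$families))),
           length(catalog$families))
  mask_raw <- raw[2:(m + 1)]
  delta <- as.integer(mask_raw >= 0.5)
  if (sum(delta) == 0) delta[which.max(mask_raw)] <- 1L
  fam <- catalog$families[[k]]
  lam_raw <- raw[(m + 2):(m + 1 + n_max)]
  lambda <- vapply(seq_along(fam$hypers), function(j) {
    h <- fam$hypers[[j]]
    u <- lam_raw[j]
    v <- if (h$scale == "log") {
      exp(log(h$lower) + u * (log(h$upper) - log(h$lower)))
    } else h$lower + u * (h$upper - h$lower)
    if (h$integer) round(v) else v
  }, numeric(1))
  names(lambda) <- vapply(fam$hypers, `[[`, character(1), "name")
  structure(list(k = k, family = fam$name, delta = delta, lambda = lambda,
                 clipped = clipped),
            class = "solution_vector")
}

#' @export
print.solution_vector <- function(x, ...) {
  cat(sprintf("<solution_vector> k=%d (%s), %d/%d features, lambda: %s\n",
              x$k, x$family, sum(x$delta), length(x$delta),
              paste(sprintf("%s=%.4g", names(x$lambda), x$lambda),
                    collapse = ", ")))
  invisible(x)
}

#' Dynamic fitness weight schedule
#'
#' Linear schedule over the iteration budget: the accuracy weight starts
#' dominant and decays while the sparsity weight rises to meet it at the
#' final iteration (`w1(Tmax) = w2(Tmax)`); the efficiency-decay weight
#' stays constant. The three weights sum to 1 at every t.
#'
#' @param t Iteration index, 0 <= t <= Tmax.
#' @param Tmax Iteration budget.
#' @param w1_start,w1_end Accuracy weight at t = 0 and t = Tmax.
#' @param w3 Constant decay-term weight.
#' @return Named vector (w1, w2, w3).
#' @export
weight_schedule <- function(t, Tmax, w1_start = 0.80, w1_end = 0.45,
                            w3 = 0.10) {
  if (t < 0 || t > Tmax) stop("`t` must lie in [0, Tmax]")
  w1 <- w1_start - (w1_start - w1_end) * t / Tmax
  w2 <- 1 - w3 - w1
  c(w1 = w1, w2 = w2, w3 = w3)
}

#' Weighted fitness from its components
#'
#' The scalar the search maximises:
#' \deqn{f = w_1 \cdot acc_{CV} + w_2 (1 - \|\delta\|_0 / m)
#'   + w_3 \exp(-t/T_{max}).}
#'
#' @param acc Cross-validated accuracy term in [0, 1].
#' @param n_selected Number of selected features, \eqn{\|\delta\|_0}.
#' @param m Total candidate features.
#' @param t,Tmax Iteration index and budget.
#' @param weights Weight vector (w1, w2, w3); default from
#'   [weight_schedule()].
#' @return Fitness value with components attached as attributes.
#' @export
fitness_value <- function(acc, n_selected, m, t, Tmax,
                          weights = weight_schedule(t, Tmax)) {
  sparsity <- 1 - n_selected / m
  decay <- exp(-t / Tmax)
  out <- weights[["w1"]] * acc + weights[["w2"]] * sparsity +
    weights[["w3"]] * decay
  attr(out, "components") <- c(acc = acc, sparsity = sparsity, decay = decay)
  attr(out, "weights") <- weights
  out
}

# seeded stratified fold assignment
make_folds <- function(y, k, seed, stratified = TRUE) {
  n <- length(y)
  local_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (lvl in unique(y)) {
        idx <- which(y == lvl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

#' Cross-validated accuracy term of a solution
#'
#' Instantiates the learner encoded by `solution`, restricts the design
#' to its feature mask, and scores it by seeded stratified 10-fold
#' cross-validation on the training rows. For classification, SMOTE is
#' applied inside each training fold only (never to held-out rows) and the
#' accuracy term is out-of-fold ACC at threshold 0.5 (or ROC-AUC with
#' `metric = "auc"`). For regression the term is out-of-fold R2 clipped to
#' [0, 1]. A fold whose training part is single-class is skipped; if all
#' folds degenerate the value is `-Inf`.
#'
#' @param solution A `solution_vector`.
#' @param data Training cohort rows (preprocessed, no missing cells).
#' @param task,catalog Task and matching catalog.
#' @param folds Number of CV folds (default 10) or a precomputed fold id
#'   vector.
#' @param seed Seed for folds and fold-level SMOTE.
#' @param smote Apply fold-level SMOTE for classification.
#' @param metric `"acc"` or `"auc"` accuracy term (classification).
#' @return The accuracy term in [0, 1] (or `-Inf`).
#' @export
cv_accuracy <- function(solution, data, task, catalog = model_catalog(task),
                        folds = 10, seed = 1L, smote = TRUE,
                        metric = c("acc", "auc")) {
  metric <- match.arg(metric)
  feats <- predictor_names()[solution$delta == 1]
  X <- cohort_matrix(data, feats)
  y <- if (task == "classification") data$complication_1mo else data$roe_1yr
  fold_id <- if (length(folds) == nrow(data)) folds else {
    make_folds(if (task == "classification") y else
                 cut(rank(y, ties.method = "first"), 10),
               folds, seed)
  }
  fam <- catalog$families[[solution$k]]
  oof <- rep(NA_real_, nrow(data))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    if (task == "classification" && length(unique(y[tr])) < 2) next
    xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    if (task == "classification" && smote) {
      y01 <- as_binary01(ytr)
      if (min(table(y01)) >= 2) {
        sm <- apply_smote(xtr, y01, seed = seed + f)
        xtr <- sm$x
        ytr <- sm$y
      }
    }
    mod <- fam$fit(xtr, ytr, solution$lambda, task)
    oof[!tr] <- mod$predict(X[!tr, , drop = FALSE])
  }
  ok <- !is.na(oof)
  if (!any(ok)) return(-Inf)
  if (task == "classification") {
    y01 <- as_binary01(y)[ok]
    if (metric == "acc") mean((oof[ok] >= 0.5) == (y01 == 1))
    else roc_auc(y01, oof[ok])
  } else {
    sstot <- sum((y[ok] - mean(y[ok]))^2)
    if (sstot == 0) return(-Inf)
    min(1, max(0, 1 - sum((y[ok] - oof[ok])^2) / sstot))
  }
}

#' Full fitness of a solution at an iteration
#'
#' Combines [cv_accuracy()] with the sparsity and decay terms under the
#' weights for iteration `t`; the value is to be maximised (negate when
#' handing to the minimising optimizer). Component values are attached as
#' attributes.
#'
#' @inheritParams cv_accuracy
#' @param t,Tmax Iteration index and budget for the weight schedule.
#' @param weights Optional explicit weights.
#' @return Numeric fitness with `components` and `weights` attributes.
#' @export
fitness <- function(solution, data, task, t, Tmax,
                    catalog = model_catalog(task),
                    weights = weight_schedule(t, Tmax),
                    folds = 10, seed = 1L, smote = TRUE,
                    metric = c("acc", "auc")) {
  acc <- cv_accuracy(solution, data, task, catalog, folds, seed, smote,
                     metric)
  if (!is.finite(acc)) return(structure(-Inf, components = NULL))
  fitness_value(acc, sum(solution$delta), length(solution$delta),
                t, Tmax, weights)
}

#' Fit a prognosis model by metaheuristic AutoML
#'
#' The main fitting function. Runs the population optimizer over the
#' `[0,1]^(1+m+n_max)` cube; each candidate decodes to a (learner,
#' feature subset, hyperparameters) triple scored by the dynamically
#' weighted cross-validated fitness. The winning configuration is refitted
#' on the full training partition (for classification, SMOTE is applied to
#' the whole training set before this final fit). Accuracy terms are
#' memoised on the decoded solution, so re-encounters of a configuration
#' cost nothing.
#'
#' Rows tagged `test`/`validation` in a `.partition` column are excluded
#' from every stage of the search and fit.
#'
#' @param data Cohort data.frame (imputed; see [impute_cohort()]).
#' @param task `"classification"` (1-month complication) or
#'   `"regression"` (1-year ROE score).
#' @param optimizer [mh_control()] for the search; defaults to a
#'   desk-scale budget (population 10, 30 iterations, INPDOA).
#' @param folds Inner CV folds; default 10.
#' @param metric Accuracy term for classification: `"acc"` (default) or
#'   `"auc"`.
#' @param smote Fold-level SMOTE during search and full-set SMOTE for the
#'   final classification fit.
#' @param seed Seed for folds, SMOTE and the search.
#' @return Object of class `automl_fit`.
#' @export
automl <- function(data, task = c("classification", "regression"),
                   optimizer = mh_control(population_size = 10L,
                                          max_iterations = 30L),
                   folds = 10, metric = c("acc", "auc"), smote = TRUE,
                   seed = 1L) {
  task <- match.arg(task)
  metric <- match.arg(metric)
  if (".partition" %in% names(data) && any(data$.partition == "train")) {
    data <- data[data$.partition == "train", , drop = FALSE]
  }
  if (nrow(data) == 0) stop("no training rows")
  catalog <- model_catalog(task)
  m <- length(predictor_names())
  pred_cols <- predictor_names()
  if (anyNA(data[, pred_cols])) {
    stop("training data contain missing cells; run impute_cohort() first")
  }
  tmax <- optimizer$max_iterations
  if (tmax < 1) stop("iteration budget must be >= 1")
  optimizer$seed <- if (is.null(optimizer$seed)) seed else optimizer$seed
  optimizer$vectorized <- FALSE

  y_strat <- if (task == "classification") data$complication_1mo else
    cut(rank(data$roe_1yr, ties.method = "first"), 10)
  fold_id <- make_folds(y_strat, folds, seed)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  acc_of <- function(sol) {
    key <- paste(sol$k, paste(sol$delta, collapse = ""),
                 paste(signif(sol$lambda, 8), collapse = "_"), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    a <- cv_accuracy(sol, data, task, catalog, folds = fold_id,
                     seed = seed, smote = smote, metric = metric)
    cache[[key]] <- a
    a
  }
  objective <- function(x, t) {
    sol <- decode_solution(x, catalog, m)
    a <- acc_of(sol)
    if (!is.finite(a)) return(Inf)
    -as.numeric(fitness_value(a, sum(sol$delta), m, t, tmax))
  }
  res <- mh_optimize(objective, rep(0, 1 + m + catalog$n_max),
                     rep(1, 1 + m + catalog$n_max), optimizer)
  best <- decode_solution(res$best_position, catalog, m)
  feats <- pred_cols[best$delta == 1]
  X <- cohort_matrix(data, feats)
  yfit <- if (task == "classification") data$complication_1mo else data$roe_1yr
  if (task == "classification" && smote) {
    y01 <- as_binary01(yfit)
    sm <- apply_smote(X, y01, seed = seed)
    X <- sm$x
    yfit <- sm$y
  }
  fam <- catalog$families[[best$k]]
  final <- fam$fit(X, yfit, best$lambda, task)
  structure(list(
    best_solution = best,
    selected_features = feats,
    cv_score = acc_of(best),
    task = task, metric = metric,
    model = final,
    search_trace = -res$trace,
    cv_evaluations = n_eval,
    optimizer = optimizer, folds = folds, seed = seed,
    n_train = nrow(data)
  ), class = "automl_fit")
}

#' Predict from a fitted AutoML model
#'
#' @param object An `automl_fit`.
#' @param newdata Cohort data.frame carrying every selected feature; a
#'   missing or NA selected feature raises an error naming it.
#' @param ... Unused.
#' @return Classification: positive-class probability in [0, 1].
#'   Regression: predicted 1-year ROE score clipped to [0, 100].
#' @export
predict.automl_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$selected_features, names(newdata))
  if (length(miss)) {
    stop(sprintf("record is missing selected feature(s): %s",
                 paste(miss, collapse = ", ")))
  }
  for (nm in object$selected_features) {
    if (anyNA(newdata[[nm]])) {
      stop(sprintf("selected feature `%s` contains missing values", nm))
    }
  }
  X <- cohort_matrix(newdata, object$selected_features)
  p <- object$model$predict(X)
  if (object$task == "classification") pmin(1, pmax(0, p))
  else pmin(100, pmax(0, p))
}

#' @export
print.automl_fit <- function(x, ...) {
  cat(sprintf("AutoML %s fit (%s)\n", x$task, x$best_solution$family))
  cat(sprintf("  features (%d/%d): %s\n", length(x$selected_features),
              length(x$best_solution$delta),
              paste(x$selected_features, collapse = ", ")))
  cat(sprintf("  hyperparameters: %s\n",
              paste(sprintf("%s=%.4g", names(x$best_solution$lambda),
                            x$best_solution$lambda), collapse = ", ")))
  cat(sprintf("  CV %s = %.4f  (%d accuracy evaluations, %d train rows)\n",
              if (x$task == "classification") toupper(x$metric) else "R2",
              x$cv_score, x$cv_evaluations, x$n_train))
  invisible(x)
}

#' @export
summary.automl_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  final search fitness: %.4f\n",
              object$search_trace[length(object$search_trace)]))
  invisible(object)
}

#' @export
plot.automl_fit <- function(x, ...) {
  graphics::plot(seq_along(x$search_trace), x$search_trace, type = "l",
                 xlab = "iteration", ylab = "best fitness",
                 main = sprintf("AutoML search (%s)", x$task), ...)
  invisible(x)
}

#' @export
coef.automl_fit <- function(object, ...) {
  if (object$best_solution$k == 1) {
    stats::setNames(object$model$canonical,
                    c("(Intercept)", object$selected_features,
                      if (length(object$selected_features) < 2) ".pad"))
  } else {
    message("coefficients are only available for the penalised ",
            "regression family; the winner is ", object$best_solution$family)
    invisible(NULL)
  }
}

#' Stable fingerprint of a fitted model
#'
#' MD5 digest of the decoded solution, the selected features and the
#' canonical numeric representation of the fitted learner. Two fits are
#' behaviourally identical iff their fingerprints match; used to assert
#' that perturbing held-out rows cannot change the fitted model.
#'
#' @param object An `automl_fit`.
#' @return Character MD5 string.
#' @export
model_fingerprint <- function(object) {
  stopifnot(inherits(object, "automl_fit"))
  payload <- serialize(list(object$best_solution[c("k", "delta", "lambda")],
                            object$selected_features,
                            object$cv_score,
                            object$model$canonical), NULL, version = 2)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(payload, f)
  unname(tools::md5sum(f))
}
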