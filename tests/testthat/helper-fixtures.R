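# Small fixtures built in code.

# complete (no missingness) seeded synthetic cohort
tiny_cohort <- function(n = 120, seed = 1) {
  generate_cohort(n, cohort_config(missing_rate = 0), seed = seed)
}

# a deterministic classification "fit" with a known linear-logistic model,
# for exercising the report layer without a search
manual_fit <- function(features = c("nasal_collision_1mo", "folliculitis",
                                    "smoking"),
                       coefs = c(2.5, 2.0, 1.8), intercept = -2) {
  structure(list(
    best_solution = structure(list(k = 1L, family = "logistic_regression",
                                   delta = as.integer(
                                     predictor_names() %in% features),
                                   lambda = c(lambda = 0, alpha = 0)),
                              class = "solution_vector"),
    selected_features = features,
    cv_score = NA_real_, task = "classification", metric = "acc",
    model = list(predict = function(X) {
      stats::plogis(intercept + as.numeric(X %*% coefs))
    }, canonical = c(intercept, coefs)),
    search_trace = numeric(0), cv_evaluations = 0L,
    optimizer = mh_control(), folds = 10, seed = 1, n_train = 0L
  ), class = "automl_fit")
}

# brute-force all-pairs ROC-AUC oracle
auc_pairs_oracle <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# exact Shapley for an additive model over an independent background:
# phi_j = f_j(x_j) - mean(f_j(background_j))
additive_shap_oracle <- function(fs, x, background) {
  vapply(seq_along(fs), function(j) {
    fs[[j]](x[j]) - mean(fs[[j]](background[, j]))
  }, numeric(1))
}
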