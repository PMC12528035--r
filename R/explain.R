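# Model-agnostic Shapley attribution under interventional semantics: the
# value of a feature coalition is the mean model output when all features
# outside the coalition are replaced by background values. The exact
# method enumerates all 2^m coalitions with Shapley weights and serves as
# the oracle; the sampling method averages marginal contributions over
# seeded random permutations and scales to any feature count.

#' Shapley attribution values
#'
#' For each sample, decomposes the model prediction into per-feature
#' contributions that sum (with the base value, the expected prediction
#' over the background set) to the prediction itself: the local-accuracy
#' property of Shapley values. The coalition value function replaces
#' out-of-coalition features with background rows (interventional
#' semantics), so attributions do not depend on how the model was trained.
#'
#' @param model Prediction function: numeric matrix (or data.frame) in,
#'   numeric vector out.
#' @param background Background/reference sample matrix (rows = samples);
#'   its mean prediction is the base value.
#' @param samples Matrix of samples to explain, columns matching
#'   `background`.
#' @param method `"exact"` (full coalition enumeration, feature count
#'   <= 12) or `"sampling"` (permutation estimator).
#' @param n_permutations Permutation count for the sampling method.
#' @param seed Seed for the sampling method.
#' @return Object of class `shap_matrix`: `values` (samples x features),
#'   `base_value`, `feature_values` (the raw inputs), `method`.
#' @export
shap_values <- function(model, background, samples,
                        method = c("exact", "sampling"),
                        n_permutations = 2000L, seed = 1L) {
  method <- match.arg(method)
  background <- as.matrix(background)
  samples <- as.matrix(samples)
  if (nrow(background) == 0) stop("`background` must contain samples")
  m <- ncol(samples)
  if (ncol(background) != m) stop("background/sample columns differ")
  if (method == "exact" && m > 12) {
    stop("exact enumeration supports at most 12 features; use method = \"sampling\"")
  }
  base_value <- mean(model(background))
  vals <- if (method == "exact") {
    shap_exact(model, background, samples)
  } else {
    local_seed(seed, shap_sampling(model, background, samples,
                                   n_permutations))
  }
  colnames(vals) <- colnames(samples)
  structure(list(values = vals, base_value = base_value,
                 feature_values = samples, method = method),
            class = "shap_matrix")
}

# exact Shapley by coalition enumeration; coalition values are computed
# once per sample with a single batched model call over all 2^m x nb rows
shap_exact <- function(model, background, samples) {
  m <- ncol(samples)
  nb <- nrow(background)
  n_coal <- 2^m
  # coalition membership matrix (n_coal x m), bit j of coalition c
  member <- t(vapply(seq_len(n_coal) - 1L,
                     function(cc) as.logical(bitwAnd(cc, 2^(seq_len(m) - 1))),
                     logical(m)))
  csize <- rowSums(member)
  # Shapley weight |S|!(m-|S|-1)!/m! indexed by |S|
  wt <- exp(lfactorial(0:(m - 1)) + lfactorial(m - 1 - (0:(m - 1))) -
              lfactorial(m))
  out <- matrix(0, nrow(samples), m)
  big <- background[rep(seq_len(nb), n_coal), , drop = FALSE]
  for (s in seq_len(nrow(samples))) {
    x <- samples[s, ]
    X <- big
    for (cc in seq_len(n_coal)) {
      sel <- member[cc, ]
      if (any(sel)) {
        rows <- ((cc - 1) * nb + 1):(cc * nb)
        X[rows, sel] <- matrix(x[sel], nb, sum(sel), byrow = TRUE)
      }
    }
    v <- rowsum(model(X), rep(seq_len(n_coal), each = nb)) / nb
    for (j in seq_len(m)) {
      without <- which(!member[, j])
      with_j <- without + 2^(j - 1)
      out[s, j] <- sum(wt[csize[without] + 1] * (v[with_j] - v[without]))
    }
  }
  out
}

# permutation-sampling estimator: average marginal contribution of each
# feature over random orderings. Each permutation step is valued over the
# *entire* background (so the only Monte Carlo noise is the choice of
# orderings; for purely additive model components the estimator is exact),
# and permutations are drawn in antithetic pairs (an ordering and its
# reverse) for further variance reduction.
shap_sampling <- function(model, background, samples, n_permutations) {
  m <- ncol(samples)
  nb <- nrow(background)
  n_pairs <- ceiling(n_permutations / 2)
  out <- matrix(0, nrow(samples), m)
  for (s in seq_len(nrow(samples))) {
    x <- samples[s, ]
    perms <- vector("list", 2 * n_pairs)
    for (p in seq_len(n_pairs)) {
      sig <- sample.int(m)
      perms[[2 * p - 1]] <- sig
      perms[[2 * p]] <- rev(sig)
    }
    acc <- numeric(m)
    # batch the (m+1) x nb hybrid grids in chunks of permutations
    chunk <- max(1L, floor(5e4 / ((m + 1) * nb)))
    p0 <- 1L
    while (p0 <= length(perms)) {
      pp <- perms[p0:min(p0 + chunk - 1L, length(perms))]
      X <- matrix(0, length(pp) * (m + 1) * nb, m)
      for (j in seq_along(pp)) {
        block <- background[rep(seq_len(nb), m + 1), , drop = FALSE]
        filled <- logical(m)
        for (step in seq_len(m)) {
          filled[pp[[j]][step]] <- TRUE
          rows <- (step * nb + 1):((step + 1) * nb)
          block[rows, filled] <- matrix(x[filled], nb, sum(filled),
                                        byrow = TRUE)
        }
        off <- (j - 1) * (m + 1) * nb
        X[(off + 1):(off + (m + 1) * nb), ] <- block
      }
      pred <- model(X)
      for (j in seq_along(pp)) {
        off <- (j - 1) * (m + 1) * nb
        v <- rowsum(pred[(off + 1):(off + (m + 1) * nb)],
                    rep(seq_len(m + 1), each = nb)) / nb
        acc[pp[[j]]] <- acc[pp[[j]]] + diff(as.numeric(v))
      }
      p0 <- p0 + chunk
    }
    out[s, ] <- acc / length(perms)
  }
  out
}

#' Global feature importance from a Shapley matrix
#'
#' Ranks features by mean absolute attribution; ties are broken by the
#' column (data-dictionary) order.
#'
#' @param matrix A `shap_matrix`.
#' @return Data.frame (`feature`, `importance`) sorted descending.
#' @export
shap_importance <- function(matrix) {
  stopifnot(inherits(matrix, "shap_matrix"))
  imp <- colMeans(abs(matrix$values))
  nm <- colnames(matrix$values)
  if (is.null(nm)) nm <- paste0("x", seq_along(imp))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = nm[ord], importance = imp[ord],
             stringsAsFactors = FALSE)
}

#' Dependence-plot data for one feature
#'
#' Pairs each sample's raw feature value with its attribution; optionally
#' adds a second feature's raw values as the interaction colouring
#' variable.
#'
#' @param matrix A `shap_matrix` with named columns.
#' @param feature Feature to plot.
#' @param interaction_feature Optional second feature for colouring.
#' @return Data.frame with `value`, `shap` and (when requested)
#'   `interaction_value`; one row per explained sample.
#' @export
shap_dependence <- function(matrix, feature, interaction_feature = NULL) {
  stopifnot(inherits(matrix, "shap_matrix"))
  nm <- colnames(matrix$values)
  if (!feature %in% nm) stop(sprintf("unknown feature `%s`", feature))
  out <- data.frame(value = matrix$feature_values[, feature],
                    shap = matrix$values[, feature])
  if (!is.null(interaction_feature)) {
    if (!interaction_feature %in% nm) {
      stop(sprintf("unknown feature `%s`", interaction_feature))
    }
    out$interaction_value <- matrix$feature_values[, interaction_feature]
  }
  out
}

#' Summary-plot data export
#'
#' Long-format per-sample attributions with each feature's raw value
#' recorded as a normalised rank in [0, 1] (the high/low colouring scale
#' used by beeswarm-style summary plots).
#'
#' @param matrix A `shap_matrix`.
#' @return Data.frame: `feature`, `sample`, `shap`, `value_rank`.
#' @export
shap_summary_data <- function(matrix) {
  stopifnot(inherits(matrix, "shap_matrix"))
  nm <- colnames(matrix$values)
  n <- nrow(matrix$values)
  do.call(rbind, lapply(seq_along(nm), function(j) {
    v <- matrix$feature_values[, j]
    rk <- if (length(unique(v)) == 1) rep(0.5, n) else {
      (rank(v, ties.method = "average") - 1) / (n - 1)
    }
    data.frame(feature = nm[j], sample = seq_len(n),
               shap = matrix$values[, j], value_rank = rk,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d samples x %d features (%s), base value %.4g\n",
              nrow(x$values), ncol(x$values), x$method, x$base_value))
  invisible(x)
}
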