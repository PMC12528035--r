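# CEC2022-style test suite: 12 shifted/rotated functions spanning the
# unimodal / basic multimodal / hybrid / composition class structure, with
# seeded self-generated shifts and rotations (the official instance data
# files are deliberately not used; difficulty structure, not byte-level
# instances, is what the comparison needs).

# ---- basic functions; all take a matrix Z (rows = points), return a vector ----

f_zakharov <- function(Z) {
  d <- ncol(Z)
  s2 <- rowSums(0.5 * Z * rep(seq_len(d), each = nrow(Z)))
  rowSums(Z^2) + s2^2 + s2^4
}
f_rosenbrock <- function(Z) {
  Z1 <- Z[, -ncol(Z), drop = FALSE]
  Z2 <- Z[, -1, drop = FALSE]
  rowSums(100 * (Z2 - Z1^2)^2 + (Z1 - 1)^2)
}
f_rastrigin <- function(Z) rowSums(Z^2 - 10 * cos(2 * pi * Z) + 10)
f_schaffer6exp <- function(Z) {
  g <- function(x, y) {
    s <- x^2 + y^2
    0.5 + (sin(sqrt(s))^2 - 0.5) / (1 + 0.001 * s)^2
  }
  d <- ncol(Z)
  out <- numeric(nrow(Z))
  for (j in seq_len(d)) {
    k <- if (j == d) 1L else j + 1L
    out <- out + g(Z[, j], Z[, k])
  }
  out
}
f_levy <- function(Z) {
  W <- 1 + Z / 4
  W1 <- W[, 1]
  Wd <- W[, ncol(W)]
  Wm <- W[, -ncol(W), drop = FALSE]
  sin(pi * W1)^2 +
    rowSums((Wm - 1)^2 * (1 + 10 * sin(pi * Wm + 1)^2)) +
    (Wd - 1)^2 * (1 + sin(2 * pi * Wd)^2)
}
f_ackley <- function(Z) {
  d <- ncol(Z)
  -20 * exp(-0.2 * sqrt(rowSums(Z^2) / d)) -
    exp(rowSums(cos(2 * pi * Z)) / d) + 20 + exp(1)
}
f_griewank <- function(Z) {
  d <- ncol(Z)
  prodterm <- apply(cos(Z / rep(sqrt(seq_len(d)), each = nrow(Z))), 1, prod)
  rowSums(Z^2) / 4000 - prodterm + 1
}
f_elliptic <- function(Z) {
  d <- ncol(Z)
  w <- 1e6^((seq_len(d) - 1) / max(d - 1, 1))
  rowSums(Z^2 * rep(w, each = nrow(Z)))
}
f_bentcigar <- function(Z) Z[, 1]^2 + 1e6 * rowSums(Z[, -1, drop = FALSE]^2)
f_discus <- function(Z) 1e6 * Z[, 1]^2 + rowSums(Z[, -1, drop = FALSE]^2)

# internal scale applied before a basic function so its natural domain is
# reached from the +/-100 box (CEC convention)
basic_table <- list(
  zakharov   = list(fn = f_zakharov,    scale = 1),
  rosenbrock = list(fn = f_rosenbrock,  scale = 2.048 / 100),
  rastrigin  = list(fn = f_rastrigin,   scale = 5.12 / 100),
  schaffer   = list(fn = f_schaffer6exp, scale = 1),
  levy       = list(fn = f_levy,        scale = 1),
  ackley     = list(fn = f_ackley,      scale = 1),
  griewank   = list(fn = f_griewank,    scale = 6),
  elliptic   = list(fn = f_elliptic,    scale = 1),
  bentcigar  = list(fn = f_bentcigar,   scale = 1),
  discus     = list(fn = f_discus,      scale = 1)
)

# seeded random orthogonal matrix via QR of a Gaussian matrix
random_rotation <- function(dim) {
  qr_ <- qr(matrix(stats::rnorm(dim * dim), dim))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), dim)
}

#' Build the 12-function benchmark suite
#'
#' Constructs twelve box-constrained test functions on \eqn{[-100,100]^d}
#' following the CEC2022 class structure: one shifted-rotated unimodal
#' function (Zakharov), four shifted-rotated basic multimodal functions
#' (Rosenbrock, expanded Schaffer F6, Rastrigin, Levy), three hybrid
#' functions (the coordinate vector is split into blocks, each passed to a
#' different basic function), and four composition functions (distance-
#' weighted mixtures of shifted basics). Shifts are drawn uniformly inside
#' the box and rotations from the seeded orthogonal group, so the suite is
#' fully reproducible from `seed`. By construction every function returns
#' its recorded `known_optimum` at its own shift point.
#'
#' @param dim Dimension (>= 2); the benchmark protocol uses 10.
#' @param seed Integer seed for shifts and rotations.
#' @return A list of 12 objects of class `benchmark_function`, each with
#'   `name`, `dim`, `lower`, `upper`, `shift`, `rotation`, `known_optimum`
#'   and the callable `fn` (matrix in, vector out).
#' @export
build_suite <- function(dim, seed = 1L) {
  if (dim < 2) stop("`dim` must be >= 2")
  local_seed(seed, {
    lower <- rep(-100, dim)
    upper <- rep(100, dim)
    mk <- function(name, core) {
      shift <- stats::runif(dim, -80, 80)
      rot <- random_rotation(dim)
      fn <- function(X) {
        Z <- (X - matrix(shift, nrow(X), dim, byrow = TRUE)) %*% t(rot)
        core(Z)
      }
      obj <- structure(list(name = name, dim = dim, lower = lower,
                            upper = upper, shift = shift, rotation = rot,
                            fn = fn, known_optimum = NA_real_),
                       class = "benchmark_function")
      obj$known_optimum <- evaluate_function(obj, shift)
      obj
    }
    basic_core <- function(key, offset = 0) {
      b <- basic_table[[key]]
      function(Z) b$fn(Z * b$scale) + offset
    }
    # hybrid: split the (rotated, shifted) coordinates into blocks; at
    # small dimensions surplus sub-functions are dropped so every block
    # keeps at least one coordinate
    hybrid_core <- function(keys, props) {
      if (dim < length(keys)) {
        keys <- keys[seq_len(dim)]
        props <- props[seq_len(dim)]
      }
      k <- length(keys)
      sizes <- rep(1L, k)
      rem <- dim - k
      if (rem > 0) {
        share <- props / sum(props) * rem
        add <- floor(share)
        sizes <- sizes + add
        left <- rem - sum(add)
        if (left > 0) {
          ord <- order(share - add, decreasing = TRUE)
          sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1L
        }
      }
      idx <- split(seq_len(dim), rep(seq_along(sizes), sizes))
      function(Z) {
        out <- numeric(nrow(Z))
        for (j in seq_along(keys)) {
          b <- basic_table[[keys[j]]]
          out <- out + b$fn(Z[, idx[[j]], drop = FALSE] * b$scale)
        }
        out
      }
    }
    # composition: distance-weighted mixture of basics anchored at local
    # shifts (the first anchor sits at the origin of the already-shifted
    # frame, so the function's own shift stays its anchor point)
    composition_core <- function(keys, sigmas, lambdas) {
      k <- length(keys)
      anchors <- rbind(rep(0, dim),
                       matrix(stats::runif((k - 1) * dim, -60, 60), k - 1))
      biases <- c(0, seq_len(k - 1) * 100)
      function(Z) {
        W <- matrix(0, nrow(Z), k)
        vals <- matrix(0, nrow(Z), k)
        for (j in seq_len(k)) {
          D2 <- rowSums((Z - matrix(anchors[j, ], nrow(Z), dim,
                                    byrow = TRUE))^2)
          W[, j] <- exp(-D2 / (2 * dim * sigmas[j]^2)) / pmax(sqrt(D2), 1e-12)
          b <- basic_table[[keys[j]]]
          vals[, j] <- lambdas[j] *
            b$fn((Z - matrix(anchors[j, ], nrow(Z), dim, byrow = TRUE)) *
                   b$scale) + biases[j]
        }
        W <- W / pmax(rowSums(W), 1e-300)
        rowSums(W * vals)
      }
    }
    list(
      mk("shifted_rotated_zakharov",   basic_core("zakharov")),
      mk("shifted_rotated_rosenbrock", function(Z) {
        b <- basic_table$rosenbrock
        b$fn(Z * b$scale + 1) # optimum of Rosenbrock sits at the ones vector
      }),
      mk("shifted_rotated_schaffer",   basic_core("schaffer")),
      mk("shifted_rotated_rastrigin",  basic_core("rastrigin")),
      mk("shifted_rotated_levy",       basic_core("levy")),
      mk("hybrid_cigar_rastrigin_zakharov",
         hybrid_core(c("bentcigar", "rastrigin", "zakharov"),
                     c(0.4, 0.4, 0.2))),
      mk("hybrid_ackley_griewank_rosenbrock",
         hybrid_core(c("ackley", "griewank", "rosenbrock"),
                     c(0.3, 0.3, 0.4))),
      mk("hybrid_schaffer_levy_discus",
         hybrid_core(c("schaffer", "levy", "discus"), c(0.3, 0.4, 0.3))),
      mk("composition_rastrigin_griewank_schaffer",
         composition_core(c("rastrigin", "griewank", "schaffer"),
                          c(10, 20, 30), c(1, 10, 1))),
      mk("composition_ackley_elliptic_rosenbrock",
         composition_core(c("ackley", "elliptic", "rosenbrock"),
                          c(10, 20, 30), c(1, 1e-6, 1))),
      mk("composition_levy_rastrigin_bentcigar_griewank",
         composition_core(c("levy", "rastrigin", "bentcigar", "griewank"),
                          c(10, 20, 30, 40), c(1, 1, 1e-6, 10))),
      mk("composition_schaffer_discus_rosenbrock_ackley",
         composition_core(c("schaffer", "discus", "rosenbrock", "ackley"),
                          c(10, 20, 30, 40), c(1, 1e-6, 1, 1)))
    )
  })
}

#' Evaluate a benchmark function at one point or a matrix of points
#'
#' @param fn A `benchmark_function` from [build_suite()].
#' @param x Numeric vector of length `fn$dim`, or a matrix with `fn$dim`
#'   columns (rows = points).
#' @return A numeric value (vector input) or vector (matrix input).
#' @export
evaluate_function <- function(fn, x) {
  stopifnot(inherits(fn, "benchmark_function"))
  if (is.matrix(x)) {
    if (ncol(x) != fn$dim) stop("point dimension does not match the function")
    fn$fn(x)
  } else {
    if (length(x) != fn$dim) stop("point dimension does not match the function")
    as.numeric(fn$fn(matrix(x, 1)))
  }
}

#' @export
print.benchmark_function <- function(x, ...) {
  cat(sprintf("<benchmark_function> %s, dim %d, box [%g, %g], f(shift) = %g\n",
              x$name, x$dim, x$lower[1], x$upper[1], x$known_optimum))
  invisible(x)
}

#' Multi-algorithm benchmark comparison
#'
#' Runs each algorithm on each suite function for `runs` independent
#' repeats. The i-th repeat of every algorithm uses the same derived seed,
#' so algorithms are compared on paired initial conditions. A run that
#' errors is recorded as failed (`NA` fitness) and flagged rather than
#' aborting the harness.
#'
#' @param algorithms Character vector from
#'   `c("inpdoa", "npdoa", "ga", "woa")`.
#' @param suite A list of `benchmark_function`s from [build_suite()].
#' @param runs Number of independent repeats (>= 2, or 1 for a smoke run).
#' @param control Base [mh_control()]; its seed field is overridden by the
#'   derived per-run seeds.
#' @param master_seed Integer from which per-run seeds are derived.
#' @return An object of class `benchmark_report`: `results` (long
#'   data.frame of algorithm, fn, run, seed, fitness, failed), `traces`
#'   (list of per-run best-so-far vectors), and `summary` (median, IQR,
#'   boxplot outlier count per algorithm x function).
#' @export
run_comparison <- function(algorithms, suite, runs = 30L,
                           control = mh_control(), master_seed = 1L) {
  stopifnot(runs >= 1)
  seeds <- as.integer(master_seed) + seq_len(runs) * 1000L
  rows <- list()
  traces <- list()
  for (fi in seq_along(suite)) {
    fn <- suite[[fi]]
    for (alg in algorithms) {
      for (r in seq_len(runs)) {
        ctl <- control
        ctl$algorithm <- alg
        ctl$seed <- seeds[r]
        ctl$vectorized <- TRUE
        res <- tryCatch(
          mh_optimize(function(X) evaluate_function(fn, X),
                      fn$lower, fn$upper, ctl),
          error = function(e) NULL
        )
        failed <- is.null(res)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, fn = fn$name, run = r, seed = seeds[r],
          fitness = if (failed) NA_real_ else res$best_fitness,
          failed = failed, stringsAsFactors = FALSE
        )
        traces[[paste(fn$name, alg, r, sep = "|")]] <-
          if (failed) NULL else res$trace
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, traces = traces,
                 summary = summarize_benchmark(results),
                 runs = runs, master_seed = master_seed),
            class = "benchmark_report")
}

# pure aggregation over raw run records
summarize_benchmark <- function(results) {
  agg <- split(results, list(results$algorithm, results$fn), drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(g) {
    v <- g$fitness[!g$failed & is.finite(g$fitness)]
    bs <- if (length(v)) grDevices::boxplot.stats(v) else NULL
    data.frame(algorithm = g$algorithm[1], fn = g$fn[1],
               n = nrow(g), failed = sum(g$failed),
               median = if (length(v)) stats::median(v) else NA_real_,
               iqr = if (length(v)) stats::IQR(v) else NA_real_,
               outliers = if (length(v)) length(bs$out) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d runs x %d algorithm-function cells\n",
              x$runs, nrow(x$summary)))
  print(utils::head(x$summary, 12))
  invisible(x)
}

#' Mean convergence traces per algorithm and function
#'
#' @param report A `benchmark_report`.
#' @return Long data.frame (fn, algorithm, iteration, mean_best).
#' @export
convergence_traces <- function(report) {
  keys <- strsplit(names(report$traces), "|", fixed = TRUE)
  df <- do.call(rbind, Map(function(k, tr) {
    data.frame(fn = k[1], algorithm = k[2], run = as.integer(k[3]),
               iteration = seq_along(tr), best = tr,
               stringsAsFactors = FALSE)
  }, keys, report$traces))
  out <- stats::aggregate(best ~ fn + algorithm + iteration, df, mean)
  names(out)[names(out) == "best"] <- "mean_best"
  out[order(out$fn, out$algorithm, out$iteration), ]
}
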