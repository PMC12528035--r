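test_that("Bernoulli shift map reproduces hand-evaluated orbit values", {
  # x < 1-beta: x/(1-beta); else (x-(1-beta))/beta, beta = 0.4
  expect_equal(bernoulli_sequence(1, beta = 0.4, start = 0.3), 0.5)
  expect_equal(bernoulli_sequence(1, beta = 0.4, start = 0.9), 0.75)
  # consecutive values follow the map (independent re-evaluation)
  v <- bernoulli_sequence(500, beta = 0.4, seed = 3)
  map <- function(x) ifelse(x < 0.6, x / 0.6, (x - 0.6) / 0.4)
  expect_equal(v[-1], map(v[-length(v)]) %% 1, tolerance = 1e-12)
  expect_true(all(v >= 0 & v < 1))
  expect_error(bernoulli_sequence(10, beta = 1.2), "beta")
  expect_error(bernoulli_sequence(10, beta = 0), "beta")
})

test_that("chaotic-map initial population respects bounds and is seeded", {
  lo <- rep(-100, 10); up <- rep(100, 10)
  X <- bernoulli_init(lo, up, 30, seed = 7)
  expect_equal(dim(X), c(30, 10))
  expect_true(all(X >= -100 & X <= 100))
  expect_identical(X, bernoulli_init(lo, up, 30, seed = 7))
  expect_false(identical(X, bernoulli_init(lo, up, 30, seed = 8)))
  expect_error(bernoulli_init(lo, up, 1, seed = 1), "population_size")
  expect_error(bernoulli_init(c(1, 2), c(2, 1), 10), "bound")
})

test_that("map orbit is approximately uniform on the unit interval", {
  u <- bernoulli_sequence(1e4, beta = 0.4, seed = 11)
  counts <- table(cut(u, seq(0, 1, by = 0.1)))
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("Levy steps have the closed-form scale and heavy tails", {
  expect_equal(levy_sigma(1.5), 0.6965745, tolerance = 1e-4)
  set.seed(5)
  expect_length(levy_step(10, 1.5, 1), 10)
  set.seed(5)
  s <- replicate(1e5, 0)
  s <- levy_step(1e5, 1.5, 1)
  kurt <- mean((s - mean(s))^4) / stats::sd(s)^4
  g <- stats::rnorm(1e5)
  kurt_g <- mean((g - mean(g))^4) / stats::sd(g)^4
  expect_gt(kurt, 10 * kurt_g)
  # polynomially decaying survival: the extreme-quantile ratio is far
  # larger than any Gaussian's
  q <- stats::quantile(abs(s), c(0.99, 0.9999))
  expect_gt(q[[2]] / q[[1]], 10)
  expect_error(levy_step(5, 2.5, 1), "levy_beta")
})

test_that("all four algorithms satisfy the elitism and feasibility contracts", {
  lo <- rep(-5, 4); up <- rep(5, 4)
  viol <- new.env(); viol$n <- 0L
  sphere_checked <- function(x) {
    if (any(x < lo - 1e-12 | x > up + 1e-12)) viol$n <- viol$n + 1L
    sum(x^2)
  }
  for (alg in c("inpdoa", "npdoa", "ga", "woa")) {
    for (s in 1:3) {
      r <- mh_optimize(sphere_checked, lo, up,
                       mh_control(population_size = 12, max_iterations = 40,
                                  seed = s, algorithm = alg))
      expect_length(r$trace, 40)
      expect_false(is.unsorted(-r$trace))           # monotone non-increasing
      expect_equal(r$best_fitness, r$trace[40])
      expect_true(all(r$best_position >= lo & r$best_position <= up))
    }
  }
  expect_identical(viol$n, 0L)                      # every evaluation in-bounds
})

test_that("runs are deterministic under a fixed seed", {
  ctl <- mh_control(population_size = 10, max_iterations = 30, seed = 99)
  f <- function(x) sum((x - 1)^2)
  r1 <- mh_optimize(f, rep(-3, 3), rep(3, 3), ctl)
  r2 <- mh_optimize(f, rep(-3, 3), rep(3, 3), ctl)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$trace, r2$trace)
})

test_that("a constant objective yields a flat trace at its value", {
  r <- mh_optimize(function(x) 7, rep(0, 3), rep(1, 3),
                   mh_control(population_size = 8, max_iterations = 20,
                              seed = 1))
  expect_equal(r$best_fitness, 7)
  expect_true(all(r$trace == 7))
})

test_that("non-finite objective values are tolerated, not fatal", {
  f <- function(x) if (x[1] < 0.5) NaN else sum(x^2)
  r <- mh_optimize(f, rep(0, 2), rep(1, 2),
                   mh_control(population_size = 8, max_iterations = 25,
                              seed = 2))
  expect_true(is.finite(r$best_fitness))
})

test_that("the search dominates blind uniform sampling on the sphere", {
  lo <- rep(-100, 10); up <- rep(100, 10)
  sphere <- function(X) rowSums(X^2)
  budget <- 30 * 101 # population x (init + iterations)
  meds <- sapply(1:20, function(s) {
    opt <- mh_optimize(sphere, lo, up,
                       mh_control(max_iterations = 100, seed = s,
                                  vectorized = TRUE))$best_fitness
    rnd <- local({
      set.seed(s)
      X <- matrix(stats::runif(budget * 10, -100, 100), budget)
      min(sphere(X))
    })
    c(opt = opt, rnd = rnd)
  })
  expect_lt(stats::median(meds["opt", ]), stats::median(meds["rnd", ]))
})

test_that("control validation rejects bad parameters", {
  expect_error(mh_control(population_size = 1), "population_size")
  expect_error(mh_control(max_iterations = 0), "max_iterations")
  expect_error(mh_control(bernoulli_beta = 1), "bernoulli_beta")
  expect_error(mh_control(levy_beta = 1), "levy_beta")
})
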