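# Multilinear model machinery: normal-equations and refit-loop oracles,
# subset selection recovery, prediction transforms and fit-statistic
# identities.

random_dataset <- function(n = 20, p = 3, seed = 1, noise_sd = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  y <- 1 + drop(X %*% seq_len(p)) + rnorm(n, sd = noise_sd)
  descriptor_matrix(X, response = y)
}

test_that("noiseless linear data is fitted perfectly", {
  X <- generate_linear_dataset(simulation_spec(
    n = 30, p = 5, informative = 1:3, coefficients = c(1.5, -2, 1),
    intercept = 0.5, noise_sd = 0, seed = 11))
  m <- fit_ols(X, c("d1", "d2", "d3"))
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_lt(m$s2, 1e-10)
  expect_equal(unname(m$coefficients), c(1.5, -2, 1), tolerance = 1e-8)
  expect_equal(m$intercept, 0.5, tolerance = 1e-8)
  expect_equal(loo_cv(X, c("d1", "d2", "d3")), 1, tolerance = 1e-10)
})

test_that("OLS equals the normal-equations closed form", {
  for (seed in 1:5) {
    X <- random_dataset(n = 20, p = 3, seed = seed)
    m <- fit_ols(X, colnames(X$values))
    D <- cbind(1, X$values)
    beta <- solve(t(D) %*% D, t(D) %*% X$response)
    expect_equal(c(m$intercept, m$coefficients), drop(beta),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("fit statistics satisfy their defining identities", {
  X <- random_dataset(n = 25, p = 3, seed = 9)
  m <- fit_ols(X, colnames(X$values))
  n <- m$n; k <- m$k
  expect_equal(m$f, (m$r2 / k) / ((1 - m$r2) / (n - k - 1)),
               tolerance = 1e-8)
  expect_equal(m$s2, m$rss / (n - k - 1), tolerance = 1e-12)
  # t-values agree with lm's
  ref <- summary(lm(X$response ~ X$values))
  expect_equal(unname(m$t_values), unname(ref$coefficients[-1, "t value"]),
               tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  X <- random_dataset(n = 20, p = 3, seed = 2)
  vals <- cbind(X$values, d4 = X$values[, "d1"] * 2)
  X2 <- descriptor_matrix(vals, response = X$response)
  expect_error(fit_ols(X2, colnames(vals)), "collinear.*d4|d4.*collinear")
})

test_that("hat-matrix LOO equals the naive n-refit loop", {
  naive_loo <- function(X, cols) {
    y <- X$response
    M <- X$values[, cols, drop = FALSE]
    press <- 0
    for (i in seq_along(y)) {
      D <- cbind(1, M[-i, , drop = FALSE])
      cf <- qr.coef(qr(D), y[-i])
      press <- press + (y[i] - sum(c(1, M[i, ]) * cf))^2
    }
    1 - press / sum((y - mean(y))^2)
  }
  for (seed in 1:10) {
    X <- random_dataset(n = 15 + seed, p = 3, seed = seed, noise_sd = 1)
    cols <- colnames(X$values)
    expect_equal(loo_cv(X, cols), naive_loo(X, cols), tolerance = 1e-10)
  }
})

test_that("pure-noise responses give q2 below R2", {
  set.seed(99)
  X <- descriptor_matrix(
    matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("d", 1:3))),
    response = rnorm(30))
  m <- fit_ols(X, paste0("d", 1:3))
  expect_lt(loo_cv(X, paste0("d", 1:3)), m$r2)
})

test_that("leave-many-out reduces to leave-one-out and is seeded", {
  X <- random_dataset(n = 24, p = 3, seed = 5, noise_sd = 1)
  cols <- colnames(X$values)
  expect_equal(lmo_cv(X, cols, n_groups = 24, n_repeats = 3, seed = 1),
               loo_cv(X, cols), tolerance = 1e-10)
  a <- lmo_cv(X, cols, n_groups = 3, n_repeats = 20, seed = 7)
  b <- lmo_cv(X, cols, n_groups = 3, n_repeats = 20, seed = 7)
  expect_identical(a, b)
  X0 <- generate_linear_dataset(simulation_spec(
    n = 30, p = 4, informative = 1:3, coefficients = c(1, 2, 3),
    noise_sd = 0, seed = 3))
  expect_equal(lmo_cv(X0, paste0("d", 1:3), n_groups = 3, n_repeats = 5,
                      seed = 42), 1, tolerance = 1e-10)
  expect_error(lmo_cv(X, cols, n_groups = 5), "folds too small")
})

test_that("subset selection returns the only subset when p = k", {
  X <- random_dataset(n = 20, p = 3, seed = 4)
  m <- bmlr_select(X, k = 3)
  expect_setequal(m$descriptors, paste0("d", 1:3))
  expect_true(m$r2cv_loo <= m$r2 + 1e-12)
})

test_that("exhaustive and stepwise modes agree on near-orthogonal signals", {
  X <- generate_linear_dataset(simulation_spec(
    n = 50, p = 8, informative = c(1, 4, 7), coefficients = c(3, -2, 2.5),
    noise_sd = 0.05, rho = 0, seed = 21))
  exhaustive <- bmlr_select(X, k = 3)
  stepwise <- bmlr_select(X, k = 3, max_exhaustive = 1)
  expect_setequal(exhaustive$descriptors, c("d1", "d4", "d7"))
  expect_setequal(stepwise$descriptors, exhaustive$descriptors)
})

test_that("selection recovers an informative triple under mild noise", {
  hits <- 0
  for (seed in 1:25) {
    spec <- simulation_spec(n = 40, p = 10, informative = c(2, 5, 9),
                            coefficients = c(2, -1.5, 1), noise_sd = 0,
                            seed = seed)
    base <- generate_linear_dataset(spec)
    sd_y <- sd(base$response)
    spec$noise_sd <- 0.05 * sd_y
    X <- generate_linear_dataset(spec)
    m <- bmlr_select(X, k = 3)
    if (setequal(m$descriptors, c("d2", "d5", "d9"))) hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("prediction applies coefficients and the response transform", {
  m <- structure(list(descriptors = "x", coefficients = c(x = 2),
                      intercept = 1, transform = "identity"),
                 class = "qsar_model")
  expect_equal(predict(m, c(x = 3)), 7)
  m$transform <- "reciprocal"
  m$intercept <- 0.02; m$coefficients <- c(x = 0)
  expect_equal(predict(m, c(x = 5)), 50)
  expect_error(predict(m, c(z = 1)), "missing descriptor")
  m$intercept <- 0
  expect_error(predict(m, c(x = 1)), "zero linear predictor")
})

test_that("a negative coefficient gives monotonically decreasing predictions", {
  # the donor-surface-area term of the anti-inflammatory model: coefficient
  # -0.0149 means higher descriptor values predict lower activity
  m <- structure(list(descriptors = "hdonors_psa",
                      coefficients = c(hdonors_psa = -0.0149),
                      intercept = 1, transform = "identity"),
                 class = "qsar_model")
  lo <- predict(m, c(hdonors_psa = 1.909))
  hi <- predict(m, c(hdonors_psa = 11.928))
  expect_lt(hi, lo)
})

test_that("R2 is invariant to affine descriptor rescaling", {
  X <- random_dataset(n = 25, p = 3, seed = 13)
  m1 <- fit_ols(X, paste0("d", 1:3))
  vals <- X$values
  vals[, "d1"] <- 10 * vals[, "d1"] + 5
  X2 <- descriptor_matrix(vals, response = X$response)
  m2 <- fit_ols(X2, paste0("d", 1:3))
  expect_equal(m2$r2, m1$r2, tolerance = 1e-10)
  expect_equal(unname(m2$coefficients["d1"]),
               unname(m1$coefficients["d1"]) / 10, tolerance = 1e-10)
})

test_that("adding a pure-noise column never lowers in-sample R2", {
  for (seed in 1:5) {
    X <- random_dataset(n = 30, p = 3, seed = seed, noise_sd = 1)
    m1 <- fit_ols(X, paste0("d", 1:3))
    set.seed(seed + 100)
    vals <- cbind(X$values, noise = rnorm(30))
    X2 <- descriptor_matrix(vals, response = X$response)
    m2 <- fit_ols(X2, colnames(vals))
    expect_gte(m2$r2, m1$r2 - 1e-12)
  }
})

test_that("model serialisation round-trips through the text format", {
  X <- random_dataset(n = 20, p = 3, seed = 6)
  m <- bmlr_select(X, k = 2)
  f <- tempfile(fileext = ".yml")
  write_qsar_model(m, f)
  back <- read_qsar_model(f)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-9)
  expect_equal(back$r2, m$r2, tolerance = 1e-9)
  expect_equal(back$descriptors, m$descriptors)
  expect_equal(predict(back, X$values[1, ]), predict(m, X$values[1, ]),
               tolerance = 1e-9)
  unlink(f)
})
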