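test_that("log2-offset transform matches closed forms", {
  expect_equal(coverage_transform(matrix(0), offset = 0.5)[1], -1)
  expect_equal(coverage_transform(matrix(3.5), offset = 0.5)[1], 2)
  expect_equal(coverage_transform(matrix(0), offset = 1)[1], 0)
  expect_error(coverage_transform(matrix(1), offset = 0), "positive")
})

test_that("per-base OLS recovers the hand-worked two-group fit", {
  y <- matrix(c(1, 2, 3, 4), nrow = 1)
  d <- der_design(c("g1", "g1", "g2", "g2"))
  fit <- fit_base_models(y, d)
  expect_equal(unname(fit$coefficients[1, 2]), 2)
  expect_equal(unname(fit$resid_var[1]), 0.5)
  expect_equal(fit$df, 2)
  expect_equal(unname(fit$contrast_scale), 1)  # 1/2 + 1/2
  # constant row: zero effect, zero variance
  fit0 <- fit_base_models(matrix(5, 1, 4), d)
  expect_equal(unname(fit0$coefficients[1, 2]), 0)
  expect_equal(unname(fit0$resid_var[1]), 0)
  # collinear confounder is named in the error
  dd <- der_design(c("g1", "g1", "g2", "g2"),
                   confounders = cbind(const = rep(1, 4)))
  expect_error(fit_base_models(y, dd), "const")
})

test_that("vectorized OLS agrees with a direct normal-equations solve", {
  set.seed(7)
  for (rep in 1:5) {
    nb <- sample(5:20, 1); n <- sample(c(6, 8), 1)
    y <- matrix(rnorm(nb * n), nb, n)
    d <- der_design(rep(c("g1", "g2"), each = n / 2),
                    confounders = cbind(w = rnorm(n)))
    fit <- fit_base_models(y, d)
    X <- fit$design_matrix
    for (j in seq_len(nb)) {
      beta <- solve(t(X) %*% X, t(X) %*% y[j, ])
      expect_equal(unname(fit$coefficients[j, ]), unname(drop(beta)),
                   tolerance = 1e-10)
    }
  }
})

test_that("moderated t matches the posterior-variance closed form", {
  # hand example: beta = 2, s2 = 0.5, d = 2, v = 1, d0 = 4, s02 = 1
  fit <- structure(list(coefficients = cbind(a = 0, g = 2),
                        resid_var = 0.5, df = 2, contrast_scale = 1,
                        vcov_unscaled = diag(2), group_cols = 2L),
                   class = "base_fit")
  cov1 <- coverage_matrix("c", 0L, matrix(10, 1, 4), paste0("s", 1:4))
  bs <- moderate_statistics(fit, cov1, cutoff = 5, d0 = 4, s02 = 1)
  expect_equal(bs$posterior_var[1], 5 / 6)
  expect_equal(bs$statistic[1], 2 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(bs$statistic[1], 2.1909, tolerance = 1e-4)
})

test_that("d0 = 0 reduces to the ordinary t statistic", {
  set.seed(21)
  n <- 8
  y <- matrix(rnorm(1000 * n, mean = 5), 1000, n)
  d <- der_design(rep(c("g1", "g2"), each = 4))
  cov <- coverage_matrix("c", 0:999,
                         matrix(rpois(1000 * n, 20), 1000, n),
                         paste0("s", 1:n))
  fit <- fit_base_models(y, d)
  bs <- moderate_statistics(fit, cov, cutoff = 1, d0 = 0, s02 = 1)
  plain <- fit$coefficients[, 2] / sqrt(fit$resid_var * fit$contrast_scale)
  expect_equal(bs$statistic, unname(plain), tolerance = 1e-10)
})

test_that("posterior variance lies between sample and prior variance", {
  set.seed(22)
  n <- 6
  # heterogeneous per-base variances so the prior df is finite
  y <- matrix(rnorm(500 * n, sd = rep(exp(rnorm(500, 0, 0.6)), n)), 500, n)
  d <- der_design(rep(c("g1", "g2"), each = 3))
  cov <- coverage_matrix("c", 0:499, matrix(10, 500, n), paste0("s", 1:n))
  fit <- fit_base_models(y, d)
  bs <- moderate_statistics(fit, cov, cutoff = 1)
  expect_true(is.finite(bs$d0) && bs$d0 > 0)
  lo <- pmin(fit$resid_var, bs$s02) - 1e-12
  hi <- pmax(fit$resid_var, bs$s02) + 1e-12
  expect_true(all(bs$posterior_var >= lo & bs$posterior_var <= hi))
  # statistic is beta over the moderated standard error, hence monotone in
  # beta_hat for fixed (s2, d, d0, s02, v)
  expect_equal(bs$statistic,
               unname(fit$coefficients[, 2] /
                        sqrt(bs$posterior_var * fit$contrast_scale)),
               tolerance = 1e-12)
})

test_that("shrinkage hyperparameters agree with limma's moment matching", {
  skip_if_not_installed("limma")
  set.seed(23)
  s2 <- 0.4 * rchisq(2000, df = 5) / 5 * exp(rnorm(2000, 0, 0.4))
  pr <- derseg:::estimate_shrink_prior(s2, df = 5)
  sq <- limma::squeezeVar(s2, df = 5)
  expect_equal(pr$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(pr$s02, sq$var.prior, tolerance = 0.05)
  post <- (pr$d0 * pr$s02 + 5 * s2) / (pr$d0 + 5)
  expect_equal(post, sq$var.post, tolerance = 0.05)
})

test_that("unexpressed bases carry statistic exactly zero", {
  sim <- small_sim()
  y <- coverage_transform(sim$coverage)
  fit <- fit_base_models(y, sim$design)
  bs <- moderate_statistics(fit, sim$coverage, cutoff = 5)
  expect_true(all(bs$statistic[!bs$expressed] == 0))
  expect_true(all(is.finite(bs$statistic)))
})

test_that("statistic track writes and reads back bit-exactly", {
  sim <- small_sim()
  y <- coverage_transform(sim$coverage)
  fit <- fit_base_models(y, sim$design)
  bs <- moderate_statistics(fit, sim$coverage)
  f <- tempfile(fileext = ".tsv")
  write_base_stats(bs, f)
  back <- read_base_stats(f)
  expect_identical(back$statistic, bs$statistic)
  expect_identical(back$expressed, bs$expressed)
  expect_identical(back$position, bs$positions)
})
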