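test_that("lagged designs have the documented geometry", {
  ps <- make_processed(n = 1, T = 3, seed = 1)
  d <- build_lagged_design(ps, "g01", 1L)
  expect_equal(d$y, ps$values[1, 2:3])
  expect_equal(unname(d$X), matrix(ps$values[1, 1:2], 2, 1))

  ps2 <- make_processed(n = 3, T = 50, seed = 2)
  d2 <- build_lagged_design(ps2, "g02", 4L)
  expect_equal(ncol(d2$X), 12)
  expect_equal(nrow(d2$X), 46)
  # row r, column (g, k) holds genus g at time r + L - k
  for (r in c(1, 20, 46)) for (g in 1:3) for (k in 1:4)
    expect_equal(d2$X[[r, (g - 1) * 4 + k]], ps2$values[[g, r + 4 - k]])
  # columns ordered by taxon then ascending lag
  expect_identical(d2$labels$taxon[1:8], rep(c("g01", "g02"), each = 4))
  expect_identical(d2$labels$lag[1:4], 1:4)
  expect_error(build_lagged_design(ps2, "g02", 50L), "smaller")
  expect_error(build_lagged_design(ps2, "nope", 4L), "unknown response")
})

test_that("hypothesis budgets reproduce pairwise and conditional arithmetic", {
  expect_equal(hypothesis_budget(23, 0.05, "pairwise"),
               list(hypotheses = 253L, expected_false_positives = 13L))
  expect_equal(hypothesis_budget(52, 0.05, "pairwise"),
               list(hypotheses = 1326L, expected_false_positives = 66L))
  expect_equal(hypothesis_budget(52, 0.05, "conditional"),
               list(hypotheses = 52L, expected_false_positives = 3L))
  expect_equal(hypothesis_budget(23, 0.05, "conditional")$hypotheses, 23L)
})

test_that("lambda_max is the activation boundary and scales with y", {
  set.seed(3)
  X <- matrix(rnorm(60 * 5), 60)
  y <- X %*% c(1, -1, 0, 0, 0.5) + rnorm(60, sd = 0.3)
  d <- list(X = X, y = as.numeric(y))
  lm0 <- lambda_max(d)
  expect_true(all(lasso_fit(d, 1.01 * lm0)$coefficients == 0))
  expect_lt(max(abs(lasso_fit(d, lm0)$coefficients)), 1e-15)
  expect_gt(sum(lasso_fit(d, 0.5 * lm0)$coefficients != 0), 0)
  d2 <- list(X = X, y = 3 * d$y)
  expect_equal(lambda_max(d2), 3 * lm0)
  # y orthogonal to all columns (after centering): lambda_max 0
  dortho <- list(X = matrix(c(1, -1, 0, 0, 0, 0, 1, -1), 4), y = rep(2, 4))
  expect_equal(lambda_max(dortho), 0)
})

test_that("unpenalized fit matches least squares on a well-conditioned design", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30)
  y <- as.numeric(X %*% c(2, -1, 0.5) + rnorm(30, sd = 0.1))
  f <- lasso_fit(list(X = X, y = y), 0)
  ols <- lm(y ~ X)
  expect_lt(max(abs(f$coefficients - coef(ols)[-1])), 1e-6)
  expect_lt(abs(f$intercept - coef(ols)[1]), 1e-6)
})

test_that("single orthonormalized predictor soft-thresholds the OLS value", {
  set.seed(5)
  x <- rnorm(50)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 0.8 * x + rnorm(50, sd = 0.2)
  b_ols <- mean(x * (y - mean(y)))
  for (lam in c(0.05, 0.3, 1.2)) {
    f <- lasso_fit(list(X = matrix(x), y = y), lam)
    expect_equal(unname(f$coefficients),
                 sign(b_ols) * max(abs(b_ols) - lam, 0), tolerance = 1e-7)
  }
})

test_that("fitted support and signs match exhaustive sign enumeration", {
  set.seed(6)
  for (rep in 1:3) {
    p <- sample(3:5, 1)
    X <- matrix(rnorm(25 * p), 25)
    beta <- numeric(p); beta[1:2] <- c(1, -0.7)
    y <- as.numeric(X %*% beta + rnorm(25, sd = 0.4))
    lam <- 0.1 * rep
    f <- lasso_fit(list(X = X, y = y), lam)
    bf <- lasso_brute(X, y, lam)
    expect_equal(unname(f$coefficients), as.numeric(bf$beta),
                 tolerance = 1e-6)
  }
})

test_that("coordinate descent agrees with an independent lasso solver", {
  set.seed(7)
  X <- matrix(rnorm(200 * 12), 200)
  y <- as.numeric(X[, 1] * 0.5 - X[, 3] * 0.4 + rnorm(200, sd = 0.5))
  for (lam in c(0.02, 0.1)) {
    f <- lasso_fit(list(X = X, y = y), lam)
    g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                        thresh = 1e-12)
    expect_equal(unname(f$coefficients), as.numeric(g$beta),
                 tolerance = 1e-6)
  }
})

test_that("objective is non-increasing and sparsity is monotone at the extremes", {
  set.seed(8)
  X <- matrix(rnorm(80 * 15), 80)
  y <- as.numeric(X %*% rnorm(15, sd = 0.3) + rnorm(80))
  d <- list(X = X, y = y)
  f <- lasso_fit(d, 0.05)
  expect_true(all(diff(f$objective) <= 1e-10))
  lmx <- lambda_max(d)
  grid <- exp(seq(log(lmx), log(lmx / 1e4), length.out = 10))
  nz <- vapply(grid, function(l)
    sum(lasso_fit(d, l)$coefficients != 0), integer(1))
  expect_gte(nz[length(nz)], nz[1])
  expect_equal(nz[1], 0L)
})

test_that("rolling selection recovers planted predictors and handles noise", {
  kp <- make_known_predictor_series(Tprime = 350, seed = 1)
  cfg <- run_config(seed = 1)
  pp <- rolling_cv_select(kp$series, kp$response, cfg)
  expect_s3_class(pp, "penalty_path")
  expect_true(all(diff(pp$grid) < 0))
  expect_true(pp$selected %in% pp$grid)
  d <- build_lagged_design(kp$series, kp$response, cfg$lags)
  fit <- lasso_fit(d, pp$selected)
  got <- fit$coefficients[paste0(kp$truth$taxon, ".L", kp$truth$lag)]
  expect_true(all(got != 0))
  expect_equal(sign(unname(got)), sign(kp$truth$coefficient))

  # grid of size 1 selects that penalty
  cfg1 <- run_config(lambda_grid_size = 1L, seed = 1)
  pp1 <- rolling_cv_select(kp$series, kp$response, cfg1)
  expect_equal(pp1$selected, pp1$grid[1])

  expect_error(rolling_cv_select(make_processed(n = 2, T = 50, seed = 2),
                                 "g01", run_config(lags = 20L)),
               "too short")
})

test_that("rolling msfe is independent of warm starting", {
  ps <- make_processed(n = 2, T = 60, seed = 9)
  cfg <- run_config(lags = 3L, short_range = c(1L, 1L),
                    long_range = c(3L, 3L), lambda_grid_size = 8L, seed = 9)
  a <- rolling_cv_select(ps, "g01", cfg, warm = TRUE, cv_tol = 1e-9,
                         cv_maxit = 5000L)
  b <- rolling_cv_select(ps, "g01", cfg, warm = FALSE, cv_tol = 1e-9,
                         cv_maxit = 5000L)
  expect_equal(a$msfe, b$msfe, tolerance = 1e-6)
  expect_equal(a$selected, b$selected)
})

test_that("full-community fits are sparse on independent white noise", {
  ps <- make_processed(n = 2, T = 150, seed = 12)
  cfg <- run_config(lags = 10L, short_range = c(1L, 3L),
                    long_range = c(8L, 10L), seed = 12)
  tensor <- fit_all_responses(ps, cfg)
  expect_equal(dim(tensor$B), c(2, 2, 10))
  expect_gte(mean(tensor$B == 0), 0.9)
})
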