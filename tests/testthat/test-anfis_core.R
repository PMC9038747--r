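test_that("gaussian membership peaks at the center and decays monotonically", {
  expect_equal(gaussian_membership(3, 3, 0.7), 1)
  expect_equal(gaussian_membership(1 + 2, c = 1, sigma = 2), exp(-0.5))
  m_wide <- gaussian_membership(2, 0, 1)
  m_narrow <- gaussian_membership(2, 0, 0.5)
  expect_lt(m_narrow, m_wide)
  expect_error(gaussian_membership(1, 0, 0), "positive")
  # strictly decreasing in |x - c|
  xs <- seq(0, 4, by = 0.5)
  expect_true(all(diff(gaussian_membership(xs, 0, 1.3)) < 0))
})

test_that("rule firing is the product of per-input memberships", {
  expect_equal(rule_firing(c(1, 2), centers = c(1, 2), sigmas = c(1, 1)), 1)
  # two inputs, each at membership 0.5
  off <- sqrt(-2 * log(0.5))
  expect_equal(rule_firing(c(off, off), c(0, 0), c(1, 1)), 0.25)
  expect_error(rule_firing(c(1, 2, 3), c(0, 0), c(1, 1)), "length")
})

test_that("inference is the firing-weighted average of rule outputs", {
  m1 <- anfis_model(matrix(0, 1, 2), matrix(1, 1, 2),
                    consequents = matrix(c(2, -1, 0.5), 1, 3))
  x <- c(1.3, -0.4)
  expect_equal(anfis_infer(m1, x), 2 * 1.3 - 1 * (-0.4) + 0.5)

  # raw firings 0.6 and 0.2 normalize to 0.75 / 0.25; outputs 4 and 8 -> 5
  c1 <- sqrt(-2 * log(0.6))
  c2 <- sqrt(-2 * log(0.2))
  m2 <- anfis_model(matrix(c(c1, c2), 2, 1), matrix(1, 2, 1),
                    consequents = rbind(c(0, 4), c(0, 8)))
  expect_equal(anfis_infer(m2, 0), 5)

  # equal firing -> arithmetic mean of the consequents
  m3 <- anfis_model(matrix(c(-1, 1), 2, 1), matrix(1, 2, 1),
                    consequents = rbind(c(0, 10), c(0, 20)))
  expect_equal(anfis_infer(m3, 0), 15)
})

test_that("inference falls back to the nearest rule when firing underflows", {
  m <- anfis_model(matrix(c(0, 100), 2, 1), matrix(c(1e-4, 1e-4), 2, 1),
                   consequents = rbind(c(0, -7), c(0, 7)))
  expect_equal(anfis_infer(m, 60), 7)   # nearer (sigma-scaled) to 100
  expect_equal(anfis_infer(m, 40), -7)
  # output stays within the hull of the rule outputs at the query point
  xs <- matrix(seq(-5, 105, length.out = 50), ncol = 1)
  preds <- anfis_infer(m, xs)
  expect_true(all(preds >= -7 - 1e-12 & preds <= 7 + 1e-12))
})

test_that("fcm recovers trivial and well-separated structure", {
  X <- matrix(rnorm(60), 30, 2)
  one <- fcm_cluster(X, k = 1, seed = 1)
  expect_equal(drop(one$centers), colMeans(X), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(one$memberships - 1) < 1e-12))

  set.seed(7)
  blob1 <- matrix(rnorm(100, mean = 0, sd = 0.3), 50, 2)
  blob2 <- matrix(rnorm(100, mean = 6, sd = 0.3), 50, 2)
  X2 <- rbind(blob1, blob2)
  fit <- fcm_cluster(X2, k = 2, seed = 2)
  # each center within 3 intra-blob sd of a blob mean
  d_to <- function(center, blob) sqrt(sum((center - colMeans(blob))^2))
  d1 <- apply(fit$centers, 1, d_to, blob = blob1)
  d2 <- apply(fit$centers, 1, d_to, blob = blob2)
  expect_lt(min(d1), 3 * 0.3)
  expect_lt(min(d2), 3 * 0.3)
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  expect_true(all(diff(fit$objective) <= 1e-8))  # non-increasing objective
})

test_that("fcm handles duplicate points and coincident centers", {
  X <- matrix(rep(c(0, 0, 5, 5), each = 10), ncol = 1)
  fit <- fcm_cluster(X, k = 2, seed = 3)
  expect_true(all(is.finite(fit$memberships)))
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  expect_error(fcm_cluster(X[1:1, , drop = FALSE], k = 2), "at least")
})

test_that("fcm-initialized models beat a global linear fit on clustered data", {
  set.seed(21)
  n <- 60
  grp <- rep(1:3, each = n)
  X <- cbind(rnorm(3 * n, mean = c(0, 5, 10)[grp], sd = 0.5),
             rnorm(3 * n, mean = c(0, -4, 4)[grp], sd = 0.5))
  slopes <- rbind(c(2, 1), c(-3, 0.5), c(1, -2))
  y <- rowSums(X * slopes[grp, ]) + c(0, 10, -5)[grp] + rnorm(3 * n, 0, 0.05)
  model <- anfis_init_fcm(X, y, k = 3, seed = 4)
  expect_equal(nrow(model$centers), 3)
  expect_true(all(model$sigmas > 0))
  rmse_fcm <- sqrt(mean((y - anfis_infer(model, X))^2))
  rmse_lm <- sqrt(mean(stats::lm.fit(cbind(1, X), y)$residuals^2))
  expect_lt(rmse_fcm, rmse_lm)
})

test_that("width floor engages for a degenerate single-point cluster", {
  X <- rbind(matrix(rnorm(40, sd = 0.2), 20, 2), c(100, 100))
  y <- rnorm(21)
  model <- anfis_init_fcm(X, y, k = 2, seed = 5)
  floor_sigma <- 0.01 * apply(X, 2, function(v) diff(range(v)))
  expect_true(all(sweep(model$sigmas, 2, floor_sigma, `-`) >= -1e-12))
})

test_that("consequent solving recovers a known model and handles edge cases", {
  truth <- tiny_tsk_model()
  X <- tiny_feature_grid(60)
  y <- anfis_infer(truth, X)
  blank <- anfis_model(truth$centers, truth$sigmas,
                       input_names = truth$input_names)
  solved <- solve_consequents(blank, X, y)
  expect_equal(solved$consequents, truth$consequents, tolerance = 1e-4)
  expect_equal(anfis_infer(solved, X), y, tolerance = 1e-6)

  # constant target reproduced exactly
  const <- solve_consequents(blank, X, rep(4.2, nrow(X)))
  expect_equal(anfis_infer(const, X), rep(4.2, nrow(X)), tolerance = 1e-6)

  # fewer samples than parameters: still finite (ridge)
  tiny <- solve_consequents(blank, X[1:3, ], y[1:3])
  expect_true(all(is.finite(tiny$consequents)))
})

test_that("a one-rule wide model reduces to ordinary least squares", {
  set.seed(31)
  X <- matrix(runif(80, -1, 1), 40, 2)
  y <- 3 * X[, 1] - 2 * X[, 2] + 0.7 + rnorm(40, 0, 0.1)
  m <- anfis_model(matrix(colMeans(X), 1, 2), matrix(1e6, 1, 2))
  m <- solve_consequents(m, X, y)
  ols <- stats::lm.fit(cbind(X, 1), y)$coefficients
  expect_equal(drop(m$consequents), unname(ols), tolerance = 1e-6)
})

test_that("JSON serialization round-trips a model bit-exactly", {
  m <- tiny_tsk_model()
  m$centers[1, 1] <- 1 / 3  # not representable in short decimal
  m$sigmas[2, 2] <- sqrt(2)
  js <- anfis_to_json(m)
  back <- anfis_from_json(js)
  expect_identical(back$centers, m$centers)
  expect_identical(back$sigmas, m$sigmas)
  expect_identical(back$consequents, m$consequents)
  expect_identical(back$input_names, m$input_names)
  expect_identical(back$target_name, m$target_name)
  # file round trip, consequent-free model
  blank <- anfis_model(m$centers, m$sigmas, input_names = m$input_names)
  path <- tempfile(fileext = ".json")
  anfis_to_json(blank, path)
  expect_null(anfis_from_json(path)$consequents)
})

test_that("model constructor enforces its invariants", {
  expect_error(anfis_model(matrix(0, 1, 2), matrix(c(1, -1), 1, 2)),
               "positive")
  expect_error(anfis_model(matrix(0, 1, 2), matrix(1, 2, 2)), "identical")
  expect_error(anfis_model(matrix(0, 1, 2), matrix(1, 1, 2),
                           consequents = matrix(0, 1, 2)), "n x")
  expect_error(anfis_infer(anfis_model(matrix(0, 1, 1), matrix(1, 1, 1)), 0),
               "consequent")
})
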