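test_that("kernel PLS reproduces NIPALS PLS1 predictions", {
  set.seed(11)
  for (i in 1:5) {
    X <- matrix(rnorm(30 * 50), 30, 50)
    beta0 <- rnorm(50)
    y <- drop(X %*% beta0) + rnorm(30, sd = 0.3)
    Xnew <- matrix(rnorm(8 * 50), 8, 50)
    for (k in c(1, 3, 5)) {
      m <- fit_phenolic_model(X, y, "kpls", weight = k)
      ref <- nipals_pls(X, y, k)
      expect_equal(predict(m, Xnew), nipals_predict(ref, Xnew),
                   tolerance = 1e-8)
    }
  }
})

test_that("full-rank kernel PLS equals ordinary least squares", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(40)
  Xnew <- matrix(rnorm(10 * 6), 10, 6)
  m <- fit_phenolic_model(X, y, "kpls", weight = 6)
  expect_equal(predict(m, Xnew), oracle_ols_predict(X, y, Xnew),
               tolerance = 1e-8)
})

test_that("kernel ridge converges to least squares as the penalty vanishes", {
  set.seed(13)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(50)
  Xnew <- matrix(rnorm(10 * 5), 10, 5)
  m <- fit_phenolic_model(X, y, "krr", weight = 1e-8)
  expect_equal(predict(m, Xnew), oracle_ols_predict(X, y, Xnew),
               tolerance = 1e-5)
})

test_that("ridge training error grows monotonically with the penalty", {
  set.seed(14)
  X <- matrix(rnorm(60 * 20), 60, 20)
  y <- drop(X %*% rnorm(20)) + rnorm(60)
  errs <- vapply(10^seq(-4, 3), function(lam) {
    m <- fit_phenolic_model(X, y, "krr", weight = lam)
    rmse(predict(m, X), y)
  }, numeric(1))
  expect_true(all(diff(errs) >= -1e-10))
})

test_that("SVR training error shrinks with cost on noise-free data", {
  set.seed(15)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- drop(X %*% rnorm(10))
  errs <- vapply(c(0.1, 10, 1000), function(cost) {
    m <- fit_phenolic_model(X, y, "svr", weight = cost, epsilon = 0.01)
    rmse(predict(m, X), y)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_lt(errs[3], errs[1] / 2)
})

test_that("linear back-ends are exactly equivariant to response scaling", {
  set.seed(16)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- drop(X %*% rnorm(12)) + rnorm(40, sd = 0.1)
  Xnew <- matrix(rnorm(6 * 12), 6, 12)
  c0 <- 37.5
  for (alg in c("krr", "kpls")) {
    w <- if (alg == "krr") 0.5 else 4
    p1 <- predict(fit_phenolic_model(X, y, alg, weight = w), Xnew)
    p2 <- predict(fit_phenolic_model(X, c0 * y, alg, weight = w), Xnew)
    expect_equal(p2, c0 * p1, tolerance = 1e-8)
  }
  # SVR scales once cost and tube half-width are rescaled with the response
  p1 <- predict(fit_phenolic_model(X, y, "svr", weight = 10, epsilon = 0.1), Xnew)
  p2 <- predict(fit_phenolic_model(X, c0 * y, "svr", weight = 10 * c0,
                                   epsilon = 0.1 * c0), Xnew)
  expect_equal(p2, c0 * p1, tolerance = 1e-3)
})

test_that("prediction is equivariant to row permutations", {
  set.seed(17)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- drop(X %*% rnorm(8))
  Xnew <- matrix(rnorm(9 * 8), 9, 8)
  perm <- sample(9)
  for (alg in c("svr", "krr", "kpls")) {
    m <- fit_phenolic_model(X, y, alg, weight = if (alg == "kpls") 3 else 1)
    expect_equal(predict(m, Xnew)[perm], predict(m, Xnew[perm, ]),
                 tolerance = 1e-12)
  }
})

test_that("model input contracts are enforced", {
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  expect_error(fit_phenolic_model(X, y[-1], "svr", weight = 1),
               class = "wp_usage_error")
  expect_error(fit_phenolic_model(X, y, "kpls", weight = 0),
               class = "wp_usage_error")
  expect_error(fit_phenolic_model(X, y, "kpls", weight = 2.5),
               class = "wp_usage_error")
  expect_error(fit_phenolic_model(X, y, "kpls", weight = 6),
               class = "wp_usage_error")  # > min(n - 1, p)
  expect_error(fit_phenolic_model(X, y, "svr", weight = -1),
               class = "wp_usage_error")
  X[2, 2] <- Inf
  expect_error(fit_phenolic_model(X, y, "krr", weight = 1),
               class = "wp_data_error")
  m <- fit_phenolic_model(matrix(rnorm(100), 20, 5), y, "krr", weight = 1)
  expect_error(predict(m, matrix(rnorm(12), 3, 4)), class = "wp_usage_error")
})

test_that("models built from spectra enforce matching wavelengths", {
  sim <- simulate_calibration_set(mixture_design(n = 30, seed = 19))
  feats <- features_for(sim$spectra, "anthocyanins")
  m <- fit_phenolic_model(feats, sim$assays$anthocyanins, "kpls", weight = 3)
  other <- restrict_spectra(sim$spectra, 230, 500)  # same count, wrong window
  expect_error(predict(m, other), class = "wp_usage_error")
  expect_equal(length(predict(m, feats[1, ])), 1L)
})

test_that("random_split honors the 90/10 protocol and is reproducible", {
  s <- random_split(323, 0.9, seed = 1)
  expect_equal(length(s$train), 290L)
  expect_equal(length(s$test), 33L)
  expect_identical(sort(c(s$train, s$test)), 1:323)
  expect_identical(s, random_split(323, 0.9, seed = 1))
  expect_false(identical(s$train, random_split(323, 0.9, seed = 2)$train))
  expect_error(random_split(1), class = "wp_usage_error")
  expect_error(random_split(10, 1.2), class = "wp_usage_error")
})

test_that("repeated validation recovers a noise-free linear signal", {
  sim <- simulate_calibration_set(noise_free_design(80, seed = 21))
  feats <- features_for(sim$spectra, "anthocyanins")
  y <- sim$assays$anthocyanins
  # noise-free single-component visible spectra have rank 1: one PLS
  # component captures everything
  for (alg in c("svr", "krr", "kpls")) {
    w <- switch(alg, svr = 1000, krr = 1e-4, kpls = 1)
    res <- repeated_validation(feats, y, alg, weight = w, repeats = 3, seed = 5)
    expect_gt(res$summary$r2_p, 0.99)
    expect_gt(res$summary$r2_c, 0.99)
  }
})

test_that("a single repeat makes CV and prediction metrics coincide", {
  sim <- simulate_calibration_set(mixture_design(n = 40, seed = 22))
  feats <- features_for(sim$spectra, "anthocyanins")
  res <- repeated_validation(feats, sim$assays$anthocyanins, "kpls",
                             weight = 3, repeats = 1, seed = 9)
  expect_equal(res$summary$r2_cv, res$summary$r2_p)
  expect_equal(res$summary$rmsecv, res$summary$rmsep)
  expect_equal(nrow(res$per_repeat), 1L)
  expect_equal(nrow(res$pooled), 4L)  # floor(0.9 * 40) = 36 train, 4 test
})

test_that("validation is deterministic for a fixed master seed", {
  sim <- simulate_calibration_set(mixture_design(n = 40, seed = 23))
  feats <- features_for(sim$spectra, "anthocyanins")
  r1 <- repeated_validation(feats, sim$assays$anthocyanins, "krr",
                            weight = 0.01, repeats = 4, seed = 77)
  r2 <- repeated_validation(feats, sim$assays$anthocyanins, "krr",
                            weight = 0.01, repeats = 4, seed = 77)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$pooled, r2$pooled)
})

test_that("weight_search follows the floor, peak and stop rules on stubs", {
  grid <- 1:7
  # unimodal: peak at 3, two declines stop the walk before exhausting
  ws <- weight_search(grid = grid,
                      evaluator = profile_evaluator(grid, c(0.55, 0.7, 0.9,
                                                            0.8, 0.75, 0.6, 0.5)))
  expect_equal(ws$chosen_weight, 3)
  expect_equal(ws$termination, "declined")
  expect_lt(nrow(ws$trace), length(grid))

  # monotone: never declines, runs out of grid, picks the last point
  ws2 <- weight_search(grid = grid,
                       evaluator = profile_evaluator(grid, seq(0.2, 0.9, length.out = 7)))
  expect_equal(ws2$chosen_weight, 7)
  expect_equal(ws2$termination, "grid exhausted")

  # flat: ties break toward the least flexible weight
  ws3 <- weight_search(grid = grid,
                       evaluator = profile_evaluator(grid, rep(0.8, 7)))
  expect_equal(ws3$chosen_weight, 1)
  expect_equal(ws3$termination, "grid exhausted")
})

test_that("weight_search starts at the last sub-floor grid point", {
  grid <- 1:6
  ws <- weight_search(grid = grid,
                      evaluator = profile_evaluator(grid, c(0.3, 0.45, 0.9,
                                                            0.7, 0.6, 0.55)))
  # the initial sub-floor run ends at index 2: index 1 is not a candidate,
  # the last sub-floor point itself is
  expect_equal(ws$termination, "declined")
  expect_identical(ws$trace$candidate,
                   c(FALSE, TRUE, TRUE, TRUE, TRUE)[seq_len(nrow(ws$trace))])
  expect_equal(ws$chosen_weight, 3)
})

test_that("weight_search validates its grid", {
  expect_error(weight_search(grid = numeric(0), evaluator = identity),
               class = "wp_usage_error")
  expect_error(weight_search(grid = c(1, 3, 2), evaluator = identity),
               class = "wp_usage_error")
  expect_error(weight_search(grid = NULL), class = "wp_usage_error")
})

test_that("evaluate_all produces the nine-row tuned report", {
  sim <- simulate_calibration_set(mixture_design(n = 60, seed = 30))
  mc <- sum_normalize(default_component_library()$standard)
  grids <- list(svr = 2^seq(0, 12, by = 3), krr = 10^seq(1, -4, by = -2),
                kpls = c(2L, 6L, 10L))
  rep1 <- evaluate_all(sim$spectra, sim$assays, mc, repeats = 2, seed = 3,
                       grids = grids)
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(nrow(rep1), 9L)
  expect_equal(unique(rep1$phenolic), c("anthocyanins", "tannins", "tips"))
  expect_equal(unique(rep1$algorithm), c("svr", "krr", "kpls"))
  num_cols <- c("weight", "r2_c", "rmsec", "r2_p", "rmsep", "r2_cv", "rmsecv")
  expect_true(all(vapply(rep1[num_cols], function(v) all(is.finite(v)),
                         logical(1))))
  expect_true(all(rep1$r2_p >= 0 & rep1$r2_p <= 1))
  # deterministic under the master seed
  rep2 <- evaluate_all(sim$spectra, sim$assays, mc, repeats = 2, seed = 3,
                       grids = grids)
  expect_equal(rep1, rep2, ignore_attr = TRUE)
})
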