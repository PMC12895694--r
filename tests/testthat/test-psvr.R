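# Circular label arithmetic, scaling, and the periodic SVR itself.

test_that("degree-to-angle mapping is the stated linear bijection", {
  expect_equal(degrees_to_theta(0), -pi)
  expect_equal(degrees_to_theta(90), 0)
  expect_equal(degrees_to_theta(45), -pi / 2)
  expect_equal(degrees_to_theta(183), degrees_to_theta(3))  # wrapped
  deg <- runif(200, 0, 180)
  expect_equal(theta_to_degrees(degrees_to_theta(deg)), deg, tolerance = 1e-10)
})

test_that("sine/cosine projection and angle reconstruction invert each other", {
  sc <- theta_to_sincos(c(0, pi / 2))
  expect_equal(sc$x, c(1, 0))
  expect_equal(sc$y, c(0, 1))
  expect_equal(reconstruct_angle(1, 0), 0)
  expect_equal(reconstruct_angle(0, -1), -pi / 2)
  expect_equal(reconstruct_angle(-0.3, 0.3), 3 * pi / 4)
  expect_warning(z <- reconstruct_angle(0, 0), "degenerate")
  expect_equal(z, 0)

  set.seed(1)
  theta <- runif(1000, -pi, pi)
  sc <- theta_to_sincos(theta)
  expect_equal(reconstruct_angle(sc$x, sc$y), theta, tolerance = 1e-12)
})

test_that("angular error is the circular absolute difference in [0, pi]", {
  expect_equal(angular_error(1.2, 1.2), 0)
  expect_equal(angular_error(pi - 0.1, -pi + 0.1), 0.2)
  expect_equal(angular_error(0, pi / 2), pi / 2)
  set.seed(2)
  a <- runif(500, -10, 10); b <- runif(500, -10, 10)
  e <- angular_error(a, b)
  expect_true(all(e >= 0 & e <= pi))
  expect_equal(angular_error(a, b), angular_error(b, a))
})

test_that("FCA above chance maps the three anchor errors correctly", {
  expect_equal(fca_above_chance(rep(0, 5)), 50)
  expect_equal(fca_above_chance(rep(pi / 2, 5)), 0)
  expect_equal(fca_above_chance(rep(pi, 5)), -50)
  expect_error(fca_above_chance(numeric(0)), "at least one")
  expect_error(fca_above_chance(c(0.1, 4)), "\\[0, pi\\]")
})

test_that("min-max scaling is fitted on training data only", {
  s <- scale_train_apply_test(matrix(c(2, 4, 6), 3, 1), matrix(8, 1, 1))
  expect_equal(s$train[, 1], c(0, 0.5, 1))
  expect_equal(s$test[, 1], 1.5)
  # constant training voxel maps to 0 everywhere, no division error
  s2 <- scale_train_apply_test(matrix(5, 3, 1), matrix(7, 1, 1))
  expect_equal(s2$train[, 1], c(0, 0, 0))
  expect_equal(s2$test[, 1], 0)
  expect_error(scale_train_apply_test(matrix(1, 1, 2)), "at least 2")
})

test_that("the SVR solver reproduces frozen scikit-learn predictions", {
  # fixture regenerated exactly as used to produce the frozen oracle values
  # (sklearn.svm.SVR, C = 1, epsilon = 0.1, gamma = 0.5, tol = 1e-4)
  set.seed(42)
  n <- 25; p <- 6
  x <- matrix(runif(n * p), n, p)
  y <- sin(2 * pi * x[, 1]) + 0.3 * x[, 2] + rnorm(n, 0, 0.1)
  xt <- matrix(runif(10 * p), 10, p)
  K <- psvrcap:::rbf_kernel_cpp(x, x, 0.5)
  f <- psvrcap:::svr_fit_cpp(K, y, 1.0, 0.1, 1e-4, 100000L)
  pred <- drop(psvrcap:::rbf_kernel_cpp(xt, x, 0.5) %*% f$beta) + f$b
  sklearn <- c(-0.1159868, 0.31787141, -0.14517092, 0.19436437, 0.45631198,
               0.46868805, -0.09435489, 0.01446358, 0.48596569, 0.49280949)
  expect_equal(pred, sklearn, tolerance = 2e-3)
})

test_that("periodic SVR fits are deterministic and decode a strong signal", {
  ds <- strong_signal_dataset()
  rows <- which(ds$design$participant == 1 & ds$design$condition == "load1")
  run <- ds$design$run[rows]
  theta <- degrees_to_theta(ds$design$label_1[rows])
  tr <- rows[run != 4]; te <- rows[run == 4]
  sc <- scale_train_apply_test(ds$data[tr, ], ds$data[te, ])
  fit1 <- fit_psvr(sc$train, theta[run != 4])
  fit2 <- fit_psvr(sc$train, theta[run != 4])
  p1 <- predict(fit1, sc$test)
  expect_identical(p1, predict(fit2, sc$test))   # determinism
  err <- angular_error(theta[run == 4], p1$theta_hat)
  expect_lt(mean(err), 0.25)                      # near-zero error, strong signal
  expect_error(fit_psvr(sc$train[1, , drop = FALSE], theta[1]), "at least 2")
})

test_that("the fast decode path agrees with the R-level fit/predict route", {
  ds <- strong_signal_dataset()
  for (cond in c("load1", "load2-cap2")) {
    rows <- which(ds$design$participant == 2 & ds$design$condition == cond)
    des <- ds$design[rows, ]
    run <- des$run
    th1 <- degrees_to_theta(des$label_1)
    load2 <- cond != "load1"
    th2 <- if (load2) degrees_to_theta(des$label_2) else th1
    code <- if (load2) 1L else 0L
    fast <- psvrcap:::psvr_decode_cpp(ds$data[rows, ], th1, th2,
                                      as.integer(run), code, 1, 0.1, -1,
                                      1e-3, 50000L)
    # independent route: make_folds + scale + fit_psvr + predict
    fold_err <- vapply(make_folds(run), function(f) {
      psvrcap:::.decode_cell(ds$data[rows, ], des, f$train, f$test,
                             code, code, 1, 0.1, NULL, 1e-3, 50000L)
    }, numeric(1))
    # float32 kernel in the fast path vs double in the R route, SMO tol 1e-3
    expect_equal(fast$mean_error, mean(fold_err), tolerance = 5e-3)
    expect_equal(fast$fca_above_chance, 50 - mean(fold_err) / pi * 100,
                 tolerance = 1e-3)
  }
})

test_that("decoding a pure-noise dataset sits at chance", {
  p <- sim_params(n_participants = 50, n_runs = 3, n_voxels = 40,
                  trials_per_run_per_condition = 12, signal_factor = 0,
                  noise_factor = 1, seed = 13)
  sc <- cross_validated_decode(simulate_dataset(p, "load1"), "load1")
  se <- sd(sc$fca_above_chance) / sqrt(nrow(sc))
  expect_lt(abs(mean(sc$fca_above_chance)), 3 * se + 0.5)
  expect_true(all(sc$fca_above_chance >= -50 & sc$fca_above_chance <= 50))
})
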