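# Periodic support vector regression: two independent RBF-kernel epsilon-SVRs
# predict the sine and cosine of the (doubled) orientation angle; the angle is
# reconstructed with atan2. The quadratic programs are solved by the package's
# own deterministic SMO (src/svr.cpp).

#' Min-max scale training patterns and apply the same scaling to test patterns
#'
#' Per-voxel scaling to `[0, 1]` fitted on the training trials only; test
#' values may fall outside that interval. A voxel that is constant in
#' training carries no information and is mapped to 0 in both sets.
#'
#' @param train Training matrix (trials x voxels), at least 2 rows.
#' @param test Test matrix with the same voxel columns (may be `NULL`).
#' @return List with `train`, `test`, and the fitted `min` / `range` vectors.
#' @export
#' @examples
#' s <- scale_train_apply_test(matrix(c(2, 4, 6), 3, 1), matrix(8, 1, 1))
#' s$train[, 1]  # 0, 0.5, 1
#' s$test[, 1]   # 1.5
scale_train_apply_test <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 training trials to fit scaling")
  mn <- apply(train, 2, min)
  rg <- apply(train, 2, max) - mn
  const <- rg <= 0
  rg[const] <- 1
  sc <- function(m) {
    m <- sweep(sweep(as.matrix(m), 2, mn, "-"), 2, rg, "/")
    m[, const] <- 0
    m
  }
  list(train = sc(train),
       test = if (is.null(test)) NULL else sc(test),
       min = mn, range = ifelse(const, 0, rg))
}

# variance-scaled kernel width, 1 / (n_features * var of all entries)
.default_gamma <- function(x) {
  v <- mean((x - mean(x))^2)
  if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
}

#' Fit a periodic SVR to multivoxel patterns
#'
#' Trains two epsilon-insensitive support vector regressions with a shared
#' radial-basis-function kernel: one for the cosine and one for the sine of
#' the angular label. Patterns are expected pre-scaled (see
#' [scale_train_apply_test()]). The fit is deterministic given the data.
#'
#' @param x Training patterns (trials x voxels), at least 2 rows.
#' @param theta Angular labels in radians (as from [degrees_to_theta()]).
#' @param cost SVR cost parameter C.
#' @param epsilon Width of the insensitive tube.
#' @param gamma RBF kernel width; `NULL` uses the variance-scaled default
#'   `1 / (n_voxels * var(x))`.
#' @param tol SMO convergence tolerance.
#' @param max_iter SMO iteration cap.
#' @return An object of class `psvr_fit`.
#' @export
fit_psvr <- function(x, theta, cost = 1, epsilon = 0.1, gamma = NULL,
                     tol = 1e-3, max_iter = 50000L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training trials")
  stopifnot(length(theta) == nrow(x), all(is.finite(theta)))
  if (is.null(gamma)) gamma <- .default_gamma(x)
  K <- rbf_kernel_cpp(x, x, gamma)
  fx <- svr_fit_cpp(K, cos(theta), cost, epsilon, tol, max_iter)
  fy <- svr_fit_cpp(K, sin(theta), cost, epsilon, tol, max_iter)
  structure(list(x = x, gamma = gamma, cost = cost, epsilon = epsilon,
                 beta_x = drop(fx$beta), b_x = fx$b,
                 beta_y = drop(fy$beta), b_y = fy$b,
                 iterations = c(x = fx$iterations, y = fy$iterations)),
            class = "psvr_fit")
}

#' Predict orientations from a fitted periodic SVR
#'
#' @param object A `psvr_fit`.
#' @param newdata Patterns to predict (trials x voxels), scaled with the
#'   training scaling.
#' @param ... Unused.
#' @return data.frame with predicted components `xhat`, `yhat` and the
#'   reconstructed angle `theta_hat` in radians.
#' @export
predict.psvr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == ncol(object$x))
  K <- rbf_kernel_cpp(newdata, object$x, object$gamma)
  xhat <- drop(K %*% object$beta_x) + object$b_x
  yhat <- drop(K %*% object$beta_y) + object$b_y
  data.frame(xhat = xhat, yhat = yhat,
             theta_hat = reconstruct_angle(xhat, yhat))
}

#' @export
print.psvr_fit <- function(x, ...) {
  cat(sprintf("Periodic SVR fit: %d training trials, %d voxels\n",
              nrow(x$x), ncol(x$x)))
  cat(sprintf("  cost %g, epsilon %g, gamma %.3g\n", x$cost, x$epsilon, x$gamma))
  invisible(x)
}
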