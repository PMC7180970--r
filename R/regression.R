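# Three kernel regression back-ends share one fitting surface. Each is tuned
# by a single "weight": SVR cost, kernel-ridge regularization strength, or
# PLS component count. Features are mean-centered (optionally unit-variance
# scaled) with training statistics only; the same statistics are applied to
# prediction inputs so no test information leaks into the fit.

as_feature_matrix <- function(x) {
  if (inherits(x, "spectra_set") ||
      (is.data.frame(x) && "sample_id" %in% names(x))) {
    return(spectra_matrix(assert_spectra(x)))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    wp_usage_error("features must be a numeric matrix, spectra_set or data frame")
  }
  storage.mode(x) <- "double"
  x
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Linear PLS via the cross-product ("kernel") algorithm: works entirely from
# X'X and X'y, never deflating X itself. Equivalent to NIPALS PLS1.
kpls_coefficients <- function(X, y, ncomp) {
  XtX <- crossprod(X)
  s <- drop(crossprod(X, y))
  p <- ncol(X)
  R <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    nw <- sqrt(sum(s^2))
    if (nw < 1e-12) {
      wp_numeric_error(sprintf(
        "kernel PLS: residual X'y vanished at component %d; reduce the component count", a
      ))
    }
    w <- s / nw
    r <- w
    if (a > 1) {
      for (j in seq_len(a - 1)) r <- r - sum(P[, j] * w) * R[, j]
    }
    tXr <- drop(XtX %*% r)
    tt <- sum(r * tXr)
    if (tt <= 1e-14) {
      wp_numeric_error(sprintf(
        "kernel PLS: degenerate score variance at component %d", a
      ))
    }
    P[, a] <- tXr / tt
    q[a] <- sum(r * s) / tt
    s <- s - tt * q[a] * P[, a]
    R[, a] <- r
  }
  drop(R %*% q)
}

#' Fit a phenolic calibration model
#'
#' Fits one of the three kernel regression back-ends to a feature matrix
#' (typically per-phenolic feature spectra from [features_for()]) and a
#' concentration vector. The single tuned hyperparameter is called the
#' *weight* across all three algorithms:
#'
#' * `svr` — epsilon-insensitive support vector regression (via
#'   \pkg{e1071}); the weight is the cost C. Radial basis kernel with width
#'   `gamma = 1/p` and `epsilon = 0.1` (in mg/L) by default.
#' * `krr` — kernel ridge regression; the weight is the regularization
#'   strength lambda (dual solution `(K + lambda I)^-1 y`). Linear kernel by
#'   default, radial available.
#' * `kpls` — linear partial least squares computed by the cross-product
#'   kernel algorithm; the weight is the (positive integer) number of latent
#'   components, at most `min(n - 1, p)`.
#'
#' @param x Feature matrix, `spectra_set`, or data frame with `sample_id`.
#' @param y Numeric concentration vector, one value per row of `x`.
#' @param algorithm `"svr"`, `"krr"` or `"kpls"`.
#' @param weight The algorithm's tuning weight (see Details).
#' @param kernel Kernel family for svr/krr: `"radial"` or `"linear"`
#'   (defaults: radial for svr, linear for krr; kpls is always linear).
#' @param gamma Radial kernel width; default `1/p`.
#' @param epsilon SVR insensitivity tube half-width in the units of `y`.
#' @param center,scale Standardize features with training statistics
#'   (centering on, scaling off by default). `y` is always centered.
#' @return A `phenolic_model` object with a [predict()] method.
#' @export
fit_phenolic_model <- function(x, y, algorithm = c("svr", "krr", "kpls"),
                               weight, kernel = NULL, gamma = NULL,
                               epsilon = 0.1, center = TRUE, scale = FALSE) {
  algorithm <- match.arg(algorithm)
  X <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    wp_usage_error("x and y must have matching sample counts")
  }
  if (nrow(X) < 2) wp_usage_error("at least 2 training samples required")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    wp_data_error("non-finite values in training data")
  }
  n <- nrow(X); p <- ncol(X)
  if (algorithm == "kpls") {
    if (length(weight) != 1 || weight < 1 || weight != round(weight)) {
      wp_usage_error("kpls weight must be a positive integer component count")
    }
    if (weight > min(n - 1, p)) {
      wp_usage_error(sprintf(
        "kpls capacity exceeded: %d components > min(n - 1, p) = %d",
        as.integer(weight), min(n - 1, p)
      ))
    }
  } else if (length(weight) != 1 || !is.finite(weight) || weight <= 0) {
    wp_usage_error(sprintf("%s weight must be a positive scalar", algorithm))
  }
  kernel <- kernel %||% switch(algorithm, svr = "radial", krr = "linear",
                               kpls = "linear")
  kernel <- match.arg(kernel, c("radial", "linear"))
  gamma <- gamma %||% (1 / p)

  x_center <- if (center) colMeans(X) else rep(0, p)
  x_scale <- if (scale) {
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1
    sds
  } else {
    rep(1, p)
  }
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  yc <- y - y_center

  fit <- switch(algorithm,
    svr = e1071::svm(
      x = Xs, y = yc, type = "eps-regression",
      kernel = kernel, gamma = gamma, cost = weight, epsilon = epsilon,
      scale = FALSE
    ),
    krr = {
      K <- if (kernel == "linear") tcrossprod(Xs) else rbf_kernel(Xs, Xs, gamma)
      dual <- solve(K + diag(weight, n), yc)
      list(X_train = Xs, dual = dual)
    },
    kpls = list(beta = kpls_coefficients(Xs, yc, as.integer(weight)))
  )

  train_pred <- NULL
  structure(
    list(
      algorithm = algorithm, weight = weight, kernel = kernel, gamma = gamma,
      epsilon = epsilon, fit = fit,
      x_center = x_center, x_scale = x_scale, y_center = y_center,
      n_train = n, n_features = p,
      feature_names = colnames(X),
      format_version = 1L
    ),
    class = "phenolic_model"
  )
}

#' Predict concentrations from a fitted phenolic model
#'
#' @param object A `phenolic_model`.
#' @param newdata Feature matrix / `spectra_set` with the same feature count
#'   (and, when named, the same wavelengths) as the training data.
#' @param ... Unused.
#' @return A numeric vector of predicted concentrations, one per row,
#'   deterministic for a given fitted model.
#' @export
predict.phenolic_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$n_features) {
    wp_usage_error(sprintf(
      "feature count mismatch: model expects %d, got %d",
      object$n_features, ncol(X)
    ))
  }
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    wp_usage_error("feature wavelengths do not match the training features")
  }
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  yc <- switch(object$algorithm,
    svr = as.numeric(predict(object$fit, Xs)),
    krr = {
      K <- if (object$kernel == "linear") {
        tcrossprod(Xs, object$fit$X_train)
      } else {
        rbf_kernel(Xs, object$fit$X_train, object$gamma)
      }
      drop(K %*% object$fit$dual)
    },
    kpls = drop(Xs %*% object$fit$beta)
  )
  unname(yc) + object$y_center
}

#' @export
print.phenolic_model <- function(x, ...) {
  cat(sprintf(
    "<phenolic_model> %s (weight %.6g, %s kernel), %d training samples, %d features\n",
    x$algorithm, x$weight, x$kernel, x$n_train, x$n_features
  ))
  invisible(x)
}

#' @describeIn fit_phenolic_model One-row tibble of the model's algorithm,
#'   weight, kernel settings and training dimensions.
#' @export
glance.phenolic_model <- function(x, ...) {
  tibble(
    algorithm = x$algorithm, weight = x$weight, kernel = x$kernel,
    gamma = x$gamma, epsilon = x$epsilon,
    n_train = x$n_train, n_features = x$n_features
  )
}

#' @describeIn fit_phenolic_model Per-feature coefficients for the linear
#'   back-ends (kpls directly; krr with a linear kernel via the dual
#'   expansion); dual coefficients per support vector for svr and radial krr.
#' @export
tidy.phenolic_model <- function(x, ...) {
  if (x$algorithm == "kpls") {
    return(tibble(term = x$feature_names %||%
                    paste0("x", seq_len(x$n_features)),
                  estimate = x$fit$beta))
  }
  if (x$algorithm == "krr" && x$kernel == "linear") {
    beta <- drop(crossprod(x$fit$X_train, x$fit$dual))
    return(tibble(term = x$feature_names %||%
                    paste0("x", seq_len(x$n_features)),
                  estimate = beta))
  }
  if (x$algorithm == "krr") {
    return(tibble(term = paste0("dual_", seq_along(x$fit$dual)),
                  estimate = x$fit$dual))
  }
  tibble(term = paste0("sv_", seq_along(x$fit$coefs)),
         estimate = drop(x$fit$coefs))
}
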