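# Independent oracles used to validate the package's numerics. These are
# deliberately written in the most literal textbook form, sharing no code
# with the package implementation.

# PLS1 by classical NIPALS with explicit X/y deflation.
nipals_pls <- function(X, y, ncomp) {
  xm <- colMeans(X)
  ym <- mean(y)
  E <- sweep(X, 2, xm)
  f <- y - ym
  W <- NULL
  P <- NULL
  Q <- numeric(0)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    E <- E - tcrossprod(t, p)
    f <- f - t * q
    W <- cbind(W, w)
    P <- cbind(P, p)
    Q <- c(Q, q)
  }
  beta <- W %*% solve(t(P) %*% W, Q)
  list(beta = drop(beta), x_center = xm, y_center = ym)
}

nipals_predict <- function(fit, X) {
  drop(sweep(X, 2, fit$x_center) %*% fit$beta) + fit$y_center
}

# Literal metric formulas.
oracle_rmse <- function(p, o) sqrt(sum((p - o)^2) / length(p))

oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Ordinary least squares coefficients (with intercept) via QR.
oracle_ols_predict <- function(X, y, Xnew) {
  fit <- lm.fit(cbind(1, X), y)
  drop(cbind(1, Xnew) %*% fit$coefficients)
}

# Shared fixtures -----------------------------------------------------------

# The component library's true shape vector on the default grid (AU per mg/L).
true_shape <- function(lib, name) {
  winephenols:::component_shape(lib$components[[name]])
}

# A noise-free mixture design: no spectral noise, exact assays.
noise_free_design <- function(n, seed = 1, ...) {
  mixture_design(n = n, noise_sd = 0, noise_mult = 0, assay_cv = 0,
                 seed = seed, ...)
}

# Stub evaluator for weight_search: replays a fixed score profile indexed by
# position in the grid.
profile_evaluator <- function(grid, profile) {
  force(grid)
  force(profile)
  function(w) profile[match(w, grid)]
}
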