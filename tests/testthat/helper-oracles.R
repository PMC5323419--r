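# Independent oracles used across the suite. These evaluate the same
# quantities as the package by a different route (dense linear algebra,
# brute-force grids), so agreement is evidence, not tautology.

# Direct dense evaluation of -2 * restricted log-likelihood for the
# two-level model with ID/AR(1) residuals: per-subject dense Sigma_i,
# solve() and determinant(), no Woodbury, no lag cross-products.
dense_reml_neg2 <- function(designs, G, sigma2, rho = 0) {
  nf <- ncol(designs[[1]]$X)
  XtSX <- matrix(0, nf, nf)
  XtSy <- numeric(nf)
  ytSy <- 0
  logdet <- 0
  ntot <- 0L
  for (d in designs) {
    n <- length(d$y)
    R <- sigma2 * stats::toeplitz(rho^(0:(n - 1)))
    S <- d$Z %*% G %*% t(d$Z) + R
    Si <- solve(S)
    logdet <- logdet + as.numeric(determinant(S, logarithm = TRUE)$modulus)
    XtSX <- XtSX + t(d$X) %*% Si %*% d$X
    XtSy <- XtSy + as.numeric(t(d$X) %*% Si %*% d$y)
    ytSy <- ytSy + sum(d$y * (Si %*% d$y))
    ntot <- ntot + n
  }
  gamma <- solve(XtSX, XtSy)
  as.numeric(logdet +
    determinant(XtSX, logarithm = TRUE)$modulus +
    ytSy - sum(XtSy * gamma) + (ntot - nf) * log(2 * pi))
}

# Exact Gaussian profile log-likelihood of regression with AR(1) errors at
# fixed rho, evaluated through the dense stationary covariance (not through
# the package's whitening operator).
dense_ar1_profile_loglik <- function(rho, y, X) {
  n <- length(y)
  V <- stats::toeplitz(rho^(0:(n - 1))) / (1 - rho^2)  # unit innovation var
  cV <- chol(V)
  yw <- backsolve(cV, y, transpose = TRUE)
  Xw <- backsolve(cV, X, transpose = TRUE)
  beta <- qr.coef(qr(Xw), yw)
  rss <- sum((yw - Xw %*% beta)^2)
  s2 <- rss / n
  ldV <- 2 * sum(log(diag(cV)))
  -n / 2 * (log(2 * pi * s2) + 1) - ldV / 2
}

# Simulate one AR(1) series with stationary initialization.
sim_ar1 <- function(n, rho, sigma_w = 1) {
  w <- rnorm(n, sd = sigma_w)
  e <- numeric(n)
  e[1] <- w[1] / sqrt(1 - rho^2)
  for (t in 2:n) e[t] <- rho * e[t - 1] + w[t]
  e
}

# A tiny deterministic panel for engine tests (generate_dataset is a pure
# function of its seed).
tiny_panel <- function(N = 3, L = 4, seed = 42) {
  generate_dataset(simulation_condition(N = N, L = L, rho_bar = 0.3,
                                        reps = 1, seed = seed))
}

lag1_autocor <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  sum(x[-1] * x[-n]) / sum(x^2)
}
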