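#' Autocovariance of a stationary AR(1) process
#'
#' For the first-order autoregressive process \eqn{e_t = \rho e_{t-1} + w_t}
#' with innovation variance \eqn{\sigma^2_w}, the autocovariance at lag
#' \eqn{h \ge 0} is \eqn{\gamma(h) = \sigma^2_w \rho^h / (1 - \rho^2)}.
#'
#' @param rho AR(1) parameter, \code{abs(rho) < 1}.
#' @param sigma_w2 Innovation variance, positive scalar.
#' @param h Non-negative integer lag (vectorized).
#' @return Numeric vector of autocovariances, one per element of \code{h}.
#' @examples
#' ar1_autocovariance(0.6, 1, 0:3)
#' @export
ar1_autocovariance <- function(rho, sigma_w2, h) {
  check_ar1_rho(rho)
  check_sigma_w2(sigma_w2)
  if (any(h < 0)) stop("lag 'h' must be non-negative")
  sigma_w2 * rho^h / (1 - rho^2)
}

#' Stationary AR(1) residual covariance matrix
#'
#' Builds the \code{n} x \code{n} covariance matrix of a stationary AR(1)
#' process, with entries \eqn{\gamma(|t-s|) = \sigma^2_w \rho^{|t-s|}/(1-\rho^2)}.
#'
#' @inheritParams ar1_autocovariance
#' @param n Dimension (number of occasions), \code{n >= 1}.
#' @return Symmetric positive definite \code{n} x \code{n} matrix.
#' @seealso [ar1_precision()] for the tridiagonal inverse,
#'   [ar1_whitening()] for the inverse Cholesky factor.
#' @export
ar1_covariance <- function(rho, sigma_w2, n) {
  check_ar1_rho(rho)
  check_sigma_w2(sigma_w2)
  stopifnot(n >= 1)
  idx <- seq_len(n)
  ar1_autocovariance(rho, sigma_w2, abs(outer(idx, idx, "-")))
}

#' Tridiagonal inverse of the AR(1) covariance matrix
#'
#' The inverse of [ar1_covariance()] in closed form: a tridiagonal matrix with
#' corner diagonal entries \eqn{1/\sigma^2_w}, interior diagonal entries
#' \eqn{(1+\rho^2)/\sigma^2_w}, and off-diagonal entries
#' \eqn{-\rho/\sigma^2_w}; all entries beyond the first off-diagonal are
#' exactly zero.
#'
#' @inheritParams ar1_covariance
#' @param n Dimension, \code{n >= 2}.
#' @return The \code{n} x \code{n} precision matrix.
#' @export
ar1_precision <- function(rho, sigma_w2, n) {
  check_ar1_rho(rho)
  check_sigma_w2(sigma_w2)
  stopifnot(n >= 2)
  P <- diag(c(1, rep(1 + rho^2, n - 2), 1))
  P[cbind(seq_len(n - 1), 2:n)] <- -rho
  P[cbind(2:n, seq_len(n - 1))] <- -rho
  P / sigma_w2
}

check_ar1_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1)
    stop("'rho' must satisfy |rho| < 1 (stationarity)")
  invisible(rho)
}

check_sigma_w2 <- function(sigma_w2) {
  if (!is.numeric(sigma_w2) || length(sigma_w2) != 1L || sigma_w2 <= 0)
    stop("'sigma_w2' must be a positive scalar")
  invisible(sigma_w2)
}

#' Stationarity check for AR(p) coefficients
#'
#' Tests whether all roots of \eqn{1 - \phi_1 x - \dots - \phi_p x^p} lie
#' outside the unit circle.
#'
#' @param phi Numeric vector of AR coefficients (may be empty for p = 0).
#' @return \code{TRUE} if the process is stationary.
#' @export
is_stationary_ar <- function(phi) {
  if (length(phi) == 0L) return(TRUE)
  if (!all(is.finite(phi))) return(FALSE)
  all(Mod(polyroot(c(1, -phi))) > 1)
}

# Stationary autocovariances gamma(0..lag_max) of AR(p) with unit innovation
# variance, via the ACF and gamma(0) = 1 / (1 - sum(phi_k * acf_k)).
arp_autocovariance <- function(phi, lag_max) {
  p <- length(phi)
  if (p == 0L) return(c(1, rep(0, lag_max)))
  acf <- stats::ARMAacf(ar = phi, lag.max = max(lag_max, p))
  gamma0 <- 1 / (1 - sum(phi * acf[1 + seq_len(p)]))
  gamma0 * acf[1 + 0:lag_max]
}
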