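#' Whitening operators for autoregressive residual covariance
#'
#' A whitening operator is the inverse Cholesky factor \eqn{A = L^{-1}} of the
#' scaled residual covariance \eqn{V_w = \Sigma / \sigma^2_w}, so that
#' \eqn{A \Sigma A' = \sigma^2_w I}. For an AR(p) process the operator is
#' lower triangular and banded: rows \eqn{t > p} apply the AR filter
#' \eqn{w_t = e_t - \sum_j \phi_j e_{t-j}}, and the first \eqn{p} rows are the
#' inverse Cholesky factor of the leading \eqn{p \times p} block of the
#' stationary covariance (scaled to unit innovation variance). Operators are
#' stored in banded form so application costs O(n p), but can be materialized
#' with [as.matrix()].
#'
#' @param rho AR(1) parameter, \code{abs(rho) < 1}.
#' @param n Dimension (series length).
#' @param subject_id Optional identifier carried along for diagnostics.
#' @param sigma_w2 Innovation variance the operator targets (metadata only;
#'   the operator itself is scale free).
#' @return An object of class \code{"whitening_operator"} with fields
#'   \code{phi}, \code{n}, \code{head} (the dense p x p leading block),
#'   \code{sigma_w2} and \code{subject_id}.
#' @examples
#' A <- as.matrix(ar1_whitening(0.6, 3))
#' A %*% ar1_covariance(0.6, 1, 3) %*% t(A)  # = identity
#' @export
ar1_whitening <- function(rho, n, subject_id = NA, sigma_w2 = 1) {
  check_ar1_rho(rho)
  stopifnot(n >= 1)
  new_whitening_operator(phi = rho, n = n,
                         head = matrix(sqrt(1 - rho^2), 1, 1),
                         subject_id = subject_id, sigma_w2 = sigma_w2)
}

#' @rdname ar1_whitening
#' @param phi Numeric vector of AR(p) coefficients; must be stationary.
#' @export
arp_whitening <- function(phi, n, subject_id = NA, sigma_w2 = 1) {
  p <- length(phi)
  if (!is_stationary_ar(phi))
    stop("'phi' is not stationary: roots of the AR polynomial inside unit circle")
  stopifnot(n > p)
  if (p == 0L) {
    head <- matrix(numeric(0), 0, 0)
  } else if (p == 1L) {
    head <- matrix(sqrt(1 - phi^2), 1, 1)
  } else {
    Vp <- toeplitz(arp_autocovariance(phi, p - 1))  # unit innovation variance
    Lp <- t(chol(Vp))
    head <- forwardsolve(Lp, diag(p))
  }
  new_whitening_operator(phi = phi, n = n, head = head,
                         subject_id = subject_id, sigma_w2 = sigma_w2)
}

new_whitening_operator <- function(phi, n, head, subject_id, sigma_w2) {
  structure(list(phi = as.numeric(phi), n = as.integer(n), head = head,
                 subject_id = subject_id, sigma_w2 = sigma_w2),
            class = "whitening_operator")
}

#' Apply a whitening operator
#'
#' Computes \code{A \%*\% x} using the banded structure (O(n p) per column).
#' The intercept column of a design matrix is transformed like any other
#' column; it is not reset to ones.
#'
#' @param op A \code{"whitening_operator"}.
#' @param x Numeric vector of length \code{op$n} or matrix with \code{op$n}
#'   rows.
#' @return Transformed vector or matrix of the same shape.
#' @export
whiten <- function(op, x) {
  stopifnot(inherits(op, "whitening_operator"))
  vec <- is.null(dim(x))
  M <- as.matrix(x)
  if (nrow(M) != op$n)
    stop(sprintf("dimension mismatch: operator is %d x %d but input has %d rows",
                 op$n, op$n, nrow(M)))
  p <- length(op$phi)
  out <- M
  if (p > 0L) {
    for (j in seq_len(p)) {
      tt <- (p + 1):op$n
      out[tt, ] <- out[tt, , drop = FALSE] -
        op$phi[j] * M[tt - j, , drop = FALSE]
    }
    out[seq_len(p), ] <- op$head %*% M[seq_len(p), , drop = FALSE]
  }
  if (vec) drop(out) else out
}

#' @export
as.matrix.whitening_operator <- function(x, ...) {
  n <- x$n
  p <- length(x$phi)
  A <- diag(n)
  if (p > 0L) {
    for (j in seq_len(p)) {
      tt <- (p + 1):n
      A[cbind(tt, tt - j)] <- -x$phi[j]
    }
    A[seq_len(p), seq_len(p)] <- x$head
  }
  A
}

#' @export
print.whitening_operator <- function(x, ...) {
  cat(sprintf("AR(%d) whitening operator, n = %d\n", length(x$phi), x$n))
  if (length(x$phi)) cat("  phi:", format(x$phi, digits = 4), "\n")
  cat("  target innovation variance:", format(x$sigma_w2, digits = 4), "\n")
  invisible(x)
}
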