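#' OLS fit for one individual's series
#'
#' Ordinary least squares of a subject's outcome on a subject-level design
#' (typically an intercept and the time-varying covariate), the first step of
#' the Cholesky-transformation procedure.
#'
#' @param y Outcome vector.
#' @param design Numeric matrix with \code{length(y)} rows and full column
#'   rank.
#' @param subject_id Identifier used in error messages.
#' @return List with components \code{beta} (coefficients) and
#'   \code{residuals} (\code{y - design \%*\% beta}).
#' @export
fit_ols_individual <- function(y, design, subject_id = NA) {
  design <- as.matrix(design)
  if (nrow(design) != length(y)) stop("'y' and 'design' have different lengths")
  if (nrow(design) <= ncol(design))
    stop("series too short for the design (need L > number of columns)")
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop(sprintf("collinear design for subject '%s' (e.g. constant covariate)",
                 as.character(subject_id)))
  beta <- qr.coef(qr_d, y)
  list(beta = as.numeric(beta),
       residuals = as.numeric(y - design %*% beta))
}

# Levinson-Durbin map from partial autocorrelations to AR coefficients.
# |pacf_k| < 1 for all k guarantees stationarity of the result.
pacf_to_phi <- function(pacf) {
  p <- length(pacf)
  if (p == 0L) return(numeric(0))
  phi <- pacf[1]
  if (p > 1L) {
    for (k in 2:p) {
      phi <- c(phi - pacf[k] * rev(phi), pacf[k])
    }
  }
  phi
}

# Exact Gaussian profile log-likelihood of the regression with AR(p) errors,
# at fixed AR coefficients phi: beta and sigma^2_w are profiled out in closed
# form through the whitening operator. Returns the profile log-likelihood and
# the profiled (beta, sigma_w2, rss).
ar_profile_loglik <- function(phi, y, design) {
  n <- length(y)
  op <- arp_whitening(phi, n)
  ys <- whiten(op, y)
  if (ncol(design) > 0L) {
    Xs <- whiten(op, design)
    fit <- stats::lm.fit(Xs, ys)
    beta <- fit$coefficients
    rss <- sum(fit$residuals^2)
  } else {
    beta <- numeric(0)
    rss <- sum(ys^2)
  }
  sigma_w2 <- rss / n
  logdetA <- if (length(phi)) sum(log(diag(op$head))) else 0
  ll <- -n / 2 * (log(2 * pi * sigma_w2) + 1) + logdetA
  list(loglik = ll, beta = beta, sigma_w2 = sigma_w2, rss = rss)
}

# Fast exact profile log-likelihood for p = 1 from lag cross-products of
# W = [design, y]: each evaluation is O(q^3) independent of series length.
ar1_profile_stats <- function(y, design) {
  W <- cbind(design, y)
  n <- nrow(W)
  C0 <- crossprod(W)
  C1 <- crossprod(W[-1, , drop = FALSE], W[-n, , drop = FALSE])
  list(C0 = C0, C1s = C1 + t(C1),
       B = tcrossprod(W[1, ]) + tcrossprod(W[n, ]),
       n = n, q = ncol(W) - 1L)
}

ar1_profile_loglik_stats <- function(rho, st) {
  S <- st$C0 - rho * st$C1s + rho^2 * (st$C0 - st$B)
  q <- st$q
  iy <- q + 1L
  if (q > 0L) {
    beta <- solve(S[seq_len(q), seq_len(q), drop = FALSE], S[seq_len(q), iy])
    rss <- S[iy, iy] - sum(S[seq_len(q), iy] * beta)
  } else {
    beta <- numeric(0)
    rss <- S[iy, iy]
  }
  rss <- max(rss, 1e-300)
  sigma_w2 <- rss / st$n
  list(loglik = -st$n / 2 * (log(2 * pi * sigma_w2) + 1) +
         0.5 * log(1 - rho^2),
       beta = beta, sigma_w2 = sigma_w2)
}

#' Exact ML regression with AR(p) errors for one individual
#'
#' Joint exact Gaussian maximum likelihood of a subject-level regression whose
#' residuals follow a stationary AR(p) process: the first \code{p}
#' observations contribute through the stationary distribution, and the
#' regression coefficients and innovation variance are profiled out in closed
#' form so the optimization runs over the AR parameters only. Stationarity is
#' enforced by bounding the (partial) autocorrelations to magnitude at most
#' 0.98; an estimate at that bound is flagged in \code{cap_hit}.
#'
#' @param y Outcome vector (length \code{L}).
#' @param design Subject-level design matrix (\code{L} rows); may have zero
#'   columns to fit a pure AR model (used for order selection on residuals).
#' @param p Autoregressive order, \code{p >= 0}.
#' @param method \code{"exact_ml"} (default) for joint exact ML, or
#'   \code{"two_stage"} for OLS residuals followed by exact ML of the AR
#'   parameters on those residuals (diagnostic variant).
#' @param subject_id Identifier used in messages and carried into the result.
#' @return An object of class \code{"ar_fit"}: \code{order}, \code{phi},
#'   \code{rho} (lag-1 autocorrelation; equals \code{phi} when p = 1),
#'   \code{sigma_w2}, \code{beta}, \code{loglik} (exact log-likelihood at the
#'   optimum), \code{converged}, \code{cap_hit}, \code{n}.
#' @export
fit_ar_regression <- function(y, design, p = 1L,
                              method = c("exact_ml", "two_stage"),
                              subject_id = NA) {
  method <- match.arg(method)
  design <- as.matrix(design)
  if (is.null(dim(design))) design <- matrix(design, ncol = 1L)
  n <- length(y)
  p <- as.integer(p)
  if (nrow(design) != n) stop("'y' and 'design' have different lengths")
  if (n < p + ncol(design) + 2L)
    stop(sprintf("series too short for subject '%s': L = %d with p = %d and %d design columns",
                 as.character(subject_id), n, p, ncol(design)))
  if (ncol(design) > 0L && qr(design)$rank < ncol(design))
    stop(sprintf("collinear design for subject '%s'", as.character(subject_id)))

  if (method == "two_stage" && ncol(design) > 0L) {
    ols <- fit_ols_individual(y, design, subject_id)
    arfit <- fit_ar_regression(ols$residuals, matrix(numeric(0), n, 0),
                               p = p, method = "exact_ml",
                               subject_id = subject_id)
    arfit$beta <- ols$beta
    return(arfit)
  }

  cap <- 0.98
  if (p == 0L) {
    prof <- ar_profile_loglik(numeric(0), y, design)
    phi <- numeric(0)
    conv <- TRUE
    cap_hit <- FALSE
  } else if (p == 1L) {
    st <- ar1_profile_stats(y, design)
    opt <- stats::optimize(function(r) ar1_profile_loglik_stats(r, st)$loglik,
                           lower = -cap, upper = cap, maximum = TRUE,
                           tol = 1e-9)
    phi <- opt$maximum
    prof <- ar1_profile_loglik_stats(phi, st)
    conv <- TRUE
    cap_hit <- abs(phi) > cap - 1e-4
  } else {
    # parameterize by partial autocorrelations, pacf = cap * tanh(theta)
    negll <- function(theta) {
      phi_k <- pacf_to_phi(cap * tanh(theta))
      -ar_profile_loglik(phi_k, y, design)$loglik
    }
    start <- rep(0, p)
    opt <- stats::optim(start, negll, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
    pacf <- cap * tanh(opt$par)
    phi <- pacf_to_phi(pacf)
    prof <- ar_profile_loglik(phi, y, design)
    conv <- opt$convergence == 0L
    cap_hit <- any(abs(pacf) > cap - 1e-4)
  }

  structure(list(order = p, phi = phi,
                 rho = if (p >= 1L) unname(phi[1]) else 0,
                 sigma_w2 = prof$sigma_w2, beta = unname(prof$beta),
                 loglik = prof$loglik, converged = conv, cap_hit = cap_hit,
                 n = n, subject_id = subject_id),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("AR(%d) regression fit (exact ML), n = %d\n", x$order, x$n))
  if (x$order) cat("  phi:", format(x$phi, digits = 4), "\n")
  cat("  sigma_w2:", format(x$sigma_w2, digits = 4),
      " loglik:", format(x$loglik, digits = 6), "\n")
  if (length(x$beta)) cat("  beta:", format(x$beta, digits = 4), "\n")
  if (x$cap_hit) cat("  note: AR parameter at the stationarity cap (0.98)\n")
  invisible(x)
}

#' Select the autoregressive order for a residual series
#'
#' Fits pure AR(p) models to a residual series by exact ML for
#' \code{p = 0, ..., p_max} and selects the order by an information
#' criterion. With \code{criterion = "fixed"} the order is \code{p_max}
#' unchanged (the default analysis order used by the transformation
#' pipeline).
#'
#' @param residuals Numeric residual series.
#' @param p_max Maximum order considered, \code{p_max >= 0}.
#' @param criterion One of \code{"fixed"}, \code{"aic"}, \code{"bic"}.
#' @return Selected integer order.
#' @export
select_ar_order <- function(residuals, p_max, criterion = c("fixed", "aic", "bic")) {
  criterion <- match.arg(criterion)
  p_max <- as.integer(p_max)
  if (p_max < 0L) stop("'p_max' must be non-negative")
  n <- length(residuals)
  if (n < p_max + 3L) stop("residual series too short for 'p_max'")
  if (criterion == "fixed") return(p_max)
  empty <- matrix(numeric(0), n, 0)
  score <- vapply(0:p_max, function(p) {
    fit <- fit_ar_regression(residuals, empty, p = p)
    k <- p + 1  # AR coefficients + innovation variance
    if (criterion == "aic") -2 * fit$loglik + 2 * k
    else -2 * fit$loglik + k * log(n)
  }, numeric(1))
  (0:p_max)[which.min(score)]
}
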