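# Per-subject sufficient statistics for the blockwise REML criterion:
# lag cross-products of W_i = [X_i, Z_i, y_i], stacked into q x q x N arrays.
reml_suffstats <- function(designs) {
  stopifnot(inherits(designs, "mlm_designs"))
  nf <- ncol(designs[[1]]$X)
  nr <- ncol(designs[[1]]$Z)
  q <- nf + nr + 1L
  N <- length(designs)
  C0 <- C1s <- B <- array(0, c(q, q, N))
  Ls <- integer(N)
  for (i in seq_len(N)) {
    d <- designs[[i]]
    W <- cbind(d$X, d$Z, d$y)
    L <- nrow(W)
    if (L < 2L) stop("each subject needs at least 2 occasions")
    C0[, , i] <- crossprod(W)
    C1 <- crossprod(W[-1, , drop = FALSE], W[-L, , drop = FALSE])
    C1s[, , i] <- C1 + t(C1)
    B[, , i] <- tcrossprod(W[1, ]) + tcrossprod(W[L, ])
    Ls[i] <- L
  }
  list(C0 = C0, C1s = C1s, B = B, Ls = Ls, nf = nf, nr = nr,
       ntot = sum(Ls), subjects = vapply(designs, function(d)
         as.character(d$subject), character(1)))
}

#' Evaluate the REML criterion of the two-level model
#'
#' Minus twice the restricted log-likelihood of the model
#' \eqn{y_i = X_i \gamma + Z_i u_i + e_i}, \eqn{u_i \sim N(0, G)},
#' \eqn{e_i \sim N(0, R_i)} with homogeneous ID or AR(1) \eqn{R_i}, at an
#' arbitrary parameter point. Fixed effects are profiled out by GLS. Exposed
#' so the criterion can be checked against a direct dense evaluation.
#'
#' @param designs An \code{"mlm_designs"} list from [assemble_design()].
#' @param G Random-effects covariance matrix (positive definite).
#' @param sigma2 Residual variance.
#' @param rho AR(1) residual parameter (0 for the ID structure).
#' @return List: \code{neg2} (the criterion, \eqn{-2\,\ell_{REML}}),
#'   \code{gamma} (profiled GLS fixed effects), \code{XtSX}
#'   (\eqn{\sum_i X_i'\Sigma_i^{-1}X_i}).
#' @export
reml_criterion <- function(designs, G, sigma2, rho = 0) {
  st <- reml_suffstats(designs)
  reml_eval_cpp(st$C0, st$C1s, st$B, st$Ls, st$nf, st$nr,
                as.matrix(G), sigma2, rho)
}

# theta -> variance parameters. G via log-Cholesky (guarantees PD),
# sigma2 via log, rho via tanh scaled into (-0.98, 0.98).
theta_to_params <- function(theta, nr, ar1) {
  ntheta_g <- nr * (nr + 1L) / 2L
  Lg <- matrix(0, nr, nr)
  Lg[lower.tri(Lg, diag = TRUE)] <- theta[seq_len(ntheta_g)]
  diag(Lg) <- exp(diag(Lg))
  G <- tcrossprod(Lg)
  sigma2 <- exp(theta[ntheta_g + 1L])
  rho <- if (ar1) 0.98 * tanh(theta[ntheta_g + 2L]) else 0
  list(G = G, sigma2 = sigma2, rho = rho)
}

# Method-of-moments starting values: pooled OLS residual variance split
# between the random-intercept variance and the residual variance; the AR
# start is the pooled lag-1 autocorrelation of the OLS residuals.
reml_start <- function(designs, ar1) {
  X <- do.call(rbind, lapply(designs, `[[`, "X"))
  y <- unlist(lapply(designs, `[[`, "y"), use.names = FALSE)
  ols <- stats::lm.fit(X, y)
  v <- sum(ols$residuals^2) / (length(y) - ncol(X))
  r1 <- 0
  if (ar1) {
    offset <- 0L
    num <- den <- 0
    for (d in designs) {
      L <- length(d$y)
      r <- ols$residuals[offset + seq_len(L)]
      num <- num + sum(r[-1] * r[-L])
      den <- den + sum(r^2)
      offset <- offset + L
    }
    r1 <- max(min(num / den, 0.9), -0.9)
  }
  g0 <- sqrt(v / 2)
  theta <- c(log(g0), 0, log(g0 / 2), log(v / 2))
  if (ar1) theta <- c(theta, atanh(r1 / 0.98))
  theta
}

#' REML fit of the two-level model
#'
#' Restricted maximum likelihood estimation of the random-intercept-and-slope
#' model with homogeneous ID or AR(1) residual covariance. The variance
#' parameters are optimized by quasi-Newton (BFGS, numerical gradients) under
#' a log-Cholesky parameterization of \eqn{G}; fixed effects are the GLS
#' estimates at the optimum and their model-based standard errors are
#' \eqn{\sqrt{\mathrm{diag}[(\sum_i X_i'\hat\Sigma_i^{-1}X_i)^{-1}]}}. Failed
#' optimizations are retried from up to 3 jittered starts.
#'
#' @param panel A raw panel (data frame with columns \code{subject},
#'   \code{occasion}, \code{y}, \code{z}, \code{c}), a transformed panel from
#'   [mlm_ct_transform()], or an \code{"mlm_designs"} object.
#' @param residual \code{"ID"} or \code{"AR1"}.
#' @return An object of class \code{"mlm_fit"}: \code{fixed}, \code{se},
#'   \code{G} (with \code{var_u0}, \code{var_u1}, \code{cov_u0u1} accessors in
#'   \code{vcomp}), \code{resid}, \code{reml_loglik}, \code{converged},
#'   \code{n_iter}.
#' @examples
#' \donttest{
#' panel <- generate_dataset(simulation_condition(N = 30, L = 25, rho_bar = 0.3),
#'                           replicate_index = 1)
#' mlm_reml(panel, residual = "AR1")
#' }
#' @export
mlm_reml <- function(panel, residual = c("ID", "AR1")) {
  residual <- match.arg(residual)
  designs <- if (inherits(panel, "mlm_designs")) panel else assemble_design(panel)
  st <- reml_suffstats(designs)
  if (st$ntot <= st$nf)
    stop("fewer observations than fixed effects")
  ar1 <- residual == "AR1"

  neg2 <- function(theta) {
    p <- theta_to_params(theta, st$nr, ar1)
    if (!all(is.finite(p$G)) || !is.finite(p$sigma2) || !is.finite(p$rho))
      return(1e10)
    reml_eval_cpp(st$C0, st$C1s, st$B, st$Ls, st$nf, st$nr,
                  p$G, p$sigma2, p$rho)$neg2
  }

  theta0 <- reml_start(designs, ar1)
  best <- NULL
  n_iter <- 0L
  for (attempt in 0:3) {
    start <- if (attempt == 0) theta0 else
      theta0 + stats::rnorm(length(theta0), sd = 0.3 * attempt)
    opt <- try(stats::optim(start, neg2, method = "BFGS",
                            control = list(reltol = 1e-12, maxit = 1000)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    n_iter <- n_iter + opt$counts[["function"]]
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
    if (opt$convergence == 0L && opt$value < 1e9) break
  }
  if (is.null(best)) stop("REML optimization failed on all starts")
  converged <- best$convergence == 0L && best$value < 1e9

  p <- theta_to_params(best$par, st$nr, ar1)
  ev <- reml_eval_cpp(st$C0, st$C1s, st$B, st$Ls, st$nf, st$nr,
                      p$G, p$sigma2, p$rho)
  cov_gamma <- solve(ev$XtSX)
  se <- sqrt(diag(cov_gamma))
  fixed <- as.numeric(ev$gamma)
  names(fixed) <- names(se) <- attr(designs, "fixed_names")
  vcomp <- c(var_u0 = p$G[1, 1], var_u1 = p$G[2, 2], cov_u0u1 = p$G[1, 2])
  boundary <- any(diag(p$G) < 1e-6 * p$sigma2)

  structure(list(fixed = fixed, se = se, G = p$G, vcomp = vcomp,
                 resid = residual_structure(residual, sigma2 = p$sigma2,
                                            rho = if (ar1) p$rho else NULL),
                 reml_loglik = -ev$neg2 / 2, converged = converged,
                 boundary = boundary, n_iter = n_iter,
                 cov_gamma = cov_gamma, n_subjects = length(designs),
                 n_obs = st$ntot),
            class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat(sprintf("Two-level REML fit (%s residuals): %d subjects, %d observations\n",
              x$resid$kind, x$n_subjects, x$n_obs))
  est <- cbind(Estimate = x$fixed, `Std.Error` = x$se)
  print(round(est, 4))
  cat("Random effects:  var_u0 =", format(x$vcomp[1], digits = 4),
      " var_u1 =", format(x$vcomp[2], digits = 4),
      " cov_u0u1 =", format(x$vcomp[3], digits = 4), "\n")
  cat("Residual: sigma2 =", format(x$resid$sigma2, digits = 4))
  if (x$resid$kind == "AR1") cat("  rho =", format(x$resid$rho, digits = 4))
  cat("\nREML log-likelihood:", format(x$reml_loglik, digits = 8),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' GLS estimator of regression coefficients
#'
#' \eqn{\tilde\beta = (X'\Sigma^{-1}X)^{-1} X'\Sigma^{-1} y}; reduces to OLS
#' when \eqn{\Sigma \propto I}, and equals OLS on data whitened by any
#' \eqn{A} with \eqn{A\Sigma A' = \sigma^2_w I}.
#'
#' @param y Outcome vector.
#' @param X Design matrix, full column rank.
#' @param Sigma Positive definite covariance matrix.
#' @return Coefficient vector.
#' @export
gls_fixed_effects <- function(y, X, Sigma) {
  X <- as.matrix(X)
  cS <- chol(Sigma)
  Xw <- backsolve(cS, X, transpose = TRUE)
  yw <- backsolve(cS, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12) stop("singular X' Sigma^-1 X (rank-deficient design)")
  as.numeric(solve(XtX, crossprod(Xw, yw)))
}

#' Model-based standard errors of fixed effects
#'
#' \eqn{\mathrm{se} = \sqrt{\mathrm{diag}[(\sum_i X_i'\Sigma_i^{-1}X_i)^{-1}]}}
#' given per-subject designs and fitted marginal covariances.
#'
#' @param X_list List of per-subject fixed-effects design matrices.
#' @param Sigma_list List of per-subject marginal covariance matrices.
#' @return Standard-error vector.
#' @export
fixed_effect_se <- function(X_list, Sigma_list) {
  stopifnot(length(X_list) == length(Sigma_list))
  info <- 0
  for (i in seq_along(X_list)) {
    cS <- chol(Sigma_list[[i]])
    Xw <- backsolve(cS, as.matrix(X_list[[i]]), transpose = TRUE)
    info <- info + crossprod(Xw)
  }
  if (rcond(info) < 1e-12) stop("singular information matrix")
  sqrt(diag(solve(info)))
}
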