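#' Validate a long-format two-level panel
#'
#' The package's input contract: one row per subject x occasion with columns
#' \code{subject}, \code{occasion} (integer, strictly increasing with constant
#' spacing within subject), outcome \code{y}, time-varying covariate \code{z},
#' and time-invariant covariate \code{c}. Balance across subjects is not
#' required.
#'
#' @param panel A data frame.
#' @param min_length Minimum series length per subject (default 3).
#' @return The panel, with subjects in stable (first-appearance) order,
#'   invisibly classed as validated.
#' @export
validate_panel <- function(panel, min_length = 3L) {
  required <- c("subject", "occasion", "y", "z", "c")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols))
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("occasion", "y", "z", "c")) {
    if (!is.numeric(panel[[col]]))
      stop(sprintf("column '%s' must be numeric", col))
    bad <- which(!is.finite(panel[[col]]))
    if (length(bad))
      stop(sprintf("column '%s' has missing/non-finite values at row(s) %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(panel$occasion != round(panel$occasion)))
    stop("column 'occasion' must be integer-valued")
  key <- paste(panel$subject, panel$occasion)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicated (subject, occasion) at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  for (s in unique(panel$subject)) {
    occ <- panel$occasion[panel$subject == s]
    if (is.unsorted(occ, strictly = TRUE))
      stop(sprintf("occasions not strictly increasing for subject '%s'", s))
    if (length(occ) < min_length)
      stop(sprintf("subject '%s' has fewer than %d occasions", s, min_length))
    if (length(unique(diff(occ))) > 1L)
      stop(sprintf("unequally spaced occasions for subject '%s'", s))
  }
  panel
}

#' Assemble per-subject design matrices for the two-level model
#'
#' Builds, for every subject, the random-effects design \eqn{Z_i = [1, z]}
#' and the fixed-effects design \eqn{X_i = Z_i C_i = [1, z, c, c z]} of the
#' model \eqn{y_{ti} = \gamma_{00} + \gamma_{10} z_{ti} + \gamma_{01} c_i +
#' \gamma_{11} c_i z_{ti} + u_{0i} + u_{1i} z_{ti} + e_{ti}}. Fixed-effect
#' column order is (intercept, z, c, c:z), i.e.
#' \eqn{(\gamma_{00}, \gamma_{10}, \gamma_{01}, \gamma_{11})}.
#'
#' For a transformed panel (output of [mlm_ct_transform()]) the already
#' whitened columns are taken verbatim; in particular no fresh intercept
#' column is injected, because the whitening operator has transformed the
#' original ones column.
#'
#' @param panel A validated raw panel or a transformed panel.
#' @return A list of class \code{"mlm_designs"}: per subject, a list with
#'   \code{subject}, \code{y}, \code{X}, \code{Z}; attribute
#'   \code{fixed_names} documents the column order.
#' @export
assemble_design <- function(panel) {
  if (inherits(panel, "mlmct_transformed")) {
    xcols <- grep("^x_star", names(panel), value = TRUE)
    zcols <- grep("^z_star", names(panel), value = TRUE)
    out <- lapply(unique(panel$subject), function(s) {
      rows <- panel$subject == s
      list(subject = s, y = panel$y_star[rows],
           X = as.matrix(panel[rows, xcols, drop = FALSE]),
           Z = as.matrix(panel[rows, zcols, drop = FALSE]))
    })
    return(structure(out, class = "mlm_designs",
                     fixed_names = xcols, random_names = zcols))
  }
  panel <- validate_panel(panel)
  out <- lapply(unique(panel$subject), function(s) {
    rows <- panel$subject == s
    ci <- unique(panel$c[rows])
    if (length(ci) > 1L)
      stop(sprintf("level-2 covariate 'c' varies within subject '%s'", s))
    z <- panel$z[rows]
    Z <- cbind(intercept = 1, z = z)
    X <- cbind(intercept = 1, z = z, c = ci, `c:z` = ci * z)
    list(subject = s, y = panel$y[rows], X = X, Z = Z)
  })
  structure(out, class = "mlm_designs",
            fixed_names = c("gamma00", "gamma10", "gamma01", "gamma11"),
            random_names = c("u0", "u1"))
}

#' Marginal covariance of one subject's outcome vector
#'
#' \eqn{\Sigma_i = Z_i G Z_i' + R_i}, where \eqn{G} is the random-effects
#' covariance and \eqn{R_i} is either \eqn{\sigma^2 I} (ID) or the AR(1)
#' matrix \eqn{\sigma^2 \rho^{|t-s|}}.
#'
#' @param G 2 x 2 (or q x q) positive semidefinite random-effects covariance.
#' @param resid List with \code{kind} ("ID" or "AR1"), \code{sigma2}, and
#'   \code{rho} (AR1 only); see [residual_structure()].
#' @param Z_i Random-effects design matrix for the subject.
#' @return Symmetric positive definite matrix of dimension \code{nrow(Z_i)}.
#' @export
marginal_covariance <- function(G, resid, Z_i) {
  G <- as.matrix(G)
  if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("'G' must be positive semidefinite")
  n <- nrow(Z_i)
  R <- switch(resid$kind,
    ID = diag(resid$sigma2, n),
    AR1 = {
      check_ar1_rho(resid$rho)
      resid$sigma2 * toeplitz(resid$rho^(0:(n - 1)))
    },
    stop("unknown residual kind: ", resid$kind))
  Sigma <- Z_i %*% G %*% t(Z_i) + R
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("marginal covariance not positive definite")
  Sigma
}

#' Residual covariance structure descriptor
#'
#' @param kind \code{"ID"} (independent homoscedastic) or \code{"AR1"}.
#' @param sigma2 Residual variance (diagonal of \eqn{R_i}), positive.
#' @param rho AR(1) parameter, required when \code{kind = "AR1"}.
#' @return List of class \code{"residual_structure"}.
#' @export
residual_structure <- function(kind = c("ID", "AR1"), sigma2 = 1, rho = NULL) {
  kind <- match.arg(kind)
  check_sigma_w2(sigma2)
  if (kind == "AR1") {
    if (is.null(rho)) stop("'rho' required for AR1 residual structure")
    check_ar1_rho(rho)
  } else {
    rho <- 0
  }
  structure(list(kind = kind, sigma2 = sigma2, rho = rho),
            class = "residual_structure")
}
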