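#' Whiten one subject's outcome and design matrices
#'
#' Applies a subject's whitening operator to the outcome, fixed-effects
#' design, and random-effects design: \eqn{y^* = A y}, \eqn{X^* = A X},
#' \eqn{Z^* = A Z}. All columns are transformed, including the intercept
#' column (which becomes \eqn{A \mathbf{1}}, not a fresh ones column).
#'
#' @param op A \code{"whitening_operator"} with \code{op$n} equal to the
#'   number of rows of the inputs.
#' @param y_i Outcome vector.
#' @param X_i Fixed-effects design matrix.
#' @param Z_i Random-effects design matrix.
#' @return List with \code{y_star}, \code{X_star}, \code{Z_star}.
#' @export
whiten_subject <- function(op, y_i, X_i, Z_i) {
  list(y_star = whiten(op, y_i),
       X_star = whiten(op, as.matrix(X_i)),
       Z_star = whiten(op, as.matrix(Z_i)))
}

#' Cholesky-transformation pipeline (step 1 of MLM-CT)
#'
#' For every subject: fit the subject-level regression \eqn{y_i = \beta_0 +
#' \beta_1 z_i + e_i} with AR(p) errors by exact maximum likelihood, build
#' the inverse-Cholesky whitening operator from the estimated AR
#' coefficients, and transform the outcome, the fixed-effects design
#' \eqn{[1, z, c, cz]}, and the random-effects design \eqn{[1, z]}. The
#' transformed panel is then fitted with [mlm_reml()] using the ID residual
#' structure (step 2); see [mlm_ct_fit()] for the one-call wrapper.
#'
#' Subjects are transformed independently; no information is pooled across
#' subjects. Rescaling each subject's block to unit innovation variance is
#' off by default and recommended when residual variances differ across
#' subjects.
#'
#' @param panel Raw panel data frame (\code{subject}, \code{occasion},
#'   \code{y}, \code{z}, \code{c}).
#' @param p Autoregressive order used for every subject (default 1).
#' @param order_select \code{"fixed"} uses \code{p} as given; \code{"aic"} or
#'   \code{"bic"} selects each subject's order from OLS residuals with
#'   maximum order \code{p}.
#' @param rescale If \code{TRUE}, apply [rescale_to_unit_variance()].
#' @param method First-step estimator, passed to [fit_ar_regression()].
#' @param on_error \code{"stop"} (default) fails loudly naming the subject;
#'   \code{"skip"} drops failing subjects and records them in the
#'   \code{"skipped"} attribute.
#' @return A data frame of class \code{"mlmct_transformed"}: the input
#'   columns plus \code{y_star}, \code{x_star_1..4}, \code{z_star_1..2}, with
#'   attributes \code{ar_fits} (per-subject \code{"ar_fit"} objects) and
#'   \code{rescaled}.
#' @export
mlm_ct_transform <- function(panel, p = 1L,
                             order_select = c("fixed", "aic", "bic"),
                             rescale = FALSE,
                             method = c("exact_ml", "two_stage"),
                             on_error = c("stop", "skip")) {
  order_select <- match.arg(order_select)
  method <- match.arg(method)
  on_error <- match.arg(on_error)
  p <- as.integer(p)
  panel <- validate_panel(panel, min_length = p + 4L)

  subjects <- unique(panel$subject)
  ar_fits <- vector("list", length(subjects))
  names(ar_fits) <- as.character(subjects)
  blocks <- vector("list", length(subjects))
  skipped <- character(0)

  for (k in seq_along(subjects)) {
    s <- subjects[k]
    rows <- which(panel$subject == s)
    yi <- panel$y[rows]
    zi <- panel$z[rows]
    ci <- panel$c[rows][1]
    L <- length(yi)
    res <- tryCatch({
      design1 <- cbind(1, zi)
      p_i <- p
      if (order_select != "fixed") {
        ols <- fit_ols_individual(yi, design1, subject_id = s)
        p_i <- select_ar_order(ols$residuals, p_max = p,
                               criterion = order_select)
      }
      fit <- fit_ar_regression(yi, design1, p = p_i, method = method,
                               subject_id = s)
      op <- arp_whitening(fit$phi, L, subject_id = s,
                          sigma_w2 = fit$sigma_w2)
      Xi <- cbind(1, zi, ci, ci * zi)
      Zi <- cbind(1, zi)
      tr <- whiten_subject(op, yi, Xi, Zi)
      list(fit = fit, tr = tr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop")
        stop(sprintf("transformation failed for subject '%s': %s",
                     as.character(s), conditionMessage(res)))
      skipped <- c(skipped, as.character(s))
      next
    }
    ar_fits[[k]] <- res$fit
    blocks[[k]] <- data.frame(row = rows, y_star = res$tr$y_star,
                              x_star_1 = res$tr$X_star[, 1],
                              x_star_2 = res$tr$X_star[, 2],
                              x_star_3 = res$tr$X_star[, 3],
                              x_star_4 = res$tr$X_star[, 4],
                              z_star_1 = res$tr$Z_star[, 1],
                              z_star_2 = res$tr$Z_star[, 2])
  }

  keep <- !vapply(blocks, is.null, logical(1))
  ar_fits <- ar_fits[keep]
  blocks <- do.call(rbind, blocks[keep])
  out <- cbind(panel[blocks$row, , drop = FALSE],
               blocks[, setdiff(names(blocks), "row")])
  rownames(out) <- NULL
  attr(out, "ar_fits") <- ar_fits
  attr(out, "rescaled") <- FALSE
  attr(out, "skipped") <- skipped
  class(out) <- c("mlmct_transformed", class(out))
  if (rescale) out <- rescale_to_unit_variance(out)
  out
}

#' Rescale a transformed panel to unit innovation variance
#'
#' Divides each subject's whitened block (outcome and all transformed design
#' columns) by \eqn{\sqrt{\hat\sigma^2_{w i}}}, so the transformed residual
#' variance is approximately 1 for every subject. Useful when innovation
#' variances are heterogeneous across subjects, since the second-step model
#' assumes homoscedastic residuals.
#'
#' @param tp A \code{"mlmct_transformed"} panel.
#' @return The rescaled panel (with the stored \code{sigma_w2} values set to
#'   1 and \code{rescaled = TRUE}).
#' @export
rescale_to_unit_variance <- function(tp) {
  stopifnot(inherits(tp, "mlmct_transformed"))
  if (isTRUE(attr(tp, "rescaled"))) return(tp)
  ar_fits <- attr(tp, "ar_fits")
  star_cols <- grep("star", names(tp), value = TRUE)
  for (s in names(ar_fits)) {
    sw2 <- ar_fits[[s]]$sigma_w2
    if (!is.finite(sw2) || sw2 <= 0)
      stop(sprintf("non-positive innovation variance for subject '%s'", s))
    rows <- as.character(tp$subject) == s
    tp[rows, star_cols] <- tp[rows, star_cols] / sqrt(sw2)
    ar_fits[[s]]$sigma_w2 <- 1
  }
  attr(tp, "ar_fits") <- ar_fits
  attr(tp, "rescaled") <- TRUE
  tp
}

#' Two-step Cholesky-transformation estimator (MLM-CT)
#'
#' Convenience wrapper: [mlm_ct_transform()] followed by [mlm_reml()] with ID
#' residual structure on the transformed data.
#'
#' @inheritParams mlm_ct_transform
#' @return An \code{"mlm_fit"} with the transformed panel's per-subject AR
#'   fits attached as attribute \code{"ar_fits"}.
#' @export
mlm_ct_fit <- function(panel, p = 1L, order_select = "fixed",
                       rescale = FALSE, method = "exact_ml",
                       on_error = "stop") {
  tp <- mlm_ct_transform(panel, p = p, order_select = order_select,
                         rescale = rescale, method = method,
                         on_error = on_error)
  fit <- mlm_reml(tp, residual = "ID")
  attr(fit, "ar_fits") <- attr(tp, "ar_fits")
  fit
}
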