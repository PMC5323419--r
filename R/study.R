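#' Relative bias in percent
#'
#' \eqn{\frac{1}{R}\sum_r \frac{\hat\theta_r - \theta}{\theta} \times 100}
#' over converged replicates.
#'
#' @param estimates Vector of estimates (converged fits only).
#' @param theta True parameter value (non-zero).
#' @return Relative bias in percent.
#' @export
relative_bias <- function(estimates, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta == 0)
    stop("relative bias is undefined for theta = 0")
  estimates <- estimates[is.finite(estimates)]
  mean((estimates - theta) / theta) * 100
}

#' Relative bias of model-based standard errors in percent
#'
#' Reports \eqn{\mathrm{mean}((\mathrm{SE}_r - \theta)/\theta) \times 100},
#' where \eqn{\theta} is the true standard error of the fixed effect. In the
#' simulation the true SE is known: it is the model-based formula
#' \eqn{\sqrt{\mathrm{diag}[(\sum_i X_i'\Sigma_i^{-1}X_i)^{-1}]}} evaluated at
#' the generating parameters and the true heterogeneous per-subject
#' covariance (see [true_fixed_se()]); pass those values as \code{true_se}
#' (\eqn{\theta} is their mean over converged replicates). When the
#' generating covariance is unknown, the empirical standard deviation of the
#' point estimates across converged replicates is the standard Monte Carlo
#' fallback.
#'
#' @param model_ses Model-based standard errors across replicates.
#' @param estimates Matching point estimates across replicates (used for the
#'   empirical-SD fallback and to drop non-converged entries).
#' @param true_se Optional vector (or scalar) of true standard errors under
#'   the generating model.
#' @return Relative bias in percent.
#' @export
se_relative_bias <- function(model_ses, estimates, true_se = NULL) {
  ok <- is.finite(model_ses) & is.finite(estimates)
  if (sum(ok) < 2L)
    stop("need at least 2 converged replicates for the empirical SE")
  theta <- if (is.null(true_se)) stats::sd(estimates[ok])
           else mean(rep_len(true_se, length(model_ses))[ok])
  mean((model_ses[ok] - theta) / theta) * 100
}

#' True standard errors of the fixed effects under the generating model
#'
#' Evaluates \eqn{\sqrt{\mathrm{diag}[(\sum_i X_i'\Sigma_i^{-1}X_i)^{-1}]}}
#' with the true per-subject marginal covariance \eqn{\Sigma_i = Z_i G Z_i' +
#' R_i(\rho_i)}, using each subject's own generating AR parameter: the true
#' sampling standard error of the GLS fixed effects under the heterogeneous
#' model, against which model-based SEs are judged.
#'
#' @param panel A panel produced by [generate_dataset()] (carries the
#'   per-subject \code{rho_i} as an attribute).
#' @param truth The generating [true_parameters()].
#' @return Standard-error vector (one entry per fixed effect).
#' @export
true_fixed_se <- function(panel, truth = true_parameters()) {
  rho_i <- attr(panel, "rho_i")
  if (is.null(rho_i)) stop("panel carries no generating 'rho_i' attribute")
  designs <- assemble_design(panel)
  stopifnot(length(rho_i) == length(designs))
  Sl <- lapply(seq_along(designs), function(i) {
    Zi <- designs[[i]]$Z
    Zi %*% truth$G %*% t(Zi) +
      ar1_covariance(rho_i[i], truth$sigma_w2, nrow(Zi))
  })
  fixed_effect_se(lapply(designs, `[[`, "X"), Sl)
}

fit_record <- function(fit, method) {
  data.frame(method = method,
             gamma00 = fit$fixed[1], gamma10 = fit$fixed[2],
             gamma01 = fit$fixed[3], gamma11 = fit$fixed[4],
             se_gamma00 = fit$se[1], se_gamma10 = fit$se[2],
             se_gamma01 = fit$se[3], se_gamma11 = fit$se[4],
             var_u0 = fit$vcomp[1], var_u1 = fit$vcomp[2],
             cov_u0u1 = fit$vcomp[3], sigma2 = fit$resid$sigma2,
             rho = fit$resid$rho, converged = fit$converged,
             row.names = NULL)
}

na_record <- function(method) {
  data.frame(method = method, gamma00 = NA_real_, gamma10 = NA_real_,
             gamma01 = NA_real_, gamma11 = NA_real_, se_gamma00 = NA_real_,
             se_gamma10 = NA_real_, se_gamma01 = NA_real_,
             se_gamma11 = NA_real_, var_u0 = NA_real_, var_u1 = NA_real_,
             cov_u0u1 = NA_real_, sigma2 = NA_real_, rho = NA_real_,
             converged = FALSE, row.names = NULL)
}

#' Run one simulation condition
#'
#' Generates \code{condition$reps} panels and fits every requested estimator
#' to each panel: \code{"ID"} (REML with independent residuals), \code{"AR1"}
#' (REML with a shared AR(1) residual parameter), and \code{"CT"} (the
#' two-step Cholesky-transformation estimator, AR order 1). Per-fit failures
#' are recorded as non-converged rows, never fatal.
#'
#' @param condition A [simulation_condition()].
#' @param methods Subset of \code{c("ID", "AR1", "CT")}.
#' @param truth A [true_parameters()].
#' @param ct_rescale Passed to [mlm_ct_fit()] as \code{rescale}.
#' @return Data frame (the estimate table): one row per replicate x method
#'   with all parameter estimates, model-based SEs, a convergence flag, and
#'   for CT the mean per-subject \eqn{\hat\rho_i} and the count of
#'   stationarity-cap hits.
#' @export
run_condition <- function(condition, methods = c("ID", "AR1", "CT"),
                          truth = true_parameters(), ct_rescale = FALSE) {
  stopifnot(all(methods %in% c("ID", "AR1", "CT")), length(methods) >= 1)
  rows <- vector("list", condition$reps * length(methods))
  k <- 0L
  for (r in seq_len(condition$reps)) {
    panel <- generate_dataset(condition, truth, replicate_index = r)
    designs <- assemble_design(panel)
    tse <- true_fixed_se(panel, truth)
    for (m in methods) {
      rec <- tryCatch({
        if (m == "CT") {
          fit <- mlm_ct_fit(panel, p = 1L, rescale = ct_rescale)
          rec <- fit_record(fit, m)
          ar_fits <- attr(fit, "ar_fits")
          rec$mean_rho_hat <- mean(vapply(ar_fits, `[[`, numeric(1), "rho"))
          rec$n_cap_hits <- sum(vapply(ar_fits, `[[`, logical(1), "cap_hit"))
          rec
        } else {
          fit <- mlm_reml(designs, residual = m)
          rec <- fit_record(fit, m)
          rec$mean_rho_hat <- NA_real_
          rec$n_cap_hits <- NA_integer_
          rec
        }
      }, error = function(e) {
        rec <- na_record(m)
        rec$mean_rho_hat <- NA_real_
        rec$n_cap_hits <- NA_integer_
        rec
      })
      rec$true_se_gamma00 <- tse[1]
      rec$true_se_gamma10 <- tse[2]
      rec$true_se_gamma01 <- tse[3]
      rec$true_se_gamma11 <- tse[4]
      rec$replicate <- r
      k <- k + 1L
      rows[[k]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out$N <- condition$N
  out$L <- condition$L
  out$rho_bar <- condition$rho_bar
  out
}

#' Summarize an estimate table into relative biases
#'
#' Computes, per method, the relative bias of every fixed effect and
#' random-effects covariance component, the relative bias of the model-based
#' SE of every fixed effect (against the empirical SD across converged
#' replicates), and the convergence rate.
#'
#' @param est Estimate table from [run_condition()].
#' @param truth The generating [true_parameters()].
#' @return Long-format data frame with columns \code{N}, \code{L},
#'   \code{rho_bar}, \code{method}, \code{parameter}, \code{rel_bias},
#'   \code{n_converged}, \code{conv_rate}.
#' @export
summarize_condition <- function(est, truth = true_parameters()) {
  true_vals <- c(gamma00 = truth$gamma[1], gamma10 = truth$gamma[2],
                 gamma01 = truth$gamma[3], gamma11 = truth$gamma[4],
                 var_u0 = truth$var_u0, var_u1 = truth$var_u1,
                 cov_u0u1 = truth$cov_u0u1)
  fixed <- c("gamma00", "gamma10", "gamma01", "gamma11")
  out <- list()
  for (m in unique(est$method)) {
    sub <- est[est$method == m & est$converged, , drop = FALSE]
    nconv <- nrow(sub)
    rate <- nconv / sum(est$method == m)
    for (par in names(true_vals)) {
      rb <- if (nconv) relative_bias(sub[[par]], true_vals[[par]]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        N = est$N[1], L = est$L[1], rho_bar = est$rho_bar[1], method = m,
        parameter = par, rel_bias = rb, n_converged = nconv,
        conv_rate = rate)
    }
    for (par in fixed) {
      rb <- if (nconv >= 2)
        se_relative_bias(sub[[paste0("se_", par)]], sub[[par]],
                         true_se = sub[[paste0("true_se_", par)]])
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        N = est$N[1], L = est$L[1], rho_bar = est$rho_bar[1], method = m,
        parameter = paste0("se_", par), rel_bias = rb, n_converged = nconv,
        conv_rate = rate)
    }
  }
  do.call(rbind, out)
}

#' Planned workload of a simulation grid
#'
#' @param grid List of [simulation_condition()] objects.
#' @param methods Estimators to run per dataset.
#' @return List with \code{n_conditions}, \code{n_datasets}, \code{n_fits}.
#' @export
plan_grid <- function(grid, methods = c("ID", "AR1", "CT")) {
  reps <- vapply(grid, `[[`, integer(1), "reps")
  list(n_conditions = length(grid), n_datasets = sum(reps),
       n_fits = sum(reps) * length(methods))
}

#' Run a grid of simulation conditions
#'
#' Runs [run_condition()] for every cell and stacks the per-condition
#' relative-bias summaries into a bias report. The planned dataset and fit
#' counts are reported (via \code{message}) before any computation. The
#' whole report is a pure function of (grid, truth, base seeds).
#'
#' @inheritParams plan_grid
#' @param truth A [true_parameters()].
#' @param verbose Emit per-condition progress messages.
#' @param ct_rescale Passed through to [run_condition()].
#' @return A data frame of class \code{"bias_report"} (long format, see
#'   [summarize_condition()]), with the raw estimate tables in attribute
#'   \code{"estimates"}.
#' @export
run_grid <- function(grid, methods = c("ID", "AR1", "CT"),
                     truth = true_parameters(), verbose = TRUE,
                     ct_rescale = FALSE) {
  plan <- plan_grid(grid, methods)
  if (verbose)
    message(sprintf("planned: %d conditions, %d datasets, %d fits",
                    plan$n_conditions, plan$n_datasets, plan$n_fits))
  summaries <- vector("list", length(grid))
  estimates <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cond <- grid[[i]]
    if (verbose)
      message(sprintf("condition %d/%d: N=%d L=%d rho_bar=%.1f",
                      i, length(grid), cond$N, cond$L, cond$rho_bar))
    est <- run_condition(cond, methods = methods, truth = truth,
                         ct_rescale = ct_rescale)
    if (verbose) {
      caps <- sum(est$n_cap_hits, na.rm = TRUE)
      message(sprintf("  converged %d/%d fits%s", sum(est$converged),
                      nrow(est),
                      if (caps > 0)
                        sprintf("; %d subject-level stationarity-cap hits", caps)
                      else ""))
    }
    estimates[[i]] <- est
    summaries[[i]] <- summarize_condition(est, truth)
  }
  out <- do.call(rbind, summaries)
  attr(out, "estimates") <- do.call(rbind, estimates)
  attr(out, "plan") <- plan
  class(out) <- c("bias_report", class(out))
  out
}
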