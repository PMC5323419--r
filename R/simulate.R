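#' True generating parameters of the simulation study
#'
#' Defaults are the study conditions: all four fixed effects equal 1, random
#' effects with \eqn{\sigma^2_{u0} = \sigma^2_{u1} = 0.5} and
#' \eqn{\sigma_{u0u1} = 0.15} (correlation 0.3), unit innovation variance,
#' and per-subject AR parameters drawn uniformly from
#' \eqn{(\bar\rho - 0.3, \bar\rho + 0.3)}.
#'
#' @param gamma Fixed effects \eqn{(\gamma_{00}, \gamma_{10}, \gamma_{01},
#'   \gamma_{11})}.
#' @param var_u0,var_u1,cov_u0u1 Random-effects covariance components.
#' @param sigma_w2 Innovation variance of the AR(1) errors.
#' @param rho_halfwidth Half-width of the uniform distribution of
#'   \eqn{\rho_i} around \eqn{\bar\rho}.
#' @return List of class \code{"true_parameters"} (includes the implied
#'   random-effects correlation \code{r_u0u1}).
#' @export
true_parameters <- function(gamma = c(1, 1, 1, 1), var_u0 = 0.5,
                            var_u1 = 0.5, cov_u0u1 = 0.15, sigma_w2 = 1,
                            rho_halfwidth = 0.3) {
  G <- matrix(c(var_u0, cov_u0u1, cov_u0u1, var_u1), 2, 2)
  if (cov_u0u1^2 > var_u0 * var_u1)
    stop("random-effects covariance is not positive semidefinite")
  structure(list(gamma = gamma, G = G, var_u0 = var_u0, var_u1 = var_u1,
                 cov_u0u1 = cov_u0u1,
                 r_u0u1 = cov_u0u1 / sqrt(var_u0 * var_u1),
                 sigma_w2 = sigma_w2, rho_halfwidth = rho_halfwidth),
            class = "true_parameters")
}

#' One cell of the simulation design
#'
#' @param N Number of subjects.
#' @param L Number of occasions per subject.
#' @param rho_bar Mean autocorrelation \eqn{\bar\rho}; subjects draw
#'   \eqn{\rho_i \sim U(\bar\rho - 0.3, \bar\rho + 0.3)}.
#' @param reps Number of Monte Carlo replications.
#' @param seed Base seed for the condition.
#' @return List of class \code{"simulation_condition"}.
#' @export
simulation_condition <- function(N, L, rho_bar, reps = 500L, seed = 1L) {
  stopifnot(N >= 1, L >= 3, reps >= 1)
  structure(list(N = as.integer(N), L = as.integer(L), rho_bar = rho_bar,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "simulation_condition")
}

#' The default 48-condition grid
#'
#' \eqn{N \in \{20, 50, 100, 200\}}, \eqn{L \in \{20, 50, 100, 200\}},
#' \eqn{\bar\rho \in \{0, 0.3, 0.6\}}.
#'
#' @param reps Replications per condition (default 500).
#' @param seed Base seed shared by all conditions.
#' @return List of [simulation_condition()] objects (length 48 by default).
#' @export
default_grid <- function(reps = 500L, seed = 1L) {
  cells <- expand.grid(N = c(20L, 50L, 100L, 200L),
                       L = c(20L, 50L, 100L, 200L),
                       rho_bar = c(0, 0.3, 0.6))
  lapply(seq_len(nrow(cells)), function(i)
    simulation_condition(cells$N[i], cells$L[i], cells$rho_bar[i],
                         reps = reps, seed = seed))
}

# Deterministic per-replicate seed: a small multiplicative hash of
# (base seed, N, L, rho_bar, replicate), kept below 2^31 so it is a valid
# integer seed. Any single replicate is reproducible in isolation.
replicate_seed <- function(base_seed, N, L, rho_bar, r) {
  m <- 2147483629
  h <- (base_seed %% m)
  for (v in c(N, L, round(100 * rho_bar), r)) {
    h <- (h * 1000003 + v + 12345) %% m
  }
  as.integer(h + 1)
}

#' Generate one two-level panel with heterogeneous AR(1) errors
#'
#' Draws a balanced \code{N x L} panel from
#' \deqn{y_{ti} = \gamma_{00} + \gamma_{10} z_{ti} + \gamma_{01} c_i +
#'   \gamma_{11} c_i z_{ti} + u_{0i} + u_{1i} z_{ti} + e_{ti},}
#' with \eqn{z_{ti}, c_i \sim N(0,1)} iid, \eqn{(u_{0i}, u_{1i})} bivariate
#' normal with covariance \eqn{G}, \eqn{\rho_i \sim U(\bar\rho - 0.3,
#' \bar\rho + 0.3)}, and \eqn{e_{ti} = \rho_i e_{(t-1)i} + w_{ti}},
#' \eqn{w_{ti} \sim N(0, \sigma^2_w)}, the initial state drawn from the
#' stationary distribution \eqn{N(0, \sigma^2_w/(1-\rho_i^2))}. The panel is
#' a pure function of (condition seed, condition, replicate index).
#'
#' @param condition A [simulation_condition()].
#' @param truth A [true_parameters()] object.
#' @param replicate_index Replicate number within the condition (>= 1).
#' @return Data frame with columns \code{subject}, \code{occasion}, \code{y},
#'   \code{z}, \code{c}; the per-subject \eqn{\rho_i} are attached as
#'   attribute \code{"rho_i"}.
#' @export
generate_dataset <- function(condition, truth = true_parameters(),
                             replicate_index = 1L) {
  stopifnot(inherits(condition, "simulation_condition"))
  N <- condition$N
  L <- condition$L
  seed_r <- replicate_seed(condition$seed, N, L, condition$rho_bar,
                           replicate_index)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed_r)

  ci <- stats::rnorm(N)
  rho_i <- stats::runif(N, condition$rho_bar - truth$rho_halfwidth,
                        condition$rho_bar + truth$rho_halfwidth)
  # bivariate normal random effects via Cholesky of G
  Lg <- t(chol(truth$G + diag(1e-12, 2)))
  u <- t(Lg %*% matrix(stats::rnorm(2 * N), 2, N))

  z <- matrix(stats::rnorm(N * L), N, L)
  w <- sqrt(truth$sigma_w2) * matrix(stats::rnorm(N * L), N, L)
  e <- matrix(0, N, L)
  e[, 1] <- w[, 1] / sqrt(1 - rho_i^2)
  for (t in 2:L) e[, t] <- rho_i * e[, t - 1] + w[, t]

  g <- truth$gamma
  y <- g[1] + g[2] * z + g[3] * ci + g[4] * ci * z + u[, 1] + u[, 2] * z + e

  out <- data.frame(subject = rep(seq_len(N), each = L),
                    occasion = rep(seq_len(L), times = N),
                    y = as.vector(t(y)), z = as.vector(t(z)),
                    c = rep(ci, each = L))
  attr(out, "rho_i") <- rho_i
  attr(out, "u") <- u
  attr(out, "seed") <- seed_r
  out
}
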