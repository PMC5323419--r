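test_that("assemble_design expands Z_i C_i with the documented column order", {
  panel <- data.frame(subject = 1, occasion = 1:3, y = c(1, 2, 4),
                      z = c(0, 1, 2), c = 2)
  d <- assemble_design(panel)
  expect_equal(unname(d[[1]]$X),
               matrix(c(1, 0, 2, 0, 1, 1, 2, 2, 1, 2, 2, 4), 3, byrow = TRUE))
  expect_equal(unname(d[[1]]$Z), cbind(1, c(0, 1, 2)))
  expect_equal(attr(d, "fixed_names"),
               c("gamma00", "gamma10", "gamma01", "gamma11"))

  # c = 0 zeroes the level-2 columns
  panel$c <- 0
  d0 <- assemble_design(panel)
  expect_true(all(d0[[1]]$X[, 3:4] == 0))

  # level-2 covariate varying within subject is rejected
  bad <- data.frame(subject = 1, occasion = 1:3, y = 1:3, z = rnorm(3),
                    c = c(1, 1, 2))
  expect_error(assemble_design(bad), "varies within subject")

  # transformed panels are taken verbatim: no intercept injection
  tp <- mlm_ct_transform(tiny_panel(N = 2, L = 30))
  dt <- assemble_design(tp)
  expect_equal(unname(dt[[1]]$X[, 1]),
               tp$x_star_1[tp$subject == unique(tp$subject)[1]])
})

test_that("marginal covariance is Z G Z' + R and respects known identities", {
  Z <- cbind(1, c(0, 1, 2, 3))
  expect_equal(marginal_covariance(matrix(0, 2, 2),
                                   residual_structure("ID", 2), Z),
               diag(2, 4))
  # random-intercept-only + ID == null G + compound symmetry
  G_int <- matrix(c(0.5, 0, 0, 0), 2, 2)
  S1 <- marginal_covariance(G_int, residual_structure("ID", 1), Z)
  S2 <- matrix(0.5, 4, 4) + diag(1, 4)
  expect_equal(S1, S2)
  # AR1 residuals give Toeplitz R
  S <- marginal_covariance(diag(0, 2), residual_structure("AR1", 2, rho = 0.5), Z)
  expect_equal(S, 2 * toeplitz(0.5^(0:3)))
  # PD for random valid parameter draws
  set.seed(4)
  for (k in 1:100) {
    a <- runif(1, 0.1, 2); b <- runif(1, 0.1, 2)
    cv <- runif(1, -1, 1) * sqrt(a * b) * 0.95
    G <- matrix(c(a, cv, cv, b), 2, 2)
    rs <- residual_structure("AR1", runif(1, 0.1, 3), rho = runif(1, -0.9, 0.9))
    ev <- eigen(marginal_covariance(G, rs, Z), symmetric = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(marginal_covariance(matrix(c(1, 2, 2, 1), 2),
                                   residual_structure("ID", 1), Z),
               "positive semidefinite")
})

test_that("REML criterion matches direct dense evaluation to 1e-10", {
  designs <- assemble_design(tiny_panel(N = 3, L = 4))
  pts <- list(
    list(G = matrix(c(0.5, 0.15, 0.15, 0.5), 2), s2 = 1, rho = 0),
    list(G = matrix(c(2, -0.3, -0.3, 0.7), 2), s2 = 0.4, rho = 0.55),
    list(G = diag(c(1e-3, 3)), s2 = 5, rho = -0.8))
  for (p in pts) {
    mine <- reml_criterion(designs, p$G, p$s2, p$rho)$neg2
    oracle <- dense_reml_neg2(designs, p$G, p$s2, p$rho)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("REML fit matches nlme::lme for ID and AR(1) residuals", {
  skip_if_not_installed("nlme")
  panel <- generate_dataset(simulation_condition(N = 25, L = 20,
                                                 rho_bar = 0.3, reps = 1,
                                                 seed = 99))
  fit <- mlm_reml(panel, residual = "ID")
  ref <- nlme::lme(y ~ z * c, random = ~ z | subject, data = panel,
                   method = "REML")
  expect_equal(unname(fit$fixed), unname(nlme::fixef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(ref$varFix))), tolerance = 1e-4)
  expect_equal(fit$resid$sigma2, stats::sigma(ref)^2, tolerance = 1e-4)
  expect_equal(unname(fit$vcomp),
               unname(c(nlme::getVarCov(ref)[1, 1], nlme::getVarCov(ref)[2, 2],
                        nlme::getVarCov(ref)[1, 2])), tolerance = 1e-3)

  fit_ar <- mlm_reml(panel, residual = "AR1")
  ref_ar <- nlme::lme(y ~ z * c, random = ~ z | subject, data = panel,
                      correlation = nlme::corAR1(form = ~ occasion | subject),
                      method = "REML")
  expect_equal(unname(fit_ar$fixed), unname(nlme::fixef(ref_ar)),
               tolerance = 1e-4)
  phi_ref <- as.numeric(coef(ref_ar$modelStruct$corStruct,
                             unconstrained = FALSE))
  expect_equal(fit_ar$resid$rho, phi_ref, tolerance = 1e-3)
})

test_that("REML respects shift invariance and AR1/ID nesting", {
  panel <- generate_dataset(simulation_condition(N = 15, L = 25,
                                                 rho_bar = 0.3, reps = 1,
                                                 seed = 12))
  f0 <- mlm_reml(panel, residual = "ID")
  shifted <- panel
  shifted$y <- shifted$y + 10
  f1 <- mlm_reml(shifted, residual = "ID")
  expect_equal(unname(f1$fixed[1] - f0$fixed[1]), 10, tolerance = 1e-6)
  expect_equal(f1$fixed[-1], f0$fixed[-1], tolerance = 1e-6)
  expect_equal(f1$vcomp, f0$vcomp, tolerance = 1e-6)
  expect_equal(f1$resid$sigma2, f0$resid$sigma2, tolerance = 1e-8)

  f_ar <- mlm_reml(panel, residual = "AR1")
  expect_gte(f_ar$reml_loglik, f0$reml_loglik - 1e-6)

  # local optimality: the optimum beats a grid of perturbed parameter points
  designs <- assemble_design(panel)
  opt <- reml_criterion(designs, f0$G, f0$resid$sigma2, 0)$neg2
  for (d1 in seq(-0.1, 0.1, length.out = 5)) {
    for (d2 in seq(-0.1, 0.1, length.out = 5)) {
      G <- f0$G + diag(c(d1, d1))
      if (min(eigen(G, symmetric = TRUE)$values) <= 0) next
      pert <- reml_criterion(designs, G, f0$resid$sigma2 * (1 + d2), 0)$neg2
      expect_gte(pert, opt - 1e-6)
    }
  }
})

test_that("fit with AR1 at the true rho equals the ID fit on whitened data", {
  panel <- generate_dataset(simulation_condition(N = 10, L = 40, rho_bar = 0.5,
                                                 reps = 1, seed = 7))
  # whiten with a single shared operator at a fixed rho
  rho0 <- 0.5
  designs <- assemble_design(panel)
  wh <- lapply(designs, function(d) {
    op <- ar1_whitening(rho0, length(d$y))
    list(subject = d$subject, y = whiten(op, d$y),
         X = whiten(op, d$X), Z = whiten(op, d$Z))
  })
  attributes(wh) <- attributes(designs)
  # profiled fixed effects at identical variance parameters agree
  G <- matrix(c(0.5, 0.15, 0.15, 0.5), 2)
  g_ar <- reml_criterion(designs, G, 1 / (1 - rho0^2), rho0)$gamma
  g_id <- reml_criterion(wh, G, 1, 0)$gamma
  expect_equal(as.numeric(g_ar), as.numeric(g_id), tolerance = 1e-6)
})

test_that("GLS and model-based SEs behave on canonical cases", {
  set.seed(44)
  X <- cbind(1, rnorm(12))
  y <- X %*% c(1, 2) + rnorm(12)
  expect_equal(gls_fixed_effects(y, X, diag(12)),
               unname(qr.coef(qr(X), y))[, 1], tolerance = 1e-10)
  expect_error(gls_fixed_effects(y, cbind(X, X[, 2]), diag(12)), "singular")

  # Sigma = I gives OLS standard errors with unit error variance
  se <- fixed_effect_se(list(X), list(diag(12)))
  expect_equal(se, sqrt(diag(solve(crossprod(X)))), tolerance = 1e-12)
  # doubling sigma2 scales every SE by sqrt(2)
  se2 <- fixed_effect_se(list(X), list(diag(2, 12)))
  expect_equal(se2, sqrt(2) * se, tolerance = 1e-12)
})

test_that("model-based SEs are calibrated against the Monte Carlo SD", {
  # rho_bar = 0, N = 50, L = 50: mean model SE of the z effect within 5% of
  # the empirical SD of its estimates. 1500 replicates keep the sampling
  # error of the SD denominator (~1.8%) well inside the band.
  cond <- simulation_condition(N = 50, L = 50, rho_bar = 0, reps = 1500,
                               seed = 1)
  ests <- ses <- numeric(cond$reps)
  for (r in seq_len(cond$reps)) {
    fit <- mlm_reml(generate_dataset(cond, replicate_index = r), "ID")
    ests[r] <- fit$fixed["gamma10"]
    ses[r] <- fit$se["gamma10"]
  }
  expect_lt(abs(mean(ses) / sd(ests) - 1), 0.05)
})

test_that("variance components are recovered without bias at rho_bar = 0", {
  cond <- simulation_condition(N = 200, L = 200, rho_bar = 0, reps = 100,
                               seed = 1)
  v <- vapply(seq_len(cond$reps), function(r)
    mlm_reml(generate_dataset(cond, replicate_index = r), "ID")$vcomp["var_u0"],
    numeric(1))
  expect_lt(abs(mean(v) / 0.5 - 1), 0.03)
})
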