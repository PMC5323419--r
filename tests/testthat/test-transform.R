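test_that("whiten_subject multiplies every column by A, intercept included", {
  set.seed(2)
  n <- 10
  y <- rnorm(n); X <- cbind(1, rnorm(n), 2, 2 * rnorm(n)); Z <- cbind(1, rnorm(n))
  # identity operator (rho = 0) leaves everything bit-identical
  id_op <- ar1_whitening(0, n)
  tr <- whiten_subject(id_op, y, X, Z)
  expect_identical(tr$y_star, y)
  expect_identical(tr$X_star, X)
  expect_identical(tr$Z_star, Z)

  op <- ar1_whitening(0.6, n)
  tr <- whiten_subject(op, y, X, Z)
  A <- as.matrix(op)
  expect_equal(tr$X_star, A %*% X, tolerance = 1e-12)
  # the intercept column is A %*% 1, not a ones column
  expect_equal(tr$X_star[, 1], as.numeric(A %*% rep(1, n)))
  expect_false(all(tr$X_star[, 1] == 1))
  expect_error(whiten_subject(ar1_whitening(0.5, n), rnorm(n - 1), X, Z),
               "dimension mismatch")
})

test_that("whitening with the true operator removes residual autocorrelation", {
  set.seed(9)
  n <- 2000
  z <- rnorm(n)
  y <- 1 + z + sim_ar1(n, 0.6)
  op <- ar1_whitening(0.6, n)
  ys <- whiten(op, y)
  Xs <- whiten(op, cbind(1, z))
  res <- ys - Xs %*% qr.coef(qr(Xs), ys)
  expect_lt(abs(lag1_autocor(as.numeric(res))), 0.05)
})

test_that("GLS with true Sigma equals OLS on whitened data", {
  set.seed(17)
  for (k in 1:50) {
    n <- sample(5:20, 1)
    rho <- runif(1, -0.9, 0.9)
    X <- cbind(1, rnorm(n))
    y <- X %*% c(1, 2) + sim_ar1(n, rho)
    Sigma <- ar1_covariance(rho, 1, n)
    gls <- gls_fixed_effects(y, X, Sigma)
    op <- ar1_whitening(rho, n)
    ols_w <- qr.coef(qr(whiten(op, X)), whiten(op, as.numeric(y)))
    expect_equal(gls, unname(ols_w), tolerance = 1e-8)
  }
})

test_that("transform pipeline estimates per-subject AR fits and whitens blocks", {
  cond <- simulation_condition(N = 8, L = 200, rho_bar = 0.6, reps = 1,
                               seed = 123)
  panel <- generate_dataset(cond)
  tp <- mlm_ct_transform(panel)
  expect_s3_class(tp, "mlmct_transformed")
  expect_equal(nrow(tp), nrow(panel))
  fits <- attr(tp, "ar_fits")
  expect_length(fits, 8)
  rho_i <- attr(panel, "rho_i")
  # estimated AR parameters track the heterogeneous truths
  expect_lt(max(abs(vapply(fits, `[[`, numeric(1), "rho") - rho_i)), 0.25)
  # whitened residual variance approximates the estimated innovation
  # variance (the subject-level regression absorbs that subject's random
  # effects, so the per-subject residual is the whitened AR error)
  for (s in 1:8) {
    rows <- tp$subject == s
    ys <- tp$y_star[rows]
    Xs <- as.matrix(tp[rows, c("x_star_1", "x_star_2")])
    res <- ys - Xs %*% qr.coef(qr(Xs), ys)
    expect_lt(abs(mean(res^2) / fits[[s]]$sigma_w2 - 1), 0.1)
  }
  expect_error(
    mlm_ct_transform(generate_dataset(
      simulation_condition(N = 3, L = 4, rho_bar = 0, reps = 1, seed = 1))),
    "fewer than")
})

test_that("order invariance: blockwise whitening equals block-diagonal A", {
  cond <- simulation_condition(N = 3, L = 12, rho_bar = 0.3, reps = 1,
                               seed = 77)
  panel <- generate_dataset(cond)
  tp <- mlm_ct_transform(panel)
  fits <- attr(tp, "ar_fits")
  blocks <- lapply(1:3, function(s)
    as.matrix(arp_whitening(fits[[as.character(s)]]$phi, 12)))
  Abig <- matrix(0, 36, 36)
  for (s in 1:3) Abig[(s - 1) * 12 + 1:12, (s - 1) * 12 + 1:12] <- blocks[[s]]
  expect_equal(tp$y_star, as.numeric(Abig %*% panel$y), tolerance = 1e-10)
})

test_that("rescaling divides each block by the innovation SD", {
  cond <- simulation_condition(N = 4, L = 60, rho_bar = 0.3, reps = 1,
                               seed = 5)
  panel <- generate_dataset(cond)
  tp <- mlm_ct_transform(panel)
  fits <- attr(tp, "ar_fits")
  rs <- rescale_to_unit_variance(tp)
  rows <- rs$subject == 2
  expect_equal(rs$y_star[rows],
               tp$y_star[tp$subject == 2] / sqrt(fits[["2"]]$sigma_w2))
  # all sigma_w2 = 1 leaves the panel unchanged
  expect_identical(rescale_to_unit_variance(rs), rs)

  # heteroscedastic subjects: post-rescale residual variances near 1
  set.seed(31)
  L <- 200
  blocks <- lapply(1:6, function(s) {
    sw <- if (s %% 2) sqrt(0.5) else sqrt(2)
    z <- rnorm(L)
    data.frame(subject = s, occasion = 1:L,
               y = 1 + z + sim_ar1(L, 0.4, sigma_w = sw), z = z, c = 0.5)
  })
  het <- do.call(rbind, blocks)
  rs <- mlm_ct_transform(het, rescale = TRUE)
  for (s in 1:6) {
    rows <- rs$subject == s
    ys <- rs$y_star[rows]
    Xs <- as.matrix(rs[rows, paste0("x_star", c("_1", "_2"))])
    res <- ys - Xs %*% qr.coef(qr(Xs), ys)
    expect_lt(abs(mean(res^2) - 1), 0.15)
  }
})

test_that("pipeline failures name the subject and skip policy drops them", {
  cond <- simulation_condition(N = 4, L = 30, rho_bar = 0, reps = 1, seed = 2)
  panel <- generate_dataset(cond)
  panel$z[panel$subject == 3] <- 1  # constant covariate: collinear design
  expect_error(mlm_ct_transform(panel), "subject '3'")
  tp <- mlm_ct_transform(panel, on_error = "skip")
  expect_equal(attr(tp, "skipped"), "3")
  expect_false(3 %in% tp$subject)
})
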