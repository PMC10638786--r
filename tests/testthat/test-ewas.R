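test_that("design construction drops missing exposures and checks rank", {
  x <- stats::setNames(c(1, 2, NA, 4), paste0("s", 1:4))
  d <- ewas_design(x, NULL, c("f1", "f1", "f2", "f2"))
  expect_equal(d$samples, c("s1", "s2", "s4"))
  expect_equal(colnames(d$X), c("(Intercept)", "exposure"))
  expect_equal(d$exposure_col, 2L)
  ## aliased covariate -> rank deficient
  cov <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("s", 1:4), "dup"))
  x2 <- stats::setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  expect_error(ewas_design(x2, cov, rep("f", 4)), "rank deficient")
})

test_that("GLS with rho = 0 reproduces lm() exactly", {
  set.seed(71)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  x <- stats::setNames(rnorm(n), ids)
  z <- matrix(rnorm(n), n, 1, dimnames = list(ids, "z"))
  fam <- rep(sprintf("f%02d", 1:(n / 2)), each = 2)
  des <- ewas_design(x, z, fam)
  y <- 0.3 * x + 0.1 * z[, 1] + rnorm(n)
  names(y) <- ids
  res <- fit_cpg_gls(y, des, rho = 0)
  ref <- summary(lm(y ~ x + z))$coefficients
  expect_equal(res$beta_hat, ref["x", "Estimate"], tolerance = 1e-10)
  expect_equal(res$se, ref["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(res$t, ref["x", "t value"], tolerance = 1e-10)
  expect_equal(res$p_value, ref["x", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(res$df_residual, n - 3L)
  expect_equal(res$p_count, 3L)
})

test_that("GLS matches the explicit whole-covariance solution", {
  set.seed(72)
  rho <- 0.55
  n_pairs <- 15; n_single <- 4
  n <- 2 * n_pairs + n_single
  fam <- c(rep(sprintf("p%02d", 1:n_pairs), each = 2),
           sprintf("s%02d", 1:n_single))
  ids <- sprintf("i%02d", 1:n)
  x <- stats::setNames(rnorm(n), ids)
  y <- 0.5 * x + rnorm(n)
  des <- ewas_design(x, NULL, fam)
  res <- fit_cpg_gls(y, des, rho)

  ## oracle: build the full correlation matrix and solve GLS directly
  R <- diag(n)
  for (p in unique(fam[duplicated(fam)])) {
    ij <- which(fam == p)
    R[ij[1], ij[2]] <- R[ij[2], ij[1]] <- rho
  }
  W <- solve(R)
  X <- des$X
  XtWX <- solve(t(X) %*% W %*% X)
  b <- XtWX %*% t(X) %*% W %*% y
  r <- y - X %*% b
  s2 <- drop(t(r) %*% W %*% r) / (n - ncol(X))
  se <- sqrt(s2 * XtWX[2, 2])
  expect_equal(res$beta_hat, unname(b[2, 1]), tolerance = 1e-10)
  expect_equal(res$se, unname(se), tolerance = 1e-10)
  expect_equal(res$sigma2, unname(s2), tolerance = 1e-10)
})

test_that("consensus correlation recovers the generating value", {
  nd <- null_family_data(n_pairs = 250, n_cpgs = 80, rho = 0.5, seed = 73)
  rho_hat <- estimate_consensus_correlation(nd$Y, nd$design)
  expect_lt(abs(rho_hat - 0.5), 0.06)
  ## independent pairs pool to ~ 0
  nd0 <- null_family_data(n_pairs = 250, n_cpgs = 80, rho = 0, seed = 74)
  expect_lt(abs(estimate_consensus_correlation(nd0$Y, nd0$design)), 0.06)
})

test_that("variance moderation matches the limma empirical-Bayes oracle", {
  set.seed(75)
  n_cpg <- 400; d <- 40; d0_true <- 8; s0_true <- 0.04
  ## scaled inverse-chi-square gene variances, then chi-square sample noise
  v <- d0_true * s0_true / rchisq(n_cpg, d0_true)
  s2 <- v * rchisq(n_cpg, d) / d
  res <- data.frame(cpg_id = sprintf("c%03d", 1:n_cpg), beta_hat = rnorm(n_cpg),
                    se = sqrt(s2), t = 1, df_residual = d, n = d + 2,
                    p_count = 2, p_value = 0.5, sigma2 = s2,
                    stdev_unscaled = 1, stringsAsFactors = FALSE)
  mod <- moderate_statistics(res)
  sq <- limma::squeezeVar(s2, d)
  expect_equal(attr(mod, "d0"), sq$df.prior, tolerance = 1e-4)
  expect_equal(attr(mod, "s0_2"), sq$var.prior, tolerance = 1e-4)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 1e-6)
  expect_equal(mod$df_mod[1], d + sq$df.prior, tolerance = 1e-4)
})

test_that("moderated t interpolates between raw t and the pooled z-test", {
  set.seed(76)
  n_cpg <- 50; d <- 10
  s2 <- 0.02 * rchisq(n_cpg, d) / d
  res <- data.frame(cpg_id = sprintf("c%03d", 1:n_cpg),
                    beta_hat = rnorm(n_cpg, sd = 0.05),
                    se = sqrt(s2), t = 0, df_residual = d, n = d + 2,
                    p_count = 2, p_value = 0.5, sigma2 = s2,
                    stdev_unscaled = 0.3, stringsAsFactors = FALSE)
  res$t <- res$beta_hat / (sqrt(res$sigma2) * res$stdev_unscaled)
  ## d0 = 0: no shrinkage, moderated t is the raw t on d df
  m0 <- moderate_statistics(res, d0_override = 0)
  expect_equal(m0$t_mod, res$t, tolerance = 1e-12)
  expect_equal(m0$s2_post, res$sigma2, tolerance = 1e-12)
  expect_equal(m0$p_mod, 2 * pt(-abs(res$t), d), tolerance = 1e-12)
  ## d0 = Inf: complete pooling, normal reference
  mI <- moderate_statistics(res, d0_override = Inf)
  expect_equal(var(mI$s2_post), 0)
  expect_equal(mI$p_mod, 2 * pnorm(-abs(mI$t_mod)), tolerance = 1e-12)
  ## large but finite d0 approaches the pooled limit
  mBig <- moderate_statistics(res, d0_override = 1e8)
  expect_equal(mBig$s2_post, mI$s2_post, tolerance = 1e-5)
  expect_equal(mBig$t_mod, mI$t_mod, tolerance = 1e-3)
})

test_that("moderation input validation works", {
  res <- data.frame(sigma2 = rep(0.01, 12), df_residual = c(rep(10, 11), 9),
                    beta_hat = 1, stdev_unscaled = 1)
  expect_error(moderate_statistics(res), "common residual df")
  res2 <- data.frame(sigma2 = rep(0.01, 12), df_residual = 10,
                     beta_hat = 1, stdev_unscaled = 1)
  expect_error(moderate_statistics(res2), "distinct variances")
})

test_that("AIC vote selects the covariate model that generated the data", {
  set.seed(77)
  n <- 120
  ids <- sprintf("s%03d", 1:n)
  fam <- rep(sprintf("f%03d", 1:(n / 2)), each = 2)
  x <- stats::setNames(rnorm(n), ids)
  z <- matrix(rnorm(n), n, 1, dimnames = list(ids, "batch"))
  Y <- matrix(rnorm(40 * n, sd = 0.3), 40, n, dimnames = list(NULL, ids))
  Y <- sweep(Y, 2, 0.8 * z[, 1], "+")   # strong batch effect on every CpG
  d_plain <- ewas_design(x, NULL, fam)
  d_batch <- ewas_design(x, z, fam)
  pick <- select_covariate_model(Y, list(d_plain, d_batch))
  expect_equal(as.integer(pick), 2L)
  expect_equal(sum(attr(pick, "votes")), 40L)
  ## exact tie (identical candidates): earlier design wins
  Y0 <- matrix(rnorm(2 * n), 2, n, dimnames = list(NULL, ids))
  pick0 <- select_covariate_model(Y0, list(d_plain, d_plain))
  expect_equal(as.integer(pick0), 1L)
})

test_that("bias and inflation are near 0 and 1 under the null", {
  set.seed(78)
  qc <- estimate_inflation_bias(rnorm(5000))
  expect_lt(abs(qc$bias), 0.05)
  expect_lt(abs(qc$inflation - 1), 0.05)
  ## inflated scores detected
  qc2 <- estimate_inflation_bias(rnorm(5000, sd = 1.5))
  expect_gt(qc2$inflation, 1.3)
  expect_error(estimate_inflation_bias(rnorm(5)), "at least 10")
})

test_that("family-aware EWAS keeps type-I error calibrated under clustering", {
  nd <- null_family_data(n_pairs = 200, n_cpgs = 1000, rho = 0.6, seed = 79)
  rho_hat <- estimate_consensus_correlation(nd$Y, nd$design)
  expect_lt(abs(rho_hat - 0.6), 0.05)
  res <- run_ewas(nd$Y, nd$design, rho_hat)
  frac <- mean(res$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  ## ignoring the correlation does not deflate below the naive level
  res0 <- run_ewas(nd$Y, nd$design, 0)
  expect_gt(mean(res0$p_value < 0.05), frac - 0.03)
})

test_that("run_ewas rejects invalid rho", {
  nd <- null_family_data(10, 2, 0.2, seed = 80)
  expect_error(run_ewas(nd$Y, nd$design, 1), "rho")
  expect_error(run_ewas(nd$Y, nd$design, c(0.1, 0.2)), "rho")
})
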