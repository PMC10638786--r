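test_that("simulated twin pairs hit the target correlations and are seeded", {
  p1 <- simulate_twin_pairs(2000, 2000, 0.8, 0.5, mean = 3, sd = 2, seed = 1)
  p2 <- simulate_twin_pairs(2000, 2000, 0.8, 0.5, mean = 3, sd = 2, seed = 1)
  expect_identical(p1, p2)
  mz <- p1$zygosity == "MZ"
  expect_lt(abs(cor(p1$y1[mz], p1$y2[mz]) - 0.8), 0.03)
  expect_lt(abs(cor(p1$y1[!mz], p1$y2[!mz]) - 0.5), 0.05)
  expect_lt(abs(mean(c(p1$y1, p1$y2)) - 3), 0.15)
  expect_lt(abs(sd(c(p1$y1, p1$y2)) - 2), 0.1)
})

test_that("FIML log-likelihood equals a direct bivariate-normal computation", {
  pairs <- simulate_twin_pairs(40, 40, 0.7, 0.4, seed = 2)
  ## add an incomplete pair on each side
  pairs$y2[1] <- NA; pairs$y1[41] <- NA
  fit <- fit_twin_model(pairs, "ACE", covariates = character())
  theta <- unname(fit$coefficients)
  mu <- theta[1]
  comp <- fit$components * fit$total_variance
  v <- fit$total_variance
  ll_manual <- 0
  for (i in seq_len(nrow(pairs))) {
    cv <- if (pairs$zygosity[i] == "MZ") comp[["a2"]] + comp[["c2"]] else
      0.5 * comp[["a2"]] + comp[["c2"]]
    y1 <- pairs$y1[i]; y2 <- pairs$y2[i]
    if (!is.na(y1) && !is.na(y2)) {
      S <- matrix(c(v, cv, cv, v), 2)
      d <- c(y1 - mu, y2 - mu)
      ll_manual <- ll_manual - log(2 * pi) - 0.5 * log(det(S)) -
        0.5 * drop(t(d) %*% solve(S) %*% d)
    } else {
      y <- if (is.na(y1)) y2 else y1
      ll_manual <- ll_manual + dnorm(y, mu, sqrt(v), log = TRUE)
    }
  }
  expect_equal(fit$loglik, ll_manual, tolerance = 1e-8)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
})

test_that("ACE estimates agree with the Falconer closed forms at scale", {
  pairs <- simulate_twin_pairs(4000, 4000, 0.8, 0.5, seed = 3)
  fit <- fit_twin_model(pairs, "ACE", covariates = character())
  rmz <- cor(pairs$y1[pairs$zygosity == "MZ"], pairs$y2[pairs$zygosity == "MZ"])
  rdz <- cor(pairs$y1[pairs$zygosity == "DZ"], pairs$y2[pairs$zygosity == "DZ"])
  expect_lt(abs(fit$components[["a2"]] - 2 * (rmz - rdz)), 0.03)
  expect_lt(abs(fit$components[["c2"]] - (2 * rdz - rmz)), 0.03)
  expect_lt(abs(fit$components[["a2"]] - 0.6), 0.05)
  expect_lt(abs(fit$components[["c2"]] - 0.2), 0.05)
  expect_lt(abs(fit$components[["e2"]] - 0.2), 0.03)
  expect_equal(fit$components[["d2"]], 0)
  expect_equal(sum(fit$components), 1, tolerance = 1e-9)
  ## implied correlations reproduce the generating values
  expect_lt(abs(fit$implied[["r_mz"]] - 0.8), 0.03)
  expect_lt(abs(fit$implied[["r_dz"]] - 0.5), 0.03)
})

test_that("ADE model recovers dominance structure", {
  pairs <- simulate_twin_pairs(4000, 4000, 0.8, 0.3, seed = 4)
  fit <- fit_twin_model(pairs, "ADE", covariates = character())
  ## a2 = 4 rdz - rmz = 0.4, d2 = 2 rmz - 4 rdz = 0.4
  expect_lt(abs(fit$components[["a2"]] - 0.4), 0.07)
  expect_lt(abs(fit$components[["d2"]] - 0.4), 0.07)
  expect_lt(abs(fit$components[["e2"]] - 0.2), 0.03)
  expect_equal(fit$components[["c2"]], 0)
})

test_that("mean-model covariates are estimated", {
  co <- generate_cohort(cohort_config(n_families = 600), seed = 5)
  tr <- co$truth
  vals <- stats::setNames(0.5 + 0.05 * tr$L, tr$individual_id)
  pt <- pair_table(co, vals)
  ## inject a sex effect
  pt$y1 <- pt$y1 + 0.03 * (pt$sex1 == "F")
  pt$y2 <- pt$y2 + 0.03 * (pt$sex2 == "F")
  fit <- fit_twin_model(pt, "ACE", covariates = c("age", "sex"))
  expect_true(all(c("mu", "b_age", "b_sex") %in% names(coef(fit))))
  expect_lt(abs(coef(fit)[["b_sex"]] - 0.03), 0.01)
  expect_lt(abs(coef(fit)[["b_age"]]), 0.002)
})

test_that("twin_model S3 methods work", {
  pairs <- simulate_twin_pairs(300, 300, 0.7, 0.4, seed = 6)
  fit <- fit_twin_model(pairs, "AE", covariates = character())
  expect_output(print(fit), "Twin AE model")
  expect_output(print(summary(fit)), "Implied twin correlations")
  expect_named(coef(fit), c("mu", "a", "e"))
  V <- vcov(fit)
  expect_equal(dim(V), c(3, 3))
  expect_true(all(diag(V) > 0))
  ## simulate() round trip: refit on simulated data recovers components
  sim <- simulate(fit, seed = 7)
  expect_equal(nrow(sim), nrow(pairs))
  refit <- fit_twin_model(sim, "AE", covariates = character())
  expect_lt(abs(refit$components[["a2"]] - fit$components[["a2"]]), 0.08)
  sims <- simulate(fit, nsim = 2, seed = 8)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$y1, sims[[2]]$y1))
})

test_that("profile-likelihood intervals bracket the estimate and the truth", {
  pairs <- simulate_twin_pairs(400, 400, 0.7, 0.35, seed = 9)
  fit <- fit_twin_model(pairs, "AE", covariates = character())
  ci <- confint(fit, parm = "a")
  expect_equal(rownames(ci), "a2")
  expect_true(ci["a2", "lower"] < fit$components[["a2"]])
  expect_true(ci["a2", "upper"] > fit$components[["a2"]])
  expect_true(ci["a2", "lower"] < 0.7 && 0.7 < ci["a2", "upper"])
})

test_that("a boundary component yields an NA profile bound", {
  ## data with no shared environment: c is estimated at the zero boundary
  pairs <- simulate_twin_pairs(500, 500, 0.6, 0.2, seed = 10)
  fit <- fit_twin_model(pairs, "ACE", covariates = character())
  expect_lt(fit$components[["c2"]], 0.05)
  ci <- confint(fit, parm = "c")
  expect_true(is.na(ci["c2", "lower"]))
})

test_that("model selection accepts the parsimonious generating model", {
  pairs <- simulate_twin_pairs(1500, 1500, 0.7, 0.35, seed = 11)
  sel <- select_best_model(pairs, covariates = character())
  expect_s3_class(sel, "twin_model_selection")
  expect_equal(sel$best_model, "AE")
  expect_equal(sel$best$model, "AE")
  expect_true(all(c("ACE", "ADE", "AE", "CE", "DE", "E") %in% sel$table$model))
  ## AE must not fit significantly worse than either full model
  expect_gte(sel$table$lrt_p[sel$table$model == "AE"], 0.05)
  expect_output(print(sel), "Best-fitting twin model: AE")

  ## pure unique environment: E wins
  pairs0 <- simulate_twin_pairs(1500, 1500, 0, 0, seed = 12)
  sel0 <- select_best_model(pairs0, covariates = character())
  expect_equal(sel0$best_model, "E")

  ## strong shared environment: CE wins
  pairs_c <- simulate_twin_pairs(1500, 1500, 0.6, 0.6, seed = 13)
  sel_c <- select_best_model(pairs_c, covariates = character())
  expect_equal(sel_c$best_model, "CE")
})

test_that("candidate checks flag low variability and assumption violations", {
  pairs <- simulate_twin_pairs(400, 400, 0.7, 0.4, mean = 0.5, sd = 0.1,
                               seed = 14)
  chk <- check_candidate(pairs)
  expect_true(chk$eligible)
  expect_length(chk$assumption_p, 4)
  expect_true(all(chk$assumption_p > 0.01))

  ## SD below the threshold
  small <- simulate_twin_pairs(400, 400, 0.7, 0.4, mean = 0.5, sd = 0.01,
                               seed = 15)
  chk_sd <- check_candidate(small)
  expect_false(chk_sd$eligible)
  expect_true(any(grepl("SD", chk_sd$reasons)))

  ## order-dependent mean violates the exchangeability assumption
  shifted <- pairs
  shifted$y2 <- shifted$y2 + 0.08
  chk_m <- check_candidate(shifted)
  expect_false(chk_m$eligible)
  expect_lt(chk_m$assumption_p[["order_mean"]], 0.01)

  ## zygosity-dependent variance is detected
  hetv <- pairs
  dz <- hetv$zygosity == "DZ"
  hetv$y1[dz] <- 0.5 + (hetv$y1[dz] - 0.5) * 2
  hetv$y2[dz] <- 0.5 + (hetv$y2[dz] - 0.5) * 2
  chk_v <- check_candidate(hetv)
  expect_lt(chk_v$assumption_p[["zygosity_var"]], 0.01)
})

test_that("double-entry twin correlations match a direct computation", {
  pairs <- simulate_twin_pairs(200, 250, 0.75, 0.4, seed = 16)
  rs <- twin_correlations(pairs, covariates = character())
  mz <- pairs$zygosity == "MZ"
  oracle <- function(sel)
    cor(c(pairs$y1[sel], pairs$y2[sel]), c(pairs$y2[sel], pairs$y1[sel]))
  expect_equal(rs[["r_mz"]], oracle(mz), tolerance = 1e-12)
  expect_equal(rs[["r_dz"]], oracle(!mz), tolerance = 1e-12)
  ## residualization removes a pure sex effect
  pairs$sex1 <- rep(c("M", "F"), length.out = nrow(pairs))
  pairs$sex2 <- pairs$sex1
  pairs$y1 <- pairs$y1 + 2 * (pairs$sex1 == "F")
  pairs$y2 <- pairs$y2 + 2 * (pairs$sex2 == "F")
  rs_adj <- twin_correlations(pairs, covariates = "sex")
  expect_lt(abs(rs_adj[["r_mz"]] - rs[["r_mz"]]), 0.02)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_twin_model(data.frame(y1 = 1, y2 = 1, zygosity = "MZ")),
               "at least 3")
  const <- data.frame(y1 = rep(1, 10), y2 = rep(1, 10),
                      zygosity = rep(c("MZ", "DZ"), 5))
  expect_error(fit_twin_model(const), "constant")
})

test_that("the reference twin-correlation panel is internally consistent", {
  panel <- twin_correlation_panel()
  expect_equal(nrow(panel), 14)
  expect_equal(sum(panel$best_model == "AE"), 13)
  expect_true(all(panel$r_mz > panel$r_dz))
  expect_true(all(panel$r_mz <= 1 & panel$r_dz >= 0))
  expect_false(anyDuplicated(panel$cpg_id) > 0)
})
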