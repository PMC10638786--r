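test_that("wilcoxon sex test matches stats::wilcox.test", {
  set.seed(41)
  v <- c(rnorm(30, 0.5, 0.05), rnorm(25, 0.53, 0.05))
  sex <- rep(c("M", "F"), c(30, 25))
  out <- wilcoxon_sex_test(v, sex, m_tests = 3)
  ref <- suppressWarnings(wilcox.test(v[sex == "M"], v[sex == "F"],
                                      exact = FALSE, correct = TRUE))
  expect_equal(out$statistic, unname(ref$statistic))
  expect_equal(out$p_raw, ref$p.value)
  expect_equal(out$p_bonferroni, min(1, 3 * ref$p.value))
  expect_equal(out$significant, out$p_bonferroni < 0.01)
  ## NA values are ignored
  out2 <- wilcoxon_sex_test(c(v, NA), c(sex, "F"), m_tests = 3)
  expect_equal(out2$p_raw, out$p_raw)
  expect_error(wilcoxon_sex_test(v[sex == "M"], sex[sex == "M"]), "both sexes")
  ## constant input: no evidence of a difference
  expect_equal(wilcoxon_sex_test(rep(0.5, 20), rep(c("M", "F"), 10))$p_raw, 1)
})

test_that("rank-sum statistic and p agree with complete enumeration", {
  ## small two-group problem: enumerate all assignments of ranks
  xm <- c(0.12, 0.34, 0.29, 0.51)
  xf <- c(0.18, 0.47, 0.55, 0.61, 0.40)
  out <- wilcoxon_sex_test(c(xm, xf), rep(c("M", "F"), c(4, 5)))
  ## Mann-Whitney U by direct counting
  u_obs <- sum(outer(xm, xf, ">")) + 0.5 * sum(outer(xm, xf, "=="))
  expect_equal(out$statistic, u_obs)
  ## exact two-sided p over all choose(9, 4) label assignments
  pool <- c(xm, xf)
  combs <- utils::combn(9, 4)
  u_all <- apply(combs, 2, function(i)
    sum(outer(pool[i], pool[-i], ">")) + 0.5 * sum(outer(pool[i], pool[-i], "==")))
  mu <- 4 * 5 / 2
  p_exact <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  ## the normal approximation should be close to the enumerated p
  expect_lt(abs(out$p_raw - p_exact), 0.06)
})

test_that("five-group stratification normalizes opposite-sex pairs male-first", {
  pairs <- data.frame(
    family_id = paste0("f", 1:6),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "DZ", "DZ"),
    sex1 = c("M", "F", "M", "F", "M", "F"),
    sex2 = c("M", "F", "M", "F", "F", "M"),
    y1 = as.numeric(1:6), y2 = as.numeric(11:16), stringsAsFactors = FALSE)
  g <- twinmeth:::.sexlim_groups(pairs)
  expect_equal(vapply(g, nrow, 0L),
               c(MZm = 1L, MZf = 1L, DZm = 1L, DZf = 1L, DZos = 2L))
  ## the F-first pair (family 6) must be swapped so y1 is the male value
  expect_setequal(g$DZos$y1, c(5, 16))
  expect_setequal(g$DZos$y2, c(15, 6))
})

test_that("sex-limitation fit recovers a genuine quantitative sex difference", {
  set.seed(42)
  n <- 1500
  draw <- function(n, r, s1, s2, zyg, v1, v2) {
    z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    data.frame(family_id = paste0(zyg, s1, s2, seq_len(n)), zygosity = zyg,
               sex1 = s1, sex2 = s2, y1 = sqrt(v1) * z1, y2 = sqrt(v2) * z2,
               stringsAsFactors = FALSE)
  }
  ## males a2 = 0.3, females a2 = 0.8, equal total variance 1
  pairs <- rbind(
    draw(n, 0.3, "M", "M", "MZ", 1, 1), draw(n, 0.8, "F", "F", "MZ", 1, 1),
    draw(n, 0.15, "M", "M", "DZ", 1, 1), draw(n, 0.4, "F", "F", "DZ", 1, 1),
    ## opposite-sex covariance 0.5 * sqrt(0.3 * 0.8) -> correlation ~ 0.245
    draw(n, 0.5 * sqrt(0.3 * 0.8), "M", "F", "DZ", 1, 1))
  free <- fit_sex_limitation(pairs, model = "AE")
  expect_lt(abs(free$components$M[["a2"]] - 0.3), 0.06)
  expect_lt(abs(free$components$F[["a2"]] - 0.8), 0.06)
  expect_output(print(free), "Sex-limitation AE model")

  equated <- fit_sex_limitation(pairs, model = "AE",
                                constraints = c("mean", "a", "e"))
  expect_equal(free$n_params - equated$n_params, 3L)
  omni <- omnibus_sex_test(free, equated, m_tests = 14)
  expect_true(omni$significant)
  expect_equal(omni$p_adj, min(1, omni$p * 14))

  tests <- parameter_sex_tests(free, parameters = c("mean", "a", "e", "rg"))
  expect_true(tests$significant[tests$parameter == "a"])
  expect_false(tests$significant[tests$parameter == "mean"])
  ## rg was generated at its null value of 0.5
  expect_false(tests$significant[tests$parameter == "rg"])
})

test_that("no sex difference: omnibus and parameter tests stay null", {
  pairs <- simulate_sexlim_null(n_per_group = 700, a2 = 0.7, seed = 46)
  free <- fit_sex_limitation(pairs, model = "AE")
  expect_lt(abs(free$components$M[["a2"]] - 0.7), 0.08)
  expect_lt(abs(free$components$F[["a2"]] - 0.7), 0.08)
  equated <- fit_sex_limitation(pairs, model = "AE",
                                constraints = c("mean", "a", "e"))
  omni <- omnibus_sex_test(free, equated)
  expect_gt(omni$p, 0.01)
  tests <- parameter_sex_tests(free, parameters = c("mean", "a", "e", "var", "rg"))
  expect_false(any(tests$significant))
  ## the rg refit must not leave the admissible range
  fit_rg <- fit_sex_limitation(pairs, model = "AE", rg_fixed = FALSE)
  expect_gte(fit_rg$rg, 0)
  expect_lte(fit_rg$rg, 0.5)
})

test_that("a qualitative sex difference is detected through rg", {
  set.seed(44)
  n <- 1500
  draw <- function(n, r, s1, s2, zyg) {
    z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    data.frame(family_id = paste0(zyg, s1, s2, seq_len(n)), zygosity = zyg,
               sex1 = s1, sex2 = s2, y1 = z1, y2 = z2, stringsAsFactors = FALSE)
  }
  a2 <- 0.7
  ## different genes act in each sex: opposite-sex genetic correlation 0
  pairs <- rbind(
    draw(n, a2, "M", "M", "MZ"), draw(n, a2, "F", "F", "MZ"),
    draw(n, a2 / 2, "M", "M", "DZ"), draw(n, a2 / 2, "F", "F", "DZ"),
    draw(n, 0, "M", "F", "DZ"))
  free <- fit_sex_limitation(pairs, model = "AE")
  tests <- parameter_sex_tests(free, parameters = "rg")
  expect_true(tests$significant[tests$parameter == "rg"])
  fit_rg <- fit_sex_limitation(pairs, model = "AE", rg_fixed = FALSE)
  expect_lt(fit_rg$rg, 0.15)
})

test_that("sex-limitation interface validation", {
  pairs <- simulate_sexlim_null(50, 0.5, seed = 45)
  expect_error(fit_sex_limitation(pairs, constraints = "b"), "unknown constraint")
  ss <- pairs[pairs$sex1 == pairs$sex2, ]
  expect_error(fit_sex_limitation(ss, rg_fixed = FALSE), "unidentifiable")
  free <- fit_sex_limitation(pairs)
  expect_error(omnibus_sex_test(free, free), "nested")
  expect_error(parameter_sex_tests(free, parameters = "zz"), "unknown parameter")
  ## ACE variant runs and returns shared-environment components
  fit_ace <- fit_sex_limitation(pairs, model = "ACE")
  expect_true(all(c("c_m", "c_f") %in% names(coef <- fit_ace$coefficients)))
  expect_gte(fit_ace$components$M[["c2"]], 0)
})
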