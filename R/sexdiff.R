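## Sex differences in methylation: rank tests on the values and five-group
## sex-limitation twin models on the variance components.
##
## Quantitative sex differences (same genes, different magnitudes) are tested
## by equating parameters across sexes; qualitative differences (different
## genes per sex) by freeing the opposite-sex DZ genetic correlation rg from
## its null value of 0.5. The shared-environment cross-sex correlation is
## fixed at 1 by convention.

#' Wilcoxon two-sample test for a sex difference in methylation
#'
#' Rank-sum test (normal approximation with tie and continuity corrections)
#' comparing males and females, Bonferroni-corrected over `m_tests` CpGs;
#' significance is called at adjusted p < 0.01.
#'
#' @param values numeric vector of methylation values.
#' @param sex "M"/"F" per value; both sexes must be present.
#' @param m_tests number of CpGs tested (Bonferroni multiplier).
#' @return list with `statistic` (rank-sum W), `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
wilcoxon_sex_test <- function(values, sex, m_tests = 1L) {
  ok <- !is.na(values) & sex %in% c("M", "F")
  values <- values[ok]; sex <- sex[ok]
  if (length(unique(sex)) < 2)
    stop("both sexes must be represented", call. = FALSE)
  if (m_tests < 1) stop("'m_tests' must be >= 1", call. = FALSE)
  xm <- values[sex == "M"]; xf <- values[sex == "F"]
  if (stats::sd(values) == 0) {
    w <- length(xm) * length(xf) / 2
    res <- list(statistic = w, p_raw = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(xm, xf, exact = FALSE,
                                              correct = TRUE))
    p <- if (is.na(wt$p.value)) 1 else wt$p.value
    res <- list(statistic = unname(wt$statistic), p_raw = p)
  }
  res$p_bonferroni <- min(1, res$p_raw * m_tests)
  res$significant <- res$p_bonferroni < 0.01
  res
}

## stratify complete pairs into the five sex-by-zygosity groups, opposite-sex
## pairs normalized so member 1 is male
.sexlim_groups <- function(pairs) {
  stopifnot(all(c("y1", "y2", "zygosity", "sex1", "sex2") %in% names(pairs)))
  pairs <- pairs[!is.na(pairs$y1) & !is.na(pairs$y2), , drop = FALSE]
  os <- pairs$sex1 != pairs$sex2
  swap <- os & pairs$sex1 == "F"
  tmp <- pairs$y1[swap]; pairs$y1[swap] <- pairs$y2[swap]; pairs$y2[swap] <- tmp
  grp <- ifelse(pairs$zygosity == "MZ",
                ifelse(pairs$sex1 == "M", "MZm", "MZf"),
                ifelse(os, "DZos", ifelse(pairs$sex1 == "M", "DZm", "DZf")))
  split(pairs[, c("y1", "y2")], factor(grp, c("MZm", "MZf", "DZm", "DZf", "DZos")))
}

.suff2 <- function(d) {
  list(n = nrow(d), s1 = sum(d$y1), s2 = sum(d$y2), q1 = sum(d$y1^2),
       q2 = sum(d$y2^2), q12 = sum(d$y1 * d$y2))
}

## bivariate normal loglik from sufficient stats, member-specific moments
.ll_suff2 <- function(st, mu1, mu2, v1, v2, cv) {
  det <- v1 * v2 - cv^2
  if (det <= 0 || v1 <= 0 || v2 <= 0) return(-Inf)
  if (st$n == 0) return(0)
  d1q <- st$q1 - 2 * mu1 * st$s1 + st$n * mu1^2
  d2q <- st$q2 - 2 * mu2 * st$s2 + st$n * mu2^2
  d12 <- st$q12 - mu2 * st$s1 - mu1 * st$s2 + st$n * mu1 * mu2
  Q <- (v2 * d1q - 2 * cv * d12 + v1 * d2q) / det
  -st$n * log(2 * pi) - st$n / 2 * log(det) - Q / 2
}

#' Fit a five-group sex-limitation twin model
#'
#' FIML over the MZ-male, MZ-female, DZ-male, DZ-female and opposite-sex DZ
#' groups with sex-indexed means and path coefficients. The opposite-sex
#' cotwin covariance is rg * a_m * a_f + c_m * c_f, with rg bounded in
#' [0, 0.5] (0.5 = the same-sex DZ value, i.e. no qualitative difference).
#'
#' @param pairs data.frame with y1, y2, zygosity, sex1, sex2 (complete pairs
#'   are used).
#' @param model "AE" or "ACE".
#' @param constraints character subset of `c("mean", "a", "c", "e", "var")`:
#'   parameters equated across sexes ("var" equates the total phenotypic
#'   variance while leaving its composition free).
#' @param rg_fixed if TRUE (default) rg is fixed at 0.5; if FALSE it is
#'   estimated (requires a nonempty opposite-sex group).
#' @param n_starts optimization starts.
#' @return list of class `sexlim_model`: per-sex standardized components,
#'   coefficients, rg, loglik, n_params, group sizes.
#' @export
fit_sex_limitation <- function(pairs, model = c("AE", "ACE"),
                               constraints = character(), rg_fixed = TRUE,
                               n_starts = 3) {
  model <- match.arg(model)
  bad <- setdiff(constraints, c("mean", "a", "c", "e", "var"))
  if (length(bad)) stop("unknown constraint: ", bad[1], call. = FALSE)
  groups <- .sexlim_groups(pairs)
  n_g <- vapply(groups, nrow, 0L)
  if (!rg_fixed && n_g[["DZos"]] == 0)
    stop("rg is unidentifiable without opposite-sex DZ pairs", call. = FALSE)
  st <- lapply(groups, .suff2)

  use_c <- model == "ACE"
  eq <- function(p) p %in% constraints
  ## free parameters, in order
  pnames <- c("mu_m", if (!eq("mean")) "mu_f",
              "a_m", if (!eq("a")) "a_f",
              if (use_c) c("c_m", if (!eq("c")) "c_f"),
              "e_m", if (!eq("e") && !eq("var")) "e_f",
              if (!rg_fixed) "rg")
  np <- length(pnames)

  unpack <- function(th) {
    g <- function(nm) unname(th[match(nm, pnames)])
    mu_m <- g("mu_m"); mu_f <- if (eq("mean")) mu_m else g("mu_f")
    a_m <- g("a_m"); a_f <- if (eq("a")) a_m else g("a_f")
    c_m <- if (use_c) g("c_m") else 0
    c_f <- if (!use_c) 0 else if (eq("c")) c_m else g("c_f")
    e_m <- g("e_m")
    e_f <- if (eq("e")) e_m else if (eq("var")) {
      v_m <- a_m^2 + c_m^2 + e_m^2
      sqrt(max(v_m - a_f^2 - c_f^2, 1e-10))
    } else g("e_f")
    rg <- if (rg_fixed) 0.5 else g("rg")
    list(mu_m = mu_m, mu_f = mu_f, a_m = a_m, a_f = a_f, c_m = c_m,
         c_f = c_f, e_m = e_m, e_f = e_f, rg = rg)
  }

  negll <- function(th) {
    p <- unpack(th)
    v_m <- p$a_m^2 + p$c_m^2 + p$e_m^2
    v_f <- p$a_f^2 + p$c_f^2 + p$e_f^2
    ll <- .ll_suff2(st$MZm, p$mu_m, p$mu_m, v_m, v_m, p$a_m^2 + p$c_m^2) +
      .ll_suff2(st$MZf, p$mu_f, p$mu_f, v_f, v_f, p$a_f^2 + p$c_f^2) +
      .ll_suff2(st$DZm, p$mu_m, p$mu_m, v_m, v_m, 0.5 * p$a_m^2 + p$c_m^2) +
      .ll_suff2(st$DZf, p$mu_f, p$mu_f, v_f, v_f, 0.5 * p$a_f^2 + p$c_f^2) +
      .ll_suff2(st$DZos, p$mu_m, p$mu_f, v_m, v_f,
                p$rg * p$a_m * p$a_f + p$c_m * p$c_f)
    if (!is.finite(ll)) 1e10 else -ll
  }

  yall <- c(pairs$y1, pairs$y2)
  s0 <- stats::sd(yall, na.rm = TRUE); m0 <- mean(yall, na.rm = TRUE)
  base <- c(mu_m = m0, mu_f = m0, a_m = s0 * 0.6, a_f = s0 * 0.6,
            c_m = s0 * 0.3, c_f = s0 * 0.3, e_m = s0 * 0.6, e_f = s0 * 0.6,
            rg = 0.4)
  lower <- stats::setNames(rep(0, np), pnames)
  upper <- stats::setNames(rep(Inf, np), pnames)
  lower[grepl("^mu", pnames)] <- -Inf
  lower[grepl("^e_", pnames)] <- 1e-6 * s0
  if (!rg_fixed) upper["rg"] <- 0.5

  best <- NULL
  for (i in seq_len(max(1, n_starts))) {
    start <- base[pnames]
    if (i > 1)
      start <- start * ifelse(grepl("^mu", pnames) | pnames == "rg", 1,
                              0.5 + 0.4 * i / n_starts)
    fit <- try(stats::optim(start, negll, method = "L-BFGS-B", lower = lower,
                            upper = upper, control = list(maxit = 600)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("sex-limitation fit failed", call. = FALSE)

  p <- unpack(best$par)
  v_m <- p$a_m^2 + p$c_m^2 + p$e_m^2
  v_f <- p$a_f^2 + p$c_f^2 + p$e_f^2
  structure(list(
    model = model, constraints = constraints, rg_fixed = rg_fixed,
    coefficients = stats::setNames(best$par, pnames),
    params = p,
    components = list(
      M = c(a2 = p$a_m^2 / v_m, c2 = p$c_m^2 / v_m, e2 = p$e_m^2 / v_m),
      F = c(a2 = p$a_f^2 / v_f, c2 = p$c_f^2 / v_f, e2 = p$e_f^2 / v_f)),
    total_variance = c(M = v_m, F = v_f),
    rg = p$rg,
    loglik = -best$value, n_params = np, n_groups = n_g,
    convergence = best$convergence, data = pairs
  ), class = "sexlim_model")
}

#' @export
print.sexlim_model <- function(x, digits = 3, ...) {
  cat(sprintf("Sex-limitation %s model: logLik = %.2f (%d parameters)\n",
              x$model, x$loglik, x$n_params))
  cat("  males:  "); print(round(x$components$M, digits))
  cat("  females:"); print(round(x$components$F, digits))
  cat(sprintf("  rg (opposite-sex genetic correlation): %.3f%s\n", x$rg,
              if (x$rg_fixed) " [fixed]" else ""))
  invisible(x)
}

#' @export
logLik.sexlim_model <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Omnibus test for any sex difference in the twin model
#'
#' Likelihood-ratio test of the freely sex-indexed model against the model
#' with every parameter equated across sexes, Bonferroni-corrected over
#' `m_tests` CpGs (significance at adjusted p < 0.01).
#'
#' @param fit_free,fit_equated `sexlim_model` fits on the same data; the
#'   equated fit must be nested in the free fit.
#' @param m_tests Bonferroni multiplier.
#' @return list with `lrt_stat`, `df`, `p`, `p_adj`, `significant`.
#' @export
omnibus_sex_test <- function(fit_free, fit_equated, m_tests = 1L) {
  if (fit_equated$n_params >= fit_free$n_params ||
      !all(fit_equated$n_groups == fit_free$n_groups))
    stop("'fit_equated' must be nested in 'fit_free'", call. = FALSE)
  stat <- max(0, 2 * (fit_free$loglik - fit_equated$loglik))
  df <- fit_free$n_params - fit_equated$n_params
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  p_adj <- min(1, p * m_tests)
  list(lrt_stat = stat, df = df, p = p, p_adj = p_adj,
       significant = p_adj < 0.01)
}

#' Per-parameter sex-difference tests
#'
#' For each named parameter, the freely estimated model is compared against a
#' model with that parameter equated across sexes (`"rg"` instead tests the
#' qualitative difference: rg free vs fixed at 0.5). P-values are Bonferroni
#' corrected over `m_tests`; significance at adjusted p < 0.01.
#'
#' @param fit_free a `sexlim_model` fitted without equality constraints
#'   (rg fixed at 0.5 for the quantitative tests).
#' @param parameters subset of `c("mean", "a", "c", "e", "var", "rg")`.
#' @param m_tests Bonferroni multiplier.
#' @param n_starts passed to refits.
#' @return data.frame with parameter, lrt_stat, df, p, p_adj, significant.
#' @export
parameter_sex_tests <- function(fit_free,
                                parameters = c("mean", "a", "e", "var", "rg"),
                                m_tests = 1L, n_starts = 3) {
  allowed <- c("mean", "a", "c", "e", "var", "rg")
  bad <- setdiff(parameters, allowed)
  if (length(bad)) stop("unknown parameter: ", bad[1], call. = FALSE)
  pairs <- fit_free$data
  rows <- lapply(parameters, function(pm) {
    if (pm == "rg") {
      fit_rg <- fit_sex_limitation(pairs, model = fit_free$model,
                                   constraints = fit_free$constraints,
                                   rg_fixed = FALSE, n_starts = n_starts)
      stat <- max(0, 2 * (fit_rg$loglik - fit_free$loglik))
      df <- 1L
    } else {
      fit_con <- fit_sex_limitation(pairs, model = fit_free$model,
                                    constraints = union(fit_free$constraints, pm),
                                    rg_fixed = fit_free$rg_fixed,
                                    n_starts = n_starts)
      stat <- max(0, 2 * (fit_free$loglik - fit_con$loglik))
      df <- fit_free$n_params - fit_con$n_params
    }
    p <- stats::pchisq(stat, max(df, 1L), lower.tail = FALSE)
    data.frame(parameter = pm, lrt_stat = stat, df = df, p = p,
               p_adj = min(1, p * m_tests), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < 0.01
  out
}
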