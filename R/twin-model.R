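## Univariate twin variance-component models fitted by full-information
## maximum likelihood (FIML).
##
## Trait variance is decomposed into additive genetic (A), shared environment
## (C) or dominance (D), and unique environment (E) using the classical twin
## covariance contrast: cotwin covariance = kA a^2 + kC c^2 + kD d^2 with
## (kA, kC, kD) = (1, 1, 1) for MZ and (0.5, 1, 0.25) for DZ pairs. Path
## coefficients are constrained nonnegative so the standardized components are
## proper fractions. Incomplete pairs contribute univariate likelihood terms.

.twin_models <- list(
  ACE = c("a", "c", "e"), ADE = c("a", "d", "e"), AE = c("a", "e"),
  CE = c("c", "e"), DE = c("d", "e"), E = "e")

#' Simulate twin pairs from target intra-pair correlations
#'
#' Draws complete MZ and DZ pairs from bivariate normal distributions with the
#' given within-pair correlations, a common mean and variance.
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param r_mz,r_dz within-pair correlations.
#' @param mean,sd trait mean and standard deviation.
#' @param seed optional integer seed.
#' @return data.frame with columns y1, y2, zygosity.
#' @export
simulate_twin_pairs <- function(n_mz, n_dz, r_mz, r_dz, mean = 0, sd = 1,
                                seed = NULL) {
  with_seed(seed, {
    draw <- function(n, r) {
      z1 <- stats::rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
      cbind(z1, z2)
    }
    mz <- draw(n_mz, r_mz); dz <- draw(n_dz, r_dz)
    data.frame(y1 = mean + sd * c(mz[, 1], dz[, 1]),
               y2 = mean + sd * c(mz[, 2], dz[, 2]),
               zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
               stringsAsFactors = FALSE)
  })
}

## ---- likelihood machinery -------------------------------------------------

## sufficient statistics per stratum for the no-covariate fast path
.pair_suffstats <- function(y1, y2) {
  ok <- !is.na(y1) & !is.na(y2)
  single <- c(y1[!ok & !is.na(y1)], y2[!ok & !is.na(y2)])
  list(n = sum(ok), s1 = sum(y1[ok]), s2 = sum(y2[ok]),
       q1 = sum(y1[ok]^2), q2 = sum(y2[ok]^2), q12 = sum(y1[ok] * y2[ok]),
       ns = length(single), ss = sum(single), qs = sum(single^2))
}

## bivariate-normal loglik of one stratum from sufficient stats, common mean
.ll_stratum <- function(st, mu, v, cv) {
  det <- v^2 - cv^2
  if (det <= 0 || v <= 0) return(-Inf)
  ll <- 0
  if (st$n > 0) {
    d1q <- st$q1 - 2 * mu * st$s1 + st$n * mu^2
    d2q <- st$q2 - 2 * mu * st$s2 + st$n * mu^2
    d12 <- st$q12 - mu * (st$s1 + st$s2) + st$n * mu^2
    Q <- (v * (d1q + d2q) - 2 * cv * d12) / det
    ll <- ll - st$n * log(2 * pi) - st$n / 2 * log(det) - Q / 2
  }
  if (st$ns > 0) {
    dq <- st$qs - 2 * mu * st$ss + st$ns * mu^2
    ll <- ll - st$ns / 2 * log(2 * pi * v) - dq / (2 * v)
  }
  ll
}

## per-pair bivariate loglik (covariate path); m1, m2 means per pair
.ll_pairs <- function(y1, y2, m1, m2, v, cv) {
  det <- v^2 - cv^2
  if (det <= 0 || v <= 0) return(-Inf)
  ok <- !is.na(y1) & !is.na(y2)
  ll <- 0
  if (any(ok)) {
    d1 <- y1[ok] - m1[ok]; d2 <- y2[ok] - m2[ok]
    Q <- (v * (d1^2 + d2^2) - 2 * cv * d1 * d2) / det
    ll <- -sum(ok) * log(2 * pi) - sum(ok) / 2 * log(det) - sum(Q) / 2
  }
  for (side in 1:2) {
    y <- if (side == 1) y1 else y2
    m <- if (side == 1) m1 else m2
    s <- !ok & !is.na(y)
    if (any(s))
      ll <- ll + sum(stats::dnorm(y[s], m[s], sqrt(v), log = TRUE))
  }
  ll
}


#' Fit a univariate twin variance-component model
#'
#' Maximizes the full-information bivariate-normal likelihood over twin pairs
#' for one of the six classical models (ACE, ADE, AE, CE, DE, E). Mean
#' structure is a common intercept plus optional per-twin age and sex
#' regressions. Path coefficients are bounded below by zero; optimization uses
#' multiple perturbed starts around moment-based (Falconer) initial values.
#'
#' @param pairs data.frame with columns `y1`, `y2` (trait values; NA for the
#'   missing member of an incomplete pair) and `zygosity` ("MZ"/"DZ");
#'   optionally `age1`, `age2`, `sex1`, `sex2` for the mean model.
#' @param model one of "ACE", "ADE", "AE", "CE", "DE", "E".
#' @param covariates subset of `c("age", "sex")` to include in the mean model
#'   (silently intersected with the columns available).
#' @param n_starts number of optimization starts (>= 1; 3 or more
#'   recommended).
#' @param seed seed for start-point jitter.
#' @return object of class `twin_model` with standardized components `a2`,
#'   `c2`, `d2`, `e2`, total variance, mean coefficients, log-likelihood and
#'   implied twin correlations. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `confint` (profile-likelihood CIs), `vcov`, `simulate`.
#' @export
fit_twin_model <- function(pairs, model = c("ACE", "ADE", "AE", "CE", "DE", "E"),
                           covariates = c("age", "sex"), n_starts = 3,
                           seed = 11L) {
  model <- match.arg(model)
  paths <- .twin_models[[model]]
  stopifnot(all(c("y1", "y2", "zygosity") %in% names(pairs)),
            all(pairs$zygosity %in% c("MZ", "DZ")))
  pairs <- pairs[!(is.na(pairs$y1) & is.na(pairs$y2)), , drop = FALSE]
  if (nrow(pairs) < 3) stop("need at least 3 informative pairs", call. = FALSE)

  covariates <- intersect(covariates, c("age", "sex"))
  use_age <- "age" %in% covariates && all(c("age1", "age2") %in% names(pairs))
  use_sex <- "sex" %in% covariates && all(c("sex1", "sex2") %in% names(pairs)) &&
    length(unique(c(pairs$sex1, pairs$sex2))) > 1
  has_cov <- use_age || use_sex

  yall <- c(pairs$y1, pairs$y2)
  s_tot <- stats::sd(yall, na.rm = TRUE)
  m_tot <- mean(yall, na.rm = TRUE)
  if (!is.finite(s_tot) || s_tot == 0)
    stop("trait is constant; variance components undefined", call. = FALSE)

  mz <- pairs$zygosity == "MZ"
  if (!has_cov) {
    st_mz <- .pair_suffstats(pairs$y1[mz], pairs$y2[mz])
    st_dz <- .pair_suffstats(pairs$y1[!mz], pairs$y2[!mz])
  } else {
    age1c <- if (use_age) pairs$age1 - mean(c(pairs$age1, pairs$age2), na.rm = TRUE) else 0
    age2c <- if (use_age) pairs$age2 - mean(c(pairs$age1, pairs$age2), na.rm = TRUE) else 0
    f1 <- if (use_sex) as.numeric(pairs$sex1 == "F") else 0
    f2 <- if (use_sex) as.numeric(pairs$sex2 == "F") else 0
  }

  n_mean <- 1L + use_age + use_sex
  np <- n_mean + length(paths)
  mean_names <- c("mu", if (use_age) "b_age", if (use_sex) "b_sex")

  negll <- function(theta) {
    mu <- theta[1]
    pth <- theta[(n_mean + 1):np]
    comp <- stats::setNames(rep(0, 4), c("a", "c", "d", "e"))
    comp[paths] <- pth^2
    v <- sum(comp)
    if (v <= 0) return(1e10)
    ll <- if (!has_cov) {
      .ll_stratum(st_mz, mu, v, comp[["a"]] + comp[["c"]] + comp[["d"]]) +
        .ll_stratum(st_dz, mu, v,
                    0.5 * comp[["a"]] + comp[["c"]] + 0.25 * comp[["d"]])
    } else {
      b_age <- if (use_age) theta[2] else 0
      b_sex <- if (use_sex) theta[n_mean] else 0
      m1 <- mu + b_age * age1c + b_sex * f1
      m2 <- mu + b_age * age2c + b_sex * f2
      cv_mz <- comp[["a"]] + comp[["c"]] + comp[["d"]]
      cv_dz <- 0.5 * comp[["a"]] + comp[["c"]] + 0.25 * comp[["d"]]
      .ll_pairs(pairs$y1[mz], pairs$y2[mz], m1[mz], m2[mz], v, cv_mz) +
        .ll_pairs(pairs$y1[!mz], pairs$y2[!mz], m1[!mz], m2[!mz], v, cv_dz)
    }
    if (!is.finite(ll)) 1e10 else -ll
  }

  ## moment-based starting shares
  r_obs <- function(sel) {
    ok <- sel & !is.na(pairs$y1) & !is.na(pairs$y2)
    if (sum(ok) < 3) return(0.3)
    suppressWarnings(stats::cor(c(pairs$y1[ok], pairs$y2[ok]),
                                c(pairs$y2[ok], pairs$y1[ok])))
  }
  rmz <- max(min(r_obs(mz), 0.98), -0.5)
  rdz <- max(min(r_obs(!mz), 0.98), -0.5)
  clamp01 <- function(x) max(min(x, 0.9), 0.02)
  share0 <- switch(model,
    ACE = c(a = clamp01(2 * (rmz - rdz)), c = clamp01(2 * rdz - rmz),
            e = clamp01(1 - rmz)),
    ADE = c(a = clamp01(4 * rdz - rmz), d = clamp01(2 * rmz - 4 * rdz),
            e = clamp01(1 - rmz)),
    AE = c(a = clamp01(rmz), e = clamp01(1 - rmz)),
    CE = c(c = clamp01((rmz + rdz) / 2), e = clamp01(1 - (rmz + rdz) / 2)),
    DE = c(d = clamp01(rmz), e = clamp01(1 - rmz)),
    E = c(e = 1))
  share0 <- share0 / sum(share0)
  start0 <- c(m_tot, rep(0, n_mean - 1L), s_tot * sqrt(share0[paths]))
  lower <- c(rep(-Inf, n_mean), rep(0, length(paths)))
  lower[np] <- 1e-6 * s_tot  # e > 0 keeps the covariance matrix positive definite

  best <- NULL
  starts <- with_seed(derive_seed(seed, "starts"), {
    lapply(seq_len(max(1, n_starts)), function(i) {
      if (i == 1) start0 else {
        s <- start0
        s[(n_mean + 1):np] <- s[(n_mean + 1):np] *
          stats::runif(length(paths), 0.4, 1.6) + 0.05 * s_tot
        s
      }
    })
  })
  for (s in starts) {
    fit <- try(stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("twin model optimization failed for all starts", call. = FALSE)

  theta <- best$par
  comp <- stats::setNames(rep(0, 4), c("a", "c", "d", "e"))
  comp[paths] <- theta[(n_mean + 1):np]^2
  v <- sum(comp)
  shares <- comp / v
  coefs <- stats::setNames(theta, c(mean_names, paths))

  structure(list(
    model = model,
    coefficients = coefs,
    components = stats::setNames(as.numeric(shares), c("a2", "c2", "d2", "e2")),
    total_variance = v,
    loglik = -best$value,
    n_params = np,
    n_pairs = c(MZ = sum(mz), DZ = sum(!mz)),
    n_complete = sum(!is.na(pairs$y1) & !is.na(pairs$y2)),
    implied = c(r_mz = (comp[["a"]] + comp[["c"]] + comp[["d"]]) / v,
                r_dz = (0.5 * comp[["a"]] + comp[["c"]] + 0.25 * comp[["d"]]) / v),
    convergence = best$convergence,
    mean_names = mean_names,
    paths = paths,
    data = pairs,
    covariates = covariates,
    negll = negll,
    lower = lower,
    n_mean = n_mean
  ), class = "twin_model")
}

#' @export
print.twin_model <- function(x, digits = 3, ...) {
  cat(sprintf("Twin %s model (FIML), logLik = %.2f, %d MZ / %d DZ pairs\n",
              x$model, x$loglik, x$n_pairs[["MZ"]], x$n_pairs[["DZ"]]))
  print(round(x$components, digits))
  invisible(x)
}

#' @export
coef.twin_model <- function(object, ...) object$coefficients

#' @export
logLik.twin_model <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
summary.twin_model <- function(object, ...) {
  structure(list(fit = object), class = "summary.twin_model")
}

#' @export
print.summary.twin_model <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("Total variance: %.5g  AIC: %.2f\n", f$total_variance,
              2 * f$n_params - 2 * f$loglik))
  cat(sprintf("Implied twin correlations: r_MZ = %.3f, r_DZ = %.3f\n",
              f$implied[["r_mz"]], f$implied[["r_dz"]]))
  invisible(x)
}

#' @export
vcov.twin_model <- function(object, ...) {
  theta <- unname(object$coefficients)
  H <- stats::optimHess(theta, object$negll)
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error")) V <- matrix(NA_real_, length(theta), length(theta))
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' Profile-likelihood confidence intervals for standardized components
#'
#' Each free path coefficient is profiled (other parameters re-optimized) and
#' the 95\% bound located where the deviance crosses the chi-square critical
#' value; bounds are transformed to standardized variance shares at the
#' profile solution. A bound that cannot be bracketed inside the parameter
#' space (the deviance never reaches the critical value before the path hits
#' zero or the search ceiling) is reported as NA, as happens for components
#' estimated at or near the boundary.
#'
#' @param object a `twin_model`.
#' @param parm components to profile (default: all free paths).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with rows a2/c2/d2/e2 (free ones) and columns lower, upper.
#' @export
confint.twin_model <- function(object, parm = object$paths, level = 0.95, ...) {
  crit <- stats::qchisq(level, 1)
  np <- object$n_params
  n_mean <- object$n_mean
  theta_hat <- unname(object$coefficients)
  llmax <- object$loglik
  s_ceiling <- sqrt(object$total_variance) * 3

  prof_dev <- function(path_idx, value) {
    fixed <- n_mean + path_idx
    free <- setdiff(seq_len(np), fixed)
    nll <- function(th_free) {
      th <- numeric(np); th[fixed] <- value; th[free] <- th_free
      object$negll(th)
    }
    fit <- try(stats::optim(theta_hat[free], nll, method = "L-BFGS-B",
                            lower = object$lower[free],
                            control = list(maxit = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    2 * (llmax + fit$value)
  }

  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(paste0(parm, "2"), c("lower", "upper")))
  for (j in seq_along(parm)) {
    pi_ <- match(parm[j], object$paths)
    mle <- theta_hat[n_mean + pi_]
    share_at <- function(val) {
      ## standardized share implied by holding this path at `val`, with the
      ## remaining variance at its profile optimum
      fixed <- n_mean + pi_
      free <- setdiff(seq_len(np), fixed)
      nll <- function(th_free) {
        th <- numeric(np); th[fixed] <- val; th[free] <- th_free
        object$negll(th)
      }
      fit <- stats::optim(theta_hat[free], nll, method = "L-BFGS-B",
                          lower = object$lower[free], control = list(maxit = 300))
      th <- numeric(np); th[fixed] <- val; th[free] <- fit$par
      pth <- th[(n_mean + 1):np]^2
      val^2 / sum(pth)
    }
    bound <- function(lo, hi) {
      dlo <- prof_dev(pi_, lo); dhi <- prof_dev(pi_, hi)
      if (is.na(dlo) || is.na(dhi) || (dlo - crit) * (dhi - crit) > 0)
        return(NA_real_)
      for (k in 1:40) {
        mid <- (lo + hi) / 2
        dm <- prof_dev(pi_, mid)
        if (is.na(dm)) return(NA_real_)
        if ((dm - crit) * (dlo - crit) <= 0) { hi <- mid; dhi <- dm }
        else { lo <- mid; dlo <- dm }
        if (abs(hi - lo) < 1e-4 * max(s_ceiling, 1e-8)) break
      }
      (lo + hi) / 2
    }
    lo <- bound(max(object$lower[n_mean + pi_], 1e-9), mle)
    hi <- bound(mle, s_ceiling)
    out[j, 1] <- if (is.na(lo)) NA_real_ else share_at(lo)
    out[j, 2] <- if (is.na(hi)) NA_real_ else share_at(hi)
  }
  out
}

#' Simulate twin data from a fitted twin model
#'
#' Draws new pair observations with the fitted variance components and mean
#' structure, over the same zygosity (and covariate) layout as the original
#' data.
#'
#' @param object a `twin_model`.
#' @param nsim number of replicate data sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return a data.frame (nsim = 1) or list of data.frames.
#' @export
simulate.twin_model <- function(object, nsim = 1, seed = NULL, ...) {
  comp <- object$components * object$total_variance
  v <- object$total_variance
  pairs <- object$data
  mz <- pairs$zygosity == "MZ"
  cv <- ifelse(mz, comp[["a2"]] + comp[["c2"]] + comp[["d2"]],
               0.5 * comp[["a2"]] + comp[["c2"]] + 0.25 * comp[["d2"]])
  r <- cv / v
  mu <- object$coefficients[["mu"]]
  one <- function() {
    z1 <- stats::rnorm(nrow(pairs))
    z2 <- r * z1 + sqrt(pmax(1 - r^2, 0)) * stats::rnorm(nrow(pairs))
    out <- pairs
    out$y1 <- mu + sqrt(v) * z1
    out$y2 <- mu + sqrt(v) * z2
    out
  }
  with_seed(seed, {
    if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
  })
}

## ---- twin correlations, model selection, candidate checks -----------------

#' Intraclass twin correlations by zygosity
#'
#' Double-entry intraclass correlation on covariate-residualized values: each
#' complete pair contributes both orderings, removing any dependence on twin
#' labelling.
#'
#' @param pairs data.frame as in [fit_twin_model()].
#' @param covariates subset of `c("age", "sex")` to residualize on.
#' @return named vector `c(r_mz, r_dz)`; NA for a zygosity group with fewer
#'   than 2 complete pairs.
#' @export
twin_correlations <- function(pairs, covariates = c("age", "sex")) {
  use_age <- "age" %in% covariates && all(c("age1", "age2") %in% names(pairs))
  use_sex <- "sex" %in% covariates && all(c("sex1", "sex2") %in% names(pairs))
  y <- c(pairs$y1, pairs$y2)
  if (use_age || use_sex) {
    Xl <- cbind(1,
                if (use_age) c(pairs$age1, pairs$age2),
                if (use_sex) as.numeric(c(pairs$sex1, pairs$sex2) == "F"))
    ok <- stats::complete.cases(Xl) & !is.na(y)
    res <- rep(NA_real_, length(y))
    fit <- stats::lm.fit(Xl[ok, , drop = FALSE], y[ok])
    res[ok] <- fit$residuals
  } else res <- y
  n <- nrow(pairs)
  r1 <- res[seq_len(n)]; r2 <- res[n + seq_len(n)]
  icc <- function(sel) {
    ok <- sel & !is.na(r1) & !is.na(r2)
    if (sum(ok) < 2) return(NA_real_)
    stats::cor(c(r1[ok], r2[ok]), c(r2[ok], r1[ok]))
  }
  c(r_mz = icc(pairs$zygosity == "MZ"), r_dz = icc(pairs$zygosity == "DZ"))
}

#' Select the best-fitting twin model
#'
#' Fits all six candidate models. Within each family (ACE with its nested AE,
#' CE, E; ADE with AE, DE, E), reduced models are accepted when the
#' likelihood-ratio test against the full model is non-significant; the most
#' parsimonious accepted model wins within a family, the two family winners
#' are arbitrated by AIC, and remaining ties go to fewer parameters and then
#' to the ACE family.
#'
#' @param pairs data.frame as in [fit_twin_model()].
#' @param alpha significance level for the nested likelihood-ratio tests.
#' @param ... passed to [fit_twin_model()].
#' @return list of class `twin_model_selection`: `best` (a `twin_model`),
#'   `best_model` (label) and `table` (per-model loglik, parameters, AIC and
#'   LRT p vs the family full model).
#' @export
select_best_model <- function(pairs, alpha = 0.05, ...) {
  labels <- names(.twin_models)
  fits <- lapply(labels, function(m)
    try(fit_twin_model(pairs, model = m, ...), silent = TRUE))
  names(fits) <- labels
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (sum(ok) < 2) stop("fewer than 2 twin models could be fitted", call. = FALSE)

  ll <- vapply(fits[ok], `[[`, 0, "loglik")
  npar <- vapply(fits[ok], `[[`, 0, "n_params")
  aic <- 2 * npar - 2 * ll
  lrt_p <- rep(NA_real_, length(ll)); names(lrt_p) <- names(ll)
  fam <- list(ACE = c("AE", "CE", "E"), ADE = c("AE", "DE", "E"))
  for (full in names(fam)) {
    if (!full %in% names(ll)) next
    for (sub in intersect(fam[[full]], names(ll))) {
      stat <- max(0, 2 * (ll[full] - ll[sub]))
      df <- npar[full] - npar[sub]
      p <- stats::pchisq(stat, df, lower.tail = FALSE)
      ## a submodel nested in both full models must survive both tests
      lrt_p[sub] <- if (is.na(lrt_p[sub])) p else min(lrt_p[sub], p)
    }
  }
  winner_in <- function(full) {
    cand <- intersect(c(full, fam[[full]]), names(ll))
    acc <- cand[cand == full | (!is.na(lrt_p[cand]) & lrt_p[cand] >= alpha)]
    if (!length(acc)) acc <- full
    acc[order(npar[acc], -ll[acc])][1]
  }
  w <- c(ACE = if ("ACE" %in% names(ll)) winner_in("ACE") else NA,
         ADE = if ("ADE" %in% names(ll)) winner_in("ADE") else NA)
  w <- w[!is.na(w)]
  best <- w[order(aic[w], npar[w], match(names(w), c("ACE", "ADE")))][1]

  structure(list(
    best = fits[[best]], best_model = unname(best),
    fits = fits[ok],
    table = data.frame(model = names(ll), loglik = unname(ll),
                       n_params = unname(npar), AIC = unname(aic),
                       lrt_p = unname(lrt_p), stringsAsFactors = FALSE)
  ), class = "twin_model_selection")
}

#' @export
print.twin_model_selection <- function(x, ...) {
  cat("Best-fitting twin model:", x$best_model, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

## saturated bivariate-normal fit per zygosity with optional equality
## constraints, used by the assumption checks
.fit_saturated <- function(pairs, equal_order_mean = FALSE,
                           equal_order_var = FALSE,
                           equal_zyg_mean = FALSE, equal_zyg_var = FALSE) {
  mz <- pairs$zygosity == "MZ"
  st <- list(MZ = pairs[mz, ], DZ = pairs[!mz, ])
  ## parameters per zygosity: mu1, mu2, log s1, log s2, atanh r
  par0 <- unlist(lapply(st, function(d) {
    ok <- !is.na(d$y1) & !is.na(d$y2)
    c(mean(d$y1, na.rm = TRUE), mean(d$y2, na.rm = TRUE),
      log(stats::sd(d$y1, na.rm = TRUE)), log(stats::sd(d$y2, na.rm = TRUE)),
      atanh(max(min(suppressWarnings(
        stats::cor(d$y1[ok], d$y2[ok])), 0.95), -0.95)))
  }))
  expand <- function(p) {
    q <- par0; q[] <- p
    if (equal_zyg_mean) { q[6] <- q[1]; q[7] <- q[2] }
    if (equal_zyg_var) { q[8] <- q[3]; q[9] <- q[4] }
    if (equal_order_mean) { q[2] <- q[1]; q[7] <- q[6] }
    if (equal_order_var) { q[4] <- q[3]; q[9] <- q[8] }
    q
  }
  nll <- function(p) {
    q <- expand(p)
    ll <- 0
    for (g in 1:2) {
      d <- st[[g]]
      if (!nrow(d)) next
      i <- (g - 1) * 5
      s1 <- exp(q[i + 3]); s2 <- exp(q[i + 4]); r <- tanh(q[i + 5])
      ok <- !is.na(d$y1) & !is.na(d$y2)
      if (any(ok)) {
        z1 <- (d$y1[ok] - q[i + 1]) / s1; z2 <- (d$y2[ok] - q[i + 2]) / s2
        Q <- (z1^2 - 2 * r * z1 * z2 + z2^2) / (1 - r^2)
        ll <- ll - sum(ok) * (log(2 * pi) + log(s1) + log(s2) +
                                0.5 * log(1 - r^2)) - sum(Q) / 2
      }
      s <- !ok & !is.na(d$y1)
      if (any(s)) ll <- ll + sum(stats::dnorm(d$y1[s], q[i + 1], s1, log = TRUE))
      s <- !ok & !is.na(d$y2)
      if (any(s)) ll <- ll + sum(stats::dnorm(d$y2[s], q[i + 2], s2, log = TRUE))
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
  n_con <- 2 * (equal_order_mean + equal_order_var + equal_zyg_mean + equal_zyg_var)
  fit <- stats::optim(par0, nll, method = "BFGS", control = list(maxit = 500))
  list(loglik = -fit$value, n_params = 10L - n_con)
}

#' Check a CpG's eligibility for twin modelling
#'
#' A candidate CpG enters twin modelling only if (i) the sample SD of its
#' methylation values exceeds `sd_threshold` and (ii) the classical twin
#' assumption tests pass: likelihood-ratio tests against a saturated
#' bivariate-normal pair model detect no difference (at `alpha`) in means or
#' variances across twin order or across zygosity.
#'
#' @param pairs data.frame as in [fit_twin_model()].
#' @param sd_threshold minimum methylation SD.
#' @param alpha significance level of the assumption tests.
#' @return list with `eligible`, `reasons` (character), `sd` and the four
#'   assumption-test p-values.
#' @export
check_candidate <- function(pairs, sd_threshold = 0.05, alpha = 0.01) {
  yall <- c(pairs$y1, pairs$y2)
  sdv <- stats::sd(yall, na.rm = TRUE)
  reasons <- character()
  if (!is.finite(sdv) || sdv <= sd_threshold)
    reasons <- c(reasons, sprintf("methylation SD %.4f <= %.2f", sdv, sd_threshold))

  full <- .fit_saturated(pairs)
  tests <- c(order_mean = "equal_order_mean", order_var = "equal_order_var",
             zygosity_mean = "equal_zyg_mean", zygosity_var = "equal_zyg_var")
  pvals <- vapply(tests, function(con) {
    args <- list(pairs); args[[con]] <- TRUE
    red <- do.call(.fit_saturated, args)
    stat <- max(0, 2 * (full$loglik - red$loglik))
    stats::pchisq(stat, full$n_params - red$n_params, lower.tail = FALSE)
  }, 0)
  for (nm in names(pvals)[pvals < alpha])
    reasons <- c(reasons, sprintf("assumption violated: %s differs (p = %.2g)",
                                  nm, pvals[nm]))
  list(eligible = length(reasons) == 0, reasons = reasons, sd = sdv,
       assumption_p = pvals)
}

#' Reference panel of twin correlations for puberty-associated CpGs
#'
#' MZ and DZ intraclass correlations reported for the 14 blood-methylation
#' CpG sites associated with pubertal development or pubertal age that met
#' the twin-modelling assumptions, together with the best-fitting model
#' family for each. These serve as generating conditions for
#' simulation-based validation of the variance-component fitter: simulating
#' pairs at a row's correlations and refitting should recover the
#' corresponding standardized components.
#'
#' @return data.frame with cpg_id, r_mz, r_dz, best_model.
#' @export
twin_correlation_panel <- function() {
  data.frame(
    cpg_id = c("cg02614024", "cg03115019", "cg03551401", "cg05038881",
               "cg06096446", "cg08883485", "cg09179916", "cg15030014",
               "cg16198723", "cg17382841", "cg18223453", "cg22325292",
               "cg24786174", "cg25614726"),
    r_mz = c(0.69, 0.96, 0.55, 0.83, 0.89, 0.94, 0.61, 0.89, 0.79, 0.61,
             0.81, 0.98, 0.97, 0.77),
    r_dz = c(0.29, 0.50, 0.33, 0.44, 0.48, 0.52, 0.18, 0.78, 0.36, 0.28,
             0.48, 0.53, 0.55, 0.42),
    best_model = c("AE", "AE", "AE", "AE", "AE", "AE", "AE", "ACE", "AE",
                   "AE", "AE", "AE", "AE", "AE"),
    stringsAsFactors = FALSE)
}
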