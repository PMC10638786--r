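## Family-aware per-CpG association engine.
##
## Twin relatedness is handled as in the consensus-correlation approach used
## for clustered microarray designs: a single within-family residual
## correlation is pooled across CpGs, then each CpG is fitted by generalized
## least squares with that correlation inside complete pairs. Residual
## variances are moderated by empirical Bayes before testing.

#' Build an EWAS design
#'
#' @param exposure named numeric vector (names = sample ids); the per-CpG
#'   regressor of interest (e.g. a PDS score or pubertal age).
#' @param covariates numeric matrix from [prepare_covariates()], or NULL.
#' @param family family id per sample (same order as `exposure`).
#' @return list of class `ewas_design` with the full-rank model matrix `X`
#'   (intercept + exposure + covariates), the exposure column index and the
#'   family blocking vector. Samples with missing exposure are dropped.
#' @export
ewas_design <- function(exposure, covariates = NULL, family) {
  stopifnot(length(exposure) == length(family))
  keep <- !is.na(exposure)
  if (!is.null(covariates)) {
    covariates <- covariates[names(exposure), , drop = FALSE]
    keep <- keep & stats::complete.cases(covariates)
  }
  X <- cbind(`(Intercept)` = 1, exposure = exposure[keep])
  if (!is.null(covariates)) X <- cbind(X, covariates[keep, , drop = FALSE])
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  structure(list(X = X, exposure_col = 2L, family = family[keep],
                 samples = names(exposure)[keep]),
            class = "ewas_design")
}

## index complete pairs within a family vector: returns list(i1, i2)
.pair_rows <- function(family) {
  tab <- table(family)
  fams <- names(tab)[tab == 2L]
  i1 <- match(fams, family)
  idx <- seq_along(family)
  i2 <- vapply(fams, function(f) idx[family == f][2L], 0L)
  list(i1 = i1, i2 = unname(i2))
}

## whiten rows of a (samples x k) matrix so paired residual correlation rho
## becomes 0: row2 <- (row2 - rho * row1) / sqrt(1 - rho^2)
.whiten <- function(M, pr, rho) {
  if (abs(rho) < .Machine$double.eps || length(pr$i1) == 0) return(M)
  s <- sqrt(1 - rho^2)
  M[pr$i2, ] <- (M[pr$i2, , drop = FALSE] - rho * M[pr$i1, , drop = FALSE]) / s
  M
}

#' Pool the within-family residual correlation across CpGs
#'
#' For each CpG, ordinary least-squares residuals are computed and the
#' within-pair residual correlation estimated over complete families; the
#' per-CpG correlations are Fisher z-transformed, pooled by a 10\% trimmed
#' mean and transformed back. Singleton families carry no information about
#' the within-pair correlation and are ignored.
#'
#' @param Y CpG-by-sample matrix (columns ordered as `design$samples`).
#' @param design an [ewas_design()].
#' @param trim trimming fraction for the pooled mean.
#' @return pooled correlation in (-1, 1).
#' @export
estimate_consensus_correlation <- function(Y, design, trim = 0.1) {
  Y <- Y[, design$samples, drop = FALSE]
  pr <- .pair_rows(design$family)
  if (length(pr$i1) < 2) stop("need >= 2 complete families", call. = FALSE)
  X <- design$X
  H <- X %*% solve(crossprod(X), t(X))
  E <- Y - Y %*% t(H)
  e1 <- E[, pr$i1, drop = FALSE]; e2 <- E[, pr$i2, drop = FALSE]
  num <- rowSums(e1 * e2)
  den <- sqrt(rowSums(e1^2) * rowSums(e2^2))
  r <- pmax(pmin(num / pmax(den, .Machine$double.eps), 0.999), -0.999)
  tanh(mean(atanh(r), trim = trim))
}

#' Fit one CpG by family-blocked generalized least squares
#'
#' GLS with residual correlation `rho` inside complete twin pairs and zero
#' elsewhere; with `rho = 0` (or no complete pairs) this is exactly OLS.
#'
#' @param y methylation vector (ordered as `design$samples`).
#' @param design an [ewas_design()].
#' @param rho within-pair residual correlation in (-1, 1).
#' @return one-row data.frame: beta_hat, se, t, df_residual, n, p_count,
#'   p_value, sigma2, stdev_unscaled.
#' @export
fit_cpg_gls <- function(y, design, rho = 0) {
  run_ewas(matrix(y, 1, dimnames = list("cpg", design$samples)), design, rho)
}

#' Run the per-CpG GLS across a methylation matrix
#'
#' @param Y CpG-by-sample matrix.
#' @param design an [ewas_design()].
#' @param rho within-pair residual correlation in (-1, 1); typically from
#'   [estimate_consensus_correlation()].
#' @return data.frame with one row per CpG: cpg_id, beta_hat (beta-value scale
#'   per unit exposure), se, t, df_residual, n, p_count, p_value, plus sigma2
#'   and stdev_unscaled consumed by [moderate_statistics()].
#' @export
run_ewas <- function(Y, design, rho = 0) {
  if (!is.numeric(rho) || length(rho) != 1 || abs(rho) >= 1)
    stop("'rho' must be a single value with |rho| < 1", call. = FALSE)
  Y <- Y[, design$samples, drop = FALSE]
  pr <- .pair_rows(design$family)
  Xw <- .whiten(design$X, pr, rho)
  Yw <- t(.whiten(t(Y), pr, rho))
  XtXinv <- solve(crossprod(Xw))
  B <- Yw %*% Xw %*% XtXinv
  RSS <- rowSums((Yw - B %*% t(Xw))^2)
  n <- ncol(Y); p <- ncol(Xw); df <- n - p
  if (df <= 0) stop("residual degrees of freedom must be positive", call. = FALSE)
  s2 <- RSS / df
  ve <- XtXinv[design$exposure_col, design$exposure_col]
  b <- B[, design$exposure_col]
  se <- sqrt(s2 * ve)
  tt <- b / se
  data.frame(cpg_id = rownames(Y) %||% paste0("cpg", seq_len(nrow(Y))),
             beta_hat = unname(b), se = unname(se), t = unname(tt),
             df_residual = df, n = n, p_count = p,
             p_value = 2 * stats::pt(-abs(tt), df),
             sigma2 = unname(s2), stdev_unscaled = sqrt(ve),
             stringsAsFactors = FALSE, row.names = NULL)
}

## inverse of trigamma by Newton iteration on 1/x scale (monotone, stable)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderate per-CpG variances by empirical Bayes
#'
#' Residual variances are shrunk toward a pooled prior assuming a scaled
#' inverse-chi-square distribution: the prior degrees of freedom d0 and scale
#' s0^2 are estimated by moment-matching the mean and variance of log s^2
#' (digamma/trigamma method), and each CpG's variance becomes
#' (d0 s0^2 + d s^2) / (d0 + d). The moderated t statistic is tested on
#' d0 + d degrees of freedom. When the observed log-variances are no more
#' dispersed than chi-square sampling noise allows, d0 is infinite and all
#' variances collapse to s0^2.
#'
#' @param results data.frame from [run_ewas()] (>= 10 CpGs, common df).
#' @param d0_override optional fixed prior df (0 disables shrinkage; Inf
#'   forces complete pooling).
#' @return `results` with added columns s2_post, t_mod, df_mod, p_mod, and
#'   attributes `d0` and `s0_2`.
#' @export
moderate_statistics <- function(results, d0_override = NULL) {
  s2 <- results$sigma2
  d <- results$df_residual[1]
  if (!all(results$df_residual == d))
    stop("moderation assumes a common residual df across CpGs", call. = FALSE)
  if (length(unique(signif(s2, 12))) < 2 && is.null(d0_override))
    stop("fewer than 2 distinct variances: prior unidentifiable", call. = FALSE)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- mean(e)
  vv <- sum((e - ev)^2) / (length(e) - 1) - trigamma(d / 2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
  } else if (vv > 0) {
    d0 <- 2 * .trigamma_inverse(vv)
  } else {
    d0 <- Inf
  }
  s0_2 <- if (is.infinite(d0)) exp(ev) else if (d0 == 0) NA_real_ else
    exp(ev + digamma(d0 / 2) - log(d0 / 2))  # prior scale undefined at d0 = 0
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    if (d0 == 0) s2 else (d0 * s0_2 + d * s2) / (d0 + d)
  df_mod <- d0 + d
  t_mod <- results$beta_hat / (sqrt(s2_post) * results$stdev_unscaled)
  p_mod <- if (is.infinite(df_mod)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df_mod)
  results$s2_post <- s2_post
  results$t_mod <- t_mod
  results$df_mod <- df_mod
  results$p_mod <- p_mod
  attr(results, "d0") <- d0
  attr(results, "s0_2") <- s0_2
  results
}

#' Choose a covariate model by per-CpG AIC vote
#'
#' Each candidate design is fitted to every CpG by OLS; the design preferred
#' (lowest AIC) by the most CpGs wins, ties going to the design with fewer
#' columns, then to the earlier candidate.
#'
#' @param Y CpG-by-sample matrix.
#' @param designs list of [ewas_design()] objects over the same samples.
#' @return index of the chosen design, with a `"votes"` attribute.
#' @export
select_covariate_model <- function(Y, designs) {
  if (length(designs) < 1) stop("need at least one candidate", call. = FALSE)
  if (length(designs) == 1) return(structure(1L, votes = nrow(Y)))
  samp <- designs[[1]]$samples
  for (d in designs) if (!identical(d$samples, samp))
    stop("candidate designs cover different sample sets", call. = FALSE)
  n <- length(samp)
  aic <- sapply(designs, function(d) {
    X <- d$X
    H <- X %*% solve(crossprod(X), t(X))
    E <- Y[, samp, drop = FALSE] - Y[, samp, drop = FALSE] %*% t(H)
    n * log(rowSums(E^2) / n) + 2 * (ncol(X) + 1)
  })
  best <- apply(aic, 1, function(a) {
    w <- which(a <= min(a) + 1e-12)
    w[order(vapply(designs[w], function(d) ncol(d$X), 0), w)][1]
  })
  votes <- tabulate(best, length(designs))
  top <- which(votes == max(votes))
  top <- top[order(vapply(designs[top], function(d) ncol(d$X), 0), top)][1]
  structure(top, votes = votes)
}

#' Estimate test-statistic bias and inflation
#'
#' Robust location/scale surrogate for the usual EWAS quality-control check:
#' bias is the median of the z-scores and inflation their median absolute
#' deviation scaled to the normal (MAD x 1.4826). Under a well-calibrated
#' null these are 0 and 1.
#'
#' @param z vector of z-scores (>= 10; >= 1000 recommended).
#' @return list with `bias` and `inflation`.
#' @export
estimate_inflation_bias <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) < 10) stop("need at least 10 z-scores", call. = FALSE)
  list(bias = stats::median(z), inflation = stats::mad(z))
}
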