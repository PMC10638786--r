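## Dual-platform meta-analysis of partial-correlation effect sizes.

#' Convert a regression t statistic to a partial correlation effect size
#'
#' r = t / sqrt(t^2 + df) with sampling variance (1 - r^2)^2 / df, where df is
#' the residual degrees of freedom of the per-CpG regression (sample size
#' minus the number of mean-model coefficients, intercept included).
#'
#' @param t t statistic(s).
#' @param n sample size(s).
#' @param p_count number of mean-model coefficients (intercept + exposure +
#'   covariates). Whether published analyses count the intercept here is
#'   ambiguous; `count_intercept = FALSE` reproduces the off-by-one variant.
#' @param count_intercept see above.
#' @return list with `r` and `var`.
#' @export
t_to_partial_r <- function(t, n, p_count, count_intercept = TRUE) {
  df <- n - if (count_intercept) p_count else p_count - 1L
  if (any(df < 1)) stop("residual df must be >= 1", call. = FALSE)
  r <- t / sqrt(t^2 + df)
  list(r = r, var = (1 - r^2)^2 / df)
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' @param effects,variances equal-length vectors (variances > 0).
#' @return list with `est`, `se` and two-sided normal `p`.
#' @export
fixed_effect_meta <- function(effects, variances) {
  if (length(effects) != length(variances) || length(effects) < 1)
    stop("'effects' and 'variances' must be equal-length, nonempty", call. = FALSE)
  if (any(variances <= 0)) stop("variances must be positive", call. = FALSE)
  w <- 1 / variances
  est <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  list(est = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

#' Cochran's Q heterogeneity test
#'
#' @param effects,variances study effects and sampling variances (k >= 2).
#' @return list with `Q` and chi-square `q_p` on k - 1 df.
#' @export
cochran_q <- function(effects, variances) {
  if (length(effects) < 2) stop("Q requires at least 2 studies", call. = FALSE)
  w <- 1 / variances
  est <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - est)^2)
  list(Q = Q, q_p = stats::pchisq(Q, length(effects) - 1, lower.tail = FALSE))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' tau^2 = max(0, (Q - (k - 1)) / (sum w - sum w^2 / sum w)); weights are
#' 1 / (v + tau^2). With Q <= k - 1 this reduces to the fixed-effect result.
#'
#' @inheritParams fixed_effect_meta
#' @return list with `est`, `se`, `p` and `tau2`.
#' @export
random_effect_meta <- function(effects, variances) {
  if (length(effects) < 2) stop("need at least 2 studies", call. = FALSE)
  if (any(variances <= 0)) stop("variances must be positive", call. = FALSE)
  w <- 1 / variances
  Q <- cochran_q(effects, variances)$Q
  tau2 <- max(0, (Q - (length(effects) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (variances + tau2)
  est <- sum(wr * effects) / sum(wr)
  se <- sqrt(1 / sum(wr))
  list(est = est, se = se, p = 2 * stats::pnorm(-abs(est / se)), tau2 = tau2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values (monotone step-up).
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Meta-analyse two platform EWAS result sets
#'
#' CpGs present on both panels are converted to partial-correlation effect
#' sizes and combined by fixed-effect meta-analysis. Heterogeneity (Cochran's
#' Q) p-values are Benjamini-Hochberg corrected across all CpGs; CpGs with
#' corrected Q p < `q_bh_threshold` are flagged heterogeneous and re-estimated
#' by random-effects meta-analysis. Significance tiers: `strict` at the
#' 450K-recommended genome-wide cut-off, `suggestive` at 1e-5, and an absolute
#' standardized effect-size filter at 0.13.
#'
#' @param results_450K,results_EPIC data.frames from [run_ewas()] (optionally
#'   after [moderate_statistics()]).
#' @param use_moderated use the moderated t (`t_mod`) when present.
#' @param strict,suggestive,q_bh_threshold,effect_threshold thresholds.
#' @param count_intercept passed to [t_to_partial_r()].
#' @return data.frame with one row per shared CpG: r_meta, se_meta, p_value,
#'   Q, q_p, q_p_bh, heterogeneous, method, tier, passes_effect_filter.
#' @export
run_meta_pipeline <- function(results_450K, results_EPIC,
                              use_moderated = FALSE,
                              strict = 2.4e-7, suggestive = 1e-5,
                              q_bh_threshold = 0.01, effect_threshold = 0.13,
                              count_intercept = TRUE) {
  shared <- intersect(results_450K$cpg_id, results_EPIC$cpg_id)
  if (length(shared) == 0)
    stop("no CpGs shared between the two platforms", call. = FALSE)
  a <- results_450K[match(shared, results_450K$cpg_id), ]
  b <- results_EPIC[match(shared, results_EPIC$cpg_id), ]
  tcol <- if (use_moderated && !is.null(a$t_mod)) "t_mod" else "t"
  ra <- t_to_partial_r(a[[tcol]], a$n, a$p_count, count_intercept)
  rb <- t_to_partial_r(b[[tcol]], b$n, b$p_count, count_intercept)

  k <- length(shared)
  out <- data.frame(cpg_id = shared, r_meta = NA_real_, se_meta = NA_real_,
                    p_value = NA_real_, Q = NA_real_, q_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    y <- c(ra$r[i], rb$r[i]); v <- c(ra$var[i], rb$var[i])
    fe <- fixed_effect_meta(y, v)
    qq <- cochran_q(y, v)
    out$r_meta[i] <- fe$est; out$se_meta[i] <- fe$se; out$p_value[i] <- fe$p
    out$Q[i] <- qq$Q; out$q_p[i] <- qq$q_p
  }
  out$q_p_bh <- benjamini_hochberg(out$q_p)
  out$heterogeneous <- out$q_p_bh < q_bh_threshold
  out$method <- ifelse(out$heterogeneous, "random", "fixed")
  for (i in which(out$heterogeneous)) {
    re <- random_effect_meta(c(ra$r[i], rb$r[i]), c(ra$var[i], rb$var[i]))
    out$r_meta[i] <- re$est; out$se_meta[i] <- re$se; out$p_value[i] <- re$p
  }
  out$tier <- ifelse(out$p_value <= strict, "strict",
                     ifelse(out$p_value <= suggestive, "suggestive", "none"))
  out$passes_effect_filter <- abs(out$r_meta) > effect_threshold
  out
}
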