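## Within/between-pair decomposition of the exposure-methylation association.
##
## The individual-level EWAS effect is split into a between-pair effect (pair
## mean of the exposure) and a within-pair effect (each twin's deviation from
## the cotwin). A within-pair effect in MZ pairs cannot be produced by
## genetic or shared-environment confounding, so a consistent within-pair
## signal is the design's marker of an environmentally driven (potentially
## causal) association.

#' Decompose a pair exposure into between- and within-pair predictors
#'
#' The between-pair predictor is the pair mean; the within-pair predictor is
#' each twin's exposure minus the cotwin's (antisymmetric within a pair, so
#' concordant pairs contribute only between-pair information).
#'
#' @param x1,x2 exposure values of twin 1 and twin 2 (complete pairs).
#' @return list with `between` (per pair) and `within` (2-column matrix, one
#'   column per twin).
#' @export
decompose_exposure <- function(x1, x2) {
  ok <- !is.na(x1) & !is.na(x2)
  if (!all(ok)) {
    warning(sprintf("excluding %d incomplete pair(s)", sum(!ok)))
    x1 <- x1[ok]; x2 <- x2[ok]
  }
  list(between = (x1 + x2) / 2,
       within = cbind(twin1 = x1 - x2, twin2 = x2 - x1),
       n_excluded = sum(!ok))
}

#' Fit the within/between-pair mixed model for one CpG
#'
#' Linear mixed model y ~ between + within + covariates + (1 | family),
#' fitted by REML, with Wald normal tests for the between- and within-pair
#' coefficients.
#'
#' @param pairs data.frame of complete pairs with columns `y1`, `y2`
#'   (methylation), `x1`, `x2` (exposure), `family_id`, `zygosity`, and
#'   optional covariates `age1`, `age2`, `sex1`, `sex2`, `platform`.
#' @param zygosity_subset restrict to "MZ" or "DZ" pairs (default: all).
#' @return one-row data.frame: beta_between, se_between, p_between,
#'   beta_within, se_within, p_within, n_pairs, n_discordant. The within
#'   coefficient is NA (with a warning) when all pairs are concordant.
#' @export
fit_within_between <- function(pairs, zygosity_subset = NULL) {
  stopifnot(all(c("y1", "y2", "x1", "x2", "family_id") %in% names(pairs)))
  if (!is.null(zygosity_subset))
    pairs <- pairs[pairs$zygosity %in% zygosity_subset, , drop = FALSE]
  pairs <- pairs[stats::complete.cases(pairs[, c("y1", "y2", "x1", "x2")]), ,
                 drop = FALSE]
  n_pairs <- nrow(pairs)
  if (n_pairs < 10) stop("need at least 10 complete pairs", call. = FALSE)
  de <- decompose_exposure(pairs$x1, pairs$x2)

  long <- data.frame(
    y = c(pairs$y1, pairs$y2),
    between = rep(de$between, 2),
    within = c(de$within[, 1], de$within[, 2]),
    family = rep(pairs$family_id, 2), stringsAsFactors = FALSE)
  if (all(c("age1", "age2") %in% names(pairs)))
    long$age <- c(pairs$age1, pairs$age2)
  if (all(c("sex1", "sex2") %in% names(pairs)))
    long$sex <- as.numeric(c(pairs$sex1, pairs$sex2) == "F")
  if ("platform" %in% names(pairs) && length(unique(pairs$platform)) > 1)
    long$platform <- rep(as.numeric(pairs$platform == pairs$platform[1]), 2)

  if (all(long$within == 0))
    warning("all pairs concordant: within-pair effect not estimable")
  covs <- intersect(c("age", "sex", "platform"), names(long))
  rhs <- paste(c("between", if (any(long$within != 0)) "within", covs,
                 "(1 | family)"), collapse = " + ")
  fit <- lme4::lmer(stats::as.formula(paste("y ~", rhs)), data = long,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  cf <- summary(fit)$coefficients
  grab <- function(nm) {
    if (!nm %in% rownames(cf)) return(c(NA_real_, NA_real_, NA_real_))
    b <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
    c(b, se, 2 * stats::pnorm(-abs(b / se)))
  }
  bb <- grab("between"); bw <- grab("within")
  data.frame(beta_between = bb[1], se_between = bb[2], p_between = bb[3],
             beta_within = bw[1], se_within = bw[2], p_within = bw[3],
             n_pairs = n_pairs,
             n_discordant = sum(de$within[, 1] != 0))
}

#' Classify a CpG's association as environmentally driven
#'
#' A CpG is flagged when the pooled (MZ + DZ) within-pair effect is
#' significant, the MZ-only within-pair effect is at least suggestive
#' (p < `mz_threshold`), and the two within-pair effects agree in sign.
#'
#' @param pooled,mz_only one-row data.frames from [fit_within_between()].
#' @param pooled_threshold significance level for the pooled within-pair test
#'   (0.05 by default; configurable).
#' @param mz_threshold suggestive level for the MZ-only test (0.10).
#' @return list with `classified` and `reason`.
#' @export
classify_discordance <- function(pooled, mz_only, pooled_threshold = 0.05,
                                 mz_threshold = 0.10) {
  if (is.null(mz_only) || is.na(mz_only$p_within))
    return(list(classified = FALSE, reason = "MZ-only fit unavailable"))
  if (is.na(pooled$p_within))
    return(list(classified = FALSE, reason = "pooled within-pair effect not estimable"))
  if (pooled$p_within >= pooled_threshold)
    return(list(classified = FALSE, reason = "pooled within-pair effect not significant"))
  if (mz_only$p_within >= mz_threshold)
    return(list(classified = FALSE, reason = "MZ-only effect not suggestive"))
  if (sign(pooled$beta_within) != sign(mz_only$beta_within))
    return(list(classified = FALSE, reason = "within-pair effects disagree in sign"))
  list(classified = TRUE, reason = "consistent within-pair association")
}
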