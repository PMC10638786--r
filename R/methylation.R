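## Per-CpG methylation simulation on the beta-value scale.
##
## Each CpG is Gaussian on the beta scale: baseline + total_sd * (sqrt(a2) G +
## sqrt(c2) C + sqrt(d2) D + sqrt(e2) E) plus optional sex and linkage terms,
## clamped to (0, 1). Gaussian-on-beta generation (rather than a logistic
## latent scale) preserves the exact MZ/DZ correlation algebra the twin models
## rely on; capping total_sd at 0.2 keeps clamping negligible.

#' Specify one simulated CpG site
#'
#' @param cpg_id identifier.
#' @param baseline_mean mean beta value in (0, 1).
#' @param a2,c2,d2,e2 standardized variance fractions (additive genetic,
#'   shared environment, dominance, unique environment); must sum to 1 and at
#'   most one of `c2`, `d2` may be nonzero (classical twin identifiability).
#' @param total_sd beta-scale standard deviation, in (0, 0.2].
#' @param linkage_mode how the CpG relates to the cohort's latent pubertal
#'   liability: `"null"` (none), `"causal_individual"` (individual-level
#'   exposure effect), `"family_confounded"` (driven by the pair-mean of the
#'   exposure only), `"genetic_confounded"` (driven by the exposure's additive
#'   genetic deviate only).
#' @param linkage_beta beta-scale change per unit (SD) of the linked quantity.
#' @param sex_mean_shift additive mean shift for females.
#' @param panel array panel membership: `"P450K"`, `"PEPIC"` or `"both"`.
#' @return list of class `cpg_spec`.
#' @export
cpg_spec <- function(cpg_id, baseline_mean = 0.5, a2 = 0, c2 = 0, d2 = 0,
                     e2 = 1, total_sd = 0.05,
                     linkage_mode = c("null", "causal_individual",
                                      "family_confounded", "genetic_confounded"),
                     linkage_beta = 0, sex_mean_shift = 0, panel = "both") {
  linkage_mode <- match.arg(linkage_mode)
  fr <- c(a2 = a2, c2 = c2, d2 = d2, e2 = e2)
  if (any(fr < 0)) stop("variance fractions must be nonnegative", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("a2 + c2 + d2 + e2 must equal 1", call. = FALSE)
  if (c2 > 0 && d2 > 0)
    stop("at most one of 'c2' and 'd2' may be nonzero", call. = FALSE)
  if (baseline_mean <= 0 || baseline_mean >= 1)
    stop("'baseline_mean' must be inside (0, 1)", call. = FALSE)
  if (total_sd <= 0 || total_sd > 0.2)
    stop("'total_sd' must be in (0, 0.2]", call. = FALSE)
  if (!panel %in% c("P450K", "PEPIC", "both"))
    stop("'panel' must be one of P450K, PEPIC, both", call. = FALSE)
  structure(list(cpg_id = cpg_id, baseline_mean = baseline_mean,
                 a2 = a2, c2 = c2, d2 = d2, e2 = e2, total_sd = total_sd,
                 linkage_mode = linkage_mode, linkage_beta = linkage_beta,
                 sex_mean_shift = sex_mean_shift, panel = panel),
            class = "cpg_spec")
}

#' Generate a CpG-by-sample beta-value matrix for a twin cohort
#'
#' Twin sharing of the latent components follows the classical model: the
#' additive-genetic deviate G correlates 1 within MZ and 0.5 within DZ pairs
#' (`rg_os` for opposite-sex DZ pairs), the dominance deviate D correlates 1
#' (MZ) / 0.25 (DZ), C is shared within a pair and E is independent. Each CpG
#' consumes its own RNG substream, so adding CpGs never perturbs earlier ones.
#'
#' @param cohort a [generate_cohort()] result.
#' @param specs list of [cpg_spec()] objects.
#' @param truth_out if TRUE, attach the realized latent components as the
#'   `"truth"` attribute.
#' @param seed integer seed.
#' @param rg_os cross-twin genetic correlation for opposite-sex DZ pairs.
#' @return numeric matrix (CpGs x samples) of beta values in (0, 1), with a
#'   `"panel"` attribute naming each CpG's array panel. A warning is raised if
#'   clamping to (0, 1) touches more than 1\% of values.
#' @export
generate_methylation <- function(cohort, specs, truth_out = FALSE, seed = 1L,
                                 rg_os = 0.5) {
  stopifnot(inherits(cohort, "twin_cohort"), length(specs) >= 1)
  if (inherits(specs, "cpg_spec")) specs <- list(specs)
  lapply(specs, function(s) if (!inherits(s, "cpg_spec"))
    stop("'specs' must be cpg_spec objects", call. = FALSE))

  ind <- cohort$individuals
  n <- nrow(ind)
  fam <- ind$family_id
  fam_idx <- match(fam, unique(fam))
  nf <- max(fam_idx)
  zyg_f <- ind$zygosity[!duplicated(fam_idx)]
  os_f <- tapply(ind$sex, fam_idx, function(s) length(unique(s)) > 1)
  gsh <- ifelse(zyg_f == "MZ", 1, ifelse(os_f, rg_os, 0.5))
  dsh <- ifelse(zyg_f == "MZ", 1, 0.25)
  female <- as.numeric(ind$sex == "F")
  truth <- cohort$truth[match(ind$individual_id, cohort$truth$individual_id), ]
  Lx <- truth$L
  Lbetween <- stats::ave(Lx, fam_idx)
  Lgen <- truth$A

  beta <- matrix(NA_real_, length(specs), n,
                 dimnames = list(vapply(specs, `[[`, "", "cpg_id"),
                                 ind$individual_id))
  clamped <- 0L
  truth_list <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    with_seed(derive_seed(seed, "cpg", k), {
      Gf <- stats::rnorm(nf); Df <- stats::rnorm(nf); Cf <- stats::rnorm(nf)
      G <- sqrt(gsh[fam_idx]) * Gf[fam_idx] +
        sqrt(1 - gsh[fam_idx]) * stats::rnorm(n)
      D <- sqrt(dsh[fam_idx]) * Df[fam_idx] +
        sqrt(1 - dsh[fam_idx]) * stats::rnorm(n)
      E <- stats::rnorm(n)
      y <- sp$baseline_mean + sp$total_sd *
        (sqrt(sp$a2) * G + sqrt(sp$c2) * Cf[fam_idx] + sqrt(sp$d2) * D +
           sqrt(sp$e2) * E) + sp$sex_mean_shift * female
      y <- y + switch(sp$linkage_mode,
                      null = 0,
                      causal_individual = sp$linkage_beta * Lx,
                      family_confounded = sp$linkage_beta * Lbetween,
                      genetic_confounded = sp$linkage_beta * Lgen)
      clamped <- clamped + sum(y < 0.001 | y > 0.999)
      beta[k, ] <- pmin(pmax(y, 0.001), 0.999)
      if (truth_out)
        truth_list[[k]] <- list(spec = sp, G = G, C = Cf[fam_idx], D = D, E = E)
    })
  }
  if (clamped > 0.01 * length(beta))
    warning(sprintf("clamping to (0, 1) affected %.2f%% of values",
                    100 * clamped / length(beta)))
  attr(beta, "panel") <- vapply(specs, `[[`, "", "panel")
  if (truth_out) attr(beta, "truth") <- truth_list
  beta
}
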