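## meQTL simulation, counting and heritability correlation.

#' Simulate a SNP-CpG association (meQTL) table for a twin cohort
#'
#' Genotypes respect twin sharing: MZ cotwins are genetically identical and DZ
#' cotwins each receive an independent transmission from the same simulated
#' parents. Per-SNP association tests are computed on one twin per family so
#' the resulting p-values are calibrated (family clustering would otherwise
#' inflate them).
#'
#' @param cohort a [generate_cohort()] result.
#' @param specs list of [cpg_spec()] objects; the CpG's methylation for the
#'   association test is rebuilt as causal-SNP effects plus residual noise at
#'   the spec's `total_sd`.
#' @param snp_config list with `n_snps` (SNPs tested per CpG), `n_causal`
#'   (number of truly causal SNPs per CpG; scalar or vector over specs),
#'   `effect` (beta-scale effect per allele of each causal SNP) and
#'   `maf_range` (allele-frequency range, inside (0, 1)).
#' @param seed integer seed.
#' @return data.frame with columns snp_id, chrom, pos, cpg_id, cis_trans, p,
#'   beta: one row per (SNP, CpG) pair.
#' @export
generate_meqtl_table <- function(cohort, specs,
                                 snp_config = list(n_snps = 50, n_causal = 0,
                                                   effect = 0.02,
                                                   maf_range = c(0.1, 0.5)),
                                 seed = 1L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (inherits(specs, "cpg_spec")) specs <- list(specs)
  mr <- snp_config$maf_range %||% c(0.1, 0.5)
  if (any(mr <= 0) || any(mr >= 1))
    stop("allele frequencies in 'maf_range' must lie inside (0, 1)", call. = FALSE)
  n_causal <- rep_len(snp_config$n_causal %||% 0, length(specs))
  n_snps <- snp_config$n_snps %||% 50
  eff <- snp_config$effect %||% 0.02

  ind <- cohort$individuals
  fam_idx <- match(ind$family_id, unique(ind$family_id))
  nf <- max(fam_idx)
  mz_f <- ind$zygosity[!duplicated(fam_idx)] == "MZ"
  order2 <- ind$twin_order == 2L
  test_idx <- which(ind$twin_order == 1L)  # one twin per family

  out <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    with_seed(derive_seed(seed, "meqtl", k), {
      maf <- stats::runif(n_snps, mr[1], mr[2])
      ## parental genotypes per family, independent transmissions to DZ twins
      G <- matrix(0L, nrow(ind), n_snps)
      for (j in seq_len(n_snps)) {
        m1 <- stats::rbinom(nf, 1L, maf[j]); m2 <- stats::rbinom(nf, 1L, maf[j])
        f1 <- stats::rbinom(nf, 1L, maf[j]); f2 <- stats::rbinom(nf, 1L, maf[j])
        pick <- function() stats::rbinom(nf, 1L, 0.5)
        gt1 <- ifelse(pick() == 1L, m1, m2) + ifelse(pick() == 1L, f1, f2)
        gt2 <- ifelse(pick() == 1L, m1, m2) + ifelse(pick() == 1L, f1, f2)
        gt2[mz_f] <- gt1[mz_f]
        g <- gt1[fam_idx]
        g[order2] <- gt2[fam_idx[order2]]
        G[, j] <- g
      }
      causal <- seq_len(min(n_causal[k], n_snps))
      y <- sp$baseline_mean + stats::rnorm(nrow(ind), sd = sp$total_sd)
      for (j in causal) y <- y + eff * G[, j]
      ## per-SNP simple regression on unrelated subset
      yt <- y[test_idx]
      res <- vapply(seq_len(n_snps), function(j) {
        g <- G[test_idx, j]
        if (stats::var(g) == 0) return(c(NA_real_, 1))
        fit <- stats::lm.fit(cbind(1, g), yt)
        rdf <- length(yt) - 2L
        s2 <- sum(fit$residuals^2) / rdf
        se <- sqrt(s2 / sum((g - mean(g))^2))
        tt <- fit$coefficients[2] / se
        c(fit$coefficients[2], 2 * stats::pt(-abs(tt), rdf))
      }, numeric(2))
      out[[k]] <- data.frame(
        snp_id = sprintf("%s_snp%03d", sp$cpg_id, seq_len(n_snps)),
        chrom = paste0("chr", 1 + (k - 1L) %% 22L),
        pos = 1e6 + seq_len(n_snps) * 1000L,
        cpg_id = sp$cpg_id,
        cis_trans = ifelse(seq_len(n_snps) <= max(1, n_snps * 0.9), "cis", "trans"),
        p = pmax(res[2, ], .Machine$double.xmin),
        beta = res[1, ], stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}

#' Count genome-wide significant meQTLs per CpG
#'
#' @param table meQTL association table: data.frame with at least `snp_id`,
#'   `cpg_id`, `p` and optionally `cis_trans`.
#' @param cpg_ids CpGs to report; CpGs absent from the table get count 0.
#' @param threshold significance threshold; rows with `p < threshold` count
#'   (strict inequality). Default 5e-8, the conventional genome-wide level.
#' @return data.frame with cpg_id, n_meqtl, n_cis, n_trans.
#' @export
count_meqtls <- function(table, cpg_ids, threshold = 5e-8) {
  stop_if_not_prob(threshold, "threshold")
  if (threshold == 0) stop("'threshold' must be in (0, 1)", call. = FALSE)
  if (nrow(table) > 0) {
    key <- paste(table$snp_id, table$cpg_id)
    if (anyDuplicated(key))
      stop(sprintf("duplicate (snp, cpg) row: %s", key[duplicated(key)][1]),
           call. = FALSE)
  }
  hit <- table[table$p < threshold, , drop = FALSE]
  ct <- if (is.null(hit$cis_trans)) rep("cis", nrow(hit)) else hit$cis_trans
  data.frame(
    cpg_id = cpg_ids,
    n_meqtl = as.integer(vapply(cpg_ids, function(id) sum(hit$cpg_id == id), 0)),
    n_cis = as.integer(vapply(cpg_ids, function(id)
      sum(hit$cpg_id == id & ct == "cis"), 0)),
    n_trans = as.integer(vapply(cpg_ids, function(id)
      sum(hit$cpg_id == id & ct == "trans"), 0)),
    stringsAsFactors = FALSE)
}

#' Spearman rank correlation with midrank ties
#'
#' Used to relate per-CpG meQTL counts to heritability. The p-value uses the
#' t approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p` and `n`; `rho` is NA (with a warning) if
#'   either vector is constant.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}
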