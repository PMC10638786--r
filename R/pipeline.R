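## End-to-end orchestration: phenotypes -> per-platform EWAS -> meta-analysis
## -> candidate selection -> twin models -> sex differences -> discordant
## pairs -> meQTL correlation.

## short deterministic hash of a configuration, embedded in outputs
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Bundles the synthetic-cohort block, the CpG specification list, the model
#' list and every downstream threshold.
#'
#' @param cohort [cohort_config()] for the synthetic cohort.
#' @param cpg_specs list of [cpg_spec()] objects.
#' @param models character vector of analysis models; each is
#'   `<exposure>_<subset>` with exposure `pds12`, `pds14` or `pa` and subset
#'   `all`, `M` or `F`.
#' @param suggestive,strict meta-analysis significance cut-offs.
#' @param q_bh_threshold corrected heterogeneity cut-off.
#' @param effect_threshold absolute standardized effect-size filter.
#' @param sd_threshold methylation SD filter for twin modelling.
#' @param followup_alpha significance level for follow-up (sex-difference)
#'   tests after Bonferroni correction.
#' @param use_moderated feed moderated t statistics into the meta-analysis.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            cpg_specs = NULL,
                            models = c("pds12_all", "pds12_M", "pds12_F",
                                       "pds14_all", "pds14_M", "pds14_F",
                                       "pa_M", "pa_F"),
                            suggestive = 1e-5, strict = 2.4e-7,
                            q_bh_threshold = 0.01, effect_threshold = 0.13,
                            sd_threshold = 0.05, followup_alpha = 0.01,
                            use_moderated = FALSE) {
  for (v in c(suggestive, strict, q_bh_threshold, effect_threshold,
              sd_threshold, followup_alpha))
    if (!is.numeric(v) || v <= 0) stop("thresholds must be positive", call. = FALSE)
  exposures <- sub("_.*$", "", models)
  if (!all(exposures %in% c("pds12", "pds14", "pa")))
    stop("unknown exposure in 'models'", call. = FALSE)
  structure(list(cohort = cohort, cpg_specs = cpg_specs, models = models,
                 suggestive = suggestive, strict = strict,
                 q_bh_threshold = q_bh_threshold,
                 effect_threshold = effect_threshold,
                 sd_threshold = sd_threshold, followup_alpha = followup_alpha,
                 use_moderated = use_moderated),
            class = "pipeline_config")
}

## named exposure vector for one model on one cohort
.model_exposure <- function(model, cohort) {
  ind <- cohort$individuals
  exposure <- sub("_.*$", "", model)
  subset <- sub("^.*_", "", model)
  x <- if (exposure %in% c("pds12", "pds14")) {
    wave <- if (exposure == "pds12") 12L else 14L
    it <- cohort$pds_items[cohort$pds_items$wave == wave, ]
    stats::setNames(compute_pds(it), it$individual_id)[ind$individual_id]
  } else {
    stats::setNames(code_pubertal_age(cohort$pa_reports),
                    cohort$pa_reports$individual_id)[ind$individual_id]
  }
  names(x) <- ind$individual_id
  if (subset %in% c("M", "F")) x[ind$sex != subset] <- NA
  x
}

#' Run the full twin EWAS analysis
#'
#' Executes every stage on a synthetic cohort: phenotype scoring, per-platform
#' family-aware EWAS with variance moderation, dual-platform meta-analysis,
#' candidate selection at the suggestive tier, univariate twin modelling with
#' assumption checks, sex-difference tests, discordant-pair decomposition and
#' meQTL-heritability correlation. Any stage failure is reported with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed (all stages derive substreams from it).
#' @param meqtl_table optional user-supplied meQTL association table; if NULL
#'   a synthetic one is generated for the candidate CpGs.
#' @return list of class `twinmeth_report` with per-stage results, the config
#'   hash and the seed.
#' @export
run_full_analysis <- function(config = pipeline_config(), seed = 1L,
                              meqtl_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- stage("simulate", generate_cohort(config$cohort, seed))
  specs <- config$cpg_specs
  if (is.null(specs))
    specs <- lapply(seq_len(50), function(i)
      cpg_spec(sprintf("cpg%04d", i), baseline_mean = 0.5,
               a2 = 0.4, c2 = 0.1, e2 = 0.5, total_sd = 0.06))
  Y <- stage("simulate", generate_methylation(cohort, specs, seed = seed))
  panel <- attr(Y, "panel")
  ind <- cohort$individuals

  ewas_results <- list(); metas <- list()
  for (model in config$models) {
    x <- stage("phenotypes", .model_exposure(model, cohort))
    per_platform <- list()
    for (pf in c("P450K", "PEPIC")) {
      on_pf <- ind$platform == pf
      keep <- on_pf & !is.na(x)
      if (sum(keep) < 30) next
      sub <- ind[keep, ]
      covs <- stage("ewas", suppressWarnings(
        prepare_covariates(sub, include_sex = grepl("_all$", model),
                           include_cohort = grepl("^pa_", model))))
      des <- stage("ewas", ewas_design(x[sub$individual_id], covs,
                                       sub$family_id))
      Yp <- Y[panel %in% c(pf, "both"), des$samples, drop = FALSE]
      rho <- stage("ewas", estimate_consensus_correlation(Yp, des))
      res <- stage("ewas", run_ewas(Yp, des, rho))
      if (nrow(res) >= 10)
        res <- stage("ewas", moderate_statistics(res))
      res$rho <- rho
      per_platform[[pf]] <- res
    }
    ewas_results[[model]] <- per_platform
    if (length(per_platform) == 2)
      metas[[model]] <- stage("meta", run_meta_pipeline(
        per_platform$P450K, per_platform$PEPIC,
        use_moderated = config$use_moderated, strict = config$strict,
        suggestive = config$suggestive,
        q_bh_threshold = config$q_bh_threshold,
        effect_threshold = config$effect_threshold))
  }

  ## candidate set: suggestive tier in any model
  cand <- unique(unlist(lapply(names(metas), function(m) {
    mm <- metas[[m]]
    mm$cpg_id[mm$tier != "none"]
  })))
  message(sprintf("%d candidate CpG(s) at the suggestive tier", length(cand)))

  twin <- list(); sexdiff <- list(); discord <- list()
  if (length(cand)) {
    n_cand <- length(cand)
    for (cg in cand) {
      vals <- stats::setNames(Y[cg, ], colnames(Y))
      pt <- pair_table(cohort, vals)
      names(pt)[names(pt) == "y1"] <- "y1"
      chk <- stage("twin", check_candidate(pt, config$sd_threshold,
                                           config$followup_alpha))
      entry <- list(check = chk, correlations = twin_correlations(pt))
      if (chk$eligible)
        entry$selection <- stage("twin", select_best_model(pt))
      twin[[cg]] <- entry

      wil <- stage("sexdiff", wilcoxon_sex_test(vals, ind$sex, n_cand))
      sd_entry <- list(wilcoxon = wil)
      if (chk$eligible) {
        free <- stage("sexdiff", fit_sex_limitation(pt))
        eq <- stage("sexdiff", fit_sex_limitation(
          pt, constraints = c("mean", "a", "e")))
        sd_entry$omnibus <- stage("sexdiff",
                                  omnibus_sex_test(free, eq, n_cand))
        if (sd_entry$omnibus$significant)
          sd_entry$parameters <- stage("sexdiff", parameter_sex_tests(
            free, m_tests = n_cand))
      }
      sexdiff[[cg]] <- sd_entry

      ## discordant pairs on the exposure of the model that flagged the CpG
      model <- names(metas)[vapply(metas, function(mm)
        cg %in% mm$cpg_id[mm$tier != "none"], TRUE)][1]
      x <- .model_exposure(model, cohort)
      dp <- pt
      dp$x1 <- x[dp$id1]; dp$x2 <- x[dp$id2]
      dp$family_id <- dp$family_id
      pooled <- try(stage("discordant", fit_within_between(dp)), silent = TRUE)
      mzonly <- try(stage("discordant",
                          fit_within_between(dp, zygosity_subset = "MZ")),
                    silent = TRUE)
      if (!inherits(pooled, "try-error")) {
        cls <- classify_discordance(
          pooled, if (inherits(mzonly, "try-error")) NULL else mzonly)
        discord[[cg]] <- list(pooled = pooled,
                              mz_only = if (inherits(mzonly, "try-error"))
                                NULL else mzonly,
                              classification = cls)
      }
    }
  } else {
    message("no candidates: twin, sex-difference and discordant stages skipped")
  }

  ## meQTL counts vs heritability over CpGs with a fitted twin model
  meqtl <- NULL
  fitted_cgs <- names(twin)[vapply(twin, function(e) !is.null(e$selection), TRUE)]
  if (length(fitted_cgs) >= 3) {
    tab <- meqtl_table
    if (is.null(tab)) {
      specs_f <- specs[vapply(specs, `[[`, "", "cpg_id") %in% fitted_cgs]
      tab <- stage("meqtl", generate_meqtl_table(
        cohort, specs_f,
        snp_config = list(n_snps = 30,
                          n_causal = round(vapply(specs_f, `[[`, 0, "a2") * 5),
                          effect = 0.03, maf_range = c(0.1, 0.5)),
        seed = derive_seed(seed, "meqtl")))
    }
    counts <- stage("meqtl", count_meqtls(tab, fitted_cgs))
    h2 <- vapply(fitted_cgs, function(cg)
      twin[[cg]]$selection$best$components[["a2"]], 0)
    meqtl <- list(counts = counts,
                  correlation = stage("meqtl", spearman_correlation(
                    counts$n_meqtl, h2)))
  }

  structure(list(cohort = cohort, ewas = ewas_results, meta = metas,
                 candidates = cand, twin = twin, sexdiff = sexdiff,
                 discordant = discord, meqtl = meqtl,
                 config = config, config_hash = config_hash(config),
                 seed = seed),
            class = "twinmeth_report")
}

#' @export
print.twinmeth_report <- function(x, ...) {
  cat(sprintf("twinmeth analysis report (config %s, seed %d)\n",
              x$config_hash, x$seed))
  cat(sprintf("  models analysed: %d; candidate CpGs: %d\n",
              length(x$meta), length(x$candidates)))
  if (length(x$twin)) {
    elig <- sum(vapply(x$twin, function(e) e$check$eligible, TRUE))
    cat(sprintf("  twin-modelled CpGs: %d eligible of %d\n", elig,
                length(x$twin)))
  }
  invisible(x)
}

#' Quantile-quantile data for a set of p-values
#'
#' Expected vs observed -log10 p-values with a pointwise 95\% order-statistic
#' envelope (beta distribution of uniform order statistics).
#'
#' @param p vector of p-values.
#' @return data.frame with expected, observed, lower, upper (all -log10).
#' @export
qq_data <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  i <- seq_len(n)
  data.frame(expected = -log10(i / (n + 1)), observed = -log10(p),
             lower = -log10(stats::qbeta(0.975, i, n - i + 1)),
             upper = -log10(stats::qbeta(0.025, i, n - i + 1)))
}

#' Candidate summary table
#'
#' One row per candidate CpG in the layout of a published EWAS hit table:
#' originating model, per-platform effect sizes, meta-analysed standardized
#' effect, p-value and corrected heterogeneity p.
#'
#' @param report a `twinmeth_report`.
#' @return data.frame (zero rows when there are no candidates).
#' @export
candidate_table <- function(report) {
  cols <- c("model", "cpg_id", "effect_450K", "effect_EPIC",
            "standardised_effect", "p_value", "q_p_bh", "tier")
  rows <- list()
  for (m in names(report$meta)) {
    mm <- report$meta[[m]]
    hit <- mm[mm$tier != "none", , drop = FALSE]
    if (!nrow(hit)) next
    e450 <- report$ewas[[m]]$P450K
    eepc <- report$ewas[[m]]$PEPIC
    rows[[m]] <- data.frame(
      model = m, cpg_id = hit$cpg_id,
      effect_450K = e450$beta_hat[match(hit$cpg_id, e450$cpg_id)],
      effect_EPIC = eepc$beta_hat[match(hit$cpg_id, eepc$cpg_id)],
      standardised_effect = hit$r_meta, p_value = hit$p_value,
      q_p_bh = hit$q_p_bh, tier = hit$tier, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Twin-model summary table
#'
#' One row per eligible candidate CpG: observed MZ/DZ correlations, mean, SD,
#' best model and its standardized variance components.
#'
#' @param report a `twinmeth_report`.
#' @return data.frame.
#' @export
twin_table <- function(report) {
  rows <- lapply(names(report$twin), function(cg) {
    e <- report$twin[[cg]]
    if (is.null(e$selection)) return(NULL)
    best <- e$selection$best
    comp <- best$components
    data.frame(cpg_id = cg, r_mz = unname(e$correlations[["r_mz"]]),
               r_dz = unname(e$correlations[["r_dz"]]),
               mean = best$coefficients[["mu"]],
               sd = sqrt(best$total_variance),
               best_model = best$model,
               heritability = comp[["a2"]] + comp[["d2"]],
               shared_environment = comp[["c2"]],
               unique_environment = comp[["e2"]], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
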