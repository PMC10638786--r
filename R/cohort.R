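## Synthetic twin-cohort generator.
##
## Families carry a latent pubertal-timing liability with an additive-genetic /
## shared-environment / unique-environment decomposition; questionnaire items
## and pubertal-age reports are deterministic functions of that liability plus
## item-level noise, so every downstream stage has a known ground truth.

#' Configuration for the synthetic twin cohort
#'
#' Defaults describe a two-cohort Finnish-style twin sample: two questionnaire
#' waves of pubertal development items (ages 12 and 14) in the younger cohort,
#' retrospective pubertal age in both, blood sampling in early adulthood, and
#' two overlapping methylation array panels.
#'
#' @param n_families number of twin families (>= 2).
#' @param mz_fraction fraction of families that are monozygotic. The MZ:DZ
#'   ratio of the emulated sample is not pinned down by any published count;
#'   one third is a conventional population value and is exposed here.
#' @param os_dz_fraction fraction of DZ families that are opposite-sex.
#' @param female_fraction probability that a same-sex family is female.
#' @param singleton_fraction fraction of families contributing only one twin
#'   (incomplete pairs).
#' @param cohort_split fraction of families in the younger cohort ("FTA";
#'   the rest are "FTB").
#' @param platform_split fraction of families assayed on the P450K panel (the
#'   rest on PEPIC).
#' @param liability_a2,liability_c2 additive-genetic and shared-environment
#'   variance fractions of the latent pubertal-timing liability (the rest is
#'   unique environment).
#' @param rg_os cross-sex additive-genetic correlation used for opposite-sex
#'   DZ pairs (0.5 = same genes in both sexes).
#' @param pa_mean_f,pa_mean_m,pa_sd mean age at menarche / voice break and its
#'   SD on the latent scale.
#' @param smoking_probs probabilities for never/current/former smoking.
#' @param n_chip_dates number of BeadChip run dates (batch levels).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 500,
                          mz_fraction = 1 / 3,
                          os_dz_fraction = 0.5,
                          female_fraction = 0.5,
                          singleton_fraction = 0.05,
                          cohort_split = 0.5,
                          platform_split = 0.5,
                          liability_a2 = 0.6,
                          liability_c2 = 0.2,
                          rg_os = 0.5,
                          pa_mean_f = 12.9,
                          pa_mean_m = 13.9,
                          pa_sd = 1.2,
                          smoking_probs = c(never = 0.55, current = 0.30, former = 0.15),
                          n_chip_dates = 8L) {
  if (!is.numeric(n_families) || n_families < 2)
    stop("'n_families' must be >= 2", call. = FALSE)
  for (nm in c("mz_fraction", "os_dz_fraction", "female_fraction",
               "singleton_fraction", "cohort_split", "platform_split",
               "liability_a2", "liability_c2"))
    stop_if_not_prob(get(nm), nm)
  if (liability_a2 + liability_c2 > 1)
    stop("'liability_a2' + 'liability_c2' must not exceed 1", call. = FALSE)
  if (rg_os < 0 || rg_os > 0.5)
    stop("'rg_os' must be in [0, 0.5]", call. = FALSE)
  if (abs(sum(smoking_probs) - 1) > 1e-9 || any(smoking_probs < 0))
    stop("'smoking_probs' must be nonnegative and sum to 1", call. = FALSE)
  structure(list(
    n_families = as.integer(n_families), mz_fraction = mz_fraction,
    os_dz_fraction = os_dz_fraction, female_fraction = female_fraction,
    singleton_fraction = singleton_fraction, cohort_split = cohort_split,
    platform_split = platform_split, liability_a2 = liability_a2,
    liability_c2 = liability_c2, rg_os = rg_os,
    pa_mean_f = pa_mean_f, pa_mean_m = pa_mean_m, pa_sd = pa_sd,
    smoking_probs = smoking_probs, n_chip_dates = as.integer(n_chip_dates)
  ), class = "cohort_config")
}

## Reference blood cell-type mixture (granulocytes, CD4T, CD8T, B, monocytes,
## NK); Dirichlet concentration 60 keeps realistic person-to-person spread.
.cell_alpha <- c(Gran = 0.58, CD4T = 0.15, CD8T = 0.10, Bcell = 0.07,
                 Mono = 0.07, NK = 0.03) * 60

#' Generate a synthetic twin cohort
#'
#' Draws families (zygosity, sex composition, cohort, platform), a latent
#' pubertal-timing liability with the configured A/C/E structure (additive
#' genetic deviates correlate 1 in MZ pairs, 0.5 in same-sex DZ pairs and
#' `rg_os`/2 scaled for opposite-sex pairs), adult covariates, pubertal
#' development items at two waves and censored pubertal-age reports.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical `(config, seed)` give identical cohorts.
#' @return object of class `twin_cohort`: list with `individuals` (one row per
#'   individual), `pds_items` (one row per individual per wave), `pa_reports`,
#'   `pairs` (index of complete families), `truth` (latent liability and its
#'   A/C/E components) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(seed, "cohort"), {
    nf <- config$n_families
    zyg <- ifelse(stats::runif(nf) < config$mz_fraction, "MZ", "DZ")
    os <- zyg == "DZ" & stats::runif(nf) < config$os_dz_fraction
    fam_female <- stats::runif(nf) < config$female_fraction
    sex1 <- ifelse(os, "M", ifelse(fam_female, "F", "M"))
    sex2 <- ifelse(os, "F", sex1)
    cohort <- ifelse(stats::runif(nf) < config$cohort_split, "FTA", "FTB")
    platform <- ifelse(stats::runif(nf) < config$platform_split, "P450K", "PEPIC")
    singleton <- stats::runif(nf) < config$singleton_fraction

    ## latent liability: L = sqrt(a2) A + sqrt(c2) C + sqrt(e2) E
    a2 <- config$liability_a2; c2 <- config$liability_c2; e2 <- 1 - a2 - c2
    ## cross-twin additive-genetic correlation: MZ 1, same-sex DZ 0.5,
    ## opposite-sex DZ rg_os (default 0.5 = no qualitative sex difference)
    gsh <- ifelse(zyg == "MZ", 1, ifelse(os, config$rg_os, 0.5))
    Af <- stats::rnorm(nf)
    A1 <- sqrt(gsh) * Af + sqrt(1 - gsh) * stats::rnorm(nf)
    A2 <- sqrt(gsh) * Af + sqrt(1 - gsh) * stats::rnorm(nf)
    ## MZ pairs: force exact sharing
    A2[zyg == "MZ"] <- A1[zyg == "MZ"]
    Cf <- stats::rnorm(nf)
    E1 <- stats::rnorm(nf); E2 <- stats::rnorm(nf)
    L1 <- sqrt(a2) * A1 + sqrt(c2) * Cf + sqrt(e2) * E1
    L2 <- sqrt(a2) * A2 + sqrt(c2) * Cf + sqrt(e2) * E2

    ## assemble individuals (twin 2 dropped for singleton families)
    fam_id <- sprintf("fam%05d", seq_len(nf))
    mk_twin <- function(order, sex, A, L) {
      data.frame(individual_id = paste0(fam_id, "_", order), family_id = fam_id,
                 twin_order = order, sex = sex, zygosity = zyg, cohort = cohort,
                 platform = platform, A = A, L = L, stringsAsFactors = FALSE)
    }
    ind <- rbind(mk_twin(1L, sex1, A1, L1), mk_twin(2L, sex2, A2, L2))
    ind$C <- rep(Cf, 2); ind$E <- c(E1, E2)
    ind <- ind[!(ind$twin_order == 2L & rep(singleton, 2)), ]
    ind <- ind[order(ind$family_id, ind$twin_order), ]
    n <- nrow(ind)

    ## adult covariates
    ind$age_at_sampling <- round(ifelse(ind$cohort == "FTA",
                                        stats::runif(n, 21, 33.7),
                                        stats::runif(n, 23.3, 42.7)), 1)
    ind$smoking <- sample(names(config$smoking_probs), n, replace = TRUE,
                          prob = config$smoking_probs)
    ind$alcohol_g_day <- round(stats::rgamma(n, shape = 1.2,
                                             scale = ifelse(ind$sex == "M", 13, 6.5)), 2)
    cells <- matrix(stats::rgamma(n * 6, shape = rep(.cell_alpha, each = n)), n, 6)
    cells <- cells / rowSums(cells)
    colnames(cells) <- paste0("cell_", names(.cell_alpha))
    ind <- cbind(ind, as.data.frame(cells))
    ind$chip_date <- paste0("batch", sample.int(config$n_chip_dates, n, replace = TRUE))
    ind$array_row <- sample.int(8L, n, replace = TRUE)

    ## pubertal development items: stage s = L + sex/wave offset + item noise.
    ## Girls are ahead at 12; by 14 most markers are well underway.
    pds <- do.call(rbind, lapply(c(12L, 14L), function(wave) {
      off <- ifelse(ind$sex == "F", 0.4, -0.4) + ifelse(wave == 14L, 1.6, 0)
      item <- function(shift, max_code) {
        s <- ind$L + off + shift + stats::rnorm(n, sd = 0.7)
        pmin(findInterval(s, c(0, 1.1, 2.2)) + 1L, max_code)
      }
      max_main <- if (wave == 14L) 4L else 3L
      men <- ifelse(ind$L + off + stats::rnorm(n, sd = 0.7) > 1.3, 4L, 1L)
      fac <- item(-0.5, 3L)
      data.frame(individual_id = ind$individual_id, wave = wave, sex = ind$sex,
                 growth_spurt = item(0, max_main), body_hair = item(-0.2, max_main),
                 skin_changes = item(-0.1, max_main),
                 breast_or_voice = item(0.1, max_main),
                 menarche_or_facial_hair = ifelse(ind$sex == "F", men, fac),
                 stringsAsFactors = FALSE)
    }))

    ## pubertal age: earlier puberty for higher liability; censored at the
    ## report age ("not yet"), a few percent missing.
    pa_mean <- ifelse(ind$sex == "F", config$pa_mean_f, config$pa_mean_m)
    event <- round(pa_mean - config$pa_sd * ind$L +
                     stats::rnorm(n, sd = 0.3), 1)
    report_age <- round(ifelse(ind$cohort == "FTA", 17.6, 16.2), 1)
    ea <- ifelse(event > pmin(report_age, 17), "not_yet", format(event))
    ea[stats::runif(n) < 0.02] <- NA
    pa <- data.frame(individual_id = ind$individual_id, sex = ind$sex,
                     event_age = ea, report_age = report_age,
                     stringsAsFactors = FALSE)

    fam_n <- table(ind$family_id)
    pairs <- names(fam_n)[fam_n == 2L]
    truth <- ind[, c("individual_id", "family_id", "A", "C", "E", "L")]
    ind$A <- ind$C <- ind$E <- ind$L <- NULL
    rownames(ind) <- NULL
    structure(list(individuals = ind, pds_items = pds, pa_reports = pa,
                   pairs = pairs, truth = truth, config = config),
              class = "twin_cohort")
  })
}

#' @export
print.twin_cohort <- function(x, ...) {
  n <- nrow(x$individuals)
  zy <- table(x$individuals$zygosity[x$individuals$twin_order == 1L])
  cat(sprintf("Synthetic twin cohort: %d individuals in %d families (%d complete pairs)\n",
              n, length(unique(x$individuals$family_id)), length(x$pairs)))
  cat(sprintf("  MZ families: %d, DZ families: %d\n",
              zy[["MZ"]] %||% 0L, zy[["DZ"]] %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (is.character(a) && !length(a))) b else a

#' Extract complete twin pairs in wide (one row per pair) format
#'
#' @param cohort a `twin_cohort`.
#' @param values optional named numeric vector (names = individual ids), e.g.
#'   one CpG's methylation, attached as `y1`/`y2`.
#' @return data.frame with one row per complete pair: family id, zygosity,
#'   per-twin sex, age, and optionally `y1`, `y2`.
#' @export
pair_table <- function(cohort, values = NULL) {
  ind <- cohort$individuals
  ind <- ind[ind$family_id %in% cohort$pairs, ]
  t1 <- ind[ind$twin_order == 1L, ]
  t2 <- ind[ind$twin_order == 2L, ]
  t2 <- t2[match(t1$family_id, t2$family_id), ]
  out <- data.frame(family_id = t1$family_id, zygosity = t1$zygosity,
                    sex1 = t1$sex, sex2 = t2$sex,
                    age1 = t1$age_at_sampling, age2 = t2$age_at_sampling,
                    id1 = t1$individual_id, id2 = t2$individual_id,
                    stringsAsFactors = FALSE)
  if (!is.null(values)) {
    out$y1 <- unname(values[out$id1])
    out$y2 <- unname(values[out$id2])
  }
  out
}
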