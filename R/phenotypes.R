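## Pubertal phenotype scoring and covariate preparation.

.pds_items <- c("growth_spurt", "body_hair", "skin_changes",
                "breast_or_voice", "menarche_or_facial_hair")

#' Compute the pubertal development scale (PDS) score
#'
#' The PDS is the sum of five self-reported ordinal puberty markers divided by
#' five, preserving the individual item range. The four main markers (growth
#' spurt, body hair, skin changes, breast development / voice change) are
#' coded 1-3 at the age-12 wave and 1-4 at the age-14 wave; menarche is coded
#' 1 (no) / 4 (yes) and facial hair 1-3 at both waves.
#'
#' @param items data.frame with columns `wave` (12 or 14), `sex` ("M"/"F") and
#'   the five item codes `growth_spurt`, `body_hair`, `skin_changes`,
#'   `breast_or_voice`, `menarche_or_facial_hair`.
#' @return numeric vector of scores; individuals with any missing item are
#'   excluded (NA score). Out-of-range codes raise an error naming the item.
#' @export
compute_pds <- function(items) {
  stopifnot(all(c("wave", "sex", .pds_items) %in% names(items)))
  if (!all(items$wave %in% c(12L, 14L)))
    stop("'wave' must be 12 or 14", call. = FALSE)
  main_max <- ifelse(items$wave == 14L, 4L, 3L)
  for (it in .pds_items[1:4]) {
    v <- items[[it]]
    bad <- !is.na(v) & (v < 1L | v > main_max | v != round(v))
    if (any(bad))
      stop(sprintf("out-of-range code for item '%s' (row %d)", it,
                   which(bad)[1]), call. = FALSE)
  }
  v <- items$menarche_or_facial_hair
  bad <- !is.na(v) & ifelse(items$sex == "F", !v %in% c(1L, 4L),
                            !v %in% c(1L, 2L, 3L))
  if (any(bad))
    stop(sprintf("out-of-range code for item 'menarche_or_facial_hair' (row %d)",
                 which(bad)[1]), call. = FALSE)
  rowSums(items[, .pds_items]) / 5
}

#' Code self-reported pubertal age
#'
#' Pubertal age (PA) is the self-reported age at menarche (females) or voice
#' break (males). Respondents reporting that the event had not yet happened
#' are coded as the event occurring at age 17; missing reports and
#' inconsistent ones (event age later than the report age) are excluded.
#'
#' @param report data.frame with columns `event_age` (numeric years, the
#'   string `"not_yet"`, or NA), `report_age` (numeric years) and `sex`.
#' @return numeric vector of pubertal ages, NA for excluded individuals.
#' @export
code_pubertal_age <- function(report) {
  stopifnot(all(c("event_age", "report_age") %in% names(report)))
  ea <- report$event_age
  out <- rep(NA_real_, length(ea))
  not_yet <- !is.na(ea) & ea == "not_yet"
  out[not_yet] <- 17
  num <- suppressWarnings(as.numeric(ea))
  ok <- !is.na(num) & num <= report$report_age
  out[ok] <- num[ok]
  out
}

#' Prepare the EWAS covariate table
#'
#' Expands the adjustment set used by every per-CpG model: smoking status (two
#' indicators, never-smoker reference), alcohol (g/day), age at blood
#' sampling, cell-type proportions (last component dropped, they sum to one),
#' BeadChip run date and array row (indicator-coded, first level reference).
#' Sex (female = 1) and cohort (first level reference) indicators are added on
#' request, for combined-sex and pubertal-age models respectively. Constant or
#' aliased columns are dropped with a warning so the design stays full rank.
#'
#' @param cohort a `twin_cohort`, or any data.frame with the covariate fields.
#' @param include_sex,include_cohort add the respective indicator.
#' @return numeric matrix (samples x covariates) with rownames = individual
#'   ids and an attribute `"dropped"` naming removed columns.
#' @export
prepare_covariates <- function(cohort, include_sex = FALSE,
                               include_cohort = FALSE) {
  ind <- if (inherits(cohort, "twin_cohort")) cohort$individuals else cohort
  need <- c("individual_id", "smoking", "alcohol_g_day", "age_at_sampling",
            "chip_date", "array_row")
  miss <- setdiff(need, names(ind))
  if (length(miss)) stop("missing covariate fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !ind$smoking %in% c("never", "current", "former")
  if (any(bad))
    stop(sprintf("unknown smoking level '%s' for sample %s",
                 ind$smoking[bad][1], ind$individual_id[bad][1]), call. = FALSE)

  cols <- list(
    age = ind$age_at_sampling,
    alcohol = ind$alcohol_g_day,
    smoking_current = as.numeric(ind$smoking == "current"),
    smoking_former = as.numeric(ind$smoking == "former")
  )
  cell_cols <- grep("^cell_", names(ind), value = TRUE)
  for (cc in utils::head(cell_cols, -1L)) cols[[cc]] <- ind[[cc]]
  for (lv in sort(unique(ind$chip_date))[-1])
    cols[[paste0("chip_", lv)]] <- as.numeric(ind$chip_date == lv)
  for (rv in sort(unique(ind$array_row))[-1])
    cols[[paste0("row_", rv)]] <- as.numeric(ind$array_row == rv)
  if (include_sex) cols$sex_female <- as.numeric(ind$sex == "F")
  if (include_cohort && length(unique(ind$cohort)) > 1)
    for (lv in sort(unique(ind$cohort))[-1])
      cols[[paste0("cohort_", lv)]] <- as.numeric(ind$cohort == lv)

  X <- do.call(cbind, cols)
  rownames(X) <- ind$individual_id
  dropped <- character()
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    dropped <- colnames(X)[const]
    warning("dropping constant covariate column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    keep <- qx$pivot[seq_len(qx$rank)] - 1L
    keep <- keep[keep > 0]
    aliased <- setdiff(colnames(X), colnames(X)[keep])
    warning("dropping aliased covariate column(s): ",
            paste(aliased, collapse = ", "))
    dropped <- c(dropped, aliased)
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}
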