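## Shared fixtures and small oracles used across test files.

## One moderately sized cohort, generated once per test run.
.tm_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.tm_env$cohort))
    .tm_env$cohort <- generate_cohort(cohort_config(n_families = 300), seed = 101)
  .tm_env$cohort
}

## Brute-force Benjamini-Hochberg step-up, written independently of p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## Twin pairs with a known within-pair residual correlation and a null
## exposure, for EWAS calibration checks. Returns list(Y, design).
null_family_data <- function(n_pairs, n_cpgs, rho, seed) {
  set.seed(seed)
  n <- 2L * n_pairs
  fam <- rep(sprintf("f%04d", seq_len(n_pairs)), each = 2L)
  ids <- paste0(fam, "_", rep(1:2, n_pairs))
  Z_fam <- matrix(rnorm(n_cpgs * n_pairs), n_cpgs, n_pairs)
  Y <- sqrt(rho) * Z_fam[, rep(seq_len(n_pairs), each = 2L)] +
    sqrt(1 - rho) * matrix(rnorm(n_cpgs * n), n_cpgs, n)
  rownames(Y) <- sprintf("cpg%05d", seq_len(n_cpgs))
  colnames(Y) <- ids
  x <- stats::setNames(rnorm(n), ids)
  list(Y = Y, design = ewas_design(x, NULL, fam))
}

## All permutations of 1..n as rows of a matrix (n! x n), for exact
## permutation-null enumerations.
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

## Balanced five-group pair data with identical AE structure in both sexes
## and full cross-sex genetic correlation (no sex difference of any kind).
simulate_sexlim_null <- function(n_per_group, a2, seed) {
  set.seed(seed)
  draw <- function(n, r, s1, s2, zyg) {
    z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    data.frame(family_id = paste0(zyg, s1, s2, seq_len(n)), zygosity = zyg,
               sex1 = s1, sex2 = s2, y1 = z1, y2 = z2,
               stringsAsFactors = FALSE)
  }
  rbind(draw(n_per_group, a2, "M", "M", "MZ"),
        draw(n_per_group, a2, "F", "F", "MZ"),
        draw(n_per_group, a2 / 2, "M", "M", "DZ"),
        draw(n_per_group, a2 / 2, "F", "F", "DZ"),
        draw(n_per_group, a2 / 2, "M", "F", "DZ"))
}
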