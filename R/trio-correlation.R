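#' Mendelian distribution of the offspring genotype given both parents
#'
#' Exact transmission distribution at a biallelic locus: each parent transmits
#' the minor allele with probability `dosage / 2`, so the child dosage is the
#' sum of two independent Bernoulli draws (e.g. two heterozygous parents give
#' `{0: 1/4, 1: 1/2, 2: 1/4}`, mean 1).
#'
#' @param father,mother parental minor-allele dosages (0/1/2).
#' @return list with `dist` (named probabilities over dosages 0-2) and `mean`
#'   (`= (father + mother) / 2`); `NA` fields if a parent is missing.
#' @export
expected_offspring <- function(father, mother) {
  if (is.na(father) || is.na(mother))
    return(list(dist = stats::setNames(rep(NA_real_, 3), 0:2), mean = NA_real_))
  stopifnot(father %in% 0:2, mother %in% 0:2)
  pf <- father / 2; pm <- mother / 2
  dist <- c(`0` = (1 - pf) * (1 - pm),
            `1` = pf * (1 - pm) + (1 - pf) * pm,
            `2` = pf * pm)
  list(dist = dist, mean = pf + pm)
}

# Residual matrix child - E[child | parents] and informativeness (at least
# one heterozygous parent, all three genotypes observed).
trio_residuals <- function(cohort) {
  stop_if_not_cohort(cohort)
  res <- cohort$child - (cohort$father + cohort$mother) / 2
  informative <- (cohort$father == 1L | cohort$mother == 1L) &
    !is.na(cohort$father) & !is.na(cohort$mother) & !is.na(cohort$child)
  informative[is.na(informative)] <- FALSE
  res[!informative] <- NA_real_
  list(residuals = res, informative = informative)
}

#' Trio correlation test for epistasis at a SNP pair
#'
#' Independent validation of case-only hits that uses parental genotypes:
#' at each locus the transmission residual is the observed child dosage minus
#' its Mendelian expectation given both parents (mean zero under Mendelian
#' transmission regardless of population structure or main effects at either
#' locus alone). Cross-locus Pearson correlation `r` of residuals over
#' doubly-informative trios is tested with `z = r * sqrt(n)` against a
#' standard normal (two-sided).
#'
#' @param cohort a `trio_cohort` of affected offspring.
#' @param snp1,snp2 SNP ids.
#' @param min_informative minimum doubly-informative trios (default 30);
#'   below it the test is `NA` with the count reported.
#' @return data.frame row: `snp1`, `snp2`, `n_informative`, `r`, `z`, `p`.
#' @export
trio_corr_test <- function(cohort, snp1, snp2, min_informative = 30L) {
  tr <- trio_residuals(cohort)
  j1 <- match(snp1, cohort$snps$snp_id)
  j2 <- match(snp2, cohort$snps$snp_id)
  if (is.na(j1) || is.na(j2)) stop("unknown SNP id", call. = FALSE)
  both <- tr$informative[, j1] & tr$informative[, j2]
  n <- sum(both)
  if (n < min_informative)
    return(data.frame(snp1 = snp1, snp2 = snp2, n_informative = n,
                      r = NA_real_, z = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE))
  r1 <- tr$residuals[both, j1]; r2 <- tr$residuals[both, j2]
  if (stats::sd(r1) == 0 || stats::sd(r2) == 0)
    return(data.frame(snp1 = snp1, snp2 = snp2, n_informative = n,
                      r = NA_real_, z = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE))
  r <- stats::cor(r1, r2)
  z <- r * sqrt(n)
  data.frame(snp1 = snp1, snp2 = snp2, n_informative = n, r = r, z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Validate case-only screen hits with the trio correlation test
#'
#' Applies [trio_corr_test()] to every screened pair at or below `p_cut` and
#' reports the Spearman rank correlation between the two tests' P-values —
#' agreement indicates the screen's signals behave like transmission-level
#' epistasis rather than marginal effects.
#'
#' @param screen_results `results` data.frame from [set_by_all_screen()]
#'   (columns `snp1`, `snp2`, `p`).
#' @param cohort the `trio_cohort` the screen was run on.
#' @param p_cut validate pairs with case-only `p <= p_cut` (default `1e-6`).
#' @param min_informative passed to [trio_corr_test()].
#' @return list: `table` (per pair: case-only and trio-correlation results),
#'   `rho` (Spearman), `rho_p`. Empty hit list gives an empty table with a
#'   warning.
#' @export
validate_hits <- function(screen_results, cohort, p_cut = 1e-6,
                          min_informative = 30L) {
  hits <- screen_results[!is.na(screen_results$p) & screen_results$p <= p_cut, ,
                         drop = FALSE]
  if (!nrow(hits)) {
    warning("no screen hits at p_cut = ", p_cut)
    return(list(table = data.frame(), rho = NA_real_, rho_p = NA_real_))
  }
  rows <- lapply(seq_len(nrow(hits)), function(i)
    trio_corr_test(cohort, hits$snp1[i], hits$snp2[i], min_informative))
  tc <- do.call(rbind, rows)
  tab <- data.frame(
    snp1 = hits$snp1, snp2 = hits$snp2,
    case_only_p = hits$p, case_only_z = hits$z,
    trio_corr_p = tc$p, trio_corr_z = tc$z,
    n_informative = tc$n_informative, stringsAsFactors = FALSE
  )
  ok <- !is.na(tab$trio_corr_p)
  if (sum(ok) >= 3) {
    ct <- suppressWarnings(
      stats::cor.test(tab$case_only_p[ok], tab$trio_corr_p[ok],
                      method = "spearman"))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  } else {
    rho <- NA_real_; rho_p <- NA_real_
  }
  list(table = tab, rho = rho, rho_p = rho_p)
}
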