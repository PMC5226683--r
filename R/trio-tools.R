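#' Check Mendelian consistency of trio genotypes
#'
#' Flags child genotypes impossible under Mendelian transmission given both
#' parents' dosages. At a biallelic locus each parent transmits at least
#' `1` minor allele when homozygous minor and at most `0` when homozygous
#' major, so the child's dosage must lie in
#' `[ (f==2)+(m==2), 2-(f==0)-(m==0) ]`. Any missing genotype in the trio at
#' a SNP makes that trio x SNP unclassifiable and it is never flagged.
#'
#' @param cohort a `trio_cohort`.
#' @return list with `error_matrix` (logical trios x SNPs), `snp_errors`,
#'   `trio_errors` (integer counts) and `n_errors` (total).
#' @export
mendel_check <- function(cohort) {
  stop_if_not_cohort(cohort)
  f <- cohort$father; m <- cohort$mother; c_ <- cohort$child
  lo <- (f == 2L) + (m == 2L)
  hi <- 2L - (f == 0L) - (m == 0L)
  err <- (c_ < lo) | (c_ > hi)
  err[is.na(err)] <- FALSE
  list(
    error_matrix = err,
    snp_errors = colSums(err),
    trio_errors = rowSums(err),
    n_errors = sum(err)
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the minor-allele count, the probability of
#' each possible heterozygote count is computed by full enumeration and the
#' P-value is the sum of probabilities of configurations no more probable
#' than the observed one (plain exact P, no mid-P).
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom);
#'   vectors are accepted and tested element-wise.
#' @return vector of exact P-values in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n == 0) return(NA_real_)
    n_minor <- 2L * bb + ab
    # heterozygote count shares parity with the minor-allele count
    hets <- seq(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
    # log P(het = h | n, n_minor) up to a constant
    lp <- vapply(hets, function(h) {
      q <- (n_minor - h) / 2  # minor homs
      p <- n - h - q          # major homs
      lfactorial(n) - lfactorial(p) - lfactorial(q) - lfactorial(h) +
        h * log(2)
    }, numeric(1))
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    p_obs <- pr[match(ab, hets)]
    sum(pr[pr <= p_obs * (1 + 1e-9)])
  }, n_aa, n_ab, n_bb)
}

#' Quality-control filter for a trio cohort
#'
#' Removes SNPs with low minor-allele frequency (computed in founders), low
#' call rate, or severe departure from Hardy-Weinberg equilibrium tested in
#' founders only with the exact test. Idempotent: filtering an already
#' filtered cohort removes nothing.
#'
#' @param cohort a `trio_cohort`.
#' @param hwe_p_min remove SNPs with founder HWE exact P below this
#'   (default `1e-6`).
#' @param maf_min minimum founder MAF (default `0.02`); monomorphic SNPs are
#'   always removed.
#' @param call_rate_min minimum genotype call rate over all cohort members.
#' @return list with the filtered `cohort` and a `report` data.frame
#'   (`snp_id`, `maf`, `call_rate`, `hwe_p`, `removed`, `reason`).
#' @export
qc_filter <- function(cohort, hwe_p_min = 1e-6, maf_min = 0.02,
                      call_rate_min = 0.9) {
  stop_if_not_cohort(cohort)
  stopifnot(hwe_p_min > 0, hwe_p_min < 1, maf_min >= 0, maf_min < 1)
  founders <- rbind(cohort$father, cohort$mother)
  n_called <- colSums(!is.na(founders))
  maf <- colSums(founders, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  call_rate <- (colSums(!is.na(cohort$father)) + colSums(!is.na(cohort$mother)) +
    colSums(!is.na(cohort$child))) / (3 * cohort$n_trios)
  n_bb <- colSums(founders == 2L, na.rm = TRUE)
  n_ab <- colSums(founders == 1L, na.rm = TRUE)
  n_aa <- n_called - n_bb - n_ab
  hwe_p <- hwe_exact_test(n_aa, n_ab, n_bb)

  reason <- character(nrow(cohort$snps))
  reason[!is.na(hwe_p) & hwe_p < hwe_p_min] <- "hwe"
  reason[call_rate < call_rate_min] <- "call_rate"
  reason[maf < maf_min | maf == 0] <- "maf"
  removed <- nzchar(reason)
  if (all(removed)) stop("qc_filter removed all SNPs", call. = FALSE)
  report <- data.frame(
    snp_id = cohort$snps$snp_id, maf = maf, call_rate = call_rate,
    hwe_p = hwe_p, removed = removed, reason = reason,
    stringsAsFactors = FALSE
  )
  keep <- which(!removed)
  out <- new_trio_cohort(
    cohort$father[, keep, drop = FALSE], cohort$mother[, keep, drop = FALSE],
    cohort$child[, keep, drop = FALSE], cohort$snps[keep, , drop = FALSE],
    cohort$sex, cohort$affected
  )
  list(cohort = out, report = report)
}

#' Transmission disequilibrium test
#'
#' Counts, over heterozygous parents of affected offspring, the minor alleles
#' transmitted (`b`) versus untransmitted (`c`) and forms the McNemar
#' statistic `chi2 = (b - c)^2 / (b + c)` with a 1-df chi-square P-value.
#' Trios that are Mendel-inconsistent or incomplete at a SNP are excluded at
#' that SNP. For a Mendel-consistent complete trio the transmitted-minor count
#' from heterozygous parents equals `child - #(homozygous-minor parents)`.
#'
#' @param cohort a `trio_cohort`.
#' @param exact also compute an exact binomial P for SNPs with
#'   `b + c < exact_max` and report it in place of the asymptotic one.
#' @param exact_max threshold for the exact option (default 20).
#' @return data.frame `snp_id`, `chr`, `bp`, `b`, `c`, `chisq`, `p`
#'   (`NA` where `b + c = 0`).
#' @export
tdt <- function(cohort, exact = FALSE, exact_max = 20L) {
  stop_if_not_cohort(cohort)
  f <- cohort$father; m <- cohort$mother; c_ <- cohort$child
  ok <- !mendel_check(cohort)$error_matrix & !is.na(f) & !is.na(m) & !is.na(c_)
  trans_minor <- (c_ - (f == 2L) - (m == 2L))
  het <- (f == 1L) + (m == 1L)
  trans_minor[!ok] <- 0L; het[!ok] <- 0L
  b <- colSums(trans_minor)
  c_cnt <- colSums(het) - b
  chisq <- ifelse(b + c_cnt > 0, (b - c_cnt)^2 / (b + c_cnt), NA_real_)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  if (exact) {
    small <- which(!is.na(chisq) & (b + c_cnt) < exact_max)
    for (j in small)
      p[j] <- stats::binom.test(b[j], b[j] + c_cnt[j], 0.5)$p.value
  }
  data.frame(
    snp_id = cohort$snps$snp_id, chr = cohort$snps$chr, bp = cohort$snps$pos,
    b = as.integer(b), c = as.integer(c_cnt), chisq = chisq, p = p,
    stringsAsFactors = FALSE
  )
}

#' Construct pseudo-controls from non-transmitted parental alleles
#'
#' For each trio and SNP the pseudo-control genotype is the multiset of the
#' two parental alleles NOT transmitted to the child, i.e.
#' `father + mother - child` in minor-allele dosage. This is determined for
#' every Mendel-consistent configuration even when transmission phase is
#' ambiguous (double-heterozygous parents), because only the multiset is
#' needed. Mendel-inconsistent or incomplete trio x SNP entries yield `NA`.
#'
#' Conservation identity on complete data:
#' `case dosage + pseudo-control dosage = father dosage + mother dosage`.
#'
#' @param cohort a `trio_cohort`.
#' @return object of class `control_cohort`: `dosage` matrix, `type =
#'   "pseudo_control"`, and `n_excluded` per SNP.
#' @export
make_pseudo_controls <- function(cohort) {
  stop_if_not_cohort(cohort)
  pc <- cohort$father + cohort$mother - cohort$child
  bad <- mendel_check(cohort)$error_matrix
  pc[bad] <- NA_integer_
  structure(list(
    dosage = pc, type = "pseudo_control",
    n_excluded = colSums(is.na(pc))
  ), class = "control_cohort")
}

#' Construct matched-sex parent controls
#'
#' The control genotype for each case is the genotype of the parent of the
#' same sex as the affected child (father for male cases, mother for female
#' cases), a negative-control device against interactions associated with
#' viability rather than disease.
#'
#' @param cohort a `trio_cohort`.
#' @param case_sexes vector of child sexes (1 = male, 2 = female); defaults to
#'   `cohort$sex`. Trios with missing or invalid sex are skipped with a
#'   warning.
#' @return `control_cohort` with `dosage`, `type = "parent_control"` and
#'   `kept` (row indices of the cohort that contributed).
#' @export
make_parent_controls <- function(cohort, case_sexes = NULL) {
  stop_if_not_cohort(cohort)
  sex <- case_sexes %||% cohort$sex
  ok <- !is.na(sex) & sex %in% c(1L, 2L)
  if (!all(ok))
    warning(sum(!ok), " trio(s) skipped for missing/unknown child sex")
  keep <- which(ok)
  dos <- cohort$father[keep, , drop = FALSE]
  fem <- sex[keep] == 2L
  dos[fem, ] <- cohort$mother[keep[fem], , drop = FALSE]
  structure(list(dosage = dos, type = "parent_control", kept = keep),
            class = "control_cohort")
}
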