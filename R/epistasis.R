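#' Collapse two-locus genotypes into an allelic 2x2 table
#'
#' The 4N alleles observed at two loci in N individuals are collapsed into a
#' 2x2 table whose unit of analysis is the allele. With `A`/`B` the major and
#' `a`/`b` the minor alleles, the four cells are
#' \describe{
#'   \item{a}{`4*AABB + 2*AABb + 2*AaBB + AaBb`}
#'   \item{b}{`4*AAbb + 2*AABb + 2*Aabb + AaBb`}
#'   \item{c}{`4*aaBB + 2*aaBb + 2*AaBB + AaBb`}
#'   \item{d}{`4*aabb + 2*aaBb + 2*Aabb + AaBb`}
#' }
#' so `a + b + c + d = 4 * n_complete`. Individuals missing either genotype
#' are dropped (pairwise-complete deletion).
#'
#' @param g1,g2 minor-allele dosage vectors (0/1/2, `NA` missing) of equal
#'   length.
#' @return object of class `allelic_table` with fields `a`, `b`, `c`, `d`
#'   and `n_complete`.
#' @export
allelic_table <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n == 0) stop("no pairwise-complete individuals", call. = FALSE)
  if (any(!(g1 %in% 0:2)) || any(!(g2 %in% 0:2)))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  N <- matrix(0, 3, 3)
  for (j in 0:2) for (k in 0:2) N[j + 1, k + 1] <- sum(g1 == j & g2 == k)
  structure(list(
    a = 4 * N[1, 1] + 2 * N[1, 2] + 2 * N[2, 1] + N[2, 2],
    b = 4 * N[1, 3] + 2 * N[1, 2] + 2 * N[2, 3] + N[2, 2],
    c = 4 * N[3, 1] + 2 * N[3, 2] + 2 * N[2, 1] + N[2, 2],
    d = 4 * N[3, 3] + 2 * N[3, 2] + 2 * N[2, 3] + N[2, 2],
    n_complete = n
  ), class = "allelic_table")
}

# Shared cell arithmetic: Haldane-Anscombe +0.5 on all cells when exactly one
# cell is zero; >= 2 zero cells yield NA (uninformative table).
allelic_z <- function(a, b, c, d) {
  nz <- (a == 0) + (b == 0) + (c == 0) + (d == 0)
  corr <- nz >= 1 & nz < 2
  a <- a + 0.5 * corr; b <- b + 0.5 * corr
  c <- c + 0.5 * corr; d <- d + 0.5 * corr
  bad <- nz >= 2
  log_or <- log(a * d / (b * c))
  v <- 1 / a + 1 / b + 1 / c + 1 / d
  log_or[bad] <- NA_real_; v[bad] <- NA_real_
  list(log_or = log_or, var = v, z = log_or / sqrt(v))
}

#' Case-only allelic test of epistasis
#'
#' Estimates the allelic odds ratio `OR = a*d / (b*c)` with variance
#' `1/a + 1/b + 1/c + 1/d` on the log scale; `z = ln(OR) / sqrt(var)` follows
#' a standard normal distribution under the multiplicative model of no
#' interaction, and P is two-sided. Within affected individuals at unlinked
#' loci, OR deviating from 1 is evidence for epistasis contributing to
#' disease risk.
#'
#' Zero cells: if exactly one cell is zero, 0.5 is added to all four cells
#' (Haldane-Anscombe); with two or more zero cells the test is returned `NA`
#' with a reason.
#'
#' @param table an [allelic_table()].
#' @return data.frame row: `or`, `log_or`, `log_or_var`, `z`, `p`, `reason`.
#' @export
case_only_test <- function(table) {
  stopifnot(inherits(table, "allelic_table"))
  s <- allelic_z(table$a, table$b, table$c, table$d)
  reason <- if (is.na(s$z)) "two or more zero cells" else ""
  data.frame(
    or = exp(s$log_or), log_or = s$log_or, log_or_var = s$var,
    z = s$z, p = 2 * stats::pnorm(-abs(s$z)), reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Case-versus-control allelic test of epistasis
#'
#' The two-group form of the allelic test: the difference of case and control
#' allelic log odds ratios divided by the root of the summed variances,
#' standard normal under no case/control difference in cross-locus allelic
#' association. This is the statistic whose correlation with the logistic
#' regression interaction z is near unity.
#'
#' @param table_case,table_ctrl [allelic_table()]s for cases and controls.
#' @return data.frame row: `log_or_case`, `log_or_ctrl`, `z`, `p`.
#' @export
epistasis_cc_test <- function(table_case, table_ctrl) {
  stopifnot(inherits(table_case, "allelic_table"),
            inherits(table_ctrl, "allelic_table"))
  s1 <- allelic_z(table_case$a, table_case$b, table_case$c, table_case$d)
  s2 <- allelic_z(table_ctrl$a, table_ctrl$b, table_ctrl$c, table_ctrl$d)
  z <- (s1$log_or - s2$log_or) / sqrt(s1$var + s2$var)
  data.frame(log_or_case = s1$log_or, log_or_ctrl = s2$log_or,
             z = z, p = 2 * stats::pnorm(-abs(z)))
}

# 9 genotype-combination count matrices (set SNPs x genome SNPs) by indicator
# cross-products; counts only pairwise-complete individuals.
pair_counts <- function(G_set, G_all) {
  I_set <- lapply(0:2, function(v) dosage_indicator(G_set, v))
  I_all <- lapply(0:2, function(v) dosage_indicator(G_all, v))
  out <- vector("list", 9L)
  for (j in 0:2) for (k in 0:2)
    out[[3 * j + k + 1]] <- crossprod(I_set[[j + 1]], I_all[[k + 1]])
  out
}

#' Set-by-genome case-only epistasis screen
#'
#' Tests every (pathway SNP, genome SNP) pair on different chromosomes with
#' the allelic case-only test. Pairs with `p <= min_p_report` are returned in
#' full; all tests contribute to per-threshold tail counts (for threshold
#' curves and case-vs-control enrichment) so memory stays bounded.
#'
#' @param genotypes dosage matrix (individuals x SNPs), column names = SNP
#'   ids; typically affected children, pseudo-controls or parent controls.
#' @param snps SNP definition table covering every column.
#' @param set_ids character vector of pathway SNP ids (columns of
#'   `genotypes`); `NULL` screens all unordered cross-chromosome pairs
#'   (all-by-all, each pair once).
#' @param min_p_report keep full records for pairs with `p` at or below this
#'   (default `1e-4`).
#' @param alphas thresholds at which tail counts are reported.
#' @return list: `results` (data.frame `snp1`, `snp2`, `a`, `b`, `c`, `d`,
#'   `n_complete`, `or`, `z`, `p`), `n_tests`, `n_na`, and `tail_counts`
#'   (named counts of tests with `p < alpha`).
#' @export
set_by_all_screen <- function(genotypes, snps, set_ids = NULL,
                              min_p_report = 1e-4,
                              alphas = c(1e-2, 1e-3, 1e-4, 1e-5, 1e-6)) {
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)))
  missing_meta <- setdiff(colnames(genotypes), snps$snp_id)
  if (length(missing_meta))
    stop("SNPs absent from metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  all_ids <- colnames(genotypes)
  all_pairs <- is.null(set_ids)
  if (all_pairs) {
    set_ids <- all_ids
  } else {
    absent <- setdiff(set_ids, all_ids)
    if (length(absent))
      stop("set SNPs absent from genotype matrix: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  chr <- snps$chr[match(all_ids, snps$snp_id)]
  chr_set <- snps$chr[match(set_ids, snps$snp_id)]

  N <- pair_counts(genotypes[, set_ids, drop = FALSE], genotypes)
  idx <- function(j, k) N[[3 * j + k + 1]]
  a <- 4 * idx(0, 0) + 2 * idx(0, 1) + 2 * idx(1, 0) + idx(1, 1)
  b <- 4 * idx(0, 2) + 2 * idx(0, 1) + 2 * idx(1, 2) + idx(1, 1)
  c_ <- 4 * idx(2, 0) + 2 * idx(2, 1) + 2 * idx(1, 0) + idx(1, 1)
  d <- 4 * idx(2, 2) + 2 * idx(2, 1) + 2 * idx(1, 2) + idx(1, 1)
  n_complete <- Reduce(`+`, N)

  keep <- outer(chr_set, chr, `!=`)
  if (all_pairs) {
    # count each unordered pair once
    keep <- keep & outer(match(set_ids, all_ids), seq_along(all_ids), `<`)
  }
  s <- allelic_z(a[keep], b[keep], c_[keep], d[keep])
  p <- 2 * stats::pnorm(-abs(s$z))
  n_tests <- length(p)
  n_na <- sum(is.na(p))
  tails <- vapply(alphas, function(al) sum(p < al, na.rm = TRUE), numeric(1))
  names(tails) <- formatC(alphas, format = "e", digits = 0)

  ij <- which(keep, arr.ind = TRUE)
  sel <- which(!is.na(p) & p <= min_p_report)
  results <- data.frame(
    snp1 = set_ids[ij[sel, 1]], snp2 = all_ids[ij[sel, 2]],
    a = a[keep][sel], b = b[keep][sel], c = c_[keep][sel], d = d[keep][sel],
    n_complete = n_complete[keep][sel],
    or = exp(s$log_or[sel]), z = s$z[sel], p = p[sel],
    stringsAsFactors = FALSE
  )
  results <- results[order(results$p), , drop = FALSE]
  rownames(results) <- NULL
  list(results = results, n_tests = n_tests, n_na = n_na,
       tail_counts = tails, alphas = alphas)
}

#' Logistic-regression interaction test (oracle for the allelic screen)
#'
#' Wald z and P for the `g1 x g2` coefficient in
#' `logit(P(case)) ~ g1 + g2 + g1:g2`, the regression benchmark against which
#' the allelic epistasis statistic is calibrated.
#'
#' @param g1,g2 dosage vectors.
#' @param status 0/1 (or logical) case indicator.
#' @return data.frame row: `beta`, `se`, `z`, `p`, `reason` (`NA` fields on
#'   separation or a degenerate design).
#' @export
logistic_interaction_test <- function(g1, g2, status) {
  status <- as.integer(status)
  if (length(unique(status[!is.na(status)])) < 2)
    stop("both case and control statuses are required", call. = FALSE)
  fit <- tryCatch(
    suppressWarnings(stats::glm(status ~ g1 * g2, family = stats::binomial())),
    error = function(e) NULL
  )
  na_row <- data.frame(beta = NA_real_, se = NA_real_, z = NA_real_,
                       p = NA_real_, reason = "degenerate design",
                       stringsAsFactors = FALSE)
  if (is.null(fit)) return(na_row)
  cf <- stats::coef(summary(fit))
  if (!"g1:g2" %in% rownames(cf)) return(na_row)
  est <- cf["g1:g2", ]
  if (est["Std. Error"] > 100) {  # quasi-separation: SE blows up
    na_row$reason <- "separation"
    return(na_row)
  }
  data.frame(beta = est["Estimate"], se = est["Std. Error"],
             z = est["z value"], p = est["Pr(>|z|)"], reason = "",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' 2x2 chi-square enrichment of screen hits in cases versus controls
#'
#' Compares the number of tests meeting a significance threshold in the case
#' screen against the control screen: Pearson chi-square (no continuity
#' correction by default) on `[hits, tests - hits] x [case, control]` and the
#' cross-product odds ratio.
#'
#' @param n_case_hits,n_case_tests,n_ctrl_hits,n_ctrl_tests counts,
#'   `hits <= tests`.
#' @param correct apply Yates continuity correction.
#' @return data.frame row: `or`, `chisq`, `p` (`NA` on a zero margin).
#' @export
enrichment_2x2 <- function(n_case_hits, n_case_tests, n_ctrl_hits,
                           n_ctrl_tests, correct = FALSE) {
  stopifnot(n_case_hits <= n_case_tests, n_ctrl_hits <= n_ctrl_tests)
  m <- matrix(c(n_case_hits, n_case_tests - n_case_hits,
                n_ctrl_hits, n_ctrl_tests - n_ctrl_hits), 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(data.frame(or = NA_real_, chisq = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  data.frame(or = or, chisq = unname(ct$statistic), p = ct$p.value)
}

#' Observed versus expected genotype-combination counts for a SNP pair
#'
#' Tabulates the 3x3 dosage combinations over pairwise-complete individuals
#' and compares them with the counts expected under independence (product of
#' the observed marginal genotype frequencies). The double-heterozygote cell
#' `(1,1)` is the diagnostic one: minor-allele interactions that raise risk
#' inflate it in ascertained cases, while minor-homozygote combinations stay
#' rare.
#'
#' @param g1,g2 dosage vectors.
#' @return list with `observed`, `expected` (3x3 matrices, dosage 0-2) and
#'   `ratio` (observed / expected, `NaN` where expected is 0).
#' @export
genotype_combo_decomposition <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  obs <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  for (j in 0:2) for (k in 0:2) obs[j + 1, k + 1] <- sum(g1 == j & g2 == k)
  expd <- outer(rowSums(obs), colSums(obs)) / max(n, 1L)
  list(observed = obs, expected = expd, ratio = obs / expd)
}

#' Multiple-testing thresholds for a pathway-set epistasis screen
#'
#' The gene-based threshold treats all SNPs in one pathway gene as a single
#' hypothesis: the genome-wide association threshold divided by the number of
#' genes in the set. The genome-wide epistasis threshold additionally accounts
#' for multiple LD groups per gene and the fraction of the genome screened;
#' because those two inputs come from an external LD map, it is exposed as a
#' configurable Bonferroni bound `0.05 / (ld_groups * genome_tests)` or an
#' explicit override (default `7.6e-10`).
#'
#' @param n_set_genes number of genes in the pathway set (>= 1).
#' @param gwas_alpha genome-wide association significance (default `5e-8`).
#' @param genome_wide explicit genome-wide epistasis threshold; overrides the
#'   `ld_groups`/`genome_tests` computation.
#' @param ld_groups,genome_tests optional inputs for
#'   `0.05 / (ld_groups * genome_tests)` when no override is given.
#' @return list `gene_based`, `genome_wide`, `gwas_alpha`, `n_set_genes`.
#' @export
compute_thresholds <- function(n_set_genes, gwas_alpha = 5e-8,
                               genome_wide = NULL, ld_groups = NULL,
                               genome_tests = NULL) {
  stopifnot(n_set_genes >= 1)
  gw <- if (!is.null(genome_wide)) genome_wide
        else if (!is.null(ld_groups) && !is.null(genome_tests))
          0.05 / (ld_groups * genome_tests)
        else 7.6e-10
  list(gene_based = gwas_alpha / n_set_genes, genome_wide = gw,
       gwas_alpha = gwas_alpha, n_set_genes = n_set_genes)
}

#' Power to detect a squared cross-locus correlation
#'
#' Power of the case-only design viewed as a correlation test: analytic form
#' via the Fisher z transform with noncentrality
#' `delta = sqrt(n - 3) * atanh(sqrt(r2))`,
#' `power = pnorm(delta - z_{1-alpha/2}) + pnorm(-delta - z_{1-alpha/2})`
#' (both rejection tails, so the null limit `r2 -> 0` recovers `alpha`),
#' or Monte-Carlo simulation of bivariate-normal replicates tested at `alpha`.
#'
#' @param n sample size.
#' @param r2 squared correlation to detect, in (0, 1).
#' @param alpha two-sided significance threshold.
#' @param method `"analytic"` (default) or `"simulation"`.
#' @param n_rep simulation replicates.
#' @param seed seed for the simulation path.
#' @return power in `[0, 1]`.
#' @export
power_correlation <- function(n, r2, alpha, method = c("analytic", "simulation"),
                              n_rep = 2000L, seed = 1L) {
  stopifnot(r2 > 0, r2 < 1, alpha > 0, alpha < 1, n > 3)
  method <- match.arg(method)
  if (method == "analytic") {
    delta <- sqrt(n - 3) * atanh(sqrt(r2))
    crit <- stats::qnorm(1 - alpha / 2)
    return(stats::pnorm(delta - crit) + stats::pnorm(-delta - crit))
  }
  set.seed(seed)
  rho <- sqrt(r2)
  crit <- stats::qnorm(1 - alpha / 2)
  hits <- vapply(seq_len(n_rep), function(i) {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - r2) * stats::rnorm(n)
    abs(atanh(stats::cor(x, y))) * sqrt(n - 3) > crit
  }, logical(1))
  mean(hits)
}
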