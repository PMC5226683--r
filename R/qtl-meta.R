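#' Within-group trait scaling with outlier exclusion
#'
#' Scales scores to mean 0 and variance 1 within each group, excludes values
#' more than `sd_limit` SDs from the mean (applied once, no iteration), and by
#' default re-scales the remaining values once so the mean-0/variance-1
#' contract holds after exclusion.
#'
#' @param scores numeric vector of trait scores (e.g. sex-normalized T-scores).
#' @param group optional group factor; scaling is per group.
#' @param sd_limit exclusion threshold in SD units (default 3).
#' @param rescale re-scale once after exclusion (default `TRUE`).
#' @return data.frame `score` (scaled, `NA` for excluded), `excluded`
#'   (logical), `group`.
#' @export
scale_trait <- function(scores, group = NULL, sd_limit = 3, rescale = TRUE) {
  group <- group %||% rep("all", length(scores))
  out <- data.frame(score = NA_real_, excluded = FALSE, group = group,
                    stringsAsFactors = FALSE)
  for (g in unique(group)) {
    idx <- which(group == g)
    x <- scores[idx]
    if (sum(!is.na(x)) < 2 || stats::sd(x, na.rm = TRUE) == 0)
      stop("group '", g, "' has fewer than 2 values or zero variance",
           call. = FALSE)
    zscore <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    z <- zscore(x)
    excl <- !is.na(z) & abs(z) > sd_limit
    z[excl] <- NA_real_
    if (rescale && any(excl)) z <- zscore(z)
    out$score[idx] <- z
    out$excluded[idx] <- excl
  }
  out
}

#' Quantitative-trait linear regression for one SNP
#'
#' OLS fit of `trait ~ dosage + covariates`; reports the additive dosage
#' coefficient with its two-sided t-test P-value.
#'
#' @param y scaled trait scores (`NA`s dropped casewise).
#' @param g minor-allele dosage vector.
#' @param covs matrix or data.frame of covariates (default none).
#' @return data.frame row: `beta`, `se`, `p`, `n`, `reason` (`NA` fields when
#'   the dosage is constant or the design is rank deficient).
#' @export
qtl_regress <- function(y, g, covs = NULL) {
  X <- if (is.null(covs)) data.frame(g = g)
       else data.frame(g = g, covs)
  ok <- stats::complete.cases(X) & !is.na(y)
  na_row <- function(reason)
    data.frame(beta = NA_real_, se = NA_real_, p = NA_real_, n = sum(ok),
               reason = reason, stringsAsFactors = FALSE)
  if (sum(ok) < ncol(X) + 2) return(na_row("insufficient observations"))
  if (stats::var(X$g[ok]) == 0) return(na_row("constant dosage"))
  fit <- stats::lm(y ~ ., data = X, subset = ok)
  cf <- stats::coef(summary(fit))
  if (!"g" %in% rownames(cf) || anyNA(stats::coef(fit)))
    return(na_row("rank-deficient design"))
  data.frame(beta = cf["g", "Estimate"], se = cf["g", "Std. Error"],
             p = cf["g", "Pr(>|t|)"], n = sum(ok), reason = "",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-group QTL scan of a simulated or loaded quantitative-trait dataset
#'
#' Convenience wrapper: scales the trait within groups ([scale_trait()]) and
#' runs [qtl_regress()] per group for each dosage column.
#'
#' @param data data.frame with `group`, `trait`, dosage columns and covariate
#'   columns `cov1..covk` (as produced by [simulate_qtl()]).
#' @param snp_cols names of the dosage columns to test.
#' @param cov_cols names of covariate columns (default all `cov*` columns).
#' @param sd_limit,rescale passed to [scale_trait()].
#' @return data.frame: one row per group x SNP with `group`, `snp`, `beta`,
#'   `se`, `p`, `n`.
#' @export
qtl_scan <- function(data, snp_cols = "snp1", cov_cols = NULL, sd_limit = 3,
                     rescale = TRUE) {
  cov_cols <- cov_cols %||% grep("^cov", names(data), value = TRUE)
  sc <- scale_trait(data$trait, data$group, sd_limit = sd_limit,
                    rescale = rescale)
  rows <- list()
  for (g in unique(data$group)) {
    idx <- which(data$group == g)
    for (s in snp_cols) {
      fit <- qtl_regress(sc$score[idx], data[[s]][idx],
                         if (length(cov_cols)) data[idx, cov_cols, drop = FALSE])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(group = g, snp = s, stringsAsFactors = FALSE),
        fit[, c("beta", "se", "p", "n")]
      )
    }
  }
  do.call(rbind, rows)
}

# Profile log-likelihood pieces for the RE2 likelihood-ratio test.
re2_loglik <- function(tau2, beta, v, mu = NULL) {
  w <- 1 / (v + tau2)
  if (is.null(mu)) mu <- sum(w * beta) / sum(w)
  sum(0.5 * log(w) - 0.5 * w * (beta - mu)^2)
}

#' Random-effects meta-analysis across groups (fixed effects, Cochran's Q,
#' Han-Eskin RE2)
#'
#' Inverse-variance fixed-effects pooling with Cochran's Q heterogeneity
#' (chi-square, df = k - 1) and the Han-Eskin RE2 likelihood-ratio statistic
#' jointly testing zero mean effect and zero heterogeneity
#' (`H0: mu = 0, tau2 = 0` vs free `mu, tau2`), with the asymptotic null
#' `0.5 * chisq(1) + 0.5 * chisq(2)` mixture. Tabulated small-k critical
#' values are not applied.
#'
#' @param beta per-group effect estimates.
#' @param se per-group standard errors (finite, > 0).
#' @return list: `beta_fe`, `se_fe`, `p_fe`, `q`, `q_df`, `q_p`, `tau2`,
#'   `re2_stat`, `re2_p`, `k`. With a single group the fixed-effects fields
#'   are returned and `q`/`re2` are `NA`.
#' @export
meta_analyze <- function(beta, se) {
  ok <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[ok]; se <- se[ok]
  k <- length(beta)
  if (k == 0) stop("no groups with finite effect and se", call. = FALSE)
  w <- 1 / se^2
  beta_fe <- sum(w * beta) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  p_fe <- 2 * stats::pnorm(-abs(beta_fe / se_fe))
  if (k == 1)
    return(list(beta_fe = beta_fe, se_fe = se_fe, p_fe = p_fe,
                q = NA_real_, q_df = NA_integer_, q_p = NA_real_,
                tau2 = NA_real_, re2_stat = NA_real_, re2_p = NA_real_, k = k))
  q <- sum(w * (beta - beta_fe)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  v <- se^2
  # ML of tau2 under the free model (profile over mu)
  upper <- max(stats::var(beta) * 5, max(v) * 5, 1e-6)
  opt <- stats::optimize(function(t2) re2_loglik(t2, beta, v),
                         interval = c(0, upper), maximum = TRUE)
  ll0 <- re2_loglik(0, beta, v, mu = 0)
  tau2 <- if (opt$objective > re2_loglik(0, beta, v)) opt$maximum else 0
  ll1 <- max(opt$objective, re2_loglik(0, beta, v))
  stat <- max(0, 2 * (ll1 - ll0))
  re2_p <- 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(stat, 2, lower.tail = FALSE)
  list(beta_fe = beta_fe, se_fe = se_fe, p_fe = p_fe,
       q = q, q_df = k - 1L, q_p = q_p,
       tau2 = tau2, re2_stat = stat, re2_p = re2_p, k = k)
}

#' Meta-analyze a per-group QTL scan across disorder groups
#'
#' Runs [meta_analyze()] per SNP over the named disorder groups of a
#' [qtl_scan()] table.
#'
#' @param scan output of [qtl_scan()].
#' @param groups groups to pool (default: all groups in `scan`).
#' @return data.frame: per SNP `snp`, `beta_fe`, `se_fe`, `p_fe`, `q`, `q_p`,
#'   `re2_stat`, `re2_p`, `best_group` (smallest per-group P) and
#'   `supporting_groups` (same effect sign as the best group, comma-joined).
#' @export
meta_scan <- function(scan, groups = NULL) {
  groups <- groups %||% unique(scan$group)
  rows <- lapply(unique(scan$snp), function(s) {
    sub <- scan[scan$snp == s & scan$group %in% groups, , drop = FALSE]
    m <- meta_analyze(sub$beta, sub$se)
    ok <- !is.na(sub$p)
    best <- if (any(ok)) sub$group[ok][which.min(sub$p[ok])] else NA_character_
    supp <- if (!is.na(best)) {
      sgn <- sign(sub$beta[sub$group == best])
      sub$group[!is.na(sub$beta) & sign(sub$beta) == sgn]
    } else character(0)
    data.frame(snp = s, beta_fe = m$beta_fe, se_fe = m$se_fe, p_fe = m$p_fe,
               q = m$q, q_p = m$q_p, re2_stat = m$re2_stat, re2_p = m$re2_p,
               best_group = best,
               supporting_groups = paste(supp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sibling-control contrast for modifier candidates
#'
#' Annotates meta-analysis candidates with the sibling-group association:
#' a modifier of the disorder phenotype should associate in the disorder
#' groups but not in unaffected siblings. SNPs whose sibling P-value falls
#' below `sibling_alpha` are flagged non-specific.
#'
#' @param meta output of [meta_scan()].
#' @param sibling_assoc data.frame `snp`, `beta`, `se`, `p` for the sibling
#'   group (e.g. the sibling rows of a [qtl_scan()]).
#' @param p_threshold report SNPs with meta (RE2) P at or below this
#'   (default `1e-4`).
#' @param sibling_alpha non-specificity flag threshold (default 0.05).
#' @return data.frame of candidates: meta columns plus `sibling_beta`,
#'   `sibling_p`, `specific`.
#' @export
sibling_contrast <- function(meta, sibling_assoc, p_threshold = 1e-4,
                             sibling_alpha = 0.05) {
  idx <- match(meta$snp, sibling_assoc$snp)
  out <- meta
  out$sibling_beta <- sibling_assoc$beta[idx]
  out$sibling_p <- sibling_assoc$p[idx]
  out$specific <- is.na(out$sibling_p) | out$sibling_p > sibling_alpha
  keep <- !is.na(out$re2_p) & out$re2_p <= p_threshold
  out[keep, , drop = FALSE]
}
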