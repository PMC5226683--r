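#' Define a panel of unlinked biallelic SNPs
#'
#' Builds the per-SNP metadata table used throughout the package: SNP id,
#' chromosome, 1-based position, minor-allele frequency and allele labels.
#' Positions are strictly increasing within a chromosome; loci are treated as
#' unlinked everywhere (the epistasis screen discards same-chromosome pairs).
#'
#' @param n_snps number of SNPs.
#' @param maf minor-allele frequencies, recycled to length `n_snps`; each must
#'   lie in (0, 0.5].
#' @param chromosomes chromosome assignment (integers 1-22), recycled; default
#'   spreads SNPs across all 22 autosomes in round-robin order.
#' @param spacing base-pair gap between consecutive SNPs on a chromosome.
#' @param prefix prefix for generated SNP ids.
#' @return data.frame with columns `snp_id`, `chr`, `pos`, `a1` (minor), `a2`
#'   (major), `maf`.
#' @export
make_snp_defs <- function(n_snps, maf = 0.3, chromosomes = NULL,
                          spacing = 10000L, prefix = "rs") {
  stopifnot(n_snps >= 1)
  maf <- rep_len(maf, n_snps)
  if (any(maf <= 0 | maf > 0.5))
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  chr <- if (is.null(chromosomes)) ((seq_len(n_snps) - 1L) %% 22L) + 1L
         else rep_len(as.integer(chromosomes), n_snps)
  if (any(chr < 1L | chr > 22L))
    stop("chromosomes must be autosomes 1-22", call. = FALSE)
  pos <- integer(n_snps)
  for (c_ in unique(chr)) {
    idx <- which(chr == c_)
    pos[idx] <- seq_along(idx) * spacing
  }
  data.frame(
    snp_id = paste0(prefix, seq_len(n_snps)),
    chr = chr, pos = pos,
    a1 = "a", a2 = "A",
    maf = maf,
    stringsAsFactors = FALSE
  )
}

#' Specify a logistic disease risk model for trio simulation
#'
#' The affection status of an offspring with minor-allele dosages `g` is
#' Bernoulli with probability
#' `plogis(intercept + sum(main * g) + sum(interaction * g1 * g2))`.
#' Interaction pairs must lie on different chromosomes: the case-only design
#' interprets cross-chromosome allelic correlation in affected individuals as
#' epistasis, so the generator never places interacting loci in linkage.
#'
#' @param snps SNP definition table (see [make_snp_defs()]).
#' @param intercept baseline log-odds of disease (controls prevalence and,
#'   under ascertainment, the rejection-sampling acceptance rate).
#' @param main named numeric vector of per-minor-allele log odds ratios,
#'   names are SNP ids; missing SNPs get effect 0.
#' @param interaction data.frame with columns `snp1`, `snp2`, `beta` giving
#'   log odds ratios per product of minor-allele dosages.
#' @return object of class `risk_model`.
#' @export
risk_model <- function(snps, intercept = -4, main = NULL, interaction = NULL) {
  main <- main %||% numeric(0)
  if (length(main) && !all(names(main) %in% snps$snp_id))
    stop("main effects reference unknown SNP ids: ",
         paste(setdiff(names(main), snps$snp_id), collapse = ", "), call. = FALSE)
  if (!is.null(interaction) && nrow(interaction)) {
    bad <- !(interaction$snp1 %in% snps$snp_id) | !(interaction$snp2 %in% snps$snp_id)
    if (any(bad)) stop("interaction terms reference unknown SNP ids", call. = FALSE)
    chr1 <- snps$chr[match(interaction$snp1, snps$snp_id)]
    chr2 <- snps$chr[match(interaction$snp2, snps$snp_id)]
    if (any(chr1 == chr2))
      stop("interaction pairs must be on different chromosomes", call. = FALSE)
  }
  structure(list(intercept = intercept, main = main,
                 interaction = interaction),
            class = "risk_model")
}

risk_eta <- function(model, G, snps) {
  eta <- rep(model$intercept, nrow(G))
  if (length(model$main)) {
    j <- match(names(model$main), snps$snp_id)
    g <- G[, j, drop = FALSE]
    g[is.na(g)] <- 0
    eta <- eta + as.vector(g %*% model$main)
  }
  if (!is.null(model$interaction) && nrow(model$interaction)) {
    j1 <- match(model$interaction$snp1, snps$snp_id)
    j2 <- match(model$interaction$snp2, snps$snp_id)
    for (k in seq_along(j1)) {
      g1 <- G[, j1[k]]; g2 <- G[, j2[k]]
      g1[is.na(g1)] <- 0; g2[is.na(g2)] <- 0
      eta <- eta + model$interaction$beta[k] * g1 * g2
    }
  }
  eta
}

new_trio_cohort <- function(father, mother, child, snps, sex, affected) {
  stopifnot(all(dim(father) == dim(mother)), all(dim(father) == dim(child)),
            ncol(father) == nrow(snps))
  colnames(father) <- colnames(mother) <- colnames(child) <- snps$snp_id
  structure(list(
    father = father, mother = mother, child = child,
    snps = snps, sex = sex, affected = affected,
    n_trios = nrow(child)
  ), class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("trio_cohort:", x$n_trios, "trios x", nrow(x$snps), "SNPs on",
      length(unique(x$snps$chr)), "chromosome(s)\n")
  invisible(x)
}

sample_founders <- function(n, maf) {
  m <- length(maf)
  matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
}

# One transmitted allele per parent: homozygotes are forced, heterozygotes
# transmit the minor allele with probability 1/2.
transmit <- function(G) {
  t_ <- matrix(0L, nrow(G), ncol(G))
  t_[G == 2L] <- 1L
  het <- which(G == 1L)
  t_[het] <- stats::rbinom(length(het), 1L, 0.5)
  t_
}

#' Simulate a case-parent trio cohort
#'
#' Parents are drawn from Hardy-Weinberg equilibrium at each SNP independently
#' (unlinked loci); the child receives one allele per parent by Mendelian
#' transmission. With `ascertain = TRUE`, complete trios are rejection-sampled
#' until the child is affected under the logistic [risk_model()], emulating a
#' study that recruits affected offspring with both parents.
#'
#' @param n_trios number of trios to return.
#' @param snps SNP definition table ([make_snp_defs()]).
#' @param model [risk_model()]; default is a null model (no genetic effects).
#' @param ascertain keep only trios whose child is affected.
#' @param seed integer seed; the same seed and configuration reproduce the
#'   cohort exactly.
#' @param missing_rate proportion of genotypes set missing at random
#'   (independently in fathers, mothers and children), for QC testing.
#' @param max_attempts abort with a diagnostic if more than
#'   `max_attempts * n_trios` candidate trios are drawn without filling the
#'   cohort (non-invertible ascertainment).
#' @param child_sex vector of child sexes (1 = male, 2 = female) or `NULL` to
#'   draw them uniformly.
#' @return a `trio_cohort`: dosage matrices `father`, `mother`, `child`
#'   (minor-allele counts 0/1/2, `NA` = missing), `snps`, child `sex`, and
#'   `affected` flags (all `TRUE` under ascertainment).
#' @export
simulate_trios <- function(n_trios, snps, model = NULL, ascertain = FALSE,
                           seed = 1L, missing_rate = 0, max_attempts = 1e6,
                           child_sex = NULL) {
  stopifnot(n_trios >= 1)
  if (any(snps$maf <= 0 | snps$maf > 0.5))
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  model <- model %||% risk_model(snps, intercept = 0)
  set.seed(seed)
  m <- nrow(snps)

  fa <- mo <- ch <- matrix(NA_integer_, 0L, m)
  aff <- logical(0)
  attempts <- 0
  batch <- max(n_trios, 1000L)
  repeat {
    need <- n_trios - nrow(ch)
    if (need <= 0) break
    nb <- if (ascertain) batch else need
    f <- sample_founders(nb, snps$maf)
    m_ <- sample_founders(nb, snps$maf)
    c_ <- transmit(f) + transmit(m_)
    eta <- risk_eta(model, c_, snps)
    affected <- stats::runif(nb) < stats::plogis(eta)
    attempts <- attempts + nb
    keep <- if (ascertain) which(affected) else seq_len(nb)
    if (length(keep) > need) keep <- keep[seq_len(need)]
    fa <- rbind(fa, f[keep, , drop = FALSE])
    mo <- rbind(mo, m_[keep, , drop = FALSE])
    ch <- rbind(ch, c_[keep, , drop = FALSE])
    aff <- c(aff, affected[keep])
    if (ascertain && attempts > max_attempts * n_trios)
      stop(sprintf(paste0("ascertainment acceptance probability ~%.2e after %d ",
                          "attempts; raise the model intercept or max_attempts"),
                   nrow(ch) / attempts, attempts), call. = FALSE)
    if (ascertain) batch <- min(2L * batch, 200000L)
  }

  if (missing_rate > 0) {
    drop_at <- function(G) {
      G[stats::runif(length(G)) < missing_rate] <- NA_integer_
      G
    }
    fa <- drop_at(fa); mo <- drop_at(mo); ch <- drop_at(ch)
  }
  sex <- child_sex %||% sample(1:2, n_trios, replace = TRUE)
  new_trio_cohort(fa, mo, ch, snps, sex = rep_len(sex, n_trios), affected = aff)
}

#' Simulate a multi-group quantitative-trait dataset
#'
#' Emulates a modifier-QTL study: several disorder groups plus an unaffected
#' sibling group, a quantitative trait score, one candidate SNP with
#' group-specific additive effects, optional extra null SNPs, and covariates
#' (ancestry-component stand-ins) with a configurable trait loading.
#' `trait = group_mean + effect[group] * dosage + loading * covariates + noise`.
#'
#' @param group_sizes named integer vector, e.g.
#'   `c(CFC = 60, CS = 40, NF1 = 120, NS = 60, SIB = 140)`.
#' @param snp_effects named numeric vector of per-group additive effects for
#'   the causal SNP (trait units per minor allele); groups not named get 0 —
#'   by default the sibling group, so it serves as the negative contrast.
#' @param heterogeneity SD of an extra group-level random effect added to each
#'   named group's slope, to create Cochran's-Q-positive scenarios.
#' @param noise_sd residual SD (> 0).
#' @param maf minor allele frequency of every simulated SNP.
#' @param n_null_snps extra SNPs with no trait effect.
#' @param n_covariates number of standard-normal covariates.
#' @param covariate_loading common loading of each covariate on the trait.
#' @param group_means named numeric vector of group trait means (default 0).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `group`, dosage columns (`snp1` causal,
#'   `null1..`), `trait`, covariates `cov1..covk`; the realized per-group
#'   slopes are stored in `attr(, "effects")`.
#' @export
simulate_qtl <- function(group_sizes, snp_effects = NULL, heterogeneity = 0,
                         noise_sd = 1, maf = 0.3, n_null_snps = 0,
                         n_covariates = 5, covariate_loading = 0,
                         group_means = NULL, seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector", call. = FALSE)
  if (any(group_sizes < 1)) stop("empty group", call. = FALSE)
  stopifnot(noise_sd > 0)
  set.seed(seed)
  groups <- names(group_sizes)
  eff <- stats::setNames(rep(0, length(groups)), groups)
  if (!is.null(snp_effects)) eff[names(snp_effects)] <- snp_effects
  if (heterogeneity > 0 && !is.null(snp_effects)) {
    hit <- names(snp_effects)
    eff[hit] <- eff[hit] + stats::rnorm(length(hit), 0, heterogeneity)
  }
  mu <- stats::setNames(rep(0, length(groups)), groups)
  if (!is.null(group_means)) mu[names(group_means)] <- group_means

  n <- sum(group_sizes)
  grp <- rep(groups, times = group_sizes)
  k_snp <- 1L + n_null_snps
  G <- matrix(stats::rbinom(n * k_snp, 2L, maf), n, k_snp)
  colnames(G) <- c("snp1", if (n_null_snps > 0) paste0("null", seq_len(n_null_snps)))
  covs <- matrix(stats::rnorm(n * n_covariates), n, n_covariates)
  colnames(covs) <- paste0("cov", seq_len(n_covariates))
  trait <- mu[grp] + eff[grp] * G[, "snp1"] +
    covariate_loading * rowSums(covs) + stats::rnorm(n, 0, noise_sd)
  out <- data.frame(sample_id = paste0("S", seq_len(n)), group = grp,
                    G, trait = as.numeric(trait), covs,
                    stringsAsFactors = FALSE)
  attr(out, "effects") <- eff
  out
}

#' Generate a synthetic gene universe with a SNP map
#'
#' Stand-in for a transcriptome-wide gene list (longest-transcript lengths)
#' used by the length-matched permutation null: genes with log-normal lengths
#' placed without overlap along 22 autosomes, and SNPs assigned uniformly at a
#' configurable density.
#'
#' @param n_genes number of genes.
#' @param mean_log_length,sd_log_length parameters of the log-normal length
#'   distribution (defaults give a median of ~20 kb).
#' @param snp_density expected SNPs per base pair (default 1 per kb).
#' @param gap_mean mean exponential gap between adjacent genes, bp.
#' @param chrom_length length of each autosome, bp; an error is raised if the
#'   draw does not fit.
#' @param seed integer seed; the same seed reproduces the universe exactly.
#' @return list with `genes` (data.frame `gene`, `chr`, `start`, `end`,
#'   `tx_length`) and `snps` (a SNP definition table; MAFs uniform 0.05-0.5).
#' @export
make_gene_universe <- function(n_genes, mean_log_length = log(2e4),
                               sd_log_length = 0.6, snp_density = 1e-3,
                               gap_mean = 5e3, chrom_length = 1.5e8,
                               seed = 1L) {
  stopifnot(n_genes >= 1, snp_density >= 0)
  set.seed(seed)
  len <- pmax(200L, as.integer(round(stats::rlnorm(n_genes, mean_log_length,
                                                   sd_log_length))))
  chr <- ((seq_len(n_genes) - 1L) %% 22L) + 1L
  start <- integer(n_genes)
  for (c_ in 1:22) {
    idx <- which(chr == c_)
    if (!length(idx)) next
    gaps <- as.integer(round(stats::rexp(length(idx), 1 / gap_mean))) + 1L
    s <- cumsum(gaps + c(0L, len[idx[-length(idx)]]))
    start[idx] <- s
    if (s[length(s)] + len[idx[length(idx)]] > chrom_length)
      stop("genome too small to place genes without overlap; increase ",
           "chrom_length or reduce n_genes", call. = FALSE)
  }
  genes <- data.frame(
    gene = paste0("G", seq_len(n_genes)), chr = chr,
    start = start, end = start + len, tx_length = len,
    stringsAsFactors = FALSE
  )
  # SNPs uniform along the covered span of each chromosome
  snps_list <- lapply(1:22, function(c_) {
    span <- max(genes$end[genes$chr == c_], 0L) + 10000L
    n_snp <- stats::rpois(1, snp_density * span)
    if (n_snp == 0) return(NULL)
    data.frame(chr = c_, pos = sort(sample.int(span, n_snp)))
  })
  snp_pos <- do.call(rbind, snps_list)
  if (is.null(snp_pos) || !nrow(snp_pos)) {
    snps <- make_snp_defs(1, maf = 0.3)[0, ]
  } else {
    snps <- data.frame(
      snp_id = paste0("u", seq_len(nrow(snp_pos))),
      chr = snp_pos$chr, pos = snp_pos$pos,
      a1 = "a", a2 = "A",
      maf = stats::runif(nrow(snp_pos), 0.05, 0.5),
      stringsAsFactors = FALSE
    )
  }
  list(genes = genes, snps = snps)
}
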