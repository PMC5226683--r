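#' SNPs within a flank of a gene set
#'
#' A SNP belongs to the set if its position lies in the closed interval
#' `[start - flank, end + flank]` of any set gene on the same chromosome
#' (1-based coordinates). SNPs covered by several genes are counted once.
#'
#' @param snps SNP definition table (`snp_id`, `chr`, `pos`).
#' @param genes data.frame `gene`, `chr`, `start`, `end` (1-based, closed).
#' @param flank flank in bp (default 5000).
#' @return character vector of SNP ids (unique, in map order); empty with a
#'   warning if nothing falls in the set.
#' @export
snps_in_set <- function(snps, genes, flank = 5000L) {
  stopifnot(all(genes$start < genes$end))
  hit <- rep(FALSE, nrow(snps))
  for (i in seq_len(nrow(genes))) {
    hit <- hit | (snps$chr == genes$chr[i] &
                    snps$pos >= genes$start[i] - flank &
                    snps$pos <= genes$end[i] + flank)
  }
  ids <- snps$snp_id[hit]
  if (!length(ids)) warning("no SNPs fall within the gene set (+/- flank)")
  ids
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{j >= i} p_(j) * m / j` over the ascending order statistics,
#' mapped back to the input order; `NA` P-values propagate to `NA` q-values
#' and do not count toward `m`.
#'
#' @param p vector of P-values in `[0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Length-matched permuted gene sets
#'
#' For each target gene, the candidate pool is the `k_nearest` universe genes
#' closest in longest-transcript length (target genes themselves excluded;
#' ties broken by `(|length difference|, gene name)` for determinism) and one
#' candidate is drawn uniformly — without replacement within a permuted set,
#' independently across permutations.
#'
#' @param universe data.frame `gene`, `tx_length` (plus any interval columns,
#'   carried through).
#' @param target data.frame of target genes (`gene`, `tx_length`).
#' @param n_perm number of permuted sets (default 100).
#' @param k_nearest pool size per target gene (default 100).
#' @param seed integer seed; fixed seed reproduces identical sets.
#' @return list of `n_perm` data.frames shaped like `universe` rows.
#' @export
permuted_sets <- function(universe, target, n_perm = 100L, k_nearest = 100L,
                          seed = 1L) {
  pool_universe <- universe[!(universe$gene %in% target$gene), , drop = FALSE]
  if (nrow(pool_universe) < k_nearest + nrow(target))
    stop("gene universe too small: need at least k_nearest + |target| ",
         "non-target genes", call. = FALSE)
  pools <- lapply(seq_len(nrow(target)), function(i) {
    d <- abs(pool_universe$tx_length - target$tx_length[i])
    ord <- order(d, pool_universe$gene)
    ord[seq_len(k_nearest)]
  })
  set.seed(seed)
  lapply(seq_len(n_perm), function(b) {
    chosen <- integer(0)
    for (pool in pools) {
      avail <- setdiff(pool, chosen)
      if (!length(avail))
        stop("candidate pool exhausted; increase k_nearest", call. = FALSE)
      pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
      chosen <- c(chosen, pick)
    }
    pool_universe[chosen, , drop = FALSE]
  })
}

#' Permutation enrichment of set association at an FDR threshold
#'
#' Computes the percentage of set SNPs with BH q-value at or below
#' `q_threshold` in an association table, the same percentage for each
#' permuted SNP set, and the empirical P-value: the proportion of permuted
#' percentages greater than or equal to the observed one. With `n_perm`
#' permutations the resolution is `1/n_perm`; an observed percentage above
#' every permutation is reported as `p_label = "<1/n_perm"`.
#'
#' @param assoc data.frame with `snp_id` and `p` (e.g. [tdt()] output).
#' @param target_snp_ids SNP ids of the pathway set.
#' @param permuted_snp_ids list of SNP-id vectors, one per permuted set.
#' @param q_threshold BH FDR threshold (default 0.2).
#' @param fdr_scope `"set"` applies BH within each set separately (each set
#'   analyzed with the same protocol); `"global"` computes q-values once over
#'   the whole association table.
#' @return list: `observed_pct`, `permutation_pcts`, `empirical_p`, `p_label`,
#'   `q_threshold`, `n_perm`.
#' @export
enrichment_test <- function(assoc, target_snp_ids, permuted_snp_ids,
                            q_threshold = 0.2,
                            fdr_scope = c("set", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  if (!length(target_snp_ids)) stop("empty target SNP set", call. = FALSE)
  if (!length(permuted_snp_ids)) stop("at least one permuted set required",
                                      call. = FALSE)
  pct_for <- function(ids) {
    idx <- match(ids, assoc$snp_id)
    if (anyNA(idx))
      stop("association table does not cover SNPs: ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    p <- assoc$p[idx]
    q <- if (fdr_scope == "set") bh_fdr(p) else assoc$q_global[idx]
    100 * mean(q <= q_threshold, na.rm = TRUE)
  }
  if (fdr_scope == "global") assoc$q_global <- bh_fdr(assoc$p)
  observed <- pct_for(target_snp_ids)
  perms <- vapply(permuted_snp_ids, pct_for, numeric(1))
  emp <- mean(perms >= observed)
  list(
    observed_pct = observed, permutation_pcts = perms, empirical_p = emp,
    p_label = if (emp == 0) paste0("<", format(1 / length(perms))) else
      format(emp),
    q_threshold = q_threshold, n_perm = length(perms)
  )
}
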