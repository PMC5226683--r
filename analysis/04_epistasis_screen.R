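#!/usr/bin/env Rscript
# Stage 4: the case-only set-by-genome epistasis screen.
#
# Runs the allelic screen in affected children, repeats it in pseudo-controls
# (non-transmitted alleles) and matched-sex parent controls, compares hit
# counts with a 2x2 chi-square at several thresholds, and decomposes the top
# pair into genotype-combination O/E counts.

suppressPackageStartupMessages(library(epitrio))
out <- "results/analysis"

cohort <- read_ped_map(file.path(out, "trios.ped"), file.path(out, "trios.map"))
qc <- qc_filter(cohort)
cohort <- qc$cohort
set_ids <- intersect(
  utils::read.delim(file.path(out, "pathway_set.tsv"))$snp_id,
  cohort$snps$snp_id)

pseudo <- make_pseudo_controls(cohort)
parent <- make_parent_controls(cohort)

alphas <- c(1e-2, 1e-3, 1e-4, 1e-5, 1e-6)
scr_case <- set_by_all_screen(cohort$child, cohort$snps, set_ids,
                              min_p_report = 1e-3, alphas = alphas)
scr_pseudo <- set_by_all_screen(pseudo$dosage, cohort$snps, set_ids,
                                min_p_report = 1e-3, alphas = alphas)
scr_parent <- set_by_all_screen(parent$dosage, cohort$snps, set_ids,
                                min_p_report = 1e-3, alphas = alphas)

write_tsv(scr_case$results, file.path(out, "episcan_cases.tsv"))
write_tsv(scr_pseudo$results, file.path(out, "episcan_pseudo.tsv"))
write_tsv(scr_parent$results, file.path(out, "episcan_parent.tsv"))
message("screen: ", scr_case$n_tests, " cross-chromosome pairs per group")

th <- compute_thresholds(n_set_genes = 17)
message(sprintf("thresholds: gene-based %.2g, genome-wide %.2g",
                th$gene_based, th$genome_wide))

curve <- do.call(rbind, lapply(seq_along(alphas), function(k) {
  e_ps <- enrichment_2x2(scr_case$tail_counts[k], scr_case$n_tests,
                         scr_pseudo$tail_counts[k], scr_pseudo$n_tests)
  data.frame(alpha = alphas[k],
             case_hits = scr_case$tail_counts[k],
             pseudo_hits = scr_pseudo$tail_counts[k],
             parent_hits = scr_parent$tail_counts[k],
             or_vs_pseudo = e_ps$or, chi2 = e_ps$chisq, p = e_ps$p)
}))
write_tsv(curve, file.path(out, "threshold_curve.tsv"))
message("case vs pseudo-control hit counts by threshold:")
for (k in seq_along(alphas))
  message(sprintf("  P<%g: cases %d, pseudo %d, parent %d (OR %.2f)",
                  alphas[k], curve$case_hits[k], curve$pseudo_hits[k],
                  curve$parent_hits[k], curve$or_vs_pseudo[k]))

top <- scr_case$results[1, ]
dec <- genotype_combo_decomposition(cohort$child[, top$snp1],
                                    cohort$child[, top$snp2])
write_tsv(as.data.frame(as.table(dec$ratio)),
          file.path(out, "top_pair_combo_oe.tsv"))
message(sprintf(
  "top pair %s x %s (P = %.2g): double-heterozygote O/E = %.2f",
  top$snp1, top$snp2, top$p, dec$ratio["1", "1"]))
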