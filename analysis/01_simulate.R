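#!/usr/bin/env Rscript
# Stage 1: build the synthetic study.
#
# A case-parent trio cohort ascertained for affected offspring under a
# logistic risk model in which four cross-chromosome SNP pairs anchored in a
# designated "pathway" SNP set interact (log-OR 0.4-0.85 per dosage product,
# disease prevalence ~3% so ascertainment bites), plus
# a multi-group quantitative-trait dataset for the modifier-mapping arm
# (four disorder groups with a shared modifier SNP, unaffected siblings
# without it). Writes PLINK text .ped/.map and a phenotype TSV.

suppressPackageStartupMessages(library(epitrio))

seed <- 20260928L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(seed)

n_snps <- 360L
n_set <- 36L   # first 36 SNPs form the pathway set
snps <- make_snp_defs(n_snps, maf = runif(n_snps, 0.1, 0.5))

inter <- data.frame(
  snp1 = snps$snp_id[c(1, 2, 3, 4)],         # pathway side
  snp2 = snps$snp_id[c(150, 231, 268, 305)], # genome side, other chromosomes
  beta = c(0.5, 0.7, 0.9, 1.1)
)
stopifnot(snps$chr[c(1, 2, 3, 4)] != snps$chr[c(150, 231, 268, 305)])
model <- risk_model(snps, intercept = -3.5, interaction = inter)

cohort <- simulate_trios(3000, snps, model, ascertain = TRUE, seed = seed,
                         missing_rate = 0.01)
write_ped_map(cohort, file.path(out, "trios"))
message("wrote ", cohort$n_trios, " ascertained trios x ", n_snps,
        " SNPs (interacting pairs: ",
        paste(inter$snp1, inter$snp2, sep = "x", collapse = ", "), ")")

qtl <- simulate_qtl(
  c(CFC = 60, CS = 40, NF1 = 120, NS = 60, SIB = 140),
  snp_effects = c(CFC = 0.45, CS = 0.45, NF1 = 0.45, NS = 0.45),
  heterogeneity = 0.1, n_null_snps = 30, seed = seed + 1
)
write_tsv(qtl, file.path(out, "qtl_pheno.tsv"))
message("wrote quantitative-trait dataset: ", nrow(qtl), " samples, ",
        "1 modifier SNP + 30 null SNPs, 5 covariates")

write_tsv(data.frame(snp_id = snps$snp_id[seq_len(n_set)]),
          file.path(out, "pathway_set.tsv"))
writeLines(as.character(seed), file.path(out, "seed.txt"))
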