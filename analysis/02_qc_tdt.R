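#!/usr/bin/env Rscript
# Stage 2: load the trio cohort from PLINK text files, run QC (founder HWE,
# MAF, call rate, Mendel errors) and the transmission disequilibrium test.

suppressPackageStartupMessages(library(epitrio))
out <- "results/analysis"

cohort <- read_ped_map(file.path(out, "trios.ped"), file.path(out, "trios.map"))
message("loaded ", cohort$n_trios, " trios x ", nrow(cohort$snps), " SNPs")

me <- mendel_check(cohort)
message("Mendel errors: ", me$n_errors, " (",
        sum(me$snp_errors > 0), " SNPs affected)")

qc <- qc_filter(cohort, hwe_p_min = 1e-6, maf_min = 0.02, call_rate_min = 0.9)
write_tsv(qc$report, file.path(out, "qc_report.tsv"))
message("QC: removed ", sum(qc$report$removed), " of ", nrow(qc$report),
        " SNPs (", paste(names(table(qc$report$reason[qc$report$removed])),
                         table(qc$report$reason[qc$report$removed]),
                         sep = "=", collapse = ", "), ")")

assoc <- tdt(qc$cohort)
write_tsv(assoc, file.path(out, "tdt.tsv"))
message("TDT: ", sum(!is.na(assoc$p)), " SNPs tested; min P = ",
        signif(min(assoc$p, na.rm = TRUE), 3),
        "; lambda-like median chi2 ratio = ",
        signif(median(assoc$chisq, na.rm = TRUE) / qchisq(0.5, 1), 3))
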