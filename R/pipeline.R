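#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], optionally
#' overridden from a YAML file. Every threshold defaults to the analysis
#' protocol defaults: QC (HWE exact P < 1e-6, MAF < 2%), gene flank 5 kb,
#' BH FDR q = 0.2 with 100 length-matched permutations, epistasis reporting
#' threshold 1e-4, and trio-correlation validation of case-only hits.
#'
#' @param yaml_path optional YAML file whose top-level keys override defaults.
#' @param ... named overrides applied after the YAML.
#' @return named list (class `run_config`).
#' @export
pipeline_config <- function(yaml_path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    out_dir = "results/pipeline",
    # synthetic-data stage (used when no ped/map input is given)
    n_trios = 600L, n_snps = 400L, n_set_snps = 40L,
    interaction_beta = 0.6, n_interactions = 2L, model_intercept = -2,
    # QC
    hwe_p_min = 1e-6, maf_min = 0.02, call_rate_min = 0.9,
    # enrichment
    flank = 5000L, q_threshold = 0.2, n_perm = 100L, k_nearest = 100L,
    n_universe_genes = 1200L, n_set_genes = 12L,
    # epistasis
    min_p_report = 1e-4, gwas_alpha = 5e-8, genome_wide = 7.6e-10,
    control_type = "pseudo", enrichment_alpha = 1e-3,
    # trio correlation
    validate_p_cut = 1e-4, min_informative = 30L,
    # QTL stage
    run_qtl = TRUE, qtl_group_sizes = c(CFC = 60L, CS = 40L, NF1 = 120L,
                                        NS = 60L, SIB = 140L),
    qtl_effect = 0.4, qtl_sibling_group = "SIB", n_covariates = 5L,
    pheno_path = NULL, ped_path = NULL, map_path = NULL
  )
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full reverse-pathway analysis pipeline
#'
#' Executes the stages in order — simulate (or load .ped/.map) -> QC ->
#' pseudo-controls -> TDT -> gene-set enrichment -> case and control epistasis
#' screens -> 2x2 case-vs-control enrichment -> trio-correlation validation ->
#' (optional) modifier-QTL meta-analysis — writing one TSV per stage plus a
#' JSON run summary and the verbatim configuration into `out_dir`. Reruns with
#' the same configuration are bit-identical for all deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run summary list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(config = unclass(cfg))
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = " ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate or load -----------------------------------------------------
  cohort <- stage("simulate", {
    if (!is.null(cfg$ped_path)) {
      read_ped_map(cfg$ped_path, cfg$map_path)
    } else {
      set.seed(child_seed(cfg$seed, "misc"))
      snps <- make_snp_defs(cfg$n_snps,
                            maf = stats::runif(cfg$n_snps, 0.1, 0.5))
      set_idx <- seq_len(cfg$n_set_snps)
      inter <- NULL
      if (cfg$n_interactions > 0) {
        partner <- which(snps$chr != snps$chr[1])[seq_len(cfg$n_interactions)]
        inter <- data.frame(snp1 = snps$snp_id[set_idx[seq_len(cfg$n_interactions)]],
                            snp2 = snps$snp_id[partner],
                            beta = cfg$interaction_beta)
        same <- snps$chr[match(inter$snp1, snps$snp_id)] ==
          snps$chr[match(inter$snp2, snps$snp_id)]
        inter <- inter[!same, , drop = FALSE]
      }
      model <- risk_model(snps, intercept = cfg$model_intercept,
                          interaction = inter)
      simulate_trios(cfg$n_trios, snps, model, ascertain = TRUE,
                     seed = child_seed(cfg$seed, "simulate"))
    }
  })
  summary$n_trios <- cohort$n_trios
  summary$n_snps_in <- nrow(cohort$snps)
  log_stage("simulate", cohort$n_trios, "trios,", nrow(cohort$snps), "SNPs")

  # --- QC -------------------------------------------------------------------
  qc <- stage("qc", qc_filter(cohort, cfg$hwe_p_min, cfg$maf_min,
                              cfg$call_rate_min))
  cohort <- qc$cohort
  write_tsv(qc$report, file.path(cfg$out_dir, "qc_report.tsv"))
  summary$n_snps_qc <- nrow(cohort$snps)
  log_stage("qc", sum(qc$report$removed), "SNPs removed,",
            nrow(cohort$snps), "kept")

  # --- controls -------------------------------------------------------------
  controls <- stage("controls", {
    if (cfg$control_type == "parent") make_parent_controls(cohort)
    else make_pseudo_controls(cohort)
  })

  # --- TDT ------------------------------------------------------------------
  assoc <- stage("tdt", tdt(cohort))
  write_tsv(assoc, file.path(cfg$out_dir, "tdt.tsv"))
  log_stage("tdt", sum(!is.na(assoc$p)), "SNPs tested")

  # --- gene-set enrichment --------------------------------------------------
  enr <- stage("enrichment", {
    uni <- make_gene_universe(cfg$n_universe_genes,
                              seed = child_seed(cfg$seed, "universe"))
    # map pipeline SNPs onto universe genes: reuse cohort snps as the map
    target <- uni$genes[sample.int(nrow(uni$genes), cfg$n_set_genes), ]
    perms <- permuted_sets(uni$genes, target, n_perm = cfg$n_perm,
                           k_nearest = cfg$k_nearest,
                           seed = child_seed(cfg$seed, "enrichment"))
    # SNP sets over the cohort map by interval
    tgt_ids <- snps_in_set(cohort$snps, remap_genes(target, cohort$snps),
                           cfg$flank)
    perm_ids <- lapply(perms, function(g)
      snps_in_set(cohort$snps, remap_genes(g, cohort$snps), cfg$flank))
    if (!length(tgt_ids)) stop("empty target SNP set after QC")
    enrichment_test(assoc, tgt_ids, perm_ids, cfg$q_threshold)
  })
  summary$enrichment <- enr[c("observed_pct", "empirical_p", "p_label")]
  log_stage("enrichment", "observed", round(enr$observed_pct, 2),
            "% ; empirical P =", enr$p_label)

  # --- epistasis screens ----------------------------------------------------
  set_ids <- intersect(
    cohort$snps$snp_id[seq_len(min(cfg$n_set_snps, nrow(cohort$snps)))],
    colnames(cohort$child))
  scr_case <- stage("episcan_cases",
    set_by_all_screen(cohort$child, cohort$snps, set_ids,
                      min_p_report = cfg$min_p_report))
  scr_ctrl <- stage("episcan_controls",
    set_by_all_screen(controls$dosage, cohort$snps, set_ids,
                      min_p_report = cfg$min_p_report))
  write_tsv(scr_case$results, file.path(cfg$out_dir, "episcan_cases.tsv"))
  write_tsv(scr_ctrl$results, file.path(cfg$out_dir, "episcan_controls.tsv"))
  log_stage("episcan", scr_case$n_tests, "pairs;",
            nrow(scr_case$results), "case records <=", cfg$min_p_report)

  # --- 2x2 enrichment -------------------------------------------------------
  al <- formatC(cfg$enrichment_alpha, format = "e", digits = 0)
  enr22 <- stage("enrichment_2x2",
    enrichment_2x2(scr_case$tail_counts[[al]], scr_case$n_tests,
                   scr_ctrl$tail_counts[[al]], scr_ctrl$n_tests))
  summary$case_control_2x2 <- as.list(enr22)
  log_stage("enrichment_2x2", "OR =", signif(enr22$or, 3),
            "P =", signif(enr22$p, 3))

  # --- trio-correlation validation ------------------------------------------
  val <- stage("triocorr", validate_hits(scr_case$results, cohort,
                                         p_cut = cfg$validate_p_cut,
                                         min_informative = cfg$min_informative))
  if (nrow(val$table))
    write_tsv(val$table, file.path(cfg$out_dir, "triocorr_validation.tsv"))
  summary$validation_rho <- val$rho
  log_stage("triocorr", nrow(val$table), "pairs validated; rho =",
            round(val$rho %||% NA_real_, 3))

  # --- modifier QTL ----------------------------------------------------------
  if (isTRUE(cfg$run_qtl)) {
    qtl <- stage("qtl", {
      dat <- if (!is.null(cfg$pheno_path)) read_pheno(cfg$pheno_path)
        else {
          eff_groups <- setdiff(names(cfg$qtl_group_sizes),
                                cfg$qtl_sibling_group)
          simulate_qtl(cfg$qtl_group_sizes,
                       snp_effects = stats::setNames(
                         rep(cfg$qtl_effect, length(eff_groups)), eff_groups),
                       n_covariates = cfg$n_covariates,
                       seed = child_seed(cfg$seed, "qtl"))
        }
      snp_cols <- grep("^(snp|null)", names(dat), value = TRUE)
      scan <- qtl_scan(dat, snp_cols = snp_cols)
      groups <- setdiff(unique(scan$group), cfg$qtl_sibling_group)
      meta <- meta_scan(scan, groups)
      sib <- scan[scan$group == cfg$qtl_sibling_group, , drop = FALSE]
      cand <- sibling_contrast(meta, sib, p_threshold = 1)
      list(scan = scan, meta = meta, candidates = cand)
    })
    write_tsv(qtl$scan, file.path(cfg$out_dir, "qtl_scan.tsv"))
    write_tsv(qtl$meta, file.path(cfg$out_dir, "qtl_meta.tsv"))
    write_tsv(qtl$candidates, file.path(cfg$out_dir, "qtl_candidates.tsv"))
    summary$qtl_top_re2_p <- suppressWarnings(min(qtl$meta$re2_p, na.rm = TRUE))
    log_stage("qtl", nrow(qtl$meta), "SNPs meta-analyzed")
  } else if (!is.null(cfg$pheno_path) && !file.exists(cfg$pheno_path)) {
    stop("pipeline stage 'qtl' failed: phenotype file not found: ",
         cfg$pheno_path, call. = FALSE)
  }

  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}

# Project universe gene intervals onto the cohort's SNP coordinate space so
# synthetic gene sets overlap the cohort map (internal).
remap_genes <- function(genes, snps) {
  g <- genes
  for (i in seq_len(nrow(g))) {
    on_chr <- snps[snps$chr == g$chr[i], , drop = FALSE]
    if (!nrow(on_chr)) next
    anchor <- on_chr$pos[1 + (i %% nrow(on_chr))]
    width <- g$end[i] - g$start[i]
    g$start[i] <- max(1, anchor - width %/% 2)
    g$end[i] <- g$start[i] + width
  }
  g
}
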