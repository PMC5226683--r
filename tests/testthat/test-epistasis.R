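test_that("allelic_table matches the hand example and the per-person enumeration oracle", {
  g1 <- c(rep(0, 3), rep(1, 2), 2)  # AABB x3, AaBb x2, aabb x1
  g2 <- c(rep(0, 3), rep(1, 2), 2)
  tab <- allelic_table(g1, g2)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 14, b = 2, c = 2, d = 6))
  expect_equal(tab$a + tab$b + tab$c + tab$d, 4 * tab$n_complete)
  # 1000 random tables vs the enumeration oracle
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    h1 <- sample(0:2, n, replace = TRUE)
    h2 <- sample(0:2, n, replace = TRUE)
    if (runif(1) < 0.3) h1[sample(n, 1)] <- NA
    if (all(is.na(h1))) next
    t_ <- allelic_table(h1, h2)
    o <- oracle_allelic_table(h1, h2)
    expect_equal(unlist(t_[c("a", "b", "c", "d")]), o)
    expect_equal(sum(o), 4 * t_$n_complete)
  }
})

test_that("all-double-heterozygote samples give a = b = c = d = n", {
  n <- 17
  tab <- allelic_table(rep(1, n), rep(1, n))
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = n, b = n, c = n, d = n))
})

test_that("minor/major relabeling and locus swap act as symmetries", {
  set.seed(42)
  g1 <- sample(0:2, 60, replace = TRUE)
  g2 <- sample(0:2, 60, replace = TRUE)
  t0 <- allelic_table(g1, g2)
  t_swap1 <- allelic_table(2 - g1, g2)  # relabel locus 1
  expect_equal(unname(unlist(t_swap1[c("a", "b", "c", "d")])),
               unname(unlist(t0[c("c", "d", "a", "b")])))
  # |z| and p invariant under relabeling at either locus and locus order swap
  z0 <- case_only_test(t0)
  for (t_ in list(t_swap1, allelic_table(g1, 2 - g2), allelic_table(g2, g1))) {
    zi <- case_only_test(t_)
    expect_equal(abs(zi$z), abs(z0$z), tolerance = 1e-12)
    expect_equal(zi$p, z0$p, tolerance = 1e-12)
  }
})

test_that("case_only_test reproduces the hand-computed example and null identity", {
  g1 <- c(rep(0, 3), rep(1, 2), 2); g2 <- g1
  res <- case_only_test(allelic_table(g1, g2))
  expect_equal(res$or, 21)
  expect_equal(res$log_or, log(21), tolerance = 1e-9)
  expect_equal(res$log_or_var, 1 / 14 + 1 / 2 + 1 / 2 + 1 / 6, tolerance = 1e-12)
  expect_equal(res$z, 2.736164, tolerance = 1e-5)
  expect_equal(res$p, 0.006216, tolerance = 1e-4)
  # a*d = b*c -> OR 1, z 0, p 1
  balanced <- structure(list(a = 10, b = 10, c = 10, d = 10, n_complete = 10),
                        class = "allelic_table")
  res0 <- case_only_test(balanced)
  expect_equal(res0$or, 1); expect_equal(res0$z, 0); expect_equal(res0$p, 1)
})

test_that("zero cells get the Haldane-Anscombe correction; >= 2 zero cells are NA", {
  one_zero <- structure(list(a = 0, b = 5, c = 6, d = 7, n_complete = 4.5),
                        class = "allelic_table")
  res <- case_only_test(one_zero)
  expect_equal(res$or, (0.5 * 7.5) / (5.5 * 6.5))
  two_zero <- structure(list(a = 0, b = 0, c = 6, d = 7, n_complete = 3.25),
                        class = "allelic_table")
  res2 <- case_only_test(two_zero)
  expect_true(is.na(res2$z))
  expect_match(res2$reason, "zero cells")
})

test_that("set_by_all_screen honors the same-chromosome exclusion and counting contract", {
  # all SNPs on one chromosome -> no tests
  snps <- make_snp_defs(10, maf = 0.3, chromosomes = 12)
  co <- simulate_trios(50, snps, seed = 3)
  scr <- set_by_all_screen(co$child, snps, snps$snp_id[1:3])
  expect_equal(scr$n_tests, 0)
  # 5 set x 100 genome SNPs with disjoint chromosomes -> exactly 500 tests
  snps2 <- make_snp_defs(105, maf = 0.3,
                         chromosomes = c(rep(1, 5), rep(2:11, each = 10)))
  co2 <- simulate_trios(80, snps2, seed = 4)
  scr2 <- set_by_all_screen(co2$child, snps2, snps2$snp_id[1:5],
                            min_p_report = 1)
  expect_equal(scr2$n_tests, 500)
  expect_equal(nrow(scr2$results), 500 - scr2$n_na)
  # cell conservation on every reported pair
  with(scr2$results,
       expect_true(all(a + b + c + d == 4 * n_complete)))
  # screened statistics equal the single-pair path
  i <- which.min(scr2$results$p)
  pair <- scr2$results[i, ]
  single <- case_only_test(allelic_table(co2$child[, pair$snp1],
                                         co2$child[, pair$snp2]))
  expect_equal(pair$z, single$z, tolerance = 1e-9)
  expect_equal(pair$p, single$p, tolerance = 1e-9)
  # missing set SNP id errors informatively
  expect_error(set_by_all_screen(co2$child, snps2, "nope"), "absent")
})

test_that("screen results are invariant to whether records are truncated", {
  snps <- fixture_snps(40, seed = 51)
  co <- simulate_trios(120, snps, seed = 52)
  full <- set_by_all_screen(co$child, snps, snps$snp_id[1:6], min_p_report = 1)
  trunc <- set_by_all_screen(co$child, snps, snps$snp_id[1:6],
                             min_p_report = 0.01)
  expect_equal(trunc$n_tests, full$n_tests)
  expect_equal(trunc$tail_counts, full$tail_counts)
  expect_true(all(trunc$results$p <= 0.01))
  expect_equal(nrow(trunc$results), sum(full$results$p <= 0.01))
})

test_that("allelic case/control z tracks the logistic interaction z (r >= 0.995)", {
  set.seed(61)
  n_pairs <- 200
  z_allelic <- z_logit <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    maf1 <- runif(1, 0.1, 0.5); maf2 <- runif(1, 0.1, 0.5)
    bint <- if (i %% 2 == 0) 0 else runif(1, -0.25, 0.25)
    d <- sim_cc_pair(2000, 2000, maf1, maf2, -2, 0.1, 0.1, bint)
    cc <- epistasis_cc_test(allelic_table(d$case1, d$case2),
                            allelic_table(d$ctrl1, d$ctrl2))
    z_allelic[i] <- cc$z
    z_logit[i] <- logistic_interaction_test(
      c(d$case1, d$ctrl1), c(d$case2, d$ctrl2),
      rep(1:0, each = 2000))$z
  }
  ok <- !is.na(z_allelic) & !is.na(z_logit)
  expect_gte(sum(ok), 195)
  expect_gte(cor(z_allelic[ok], z_logit[ok]), 0.995)
  # a strongly interacting pair is significant in both tests
  d <- sim_cc_pair(2000, 2000, 0.3, 0.3, -2, 0.1, 0.1, 0.6)
  cc <- epistasis_cc_test(allelic_table(d$case1, d$case2),
                          allelic_table(d$ctrl1, d$ctrl2))
  lg <- logistic_interaction_test(c(d$case1, d$ctrl1), c(d$case2, d$ctrl2),
                                  rep(1:0, each = 2000))
  expect_lt(cc$p, 1e-4); expect_lt(lg$p, 1e-4)
})

test_that("logistic interaction z is centered under no interaction", {
  set.seed(62)
  z <- vapply(1:60, function(i) {
    d <- sim_cc_pair(400, 400, 0.3, 0.3, -1, 0, 0, 0)
    logistic_interaction_test(c(d$case1, d$ctrl1), c(d$case2, d$ctrl2),
                              rep(1:0, each = 400))$z
  }, numeric(1))
  expect_lt(abs(mean(z, na.rm = TRUE)), 3 / sqrt(sum(!is.na(z))))
})

test_that("enrichment_2x2 reproduces the textbook example and sign contracts", {
  res <- enrichment_2x2(30, 1000, 10, 1000)
  expect_equal(res$or, (30 * 990) / (10 * 970), tolerance = 1e-12)
  expect_equal(res$chisq, 10.204, tolerance = 1e-3)
  expect_equal(res$p, 0.0014, tolerance = 1e-1)
  expect_equal(enrichment_2x2(20, 400, 20, 400)$chisq, 0)
  expect_equal(enrichment_2x2(20, 400, 20, 400)$or, 1)
  expect_lt(enrichment_2x2(5, 400, 20, 400)$or, 1)
  expect_true(is.na(enrichment_2x2(0, 400, 0, 400)$p))
})

test_that("genotype-combination decomposition flags double-heterozygote excess", {
  set.seed(63)
  g1 <- rbinom(10000, 2, 0.3); g2 <- rbinom(10000, 2, 0.4)
  dec <- genotype_combo_decomposition(g1, g2)
  expect_true(max(abs(dec$ratio - 1), na.rm = TRUE) < 0.1)
  expect_equal(rowSums(dec$observed), rowSums(dec$expected), tolerance = 1e-9)
  expect_equal(colSums(dec$observed), colSums(dec$expected), tolerance = 1e-9)
  # ascertained cases under positive interaction inflate the (1,1) cell
  orc <- oracle_case_pair(8000, 0.3, 0.3, -3, log(3), seed = 64)
  dec2 <- genotype_combo_decomposition(orc$g1, orc$g2)
  expect_gt(dec2$ratio["1", "1"], 1)
})

test_that("multiple-testing thresholds follow the Bonferroni arithmetic", {
  th <- compute_thresholds(17)
  expect_equal(th$gene_based, 5e-8 / 17)
  expect_equal(signif(th$gene_based, 2), 2.9e-9)
  expect_equal(th$genome_wide, 7.6e-10)
  expect_equal(compute_thresholds(1)$gene_based, 5e-8)
  expect_equal(compute_thresholds(20, gwas_alpha = 0.05)$gene_based, 2.5e-3)
  expect_equal(compute_thresholds(5, ld_groups = 10,
                                  genome_tests = 1e6)$genome_wide, 5e-9)
})

test_that("correlation power is monotone, hits the null limit, and matches simulation", {
  expect_gt(power_correlation(4109, 0.11, 7.6e-10), 0.80)
  expect_equal(power_correlation(200, 1e-6, 0.05), 0.05, tolerance = 0.01)
  grid_n <- c(50, 100, 400, 1000)
  pw_n <- vapply(grid_n, power_correlation, numeric(1), r2 = 0.05, alpha = 0.01)
  expect_true(all(diff(pw_n) >= 0))
  grid_r2 <- c(0.01, 0.05, 0.1, 0.2)
  pw_r <- vapply(grid_r2, function(r2)
    power_correlation(200, r2, 0.01), numeric(1))
  expect_true(all(diff(pw_r) >= 0))
  sim <- power_correlation(300, 0.05, 0.05, method = "simulation",
                           n_rep = 4000, seed = 65)
  expect_lt(abs(sim - power_correlation(300, 0.05, 0.05)), 0.02)
})
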