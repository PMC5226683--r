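make_cohort <- function(f, m, c_, chromosomes = 1) {
  snps <- make_snp_defs(ncol(f), maf = 0.3, chromosomes = chromosomes)
  epitrio:::new_trio_cohort(f, m, c_, snps, sex = rep(1L, nrow(f)),
                            affected = rep(TRUE, nrow(f)))
}

test_that("mendel_check flags exactly the impossible configurations", {
  # homozygous-major parents cannot transmit a minor allele
  co <- make_cohort(matrix(0L), matrix(0L), matrix(1L))
  expect_equal(mendel_check(co)$n_errors, 1)
  # double-het parents allow any child
  for (c_ in 0:2) {
    co <- make_cohort(matrix(1L), matrix(1L), matrix(c_))
    expect_equal(mendel_check(co)$n_errors, 0)
  }
  # missing genotypes are never flagged
  co <- make_cohort(matrix(NA_integer_), matrix(0L), matrix(2L))
  expect_equal(mendel_check(co)$n_errors, 0)
})

test_that("mendel_check agrees with the 27-configuration enumeration oracle", {
  grid <- expand.grid(f = 0:2, m = 0:2, c_ = 0:2)
  for (i in seq_len(nrow(grid))) {
    co <- make_cohort(matrix(grid$f[i]), matrix(grid$m[i]), matrix(grid$c_[i]))
    expect_equal(mendel_check(co)$n_errors == 0,
                 oracle_mendel_ok(grid$f[i], grid$m[i], grid$c_[i]),
                 info = paste(grid[i, ], collapse = "/"))
  }
})

test_that("corrupting k child genotypes to impossible states yields exactly k errors", {
  snps <- fixture_snps(20)
  co <- simulate_trios(100, snps, seed = 5)
  expect_equal(mendel_check(co)$n_errors, 0)
  set.seed(6)
  k <- 15
  rows <- sample(100, k, replace = TRUE)
  cols <- sample(20, k, replace = TRUE)
  while (anyDuplicated(cbind(rows, cols))) {
    dup <- duplicated(cbind(rows, cols))
    rows[dup] <- sample(100, sum(dup), replace = TRUE)
  }
  for (i in seq_len(k)) {
    f <- co$father[rows[i], cols[i]]; m <- co$mother[rows[i], cols[i]]
    bad <- setdiff(0:2, Filter(function(c_) oracle_mendel_ok(f, m, c_), 0:2))
    # when all children are possible (het x het), force an impossible parent
    if (!length(bad)) {
      co$father[rows[i], cols[i]] <- 0L
      co$mother[rows[i], cols[i]] <- 0L
      bad <- 1:2
    }
    co$child[rows[i], cols[i]] <- bad[1]
  }
  expect_equal(mendel_check(co)$n_errors, k)
})

test_that("HWE exact test matches enumeration oracle values and known cases", {
  # frozen value from the full-enumeration oracle (MC-validated)
  expect_equal(hwe_exact_test(1469, 138, 5), 0.3825187, tolerance = 1e-6)
  # a perfectly balanced configuration is never rejected
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 0.2)
  # gross heterozygote deficit is rejected hard
  expect_lt(hwe_exact_test(500, 0, 500), 1e-100)
})

test_that("qc_filter removes SNPs by MAF, HWE and call rate, and is idempotent", {
  snps <- make_snp_defs(4, maf = c(0.3, 0.01, 0.3, 0.3))
  co <- simulate_trios(800, snps, seed = 9)
  # make rs3 grossly HWE-violating in founders, rs4 badly called
  co$father[, 3] <- rep(c(0L, 2L), 400)
  co$mother[, 3] <- rep(c(0L, 2L), 400)
  co$child[, 3] <- co$father[, 3]
  co$father[1:400, 4] <- NA_integer_
  res <- qc_filter(co, maf_min = 0.02, call_rate_min = 0.9)
  expect_setequal(res$report$snp_id[res$report$removed], c("rs2", "rs3", "rs4"))
  expect_equal(res$report$reason[res$report$snp_id == "rs2"], "maf")
  expect_equal(res$report$reason[res$report$snp_id == "rs3"], "hwe")
  expect_equal(res$report$reason[res$report$snp_id == "rs4"], "call_rate")
  twice <- qc_filter(res$cohort, maf_min = 0.02, call_rate_min = 0.9)
  expect_identical(twice$cohort$snps, res$cohort$snps)
  expect_false(any(twice$report$removed))
  # monomorphic SNP removed with MAF reason
  co2 <- simulate_trios(50, make_snp_defs(2, maf = c(0.4, 0.4)), seed = 1)
  co2$father[, 2] <- 0L; co2$mother[, 2] <- 0L; co2$child[, 2] <- 0L
  expect_equal(qc_filter(co2)$report$reason[2], "maf")
  expect_error(qc_filter(co2, maf_min = 1 - 1e-9), "all SNPs")
})

test_that("tdt reproduces closed-form counts and chi-square", {
  # construct trios with known b/c: het father x hom-major mother
  n <- 100
  f <- matrix(1L, n, 1); m <- matrix(0L, n, 1)
  c_ <- matrix(c(rep(1L, 60), rep(0L, 40)), n, 1)  # b = 60, c = 40
  co <- make_cohort(f, m, c_)
  res <- tdt(co)
  expect_equal(res$b, 60)
  expect_equal(res$c, 40)
  expect_equal(res$chisq, 4)
  expect_equal(res$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p, 0.0455, tolerance = 1e-3)
  # b == c gives chi2 = 0, P = 1
  c2 <- matrix(rep(c(0L, 1L), n / 2), n, 1)
  expect_equal(tdt(make_cohort(f, m, c2))$p, 1)
  # no heterozygous parents -> NA
  co3 <- make_cohort(matrix(0L, 5, 1), matrix(0L, 5, 1), matrix(0L, 5, 1))
  expect_true(is.na(tdt(co3)$p))
})

test_that("tdt type-I error is nominal and P-values uniform under the ascertained null", {
  snps <- fixture_snps(5000, seed = 21)
  model <- risk_model(snps, intercept = -2)
  co <- simulate_trios(650, snps, model, ascertain = TRUE, seed = 23)
  res <- tdt(co)
  p <- res$p[!is.na(res$p)]
  expect_gte(length(p), 5000 * 0.99)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04); expect_lte(rate, 0.06)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("pseudo-controls satisfy the allele-conservation identity and frequency match", {
  snps <- fixture_snps(25)
  co <- simulate_trios(400, snps, seed = 12, missing_rate = 0.02)
  pc <- make_pseudo_controls(co)
  complete <- !is.na(co$father) & !is.na(co$mother) & !is.na(co$child) &
    !mendel_check(co)$error_matrix
  expect_true(all((co$child + pc$dosage)[complete] ==
                    (co$father + co$mother)[complete]))
  # exact frequency identity on complete data
  for (j in 1:5) {
    ok <- complete[, j]
    expect_equal(mean(pc$dosage[ok, j]) + mean(co$child[ok, j]),
                 mean(co$father[ok, j]) + mean(co$mother[ok, j]))
  }
  # spot checks of forced configurations
  co1 <- make_cohort(matrix(1L), matrix(1L), matrix(2L))
  expect_equal(unname(make_pseudo_controls(co1)$dosage[1, 1]), 0)
  co2 <- make_cohort(matrix(2L), matrix(0L), matrix(1L))
  expect_equal(unname(make_pseudo_controls(co2)$dosage[1, 1]), 1)
  # Mendel-inconsistent entry -> NA
  co3 <- make_cohort(matrix(0L), matrix(0L), matrix(2L))
  expect_true(is.na(make_pseudo_controls(co3)$dosage[1, 1]))
})

test_that("matched-sex parent controls select the right parent row-wise", {
  snps <- fixture_snps(10)
  co <- simulate_trios(60, snps, seed = 31)
  co$sex <- rep(c(1L, 2L), 30)
  ctrl <- make_parent_controls(co)
  # per-trio loop oracle
  for (i in seq_len(60)) {
    want <- if (co$sex[i] == 1L) co$father[i, ] else co$mother[i, ]
    expect_equal(unname(ctrl$dosage[i, ]), unname(want))
  }
  # all-male cases -> father matrix
  co$sex <- rep(1L, 60)
  expect_equal(make_parent_controls(co)$dosage, co$father)
  # missing sex skipped with warning
  co$sex[3] <- NA
  expect_warning(ctrl2 <- make_parent_controls(co), "skipped")
  expect_equal(nrow(ctrl2$dosage), 59)
})
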