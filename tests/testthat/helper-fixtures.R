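# Shared fixtures and independent oracles for the test suite.

# Small default SNP panel spread over several chromosomes.
fixture_snps <- function(n = 30, maf = NULL, seed = 11) {
  set.seed(seed)
  make_snp_defs(n, maf = maf %||% runif(n, 0.1, 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent per-person allele-enumeration oracle for the allelic 2x2 table:
# each individual contributes its 2 x 2 = 4 cross-locus allele pairs.
oracle_allelic_table <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  cells <- c(a = 0, b = 0, c = 0, d = 0)
  for (i in seq_along(g1)) {
    # alleles at locus 1: g1[i] minor ("a"), 2 - g1[i] major ("A")
    al1 <- c(rep("A", 2 - g1[i]), rep("a", g1[i]))
    al2 <- c(rep("B", 2 - g2[i]), rep("b", g2[i]))
    for (x in al1) for (y in al2) {
      key <- if (x == "A" && y == "B") "a" else if (x == "A") "b"
             else if (y == "B") "c" else "d"
      cells[key] <- cells[key] + 1
    }
  }
  cells
}

# Brute-force BH step-up oracle (quadratic time).
oracle_bh <- function(p) {
  m <- sum(!is.na(p))
  q <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  for (i in idx) {
    rank_i <- sum(p[idx] <= p[i])
    # min over all j with p_j >= p_i of p_j * m / rank_j
    cand <- vapply(idx[p[idx] >= p[i]], function(j)
      p[j] * m / sum(p[idx] <= p[j]), numeric(1))
    q[i] <- min(1, cand)
  }
  q
}

# Enumeration oracle over the 27 trio genotype configurations: TRUE where the
# child dosage is reachable by one transmitted allele per parent.
oracle_mendel_ok <- function(f, m, c_) {
  any(vapply(0:1, function(tf) any(vapply(0:1, function(tm) {
    pf_ok <- (tf == 0 && f < 2) || (tf == 1 && f > 0)
    pm_ok <- (tm == 0 && m < 2) || (tm == 1 && m > 0)
    pf_ok && pm_ok && (tf + tm == c_)
  }, logical(1))), logical(1)))
}

# Rejection-sampling oracle for the case genotype distribution at two loci
# under a logistic risk model -- deliberately scalar/loop-free of the
# package's vectorized generator.
oracle_case_pair <- function(n_cases, maf1, maf2, intercept, beta_int,
                             seed = 1) {
  set.seed(seed)
  g1 <- integer(0); g2 <- integer(0)
  while (length(g1) < n_cases) {
    h1 <- rbinom(50000, 2, maf1)
    h2 <- rbinom(50000, 2, maf2)
    aff <- runif(50000) < plogis(intercept + beta_int * h1 * h2)
    g1 <- c(g1, h1[aff]); g2 <- c(g2, h2[aff])
  }
  list(g1 = g1[1:n_cases], g2 = g2[1:n_cases])
}

# Exact expected allelic log-OR in ascertained cases by enumeration of the
# 9 genotype combinations under the logistic model.
oracle_expected_log_or <- function(maf1, maf2, intercept, beta_int) {
  hwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  pg <- outer(hwe(maf1), hwe(maf2))
  risk <- outer(0:2, 0:2, function(i, j) plogis(intercept + beta_int * i * j))
  pcase <- pg * risk / sum(pg * risk)
  N <- pcase  # expected proportions of genotype combos in cases
  a <- 4 * N[1, 1] + 2 * N[1, 2] + 2 * N[2, 1] + N[2, 2]
  b <- 4 * N[1, 3] + 2 * N[1, 2] + 2 * N[2, 3] + N[2, 2]
  c_ <- 4 * N[3, 1] + 2 * N[3, 2] + 2 * N[2, 1] + N[2, 2]
  d <- 4 * N[3, 3] + 2 * N[3, 2] + 2 * N[2, 3] + N[2, 2]
  log(a * d / (b * c_))
}

# Simulate a case/control panel for one SNP pair under a logistic model.
sim_cc_pair <- function(n_case, n_ctrl, maf1, maf2, intercept, b1, b2, bint) {
  c1 <- c2 <- u1 <- u2 <- integer(0)
  while (length(c1) < n_case || length(u1) < n_ctrl) {
    g1 <- rbinom(20000, 2, maf1); g2 <- rbinom(20000, 2, maf2)
    aff <- runif(20000) < plogis(intercept + b1 * g1 + b2 * g2 + bint * g1 * g2)
    c1 <- c(c1, g1[aff]); c2 <- c(c2, g2[aff])
    u1 <- c(u1, g1[!aff]); u2 <- c(u2, g2[!aff])
  }
  list(case1 = c1[1:n_case], case2 = c2[1:n_case],
       ctrl1 = u1[1:n_ctrl], ctrl2 = u2[1:n_ctrl])
}
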