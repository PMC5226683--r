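---
title: "Methods: case-only epistasis, trio controls and modifier-QTL meta-analysis"
author: "epitrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-only epistasis, trio controls and modifier-QTL meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitrio)
```

# The design

A pathway whose rare coding mutations cause a Mendelian syndrome is a strong
prior for where common variation might act in a related complex disorder.
`epitrio` implements the three arms of that reverse-pathway argument for
case–parent trio data:

1. **Main effects**: are pathway SNPs enriched among the disorder's
   single-SNP association signals?
2. **Epistasis**: do pathway SNPs interact with SNPs elsewhere in the genome,
   visible as cross-chromosome allelic correlation in affected individuals
   but not in matched controls?
3. **Modifiers**: in patients already carrying a severe pathway mutation,
   do common SNPs shift a quantitative severity trait, consistently across
   diagnostic groups, but not in unaffected siblings?

All three arms are backed by a synthetic data generator, so the package's
tests measure the statistical behaviour of every stage — calibration under
the null, recovery under known alternatives — rather than assuming it.

# The case-only allelic test

For unlinked loci, genotypes at one locus carry no information about the
other in the general population. Ascertaining on disease changes that: if
minor alleles at two loci multiply risk, affected individuals are enriched
for carrying both, and the loci become correlated *within cases only*.

`allelic_table()` collapses the `4N` alleles of `N` cases into a 2×2 table
(`a` counts major–major allele pairings, `d` minor–minor, each individual
contributing its `2 × 2` cross-locus allele pairs), and `case_only_test()`
forms `OR = ad/bc`, `Var(ln OR) = 1/a+1/b+1/c+1/d`, and the standard-normal
`z = ln(OR)/√Var`, two-sided. The statistic is exactly invariant to
relabeling the minor/major allele at either locus (|z| unchanged) and to
locus order — both are covered by property tests.

Numerical choices:

* **Zero cells.** If exactly one cell is zero, 0.5 is added to all four
  (Haldane–Anscombe), keeping `ln OR` finite without materially biasing
  typical tables; with two or more zero cells the pair is reported `NA` with
  a reason. The correction is deliberately *not* applied to non-degenerate
  tables.
* **Missing data.** Pairwise-complete deletion per SNP pair, matching the
  single-pair 2×2 construction; the invariant `a+b+c+d = 4·N_complete` is
  asserted on every screened pair.
* **Screen memory.** `set_by_all_screen()` keeps full records only for pairs
  below `min_p_report` (default `1e-4`) plus tail counts at configurable
  thresholds — the threshold-curve and 2×2 enrichment analyses only use the
  tails.

The two-group form `epistasis_cc_test()` — the difference of case and
control allelic log-ORs over the root of the summed variances — is the
variant whose agreement with the logistic interaction Wald z is near-perfect
(Pearson r ≈ 0.999 over simulated panels; the case-only z alone correlates
at ≈ 0.92 with a case/control logistic z because the control arm contributes
independent noise the single-group statistic never sees). The acceptance
script measures exactly this agreement.

**Significance thresholds.** `compute_thresholds()` returns the gene-based
bound (GWAS `5e-8` divided by the number of pathway genes; 17 genes give
`2.9e-9`) and a genome-wide epistasis bound, default `7.6e-10`, exposed as
`0.05/(LD groups × genome tests)` when those inputs are available rather
than hard-wiring an external LD map. Power for the design, viewed as a
correlation test, uses the Fisher z transform with both rejection tails so
the null limit equals α; 4,109 trios give > 80% power for `r² = 0.11` at
`7.6e-10`.

# Trio-based controls

`make_pseudo_controls()` uses the identity *pseudo-control = father + mother
− child* in minor-allele dosage: the multiset of untransmitted alleles is
determined for every Mendel-consistent configuration, even when
double-heterozygous parents make transmission *phase* ambiguous — only the
multiset matters for single-marker analyses, so pseudo-controls are built
per SNP with no cross-SNP haplotyping. Mendel-inconsistent trio×SNP entries
are set missing and counted. The conservation identity holds exactly on
complete data and is asserted exactly in tests.

`mendel_check()` classifies all 27 parent–parent–child dosage
configurations via the reachability bounds
`(f=2)+(m=2) ≤ child ≤ 2−(f=0)−(m=0)`, verified against an explicit
transmission-enumeration oracle. `qc_filter()` removes SNPs on founder MAF,
call rate, and a founder-only exact Hardy–Weinberg test (full enumeration of
heterozygote counts conditional on the allele count; plain exact P, no
mid-P), and is idempotent.

The TDT is computed by counting, per Mendel-consistent complete trio,
transmitted minor alleles from heterozygous parents as
`child − #(homozygous-minor parents)`; the asymptotic 1-df chi-square is the
default with an exact binomial option for small `b+c`.

# The trio correlation test

The validation test replaces "correlation among case genotypes" with
"correlation among transmission residuals": `child − (father+mother)/2` has
expectation zero given the parents, so marginal association, population
stratification, and assortative mating cannot produce a signal — only a
departure from independent Mendelian transmission at the two loci can.
Pearson correlation over doubly-informative trios (at least one heterozygous
parent at each locus, default minimum 30) is tested with `z = r√n`. The
exact variance/weighting of the published form of this test is not
derivable from the source description; the plain residual-correlation form
is implemented and documented as such, and its null calibration is tested
directly (type-I within [0.04, 0.06] at α = 0.05; KS uniformity at 0.01).

# Set enrichment

`snps_in_set()` applies a closed 1-based interval `[start−5000, end+5000]`
per gene (BED-style half-open inputs must be converted on read; the boundary
is covered by tests at ±1 bp). `bh_fdr()` is the Benjamini–Hochberg step-up
(delegated to `stats::p.adjust`, equality-checked against a brute-force
min-over-tails oracle). `permuted_sets()` draws, for each target gene, one
of the 100 universe genes nearest in longest-transcript length (ties broken
by `(|Δlength|, name)` for determinism; without replacement within a set,
independently across the 100 permutations). The empirical P is the
proportion of permuted sets whose percentage of SNPs at q ≤ 0.2 reaches the
target set's — with 100 permutations its resolution is 0.01 and a result
below all permutations is reported `"<0.01"`.

Two deliberate choices: q = 0.2 is retained as the default threshold but is
explicitly a comparison device, not a significance claim (a sensitivity
sweep over q ∈ {0.05, 0.1, 0.2, 0.3} is a one-liner on the report); and BH
is applied *within* each set — target and permuted sets are analyzed by the
same protocol — with `fdr_scope = "global"` available. Calibration under
exchangeable null sets is tested against a genome-wide association mixture
(30% of SNPs carrying signal) rather than a flat-null table: with a flat
null the "% at q ≤ 0.2" summary is almost always zero, the ≥-rule ties make
the empirical P pile at 1, and uniformity is unobtainable by construction —
a known discreteness limitation of permutation P-values, not of the
implementation.

# Modifier-QTL meta-analysis

Trait scores are scaled to mean 0/variance 1 within group, |z| > 3 outliers
are excluded once (no iteration), and the remainder is re-scaled once so the
stated mean/variance contract holds after exclusion (the re-scale is this
package's addition and can be disabled). Per-group OLS with five covariates
mirrors ancestry-component adjustment; the covariate count is configurable.

`meta_analyze()` combines groups by inverse-variance fixed effects and
reports Cochran's `Q = Σwᵢ(βᵢ−β_FE)²` (chi-square, k−1 df) and the
Han–Eskin RE2 likelihood-ratio statistic testing `μ = 0, τ² = 0` jointly,
with the asymptotic `½χ²₁+½χ²₂` null. `τ²` is profiled by bounded
one-dimensional ML; tabulated finite-k critical values are intentionally
out of scope, so RE2 P-values for very small k are approximate. Q and the
fixed-effects fit are cross-checked against `metafor` in tests; RE2 is
validated behaviourally (null calibration, response to pure mean effect and
pure heterogeneity, rank agreement with FE under homogeneity).

`sibling_contrast()` annotates meta-analysis candidates with the sibling
association and flags SNPs significant in siblings as non-specific; the
"best group / supporting groups" labels follow the smallest per-group P and
effect-sign agreement.

# The synthetic-data generator

`simulate_trios()` draws founders from Hardy–Weinberg equilibrium at
unlinked loci, transmits alleles Mendelianly, and (optionally) rejection-
samples trios until the child is affected under a logistic model
`logit P(affected) = intercept + Σ βg + Σ γ g₁g₂`, with a cap on attempts
and a diagnostic when ascertainment is practically non-invertible. A single
root seed drives deterministic per-stage child seeds.

What it emulates: ascertainment-induced cross-locus correlation (the
epistasis signal), ascertainment-induced *marginal* transmission distortion
at interacting loci, pseudo-control structure, injectable missingness, and
multi-group quantitative traits with group-specific slopes and
heterogeneity. What it does not: linkage disequilibrium (the analysis
excludes same-chromosome pairs by design), the X chromosome, imputation
artifacts, genotyping batch structure, and real ancestry confounding —
passing tests therefore demonstrate statistical correctness of the methods
under the stated model, not robustness to every failure mode of real array
data. One subtlety: the logistic alternative is this package's choice of
generating model (the test itself only assumes multiplicativity under the
null); with strong main effects and common disease the logistic and
multiplicative models diverge, so null-calibration suites use modest main
effects and a low prevalence (~3%), where the divergence is negligible.

Problem sizes in the shipped suites were chosen to make Monte-Carlo error
small relative to the tested tolerances: ~1.07 million cross-chromosome
pairs (1,496 SNPs × 1,150 ascertained cases) for case-only type-I
calibration at α ∈ {1e-2, 1e-3, 1e-4} with binomial 99% bounds; 5,200 SNPs
× 700 trios for TDT uniformity; ≥ 2,000 pairs for trio-correlation
calibration; 4,109 trios — the reference study size — for validation-power
properties; 500 simulated SNP pairs at 3,000 cases / 3,000 controls for the
allelic-vs-logistic agreement.

# Known limitations

* RE2 uses the asymptotic mixture null only; for k = 2–4 groups its
  P-values are mildly conservative relative to tabulated critical values.
* The trio correlation test implements the plain residual-correlation form;
  finite-sample weighting refinements of the published variant are not
  reproduced.
* The genome-wide epistasis threshold depends on an external LD-group count
  and tested-genome fraction; it is exposed as a parameter (default
  `7.6e-10`), not derived.
* P-values from the allelic test are asymptotic; with fewer than ~20
  expected alleles in a cell the normal approximation (and the zero-cell
  correction) dominate behaviour — the screen reports cells so users can
  filter.
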