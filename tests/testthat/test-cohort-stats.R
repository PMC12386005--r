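test_that("genotype and allele frequencies reproduce the cohort report", {
  hla <- genotypeFrequencies(c(rep("XX", 117), rep("X58", 16)), "hla")
  expect_equal(hla$N, 133L)
  expect_equal(hla$genotypes$percent, c(87.97, 12.03, 0.00))
  expect_equal(hla$alleles$count, c(250L, 16L))
  expect_equal(hla$alleles$percent, c(93.98, 6.02))

  snp <- genotypeFrequencies(c(rep("GG", 112), rep("GA", 21)), "snp")
  expect_equal(snp$genotypes$percent, c(84.21, 15.79, 0.00))
  expect_equal(snp$alleles$percent, c(92.11, 7.89))
  expect_equal(snp$n_alleles, 266L)

  one <- genotypeFrequencies("XX", "hla")
  expect_equal(one$genotypes$percent, c(100, 0, 0))
  expect_equal(one$alleles$percent[2], 0)

  expect_error(genotypeFrequencies(c(NA, "indeterminate"), "hla"),
               "no callable")
})

test_that("frequencies conserve mass and Wilson CIs bracket estimates", {
  set.seed(9)
  for (rep in 1:10) {
    calls <- sample(c("XX", "X58", "HOM58"), sample(5:200, 1),
                    replace = TRUE)
    fr <- genotypeFrequencies(calls, "hla")
    expect_equal(sum(fr$genotypes$proportion), 1)
    expect_equal(sum(fr$alleles$count), 2L * fr$N)
    expect_true(all(fr$genotypes$ci_lower <= fr$genotypes$proportion +
                      1e-12))
    expect_true(all(fr$genotypes$ci_upper >= fr$genotypes$proportion -
                      1e-12))
  }
})

test_that("joint genotype table matches the published cross-tabulation", {
  hla <- c(rep("XX", 106), rep("XX", 11), rep("X58", 6), rep("X58", 10))
  snp <- c(rep("GG", 106), rep("GA", 11), rep("GG", 6), rep("GA", 10))
  ids <- sprintf("S%03d", seq_along(hla))
  jt <- jointGenotypeTable(setNames(hla, ids), setNames(snp, ids),
                           digits = 2)
  expect_equal(jt$counts["XX", "GG"], 106L)
  expect_equal(jt$counts["XX", "GA"], 11L)
  expect_equal(jt$counts["X58", "GG"], 6L)
  expect_equal(jt$counts["X58", "GA"], 10L)
  expect_equal(roundHalfUp(jt$percent["XX", "GG"], 1), 79.7)
  expect_equal(jt$percent["XX", "GA"], 8.27)
  expect_equal(jt$percent["X58", "GG"], 4.51)
  expect_equal(jt$percent["X58", "GA"], 7.52)

  expect_error(jointGenotypeTable(c(a = "XX"), c(b = "GG")),
               "no overlapping")
  single <- jointGenotypeTable(c(s = "X58"), c(s = "GA"))
  expect_equal(single$counts["X58", "GA"], 1L)
  expect_equal(sum(single$counts), 1L)
})

test_that("surrogate performance derives from the joint table margins", {
  jt <- list(counts = PAPER_JOINT_COUNTS, N = sum(PAPER_JOINT_COUNTS))
  sp <- surrogatePerformance(jt)
  est <- setNames(sp$estimate, sp$metric)
  expect_equal(est[["sensitivity"]], 10 / 16)
  expect_equal(est[["specificity"]], 106 / 117)
  expect_equal(est[["ppv"]], 10 / 21)
  expect_equal(est[["npv"]], 106 / 112)
  expect_true(all(sp$ci_lower <= sp$estimate & sp$estimate <= sp$ci_upper))

  perfect <- matrix(c(50L, 0L, 0L, 0L, 10L, 0L, 0L, 0L, 2L), 3, 3,
                    byrow = TRUE,
                    dimnames = dimnames(PAPER_JOINT_COUNTS))
  spp <- surrogatePerformance(list(counts = perfect, N = 62L))
  expect_equal(spp$estimate, rep(1, 4))

  none <- matrix(c(50L, 5L, 0L, rep(0L, 6)), 3, 3, byrow = TRUE,
                 dimnames = dimnames(PAPER_JOINT_COUNTS))
  spn <- surrogatePerformance(list(counts = none, N = 55L))
  expect_true(is.na(spn$estimate[spn$metric == "sensitivity"]))
  expect_match(spn$note[spn$metric == "sensitivity"], "zero margin")
})

test_that("EM haplotype estimates match the grid-search MLE oracle", {
  jt <- list(counts = PAPER_JOINT_COUNTS, N = sum(PAPER_JOINT_COUNTS))
  ld <- emHaplotypeLD(jt)
  oracle <- gridLDOracle(PAPER_JOINT_COUNTS, step = 1e-6)
  expect_lt(abs(ld$haplotypes[["p58A"]] - oracle$p58A), 1.5e-6)
  expect_equal(ld$p58, oracle$p58)
  expect_equal(ld$pA, oracle$pA)
  # margins preserved
  expect_equal(ld$haplotypes[["p58A"]] + ld$haplotypes[["p58G"]], ld$p58)
  expect_equal(ld$haplotypes[["p58A"]] + ld$haplotypes[["pXA"]], ld$pA)
  expect_true(abs(ld$Dprime) <= 1 + 1e-9)
  expect_true(ld$r2 >= 0 && ld$r2 <= 1)
})

test_that("EM equals direct counting when no double heterozygotes exist", {
  cc <- matrix(c(80L, 0L, 2L, 10L, 0L, 1L, 3L, 0L, 4L), 3, 3,
               byrow = TRUE, dimnames = dimnames(PAPER_JOINT_COUNTS))
  ld <- emHaplotypeLD(list(counts = cc, N = sum(cc)))
  N2 <- 2 * sum(cc)
  p58A <- (2 * cc["HOM58", "AA"] + cc["HOM58", "GA"] + cc["X58", "AA"]) / N2
  expect_equal(ld$haplotypes[["p58A"]], p58A, tolerance = 1e-9)
  expect_lte(ld$iterations, 2L)
})

test_that("perfect coupling reaches the D' = 1 boundary", {
  cc <- matrix(c(90L, 0L, 0L, 0L, 8L, 0L, 0L, 0L, 2L), 3, 3,
               byrow = TRUE, dimnames = dimnames(PAPER_JOINT_COUNTS))
  ld <- emHaplotypeLD(list(counts = cc, N = sum(cc)))
  expect_equal(ld$Dprime, 1, tolerance = 1e-6)
})

test_that("monomorphic locus reports zero LD with a note", {
  cc <- matrix(c(100L, 20L, 3L, rep(0L, 6)), 3, 3, byrow = TRUE,
               dimnames = dimnames(PAPER_JOINT_COUNTS))
  ld <- emHaplotypeLD(list(counts = cc, N = sum(cc)))
  expect_equal(ld$D, 0)
  expect_equal(ld$r2, 0)
  expect_identical(ld$note, "monomorphic")
})

test_that("EM matches the grid oracle over random small tables", {
  set.seed(314)
  for (rep in 1:25) {
    cc <- randomJointCounts(50)
    ld <- emHaplotypeLD(list(counts = cc, N = sum(cc)), tol = 1e-12)
    oracle <- gridLDOracle(cc, step = 1e-5)
    expect_lt(abs(ld$haplotypes[["p58A"]] - oracle$p58A), 1.5e-5,
              label = paste("table", rep))
    expect_gte(ld$logLik, oracle$logLik - 1e-6)
  }
})

test_that("exact HWE test agrees with the recurrence oracle", {
  expect_equal(hweExact(112, 21, 0), hweRecurrenceOracle(112, 21, 0))
  expect_equal(hweExact(25, 50, 25), hweRecurrenceOracle(25, 50, 25))
  expect_equal(hweExact(0, 0, 10), 1)
  expect_equal(hweExact(10, 0, 0), 1)
  set.seed(21)
  for (rep in 1:25) {
    N <- sample(5:80, 1)
    nr <- sample(0:N, 1)
    het <- if (nr == 0) 0 else sample(seq(nr %% 2, min(nr, 2 * N - nr),
                                          by = 2), 1)
    hom_r <- (nr - het) / 2
    hom_c <- N - het - hom_r
    expect_equal(hweExact(hom_c, het, hom_r),
                 hweRecurrenceOracle(hom_c, het, hom_r),
                 tolerance = 1e-10,
                 label = sprintf("(%d,%d,%d)", hom_c, het, hom_r))
  }
})

test_that("HWE p-values live in [0, 1] and equilibrium data score high", {
  p <- hweExact(25, 50, 25)
  expect_gte(p, 0.5)  # most probable configuration is included
  expect_lte(p, 1)
})
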