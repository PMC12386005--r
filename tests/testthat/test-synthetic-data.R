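test_that("simulationConfig validates its inputs", {
  expect_error(simulationConfig(mode = "sample"), "requires n")
  expect_error(simulationConfig(
    amplicon_lengths = c(HLAB_exon2 = 613L, HLAB_exon3 = 380L,
                         PSORS1C1_exon3 = 265L)), "shorter")
  expect_error(simulationConfig(mode = "sample", n = 10,
                                haplotype_freqs = c(p58A = 0.5, p58G = 0.2,
                                                    pXA = 0.2, pXG = 0.2)))
  cfg <- simulationConfig()
  expect_equal(cfg$n, 133L)
  expect_equal(sum(cfg$roster), 133L)
})

test_that("synthetic allele database embeds the published panel", {
  db <- makeAlleleDb(simulationConfig(seed = 2L))
  panel <- hlaB5801Panel()
  expect_true(verifyPanel(list(db$HLAB_exon3, db$HLAB_exon2), panel)$ok)
  pp <- panelPositions(panel)
  m3 <- as.character(alignedSequences(db$HLAB_exon3))
  p3 <- pp[pp$amplicon == "HLAB_exon3", ]
  tgt <- strsplit(m3[["B*58:01:01"]], "")[[1]]
  ref <- strsplit(m3[["HLA00132.1"]], "")[[1]]
  expect_identical(tgt[p3$position], p3$target_base)
  expect_identical(ref[p3$position], p3$reference_base)
  # no decoy carries the target base at any panel position
  for (nm in grep("DECOY", names(m3), value = TRUE)) {
    d <- strsplit(m3[[nm]], "")[[1]]
    expect_false(any(d[p3$position] == p3$target_base), label = nm)
  }
  # SNP amplicon: G and A haplotype sequences differing only at 110
  ps <- as.character(alignedSequences(db$PSORS1C1_exon3))
  g <- strsplit(ps[["rs9263726_G"]], "")[[1]]
  a <- strsplit(ps[["rs9263726_A"]], "")[[1]]
  expect_identical(which(g != a), 110L)
  expect_identical(g[110], "G")
  expect_identical(a[110], "A")
})

test_that("zero decoy divergence keeps the panel unique", {
  db <- makeAlleleDb(simulationConfig(seed = 4L, decoy_divergence = 0))
  expect_true(verifyPanel(list(db$HLAB_exon3, db$HLAB_exon2),
                          hlaB5801Panel())$ok)
})

test_that("roster mode reproduces exact joint counts", {
  roster <- simulateCohort(simulationConfig(seed = 8L))
  tab <- table(factor(roster$hla_genotype, c("XX", "X58", "HOM58")),
               factor(roster$snp_genotype, c("GG", "GA", "AA")))
  expect_equal(unclass(tab)[, ],
               unclass(PAPER_JOINT_COUNTS)[, ], ignore_attr = TRUE)
  expect_equal(nrow(roster), 133L)
  expect_equal(sum(roster$sex == "male"), 124L)
  # carriers placed among males (allele absent in the study's females)
  expect_true(all(roster$sex[roster$hla_genotype != "XX"] == "male"))
})

test_that("sample mode draws haplotypes at the configured frequencies", {
  hf <- c(p58A = 0.05, p58G = 0.01, pXA = 0.03, pXG = 0.91)
  cfg <- simulationConfig(mode = "sample", n = 5000L, seed = 11L,
                          haplotype_freqs = hf)
  roster <- simulateCohort(cfg)
  haps <- c(roster$hap1, roster$hap2)
  emp <- table(factor(haps, c("58-A", "58-G", "X-A", "X-G"))) /
    length(haps)
  expect_true(all(abs(as.numeric(emp) - unname(hf)) < 0.01))
  # genotype categories consistent with the haplotypes
  n58 <- (roster$hap1 %in% c("58-A", "58-G")) +
    (roster$hap2 %in% c("58-A", "58-G"))
  expect_identical(roster$hla_genotype,
                   c("XX", "X58", "HOM58")[n58 + 1L])

  degenerate <- simulateCohort(simulationConfig(
    mode = "sample", n = 20L, seed = 1L,
    haplotype_freqs = c(p58A = 1, p58G = 0, pXA = 0, pXG = 0)))
  expect_true(all(degenerate$hla_genotype == "HOM58"))
  expect_true(all(degenerate$snp_genotype == "AA"))
})

test_that("consensus synthesis produces the expected heterozygote codes", {
  cfg <- simulationConfig(seed = 6L, n_decoys = 0L)
  db <- makeAlleleDb(cfg)
  roster <- data.frame(sample_id = c("HET", "HOM", "WT"),
                       hla_genotype = c("X58", "HOM58", "XX"),
                       snp_genotype = c("GA", "AA", "GG"),
                       hap1 = c("58-A", "58-A", "X-G"),
                       hap2 = c("X-G", "58-A", "X-G"),
                       sex = "male", stringsAsFactors = FALSE)
  seqs <- synthesizeSequences(roster, db, seed = 6L)
  e3 <- seqs$HLAB_exon3
  # with only the reference as partner, the exon-3 panel shows
  # Y at 353 (C/T), M at 355 (A/C), A at 368, S at 379 and 387 (C/G)
  chars <- strsplit(e3[["HET"]], "")[[1]]
  expect_identical(chars[c(353, 355, 368, 379, 387)],
                   c("Y", "M", "A", "S", "S"))
  e2 <- strsplit(seqs$HLAB_exon2[["HET"]], "")[[1]]
  expect_identical(e2[c(209, 285, 319)], c("A", "R", "S"))
  # homozygote: plain target bases, no ambiguity codes anywhere
  expect_identical(seqs$HLAB_exon3[["HOM"]],
                   as.character(alignedSequences(db$HLAB_exon3))[["B*58:01:01"]])
  # non-carrier with reference/reference: reference verbatim
  expect_identical(seqs$HLAB_exon3[["WT"]],
                   as.character(alignedSequences(db$HLAB_exon3))[["HLA00132.1"]])
  # SNP consensus
  expect_identical(substr(seqs$PSORS1C1_exon3[["HET"]], 110, 110), "R")
  expect_identical(substr(seqs$PSORS1C1_exon3[["HOM"]], 110, 110), "A")
  expect_identical(substr(seqs$PSORS1C1_exon3[["WT"]], 110, 110), "G")
})

test_that("de-consensusing a heterozygote recovers the target bases", {
  cfg <- simulationConfig(seed = 13L)
  db <- makeAlleleDb(cfg)
  roster <- simulateCohort(cfg)
  seqs <- synthesizeSequences(roster, db, seed = 13L)
  tab <- iupacTable()
  ref <- strsplit(as.character(
    alignedSequences(db$HLAB_exon3))[["HLA00132.1"]], "")[[1]]
  pp <- panelPositions(hlaB5801Panel())
  p3 <- pp[pp$amplicon == "HLAB_exon3", ]
  hets <- roster$sample_id[roster$hla_genotype == "X58"]
  for (id in hets[1:5]) {
    chars <- strsplit(seqs$HLAB_exon3[[id]], "")[[1]]
    for (i in seq_len(nrow(p3))) {
      set <- tab[[chars[p3$position[i]]]]
      expect_true(p3$target_base[i] %in% set)
    }
  }
})

test_that("generation is byte-deterministic given config and seed", {
  cfg <- simulationConfig(seed = 99L)
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  runSimulate(cfg, d1)
  runSimulate(cfg, d2)
  for (f in c("HLAB_exon3.fasta", "HLAB_exon2.fasta",
              "PSORS1C1_exon3.fasta", "cohort.csv", "truth_roster.tsv",
              file.path("allele_db", "HLAB_exon3_alleles.fasta"))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the bytes
  d3 <- tempfile("sim3")
  runSimulate(simulationConfig(seed = 100L), d3)
  expect_false(identical(readLines(file.path(d1, "HLAB_exon3.fasta")),
                         readLines(file.path(d3, "HLAB_exon3.fasta"))))
})

test_that("end-to-end recovery holds over random rosters", {
  set.seed(2024)
  for (rep in 1:8) {
    roster_counts <- matrix(
      c(sample(0:40, 1), sample(0:10, 1), sample(0:3, 1),
        sample(0:10, 1), sample(0:10, 1), sample(0:3, 1),
        sample(0:3, 1), sample(0:3, 1), sample(0:3, 1)),
      3, 3, byrow = TRUE, dimnames = dimnames(PAPER_JOINT_COUNTS))
    if (sum(roster_counts) == 0) roster_counts["XX", "GG"] <- 5L
    cfg <- simulationConfig(roster = roster_counts,
                            seed = sample.int(1e6, 1))
    db <- makeAlleleDb(cfg)
    roster <- simulateCohort(cfg)
    dir <- tempfile("rt")
    synthesizeSequences(roster, db, seed = cfg$seed, out_dir = dir)
    calls <- suppressMessages(callCohort(
      file.path(dir, "HLAB_exon3.fasta"),
      file.path(dir, "HLAB_exon2.fasta"),
      file.path(dir, "PSORS1C1_exon3.fasta")))
    m <- merge(calls, roster, by = "sample_id")
    expect_identical(m$hla_call, m$hla_genotype)
    expect_identical(m$snp_call, m$snp_genotype)
    unlink(dir, recursive = TRUE)
  }
})

test_that("paraclinical generator honours means, effects and truth logs", {
  cfg <- simulationConfig(mode = "sample", n = 5000L, seed = 17L,
                          uri_correlations = c(Cre = 0.2),
                          genotype_effects = c(WBC = 2.7))
  roster <- simulateCohort(cfg)
  cohort <- simulateParaclinical(roster, cfg)
  expect_equal(nrow(cohort), 5000L)
  expect_true(all(c("truth_correlations", "truth_effects") %in%
                    names(attributes(cohort))))
  expect_lt(abs(mean(cohort$Uri) - cfg$para_means[["Uri"]]), 5)
  expect_lt(abs(cor(cohort$Cre, cohort$Uri) - 0.2), 0.03)
  carrier <- roster$hla_genotype != "XX"
  expect_lt(abs(mean(cohort$WBC[carrier]) - mean(cohort$WBC[!carrier])
                - 2.7), 0.5)

  # independence configuration: no spurious structure
  cfg0 <- simulationConfig(mode = "sample", n = 2000L, seed = 18L,
                           uri_correlations = c(Cre = 0),
                           genotype_effects = c())
  cohort0 <- simulateParaclinical(simulateCohort(cfg0), cfg0)
  expect_lt(abs(cor(cohort0$Cre, cohort0$Uri)), 0.05)
})
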