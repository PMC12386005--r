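# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force / closed form so
# the package code paths are checked against something they do not share.

# grid-search maximum-likelihood two-locus haplotype frequencies:
# scans p(58:01-A) over its feasible range with fixed allele margins
gridLDOracle <- function(counts, step = 1e-6) {
  N <- sum(counts)
  p58 <- (2 * sum(counts["HOM58", ]) + sum(counts["X58", ])) / (2 * N)
  pA <- (2 * sum(counts[, "AA"]) + sum(counts[, "GA"])) / (2 * N)
  lo <- max(0, p58 + pA - 1)
  hi <- min(p58, pA)
  grid <- seq(lo, hi, by = step)
  loglik <- vapply(grid, function(p11) {
    h <- c(p11, p58 - p11, pA - p11, 1 - p58 - pA + p11)
    gp <- rbind(
      XX = c(GG = h[4]^2, GA = 2 * h[3] * h[4], AA = h[3]^2),
      X58 = c(2 * h[2] * h[4], 2 * (h[1] * h[4] + h[2] * h[3]),
              2 * h[1] * h[3]),
      HOM58 = c(h[2]^2, 2 * h[1] * h[2], h[1]^2))
    cc <- counts[rownames(gp), colnames(gp)]
    if (any(gp[cc > 0] <= 0)) return(-Inf)
    sum(cc[cc > 0] * log(gp[cc > 0]))
  }, numeric(1))
  list(p58A = grid[which.max(loglik)], logLik = max(loglik),
       p58 = p58, pA = pA)
}

# exact HWE p-value via the heterozygote-count ratio recurrence
# (independent of the package's log-factorial enumeration)
hweRecurrenceOracle <- function(n_hom_common, n_het, n_hom_rare) {
  N <- n_hom_common + n_het + n_hom_rare
  nr <- 2 * n_hom_rare + n_het
  nc <- 2 * N - nr
  if (nr == 0 || nc == 0) return(1)
  hets <- seq(nr %% 2, min(nr, nc), by = 2)
  p <- numeric(length(hets))
  p[1] <- 1
  if (length(hets) > 1) {
    for (i in 2:length(hets)) {
      h <- hets[i]
      # P(h) / P(h-2) = 4 * a(h-2) * b(h-2) / (h * (h-1))
      a <- (nr - (h - 2)) / 2
      b <- (nc - (h - 2)) / 2
      p[i] <- p[i - 1] * 4 * a * b / (h * (h - 1))
    }
  }
  p <- p / sum(p)
  pobs <- p[hets == n_het]
  sum(p[p <= pobs * (1 + 1e-12)])
}

# random 3x3 joint genotype table with both loci polymorphic
randomJointCounts <- function(maxN = 50) {
  repeat {
    cc <- matrix(rmultinom(1, sample(5:maxN, 1), prob = runif(9)),
                 3, 3, dimnames = list(hla = c("XX", "X58", "HOM58"),
                                       snp = c("GG", "GA", "AA")))
    N <- sum(cc)
    p58 <- (2 * sum(cc["HOM58", ]) + sum(cc["X58", ])) / (2 * N)
    pA <- (2 * sum(cc[, "AA"]) + sum(cc[, "GA"])) / (2 * N)
    if (p58 > 0 && p58 < 1 && pA > 0 && pA < 1) return(cc)
  }
}

# tiny hand-built alignment fixture: target + reference + decoys with
# controlled differing columns
tinyAlignment <- function(len = 40, nDecoys = 5, seed = 42) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  tgt <- ref
  diagPos <- sort(sample(seq_len(len), 3L))
  for (j in diagPos) tgt[j] <- setdiff(c("A", "C", "G", "T"), ref[j])[1]
  alleles <- list(REF = ref, TGT = tgt)
  for (k in seq_len(nDecoys)) {
    d <- ref
    for (j in diagPos) d[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                              tgt[j]), 1)
    mut <- sample(setdiff(seq_len(len), diagPos), 3)
    for (j in mut) d[j] <- sample(setdiff(c("A", "C", "G", "T"), d[j]), 1)
    alleles[[paste0("D", k)]] <- d
  }
  aln <- AlleleAlignment(vapply(alleles, paste, character(1),
                                collapse = ""),
                         amplicon = "HLAB_exon3", target = "TGT",
                         reference = "REF")
  list(alignment = aln, diag_positions = diagPos)
}

writeTempFasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

PAPER_JOINT_COUNTS <- matrix(
  c(106L, 11L, 0L, 6L, 10L, 0L, 0L, 0L, 0L),
  nrow = 3, byrow = TRUE,
  dimnames = list(hla = c("XX", "X58", "HOM58"),
                  snp = c("GG", "GA", "AA")))
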