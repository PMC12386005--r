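#' @include AllClasses.R allele-reference.R genotype-calling.R
NULL

# run expr under a deterministic sub-seed without disturbing the caller's
# RNG stream
.withSeed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.subSeed(seed, tag))
  expr
}

.DEFAULT_ROSTER <- matrix(
  c(106L, 11L, 0L,
    6L, 10L, 0L,
    0L, 0L, 0L),
  nrow = 3, byrow = TRUE,
  dimnames = list(hla = c("XX", "X58", "HOM58"),
                  snp = c("GG", "GA", "AA")))

.DEFAULT_MEANS <- c(
  RBC = 5.120, HGB = 138.11, HCT = 41.188, WBC = 9.649, NE = 48.277,
  LYM = 19.097, PLT = 274.315, Glu = 6.313, Ure = 6.542, Cre = 104.171,
  Uri = 522.868, TC = 5.102, TG = 2.792, HDL_C = 1.295, LDL_C = 2.818)

.DEFAULT_SDS <- c(
  RBC = 1.356, HGB = 18.348, HCT = 4.857, WBC = 3.036, NE = 27.121,
  LYM = 13.672, PLT = 74.725, Glu = 2.855, Ure = 3.337, Cre = 36.676,
  Uri = 92.849, TC = 0.999, TG = 1.680, HDL_C = 0.328, LDL_C = 0.837)

# cohort-wide Pearson correlations of each variable with uric acid
.DEFAULT_URI_COR <- c(
  RBC = -0.0006, HGB = -0.064, HCT = -0.061, WBC = 0.013, NE = -0.027,
  LYM = 0.074, PLT = 0.174, Glu = -0.038, Ure = 0.159, Cre = 0.195,
  TC = -0.045, TG = -0.079, HDL_C = 0.025, LDL_C = -0.034)

#' Build a simulation configuration
#'
#' Central configuration for the synthetic-data generator. The defaults
#' encode the study conditions being emulated: a 133-subject gout cohort
#' with the observed joint genotype roster, 93.2% male, male/female age
#' distributions N(51.44, 14.59^2) / N(70.33, 10.64^2), amplicon lengths
#' 613/495/265 bp, paraclinical means and SDs of the non-carrier group,
#' cohort correlations of each variable with uric acid, and a +2.702
#' WBC shift in *58:01 carriers.
#'
#' @param mode \code{"roster"} (exact joint genotype counts) or
#'   \code{"sample"} (draw two haplotypes per subject from haplotype
#'   frequencies).
#' @param roster 3x3 integer matrix of joint counts (HLA rows XX, X58,
#'   HOM58; SNP columns GG, GA, AA); roster mode only.
#' @param haplotype_freqs named numeric (p58A, p58G, pXA, pXG) summing to
#'   1; sample mode only.
#' @param n cohort size; sample mode only (roster mode uses the roster
#'   sum).
#' @param seed integer master seed; every module derives its own
#'   sub-stream from it.
#' @param amplicon_lengths named integer vector (HLAB_exon2, HLAB_exon3,
#'   PSORS1C1_exon3).
#' @param n_decoys number of decoy alleles in the HLA-B allele database.
#' @param decoy_divergence per-base substitution rate of decoys away from
#'   the reference (outside the panel positions).
#' @param male_prop proportion of males; converted to an exact count.
#' @param carriers_male assign *58:01 carriers to male subjects (the
#'   allele was absent in the study's females).
#' @param age_mean,age_sd named numeric (male, female).
#' @param para_means,para_sds named numeric over the paraclinical
#'   variables.
#' @param uri_correlations named numeric: target Pearson correlation of
#'   each variable with \code{Uri}.
#' @param genotype_effects named numeric: additive mean shift applied to
#'   that variable in *58:01 carriers.
#' @param snp_position rs9263726 position in the PSORS1C1 amplicon frame.
#' @return a \code{list} of class \code{"hlaSimConfig"}.
#' @export
simulationConfig <- function(mode = c("roster", "sample"),
                             roster = .DEFAULT_ROSTER,
                             haplotype_freqs = NULL,
                             n = NULL,
                             seed = 1L,
                             amplicon_lengths = c(HLAB_exon2 = 613L,
                                                  HLAB_exon3 = 495L,
                                                  PSORS1C1_exon3 = 265L),
                             n_decoys = 20L,
                             decoy_divergence = 0.02,
                             male_prop = 124 / 133,
                             carriers_male = TRUE,
                             age_mean = c(male = 51.44, female = 70.33),
                             age_sd = c(male = 14.59, female = 10.64),
                             para_means = .DEFAULT_MEANS,
                             para_sds = .DEFAULT_SDS,
                             uri_correlations = .DEFAULT_URI_COR,
                             genotype_effects = c(WBC = 2.702),
                             snp_position = 110L) {
  mode <- match.arg(mode)
  if (mode == "roster") {
    roster <- as.matrix(roster)
    storage.mode(roster) <- "integer"
    stopifnot(all(dim(roster) == c(3L, 3L)), all(roster >= 0L))
    dimnames(roster) <- dimnames(.DEFAULT_ROSTER)
    n <- sum(roster)
  } else {
    if (is.null(haplotype_freqs))
      haplotype_freqs <- c(p58A = 0.05, p58G = 0.01, pXA = 0.03,
                           pXG = 0.91)
    stopifnot(abs(sum(haplotype_freqs) - 1) < 1e-9,
              all(haplotype_freqs >= 0))
    if (is.null(n)) .stopf("sample mode requires n")
    roster <- NULL
  }
  if (n < 1L) .stopf("cohort size must be >= 1")
  pp <- panelPositions(hlaB5801Panel())
  need <- c(HLAB_exon2 = max(pp$position[pp$amplicon == "HLAB_exon2"]),
            HLAB_exon3 = max(pp$position[pp$amplicon == "HLAB_exon3"]),
            PSORS1C1_exon3 = snp_position)
  if (any(amplicon_lengths[names(need)] < need))
    .stopf("amplicon shorter than its largest panel position")
  structure(list(
    mode = mode, roster = roster, haplotype_freqs = haplotype_freqs,
    n = as.integer(n), seed = as.integer(seed),
    amplicon_lengths = amplicon_lengths, n_decoys = as.integer(n_decoys),
    decoy_divergence = decoy_divergence, male_prop = male_prop,
    carriers_male = carriers_male, age_mean = age_mean, age_sd = age_sd,
    para_means = para_means, para_sds = para_sds,
    uri_correlations = uri_correlations,
    genotype_effects = genotype_effects,
    snp_position = as.integer(snp_position)), class = "hlaSimConfig")
}

.randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutate <- function(chars, idx, avoid = NULL) {
  for (j in idx) {
    pool <- setdiff(c("A", "C", "G", "T"), c(chars[j], avoid[[as.character(j)]]))
    chars[j] <- sample(pool, 1L)
  }
  chars
}

#' Generate a synthetic allele reference database
#'
#' Fabricates per-amplicon aligned allele sets embedding the published
#' diagnostic bases: the reference carries the published reference bases
#' at the panel positions, the target (B*58:01 stand-in) carries the
#' target bases, and every decoy allele differs from the target at every
#' panel position (at a panel position a decoy keeps the reference base
#' or takes a third base) plus seeded random substitutions elsewhere.
#' The PSORS1C1 amplicon gets a two-allele set (G and A at the SNP
#' position). This synthetic database stands in for a curated allele
#' alignment; it is constructed so that the published panel is the exact
#' per-position diagnostic set.
#'
#' @param config a [simulationConfig()].
#' @param seed overrides \code{config$seed} if given.
#' @return named list of [AlleleAlignment-class] objects
#'   (\code{HLAB_exon3}, \code{HLAB_exon2}, \code{PSORS1C1_exon3}).
#' @export
makeAlleleDb <- function(config = simulationConfig(), seed = config$seed) {
  panel <- panelPositions(hlaB5801Panel())
  .withSeed(seed, "allele_db", {
    db <- list()
    for (amp in c("HLAB_exon3", "HLAB_exon2")) {
      len <- config$amplicon_lengths[[amp]]
      pp <- panel[panel$amplicon == amp, , drop = FALSE]
      ref <- strsplit(.randomSeq(len), "")[[1]]
      ref[pp$position] <- pp$reference_base
      tgt <- ref
      tgt[pp$position] <- pp$target_base
      alleles <- list(HLA00132.1 = ref, `B*58:01:01` = tgt)
      for (k in seq_len(config$n_decoys)) {
        d <- ref
        # decoys never share the target base at a panel position
        for (i in seq_len(nrow(pp))) {
          j <- pp$position[i]
          d[j] <- if (stats::runif(1) < 0.7 &&
                      pp$reference_base[i] != pp$target_base[i])
            pp$reference_base[i]
          else
            sample(setdiff(c("A", "C", "G", "T"), pp$target_base[i]), 1L)
        }
        nmut <- stats::rbinom(1L, len, config$decoy_divergence)
        if (nmut > 0L) {
          at <- sample(setdiff(seq_len(len), pp$position),
                       min(nmut, len - nrow(pp)))
          d <- .mutate(d, at)
        }
        alleles[[sprintf("B*DECOY:%02d", k)]] <- d
      }
      seqs <- vapply(alleles, paste, character(1), collapse = "")
      db[[amp]] <- AlleleAlignment(seqs, amplicon = amp,
                                   target = "B*58:01:01",
                                   reference = "HLA00132.1")
    }
    len <- config$amplicon_lengths[["PSORS1C1_exon3"]]
    g <- strsplit(.randomSeq(len), "")[[1]]
    g[config$snp_position] <- "G"
    a <- g
    a[config$snp_position] <- "A"
    db[["PSORS1C1_exon3"]] <- AlleleAlignment(
      c(rs9263726_G = paste(g, collapse = ""),
        rs9263726_A = paste(a, collapse = "")),
      amplicon = "PSORS1C1_exon3",
      target = "rs9263726_A", reference = "rs9263726_G")
    db
  })
}

#' Write an allele database as per-amplicon FASTA files
#'
#' @param db list from [makeAlleleDb()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
writeAlleleDb <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(db), function(amp) {
    p <- file.path(dir, paste0(amp, "_alleles.fasta"))
    Biostrings::writeXStringSet(alignedSequences(db[[amp]]), p, width = 80L)
    p
  }, character(1))
  paths
}

#' Simulate the true genotype roster of a cohort
#'
#' Roster mode reproduces the configured joint genotype counts exactly,
#' assigning genotypes to sample ids in a seeded shuffle; sample mode
#' draws two haplotypes per subject from the configured haplotype
#' frequencies. Sex is assigned as an exact male count
#' (\code{round(male_prop * n)}); with \code{carriers_male = TRUE} the
#' *58:01 carriers are placed among the males. Phase is recorded for
#' every subject (for double heterozygotes it is drawn, and in sample
#' mode it follows from the drawn haplotypes).
#'
#' @param config a [simulationConfig()].
#' @return data.frame (the truth roster): \code{sample_id},
#'   \code{hla_genotype}, \code{snp_genotype}, \code{hap1}, \code{hap2}
#'   (each \code{"58-A"}, \code{"58-G"}, \code{"X-A"} or \code{"X-G"}),
#'   \code{sex}.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  .withSeed(config$seed, "cohort", {
    if (config$mode == "roster") {
      cells <- expand.grid(hla = rownames(config$roster),
                           snp = colnames(config$roster),
                           stringsAsFactors = FALSE)
      hla <- rep(cells$hla, config$roster[cbind(cells$hla, cells$snp)])
      snp <- rep(cells$snp, config$roster[cbind(cells$hla, cells$snp)])
      n <- length(hla)
      if (n != config$n) .stopf("roster counts do not sum to n")
      # phase: known except for the double heterozygote, drawn at random
      h58 <- ifelse(hla == "HOM58", 2L, ifelse(hla == "X58", 1L, 0L))
      hA <- ifelse(snp == "AA", 2L, ifelse(snp == "GA", 1L, 0L))
      coupling <- stats::runif(n) < 0.5
      hap1 <- hap2 <- character(n)
      for (i in seq_len(n)) {
        a1 <- if (h58[i] >= 1L) "58" else "X"
        a2 <- if (h58[i] == 2L) "58" else "X"
        b1 <- if (hA[i] >= 1L) "A" else "G"
        b2 <- if (hA[i] == 2L) "A" else "G"
        if (h58[i] == 1L && hA[i] == 1L && !coupling[i]) {
          hap1[i] <- paste0(a1, "-", b2); hap2[i] <- paste0(a2, "-", b1)
        } else {
          hap1[i] <- paste0(a1, "-", b1); hap2[i] <- paste0(a2, "-", b2)
        }
      }
      ord <- sample.int(n)
      hla <- hla[ord]; snp <- snp[ord]
      hap1 <- hap1[ord]; hap2 <- hap2[ord]
    } else {
      n <- config$n
      haps <- names(config$haplotype_freqs)
      hapLabels <- c(p58A = "58-A", p58G = "58-G", pXA = "X-A",
                     pXG = "X-G")[haps]
      draw <- matrix(sample(hapLabels, 2L * n, replace = TRUE,
                            prob = config$haplotype_freqs), ncol = 2L)
      hap1 <- draw[, 1L]; hap2 <- draw[, 2L]
      n58 <- (hap1 %in% c("58-A", "58-G")) + (hap2 %in% c("58-A", "58-G"))
      nA <- (hap1 %in% c("58-A", "X-A")) + (hap2 %in% c("58-A", "X-A"))
      hla <- c("XX", "X58", "HOM58")[n58 + 1L]
      snp <- c("GG", "GA", "AA")[nA + 1L]
    }
    nMale <- as.integer(round(config$male_prop * n))
    sex <- rep("female", n)
    if (config$carriers_male) {
      carriers <- which(hla != "XX")
      males <- carriers[seq_len(min(length(carriers), nMale))]
      rest <- setdiff(seq_len(n), carriers)
      males <- c(males, sample(rest, max(0L, nMale - length(males))))
      sex[males] <- "male"
    } else {
      sex[sample.int(n, nMale)] <- "male"
    }
    data.frame(sample_id = sprintf("S%04d", seq_len(n)),
               hla_genotype = hla, snp_genotype = snp,
               hap1 = hap1, hap2 = hap2, sex = sex,
               stringsAsFactors = FALSE)
  })
}

# diploid consensus of two aligned sequences using IUPAC two-base codes
.consensusSeq <- function(s1, s2) {
  if (s1 == s2) return(s1)
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  out <- c1
  diff <- which(c1 != c2)
  key <- ifelse(c1[diff] < c2[diff],
                paste0(c1[diff], c2[diff]), paste0(c2[diff], c1[diff]))
  out[diff] <- .PAIR_TO_CODE[key]
  paste(out, collapse = "")
}

#' Synthesize diploid consensus FASTA files for a cohort
#'
#' For every subject the two allele sequences of each amplicon are merged
#' into one Sanger-style consensus: agreeing positions keep the base,
#' disagreeing positions get the IUPAC two-base code (e.g. C/T -> Y).
#' *58:01 carriers get the target allele plus a partner drawn from the
#' non-target alleles (reference or decoys); non-carriers draw both
#' alleles from the non-target pool. The PSORS1C1 consensus merges the G
#' and A haplotype sequences according to the true SNP genotype.
#'
#' @param roster truth roster from [simulateCohort()].
#' @param db allele database from [makeAlleleDb()].
#' @param seed seed for the partner-allele draws.
#' @param out_dir if non-NULL, write \code{HLAB_exon3.fasta},
#'   \code{HLAB_exon2.fasta} and \code{PSORS1C1_exon3.fasta} there.
#' @return (invisibly when writing) list with per-amplicon named
#'   character vectors of consensus sequences and, if written,
#'   \code{paths}.
#' @export
synthesizeSequences <- function(roster, db, seed = 1L, out_dir = NULL) {
  .withSeed(seed, "sequences", {
    nonTarget <- setdiff(alleleNames(db$HLAB_exon3),
                         targetAllele(db$HLAB_exon3))
    miss2 <- setdiff(nonTarget, alleleNames(db$HLAB_exon2))
    if (length(miss2))
      .stopf("allele(s) %s missing from exon-2 alignment",
             paste(miss2, collapse = ", "))
    n <- nrow(roster)
    a1 <- a2 <- character(n)
    for (i in seq_len(n)) {
      g <- roster$hla_genotype[i]
      if (g == "HOM58") {
        a1[i] <- a2[i] <- targetAllele(db$HLAB_exon3)
      } else if (g == "X58") {
        a1[i] <- targetAllele(db$HLAB_exon3)
        a2[i] <- sample(nonTarget, 1L)
      } else {
        a1[i] <- sample(nonTarget, 1L)
        a2[i] <- sample(nonTarget, 1L)
      }
    }
    out <- list()
    for (amp in c("HLAB_exon3", "HLAB_exon2")) {
      seqs <- as.character(alignedSequences(db[[amp]]))
      pairKey <- ifelse(a1 < a2, paste(a1, a2), paste(a2, a1))
      cons <- vapply(unique(pairKey), function(k) {
        ab <- strsplit(k, " ")[[1]]
        .consensusSeq(seqs[[ab[1]]], seqs[[if (length(ab) == 2L) ab[2]
                                           else ab[1]]])
      }, character(1))
      out[[amp]] <- stats::setNames(cons[pairKey], roster$sample_id)
    }
    pseqs <- as.character(alignedSequences(db$PSORS1C1_exon3))
    gseq <- pseqs[[referenceAllele(db$PSORS1C1_exon3)]]
    aseq <- pseqs[[targetAllele(db$PSORS1C1_exon3)]]
    pcons <- c(GG = gseq, AA = aseq, GA = .consensusSeq(gseq, aseq))
    out[["PSORS1C1_exon3"]] <- stats::setNames(
      pcons[roster$snp_genotype], roster$sample_id)

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- vapply(names(out), function(amp) {
        p <- file.path(out_dir, paste0(amp, ".fasta"))
        x <- Biostrings::BStringSet(out[[amp]])
        Biostrings::writeXStringSet(x, p, width = 80L)
        p
      }, character(1))
      out$paths <- paths
    }
    out
  })
}

#' Simulate the paraclinical table for a cohort
#'
#' Ages are drawn per sex from the configured normal distributions
#' (truncated at 18 years). The paraclinical variables are drawn from a
#' multivariate normal whose correlation matrix carries the configured
#' variable-uric-acid correlations (adjusted to the nearest positive
#' definite matrix when needed); genotype effects are then added as mean
#' shifts in *58:01 carriers. The generator truths are attached as
#' attributes \code{"truth_correlations"} and \code{"truth_effects"}.
#'
#' @param roster truth roster from [simulateCohort()].
#' @param config a [simulationConfig()].
#' @return data.frame: sample_id, sex, age and the paraclinical columns.
#' @export
simulateParaclinical <- function(roster, config = simulationConfig()) {
  .withSeed(config$seed, "paraclinical", {
    n <- nrow(roster)
    age <- numeric(n)
    for (s in c("male", "female")) {
      idx <- roster$sex == s
      a <- stats::rnorm(sum(idx), config$age_mean[[s]], config$age_sd[[s]])
      age[idx] <- round(pmax(a, 18))
    }
    vars <- names(config$para_means)
    R <- diag(length(vars))
    dimnames(R) <- list(vars, vars)
    for (v in names(config$uri_correlations)) {
      if (v %in% vars && "Uri" %in% vars) {
        R[v, "Uri"] <- R["Uri", v] <- config$uri_correlations[[v]]
      }
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
      dimnames(R) <- list(vars, vars)
    }
    D <- diag(config$para_sds[vars])
    Sigma <- D %*% R %*% D
    X <- MASS::mvrnorm(n, mu = config$para_means[vars], Sigma = Sigma)
    colnames(X) <- vars
    carrier <- roster$hla_genotype %in% c("X58", "HOM58")
    for (v in names(config$genotype_effects)) {
      if (v %in% vars)
        X[carrier, v] <- X[carrier, v] + config$genotype_effects[[v]]
    }
    out <- data.frame(sample_id = roster$sample_id, sex = roster$sex,
                      age = age, X, stringsAsFactors = FALSE)
    attr(out, "truth_correlations") <- R
    attr(out, "truth_effects") <- config$genotype_effects
    out
  })
}
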