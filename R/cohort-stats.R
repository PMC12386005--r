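#' @include utils.R
NULL

.HLA_LEVELS <- c("XX", "X58", "HOM58")
.SNP_LEVELS <- c("GG", "GA", "AA")

# genotype vector -> validated factor table over the scheme's levels,
# missing/indeterminate/unconfirmed dropped with a count kept aside
.genotypeCounts <- function(calls, levels) {
  keep <- calls %in% levels
  n_dropped <- sum(!keep & !is.na(calls)) + sum(is.na(calls))
  counts <- table(factor(calls[keep], levels = levels))
  list(counts = counts, dropped = n_dropped)
}

#' Genotype and allele frequency report for one locus
#'
#' Counts genotypes over the scheme's categories and derives allele counts
#' by gene counting (2 per homozygote, 1 per heterozygote, 2N alleles in
#' total). Frequencies are reported as raw proportions, as percentages
#' rounded half-up to \code{digits} decimals, and with Wilson 95%
#' confidence intervals. Indeterminate, unconfirmed and missing calls are
#' excluded from N.
#'
#' @param calls character vector of genotype calls (\code{XX}/\code{X58}/
#'   \code{HOM58} for \code{scheme = "hla"}, \code{GG}/\code{GA}/\code{AA}
#'   for \code{scheme = "snp"}).
#' @param scheme which locus the calls belong to.
#' @param digits decimals for the percentage columns.
#' @param conf confidence level for the Wilson intervals.
#' @return list with data.frames \code{genotypes} and \code{alleles}
#'   (columns: category, count, proportion, percent, ci_lower, ci_upper),
#'   plus \code{N}, \code{n_alleles}, \code{n_dropped}.
#' @export
genotypeFrequencies <- function(calls, scheme = c("hla", "snp"),
                                digits = 2L, conf = 0.95) {
  scheme <- match.arg(scheme)
  levels <- if (scheme == "hla") .HLA_LEVELS else .SNP_LEVELS
  gc <- .genotypeCounts(calls, levels)
  N <- sum(gc$counts)
  if (N == 0L) .stopf("no callable genotypes in input")

  gprop <- as.numeric(gc$counts) / N
  gci <- t(vapply(as.numeric(gc$counts), wilsonCI, numeric(2), n = N,
                  conf = conf))
  genotypes <- data.frame(
    category = names(gc$counts), count = as.integer(gc$counts),
    proportion = gprop, percent = roundHalfUp(100 * gprop, digits),
    ci_lower = gci[, 1], ci_upper = gci[, 2],
    stringsAsFactors = FALSE, row.names = NULL)

  # allele counting: scheme category order is (hom-common, het, hom-rare)
  n_rare <- 2L * gc$counts[[3L]] + gc$counts[[2L]]
  n_common <- 2L * N - n_rare
  acat <- if (scheme == "hla") c("X", "58:01") else c("G", "A")
  acount <- c(n_common, n_rare)
  aprop <- acount / (2L * N)
  aci <- t(vapply(acount, wilsonCI, numeric(2), n = 2L * N, conf = conf))
  alleles <- data.frame(
    category = acat, count = as.integer(acount), proportion = aprop,
    percent = roundHalfUp(100 * aprop, digits),
    ci_lower = aci[, 1], ci_upper = aci[, 2],
    stringsAsFactors = FALSE, row.names = NULL)

  list(genotypes = genotypes, alleles = alleles, N = N,
       n_alleles = 2L * N, n_dropped = gc$dropped)
}

#' Joint HLA-B*58:01 x rs9263726 genotype table
#'
#' Cross-tabulates the paired calls of the two markers over the samples
#' callable at both, with cell percentages of the joint N.
#'
#' @param hla_calls,snp_calls character vectors of calls; either both
#'   named by sample id (paired by name) or of equal length (paired by
#'   position).
#' @param digits decimals for the percentage matrix.
#' @return list with \code{counts} (3x3 integer matrix, HLA rows x SNP
#'   columns), \code{percent}, \code{proportion} and \code{N}.
#' @export
jointGenotypeTable <- function(hla_calls, snp_calls, digits = 2L) {
  if (!is.null(names(hla_calls)) && !is.null(names(snp_calls))) {
    shared <- intersect(names(hla_calls), names(snp_calls))
    if (!length(shared)) .stopf("no overlapping sample ids between calls")
    hla_calls <- hla_calls[shared]
    snp_calls <- snp_calls[shared]
  } else if (length(hla_calls) != length(snp_calls)) {
    .stopf("unnamed call vectors must have equal length")
  }
  ok <- hla_calls %in% .HLA_LEVELS & snp_calls %in% .SNP_LEVELS
  if (!any(ok)) .stopf("no sample callable at both loci")
  counts <- table(factor(hla_calls[ok], levels = .HLA_LEVELS),
                  factor(snp_calls[ok], levels = .SNP_LEVELS))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("hla", "snp")
  N <- sum(counts)
  list(counts = counts, proportion = counts / N,
       percent = roundHalfUp(100 * counts / N, digits), N = N)
}

#' Surrogate-marker performance of rs9263726 for HLA-B*58:01 carriage
#'
#' Treats carriage of at least one rs9263726 A allele (GA or AA) as the
#' test and carriage of at least one *58:01 allele (X58 or HOM58) as the
#' condition, and reports sensitivity, specificity, PPV and NPV with
#' exact (Clopper-Pearson) 95% confidence intervals. A metric whose
#' denominator margin is zero is reported as \code{NA} with a reason.
#'
#' @param table a joint table from [jointGenotypeTable()].
#' @param conf confidence level.
#' @return data.frame with columns \code{metric}, \code{numerator},
#'   \code{denominator}, \code{estimate}, \code{ci_lower}, \code{ci_upper},
#'   \code{note}.
#' @export
surrogatePerformance <- function(table, conf = 0.95) {
  cc <- table$counts
  carrier <- rowSums(cc)[c("X58", "HOM58")]
  apos <- colSums(cc)[c("GA", "AA")]
  tp <- sum(cc[c("X58", "HOM58"), c("GA", "AA")])
  fn <- sum(cc[c("X58", "HOM58"), "GG"])
  fp <- sum(cc["XX", c("GA", "AA")])
  tn <- cc["XX", "GG"]

  one <- function(metric, k, n) {
    if (n == 0L)
      return(data.frame(metric = metric, numerator = NA_integer_,
                        denominator = 0L, estimate = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        note = "undefined: zero margin",
                        stringsAsFactors = FALSE))
    ci <- unname(.exactCI(k, n, conf))
    data.frame(metric = metric, numerator = as.integer(k),
               denominator = as.integer(n), estimate = unname(k / n),
               ci_lower = ci[1], ci_upper = ci[2], note = "",
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(one("sensitivity", tp, tp + fn),
        one("specificity", tn, tn + fp),
        one("ppv", tp, tp + fp),
        one("npv", tn, tn + fn))
}

# genotype-table log-likelihood given haplotype frequencies
# h = c(p58A, p58G, pXA, pXG); counts 3x3 HLA x SNP
.twoLocusLogLik <- function(h, counts) {
  p58A <- h[1]; p58G <- h[2]; pXA <- h[3]; pXG <- h[4]
  cc <- counts[c("XX", "X58", "HOM58"), c("GG", "GA", "AA")]
  gpm <- matrix(0, 3, 3, dimnames = dimnames(cc))
  gpm["HOM58", "AA"] <- p58A^2
  gpm["HOM58", "GA"] <- 2 * p58A * p58G
  gpm["HOM58", "GG"] <- p58G^2
  gpm["X58", "AA"] <- 2 * p58A * pXA
  gpm["X58", "GA"] <- 2 * (p58A * pXG + p58G * pXA)
  gpm["X58", "GG"] <- 2 * p58G * pXG
  gpm["XX", "AA"] <- pXA^2
  gpm["XX", "GA"] <- 2 * pXA * pXG
  gpm["XX", "GG"] <- pXG^2
  sum(cc[cc > 0] * log(gpm[cc > 0]))
}

#' EM haplotype frequencies and linkage disequilibrium for two loci
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotype counts by expectation-maximisation. Only the double
#' heterozygote (X58 x GA) is phase-ambiguous; all other cells contribute
#' known haplotypes. The EM starts from linkage equilibrium, preserves the
#' observed allele-frequency margins at every iteration, and has a
#' monotone non-decreasing log-likelihood. Reports D = p(58:01-A) -
#' p(58:01)p(A), the normalised D' (D/Dmax with
#' Dmax = min(p58 pG, pX pA) for D > 0, min(p58 pA, pX pG) for D < 0) and
#' r2 = D^2 / (p58 pX pA pG). A monomorphic locus gives D = D' = r2 = 0
#' with a \code{"monomorphic"} note.
#'
#' @param table a joint table from [jointGenotypeTable()].
#' @param tol convergence tolerance on the haplotype-frequency update.
#' @param max_iter iteration cap.
#' @return list with \code{haplotypes} (named vector p58A, p58G, pXA,
#'   pXG), \code{p58}, \code{pA}, \code{D}, \code{Dprime}, \code{r2},
#'   \code{iterations}, \code{logLik}, \code{note}.
#' @export
emHaplotypeLD <- function(table, tol = 1e-8, max_iter = 1000L) {
  cc <- table$counts
  N <- sum(cc)
  if (N == 0L) .stopf("empty genotype table")
  p58 <- (2 * sum(cc["HOM58", ]) + sum(cc["X58", ])) / (2 * N)
  pA  <- (2 * sum(cc[, "AA"]) + sum(cc[, "GA"])) / (2 * N)
  pX <- 1 - p58; pG <- 1 - pA

  if (p58 %in% c(0, 1) || pA %in% c(0, 1)) {
    h <- c(p58A = p58 * pA, p58G = p58 * pG, pXA = pX * pA, pXG = pX * pG)
    return(list(haplotypes = h, p58 = p58, pA = pA, D = 0, Dprime = 0,
                r2 = 0, iterations = 0L,
                logLik = .twoLocusLogLik(h, cc), note = "monomorphic"))
  }

  ndh <- cc["X58", "GA"]
  # unambiguous haplotype counts from the other eight cells
  base58A <- 2 * cc["HOM58", "AA"] + cc["HOM58", "GA"] + cc["X58", "AA"]
  base58G <- 2 * cc["HOM58", "GG"] + cc["HOM58", "GA"] + cc["X58", "GG"]
  baseXA  <- 2 * cc["XX", "AA"] + cc["XX", "GA"] + cc["X58", "AA"]
  baseXG  <- 2 * cc["XX", "GG"] + cc["XX", "GA"] + cc["X58", "GG"]

  h <- c(p58 * pA, p58 * pG, pX * pA, pX * pG)
  ll <- .twoLocusLogLik(h, cc)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: expected fraction of double heterozygotes in coupling phase
    num <- h[1] * h[4]
    den <- h[1] * h[4] + h[2] * h[3]
    f <- if (den > 0) num / den else 0.5
    # M-step
    hn <- c(base58A + ndh * f, base58G + ndh * (1 - f),
            baseXA + ndh * (1 - f), baseXG + ndh * f) / (2 * N)
    delta <- max(abs(hn - h))
    h <- hn
    if (delta < tol || iter >= max_iter) break
  }
  ll <- .twoLocusLogLik(h, cc)
  names(h) <- c("p58A", "p58G", "pXA", "pXG")

  D <- h[["p58A"]] - p58 * pA
  Dmax <- if (D >= 0) min(p58 * pG, pX * pA) else min(p58 * pA, pX * pG)
  Dprime <- if (Dmax > 0) D / Dmax else 0
  r2 <- D^2 / (p58 * pX * pA * pG)
  list(haplotypes = h, p58 = p58, pA = pA, D = D, Dprime = Dprime,
       r2 = r2, iterations = iter, logLik = ll, note = "")
}

#' Exact Hardy-Weinberg equilibrium test for a biallelic locus
#'
#' Exact conditional test: conditioning on the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed configuration. A
#' monomorphic locus returns p = 1.
#'
#' @param n_hom_common,n_het,n_hom_rare genotype counts.
#' @return p-value in \code{[0, 1]}.
#' @export
hweExact <- function(n_hom_common, n_het, n_hom_rare) {
  stopifnot(n_hom_common >= 0, n_het >= 0, n_hom_rare >= 0)
  N <- n_hom_common + n_het + n_hom_rare
  if (N == 0L) .stopf("empty genotype counts")
  nr <- 2L * n_hom_rare + n_het       # rare-allele count
  nc <- 2L * N - nr
  if (nr == 0L || nc == 0L) return(1)

  hets <- seq(nr %% 2L, min(nr, nc), by = 2L)
  # log P(het = h | allele counts) up to a shared constant
  logp <- vapply(hets, function(h) {
    a <- (nr - h) / 2L
    b <- (nc - h) / 2L
    h * log(2) + lfactorial(N) - lfactorial(a) - lfactorial(h) -
      lfactorial(b)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  pobs <- p[hets == n_het]
  if (!length(pobs)) .stopf("heterozygote count inconsistent with alleles")
  sum(p[p <= pobs * (1 + 1e-12)])
}

#' Write a frequency report as TSV
#'
#' @param report result of [genotypeFrequencies()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFrequencyReport <- function(report, path) {
  df <- rbind(cbind(level = "genotype", report$genotypes),
              cbind(level = "allele", report$alleles))
  .writeTSV(df, path)
}
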