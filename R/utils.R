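#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals, as used for the
#' printed percentage tables (R's \code{round} uses round-half-even).
#'
#' @param x numeric vector.
#' @param digits number of decimals.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(6.015, 2)   # 6.02
#' round(6.015, 2)         # 6.01 or 6.02 depending on representation
#' @export
roundHalfUp <- function(x, digits = 2L) {
  m <- 10^digits
  # nudge by a relative epsilon so values that are exactly .5 in decimal
  # but stored just below it in binary still round up
  z <- abs(x) * m
  z <- floor(z + 0.5 + 1e-9)
  sign(x) * z / m
}

#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector \code{c(lower, upper)}.
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  if (n <= 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw  <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

# Clopper-Pearson interval via the exact binomial test
.exactCI <- function(k, n, conf = 0.95) {
  if (n <= 0) return(c(lower = NA_real_, upper = NA_real_))
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  c(lower = ci[1], upper = ci[2])
}

# deterministic sub-seed derivation: one user seed drives all modules
.subSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

.readTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
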