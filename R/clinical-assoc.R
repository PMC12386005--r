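#' @include utils.R
NULL

.PARACLINICAL_VARS <- c("RBC", "HGB", "HCT", "WBC", "NE", "LYM", "PLT",
                        "Glu", "Ure", "Cre", "Uri", "TC", "TG",
                        "HDL_C", "LDL_C")

#' Pearson correlation with a t-distribution p-value
#'
#' Pairwise-complete Pearson r with the two-sided p-value from
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom. Fewer
#' than 3 complete pairs or a zero-variance vector gives \code{NA} with a
#' reason.
#'
#' @param x,y numeric vectors of equal length; missing values removed
#'   pairwise.
#' @return list with \code{r}, \code{p}, \code{n} (complete pairs used),
#'   \code{note}.
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n, note = "n < 3"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n,
                note = "zero variance"))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, note = "")
}

#' Correlation screen of paraclinical variables against a target variable
#'
#' Correlates every paraclinical variable with the target (uric acid by
#' default) in the full cohort and within each sex stratum, in the shape
#' of the usual variable-by-stratum correlation table. Strata with fewer
#' than 3 complete pairs are flagged and get no p-value.
#'
#' @param cohort data.frame with a \code{sex} column (\code{"male"}/
#'   \code{"female"}) and numeric paraclinical columns.
#' @param target name of the target column (default \code{"Uri"}).
#' @param variables columns to screen (default: all standard paraclinical
#'   variables present except the target).
#' @return data.frame with columns \code{variable}, \code{stratum},
#'   \code{r}, \code{p}, \code{n}, \code{note}.
#' @export
correlationScreen <- function(cohort, target = "Uri",
                              variables = NULL) {
  if (!target %in% names(cohort))
    .stopf("target variable '%s' not in cohort", target)
  if (is.null(variables))
    variables <- setdiff(intersect(.PARACLINICAL_VARS, names(cohort)),
                         target)
  strata <- list(all = rep(TRUE, nrow(cohort)),
                 male = cohort$sex == "male",
                 female = cohort$sex == "female")
  rows <- list()
  for (v in variables) {
    for (s in names(strata)) {
      idx <- strata[[s]] & !is.na(strata[[s]])
      res <- pearsonWithP(cohort[[v]][idx], cohort[[target]][idx])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratum = s, r = res$r, p = res$p, n = res$n,
        note = res$note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare a paraclinical variable between two genotype groups
#'
#' Mean and SD per group with a two-sided two-sample test, Student
#' (pooled variance) by default with Welch co-reported. Groups with fewer
#' than 2 observations give no p-value.
#'
#' @param cohort data.frame with the variable and a genotype column.
#' @param variable name of the numeric column to compare.
#' @param group_col genotype column name (default \code{"hla_call"}).
#' @param groups the two genotype labels to compare.
#' @param method which p-value goes in the \code{p} column.
#' @return one-row data.frame: variable, per-group n/mean/sd,
#'   \code{p_student}, \code{p_welch}, \code{p} (selected method),
#'   \code{note}.
#' @export
groupMeanCompare <- function(cohort, variable, group_col = "hla_call",
                             groups = c("XX", "X58"),
                             method = c("student", "welch")) {
  method <- match.arg(method)
  g <- cohort[[group_col]]
  v <- cohort[[variable]]
  x1 <- v[g == groups[1] & !is.na(g) & !is.na(v)]
  x2 <- v[g == groups[2] & !is.na(g) & !is.na(v)]
  out <- data.frame(
    variable = variable,
    group1 = groups[1], n1 = length(x1),
    mean1 = mean(x1), sd1 = stats::sd(x1),
    group2 = groups[2], n2 = length(x2),
    mean2 = mean(x2), sd2 = stats::sd(x2),
    p_student = NA_real_, p_welch = NA_real_, p = NA_real_,
    note = "", stringsAsFactors = FALSE)
  if (length(x1) < 2L || length(x2) < 2L) {
    out$note <- "group with n < 2: no test"
    return(out)
  }
  if (stats::sd(c(x1, x2)) == 0) {
    out$p_student <- out$p_welch <- 1
  } else {
    out$p_student <- stats::t.test(x1, x2, var.equal = TRUE)$p.value
    out$p_welch <- stats::t.test(x1, x2, var.equal = FALSE)$p.value
  }
  out$p <- if (method == "student") out$p_student else out$p_welch
  out
}

#' Group comparison report across all paraclinical variables
#'
#' Runs [groupMeanCompare()] for every paraclinical variable, overall and
#' (optionally) within a sex stratum, in the shape of the usual
#' genotype-group comparison table.
#'
#' @inheritParams groupMeanCompare
#' @param variables columns to compare (default: standard paraclinical
#'   variables present).
#' @param by_sex also report the male-only stratum.
#' @return data.frame of per-variable rows, with a \code{stratum} column.
#' @export
groupComparisonReport <- function(cohort, group_col = "hla_call",
                                  groups = c("XX", "X58"),
                                  variables = NULL, by_sex = TRUE,
                                  method = c("student", "welch")) {
  method <- match.arg(method)
  if (is.null(variables))
    variables <- intersect(.PARACLINICAL_VARS, names(cohort))
  strata <- list(all = rep(TRUE, nrow(cohort)))
  if (by_sex && "sex" %in% names(cohort))
    strata$male <- cohort$sex == "male"
  rows <- list()
  for (s in names(strata)) {
    sub <- cohort[strata[[s]], , drop = FALSE]
    for (v in variables) {
      r <- groupMeanCompare(sub, v, group_col, groups, method)
      rows[[length(rows) + 1L]] <- cbind(stratum = s, r)
    }
  }
  do.call(rbind, rows)
}

#' Age-by-sex cohort summary
#'
#' Age-bin by sex counts with row percentages, per-sex mean and SD age,
#' and a two-sample test of the age difference between sexes.
#'
#' @param cohort data.frame with \code{age} and \code{sex} columns.
#' @param breaks upper edges splitting age into bins (default gives
#'   <=40, 41-59, >=60).
#' @param method test for the age-by-sex comparison.
#' @return list with \code{bins} (bin x sex counts and row percentages),
#'   \code{age} (per-sex n, mean, sd), \code{p_age_by_sex},
#'   \code{p_method}.
#' @export
ageSexSummary <- function(cohort, breaks = c(40, 59),
                          method = c("student", "welch")) {
  method <- match.arg(method)
  if (!nrow(cohort)) .stopf("empty cohort")
  stopifnot(all(c("age", "sex") %in% names(cohort)))
  edges <- c(-Inf, breaks, Inf)
  labels <- c(sprintf("<=%d", breaks[1]),
              if (length(breaks) > 1)
                sprintf("%d-%d", breaks[-length(breaks)] + 1,
                        breaks[-1]),
              sprintf(">=%d", breaks[length(breaks)] + 1))
  bin <- cut(cohort$age, edges, labels = labels, right = TRUE)
  sex <- factor(cohort$sex, levels = c("male", "female"))
  counts <- table(bin, sex)
  counts <- rbind(counts, Total = colSums(counts))
  rowpct <- roundHalfUp(100 * counts / pmax(rowSums(counts), 1L), 1L)

  age <- do.call(rbind, lapply(levels(sex), function(s) {
    a <- cohort$age[sex == s]
    data.frame(sex = s, n = length(a), mean = mean(a),
               sd = stats::sd(a), stringsAsFactors = FALSE)
  }))
  am <- cohort$age[sex == "male"]
  af <- cohort$age[sex == "female"]
  p <- if (length(am) >= 2L && length(af) >= 2L) {
    if (stats::sd(c(am, af)) == 0) 1
    else stats::t.test(am, af, var.equal = method == "student")$p.value
  } else NA_real_
  list(bins = list(counts = counts, row_percent = rowpct), age = age,
       p_age_by_sex = p, p_method = method)
}
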