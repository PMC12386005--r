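#' @include synthetic-data.R cohort-stats.R clinical-assoc.R
NULL

.manifest <- function(out_dir, seed, inputs, outputs, stage) {
  m <- list(stage = stage, seed = seed,
            package_version = as.character(utils::packageVersion("hlaB5801")),
            inputs = as.list(inputs), outputs = as.list(outputs),
            timestamp = format(Sys.time(), tz = "UTC"))
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(m)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort data.frame from [simulateParaclinical()] (or the same
#'   shape from real data).
#' @param path CSV path.
#' @return the path (write) or the data.frame (read).
#' @export
writeCohortCSV <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic fixture bundle
#'
#' Runs the generator end to end: allele database FASTA files, truth
#' roster TSV (kept apart from the pipeline inputs), per-sample consensus
#' FASTA files for the three amplicons, and the paraclinical cohort CSV.
#' Deterministic: the same config and seed give byte-identical files.
#'
#' @param config a [simulationConfig()].
#' @param out_dir output directory.
#' @return named list of output paths, invisibly.
#' @export
runSimulate <- function(config = simulationConfig(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- makeAlleleDb(config)
  dbPaths <- writeAlleleDb(db, file.path(out_dir, "allele_db"))
  roster <- simulateCohort(config)
  seqs <- synthesizeSequences(roster, db, seed = config$seed,
                              out_dir = out_dir)
  cohort <- simulateParaclinical(roster, config)
  rosterPath <- file.path(out_dir, "truth_roster.tsv")
  .writeTSV(roster, rosterPath)
  cohortPath <- file.path(out_dir, "cohort.csv")
  writeCohortCSV(cohort, cohortPath)
  outputs <- c(dbPaths, seqs$paths,
               truth_roster = rosterPath, cohort = cohortPath)
  .manifest(out_dir, config$seed, character(), outputs, "simulate")
  invisible(as.list(outputs))
}

#' Discover and write a diagnostic panel from allele FASTA files
#'
#' @param exon3_fasta,exon2_fasta aligned allele FASTA paths.
#' @param target,reference allele names.
#' @param mode passed to [findDiagnosticPositions()].
#' @param out_path panel TSV path.
#' @return the combined [DiagnosticPanel-class], invisibly.
#' @export
runDiscover <- function(exon3_fasta, exon2_fasta, target = "B*58:01:01",
                        reference = "HLA00132.1",
                        mode = "per_position_unique",
                        out_path) {
  aln3 <- loadAlleleAlignment(exon3_fasta, "HLAB_exon3", target, reference)
  aln2 <- loadAlleleAlignment(exon2_fasta, "HLAB_exon2", target, reference)
  p3 <- findDiagnosticPositions(aln3, mode)
  p2 <- findDiagnosticPositions(aln2, mode)
  panel <- DiagnosticPanel(rbind(panelPositions(p3), panelPositions(p2)),
                           screenStage = "HLAB_exon3",
                           confirmStage = "HLAB_exon2")
  chk <- verifyPanel(list(aln3, aln2), panel)
  if (!chk$ok)
    .stopf("discovered panel fails joint verification: %s",
           paste(chk$collisions, collapse = ", "))
  writePanel(panel, out_path)
  invisible(panel)
}

#' Call both markers for a cohort and write the calls TSV
#'
#' @inheritParams callCohort
#' @param out_path calls TSV path.
#' @param vcf_path optional single-site VCF path for rs9263726.
#' @return the calls data.frame, invisibly.
#' @export
runCall <- function(exon3_fasta, exon2_fasta = NULL, psors_fasta = NULL,
                    panel = hlaB5801Panel(), snp_position = 110L,
                    out_path, vcf_path = NULL) {
  calls <- callCohort(exon3_fasta, exon2_fasta, psors_fasta, panel,
                      snp_position)
  .writeTSV(calls, out_path)
  if (!is.null(vcf_path)) writeSnpVcf(calls, vcf_path)
  invisible(calls)
}

#' Summarize calls (and optionally a cohort table) into report files
#'
#' Produces the frequency reports for both markers, the joint genotype
#' table with surrogate-marker performance and EM linkage-disequilibrium
#' estimates, Hardy-Weinberg exact p-values, and — when a cohort CSV is
#' supplied — the age/sex summary, the uric-acid correlation screen and
#' the genotype-group comparisons.
#'
#' @param calls calls data.frame (or path to the calls TSV).
#' @param cohort optional cohort data.frame or CSV path.
#' @param out_dir report directory.
#' @return list with all computed report objects, invisibly.
#' @export
runSummarize <- function(calls, cohort = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(calls)) calls <- .readTSV(calls)
  if (is.character(cohort)) cohort <- readCohortCSV(cohort)

  hla <- genotypeFrequencies(calls$hla_call, "hla")
  snp <- genotypeFrequencies(calls$snp_call, "snp")
  writeFrequencyReport(hla, file.path(out_dir, "hla_frequencies.tsv"))
  writeFrequencyReport(snp, file.path(out_dir, "snp_frequencies.tsv"))

  joint <- jointGenotypeTable(
    stats::setNames(calls$hla_call, calls$sample_id),
    stats::setNames(calls$snp_call, calls$sample_id))
  surr <- surrogatePerformance(joint)
  ld <- emHaplotypeLD(joint)
  hwe <- list(
    hla = hweExact(hla$genotypes$count[1], hla$genotypes$count[2],
                   hla$genotypes$count[3]),
    snp = hweExact(snp$genotypes$count[1], snp$genotypes$count[2],
                   snp$genotypes$count[3]))
  jointDf <- as.data.frame(as.table(joint$counts),
                           stringsAsFactors = FALSE)
  names(jointDf) <- c("hla", "snp", "count")
  jointDf$percent <- as.vector(joint$percent)
  .writeTSV(jointDf, file.path(out_dir, "joint_genotypes.tsv"))
  .writeTSV(surr, file.path(out_dir, "surrogate_performance.tsv"))
  jsonlite::write_json(
    list(haplotypes = as.list(ld$haplotypes), p58 = ld$p58, pA = ld$pA,
         D = ld$D, Dprime = ld$Dprime, r2 = ld$r2,
         iterations = ld$iterations, logLik = ld$logLik, note = ld$note,
         hwe_p = hwe),
    file.path(out_dir, "ld_report.json"), auto_unbox = TRUE, digits = NA)

  out <- list(hla = hla, snp = snp, joint = joint, surrogate = surr,
              ld = ld, hwe = hwe)
  if (!is.null(cohort)) {
    merged <- merge(cohort, calls[, c("sample_id", "hla_call")],
                    by = "sample_id")
    out$age_sex <- ageSexSummary(cohort)
    out$correlations <- correlationScreen(cohort)
    out$group_comparison <- groupComparisonReport(merged)
    .writeTSV(out$correlations,
              file.path(out_dir, "uri_correlations.tsv"))
    .writeTSV(out$group_comparison,
              file.path(out_dir, "group_comparison.tsv"))
    agedf <- out$age_sex$age
    agedf$p_age_by_sex <- out$age_sex$p_age_by_sex
    .writeTSV(agedf, file.path(out_dir, "age_sex_summary.tsv"))
  } else {
    warning("no cohort table supplied: clinical reports skipped")
  }
  invisible(out)
}

#' Run the whole pipeline on synthetic data
#'
#' Simulate, discover the panel from the synthetic allele database, call
#' both markers, and summarize — writing every intermediate and report
#' file under \code{out_dir}.
#'
#' @param config a [simulationConfig()].
#' @param out_dir output directory.
#' @return list with \code{calls}, \code{reports}, \code{panel},
#'   \code{paths}, invisibly.
#' @export
runAll <- function(config = simulationConfig(), out_dir) {
  paths <- runSimulate(config, out_dir)
  panel <- runDiscover(
    file.path(out_dir, "allele_db", "HLAB_exon3_alleles.fasta"),
    file.path(out_dir, "allele_db", "HLAB_exon2_alleles.fasta"),
    out_path = file.path(out_dir, "panel.tsv"))
  calls <- runCall(
    file.path(out_dir, "HLAB_exon3.fasta"),
    file.path(out_dir, "HLAB_exon2.fasta"),
    file.path(out_dir, "PSORS1C1_exon3.fasta"),
    panel = panel, snp_position = config$snp_position,
    out_path = file.path(out_dir, "calls.tsv"),
    vcf_path = file.path(out_dir, "rs9263726.vcf"))
  reports <- runSummarize(calls, file.path(out_dir, "cohort.csv"),
                          file.path(out_dir, "reports"))
  .manifest(out_dir, config$seed,
            inputs = unlist(paths),
            outputs = c(file.path(out_dir, "panel.tsv"),
                        file.path(out_dir, "calls.tsv")),
            stage = "run_all")
  invisible(list(calls = calls, reports = reports, panel = panel,
                 paths = paths))
}
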