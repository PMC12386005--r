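#' @include AllClasses.R allele-reference.R
NULL

#' The IUPAC nucleotide ambiguity table
#'
#' Named list mapping each IUPAC symbol to its base set. In a diploid
#' Sanger consensus a two-base code (R, Y, S, W, K, M) represents a
#' heterozygous position; \code{N} and the three-base codes represent
#' unresolved calls.
#'
#' @return named list of character vectors (base sets).
#' @examples
#' iupacTable()[["Y"]]  # C T
#' @export
iupacTable <- function() {
  lapply(Biostrings::IUPAC_CODE_MAP, function(s) strsplit(s, "")[[1]])
}

.IUPAC_SETS <- lapply(Biostrings::IUPAC_CODE_MAP,
                      function(s) strsplit(s, "")[[1]])
# two-base set -> symbol, keyed by sorted pair, e.g. "CT" -> "Y"
.PAIR_TO_CODE <- local({
  two <- .IUPAC_SETS[lengths(.IUPAC_SETS) == 2L]
  stats::setNames(names(two),
                  vapply(two, function(b) paste(sort(b), collapse = ""),
                         character(1)))
})

#' Classify one observed consensus symbol against a target base
#'
#' \code{hom_target} when the observed symbol is exactly the target base;
#' \code{het_target} when it is a two-base ambiguity code whose set
#' contains the target base; \code{absent} when the observed base set
#' excludes the target; \code{invalid} for \code{N}, three-base codes,
#' gaps, or anything outside the IUPAC alphabet (missing data must never
#' silently count as absence of the allele).
#'
#' @param observed single observed symbol (case-insensitive).
#' @param target_base the target allele's base (A/C/G/T).
#' @return one of \code{"hom_target"}, \code{"het_target"},
#'   \code{"absent"}, \code{"invalid"}.
#' @examples
#' callPosition("Y", "T")  # het_target
#' callPosition("G", "T")  # absent
#' @export
callPosition <- function(observed, target_base) {
  observed <- toupper(observed)
  target_base <- toupper(target_base)
  set <- .IUPAC_SETS[[observed]]
  if (is.null(set) || length(set) > 2L) return("invalid")
  if (!target_base %in% set) return("absent")
  if (length(set) == 1L) "hom_target" else "het_target"
}

.callPositions <- function(sequence, positions, target_bases, offset = 0L) {
  idx <- positions - offset
  if (any(idx < 1L | idx > nchar(sequence)))
    .stopf("panel position outside sequence (length %d, frame offset %d)",
           nchar(sequence), offset)
  obs <- substring(toupper(sequence), idx, idx)
  calls <- mapply(callPosition, obs, target_bases, USE.NAMES = FALSE)
  data.frame(position = positions, observed = obs, call = calls,
             stringsAsFactors = FALSE)
}

.patternString <- function(df) {
  if (is.null(df) || !nrow(df)) return("")
  paste0(df$position, df$observed, collapse = ",")
}

#' Two-stage HLA-B*58:01 genotype call for one sample
#'
#' Stage 1 screens the exon-3 consensus at the exon-3 panel positions: if
#' any position lacks the target base the sample is called \code{XX} and
#' exon 2 is never consulted. If all stage-1 positions carry the target
#' base (hom or het) the exon-2 consensus is required for confirmation; a
#' stage-1-positive sample without exon-2 data is
#' \code{candidate_unconfirmed}. Confirmed carriers are \code{HOM58} when
#' every zygosity-informative panel position is homozygous for the target
#' base and \code{X58} otherwise; a mixture of homozygous and heterozygous
#' informative positions (impossible with a reference partner allele) is
#' still called \code{X58} — carriage drives clinical risk — but flagged
#' \code{pattern_inconsistent}. Any \code{N}/unreadable symbol at a panel
#' position gives \code{indeterminate}.
#'
#' @param exon3 exon-3 consensus sequence (character, IUPAC codes allowed).
#' @param exon2 exon-2 consensus sequence, or \code{NULL} if not sequenced.
#' @param panel a [DiagnosticPanel-class] (see [hlaB5801Panel()]).
#' @param exon3_offset,exon2_offset frame offsets subtracted from panel
#'   positions to index into the supplied strings (0 when the string is
#'   the full amplicon).
#' @return list with \code{call} (\code{XX}, \code{X58}, \code{HOM58},
#'   \code{candidate_unconfirmed}, \code{indeterminate}), \code{stage1} and
#'   \code{stage2} per-position call data.frames, and \code{flags}.
#' @export
callHlaB5801 <- function(exon3, exon2 = NULL, panel = hlaB5801Panel(),
                         exon3_offset = 0L, exon2_offset = 0L) {
  pos <- panelPositions(panel)
  p1 <- pos[pos$amplicon == panel@screenStage, , drop = FALSE]
  p2 <- if (is.na(panel@confirmStage)) pos[0L, , drop = FALSE]
        else pos[pos$amplicon == panel@confirmStage, , drop = FALSE]
  if (!nrow(p1)) .stopf("panel has no stage-1 (%s) positions",
                        panel@screenStage)

  s1 <- .callPositions(exon3, p1$position, p1$target_base, exon3_offset)
  out <- list(call = NA_character_, stage1 = s1, stage2 = NULL,
              flags = character())
  if (any(s1$call == "invalid")) {
    out$call <- "indeterminate"
    out$flags <- sprintf("unreadable stage-1 position(s) %s",
                         paste(s1$position[s1$call == "invalid"],
                               collapse = ","))
    return(out)
  }
  if (any(s1$call == "absent")) {   # stage-1 short-circuit
    out$call <- "XX"
    return(out)
  }
  noExon2 <- is.null(exon2) || is.na(exon2) || !nzchar(exon2)
  if (nrow(p2) && noExon2) {
    out$call <- "candidate_unconfirmed"
    return(out)
  }
  s2 <- if (nrow(p2))
    .callPositions(exon2, p2$position, p2$target_base, exon2_offset)
  else
    data.frame(position = integer(), observed = character(),
               call = character(), stringsAsFactors = FALSE)
  out$stage2 <- s2
  if (any(s2$call == "invalid")) {
    out$call <- "indeterminate"
    out$flags <- sprintf("unreadable stage-2 position(s) %s",
                         paste(s2$position[s2$call == "invalid"],
                               collapse = ","))
    return(out)
  }
  if (any(s2$call == "absent")) {
    out$call <- "XX"
    return(out)
  }
  inform <- c(s1$call[p1$zygosity_informative], s2$call[p2$zygosity_informative])
  if (!length(inform)) {
    out$call <- "X58"
    out$flags <- "zygosity_unresolved"
  } else if (all(inform == "hom_target")) {
    out$call <- "HOM58"
  } else {
    out$call <- "X58"
    if (any(inform == "hom_target"))
      out$flags <- "pattern_inconsistent"
  }
  out
}

#' Call the rs9263726 genotype from a PSORS1C1 exon-3 consensus
#'
#' The SNP is a G>A substitution read at position 110 of the sequenced
#' amplicon: \code{G} is the homozygous wild type \code{GG}, the IUPAC
#' code \code{R} (A/G) the heterozygote \code{GA}, and \code{A} the
#' homozygous variant \code{AA}. Any other symbol is \code{indeterminate}.
#'
#' @param sequence PSORS1C1 amplicon consensus (character).
#' @param snp_position SNP position in the amplicon frame (default 110).
#' @param frame_offset offset subtracted to index into the string.
#' @return one of \code{"GG"}, \code{"GA"}, \code{"AA"},
#'   \code{"indeterminate"}.
#' @export
callRs9263726 <- function(sequence, snp_position = 110L, frame_offset = 0L) {
  idx <- snp_position - frame_offset
  if (idx < 1L || idx > nchar(sequence))
    .stopf("SNP position %d outside sequence of length %d",
           snp_position, nchar(sequence))
  switch(substring(toupper(sequence), idx, idx),
         G = "GG", R = "GA", A = "AA", "indeterminate")
}

.readSampleFasta <- function(path, what) {
  if (is.null(path)) return(stats::setNames(character(), character()))
  if (!file.exists(path)) .stopf("%s FASTA not found: %s", what, path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) .stopf("malformed FASTA '%s': %s",
                                              path, conditionMessage(e)))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    .stopf("duplicate sample_id in '%s': %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(seqs)), ids)
}

#' Call both markers across a cohort of consensus FASTA files
#'
#' Reads the three per-sample multi-FASTA files (HLA-B exon 3, HLA-B
#' exon 2, PSORS1C1 exon 3), keyed by sample id, and emits one row per
#' exon-3 sample with the two-stage HLA-B*58:01 call and the rs9263726
#' call. Samples absent from the exon-2 file that pass the stage-1 screen
#' come out \code{candidate_unconfirmed}; samples absent from the PSORS1C1
#' file get an \code{NA} SNP call.
#'
#' @param exon3_fasta,exon2_fasta,psors_fasta file paths (the latter two
#'   may be \code{NULL}); exon-2 and PSORS1C1 sample ids must be a subset
#'   of the exon-3 ids.
#' @param panel a [DiagnosticPanel-class].
#' @param snp_position rs9263726 position in the PSORS1C1 amplicon frame.
#' @param exon3_offset,exon2_offset frame offsets for the HLA-B amplicons.
#' @return data.frame with columns \code{sample_id}, \code{hla_call},
#'   \code{snp_call}, \code{stage1_pattern}, \code{stage2_pattern},
#'   \code{flags}; call-count summary attached as
#'   \code{attr(, "summary")}.
#' @export
callCohort <- function(exon3_fasta, exon2_fasta = NULL, psors_fasta = NULL,
                       panel = hlaB5801Panel(), snp_position = 110L,
                       exon3_offset = 0L, exon2_offset = 0L) {
  e3 <- .readSampleFasta(exon3_fasta, "exon-3")
  e2 <- .readSampleFasta(exon2_fasta, "exon-2")
  ps <- .readSampleFasta(psors_fasta, "PSORS1C1")
  if (!length(e3)) {
    warning("empty exon-3 FASTA: no samples to call")
    out <- data.frame(sample_id = character(), hla_call = character(),
                      snp_call = character(), stage1_pattern = character(),
                      stage2_pattern = character(), flags = character(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- list(hla = table(character()),
                                 snp = table(character()))
    return(out)
  }
  extra <- setdiff(c(names(e2), names(ps)), names(e3))
  if (length(extra))
    .stopf("sample id(s) %s present in exon-2/PSORS1C1 but not exon-3",
           paste(extra, collapse = ", "))

  rows <- lapply(names(e3), function(id) {
    hc <- callHlaB5801(e3[[id]],
                       if (id %in% names(e2)) e2[[id]] else NULL,
                       panel, exon3_offset, exon2_offset)
    sc <- if (id %in% names(ps))
      callRs9263726(ps[[id]], snp_position) else NA_character_
    data.frame(sample_id = id, hla_call = hc$call, snp_call = sc,
               stage1_pattern = .patternString(hc$stage1),
               stage2_pattern = .patternString(hc$stage2),
               flags = paste(hc$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(hla = table(out$hla_call),
                               snp = table(out$snp_call, useNA = "ifany"))
  message(sprintf("called %d samples | HLA: %s | SNP: %s", nrow(out),
                  paste(names(attr(out, "summary")$hla),
                        attr(out, "summary")$hla, sep = "=", collapse = " "),
                  paste(names(attr(out, "summary")$snp),
                        attr(out, "summary")$snp, sep = "=", collapse = " ")))
  out
}

#' Write rs9263726 calls as a minimal single-site VCF
#'
#' One variant line; sample genotypes as GT (0/0, 0/1, 1/1, ./. for
#' missing/indeterminate). Coordinates default to the amplicon frame used
#' for calling; pass genomic coordinates if a genome-aligned VCF is
#' needed.
#'
#' @param calls data.frame from [callCohort()].
#' @param path output path.
#' @param chrom,pos,id CHROM/POS/ID fields for the site.
#' @return the path, invisibly.
#' @export
writeSnpVcf <- function(calls, path, chrom = "PSORS1C1_exon3",
                        pos = 110L, id = "rs9263726") {
  gt <- c(GG = "0/0", GA = "0/1", AA = "1/1")
  g <- gt[calls$snp_call]
  g[is.na(g)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$sample_id), collapse = "\t"),
    paste(c(chrom, pos, id, "G", "A", ".", "PASS", ".", "GT", g),
          collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
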