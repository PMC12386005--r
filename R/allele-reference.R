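#' @include AllClasses.R
NULL

#' Load an aligned allele reference set from a multi-FASTA file
#'
#' Reads one aligned multi-FASTA per amplicon (one record per allele, all
#' the same aligned length, gaps as \code{-}) and validates it against the
#' named target and reference alleles.
#'
#' @param fasta_path path to the aligned multi-FASTA.
#' @param amplicon amplicon label (\code{"HLAB_exon2"}, \code{"HLAB_exon3"}
#'   or \code{"PSORS1C1_exon3"}).
#' @param target,reference allele names as they appear in the FASTA
#'   headers (first whitespace-delimited token).
#' @return an [AlleleAlignment-class].
#' @export
loadAlleleAlignment <- function(fasta_path, amplicon, target, reference) {
  if (!file.exists(fasta_path))
    .stopf("FASTA file not found: %s", fasta_path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) .stopf("malformed FASTA '%s': %s",
                               fasta_path, conditionMessage(e)))
  if (length(seqs) < 2L)
    .stopf("alignment '%s' needs at least 2 records", fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    .stopf("ragged alignment in '%s': record lengths %s", fasta_path,
           paste(unique(w), collapse = ", "))
  if (!target %in% names(seqs))
    .stopf("target allele absent: '%s' not in '%s'", target, fasta_path)
  if (!reference %in% names(seqs))
    .stopf("reference allele absent: '%s' not in '%s'", reference, fasta_path)
  AlleleAlignment(toupper(as.character(seqs)), amplicon = amplicon,
                  target = target, reference = reference)
}

# character matrix view of an alignment (alleles x columns)
.alnMatrix <- function(alignment) {
  m <- t(vapply(as.character(alignedSequences(alignment)),
                function(s) strsplit(s, "")[[1]],
                character(unique(Biostrings::width(
                  alignedSequences(alignment))))))
  rownames(m) <- alleleNames(alignment)
  m
}

#' Discover diagnostic nucleotide positions for the target allele
#'
#' Finds alignment columns whose target bases, alone or jointly, single the
#' target allele out from every other allele in the reference alignment.
#'
#' Two modes are available. \code{"per_position_unique"} returns every
#' column at which no allele other than the target carries the target's
#' base, with one deliberate exception: columns where only the
#' \emph{reference} shares the target base are retained (they still
#' discriminate against all other alleles) and flagged
#' \code{zygosity_informative = FALSE}, since against a reference partner
#' they say nothing about heterozygosity. \code{"minimal_joint"} runs a
#' greedy set cover (ties broken by lowest position) to find a small set of
#' columns whose joint pattern is unique to the target; greedy does not
#' guarantee a minimum-cardinality set.
#'
#' Gap columns in the target are never diagnostic. The result always
#' satisfies [verifyPanel()].
#'
#' @param alignment an [AlleleAlignment-class].
#' @param mode \code{"per_position_unique"} or \code{"minimal_joint"}.
#' @return a [DiagnosticPanel-class] with positions on this amplicon only
#'   (\code{screenStage} set to the amplicon, \code{confirmStage} NA).
#' @export
findDiagnosticPositions <- function(alignment,
                                    mode = c("per_position_unique",
                                             "minimal_joint")) {
  mode <- match.arg(mode)
  m <- .alnMatrix(alignment)
  tgt <- targetAllele(alignment)
  ref <- referenceAllele(alignment)
  tb <- m[tgt, ]
  others <- setdiff(rownames(m), tgt)
  dup <- others[vapply(others, function(a) all(m[a, ] == tb), logical(1))]
  if (length(dup))
    .stopf("no discriminating set: allele(s) %s identical to target '%s'",
           paste(dup, collapse = ", "), tgt)
  candidate <- tb %in% c("A", "C", "G", "T")

  if (mode == "per_position_unique") {
    decoys <- setdiff(others, ref)
    if (length(decoys)) {
      allDecoysDiffer <- colSums(m[decoys, , drop = FALSE] ==
                                   rep(tb, each = length(decoys))) == 0L
      keep <- candidate & allDecoysDiffer
    } else {
      keep <- candidate & (m[ref, ] != tb)
    }
    pos <- which(keep)
  } else {
    # greedy joint cover: shrink the set of alleles still matching the
    # target over all chosen columns
    colliding <- others
    pos <- integer()
    while (length(colliding)) {
      elim <- vapply(seq_len(ncol(m)), function(j) {
        if (!candidate[j] || j %in% pos) return(0L)
        sum(m[colliding, j] != tb[j])
      }, integer(1))
      if (max(elim) == 0L)
        .stopf("no discriminating set on amplicon %s",
               ampliconLabel(alignment))
      j <- which(elim == max(elim))[1L]   # which() scans left to right
      pos <- c(pos, j)
      colliding <- colliding[m[colliding, j] == tb[j]]
    }
    pos <- sort(pos)
  }
  if (!length(pos))
    .stopf("no discriminating set on amplicon %s", ampliconLabel(alignment))

  panel <- DiagnosticPanel(
    data.frame(amplicon = ampliconLabel(alignment), position = pos,
               target_base = tb[pos], reference_base = m[ref, pos],
               stringsAsFactors = FALSE),
    screenStage = ampliconLabel(alignment), confirmStage = NA_character_)
  chk <- verifyPanel(alignment, panel)
  if (!chk$ok)
    .stopf("no discriminating set: alleles %s match the target pattern",
           paste(chk$collisions, collapse = ", "))
  panel
}

#' Verify a diagnostic panel against one or more allele alignments
#'
#' Brute-force check of the panel's defining invariant: no allele other
#' than the target may carry the target base at \emph{every} panel position
#' (jointly, across all supplied amplicons). An empty panel is vacuously
#' matched by every allele and therefore fails.
#'
#' @param alignment an [AlleleAlignment-class], or a list of them (one per
#'   amplicon) for multi-amplicon panels.
#' @param panel a [DiagnosticPanel-class].
#' @return list with \code{ok} (logical) and \code{collisions} (character
#'   vector of non-target alleles matching the full pattern).
#' @export
verifyPanel <- function(alignment, panel) {
  alns <- if (methods::is(alignment, "AlleleAlignment")) list(alignment)
          else alignment
  stopifnot(all(vapply(alns, methods::is, logical(1), "AlleleAlignment")))
  pos <- panelPositions(panel)
  tgt <- targetAllele(alns[[1L]])
  allNames <- unique(unlist(lapply(alns, alleleNames)))
  matches <- stats::setNames(rep(TRUE, length(allNames)), allNames)
  for (aln in alns) {
    pp <- pos[pos$amplicon == ampliconLabel(aln), , drop = FALSE]
    if (!nrow(pp)) next
    m <- .alnMatrix(aln)
    if (any(pp$position > ncol(m)))
      .stopf("panel position %d outside amplicon %s (width %d)",
             max(pp$position), ampliconLabel(aln), ncol(m))
    here <- rownames(m)
    ok <- rowSums(m[, pp$position, drop = FALSE] ==
                    rep(pp$target_base, each = nrow(m))) == nrow(pp)
    matches[here] <- matches[here] & ok
  }
  collisions <- setdiff(allNames[matches], tgt)
  list(ok = length(collisions) == 0L, collisions = collisions)
}

#' The published two-stage HLA-B*58:01 diagnostic panel
#'
#' The eight diagnostic positions identifying HLA-B*58:01 against the
#' HLA00132.1 reference in the sequenced fragment coordinate frame:
#' exon-3 amplicon 353T, 355A, 368A, 379C, 387C (stage-1 screen) and
#' exon-2 amplicon 209A, 285G, 319C (stage-2 confirmation). At 368 and 209
#' the reference shares the target base, so those two positions are not
#' zygosity-informative against a reference partner allele.
#'
#' @return a [DiagnosticPanel-class].
#' @examples
#' hlaB5801Panel()
#' @export
hlaB5801Panel <- function() {
  DiagnosticPanel(
    data.frame(
      amplicon = c(rep("HLAB_exon3", 5), rep("HLAB_exon2", 3)),
      position = c(353L, 355L, 368L, 379L, 387L, 209L, 285L, 319L),
      target_base = c("T", "A", "A", "C", "C", "A", "G", "C"),
      reference_base = c("C", "C", "A", "G", "G", "A", "A", "G"),
      stringsAsFactors = FALSE),
    screenStage = "HLAB_exon3", confirmStage = "HLAB_exon2")
}

#' Write / read a diagnostic panel as TSV
#'
#' @param panel a [DiagnosticPanel-class].
#' @param path output (input) TSV path.
#' @param screenStage,confirmStage stage labels used when reading.
#' @return \code{writePanel} the path, invisibly; \code{readPanel} a
#'   [DiagnosticPanel-class].
#' @export
writePanel <- function(panel, path) {
  .writeTSV(panelPositions(panel), path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path, screenStage = "HLAB_exon3",
                      confirmStage = "HLAB_exon2") {
  DiagnosticPanel(.readTSV(path), screenStage = screenStage,
                  confirmStage = confirmStage)
}
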