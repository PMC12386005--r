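#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.AMPLICON_LABELS <- c("HLAB_exon2", "HLAB_exon3", "PSORS1C1_exon3")

#' AlleleAlignment: an aligned allele reference set for one amplicon
#'
#' Holds the aligned sequences of all alleles of one sequenced amplicon
#' (e.g. the 495 bp HLA-B exon-3 fragment), together with the name of the
#' target allele to be typed and the name of the reference allele the
#' coordinate annotations refer to. All sequences must have equal aligned
#' length; gaps are written as \code{-}.
#'
#' @slot amplicon single string, one of \code{"HLAB_exon2"},
#'   \code{"HLAB_exon3"}, \code{"PSORS1C1_exon3"}.
#' @slot sequences a \link[Biostrings]{DNAStringSet} of equal-width aligned
#'   sequences, named by allele.
#' @slot target name of the target allele (must be present).
#' @slot reference name of the reference allele (must be present).
#'
#' @seealso [loadAlleleAlignment()], [findDiagnosticPositions()],
#'   [verifyPanel()]
#' @export
setClass("AlleleAlignment",
  slots = c(
    amplicon  = "character",
    sequences = "DNAStringSet",
    target    = "character",
    reference = "character"
  )
)

setValidity("AlleleAlignment", function(object) {
  msg <- character()
  if (length(object@amplicon) != 1L || !object@amplicon %in% .AMPLICON_LABELS)
    msg <- c(msg, sprintf("amplicon must be one of %s",
                          paste(.AMPLICON_LABELS, collapse = ", ")))
  n <- length(object@sequences)
  if (n < 2L)
    msg <- c(msg, "alignment needs at least 2 records")
  nms <- names(object@sequences)
  if (is.null(nms) || anyNA(nms) || any(nms == ""))
    msg <- c(msg, "all records must be named by allele")
  else if (anyDuplicated(nms))
    msg <- c(msg, "allele names must be unique")
  w <- Biostrings::width(object@sequences)
  if (n > 0L && length(unique(w)) != 1L)
    msg <- c(msg, "ragged alignment: sequences differ in length")
  if (length(object@target) != 1L || !(object@target %in% nms))
    msg <- c(msg, "target allele absent from alignment")
  if (length(object@reference) != 1L || !(object@reference %in% nms))
    msg <- c(msg, "reference allele absent from alignment")
  # only unambiguous bases and gaps: alignments are of resolved alleles
  if (n > 0L) {
    freq <- Biostrings::alphabetFrequency(object@sequences, collapse = TRUE)
    bad <- freq[setdiff(names(freq), c("A", "C", "G", "T", "-"))]
    if (sum(bad) > 0)
      msg <- c(msg, sprintf("non-ACGT/gap characters in alignment: %s",
                            paste(names(bad)[bad > 0], collapse = ",")))
  }
  if (length(msg)) msg else TRUE
})

#' DiagnosticPanel: diagnostic nucleotide positions identifying the target
#'
#' A set of alignment columns, grouped by amplicon, whose joint target-base
#' pattern is carried by the target allele and by no other allele in the
#' reference alignment. Positions where the reference allele shares the
#' target base (e.g. 368A, 209A) still discriminate against other alleles
#' but carry no information about zygosity when the partner allele is the
#' reference; they are flagged \code{zygosity_informative = FALSE}.
#'
#' @slot positions a \link[S4Vectors]{DataFrame} with columns
#'   \code{amplicon}, \code{position} (1-based within the amplicon frame),
#'   \code{target_base}, \code{reference_base}, \code{zygosity_informative}.
#' @slot screenStage amplicon label used for the stage-1 screen.
#' @slot confirmStage amplicon label used for stage-2 confirmation
#'   (may be \code{NA} for single-stage panels).
#'
#' @seealso [hlaB5801Panel()] for the published 8-position panel.
#' @export
setClass("DiagnosticPanel",
  slots = c(
    positions    = "DataFrame",
    screenStage  = "character",
    confirmStage = "character"
  )
)

setValidity("DiagnosticPanel", function(object) {
  msg <- character()
  need <- c("amplicon", "position", "target_base", "reference_base",
            "zygosity_informative")
  if (!all(need %in% colnames(object@positions)))
    msg <- c(msg, sprintf("positions must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    p <- object@positions
    if (nrow(p)) {
      if (!all(p$amplicon %in% .AMPLICON_LABELS))
        msg <- c(msg, "unknown amplicon label in positions")
      if (any(p$position < 1L))
        msg <- c(msg, "positions must be 1-based and positive")
      if (!all(p$target_base %in% c("A", "C", "G", "T")))
        msg <- c(msg, "target_base must be an unambiguous base")
      if (anyDuplicated(paste(p$amplicon, p$position)))
        msg <- c(msg, "duplicated panel position")
    }
  }
  if (length(object@screenStage) != 1L)
    msg <- c(msg, "screenStage must be a single amplicon label")
  if (length(object@confirmStage) != 1L)
    msg <- c(msg, "confirmStage must be a single amplicon label or NA")
  if (length(msg)) msg else TRUE
})

#' Construct an AlleleAlignment
#'
#' @param sequences named character vector or
#'   \link[Biostrings]{DNAStringSet} of equal-length aligned sequences.
#' @param amplicon amplicon label.
#' @param target,reference allele names of the typing target and the
#'   coordinate reference.
#' @return an [AlleleAlignment-class] object.
#' @examples
#' aln <- AlleleAlignment(
#'   c(ref = "ACGT", tgt = "ACTT", d1 = "AGGT"),
#'   amplicon = "HLAB_exon3", target = "tgt", reference = "ref")
#' @export
AlleleAlignment <- function(sequences, amplicon, target, reference) {
  if (!methods::is(sequences, "DNAStringSet")) {
    nms <- names(sequences)
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
    names(sequences) <- nms
  }
  methods::new("AlleleAlignment",
    amplicon = amplicon, sequences = sequences,
    target = target, reference = reference)
}

#' Construct a DiagnosticPanel
#'
#' @param positions data.frame/DataFrame with columns \code{amplicon},
#'   \code{position}, \code{target_base}, \code{reference_base} and
#'   optionally \code{zygosity_informative} (defaults to
#'   \code{target_base != reference_base}).
#' @param screenStage,confirmStage amplicon labels for the two screening
#'   stages (confirm may be \code{NA_character_}).
#' @return a [DiagnosticPanel-class] object.
#' @export
DiagnosticPanel <- function(positions, screenStage = "HLAB_exon3",
                            confirmStage = "HLAB_exon2") {
  positions <- as(as.data.frame(positions), "DataFrame")
  if (!"zygosity_informative" %in% colnames(positions))
    positions$zygosity_informative <-
      positions$target_base != positions$reference_base
  positions$position <- as.integer(positions$position)
  o <- order(match(positions$amplicon, .AMPLICON_LABELS), positions$position)
  methods::new("DiagnosticPanel",
    positions = positions[o, , drop = FALSE],
    screenStage = screenStage, confirmStage = confirmStage)
}
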