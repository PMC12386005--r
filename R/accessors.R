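#' @include AllClasses.R
NULL

#' Accessors for AlleleAlignment and DiagnosticPanel
#'
#' @param x an [AlleleAlignment-class] or [DiagnosticPanel-class] object.
#' @return \code{ampliconLabel} the amplicon label; \code{alleleNames} the
#'   allele names; \code{targetAllele}/\code{referenceAllele} the designated
#'   allele names; \code{alignedSequences} the underlying
#'   \link[Biostrings]{DNAStringSet}; \code{panelPositions} the positions
#'   table as a plain \code{data.frame}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ampliconLabel", function(x) standardGeneric("ampliconLabel"))
#' @rdname accessors
#' @export
setGeneric("alleleNames", function(x) standardGeneric("alleleNames"))
#' @rdname accessors
#' @export
setGeneric("targetAllele", function(x) standardGeneric("targetAllele"))
#' @rdname accessors
#' @export
setGeneric("referenceAllele", function(x) standardGeneric("referenceAllele"))
#' @rdname accessors
#' @export
setGeneric("alignedSequences", function(x) standardGeneric("alignedSequences"))
#' @rdname accessors
#' @export
setGeneric("panelPositions", function(x) standardGeneric("panelPositions"))

#' @rdname accessors
setMethod("ampliconLabel", "AlleleAlignment", function(x) x@amplicon)
#' @rdname accessors
setMethod("alleleNames", "AlleleAlignment", function(x) names(x@sequences))
#' @rdname accessors
setMethod("targetAllele", "AlleleAlignment", function(x) x@target)
#' @rdname accessors
setMethod("referenceAllele", "AlleleAlignment", function(x) x@reference)
#' @rdname accessors
setMethod("alignedSequences", "AlleleAlignment", function(x) x@sequences)
#' @rdname accessors
setMethod("panelPositions", "DiagnosticPanel",
          function(x) as.data.frame(x@positions))

setMethod("show", "AlleleAlignment", function(object) {
  cat(sprintf("AlleleAlignment [%s]: %d alleles, width %d\n",
              object@amplicon, length(object@sequences),
              unique(Biostrings::width(object@sequences))[1]))
  cat(sprintf("  target: %s | reference: %s\n",
              object@target, object@reference))
})

setMethod("show", "DiagnosticPanel", function(object) {
  p <- object@positions
  cat(sprintf("DiagnosticPanel: %d positions (screen: %s, confirm: %s)\n",
              nrow(p), object@screenStage, object@confirmStage))
  for (amp in unique(p$amplicon)) {
    pp <- p[p$amplicon == amp, , drop = FALSE]
    cat(sprintf("  %s: %s\n", amp,
                paste0(pp$position, pp$target_base,
                       ifelse(pp$zygosity_informative, "", "*"),
                       collapse = " ")))
  }
  if (nrow(p) && any(!p$zygosity_informative))
    cat("  (* reference shares the target base: not zygosity-informative)\n")
})
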