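#' Accessors for AudiogramSet and GenotypeSet
#'
#' `thresholds()` returns the dB HL matrix (frequencies x recordings);
#' `frequencies()` the stimulus frequencies in kHz; `genotypeCalls()` the
#' 0/1/2/NA genotype matrix; `variantInfo()` the variant annotation;
#' `participantInfo()` the per-column metadata.
#'
#' @param x an [AudiogramSet-class] or [GenotypeSet-class]
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setGeneric("participantInfo", function(x) standardGeneric("participantInfo"))

#' @rdname accessors
#' @export
setMethod("thresholds", "AudiogramSet", function(x) assay(x, "dB"))

#' @rdname accessors
#' @export
setMethod("frequencies", "AudiogramSet", function(x)
  rowData(x)$frequency_kHz)

#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeSet", function(x) assay(x, "geno"))

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeSet", function(x)
  as.data.frame(rowData(x)))

#' @rdname accessors
#' @export
setMethod("participantInfo", "AudiogramSet", function(x)
  as.data.frame(colData(x)))

#' @rdname accessors
#' @export
setMethod("participantInfo", "GenotypeSet", function(x)
  as.data.frame(colData(x)))

#' Per-ear threshold matrix
#'
#' Extracts one ear's recordings as a participants x frequencies matrix
#' (rownames = participant ids), the layout used by the threshold scan.
#'
#' @param x an [AudiogramSet-class]
#' @param ear "left" or "right"
#' @return numeric matrix, participants x frequencies.
#' @export
earMatrix <- function(x, ear = c("left", "right")) {
  ear <- match.arg(ear)
  sel <- colData(x)$ear == ear
  m <- t(thresholds(x)[, sel, drop = FALSE])
  rownames(m) <- colData(x)$participant_id[sel]
  colnames(m) <- paste0("f", frequencies(x))
  m
}
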