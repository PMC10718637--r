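#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<-
NULL

#' AudiogramSet: pure-tone thresholds for a cohort
#'
#' A \linkS4class{SummarizedExperiment} holding pure-tone audiometric
#' thresholds in dB HL. Rows are stimulus frequencies (kHz, strictly
#' ascending), columns are single-ear recordings. `colData` carries
#' `participant_id`, `ear` ("left"/"right"), `sex` ("male"/"female"),
#' `age` and `noise_history` ("pos"/"neg"/"unknown"). Missing thresholds
#' are `NA`.
#'
#' Higher values mean worse hearing; valid thresholds lie in [-10, 120]
#' dB HL and each recording spans at least 4 frequencies.
#'
#' @export
setClass("AudiogramSet", contains = "SummarizedExperiment")

setValidity("AudiogramSet", function(object) {
  msg <- NULL
  if (!"dB" %in% names(assays(object)))
    msg <- c(msg, "assay 'dB' is required")
  f <- rowData(object)$frequency_kHz
  if (is.null(f))
    msg <- c(msg, "rowData must contain 'frequency_kHz'")
  else {
    if (any(f <= 0)) msg <- c(msg, "frequencies must be strictly positive")
    if (any(diff(f) <= 0)) msg <- c(msg, "frequencies must be strictly ascending")
    if (length(f) < 4) msg <- c(msg, "at least 4 frequencies required")
  }
  cd <- colData(object)
  need <- c("participant_id", "ear", "sex")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks:", paste(miss, collapse = ", ")))
  if ("ear" %in% colnames(cd) && !all(cd$ear %in% c("left", "right")))
    msg <- c(msg, "ear must be 'left' or 'right'")
  if ("dB" %in% names(assays(object))) {
    x <- assay(object, "dB")
    bad <- x[!is.na(x)]
    if (length(bad) && (min(bad) < -10 || max(bad) > 120))
      msg <- c(msg, "thresholds must lie in [-10, 120] dB HL")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an AudiogramSet
#'
#' @param thresholds numeric matrix, frequencies x recordings, dB HL.
#' @param frequencies numeric vector of stimulus frequencies in kHz,
#'   strictly ascending, one per row of `thresholds`.
#' @param info data.frame (or DataFrame) of per-recording metadata with
#'   columns `participant_id`, `ear`, `sex` and optionally `age`,
#'   `noise_history`; one row per column of `thresholds`.
#' @return An [AudiogramSet-class] object.
#' @examples
#' f <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
#' m <- matrix(10, length(f), 2)
#' info <- data.frame(participant_id = "P1", ear = c("left", "right"),
#'                    sex = "female")
#' AudiogramSet(m, f, info)
#' @export
AudiogramSet <- function(thresholds, frequencies, info) {
  thresholds <- as.matrix(thresholds)
  stopifnot(nrow(thresholds) == length(frequencies))
  info <- as(as.data.frame(info), "DataFrame")
  if (!"noise_history" %in% colnames(info)) info$noise_history <- "unknown"
  se <- SummarizedExperiment(
    assays = list(dB = thresholds),
    rowData = DataFrame(frequency_kHz = as.numeric(frequencies)),
    colData = info)
  rownames(se) <- paste0("f", frequencies)
  if (is.null(colnames(se)))
    colnames(se) <- paste(info$participant_id, substr(info$ear, 1, 1), sep = "_")
  new("AudiogramSet", se)
}

#' GenotypeSet: consensus genotype matrix with variant annotation
#'
#' A \linkS4class{SummarizedExperiment} holding merged genotype codes in
#' assay `geno`: 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing. Rows are variants; `rowData` carries the
#' annotation (`gene_id`, `impact_class`, `ref_maf`, optionally `chrom`,
#' `pos`, `ref`, `alt`, `cadd`, `spliceai`, `utr_flag`). Columns are
#' participants with `colData` columns `participant_id` and `sex`.
#'
#' @export
setClass("GenotypeSet", contains = "SummarizedExperiment")

setValidity("GenotypeSet", function(object) {
  msg <- NULL
  if (!"geno" %in% names(assays(object)))
    msg <- c(msg, "assay 'geno' is required")
  else {
    g <- assay(object, "geno")
    ok <- is.na(g) | g %in% c(0, 1, 2)
    if (!all(ok)) msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  }
  cd <- colData(object)
  if (!"participant_id" %in% colnames(cd))
    msg <- c(msg, "colData lacks 'participant_id'")
  rd <- rowData(object)
  if ("ref_maf" %in% colnames(rd)) {
    rm <- rd$ref_maf[!is.na(rd$ref_maf)]
    if (length(rm) && (min(rm) < 0 || max(rm) > 0.5))
      msg <- c(msg, "ref_maf must lie in [0, 0.5]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeSet
#'
#' @param geno integer matrix, variants x participants, codes 0/1/2/NA.
#' @param variants data.frame of per-variant annotation; must contain
#'   `variant_id`, usually also `gene_id`, `impact_class`, `ref_maf`.
#' @param participants data.frame with `participant_id` and `sex`,
#'   one row per column of `geno`.
#' @return A [GenotypeSet-class] object.
#' @export
GenotypeSet <- function(geno, variants, participants) {
  geno <- as.matrix(geno)
  variants <- as(as.data.frame(variants), "DataFrame")
  participants <- as(as.data.frame(participants), "DataFrame")
  stopifnot(nrow(geno) == nrow(variants), ncol(geno) == nrow(participants))
  se <- SummarizedExperiment(assays = list(geno = geno),
                             rowData = variants, colData = participants)
  rownames(se) <- variants$variant_id
  colnames(se) <- participants$participant_id
  new("GenotypeSet", se)
}

#' @describeIn AudiogramSet-class compact display
#' @param object an AudiogramSet
#' @export
setMethod("show", "AudiogramSet", function(object) {
  f <- rowData(object)$frequency_kHz
  cat(sprintf("AudiogramSet: %d recordings (%d participants), %d frequencies (%g-%g kHz)\n",
              ncol(object), length(unique(colData(object)$participant_id)),
              nrow(object), min(f), max(f)))
  invisible(NULL)
})

#' @describeIn GenotypeSet-class compact display
#' @param object a GenotypeSet
#' @export
setMethod("show", "GenotypeSet", function(object) {
  g <- assay(object, "geno")
  cat(sprintf("GenotypeSet: %d variants x %d participants (%.1f%% missing)\n",
              nrow(object), ncol(object), 100 * mean(is.na(g))))
  invisible(NULL)
})
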