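#' Read and write audiogram CSV files
#'
#' Long-form CSV: one row per (participant, ear) with columns
#' `participant_id`, `sex` (M/F), `age`, `noise_history`
#' (pos/neg/unknown), `ear` (L/R), then one threshold column per
#' frequency named `f0.25` ... `f8` (kHz, dB HL); empty cells are missing.
#'
#' @param path file path.
#' @return `readAudiograms`: an [AudiogramSet-class].
#' @export
readAudiograms <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fcols <- grep("^f[0-9.]+$", names(df), value = TRUE)
  freqs <- as.numeric(sub("^f", "", fcols))
  o <- order(freqs)
  fcols <- fcols[o]; freqs <- freqs[o]
  thr <- t(as.matrix(df[, fcols]))
  info <- data.frame(
    participant_id = as.character(df$participant_id),
    ear = c(L = "left", R = "right")[toupper(substr(df$ear, 1, 1))],
    sex = c(M = "male", F = "female")[toupper(substr(df$sex, 1, 1))],
    age = if ("age" %in% names(df)) df$age else NA_real_,
    noise_history = if ("noise_history" %in% names(df)) df$noise_history
                    else "unknown")
  AudiogramSet(thr, freqs, info)
}

#' @rdname readAudiograms
#' @param x an [AudiogramSet-class].
#' @export
writeAudiograms <- function(x, path) {
  stopifnot(is(x, "AudiogramSet"))
  cd <- as.data.frame(colData(x))
  thr <- t(thresholds(x))
  colnames(thr) <- paste0("f", frequencies(x))
  out <- data.frame(participant_id = cd$participant_id,
                    sex = c(male = "M", female = "F")[cd$sex],
                    age = if ("age" %in% names(cd)) cd$age else NA,
                    noise_history = cd$noise_history,
                    ear = c(left = "L", right = "R")[cd$ear],
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(thr, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# VCF genotype string <-> 0/1/2/NA code maps
gtToCode <- function(gt) {
  gt <- sub("\\|", "/", gt)
  code <- rep(NA_integer_, length(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  code
}

codeToGt <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0] <- "0/0"
  out[!is.na(code) & code == 1] <- "0/1"
  out[!is.na(code) & code == 2] <- "1/1"
  out
}

#' Read a merged-genotype VCF into a GenotypeSet
#'
#' Reads the per-sample `GT` field of a VCF (v4.x) with vcfR and attaches
#' a variant annotation table. Multiallelic records are not expected.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @param annotations optional data.frame from [readAnnotations()]; matched
#'   on `variant_id` (`chrom:pos:ref:alt`).
#' @param sexes optional named character vector participant -> sex; when
#'   absent, sex is taken from `annotations` attributes or set to NA.
#' @return a [GenotypeSet-class].
#' @export
readGenotypes <- function(vcf_path, annotations = NULL, sexes = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  vid <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = ":")
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(gtToCode(gt), nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  vars <- data.frame(variant_id = vid, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"])
  if (!is.null(annotations)) {
    m <- match(vid, annotations$variant_id)
    for (col in setdiff(names(annotations), "variant_id"))
      vars[[col]] <- annotations[[col]][m]
  }
  pid <- colnames(gt)
  participants <- data.frame(
    participant_id = pid,
    sex = if (is.null(sexes)) NA_character_ else unname(sexes[pid]))
  GenotypeSet(geno, vars, participants)
}

#' Read a multi-caller VCF into caller records
#'
#' Expects one VCF carrying per-caller genotypes in FORMAT fields
#' `GT_GATK`, `GT_BCF`, `GT_FB` and site-level INFO keys `TRANCHE`
#' (tranche1/tranche2/lower/absent) plus flags `BCF_PASS` and `FB_PASS`.
#' Mitochondrial records (contig `chrM` or `MT`) may instead carry
#' per-sample `DP` and `VF` (variant allele fraction) FORMAT fields.
#'
#' @param vcf_path path to the VCF.
#' @param sexes optional named character vector participant -> sex.
#' @return a records list consumed by [applyQcPipeline()]: `sites`,
#'   `genotypes` (per-caller code matrices), `mito` (depth/vaf matrices or
#'   NULL), `participants`.
#' @export
readCallerRecords <- function(vcf_path, sexes = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  info <- fix[, "INFO"]
  vid <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = ":")
  tranche <- vcfR::extract.info(v, element = "TRANCHE")
  tranche[is.na(tranche)] <- "absent"
  sites <- data.frame(variant_id = vid, chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      tranche = tranche,
                      bcftools_pass = grepl("(^|;)BCF_PASS(;|$)", info),
                      freebayes_pass = grepl("(^|;)FB_PASS(;|$)", info))
  grab <- function(el) {
    gt <- vcfR::extract.gt(v, element = el)
    matrix(gtToCode(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  genos <- list(gatk = grab("GT_GATK"), bcf = grab("GT_BCF"),
                fb = grab("GT_FB"))
  mito <- NULL
  if (any(sites$chrom %in% c("chrM", "MT"))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    vf <- suppressWarnings(
      vcfR::extract.gt(v, element = "VF", as.numeric = TRUE))
    rownames(dp) <- rownames(vf) <- vid
    mito <- list(depth = dp, vaf = vf)
  }
  pid <- colnames(genos$gatk)
  list(sites = sites, genotypes = genos, mito = mito,
       participants = data.frame(
         participant_id = pid,
         sex = if (is.null(sexes)) NA_character_ else unname(sexes[pid])))
}

#' Write a GenotypeSet as a multi-caller VCF
#'
#' Emits a VCF v4.2 file in which all three callers report the merged
#' genotype and every site carries `TRANCHE=tranche1;BCF_PASS;FB_PASS`,
#' i.e. a file that passes the quality gate unchanged -- the format used
#' for simulated fixtures. Records are sorted by contig and position.
#'
#' @param gset a [GenotypeSet-class] whose `rowData` carries `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
writeCallerVcf <- function(gset, path) {
  vi <- variantInfo(gset)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(vi)))
  geno <- genotypeCalls(gset)
  o <- order(suppressWarnings(as.integer(vi$chrom)), vi$chrom, vi$pos)
  vi <- vi[o, , drop = FALSE]; geno <- geno[o, , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(vi$chrom), ">"),
    "##INFO=<ID=TRANCHE,Number=1,Type=String,Description=\"GATK VQSR tranche\">",
    "##INFO=<ID=BCF_PASS,Number=0,Type=Flag,Description=\"Passed BCFtools filter\">",
    "##INFO=<ID=FB_PASS,Number=0,Type=Flag,Description=\"Passed Freebayes filter\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Merged genotype\">",
    "##FORMAT=<ID=GT_GATK,Number=1,Type=String,Description=\"GATK genotype\">",
    "##FORMAT=<ID=GT_BCF,Number=1,Type=String,Description=\"BCFtools genotype\">",
    "##FORMAT=<ID=GT_FB,Number=1,Type=String,Description=\"Freebayes genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t"))
  gts <- matrix(codeToGt(geno), nrow(geno), ncol(geno))
  sample_fields <- apply(gts, 1, function(r)
    paste(paste(r, r, r, r, sep = ":"), collapse = "\t"))
  body <- paste(vi$chrom, vi$pos, vi$variant_id, vi$ref, vi$alt, ".", "PASS",
                "TRANCHE=tranche1;BCF_PASS;FB_PASS",
                "GT:GT_GATK:GT_BCF:GT_FB", sample_fields, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a variant annotation table
#'
#' Tab-separated with header: `variant_id`, `gene_id`, `impact_class`,
#' `ref_maf`, and optionally `cadd`, `spliceai`, `utr_flag`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readAnnotations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("variant_id", "gene_id", "impact_class", "ref_maf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a gene-list file
#'
#' One gene identifier per line; `#` starts a comment.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}
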