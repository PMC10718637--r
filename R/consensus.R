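#' Site-level quality gate for multi-caller variant calls
#'
#' A variant site is kept when the calls are in the combination found to be
#' accurate by Sanger resequencing: GATK VQSR tranche 1 together with a pass
#' from at least one of BCFtools or Freebayes, or GATK VQSR tranche 2
#' together with a BCFtools pass.
#'
#' @param gatk_tranche character vector in
#'   `c("tranche1", "tranche2", "lower", "absent")`.
#' @param bcftools_pass,freebayes_pass logical vectors.
#' @return logical vector: `TRUE` = keep.
#' @examples
#' siteQualityGate("tranche1", FALSE, TRUE)  # TRUE
#' siteQualityGate("tranche2", FALSE, TRUE)  # FALSE
#' @export
siteQualityGate <- function(gatk_tranche, bcftools_pass, freebayes_pass) {
  stopifnot(all(gatk_tranche %in% c("tranche1", "tranche2", "lower", "absent")))
  bcftools_pass <- !is.na(bcftools_pass) & bcftools_pass
  freebayes_pass <- !is.na(freebayes_pass) & freebayes_pass
  (gatk_tranche == "tranche1" & (bcftools_pass | freebayes_pass)) |
    (gatk_tranche == "tranche2" & bcftools_pass)
}

#' Merge per-caller genotypes into a consensus call
#'
#' Resolves up to three callers' genotypes for one sample at one site.
#' Unanimous calls and 2-vs-1 disagreements take the majority; the
#' three-way split \{hom_ref, het, hom_alt\} is resolved to heterozygous;
#' every other combination -- including a single informative caller and a
#' 1-vs-1 split -- is missing.
#'
#' @param calls character vector (length <= 3) with values in
#'   `c("hom_ref", "het", "hom_alt", "no_call")`, or integer codes
#'   0/1/2/NA.
#' @return integer genotype code 0/1/2, or `NA` for missing.
#' @examples
#' mergeGenotype(c("het", "het", "hom_alt"))           # 1
#' mergeGenotype(c("hom_ref", "het", "hom_alt"))       # 1
#' mergeGenotype(c("het", "no_call", "no_call"))       # NA
#' @export
mergeGenotype <- function(calls) {
  if (is.character(calls)) {
    map <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, no_call = NA_integer_)
    stopifnot(all(calls %in% names(map)))
    calls <- unname(map[calls])
  }
  stopifnot(length(calls) <= 3)
  g <- calls[!is.na(calls)]
  if (length(g) < 2) return(NA_integer_)
  tab <- tabulate(g + 1L, nbins = 3L)
  if (max(tab) > length(g) / 2) return(which.max(tab) - 1L)  # unanimity or 2-vs-1
  if (all(tab == 1L)) return(1L)                             # three-way split -> het
  NA_integer_                                                # 1-vs-1 split
}

#' Hardy-Weinberg heterozygote-excess exact p-value
#'
#' One-sided exact test for heterozygote excess, conditional on the
#' observed allele counts (Levene-Haldane distribution): the p-value sums
#' the conditional probabilities of all genotype configurations with a
#' heterozygote count at least as large as observed. Used as a QC screen:
#' an excess of heterozygotes at a site is a signature of mismapped reads
#' rather than of a real polymorphism.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return p-value in (0, 1].
#' @export
excessHetPValue <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("undefined test: zero genotype total")
  a1 <- 2 * n_hom_ref + n_het
  nA <- min(a1, 2 * n - a1)                      # minor allele count
  hs <- seq.int(nA %% 2, nA, by = 2)             # feasible het counts
  logp <- hs * log(2) + lfactorial(n) -
    lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (nA + hs) / 2) +
    lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[hs >= n_het])
}

#' @rdname excessHetPValue
#' @param alpha significance level; the site is dropped when the excess-het
#'   p-value falls below it. The default 1e-6 is a common exome-QC choice.
#' @return `excessHetFilter`: `TRUE` = keep, `FALSE` = drop.
#' @export
excessHetFilter <- function(n_hom_ref, n_het, n_hom_alt, alpha = 1e-6) {
  excessHetPValue(n_hom_ref, n_het, n_hom_alt) >= alpha
}

#' Cohort allele-frequency filter
#'
#' Drops variants whose cohort allele frequency exceeds the reference-
#' population minor allele frequency by more than 0.4; such sites are
#' likely aligner miscalls in low-complexity regions.
#'
#' @param cohort_af,ref_maf fractions in \[0, 1\].
#' @return logical vector: `TRUE` = keep (strict inequality drops).
#' @export
cohortAfFilter <- function(cohort_af, ref_maf) {
  stopifnot(all(cohort_af >= 0 & cohort_af <= 1),
            all(ref_maf >= 0 & ref_maf <= 1))
  !(cohort_af > ref_maf + 0.4)
}

#' Genotype a mitochondrial variant from depth and allele fraction
#'
#' Homoplasmic calls (variant allele fraction above `hom_vaf_min`) are
#' treated as homozygous-alternate and heteroplasmic calls (fraction
#' between `het_vaf_min` and `hom_vaf_min`) as heterozygous. Calls below
#' the depth floor, or with an allele fraction below the reliable
#' heteroplasmy floor, are missing.
#'
#' @param depth read depth (vector ok).
#' @param vaf variant allele fraction in \[0, 1\].
#' @param min_depth depth floor (default 30x).
#' @param het_vaf_min heteroplasmy detection floor (default 0.40).
#' @param hom_vaf_min homoplasmy threshold (default 0.95, exclusive).
#' @return integer genotype codes 1/2/NA.
#' @export
mitoGenotype <- function(depth, vaf, min_depth = 30, het_vaf_min = 0.40,
                         hom_vaf_min = 0.95) {
  stopifnot(all(vaf >= 0 & vaf <= 1, na.rm = TRUE), all(depth >= 0, na.rm = TRUE))
  out <- rep(NA_integer_, length(vaf))
  ok <- !is.na(depth) & !is.na(vaf) & depth >= min_depth
  out[ok & vaf > hom_vaf_min] <- 2L
  out[ok & vaf >= het_vaf_min & vaf <= hom_vaf_min] <- 1L
  out
}

#' High-impact / low-MAF variant filter
#'
#' Final filter of the QC pipeline: keep only variants annotated as high
#' predicted impact with a reference-population MAF strictly below
#' `maf_max`. Variants absent from the reference MAF source are treated as
#' novel (MAF 0) by default.
#'
#' @param impact_class character vector; "high" passes, anything else fails.
#' @param ref_maf numeric vector of reference MAFs; `NA` handled per
#'   `missing_maf`.
#' @param maf_max exclusive MAF ceiling (default 0.1).
#' @param missing_maf "zero" (treat NA as 0, keep if high impact) or
#'   "drop".
#' @return logical vector: `TRUE` = keep.
#' @export
impactMafFilter <- function(impact_class, ref_maf, maf_max = 0.1,
                            missing_maf = c("zero", "drop")) {
  missing_maf <- match.arg(missing_maf)
  if (anyNA(ref_maf)) {
    if (missing_maf == "zero") {
      ref_maf[is.na(ref_maf)] <- 0
    } else {
      impact_class[is.na(ref_maf)] <- "dropped"
      ref_maf[is.na(ref_maf)] <- 1
    }
  }
  impact_class == "high" & ref_maf < maf_max
}

# cohort allele frequency from merged codes: nuclear = alt-allele dosage /
# (2 * non-missing); mitochondrial = carriers / non-missing
cohortAlleleFreq <- function(geno_row, mito = FALSE) {
  g <- geno_row[!is.na(geno_row)]
  if (!length(g)) return(NA_real_)
  if (mito) mean(g > 0) else sum(g) / (2 * length(g))
}

#' Run the full variant QC pipeline
#'
#' Applies, in order: the site quality gate, per-sample genotype consensus
#' merging, the Hardy-Weinberg excess-heterozygosity filter, the cohort
#' allele-frequency filter, and the high-impact/MAF filter. Mitochondrial
#' sites (contig `chrM`/`MT`) bypass the nuclear quality gate, merge and
#' diploid excess-het test; their genotypes come from [mitoGenotype()] and
#' their cohort allele frequency is the carrier fraction.
#'
#' @param records caller records as returned by [readCallerRecords()]:
#'   a list with `sites` (data.frame: variant_id, chrom, tranche,
#'   bcftools_pass, freebayes_pass), `genotypes` (list of per-caller
#'   0/1/2/NA matrices, variants x participants), optional `mito`
#'   (list with `depth` and `vaf` matrices for mitochondrial rows),
#'   and `participants` (data.frame with participant_id, sex).
#' @param annotations data.frame with variant_id, gene_id, impact_class,
#'   ref_maf (see [readAnnotations()]).
#' @param excess_het_alpha significance level for the excess-het drop.
#' @param maf_max MAF ceiling of the final filter.
#' @param min_depth,het_vaf_min,hom_vaf_min mitochondrial genotyping
#'   parameters, see [mitoGenotype()].
#' @return list with `genotypes` (a [GenotypeSet-class] of surviving
#'   variants) and `retention` (data.frame: stage, n_variants).
#' @export
applyQcPipeline <- function(records, annotations, excess_het_alpha = 1e-6,
                            maf_max = 0.1, min_depth = 30,
                            het_vaf_min = 0.40, hom_vaf_min = 0.95) {
  sites <- records$sites
  n0 <- nrow(sites)
  is_mito <- sites$chrom %in% c("chrM", "MT")
  ann <- annotations[match(sites$variant_id, annotations$variant_id), , drop = FALSE]

  if (n0 == 0) {
    empty <- GenotypeSet(matrix(integer(), 0, nrow(records$participants)),
                         data.frame(variant_id = character()),
                         records$participants)
    return(list(genotypes = empty,
                retention = data.frame(
                  stage = c("input", "quality_gate", "genotype_merge",
                            "excess_het", "cohort_af", "impact_maf"),
                  n_variants = 0L)))
  }

  # stage 1: quality gate (nuclear only; mito sites pass through)
  keep1 <- is_mito | siteQualityGate(sites$tranche, sites$bcftools_pass,
                                     sites$freebayes_pass)
  n1 <- sum(keep1)

  # stage 2: genotype consensus merge (drops sites with no genotyped sample)
  nP <- nrow(records$participants)
  geno <- matrix(NA_integer_, n0, nP,
                 dimnames = list(sites$variant_id,
                                 records$participants$participant_id))
  for (i in which(keep1 & !is_mito)) {
    calls <- vapply(records$genotypes, function(m) m[i, ], numeric(nP))
    geno[i, ] <- apply(calls, 1, mergeGenotype)
  }
  if (any(is_mito) && !is.null(records$mito)) {
    mi <- which(keep1 & is_mito)
    mrow <- match(sites$variant_id[mi], rownames(records$mito$vaf))
    for (k in seq_along(mi)) {
      geno[mi[k], ] <- mitoGenotype(records$mito$depth[mrow[k], ],
                                    records$mito$vaf[mrow[k], ],
                                    min_depth, het_vaf_min, hom_vaf_min)
    }
  }
  keep2 <- keep1 & rowSums(!is.na(geno)) > 0
  n2 <- sum(keep2)

  # stage 3: excess heterozygosity (nuclear only)
  keep3 <- keep2
  for (i in which(keep2 & !is_mito)) {
    g <- geno[i, ]
    cnt <- tabulate(g[!is.na(g)] + 1L, nbins = 3L)
    keep3[i] <- excessHetFilter(cnt[1], cnt[2], cnt[3], excess_het_alpha)
  }
  n3 <- sum(keep3)

  # stage 4: cohort allele frequency vs reference MAF
  ref_maf <- ann$ref_maf
  ref_maf[is.na(ref_maf)] <- 0
  keep4 <- keep3
  for (i in which(keep3)) {
    af <- cohortAlleleFreq(geno[i, ], mito = is_mito[i])
    keep4[i] <- cohortAfFilter(af, ref_maf[i])
  }
  n4 <- sum(keep4)

  # stage 5: high impact + MAF < maf_max
  impact <- ann$impact_class
  no_ann <- is.na(impact)
  if (any(no_ann & keep4))
    warning(sum(no_ann & keep4),
            " surviving variant(s) lack annotation and are dropped from",
            " gene-level analyses")
  keep5 <- keep4 & !no_ann &
    impactMafFilter(ifelse(no_ann, "other", impact), ann$ref_maf, maf_max)
  n5 <- sum(keep5)

  vkeep <- which(keep5)
  vars <- data.frame(variant_id = sites$variant_id[vkeep],
                     chrom = sites$chrom[vkeep],
                     gene_id = ann$gene_id[vkeep],
                     impact_class = ann$impact_class[vkeep],
                     ref_maf = ann$ref_maf[vkeep])
  gset <- GenotypeSet(geno[vkeep, , drop = FALSE], vars, records$participants)
  list(genotypes = gset,
       retention = data.frame(
         stage = c("input", "quality_gate", "genotype_merge", "excess_het",
                   "cohort_af", "impact_maf"),
         n_variants = c(n0, n1, n2, n3, n4, n5)))
}

#' Overall genotype-call concordance from a validation cross-tabulation
#'
#' Percent agreement (diagonal over total) of a square confusion matrix of
#' sequencing genotype calls against an orthogonal validation method such
#' as Sanger resequencing.
#'
#' @param tab square numeric matrix (e.g. 3x3 of hom-ref/het/hom-alt calls).
#' @param digits decimal places for rounding (default 1).
#' @return percent agreement.
#' @export
callConcordance <- function(tab, digits = 1) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
  round(100 * sum(diag(tab)) / sum(tab), digits)
}
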