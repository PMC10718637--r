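#' Parameters for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' audiograms built from the two presbyacusis components plus independent
#' per-frequency noise; genotypes in Hardy-Weinberg proportions at rare
#' minor allele frequencies; optional planted per-gene load enrichment in a
#' phenotype class; and optional planted carrier threshold shifts of stated
#' dB magnitudes at chosen frequencies.
#'
#' @param n_participants cohort size (default 500).
#' @param sex_ratio fraction male (default 0.5).
#' @param age_range uniform age range in years (default 55-85).
#' @param class_mixture named probabilities over OlderNormal, Metabolic,
#'   Sensory, Unclassified (must sum to 1).
#' @param component_ranges per-class uniform ranges of the true metabolic
#'   and sensory estimates (dB); defaults leave margin to the
#'   classification rule boundaries so labels are recoverable.
#' @param noise_sd_dB per-frequency audiogram noise SD (default 3).
#' @param n_genes number of baseline genes (default 100).
#' @param variants_per_gene_lambda Poisson rate; each gene gets
#'   1 + Pois(lambda) variants (default 2).
#' @param maf_range uniform range of simulated reference MAFs, within
#'   (0, 0.1) (default 0.005-0.1).
#' @param planted_load_genes `NULL` or data.frame with columns `gene`
#'   (index into the baseline genes), `class` (target phenotype) and
#'   `multiplier` (carrier-rate multiplier, capped at probability 1).
#' @param planted_effect_variants `NULL` or data.frame with columns
#'   `shift_dB` (signed; positive = worse hearing),
#'   `freqs` (comma-separated kHz, e.g. "3,4,6,8"), `sex` ("any",
#'   "male", "female") and `n_carriers` (exact realized carrier count).
#' @param frequencies_kHz simulated audiometric grid; default the 8
#'   standard clinical frequencies 0.25-8 kHz (`twinsuk_grid = TRUE`
#'   swaps 3 kHz for 0.125 kHz).
#' @param twinsuk_grid use the alternative grid lacking 3 kHz.
#' @param seed RNG seed.
#' @return a `simParams` list.
#' @export
simParams <- function(n_participants = 500, sex_ratio = 0.5,
                      age_range = c(55, 85),
                      class_mixture = c(OlderNormal = 0.2, Metabolic = 0.3,
                                        Sensory = 0.3, Unclassified = 0.2),
                      component_ranges = list(
                        OlderNormal = list(M = c(0, 8), S = c(0, 8)),
                        Metabolic = list(M = c(25, 45), S = c(0, 14)),
                        Sensory = list(M = c(0, 14), S = c(25, 50)),
                        Unclassified = list(M = c(28, 45), S = c(28, 45))),
                      noise_sd_dB = 3, n_genes = 100,
                      variants_per_gene_lambda = 2,
                      maf_range = c(0.005, 0.1),
                      planted_load_genes = NULL,
                      planted_effect_variants = NULL,
                      frequencies_kHz = NULL, twinsuk_grid = FALSE,
                      seed = 1) {
  if (abs(sum(class_mixture) - 1) > 1e-8)
    stop("class_mixture probabilities must sum to 1")
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.1)
  if (is.null(frequencies_kHz))
    frequencies_kHz <- if (twinsuk_grid) c(0.125, 0.25, 0.5, 1, 2, 4, 6, 8)
                       else c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
  list(n_participants = n_participants, sex_ratio = sex_ratio,
       age_range = age_range, class_mixture = class_mixture,
       component_ranges = component_ranges, noise_sd_dB = noise_sd_dB,
       n_genes = n_genes, variants_per_gene_lambda = variants_per_gene_lambda,
       maf_range = maf_range, planted_load_genes = planted_load_genes,
       planted_effect_variants = planted_effect_variants,
       frequencies_kHz = frequencies_kHz, seed = seed)
}

#' Generate a synthetic audiometric cohort
#'
#' Each participant draws a phenotype class, then true metabolic and
#' sensory magnitudes (M, S) uniformly from the class's ranges; each ear's
#' thresholds are `M * metabolic_shape + S * sensory_shape` plus
#' independent Normal(0, noise_sd) noise per frequency, clipped to
#' \[-10, 120\] dB HL. Deterministic given the seed.
#'
#' @param params a [simParams()] list.
#' @param basis the [profileBasis()] whose shapes build the audiograms.
#' @return list with `audiograms` (an [AudiogramSet-class]) and `truth`
#'   (data.frame: participant_id, sex, age, noise_history, class, M, S).
#' @export
generateCohort <- function(params = simParams(), basis = defaultProfileBasis()) {
  set.seed(params$seed)
  n <- params$n_participants
  freqs <- params$frequencies_kHz
  b <- resampleBasis(basis, freqs)
  ids <- sprintf("P%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < params$sex_ratio, "male", "female")
  age <- round(stats::runif(n, params$age_range[1], params$age_range[2]), 1)
  noise_hist <- ifelse(stats::runif(n) < ifelse(sex == "male", 0.6, 0.3),
                       "pos", "neg")
  cls <- sample(names(params$class_mixture), n, replace = TRUE,
                prob = params$class_mixture)
  M <- S <- numeric(n)
  for (i in seq_len(n)) {
    rg <- params$component_ranges[[cls[i]]]
    M[i] <- stats::runif(1, rg$M[1], rg$M[2])
    S[i] <- stats::runif(1, rg$S[1], rg$S[2])
  }
  nf <- length(freqs)
  thr <- matrix(NA_real_, nf, 2 * n)
  info <- data.frame(participant_id = rep(ids, each = 2),
                     ear = rep(c("left", "right"), n),
                     sex = rep(sex, each = 2), age = rep(age, each = 2),
                     noise_history = rep(noise_hist, each = 2))
  for (i in seq_len(n)) {
    mu <- M[i] * b$metabolic + S[i] * b$sensory
    thr[, 2 * i - 1] <- mu + stats::rnorm(nf, 0, params$noise_sd_dB)
    thr[, 2 * i]     <- mu + stats::rnorm(nf, 0, params$noise_sd_dB)
  }
  thr <- pmin(pmax(thr, -10), 120)
  list(audiograms = AudiogramSet(thr, freqs, info),
       truth = data.frame(participant_id = ids, sex = sex, age = age,
                          noise_history = noise_hist, class = cls,
                          M = M, S = S))
}

#' Generate synthetic genotypes (and apply planted carrier effects)
#'
#' Baseline genotypes are drawn per variant under Hardy-Weinberg
#' equilibrium at its simulated MAF. Genes listed in
#' `params$planted_load_genes` have their carrier probability multiplied
#' (capped at 1) in participants of the target class, leaving other
#' classes at baseline. Planted effect variants get exactly `n_carriers`
#' heterozygous carriers (drawn from the eligible sex) and the stated
#' `shift_dB` is added to those carriers' thresholds at the affected
#' frequencies in both ears.
#'
#' @param params a [simParams()] list.
#' @param cohort output of [generateCohort()].
#' @return list with `genotypes` (a [GenotypeSet-class], annotation in
#'   `rowData`), `audiograms` (the cohort's AudiogramSet with planted
#'   shifts applied) and `truth` (list: `participants`, `load_genes`,
#'   `effect_variants` with realized carrier ids).
#' @export
generateGenotypes <- function(params, cohort) {
  set.seed(params$seed + 1L)
  truth_p <- cohort$truth
  n <- nrow(truth_p)
  ids <- truth_p$participant_id

  n_var_per_gene <- 1L + stats::rpois(params$n_genes,
                                      params$variants_per_gene_lambda)
  gene_ids <- sprintf("G%04d", seq_len(params$n_genes))
  gene_of <- rep(gene_ids, n_var_per_gene)
  nv <- length(gene_of)
  chrom <- as.character((match(gene_of, gene_ids) - 1L) %% 22L + 1L)
  maf <- stats::runif(nv, params$maf_range[1], params$maf_range[2])

  planted <- params$planted_load_genes
  target_class_of <- mult_of <- NULL
  if (!is.null(planted)) {
    pg <- gene_ids[planted$gene]
    target_class_of <- stats::setNames(planted$class, pg)
    mult_of <- stats::setNames(planted$multiplier, pg)
  }
  geno <- matrix(0L, nv, n, dimnames = list(NULL, ids))
  for (v in seq_len(nv)) {
    g <- stats::rbinom(n, 2, maf[v])
    gn <- gene_of[v]
    if (!is.null(planted) && gn %in% names(target_class_of)) {
      tgt <- truth_p$class == target_class_of[[gn]]
      if (any(tgt)) {
        p_car <- min(1, mult_of[[gn]] * (1 - (1 - maf[v])^2))
        maf_eff <- 1 - sqrt(1 - p_car)
        g[tgt] <- stats::rbinom(sum(tgt), 2, maf_eff)
      }
    }
    geno[v, ] <- g
  }

  # positions: sequential per chromosome so the emitted VCF is sorted
  pos <- integer(nv)
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    pos[j] <- 10000L + seq_along(j) * 150L
  }
  variant_id <- paste0(chrom, ":", pos, ":A:G")

  aud <- cohort$audiograms
  effects <- list()
  pe <- params$planted_effect_variants
  if (!is.null(pe)) {
    thr <- thresholds(aud)
    cd <- colData(aud)
    freqs <- frequencies(aud)
    for (k in seq_len(nrow(pe))) {
      elig <- if (pe$sex[k] == "any") ids else ids[truth_p$sex == pe$sex[k]]
      if (pe$n_carriers[k] > length(elig))
        stop("planted effect variant ", k, ": requested carriers exceed ",
             "eligible participants")
      carriers <- sample(elig, pe$n_carriers[k])
      g <- stats::setNames(rep(0L, n), ids)
      g[carriers] <- 1L
      ch <- as.character(22L + k)
      vid <- paste0(ch, ":", 10000L + k * 150L, ":A:G")
      geno <- rbind(geno, g)
      gene_of <- c(gene_of, sprintf("GEFF%02d", k))
      chrom <- c(chrom, ch)
      pos <- c(pos, 10000L + k * 150L)
      maf <- c(maf, pe$n_carriers[k] / (2 * n))
      variant_id <- c(variant_id, vid)
      fidx <- match(as.numeric(strsplit(as.character(pe$freqs[k]), ",")[[1]]),
                    freqs)
      if (anyNA(fidx)) stop("planted effect frequencies not on the grid")
      cols <- which(cd$participant_id %in% carriers)
      thr[fidx, cols] <- pmin(pmax(thr[fidx, cols] + pe$shift_dB[k], -10), 120)
      effects[[k]] <- list(variant_id = vid, shift_dB = pe$shift_dB[k],
                           freqs_kHz = freqs[fidx], sex = pe$sex[k],
                           carriers = carriers)
    }
    aud <- AudiogramSet(thr, freqs, as.data.frame(cd))
  }

  variants <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                         ref = "A", alt = "G", gene_id = gene_of,
                         impact_class = "high", ref_maf = pmin(maf, 0.5))
  participants <- data.frame(participant_id = ids, sex = truth_p$sex)
  gset <- GenotypeSet(geno, variants, participants)
  load_truth <- if (is.null(planted)) NULL else
    data.frame(gene_id = gene_ids[planted$gene], class = planted$class,
               multiplier = planted$multiplier)
  list(genotypes = gset, audiograms = aud,
       truth = list(participants = truth_p, load_genes = load_truth,
                    effect_variants = effects))
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper: [generateCohort()] followed by
#' [generateGenotypes()].
#'
#' @inheritParams generateCohort
#' @return list with `audiograms`, `genotypes`, `truth`.
#' @export
simulateCohort <- function(params = simParams(), basis = defaultProfileBasis()) {
  cohort <- generateCohort(params, basis)
  g <- generateGenotypes(params, cohort)
  list(audiograms = g$audiograms, genotypes = g$genotypes, truth = g$truth)
}

#' Write a simulated cohort to disk in the pipeline's file formats
#'
#' Emits `audiograms.csv` (long form), `genotypes.vcf` (VCF v4.2 with the
#' merged GT plus per-caller fields GT_GATK/GT_BCF/GT_FB all agreeing, and
#' INFO TRANCHE=tranche1;BCF_PASS;FB_PASS so the QC pipeline accepts every
#' site), `annotations.tsv`, `gene_list_planted.txt` (planted load genes,
#' possibly empty), and `truth.json`. Round-trips losslessly through
#' [readAudiograms()], [readGenotypes()] and [readCallerRecords()].
#'
#' @param sim output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeFixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(audiograms = file.path(dir, "audiograms.csv"),
             genotypes = file.path(dir, "genotypes.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             gene_list = file.path(dir, "gene_list_planted.txt"),
             truth = file.path(dir, "truth.json"))
  writeAudiograms(sim$audiograms, paths["audiograms"])
  writeCallerVcf(sim$genotypes, paths["genotypes"])
  vi <- variantInfo(sim$genotypes)
  utils::write.table(
    vi[, c("variant_id", "gene_id", "impact_class", "ref_maf")],
    paths["annotations"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("# planted load genes",
               if (is.null(sim$truth$load_genes)) character()
               else sim$truth$load_genes$gene_id),
             paths["gene_list"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
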