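#' Configuration for the carrier threshold-difference scan
#'
#' The scan compares mean pure-tone thresholds of a variant's carriers
#' against non-carriers at every ear and stimulus frequency. A frequency
#' "passes" when the mean difference reaches `diff_min_dB` and the carrier
#' group's standard deviation stays under a frequency-dependent cap
#' (consistent threshold patterns only). Variants with at least
#' `min_pass_freqs_per_ear` passing frequencies in each ear go to a
#' sex-preserving permutation test; a variant is rejected when more than
#' `reject_count` of `n_perm` random regroupings reproduce the passing
#' pattern (at the defaults, 1000/20000 = nominal alpha 0.05).
#'
#' @param min_group minimum carriers per group for eligibility (default 5).
#' @param diff_min_dB minimum absolute mean threshold difference
#'   (default 20 dB).
#' @param sd_caps data.frame with columns `upper_kHz` and `cap_dB`, the
#'   half-open frequency bands (f <= upper) and their carrier-SD caps.
#'   Defaults: 15 dB up to 0.5 kHz, 20 dB to 2 kHz, 25 dB to 4 kHz,
#'   30 dB above 4 kHz.
#' @param min_pass_freqs_per_ear passing frequencies required per ear
#'   (default 2).
#' @param n_perm number of permutations (default 20000).
#' @param reject_count rejection threshold on similar permutations
#'   (default 1000).
#' @param seed RNG seed used by [scanCohort()].
#' @param similar_mode "pass_set" (a permuted replicate is similar when
#'   every observed passing (ear, frequency) passes again; default) or
#'   "min_per_ear" (similar when at least `min_pass_freqs_per_ear`
#'   observed passing frequencies per ear pass).
#' @param direction_in_permutation if `TRUE`, a permuted replicate must
#'   also reproduce the observed direction of difference; by default only
#'   magnitude and SD criteria are applied.
#' @return a `scanConfig` list.
#' @export
scanConfig <- function(min_group = 5, diff_min_dB = 20,
                       sd_caps = data.frame(
                         upper_kHz = c(0.5, 2, 4, Inf),
                         cap_dB = c(15, 20, 25, 30)),
                       min_pass_freqs_per_ear = 2,
                       n_perm = 20000, reject_count = 1000, seed = 1,
                       similar_mode = c("pass_set", "min_per_ear"),
                       direction_in_permutation = FALSE) {
  stopifnot(min_group > 0, diff_min_dB > 0, all(sd_caps$cap_dB > 0),
            min_pass_freqs_per_ear > 0, n_perm > 0,
            reject_count > 0, reject_count <= n_perm)
  list(min_group = min_group, diff_min_dB = diff_min_dB, sd_caps = sd_caps,
       min_pass_freqs_per_ear = min_pass_freqs_per_ear, n_perm = n_perm,
       reject_count = reject_count, seed = seed,
       similar_mode = match.arg(similar_mode),
       direction_in_permutation = direction_in_permutation)
}

#' @rdname scanConfig
#' @param frequency_kHz stimulus frequency (vector ok).
#' @param config a `scanConfig` list.
#' @return `sdCapFor`: the carrier-SD cap (dB) for each frequency.
#' @export
sdCapFor <- function(frequency_kHz, config = scanConfig()) {
  caps <- config$sd_caps
  vapply(frequency_kHz,
         function(f) caps$cap_dB[which(f <= caps$upper_kHz)[1]], numeric(1))
}

#' Carrier/reference groupings for one variant
#'
#' Builds the "all", "male" and "female" groupings: carriers are
#' participants with at least one alternate allele (genotype 1 or 2),
#' the reference group is homozygous-reference participants of the same
#' stratum; missing genotypes are excluded from both. Groupings with no
#' carriers are omitted.
#'
#' @param geno named integer vector of genotype codes (0/1/2/NA), names =
#'   participant ids.
#' @param sex named character vector ("male"/"female") over the same ids.
#' @return named list of groupings, each a list with `stratum`,
#'   `carriers`, `reference`.
#' @export
buildGroupings <- function(geno, sex) {
  ids <- names(geno)
  stopifnot(!is.null(ids), all(ids %in% names(sex)))
  sex <- sex[ids]
  out <- list()
  for (str in c("all", "male", "female")) {
    in_str <- if (str == "all") rep(TRUE, length(ids)) else sex == str
    carriers <- ids[in_str & !is.na(geno) & geno > 0]
    reference <- ids[in_str & !is.na(geno) & geno == 0]
    if (length(carriers))
      out[[str]] <- list(stratum = str, carriers = carriers,
                         reference = reference)
  }
  out
}

#' Test one (ear, frequency) for a carrier threshold difference
#'
#' @param carrier_dB,reference_dB threshold values (dB HL) of carriers and
#'   of the reference group at one stimulus frequency in one ear; `NA`s
#'   are dropped.
#' @param frequency_kHz the stimulus frequency (selects the SD cap).
#' @param config a [scanConfig()].
#' @return list with `mean_diff_dB` (carrier mean minus reference mean),
#'   `carrier_sd_dB`, `passed`, `direction` ("worse" = carriers higher,
#'   "better" = carriers lower) and `evaluable` (FALSE when fewer than 2
#'   carriers or no reference values carry data).
#' @export
frequencyPass <- function(carrier_dB, reference_dB, frequency_kHz,
                          config = scanConfig()) {
  cv <- carrier_dB[!is.na(carrier_dB)]
  rv <- reference_dB[!is.na(reference_dB)]
  if (length(cv) < 2 || length(rv) < 1)
    return(list(mean_diff_dB = NA_real_, carrier_sd_dB = NA_real_,
                passed = FALSE, direction = NA_character_,
                evaluable = FALSE))
  md <- mean(cv) - mean(rv)
  s <- stats::sd(cv)
  cap <- sdCapFor(frequency_kHz, config)
  list(mean_diff_dB = md, carrier_sd_dB = s,
       passed = abs(md) >= config$diff_min_dB && s <= cap,
       direction = if (md > 0) "worse" else "better",
       evaluable = TRUE)
}

# Evaluate every (ear, frequency) for one grouping at once. left/right are
# participants x frequencies matrices; returns a data.frame.
evaluateGrouping <- function(grouping, left, right, freqs, config) {
  caps <- sdCapFor(freqs, config)
  one_ear <- function(ear, m) {
    C <- m[grouping$carriers, , drop = FALSE]
    R <- m[grouping$reference, , drop = FALSE]
    nc <- colSums(!is.na(C)); nr <- colSums(!is.na(R))
    cm <- colMeans(C, na.rm = TRUE)
    csd <- apply(C, 2, stats::sd, na.rm = TRUE)
    md <- cm - colMeans(R, na.rm = TRUE)
    evaluable <- nc >= 2 & nr >= 1
    md[!evaluable] <- NA_real_; csd[!evaluable] <- NA_real_
    data.frame(ear = ear, frequency_kHz = freqs,
               mean_diff_dB = unname(md), carrier_sd_dB = unname(csd),
               passed = evaluable & !is.na(md) &
                 abs(md) >= config$diff_min_dB & csd <= caps,
               direction = ifelse(is.na(md), NA_character_,
                                  ifelse(md > 0, "worse", "better")),
               row.names = NULL)
  }
  rbind(one_ear("left", left), one_ear("right", right))
}

# Precompute the per-cohort pieces the scan needs.
scanContext <- function(audiograms) {
  pin <- participantInfo(audiograms)
  sex <- stats::setNames(pin$sex, pin$participant_id)
  list(left = earMatrix(audiograms, "left"),
       right = earMatrix(audiograms, "right"),
       freqs = frequencies(audiograms),
       sex = sex[!duplicated(names(sex))])
}

#' Pre-permutation filter for one variant
#'
#' Builds the genotype/sex groupings, drops groupings with fewer than
#' `min_group` carriers, and emits a permutation candidate for each
#' eligible grouping with at least `min_pass_freqs_per_ear` passing
#' frequencies in each ear, all sharing one direction of difference.
#'
#' @param geno named genotype vector for one variant (0/1/2/NA).
#' @param audiograms an [AudiogramSet-class].
#' @param config a [scanConfig()].
#' @param variant_id identifier carried into the results.
#' @return list of candidate lists (possibly empty), each with
#'   `variant_id`, `stratum`, `carriers`, `reference`, `direction`,
#'   `pass_set` (data.frame: ear, frequency_kHz) and the full
#'   per-frequency evaluation in `records`.
#' @export
variantFilter <- function(geno, audiograms, config = scanConfig(),
                          variant_id = "variant") {
  variantFilterCore(geno, scanContext(audiograms), config, variant_id)
}

variantFilterCore <- function(geno, ctx, config, variant_id) {
  groupings <- buildGroupings(geno, ctx$sex)
  out <- list()
  for (g in groupings) {
    if (length(g$carriers) < config$min_group) next
    rec <- evaluateGrouping(g, ctx$left, ctx$right, ctx$freqs, config)
    pass <- rec[rec$passed, , drop = FALSE]
    nL <- sum(pass$ear == "left"); nR <- sum(pass$ear == "right")
    if (nL < config$min_pass_freqs_per_ear ||
        nR < config$min_pass_freqs_per_ear) next
    if (length(unique(pass$direction)) != 1) next
    out[[length(out) + 1]] <- list(
      variant_id = variant_id, stratum = g$stratum,
      carriers = g$carriers, reference = g$reference,
      direction = pass$direction[1],
      pass_set = pass[, c("ear", "frequency_kHz")], records = rec)
  }
  out
}

#' Permutation test for one scan candidate
#'
#' Reassigns participants at random to pseudo-carrier and pseudo-reference
#' groups of the same size and sex composition as the observed groups,
#' drawing without replacement from carriers and reference combined
#' (within sex, so the carrier group's sex mix is preserved even in the
#' "all" stratum). A replicate is "similar" when the observed passing
#' (ear, frequency) set passes the magnitude and SD criteria again under
#' the permuted labelling (direction is not required unless configured).
#' The empirical p-value is `similar_count / n_perm`; the candidate is
#' rejected when `similar_count > reject_count`.
#'
#' Uses the current RNG state; [scanCohort()] seeds it from the config.
#'
#' @param candidate a candidate from [variantFilter()].
#' @param audiograms the [AudiogramSet-class] used to build the candidate.
#' @param config a [scanConfig()].
#' @return the candidate with `similar_count`, `p` and `retained` added.
#' @export
permutationTest <- function(candidate, audiograms, config = scanConfig()) {
  permutationTestCore(candidate, scanContext(audiograms), config)
}

permutationTestCore <- function(candidate, ctx, config) {
  left <- ctx$left; right <- ctx$right; freqs <- ctx$freqs; sex <- ctx$sex
  pool <- c(candidate$carriers, candidate$reference)
  k <- length(candidate$carriers)
  stopifnot(k >= 1, length(pool) > k)
  pool_by_sex <- split(seq_along(pool), sex[pool])
  k_by_sex <- table(factor(sex[candidate$carriers],
                           levels = names(pool_by_sex)))
  n_perm <- config$n_perm

  # permuted carrier index matrix (n_perm x k), positions into `pool`
  idx <- matrix(0L, n_perm, k)
  for (r in seq_len(n_perm)) {
    picks <- unlist(lapply(names(pool_by_sex), function(sx) {
      ks <- k_by_sex[[sx]]
      if (ks == 0) integer() else {
        px <- pool_by_sex[[sx]]
        px[sample.int(length(px), ks)]
      }
    }), use.names = FALSE)
    idx[r, ] <- picks
  }

  ps <- candidate$pass_set
  pass_mat <- matrix(FALSE, n_perm, nrow(ps))
  for (j in seq_len(nrow(ps))) {
    m <- if (ps$ear[j] == "left") left else right
    v <- m[pool, match(ps$frequency_kHz[j], freqs)]
    tot_s <- sum(v, na.rm = TRUE); tot_n <- sum(!is.na(v))
    V <- matrix(v[idx], n_perm, k)
    nc <- rowSums(!is.na(V))
    cs <- rowSums(V, na.rm = TRUE)
    cm <- cs / nc
    ss <- rowSums(V^2, na.rm = TRUE)
    csd <- sqrt(pmax(ss - nc * cm^2, 0) / pmax(nc - 1, 1))
    nr <- tot_n - nc
    rm_ <- (tot_s - cs) / nr
    diff <- cm - rm_
    ok <- nc >= 2 & nr >= 1 & abs(diff) >= config$diff_min_dB &
      csd <= sdCapFor(ps$frequency_kHz[j], config)
    if (config$direction_in_permutation) {
      want <- if (candidate$direction == "worse") diff > 0 else diff < 0
      ok <- ok & want
    }
    pass_mat[, j] <- ok
  }
  similar <- if (config$similar_mode == "pass_set") {
    rowSums(pass_mat) == ncol(pass_mat)
  } else {
    okL <- rowSums(pass_mat[, ps$ear == "left", drop = FALSE]) >=
      config$min_pass_freqs_per_ear
    okR <- rowSums(pass_mat[, ps$ear == "right", drop = FALSE]) >=
      config$min_pass_freqs_per_ear
    okL & okR
  }
  candidate$similar_count <- sum(similar)
  candidate$p <- empiricalPValue(candidate$similar_count, n_perm)
  candidate$retained <- candidate$similar_count <= config$reject_count
  candidate
}

#' Empirical permutation p-value
#'
#' The convention used throughout the scan: the fraction of permuted
#' replicates reproducing the observed pattern, `similar_count / n_perm`.
#'
#' @param similar_count number of similar permutations.
#' @param n_perm number of permutations (default 20000).
#' @return p-value in \[0, 1\].
#' @examples
#' empiricalPValue(38)   # 1.9e-3
#' empiricalPValue(152)  # 7.6e-3
#' @export
empiricalPValue <- function(similar_count, n_perm = 20000) {
  stopifnot(all(similar_count >= 0), all(similar_count <= n_perm))
  similar_count / n_perm
}

#' Benjamini-Hochberg adjustment over retained scan results
#'
#' Applied only to variants retained by the permutation rejection rule,
#' with m = number retained.
#'
#' @param p p-values of retained results.
#' @return adjusted p-values (monotone step-up).
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, "BH")
}

#' Scan a cohort for per-variant carrier threshold differences
#'
#' Runs [variantFilter()] and [permutationTest()] over every variant in a
#' genotype matrix, rejects candidates reproduced by chance too often, and
#' BH-adjusts the retained empirical p-values. Deterministic given
#' `config$seed`.
#'
#' @param gset a [GenotypeSet-class].
#' @param audiograms an [AudiogramSet-class] covering the same
#'   participants.
#' @param config a [scanConfig()].
#' @return data.frame with one row per retained (variant, stratum):
#'   variant_id, stratum, n_carriers_m, n_carriers_f, direction,
#'   pass_freqs_L, pass_freqs_R, similar_count, p, p_adj; sorted by p_adj
#'   then variant id. The number of candidates tested is in
#'   `attr(, "n_candidates")`.
#' @export
scanCohort <- function(gset, audiograms, config = scanConfig()) {
  stopifnot(is(gset, "GenotypeSet"), is(audiograms, "AudiogramSet"))
  geno <- genotypeCalls(gset)
  ctx <- scanContext(audiograms)
  common <- intersect(colnames(geno), names(ctx$sex))
  geno <- geno[, common, drop = FALSE]
  set.seed(config$seed)
  results <- list()
  n_candidates <- 0L
  for (i in seq_len(nrow(geno))) {
    cands <- variantFilterCore(geno[i, ], ctx, config,
                               variant_id = rownames(geno)[i])
    for (cand in cands) {
      n_candidates <- n_candidates + 1L
      res <- permutationTestCore(cand, ctx, config)
      if (!res$retained) next
      csex <- ctx$sex[res$carriers]
      results[[length(results) + 1]] <- data.frame(
        variant_id = res$variant_id, stratum = res$stratum,
        n_carriers_m = sum(csex == "male"),
        n_carriers_f = sum(csex == "female"),
        direction = res$direction,
        pass_freqs_L = paste(res$pass_set$frequency_kHz[
          res$pass_set$ear == "left"], collapse = ","),
        pass_freqs_R = paste(res$pass_set$frequency_kHz[
          res$pass_set$ear == "right"], collapse = ","),
        similar_count = res$similar_count, p = res$p)
    }
  }
  out <- if (length(results)) do.call(rbind, results)
         else data.frame(variant_id = character(), stratum = character(),
                         n_carriers_m = integer(), n_carriers_f = integer(),
                         direction = character(), pass_freqs_L = character(),
                         pass_freqs_R = character(),
                         similar_count = integer(), p = numeric())
  out$p_adj <- if (nrow(out)) bhAdjust(out$p) else numeric(0)
  out <- out[order(out$p_adj, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- n_candidates
  out
}
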