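# In-code fixtures shared across test files.

stdFreqs <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8)

# Minimal AudiogramSet: thresholds is a list of per-recording vectors
# (length 8), info rows aligned.
makeAudioSet <- function(thr_list, ids, ears, sexes, freqs = stdFreqs) {
  m <- do.call(cbind, thr_list)
  AudiogramSet(m, freqs,
               data.frame(participant_id = ids, ear = ears, sex = sexes))
}

makeFit <- function(m, s, e) list(metabolic = m, sensory = s, fit_error = e)

# Caller-records fixture for the QC pipeline: 10 variants, 50 participants,
# exactly 2 variants designed to fail at each successive stage.
qcFixtureRecords <- function() {
  n <- 50
  pid <- sprintf("S%02d", seq_len(n))
  mk <- function(fill) matrix(fill, nrow = 10, ncol = n,
                              dimnames = list(NULL, pid))
  gatk <- mk(0L); bcf <- mk(0L); fb <- mk(0L)
  # default: a few agreeing het calls so sites are genotyped and in HWE
  het_cols <- 1:8
  gatk[, het_cols] <- 1L; bcf[, het_cols] <- 1L; fb[, het_cols] <- 1L
  # v1, v2 fail the quality gate (tranche2 + only freebayes / lower tranche)
  tranche <- rep("tranche1", 10)
  bcf_pass <- rep(TRUE, 10); fb_pass <- rep(TRUE, 10)
  tranche[1] <- "tranche2"; bcf_pass[1] <- FALSE; fb_pass[1] <- TRUE
  tranche[2] <- "lower"
  # v3, v4 merge to all-missing: 1-vs-1 splits and single-caller calls
  gatk[3, ] <- 0L; bcf[3, ] <- 1L; fb[3, ] <- NA_integer_
  gatk[4, ] <- NA_integer_; bcf[4, ] <- NA_integer_; fb[4, ] <- 1L
  # v5, v6 are all-heterozygote sites (extreme excess heterozygosity)
  for (v in 5:6) { gatk[v, ] <- 1L; bcf[v, ] <- 1L; fb[v, ] <- 1L }
  # v7, v8 have cohort AF far above ref MAF + 0.4 (all hom alt);
  # v9, v10 survive every stage (high impact, rare)
  for (v in 7:8) { gatk[v, ] <- 2L; bcf[v, ] <- 2L; fb[v, ] <- 2L }
  sites <- data.frame(
    variant_id = sprintf("1:%d:A:G", 1000 + 1:10 * 10),
    chrom = "1", pos = 1000 + 1:10 * 10,
    tranche = tranche, bcftools_pass = bcf_pass, freebayes_pass = fb_pass)
  ann <- data.frame(
    variant_id = sites$variant_id,
    gene_id = sprintf("G%02d", 1:10),
    impact_class = "high",
    ref_maf = 0.01)
  list(records = list(sites = sites,
                      genotypes = list(gatk = gatk, bcf = bcf, fb = fb),
                      mito = NULL,
                      participants = data.frame(participant_id = pid,
                                                sex = "female")),
       annotations = ann)
}
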