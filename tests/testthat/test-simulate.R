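test_that("generation is deterministic under a fixed seed", {
  p <- simParams(n_participants = 40, n_genes = 10, seed = 99)
  s1 <- simulateCohort(p)
  s2 <- simulateCohort(p)
  expect_identical(thresholds(s1$audiograms), thresholds(s2$audiograms))
  expect_identical(genotypeCalls(s1$genotypes), genotypeCalls(s2$genotypes))
  expect_identical(s1$truth, s2$truth)
})

test_that("noise-free audiograms close the loop with the classifier", {
  p <- simParams(n_participants = 30, noise_sd_dB = 0, seed = 4)
  sim <- generateCohort(p)
  thr <- thresholds(sim$audiograms)
  cd <- as.data.frame(SummarizedExperiment::colData(sim$audiograms))
  # both ears identical without noise
  for (id in sim$truth$participant_id[1:5]) {
    cols <- which(cd$participant_id == id)
    expect_equal(thr[, cols[1]], thr[, cols[2]])
  }
  cls <- classifyCohort(sim$audiograms)
  m <- merge(cls$labels, sim$truth, by = "participant_id")
  expect_equal(m$label, m$class)
})

test_that("baseline genotypes respect Hardy-Weinberg carrier expectations", {
  p <- simParams(n_participants = 1000, n_genes = 40,
                 maf_range = c(0.05, 0.0500001), seed = 21)
  sim <- simulateCohort(p)
  cf <- rowMeans(genotypeCalls(sim$genotypes) > 0)
  expected <- 2 * 0.05 * 0.95 + 0.05^2
  se <- sqrt(expected * (1 - expected) / 1000)
  # each variant within 4 binomial SDs; the mean within 1
  expect_true(all(abs(cf - expected) < 4 * se))
  expect_lt(abs(mean(cf) - expected), se)
})

test_that("planted load genes raise carrier rates only in the target class", {
  p <- simParams(n_participants = 800, n_genes = 20, seed = 31,
                 maf_range = c(0.02, 0.04),
                 planted_load_genes = data.frame(gene = 3, class = "Sensory",
                                                 multiplier = 6))
  sim <- simulateCohort(p)
  vi <- variantInfo(sim$genotypes)
  geno <- genotypeCalls(sim$genotypes)
  sens <- sim$truth$participants$participant_id[
    sim$truth$participants$class == "Sensory"]
  other <- setdiff(colnames(geno), sens)
  planted_rows <- vi$gene_id == "G0003"
  rate_t <- mean(geno[planted_rows, sens] > 0)
  rate_o <- mean(geno[planted_rows, other] > 0)
  expect_gt(rate_t / rate_o, 3)  # multiplier 6, sampling noise allowed
  # multiplier 1 is a null: rates comparable across classes
  p1 <- simParams(n_participants = 800, n_genes = 20, seed = 31,
                  maf_range = c(0.02, 0.04),
                  planted_load_genes = data.frame(gene = 3, class = "Sensory",
                                                  multiplier = 1))
  sim1 <- simulateCohort(p1)
  g1 <- genotypeCalls(sim1$genotypes)
  r_t <- mean(g1[planted_rows, sens] > 0); r_o <- mean(g1[planted_rows, other] > 0)
  expect_lt(abs(r_t - r_o), 0.05)
})

test_that("planted effect variants shift exactly their carriers' thresholds", {
  p0 <- simParams(n_participants = 60, n_genes = 5, seed = 8)
  cohort <- generateCohort(p0)
  pre <- thresholds(cohort$audiograms)
  p <- p0
  p$planted_effect_variants <- data.frame(shift_dB = 30, freqs = "3,4,6,8",
                                          sex = "any", n_carriers = 8)
  g <- generateGenotypes(p, cohort)
  post <- thresholds(g$audiograms)
  eff <- g$truth$effect_variants[[1]]
  cd <- as.data.frame(SummarizedExperiment::colData(g$audiograms))
  freqs <- frequencies(g$audiograms)
  fidx <- match(eff$freqs_kHz, freqs)
  carrier_cols <- cd$participant_id %in% eff$carriers
  delta <- post - pre
  expect_true(all(abs(delta[fidx, carrier_cols] - 30) < 1e-9 |
                    post[fidx, carrier_cols] == 120))  # clipping allowed
  expect_true(all(delta[-fidx, ] == 0))
  expect_true(all(delta[, !carrier_cols] == 0))
  # genotype matrix marks exactly those carriers
  geno <- genotypeCalls(g$genotypes)[eff$variant_id, ]
  expect_setequal(names(geno)[geno > 0], eff$carriers)
  # sex-restricted planting draws only from that sex
  p$planted_effect_variants$sex <- "female"
  g2 <- generateGenotypes(p, cohort)
  eff2 <- g2$truth$effect_variants[[1]]
  sex_of <- setNames(cohort$truth$sex, cohort$truth$participant_id)
  expect_true(all(sex_of[eff2$carriers] == "female"))
  # impossible requests fail loudly
  p$planted_effect_variants$n_carriers <- 1000
  expect_error(generateGenotypes(p, cohort), "exceed")
})

test_that("fixtures round-trip losslessly through the readers", {
  p <- simParams(n_participants = 25, n_genes = 8, seed = 12,
                 planted_load_genes = data.frame(gene = 2, class = "Metabolic",
                                                 multiplier = 4))
  sim <- simulateCohort(p)
  d <- withr::local_tempdir()
  paths <- writeFixture(sim, d)
  expect_true(all(file.exists(paths)))

  a2 <- readAudiograms(paths["audiograms"])
  expect_equal(unname(thresholds(a2)), unname(thresholds(sim$audiograms)),
               tolerance = 1e-10)
  expect_equal(frequencies(a2), frequencies(sim$audiograms))

  rec <- readCallerRecords(paths["genotypes"])
  ann <- readAnnotations(paths["annotations"])
  qc <- applyQcPipeline(rec, ann)
  g0 <- genotypeCalls(sim$genotypes)
  g1 <- genotypeCalls(qc$genotypes)
  expect_setequal(rownames(g1), rownames(g0))
  expect_true(all(g1[rownames(g0), colnames(g0)] == g0, na.rm = TRUE))

  # merged-GT reader agrees too
  gset <- readGenotypes(paths["genotypes"], annotations = ann)
  expect_true(all(genotypeCalls(gset)[rownames(g0), colnames(g0)] == g0,
                  na.rm = TRUE))

  # VCF is structurally valid: parses, and positions sort within contigs
  v <- vcfR::read.vcfR(paths["genotypes"], verbose = FALSE)
  fix <- vcfR::getFIX(v)
  by_chrom <- split(as.integer(fix[, "POS"]), fix[, "CHROM"])
  expect_true(all(vapply(by_chrom, function(x) all(diff(x) > 0), logical(1))))

  # truth JSON references only emitted ids
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_true(all(truth$load_genes$gene_id %in%
                    variantInfo(sim$genotypes)$gene_id))
  expect_true(all(readGeneList(paths["gene_list"]) %in%
                    variantInfo(sim$genotypes)$gene_id))
})
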