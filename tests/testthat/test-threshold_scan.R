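test_that("groupings split carriers by sex with matched references", {
  ids <- sprintf("P%02d", 1:20)
  sex <- setNames(rep(c("male", "female"), 10), ids)
  geno <- setNames(rep(0L, 20), ids)
  geno[c(1, 3, 5)] <- 1L           # male carriers
  geno[c(2, 4, 6, 8)] <- c(1L, 1L, 2L, 1L)  # female carriers
  g <- buildGroupings(geno, sex)
  expect_named(g, c("all", "male", "female"))
  expect_length(g$all$carriers, 7)
  expect_length(g$male$carriers, 3)
  expect_length(g$female$carriers, 4)
  expect_true(all(sex[g$male$reference] == "male"))
  expect_length(intersect(g$all$carriers, g$all$reference), 0)

  # missing genotypes excluded from both sides
  geno[10] <- NA
  g <- buildGroupings(geno, sex)
  expect_false("P10" %in% c(g$all$carriers, g$all$reference))

  # no female carriers -> no female grouping
  geno[c(2, 4, 6, 8)] <- 0L
  g <- buildGroupings(geno, sex)
  expect_named(g, c("all", "male"))

  # all missing -> no groupings
  expect_length(buildGroupings(setNames(rep(NA_integer_, 20), ids), sex), 0)
})

test_that("frequency criterion combines mean difference and SD cap", {
  cfg <- scanConfig()
  fp <- frequencyPass(c(65, 70, 75), rep(40, 20), 4, cfg)
  expect_true(fp$passed)
  expect_equal(fp$direction, "worse")
  expect_equal(fp$mean_diff_dB, 30)
  # same difference at 0.25 kHz but carrier SD 16 exceeds the 15 dB cap
  spread <- c(70 - 16, 70, 70 + 16) * sqrt(1)  # sd ~ 16
  spread <- 70 + c(-1, 0, 1) * 16
  expect_false(frequencyPass(spread, rep(40, 20), 0.25, cfg)$passed)
  expect_true(frequencyPass(spread, rep(40, 20), 4, cfg)$passed)
  # protective direction
  fp <- frequencyPass(c(20, 22, 24), rep(45, 20), 8, cfg)
  expect_true(fp$passed)
  expect_equal(fp$direction, "better")
  # sub-threshold difference
  expect_false(frequencyPass(c(50, 52, 54), rep(40, 20), 4, cfg)$passed)
  # unevaluable with a single carrier datum
  expect_false(frequencyPass(c(65, NA, NA), rep(40, 5), 4, cfg)$evaluable)
})

test_that("SD caps map each frequency to exactly one band", {
  expect_equal(sdCapFor(c(0.125, 0.25, 0.5, 1, 2, 3, 4, 6, 8)),
               c(15, 15, 15, 20, 20, 25, 25, 30, 30))
})

test_that("variant filter enforces group size, per-ear passes and direction", {
  set.seed(31)
  n <- 60
  ids <- sprintf("P%02d", 1:n)
  sexes <- rep(c("male", "female"), n / 2)
  base <- lapply(1:(2 * n), function(i) rnorm(8, 20, 3))
  info_ids <- rep(ids, each = 2)
  aset <- makeAudioSet(base, info_ids, rep(c("left", "right"), n),
                       rep(sexes, each = 2))
  cfg <- scanConfig(n_perm = 100, reject_count = 5)

  # 4 male + 3 female carriers: only the pooled grouping is eligible
  geno <- setNames(rep(0L, n), ids)
  geno[c(1, 3, 5, 7)] <- 1L   # males (odd indices are male)
  geno[c(2, 4, 6)] <- 1L
  cands <- variantFilter(geno, aset, cfg, "v_elig")
  expect_true(all(vapply(cands, function(c) c$stratum, "") == "all"))

  # carriers shifted +30 dB at high frequencies in both ears -> candidate
  thr <- thresholds(aset)
  carrier_cols <- which(info_ids %in% ids[c(1:7)])
  thr[5:8, carrier_cols] <- thr[5:8, carrier_cols] + 30
  aset2 <- AudiogramSet(thr, stdFreqs,
                        data.frame(participant_id = info_ids,
                                   ear = rep(c("left", "right"), n),
                                   sex = rep(sexes, each = 2)))
  cands <- variantFilter(geno, aset2, cfg, "v_eff")
  expect_gte(length(cands), 1)
  expect_equal(cands[[1]]$direction, "worse")
  expect_gte(sum(cands[[1]]$pass_set$ear == "left"), 2)
  expect_gte(sum(cands[[1]]$pass_set$ear == "right"), 2)

  # shift in one ear only -> fails the >= 2 passes per ear rule
  thr1 <- thresholds(aset)
  left_carrier <- intersect(carrier_cols,
                            which(rep(c("left", "right"), n) == "left"))
  thr1[5:8, left_carrier] <- thr1[5:8, left_carrier] + 30
  aset3 <- AudiogramSet(thr1, stdFreqs,
                        data.frame(participant_id = info_ids,
                                   ear = rep(c("left", "right"), n),
                                   sex = rep(sexes, each = 2)))
  expect_length(variantFilter(geno, aset3, cfg, "v_oneear"), 0)

  # fewer than min_group carriers everywhere -> excluded
  geno2 <- setNames(rep(0L, n), ids)
  geno2[1:4] <- 1L
  expect_length(variantFilter(geno2, aset2, cfg, "v_small"), 0)
})

test_that("permutation p-values are deterministic and use count/n_perm", {
  expect_equal(empiricalPValue(38), 1.90e-3)
  expect_equal(empiricalPValue(152), 7.60e-3)
  expect_equal(empiricalPValue(0), 0)

  p <- simParams(n_participants = 120, n_genes = 10, seed = 41,
                 planted_effect_variants = data.frame(
                   shift_dB = 30, freqs = "3,4,6,8", sex = "any",
                   n_carriers = 8))
  sim <- simulateCohort(p)
  cfg <- scanConfig(n_perm = 500, reject_count = 25, seed = 17)
  r1 <- scanCohort(sim$genotypes, sim$audiograms, cfg)
  r2 <- scanCohort(sim$genotypes, sim$audiograms, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$p == r1$similar_count / 500))
  vid <- sim$truth$effect_variants[[1]]$variant_id
  expect_true(vid %in% r1$variant_id)
})

test_that("retention is monotone in planted effect size", {
  cfg <- scanConfig(n_perm = 400, reject_count = 20, seed = 9)
  shifts <- c(22, 35)
  sims <- lapply(shifts, function(sh)
    simulateCohort(simParams(n_participants = 150, n_genes = 5, seed = 77,
                             planted_effect_variants = data.frame(
                               shift_dB = sh, freqs = "3,4,6,8",
                               sex = "any", n_carriers = 8))))
  counts <- vapply(sims, function(s) {
    res <- scanCohort(s$genotypes, s$audiograms, cfg)
    vid <- s$truth$effect_variants[[1]]$variant_id
    sum(res$variant_id == vid)
  }, numeric(1))
  expect_true(counts[2] >= counts[1])
  expect_gte(counts[2], 1)   # a 35 dB shift in 8 carriers is detected
})

test_that("empty variant sets produce an empty, well-formed report", {
  sim <- simulateCohort(simParams(n_participants = 30, n_genes = 2, seed = 2))
  empty <- sim$genotypes[integer(0), ]
  res <- scanCohort(new("GenotypeSet", empty), sim$audiograms,
                    scanConfig(n_perm = 50, reject_count = 5))
  expect_equal(nrow(res), 0)
  expect_true(all(c("variant_id", "stratum", "similar_count", "p", "p_adj")
                  %in% names(res)))
})
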