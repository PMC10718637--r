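test_that("per-gene counts follow the dosage and carrier definitions", {
  g <- GenotypeSet(matrix(c(1L, 2L, 0L), 1, 3),
                   data.frame(variant_id = "v1", gene_id = "G1"),
                   data.frame(participant_id = c("a", "b", "c"),
                              sex = "female"))
  expect_equal(unname(countVariantsPerGene(g, list(grp = c("a", "b", "c")))[1, 1]), 3L)
  expect_equal(unname(countVariantsPerGene(g, list(grp = c("a", "b", "c")),
                                           mode = "carrier")[1, 1]), 2L)
  # empty group gives an all-zero column
  cnt <- countVariantsPerGene(g, list(grp = character()))
  expect_equal(unname(cnt[, 1]), 0L)
  # hand-computed multi-gene fixture with missing genotypes
  geno <- matrix(c(1L, NA, 2L,
                   0L, 1L, 1L,
                   2L, 2L, NA), 3, 3, byrow = TRUE)
  g2 <- GenotypeSet(geno,
                    data.frame(variant_id = c("v1", "v2", "v3"),
                               gene_id = c("GA", "GA", "GB")),
                    data.frame(participant_id = c("a", "b", "c"),
                               sex = "male"))
  cnt <- countVariantsPerGene(g2, list(g1 = c("a", "b"), g2 = "c"))
  expect_equal(cnt["GA", "g1"], 1L + 0L + 1L)  # v1:a=1, v2:a=0,b=1
  expect_equal(cnt["GA", "g2"], 2L + 1L)
  expect_equal(cnt["GB", "g1"], 4L)
  expect_equal(cnt["GB", "g2"], 0L)
})

test_that("outlier regression matches an independent recomputation", {
  # perfect fit: no outliers despite zero IQR (strict inequalities)
  x <- c(1, 5, 9, 13, 20)
  rf <- regressAndFlag(x, 2 * x, gene_ids = letters[1:5])
  expect_equal(nrow(rf$outliers), 0)
  expect_equal(rf$slope, 2, tolerance = 1e-10)
  expect_equal(rf$iqr, 0, tolerance = 1e-10)

  # 200 genes on a noisy line with one inflated gene
  set.seed(19)
  x <- rpois(200, 30)
  y <- round(1.4 * x + rnorm(200, 0, 2))
  y[57] <- y[57] + 50
  rf <- regressAndFlag(x, y, gene_ids = sprintf("G%03d", 1:200))
  expect_equal(rf$outliers$gene_id, "G057")
  expect_equal(rf$outliers$direction, "high_in_y")
  oracle <- outlierOracle(x, y)
  expect_equal(which(sprintf("G%03d", 1:200) %in%
                       rf$outliers$gene_id[rf$outliers$direction == "high_in_y"]),
               oracle$high_in_y)
  expect_length(oracle$high_in_x, 0)

  # symmetry: swapping x and y swaps the direction labels
  y2 <- x; y2[57] <- y2[57] + 50
  fwd <- regressAndFlag(x, y2)
  rev <- regressAndFlag(y2, x)
  expect_equal(fwd$outliers$direction, "high_in_y")
  expect_equal(rev$outliers$direction, "high_in_x")

  # invariance to gene order and common scaling
  o <- sample(200)
  rf_perm <- regressAndFlag(x[o], y[o], gene_ids = sprintf("G%03d", 1:200)[o])
  expect_setequal(rf_perm$outliers$gene_id, rf$outliers$gene_id)
  rf_scaled <- regressAndFlag(3 * x, 3 * y, gene_ids = sprintf("G%03d", 1:200))
  expect_setequal(rf_scaled$outliers$gene_id, rf$outliers$gene_id)

  expect_error(regressAndFlag(c(1, 2), c(1, 2)), "insufficient")
  expect_error(regressAndFlag(rep(3, 10), rnorm(10)), "degenerate")
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  u <- sprintf("g%02d", 1:10)
  et <- enrichmentTest(u[1:5], u[1:4], u)
  expect_equal(et$overlap, 4)
  expect_equal(et$p, hyperOracle(5, 4, 10, 4), tolerance = 1e-12)
  # overlap 0 and list = universe edge cases
  expect_equal(enrichmentTest(u[5:10], u[1:4], u)$p, 1, tolerance = 1e-12)
  expect_equal(enrichmentTest(u, u[1:4], u)$p, 1, tolerance = 1e-12)
  # all universes up to size 12, random sets and lists
  set.seed(23)
  for (U in 2:12) {
    uni <- sprintf("x%02d", 1:U)
    for (rep in 1:3) {
      sset <- sample(uni, sample.int(U, 1))
      lst <- sample(uni, sample.int(U, 1))
      et <- enrichmentTest(lst, sset, uni)
      # oracle assumes the set is the first |set| elements; relabel
      relab <- c(sset, setdiff(uni, sset))
      lst_idx <- match(lst, relab)
      expect_equal(et$p,
                   hyperOracle(length(lst), length(sset), U, et$overlap),
                   tolerance = 1e-10)
    }
  }
  expect_error(enrichmentTest("a", "a", character()), "empty universe")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustPvalues(0.2), 0.2)
  expect_equal(adjustPvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjustPvalues(c(0, 0.001, 0.002)), c(0, 0.0015, 0.002))
  set.seed(29)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjustPvalues(p), bhOracle(p), tolerance = 1e-12)
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
  expect_equal(adjustPvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  expect_equal(adjustPvalues(c(0.01, 0.5), "none"), c(0.01, 0.5))
})

test_that("comparison plan flags planted load genes and skips small strata", {
  p <- simParams(n_participants = 250, n_genes = 40, seed = 13,
                 planted_load_genes = data.frame(gene = 7, class = "Sensory",
                                                 multiplier = 8))
  sim <- simulateCohort(p)
  cls <- classifyCohort(sim$audiograms)
  res <- suppressWarnings(
    runComparisons(cls$labels, sim$genotypes,
                   plan = data.frame(comparison = "ON_vs_Sensory",
                                     stratum = "all"),
                   gene_sets = list(planted = "G0007"),
                   min_group_size = 20))
  hi_sens <- res$outliers$gene_id[res$outliers$high_in == "Sensory"]
  expect_true("G0007" %in% hi_sens)

  # a 12-member stratum under a minimum of 20 is skipped with a warning
  small <- cls$labels
  keep_on <- which(small$label == "OlderNormal")
  small$label[keep_on[-(1:min(12, length(keep_on)))]] <- "Unclassified"
  expect_warning(
    res2 <- runComparisons(small, sim$genotypes,
                           plan = data.frame(comparison = "ON_vs_Metabolic",
                                             stratum = "all"),
                           min_group_size = 20),
    "below minimum size")
  expect_equal(res2$skipped, "ON_vs_Metabolic.all")

  # combined candidates deduplicate genes flagged by several comparisons
  res3 <- suppressWarnings(
    runComparisons(cls$labels, sim$genotypes,
                   plan = data.frame(
                     comparison = c("ON_vs_Sensory", "Metabolic_vs_Sensory"),
                     stratum = "all"),
                   min_group_size = 20))
  cand <- res3$candidates[res3$candidates$gene_id == "G0007", ]
  expect_equal(nrow(cand), 1)
  expect_true(grepl(";", cand$provenance))
})
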