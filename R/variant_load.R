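#' Per-gene variant load per participant group
#'
#' Sums qualifying variant alleles per gene within each participant group.
#' In the default "allele" mode a heterozygote contributes 1 and a
#' homozygote-alternate 2 (homoplasmic mitochondrial calls having been
#' coded homozygous); in "carrier" mode any non-reference genotype
#' contributes 1. Missing genotypes contribute 0.
#'
#' @param gset a [GenotypeSet-class]; `rowData` must carry `gene_id`.
#' @param groups named list of participant-id vectors (disjoint groups).
#' @param mode "allele" (dosage) or "carrier" (presence).
#' @return integer matrix, genes x groups; every gene with at least one
#'   variant in the matrix appears.
#' @examples
#' # one gene, three participants: het, hom_alt, hom_ref
#' g <- GenotypeSet(matrix(c(1L, 2L, 0L), 1, 3),
#'                  data.frame(variant_id = "v1", gene_id = "G1"),
#'                  data.frame(participant_id = c("a", "b", "c"),
#'                             sex = "female"))
#' countVariantsPerGene(g, list(grp = c("a", "b", "c")))           # 3
#' countVariantsPerGene(g, list(grp = c("a", "b", "c")), "carrier") # 2
#' @export
countVariantsPerGene <- function(gset, groups, mode = c("allele", "carrier")) {
  mode <- match.arg(mode)
  stopifnot(is(gset, "GenotypeSet"), length(groups) >= 1)
  gene <- rowData(gset)$gene_id
  if (is.null(gene)) stop("GenotypeSet lacks gene_id annotation")
  known <- !is.na(gene) & gene != ""
  if (any(!known))
    warning(sum(!known), " variant(s) without a gene assignment excluded")
  geno <- genotypeCalls(gset)[known, , drop = FALSE]
  gene <- gene[known]
  dose <- geno
  dose[is.na(dose)] <- 0L
  if (mode == "carrier") dose <- (dose > 0) + 0L
  genes <- sort(unique(gene))
  out <- sapply(groups, function(ids) {
    sel <- colnames(geno) %in% ids
    v <- rowSums(dose[, sel, drop = FALSE])
    as.integer(rowsum(v, gene)[genes, 1])
  })
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, names(groups)))
  out
}

#' Regress variant loads between groups and flag outlier genes
#'
#' Ordinary least-squares fit of one group's per-gene variant counts on
#' another's (`y ~ x`); the residuals measure how far each gene's load in
#' the second group departs from what the first group predicts. Genes with
#' residuals beyond `Q3 + multiplier*D` are flagged as high in y, and below
#' `Q1 - multiplier*D` as high in x, where Q1/Q3 are the residual quartiles
#' and D = Q3 - Q1 the interquartile distance. Quartiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param counts_x,counts_y aligned per-gene count vectors (named by gene,
#'   or supply `gene_ids`).
#' @param multiplier interquartile multiplier (default 6).
#' @param gene_ids gene identifiers; defaults to `names(counts_x)`.
#' @return list with `outliers` (data.frame: gene_id, observed_x,
#'   observed_y, residual, direction), `slope`, `intercept`, `q1`, `q3`,
#'   `iqr` and `residuals`.
#' @export
regressAndFlag <- function(counts_x, counts_y, multiplier = 6,
                           gene_ids = names(counts_x)) {
  stopifnot(length(counts_x) == length(counts_y), multiplier > 0)
  if (length(counts_x) < 3) stop("insufficient data: fewer than 3 genes")
  if (stats::var(counts_x) == 0) stop("degenerate regression: x is constant")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(counts_x))
  fit <- stats::lm(counts_y ~ counts_x)
  r <- unname(stats::resid(fit))
  q <- stats::quantile(r, c(0.25, 0.75), type = 7, names = FALSE)
  d <- q[2] - q[1]
  hi_y <- r > q[2] + multiplier * d
  hi_x <- r < q[1] - multiplier * d
  flagged <- hi_y | hi_x
  outliers <- data.frame(
    gene_id = gene_ids[flagged],
    observed_x = counts_x[flagged],
    observed_y = counts_y[flagged],
    residual = r[flagged],
    direction = ifelse(hi_y[flagged], "high_in_y", "high_in_x"),
    row.names = NULL)
  list(outliers = outliers,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       q1 = q[1], q3 = q[2], iqr = d, residuals = stats::setNames(r, gene_ids))
}

#' Hypergeometric gene-set enrichment test
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between an outlier gene list and a curated gene set, drawing the list
#' from the universe of assessed genes. The gene set is intersected with
#' the universe before testing.
#'
#' @param outlier_list character vector of genes (subset of `universe`).
#' @param gene_set character vector of genes in the curated set.
#' @param universe character vector: all genes assessed.
#' @return list with `universe_size`, `set_in_universe`, `list_size`,
#'   `overlap`, `p`.
#' @export
enrichmentTest <- function(outlier_list, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("undefined test: empty universe")
  outlier_list <- unique(outlier_list)
  if (!all(outlier_list %in% universe))
    stop("outlier list must be a subset of the universe")
  set_u <- intersect(unique(gene_set), universe)
  ov <- length(intersect(outlier_list, set_u))
  p <- stats::phyper(ov - 1, length(set_u),
                     length(universe) - length(set_u),
                     length(outlier_list), lower.tail = FALSE)
  list(universe_size = length(universe), set_in_universe = length(set_u),
       list_size = length(outlier_list), overlap = ov, p = p)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (default), Bonferroni, or none.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method "benjamini_hochberg", "bonferroni" or "none".
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(p, method = c("benjamini_hochberg", "bonferroni",
                                        "none")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  switch(method,
         benjamini_hochberg = stats::p.adjust(p, "BH"),
         bonferroni = stats::p.adjust(p, "bonferroni"),
         none = p)
}

#' Run a plan of between-group variant-load comparisons
#'
#' For each planned comparison (optionally sex-stratified), counts variant
#' load per gene in the predictor and response groups, runs
#' [regressAndFlag()], tests both outlier lists for enrichment in each
#' supplied gene set, and combines outlier genes across comparisons into a
#' deduplicated candidate list with per-comparison provenance. Strata in
#' which either group falls below `min_group_size` are skipped with a
#' warning (small groups do not support a stable regression).
#'
#' @param labels data.frame with `participant_id` and `label` (from
#'   [classifyCohort()]).
#' @param gset a [GenotypeSet-class] whose `colData` carries `sex`.
#' @param plan data.frame with columns `comparison` (one of
#'   "ON_vs_all", "ON_vs_Metabolic", "ON_vs_Sensory",
#'   "Metabolic_vs_Sensory") and `stratum` ("all", "male", "female").
#' @param gene_sets named list of character vectors (e.g. deafness genes,
#'   highly variable genes); may be empty.
#' @param min_group_size minimum participants per group (default 20).
#' @param multiplier interquartile multiplier (default 6).
#' @param mode counting mode, see [countVariantsPerGene()].
#' @param adjust method for [adjustPvalues()] across all enrichment tests.
#' @return list with `outliers` (data.frame across comparisons),
#'   `enrichment` (data.frame), `candidates` (deduplicated gene list with
#'   provenance), and `skipped` (character vector of skipped plan rows).
#' @export
runComparisons <- function(labels, gset, plan = defaultComparisonPlan(),
                           gene_sets = list(), min_group_size = 20,
                           multiplier = 6, mode = "allele",
                           adjust = "benjamini_hochberg") {
  comps <- list(
    ON_vs_all = list(x = "OlderNormal", y = setdiff(
      c("Metabolic", "Sensory", "Unclassified", "Unselected"), NULL)),
    ON_vs_Metabolic = list(x = "OlderNormal", y = "Metabolic"),
    ON_vs_Sensory = list(x = "OlderNormal", y = "Sensory"),
    Metabolic_vs_Sensory = list(x = "Metabolic", y = "Sensory"))
  bad <- setdiff(plan$comparison, names(comps))
  if (length(bad)) stop("unknown comparison(s): ", paste(bad, collapse = ", "))
  pinfo <- participantInfo(gset)
  sex_of <- stats::setNames(pinfo$sex, pinfo$participant_id)
  lab_of <- stats::setNames(labels$label, labels$participant_id)
  universe <- sort(unique(rowData(gset)$gene_id))
  universe <- universe[!is.na(universe) & universe != ""]

  out_rows <- list(); enr_rows <- list(); skipped <- character()
  for (i in seq_len(nrow(plan))) {
    cmp <- plan$comparison[i]; str <- plan$stratum[i]
    ids <- pinfo$participant_id
    if (str != "all") ids <- ids[sex_of[ids] == str]
    gx <- ids[lab_of[ids] %in% comps[[cmp]]$x]
    gy <- ids[lab_of[ids] %in% comps[[cmp]]$y]
    tag <- paste(cmp, str, sep = ".")
    if (length(gx) < min_group_size || length(gy) < min_group_size) {
      warning("skipping ", tag, ": group below minimum size (",
              length(gx), " vs ", length(gy), ")")
      skipped <- c(skipped, tag)
      next
    }
    cnt <- countVariantsPerGene(gset, list(x = gx, y = gy), mode = mode)
    rf <- regressAndFlag(cnt[, "x"], cnt[, "y"], multiplier,
                         gene_ids = rownames(cnt))
    if (nrow(rf$outliers)) {
      o <- rf$outliers
      o$comparison <- cmp; o$stratum <- str
      # direction in phenotype terms: y is the second-named group
      grp_names <- strsplit(sub("^ON", "OlderNormal", cmp), "_vs_")[[1]]
      o$high_in <- ifelse(o$direction == "high_in_y", grp_names[2], grp_names[1])
      out_rows[[tag]] <- o
    }
    for (set_name in names(gene_sets)) {
      for (dir in c("high_in_y", "high_in_x")) {
        gl <- rf$outliers$gene_id[rf$outliers$direction == dir]
        if (!length(gl)) next
        et <- enrichmentTest(gl, gene_sets[[set_name]], universe)
        enr_rows[[length(enr_rows) + 1]] <- data.frame(
          comparison = cmp, stratum = str, direction = dir,
          gene_set = set_name, universe_size = et$universe_size,
          set_in_universe = et$set_in_universe, list_size = et$list_size,
          overlap = et$overlap, p = et$p)
      }
    }
  }
  outliers <- if (length(out_rows)) do.call(rbind, c(out_rows, make.row.names = FALSE))
              else data.frame(gene_id = character(), observed_x = integer(),
                              observed_y = integer(), residual = numeric(),
                              direction = character(), comparison = character(),
                              stratum = character(), high_in = character())
  enrichment <- if (length(enr_rows)) do.call(rbind, enr_rows)
                else data.frame(comparison = character(), stratum = character(),
                                direction = character(), gene_set = character(),
                                universe_size = integer(),
                                set_in_universe = integer(),
                                list_size = integer(), overlap = integer(),
                                p = numeric())
  if (nrow(enrichment)) enrichment$p_adj <- adjustPvalues(enrichment$p, adjust)
  candidates <- if (nrow(outliers)) {
    agg <- stats::aggregate(
      provenance ~ gene_id,
      data = data.frame(gene_id = outliers$gene_id,
                        provenance = paste0(outliers$comparison, ".",
                                            outliers$stratum, ":",
                                            outliers$high_in)),
      FUN = function(z) paste(sort(unique(z)), collapse = ";"))
    agg[order(agg$gene_id), ]
  } else data.frame(gene_id = character(), provenance = character())
  list(outliers = outliers, enrichment = enrichment,
       candidates = candidates, skipped = skipped)
}

#' @rdname runComparisons
#' @export
defaultComparisonPlan <- function() {
  expand.grid(comparison = c("ON_vs_all", "ON_vs_Metabolic", "ON_vs_Sensory",
                             "Metabolic_vs_Sensory"),
              stratum = c("all", "male", "female"),
              stringsAsFactors = FALSE)
}
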