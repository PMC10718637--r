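# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# Grid-search oracle for the two-component audiogram fit: exhaustive search
# over (m, s) at 0.1 dB resolution (coarse 1 dB pass over [0, 120]^2, then
# 0.1 dB refinement around the coarse optimum).
gridFitOracle <- function(y, shapes) {
  sse_grid <- function(ms, ss) {
    pred_m <- outer(shapes[, 1], ms)    # nf x nm
    best <- matrix(NA_real_, length(ms), length(ss))
    for (j in seq_along(ss)) {
      res <- y - (pred_m + shapes[, 2] * ss[j])
      best[, j] <- colSums(res^2)
    }
    best
  }
  coarse <- seq(0, 120, by = 1)
  g <- sse_grid(coarse, coarse)
  ij <- which(g == min(g), arr.ind = TRUE)[1, ]
  m0 <- coarse[ij[1]]; s0 <- coarse[ij[2]]
  fm <- seq(max(0, m0 - 2), min(120, m0 + 2), by = 0.1)
  fs <- seq(max(0, s0 - 2), min(120, s0 + 2), by = 0.1)
  g2 <- sse_grid(fm, fs)
  ij <- which(g2 == min(g2), arr.ind = TRUE)[1, ]
  c(m = fm[ij[1]], s = fs[ij[2]])
}

# Exact distribution of the heterozygote count conditional on allele counts,
# derived by the random-pairing recursion: repeatedly draw two alleles at
# random from the pool of m minor + M major alleles and pair them.
pairingHetDist <- function(m, M) {
  memo <- new.env(parent = emptyenv())
  rec <- function(m, M) {
    key <- paste(m, M)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (m + M == 0) return(c(1))           # P(het = 0) = 1
    tot <- choose(m + M, 2)
    out <- numeric(m %/% 1 + 2)            # grows below as needed
    out <- 0
    acc <- numeric(0)
    add <- function(acc, v, shift, w) {
      need <- length(v) + shift
      if (length(acc) < need) acc <- c(acc, numeric(need - length(acc)))
      idx <- seq_along(v) + shift
      acc[idx] <- acc[idx] + w * v
      acc
    }
    acc <- numeric(1)
    if (m >= 2) acc <- add(acc, rec(m - 2, M), 0, choose(m, 2) / tot)
    if (M >= 2) acc <- add(acc, rec(m, M - 2), 0, choose(M, 2) / tot)
    if (m >= 1 && M >= 1) acc <- add(acc, rec(m - 1, M - 1), 1, m * M / tot)
    memo[[key]] <- acc
    acc
  }
  rec(m, M)                                 # index k+1 = P(het = k)
}

excessHetOracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  a1 <- 2 * n_hom_ref + n_het
  m <- min(a1, 2 * n - a1)
  dist <- pairingHetDist(m, 2 * n - m)
  ks <- seq_along(dist) - 1
  sum(dist[ks >= n_het])
}

# Exhaustive hypergeometric enrichment oracle: enumerate every possible
# draw of the outlier list from the universe and count overlaps.
hyperOracle <- function(list_size, set_in_universe, universe_size, overlap) {
  draws <- utils::combn(universe_size, list_size)
  hits <- colSums(draws <= set_in_universe)  # first set_in_universe are "set"
  mean(hits >= overlap)
}

# Brute-force BH step-up from the definition:
# p_adj(i) = min over j with rank(j) >= rank(i) of m * p(j) / rank(j),
# capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  ranks <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (ranks[j] >= ranks[i]) m * p[j] / ranks[j] else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Independent outlier recomputation: closed-form OLS + manual type-7
# quartiles, no lm(), no quantile().
outlierOracle <- function(x, y, multiplier = 6) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r <- y - (a + b * x)
  s <- sort(r)
  n <- length(s)
  q7 <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75); d <- q3 - q1
  list(high_in_y = which(r > q3 + multiplier * d),
       high_in_x = which(r < q1 - multiplier * d))
}
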