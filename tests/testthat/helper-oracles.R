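# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately avoid the code paths (and, where
# possible, the library calls) they verify.

# Exhaustive one-tailed Fisher p for a 2x2 table [[a,b],[c,d]]:
# enumerate every table with the same margins and sum the probabilities
# of tables at least as extreme in the first cell.
oracle_fisher_p <- function(a, b, c, d, alternative) {
  m1 <- a + b
  m2 <- c + d
  k1 <- a + c
  N <- m1 + m2
  xs <- max(0, k1 - m2):min(k1, m1)
  prob <- choose(m1, xs) * choose(m2, k1 - xs) / choose(N, k1)
  if (alternative == "greater") {
    sum(prob[xs >= a])
  } else {
    sum(prob[xs <= a])
  }
}

# Hypergeometric over-representation tail by enumeration: overlap >= k
# when s items are drawn from a universe of N containing m specials.
oracle_hyper_tail <- function(k, m, N, s) {
  xs <- max(0, s - (N - m)):min(m, s)
  prob <- choose(m, xs) * choose(N - m, s - xs) / choose(N, s)
  sum(prob[xs >= k])
}

# Two-sample KS statistic: max absolute ECDF difference over the pooled
# support.
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Wilcoxon rank-sum statistic as reported by wilcox.test (Mann-Whitney U
# for the first sample): sum of x's ranks in the pooled sample minus
# n_x(n_x+1)/2.
oracle_wilcox_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

oracle_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# GSEA enrichment score by direct running-sum walk over the descending
# ranking: member positions add |stat|^weight (normalized over members),
# others subtract 1/(N - set size); ES is the deviation of maximum
# magnitude.
oracle_gsea_es <- function(stats_sorted, members, weight = 1) {
  N <- length(stats_sorted)
  hit <- names(stats_sorted) %in% members
  nr <- sum(abs(stats_sorted[hit])^weight)
  steps <- ifelse(hit, abs(stats_sorted)^weight / nr, -1 / (N - sum(hit)))
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

# TMM factors written directly from the method's description (reference
# by 75th-percentile CPM, doubly trimmed M/A over doubly-positive genes,
# precision-weighted mean of M, geometric-mean-1 rescaling).
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib, "/")
  q75 <- apply(cpm, 2, quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    ok <- counts[, j] > 0 & counts[, ref] > 0
    yk <- counts[ok, j]
    yr <- counts[ok, ref]
    nk <- lib[j]
    nr <- lib[ref]
    M <- log2((yk / nk) / (yr / nr))
    A <- (log2(yk / nk) + log2(yr / nr)) / 2
    n <- length(M)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    w <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Brute-force site-neighbor kNN imputation: all-pairs RMS distance over
# commonly observed samples, then the mean of the k nearest observed
# neighbors in the target sample.
oracle_knn_impute <- function(beta, k) {
  p <- nrow(beta)
  d <- matrix(Inf, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      common <- !is.na(beta[i, ]) & !is.na(beta[j, ])
      if (any(common)) {
        d[i, j] <- sqrt(mean((beta[i, common] - beta[j, common])^2))
      }
    }
  }
  out <- beta
  for (i in seq_len(p)) {
    for (j in seq_len(ncol(beta))) {
      if (!is.na(beta[i, j])) next
      cand <- order(d[i, ], rownames(beta))
      cand <- cand[is.finite(d[i, cand]) & !is.na(beta[cand, j])]
      if (length(cand) == 0) {
        out[i, j] <- mean(beta[i, ], na.rm = TRUE)
      } else {
        out[i, j] <- mean(beta[cand[seq_len(min(k, length(cand)))], j])
      }
    }
  }
  out
}

# Single-source unreachability by breadth-first search on an edge list.
oracle_bfs_reachable <- function(edges, from, nodes) {
  adj <- lapply(setNames(nm = nodes), function(v) {
    c(edges$node_b[edges$node_a == v], edges$node_a[edges$node_b == v])
  })
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}
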