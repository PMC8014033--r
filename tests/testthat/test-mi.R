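test_that("copula transform yields scaled ranks, monotone invariance, tie flag", {
  expect_equal(copula_transform(c(3, 1, 2)), c(0.75, 0.25, 0.5))
  x <- rnorm(50)
  expect_identical(copula_transform(x), copula_transform(exp(x)))
  out <- copula_transform(c(5, 5))
  expect_equal(as.numeric(out), c(0.5, 0.5))
  expect_true(attr(out, "degenerate"))
})

test_that("bandwidth resolution honors presets, passthrough and the frozen power law", {
  cfg <- mi_config()
  expect_equal(resolve_bandwidth(45, cfg), 0.211612)
  expect_equal(resolve_bandwidth(395, cfg), 0.12527)
  expect_equal(resolve_bandwidth(123, mi_config(bandwidth = 0.2)), 0.2)
  h200 <- resolve_bandwidth(200, cfg)
  expect_gt(h200, 0.12527) # below the n=395 preset's n
  expect_lt(h200, 0.16567) # above the n=128 preset's n
  # frozen least-squares fit on log h ~ log n over the five presets
  expect_equal(h200, 0.5295839 * 200^-0.2408892, tolerance = 1e-6)
  expect_equal(resolve_bandwidth(2000, cfg), 0.08486965, tolerance = 1e-6)
})

test_that("MI estimator is symmetric, monotone-invariant and near zero under independence", {
  set.seed(2)
  x <- copula_transform(rnorm(80))
  y <- copula_transform(rnorm(80))
  h <- 0.19
  expect_identical(as.numeric(mi_pair(x, y, h)), as.numeric(mi_pair(y, x, h)))
  # monotone invariance through the copula front-end
  v <- rnorm(80)
  expect_equal(
    as.numeric(mi_pair(copula_transform(v), y, h)),
    as.numeric(mi_pair(copula_transform(v^3 + 5), y, h)),
    tolerance = 1e-10
  )
  # a permuted copy is independent: raw MI should sit inside the null
  xp <- sample(x)
  p <- permutation_pvalue(x, xp, h, n_permutations = 199, seed = 4)
  expect_gt(p, 0.05)
  # self-dependence is maximal among these
  expect_gt(as.numeric(mi_pair(x, x, h)), as.numeric(mi_pair(x, y, h)))
  expect_error(mi_pair(x, y[-1], h), "length")
})

test_that("MI estimate tracks the analytic value for correlated Gaussians", {
  set.seed(11)
  n <- 1000
  rho <- 0.8
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  h <- resolve_bandwidth(n, mi_config())
  est <- as.numeric(mi_pair(copula_transform(x), copula_transform(y), h))
  truth <- -0.5 * log(1 - rho^2)
  expect_lt(abs(est - truth) / truth, 0.15)
})

test_that("all-pairs scoring enumerates admissible classes only", {
  data <- toy_normalized()
  data$cpg_m <- data$cpg_m[1:2, ]
  data$transcript_expr <- data$transcript_expr[1:2, ]
  data$mirna_expr <- data$mirna_expr[1, , drop = FALSE]
  cand <- mi_all_pairs(data, mi_config())
  counts <- table(cand$pair_class)
  expect_equal(as.vector(counts[c(
    "CpG-transcript", "CpG-miRNA", "transcript-transcript",
    "transcript-miRNA", "miRNA-miRNA"
  )]), c(4, 2, 1, 2, NA), ignore_attr = TRUE)
  expect_equal(nrow(cand), 9)
  expect_false("CpG-CpG" %in% cand$pair_class)
  # excluding everything leaves nothing
  cand0 <- mi_all_pairs(data, mi_config(excluded_classes = pair_classes()))
  expect_equal(nrow(cand0), 0)
})

test_that("a strongly planted dependency outranks every decoy of its class", {
  g <- generate_dataset(small_config(
    dependence_strength = 0.95, planted_edges_per_class = 1,
    missing_rate = 0, group_sizes = c(G = 100), n_processes = 0,
    shifts_per_group = 0
  ))
  nd <- list(
    cpg_m = beta_to_m(g$dataset$cpg_beta),
    transcript_expr = log_cpm(g$dataset$transcript_counts),
    mirna_expr = log_cpm(g$dataset$mirna_counts),
    feature_meta = g$dataset$feature_meta
  )
  cand <- mi_all_pairs(nd, mi_config())
  pe <- g$truth$planted_edges
  for (cls in unique(pe$pair_class)) {
    d <- cand[cand$pair_class == cls, ]
    top <- d[which.max(d$mi), ]
    key <- mionet:::edge_key(top$node_a, top$node_b, cls)
    pk <- mionet:::edge_key(
      pe$regulator[pe$pair_class == cls], pe$target[pe$pair_class == cls], cls
    )
    expect_identical(key, pk)
  }
})

test_that("top-k selection is per class with a lexicographic tie-break", {
  cand <- data.frame(
    node_a = c("a", "a", "b", "c", "d", "x"),
    node_b = c("b", "c", "c", "d", "e", "y"),
    pair_class = c(rep("transcript-transcript", 5), "miRNA-miRNA"),
    mi = c(5, 4, 3, 3, 1, 2), mi_raw = c(5, 4, 3, 3, 1, 2),
    stringsAsFactors = FALSE
  )
  net <- select_top_k(cand, top_k = 3)
  tt <- net$edges[net$edges$pair_class == "transcript-transcript", ]
  expect_equal(nrow(tt), 3)
  expect_true(all(tt$mi >= 3))
  # tie at the cutoff: (b,c) beats (c,d) lexicographically
  expect_true(any(tt$node_a == "b" & tt$node_b == "c"))
  expect_false(any(tt$node_a == "c" & tt$node_b == "d"))
  # other classes selected independently
  expect_equal(sum(net$edges$pair_class == "miRNA-miRNA"), 1)
  # determinism
  expect_identical(net, select_top_k(cand, top_k = 3))
})

test_that("permutation p-values use the add-one rule and are calibrated", {
  set.seed(5)
  x <- copula_transform(rnorm(50))
  # y = x: the observed MI beats every permutation
  expect_equal(permutation_pvalue(x, x, 0.2, n_permutations = 199, seed = 1),
    1 / 200)
  # calibration under independence: p approximately uniform
  ps <- vapply(seq_len(200), function(i) {
    set.seed(1000 + i)
    a <- copula_transform(rnorm(30))
    b <- copula_transform(rnorm(30))
    permutation_pvalue(a, b, 0.23, n_permutations = 99, seed = i)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("subsampling z-scores flag degenerate pairs and finite strong edges", {
  g <- generate_dataset(small_config(
    dependence_strength = 0.95, missing_rate = 0, group_sizes = c(G = 60)
  ))
  nd <- preprocess_dataset(g$dataset)
  pe <- g$truth$planted_edges
  keep <- pe$regulator %in% nd$feature_meta$feature_id &
    pe$target %in% nd$feature_meta$feature_id
  edges <- data.frame(
    node_a = pe$regulator[keep][1:3], node_b = pe$target[keep][1:3],
    stringsAsFactors = FALSE
  )
  cfg <- mi_config(n_subsamples = 20, subsample_size = 20, seed = 2)
  zs <- subsample_zscores(nd, edges, cfg)
  expect_true(all(zs$z_defined))
  expect_true(all(is.finite(zs$z)))
  # a constant feature gives identical MI across subsamples: sd = 0, flagged
  nd2 <- nd
  nd2$cpg_m[1, ] <- 0
  zdeg <- subsample_zscores(
    nd2,
    data.frame(node_a = rownames(nd2$cpg_m)[1], node_b = rownames(nd2$cpg_m)[1:2][2]),
    cfg
  )
  expect_false(zdeg$z_defined)
  expect_true(is.na(zdeg$z))
  expect_error(
    subsample_zscores(nd, edges, mi_config(subsample_size = 60)),
    "below the group size"
  )
})

test_that("MI distribution comparisons: degenerate and disjoint cases, BH column", {
  mk_net <- function(mis, cls, group) {
    n <- length(mis)
    edges <- data.frame(
      node_a = sprintf("%s_a%03d", cls, 1:n), node_b = sprintf("%s_b%03d", cls, 1:n),
      pair_class = cls, mi = mis, stringsAsFactors = FALSE
    )
    nodes <- data.frame(
      id = unique(c(edges$node_a, edges$node_b)), layer = "transcript",
      is_tf = FALSE, stringsAsFactors = FALSE
    )
    mi_network(nodes, edges, group)
  }
  set.seed(8)
  a <- mk_net(runif(30), "transcript-transcript", "A")
  b <- mk_net(runif(30) + 5, "transcript-transcript", "B") # disjoint support
  self <- compare_mi_distributions(list(A = a, B = a))
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)
  disj <- compare_mi_distributions(list(A = a, B = b))
  expect_equal(disj$statistic, 1)
  expect_identical(disj$q, p.adjust(disj$p, "BH"))
  # KS statistic agrees with the brute-force ECDF maximum
  x <- runif(25)
  y <- rnorm(25, 0.5, 0.4)
  expect_equal(
    unname(suppressWarnings(ks.test(x, y))$statistic),
    oracle_ks_stat(x, y),
    tolerance = 1e-12
  )
  expect_error(compare_mi_distributions(list(A = a)), "at least two")
})
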