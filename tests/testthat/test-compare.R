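test_that("regulator profiles count typed neighbors of annotated transcripts", {
  # one process, two transcripts, 3 distinct CpG neighbors + 1 shared miRNA
  nodes <- data.frame(
    id = c("tx1", "tx2", "cg1", "cg2", "cg3", "mir1"),
    layer = c("transcript", "transcript", "CpG", "CpG", "CpG", "miRNA"),
    is_tf = FALSE, stringsAsFactors = FALSE
  )
  edges <- data.frame(
    node_a = c("cg1", "cg2", "cg3", "tx1", "tx2"),
    node_b = c("tx1", "tx1", "tx2", "mir1", "mir1"),
    pair_class = c(rep("CpG-transcript", 3), rep("transcript-miRNA", 2)),
    mi = 1, stringsAsFactors = FALSE
  )
  en <- enriched_network(
    nodes, edges, "P1",
    data.frame(process = "P1", transcript = c("tx1", "tx2")), "toy"
  )
  pr <- regulator_profiles(en)
  expect_equal(
    unname(pr$P1$counts[c("CpG", "TF-gene", "miRNA")]), c(3, 0, 1)
  )
  expect_equal(
    unname(pr$P1$proportions[c("CpG", "TF-gene", "miRNA")]), c(0.75, 0, 0.25)
  )
  expect_setequal(pr$P1$regulator_ids$CpG, c("cg1", "cg2", "cg3"))

  # a process with no regulator neighbors is flagged undefined
  en2 <- enriched_network(
    nodes[1:2, ], edges[0, ], "P1",
    data.frame(process = "P1", transcript = "tx1"), "toy"
  )
  pr2 <- regulator_profiles(en2)
  expect_equal(pr2$P1$total, 0)
  expect_true(all(is.na(pr2$P1$proportions)))
})

test_that("regulator profiles equal an exhaustive adjacency scan on random graphs", {
  set.seed(14)
  g <- generate_dataset(small_config(planted_edges_per_class = 5, seed = 31))
  nd <- preprocess_dataset(g$dataset)
  cand <- mi_all_pairs(list(
    cpg_m = nd$cpg_m[, 1:20], transcript_expr = nd$transcript_expr[, 1:20],
    mirna_expr = nd$mirna_expr[, 1:20], feature_meta = nd$feature_meta
  ), mi_config())
  net <- select_top_k(cand, 40, group = "G")
  en <- prune_to_enriched(net, nd$gene_sets)
  if (length(en$process_nodes) > 0) {
    pr <- regulator_profiles(en)
    meta <- nd$feature_meta
    for (p in en$process_nodes) {
      tx <- en$annotation_edges$transcript[en$annotation_edges$process == p]
      nb <- unique(c(
        en$edges$node_b[en$edges$node_a %in% tx],
        en$edges$node_a[en$edges$node_b %in% tx]
      ))
      expected <- c(
        CpG = sum(nb %in% meta$feature_id[meta$layer == "CpG"]),
        `TF-gene` = sum(nb %in% meta$feature_id[meta$layer == "transcript" & meta$is_tf]),
        miRNA = sum(nb %in% meta$feature_id[meta$layer == "miRNA"])
      )
      expect_equal(pr[[p]]$counts, expected)
    }
  }
})

test_that("regulator-type Fisher tests honor the one-tailed alternatives", {
  # subtype: 10 CpG / 0 others; normal: 0 CpG / 10 others
  sub <- build_enriched(list(P1 = list(
    CpG = paste0("cg", 1:10)
  )), "sub")
  nor <- build_enriched(list(P1 = list(
    miRNA = paste0("mir", 1:5), `TF-gene` = paste0("tf", 1:5)
  )), "nor")
  res <- fisher_regulator_enrichment(
    regulator_profiles(sub), regulator_profiles(nor)
  )
  cpg <- res[res$type == "CpG", ]
  expect_equal(cpg$p, oracle_fisher_p(10, 0, 0, 10, "greater"),
    tolerance = 1e-12
  )
  expect_equal(cpg$p, 1 / choose(20, 10), tolerance = 1e-12)
  # identical profiles: no association, one-sided p at least 0.5
  res2 <- fisher_regulator_enrichment(
    regulator_profiles(sub), regulator_profiles(sub)
  )
  expect_true(all(res2$p[res2$tested] >= 0.5))
  # zero margin for a type present nowhere: p = 1
  expect_equal(res2$p[res2$type == "miRNA"], 1)
  # precondition: no regulators in one network -> NA, not a crash
  empty <- enriched_network(
    data.frame(id = "tx_P1", layer = "transcript", is_tf = FALSE),
    data.frame(node_a = character(), node_b = character(),
      pair_class = character(), mi = numeric()),
    "P1", data.frame(process = "P1", transcript = "tx_P1"), "e"
  )
  res3 <- fisher_regulator_enrichment(
    regulator_profiles(sub), regulator_profiles(empty)
  )
  expect_true(all(is.na(res3$p)))
  expect_false(any(res3$tested))
})

test_that("one-tailed Fisher p-values match exhaustive enumeration on small margins", {
  tables <- expand.grid(a = 0:4, b = 0:4, c = 0:4, d = 0:4)
  tables <- tables[rowSums(tables) > 0 & rowSums(tables) <= 12, ]
  set.seed(2)
  tables <- tables[sample(nrow(tables), 60), ]
  for (i in seq_len(nrow(tables))) {
    t <- as.integer(tables[i, ])
    for (alt in c("greater", "less")) {
      expect_equal(
        fisher.test(matrix(t, 2, byrow = TRUE), alternative = alt)$p.value,
        oracle_fisher_p(t[1], t[2], t[3], t[4], alt),
        tolerance = 1e-10
      )
    }
  }
})

test_that("topology statistics match hand counts and brute-force reachability", {
  path_nodes <- data.frame(
    id = c("cg1", "tx1", "mir1"), layer = c("CpG", "transcript", "miRNA"),
    is_tf = FALSE, stringsAsFactors = FALSE
  )
  path_edges <- data.frame(
    node_a = c("cg1", "tx1"), node_b = c("tx1", "mir1"),
    pair_class = c("CpG-transcript", "transcript-miRNA"), mi = 1,
    stringsAsFactors = FALSE
  )
  net <- mi_network(path_nodes, path_edges, "path")
  ts <- topology_stats(net)
  expect_equal(sort(ts$degrees$degree), c(1, 1, 2))
  expect_equal(sort(ts$path_lengths), c(1, 1, 2))
  expect_equal(ts$n_components, 1)
  # every transcript reachable from the one CpG
  expect_equal(ts$unreachable$fraction[ts$unreachable$layer == "CpG"], 0)

  # two disjoint edges
  nodes2 <- data.frame(
    id = c("cg1", "tx1", "cg2", "tx2"),
    layer = c("CpG", "transcript", "CpG", "transcript"),
    is_tf = FALSE, stringsAsFactors = FALSE
  )
  edges2 <- data.frame(
    node_a = c("cg1", "cg2"), node_b = c("tx1", "tx2"),
    pair_class = "CpG-transcript", mi = 1, stringsAsFactors = FALSE
  )
  ts2 <- topology_stats(mi_network(nodes2, edges2, "disjoint"))
  expect_equal(ts2$n_components, 2)
  # each CpG reaches 1 of 2 transcripts
  expect_equal(ts2$unreachable$fraction[ts2$unreachable$layer == "CpG"], 0.5)

  # random toy vs BFS brute force
  set.seed(4)
  ids <- sprintf("n%02d", 1:15)
  layer <- sample(c("CpG", "transcript", "miRNA"), 15, TRUE)
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), 18)
  la <- layer[match(pairs[pick, 1], ids)]
  lb <- layer[match(pairs[pick, 2], ids)]
  keep <- !(la == "CpG" & lb == "CpG")
  edges3 <- data.frame(
    node_a = pairs[pick, 1][keep], node_b = pairs[pick, 2][keep],
    pair_class = pair_class_of(la[keep], lb[keep]), mi = 1,
    stringsAsFactors = FALSE
  )
  nodes3 <- data.frame(id = ids, layer = layer, is_tf = FALSE,
    stringsAsFactors = FALSE)
  ts3 <- topology_stats(mi_network(nodes3, edges3, "rand"))
  targets <- ids[layer == "transcript"]
  for (tp in c("CpG", "miRNA")) {
    regs <- ids[layer == tp]
    if (length(regs) == 0 || length(targets) == 0) next
    expected <- mean(vapply(regs, function(r) {
      reach <- oracle_bfs_reachable(edges3, r, ids)
      tg <- setdiff(targets, r)
      mean(!(tg %in% reach))
    }, numeric(1)))
    expect_equal(
      ts3$unreachable$fraction[ts3$unreachable$layer == tp], expected
    )
  }
  # degree by brute force
  expect_equal(
    ts3$degrees$degree,
    vapply(ts3$degrees$node, function(v) {
      sum(edges3$node_a == v) + sum(edges3$node_b == v)
    }, numeric(1)),
    ignore_attr = TRUE
  )
})

test_that("distribution comparisons: self is null, separation is maximal, BH applied", {
  mk_summary <- function(degrees_by_layer, paths) {
    degrees <- do.call(rbind, lapply(names(degrees_by_layer), function(l) {
      data.frame(
        node = paste0(l, seq_along(degrees_by_layer[[l]])), layer = l,
        is_tf = FALSE, degree = degrees_by_layer[[l]],
        stringsAsFactors = FALSE
      )
    }))
    structure(
      list(
        degrees = degrees, path_lengths = paths, n_components = 1,
        unreachable = NULL
      ),
      class = "topology_summary"
    )
  }
  s1 <- mk_summary(list(CpG = c(1, 2, 3), transcript = c(1, 2, 3)), c(1, 1, 2))
  res <- compare_node_distributions(list(A = s1))
  expect_equal(res$p, 1) # identical distributions, continuity-corrected normal approx
  s2 <- mk_summary(list(CpG = c(101, 102, 103)), c(5, 6, 7))
  res2 <- compare_node_distributions(list(A = s1, B = s2))
  sep <- res2[res2$scope == "between_networks" & res2$metric == "degree", ]
  expect_equal(sep$statistic, oracle_wilcox_stat(c(1, 2, 3), c(101, 102, 103)))
  expect_equal(sep$statistic, 0) # minimal rank-sum statistic
  expect_identical(res2$q, p.adjust(res2$p, "BH"))
  # Wilcoxon statistic equals the brute-force rank computation generally
  set.seed(3)
  x <- rnorm(9)
  y <- rnorm(7)
  expect_equal(
    unname(suppressWarnings(wilcox.test(x, y, exact = FALSE))$statistic),
    oracle_wilcox_stat(x, y)
  )
})

test_that("Jaccard index follows set arithmetic and flags the empty case", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  und <- jaccard(character(), character())
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  set.seed(10)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    expect_equal(as.numeric(jaccard(a, b)), oracle_jaccard(a, b))
  }
})

test_that("intra-network sharing classifies exclusivity and tests it directionally", {
  # all CpGs exclusive to one process; the miRNA shared by all three
  wiring <- list(
    P1 = list(CpG = c("cg1", "cg2"), miRNA = "mirS"),
    P2 = list(CpG = c("cg3"), miRNA = "mirS"),
    P3 = list(CpG = c("cg4", "cg5"), miRNA = "mirS")
  )
  en <- build_enriched(wiring)
  sh <- intra_subtype_sharing(regulator_profiles(en))
  f <- sh$fisher
  expect_equal(f$exclusive[f$type == "CpG"], 5)
  expect_equal(f$shared[f$type == "CpG"], 0)
  expect_equal(f$exclusive[f$type == "miRNA"], 0)
  expect_equal(f$shared[f$type == "miRNA"], 1)
  expect_equal(
    f$p[f$type == "CpG"],
    oracle_fisher_p(5, 0, 0, 1, "greater"),
    tolerance = 1e-12
  )
  expect_equal(
    f$p[f$type == "miRNA"],
    oracle_fisher_p(0, 1, 5, 0, "less"),
    tolerance = 1e-12
  )
  # pairwise node Jaccard per type
  j <- sh$jaccard
  expect_equal(
    j$jaccard[j$type == "miRNA"], rep(1, 3) # mirS shared by every pair
  )
  expect_equal(j$jaccard[j$type == "CpG"], rep(0, 3))
  # single process: no pairs
  sh1 <- intra_subtype_sharing(regulator_profiles(build_enriched(wiring[1])))
  expect_equal(nrow(sh1$jaccard), 0)
})

test_that("inter-network edge sharing counts conserved interactions", {
  w1 <- list(P1 = list(CpG = c("cg1", "cg2"), miRNA = "mir1", `TF-gene` = "tf1"))
  n1 <- build_enriched(w1, "A")
  # identical networks share everything
  res_same <- inter_subtype_sharing(list(A = n1, B = build_enriched(w1, "B")))
  expect_true(all(res_same$jaccard$jaccard[res_same$jaccard$size_a > 0] == 1))
  # disjoint regulator wiring shares nothing
  w2 <- list(P1 = list(CpG = c("cg8", "cg9"), miRNA = "mir8", `TF-gene` = "tf8"))
  res_disj <- inter_subtype_sharing(list(A = n1, B = build_enriched(w2, "B")))
  expect_true(all(res_disj$jaccard$jaccard == 0))
  # hand-built overlap: 4 vs 4 CpG edges sharing 2 -> 2/6
  wa <- list(P1 = list(CpG = paste0("cg", 1:4)))
  wb <- list(P1 = list(CpG = paste0("cg", 3:6)))
  res <- inter_subtype_sharing(list(A = build_enriched(wa, "A"), B = build_enriched(wb, "B")))
  expect_equal(
    res$jaccard$jaccard[res$jaccard$type == "CpG"], 2 / 6
  )
})

test_that("cross-referencing labels every regulator edge exactly once", {
  meta <- data.frame(
    feature_id = c("cg1", "cg2", "cg3", "tx1", "tx2", "mir1"),
    layer = c("CpG", "CpG", "CpG", "transcript", "transcript", "miRNA"),
    is_tf = FALSE,
    chromosome = c("chr1", "chr2", "chr5", "chr1", "chr2", "chr3"),
    mapped_gene = c(NA, "tx2", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  nodes <- data.frame(
    id = meta$feature_id, layer = meta$layer, is_tf = meta$is_tf,
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    node_a = c("cg1", "cg2", "cg3", "tx1"),
    node_b = c("tx1", "tx2", "tx1", "mir1"),
    pair_class = c("CpG-transcript", "CpG-transcript", "CpG-transcript", "transcript-miRNA"),
    mi = 1, stringsAsFactors = FALSE
  )
  net <- mi_network(nodes, edges, "toy")
  ref <- data.frame(
    regulator = c("mir1", "cg3"), target = c("tx1", "tx1"),
    evidence_class = c("validated", "predicted"), stringsAsFactors = FALSE
  )
  out <- cross_reference_edges(net, ref, meta)
  lab <- setNames(out$edges$label, paste(out$edges$node_a, out$edges$node_b))
  expect_identical(unname(lab["cg1 tx1"]), "same-chromosome") # both chr1
  expect_identical(unname(lab["cg2 tx2"]), "mapped") # annotation rule
  expect_identical(unname(lab["cg3 tx1"]), "predicted") # reference, non-validated
  expect_identical(unname(lab["tx1 mir1"]), "validated")
  # fractions partition each class
  sums <- tapply(out$fractions$fraction, out$fractions$pair_class, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # empty reference: metadata labels still computable
  out2 <- cross_reference_edges(net, NULL, meta)
  expect_identical(
    unname(setNames(out2$edges$label, out2$edges$node_a)["cg2"]), "mapped"
  )
  expect_false(any(out2$edges$label %in% c("validated", "predicted")))
})
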