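test_that("fold-change-threshold ranking zeroes the null band and matches hand arithmetic", {
  set.seed(6)
  n <- 6
  expr <- matrix(rnorm(10 * 2 * n, sd = 0.1), 10, 2 * n,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:(2 * n)))
  )
  a <- paste0("s", 1:n)
  b <- paste0("s", (n + 1):(2 * n))
  # g1: logFC exactly at the threshold; g2: logFC 0; g3: strong up
  expr["g1", a] <- expr["g1", a] - mean(expr["g1", a]) + log2(1.5)
  expr["g1", b] <- expr["g1", b] - mean(expr["g1", b])
  expr["g2", ] <- expr["g2", ] - mean(expr["g2", ])
  expr["g2", a] <- expr["g2", a] - mean(expr["g2", a])
  expr["g2", b] <- expr["g2", b] - mean(expr["g2", b])
  expr["g3", a] <- expr["g3", a] + 3
  rk <- treat_rank(expr, a, b)
  expect_equal(unname(rk["g1"]), 0)
  expect_equal(unname(rk["g2"]), 0)
  expect_identical(names(rk)[1], "g3")
  expect_identical(names(rk), names(sort(rk, decreasing = TRUE)))

  # hand computation of the soft-threshold moderated t for one gene
  ma <- rowMeans(expr[, a])
  mb <- rowMeans(expr[, b])
  s2 <- (rowSums((expr[, a] - ma)^2) + rowSums((expr[, b] - mb)^2)) / (2 * n - 2)
  s2m <- (4 * mean(s2) + (2 * n - 2) * s2) / (4 + 2 * n - 2)
  se <- sqrt(s2m * (2 / n))
  lfc <- ma - mb
  expected_g3 <- (abs(lfc["g3"]) - log2(1.5)) / se["g3"]
  expect_equal(unname(rk["g3"]), unname(expected_g3), tolerance = 1e-12)
  expect_error(treat_rank(expr, a[1:2], b), "at least 3")
})

test_that("enrichment scores equal a brute-force running-sum walk", {
  set.seed(9)
  N <- 60
  stats <- sort(setNames(rnorm(N), paste0("g", 1:N)), decreasing = TRUE)
  sets <- list(
    s1 = names(stats)[c(1, 3, 8, 40)],
    s2 = names(stats)[c(55, 57, 60)],
    s3 = sample(names(stats), 10)
  )
  res <- gsea_preranked(stats, sets, enrichment_config(gsea_permutations = 100))
  for (s in names(sets)) {
    expect_equal(
      res$es[res$process == s],
      oracle_gsea_es(stats, sets[[s]], weight = 1),
      tolerance = 1e-10
    )
  }
  # weight 0: ES invariant under order-preserving rescaling of statistics
  res0a <- gsea_preranked(stats, sets, enrichment_config(gsea_weight = 0, gsea_permutations = 50))
  res0b <- gsea_preranked(
    sort(setNames(exp(stats / 2), names(stats)), decreasing = TRUE), sets,
    enrichment_config(gsea_weight = 0, gsea_permutations = 50)
  )
  expect_equal(res0a$es, res0b$es, tolerance = 1e-10)
  expect_equal(res0a$es, vapply(sets, function(s) {
    oracle_gsea_es(stats, s, weight = 0)
  }, numeric(1)), ignore_attr = TRUE, tolerance = 1e-10)
  # the full running sum returns to zero by construction
  walk <- function(members, weight) {
    hit <- names(stats) %in% members
    nr <- sum(abs(stats[hit])^weight)
    sum(ifelse(hit, abs(stats)^weight / nr, -1 / (N - sum(hit))))
  }
  expect_equal(walk(sets$s1, 1), 0, tolerance = 1e-9)
  expect_equal(walk(sets$s3, 0), 0, tolerance = 1e-9)
})

test_that("degenerate gene sets are dropped or rejected", {
  stats <- sort(setNames(rnorm(20), paste0("g", 1:20)), decreasing = TRUE)
  expect_message(
    res <- gsea_preranked(
      stats, list(ok = names(stats)[1:3], gone = c("zz1", "zz2")),
      enrichment_config(gsea_permutations = 50)
    ),
    "no member"
  )
  expect_identical(res$process, "ok")
  expect_error(
    gsea_preranked(stats, list(all = names(stats)),
      enrichment_config(gsea_permutations = 50)
    ),
    "every ranked gene"
  )
})

test_that("a planted activity shift is detected with the right sign", {
  g <- generate_dataset(small_config(
    group_sizes = c(TumorA = 25, Normal = 30), shift_effect = 1.5,
    shifts_per_group = 2, seed = 21
  ))
  nd <- preprocess_dataset(g$dataset)
  tum <- names(nd$sample_groups)[nd$sample_groups == "TumorA"]
  nor <- names(nd$sample_groups)[nd$sample_groups == "Normal"]
  rk <- treat_rank(nd$transcript_expr, tum, nor)
  res <- gsea_preranked(rk, nd$gene_sets, enrichment_config(gsea_permutations = 500))
  truth <- g$truth$shifted_sets
  for (i in seq_len(nrow(truth))) {
    row <- res[res$process == truth$process[i], ]
    expect_lte(row$q, 0.05)
    expect_equal(row$direction, truth$direction[i])
  }
})

test_that("network over-representation matches exact hypergeometric enumeration", {
  universe <- paste0("g", 1:20)
  network <- universe[1:10]
  sets <- list(
    nested = universe[1:5], # fully inside the network
    spread = universe[c(1, 6, 11, 16, 17)],
    outside = universe[16:20]
  )
  res <- ora_network(network, sets, universe, q_max = 0.05)
  for (s in names(sets)) {
    k <- length(intersect(sets[[s]], network))
    expect_equal(
      res$p[res$process == s],
      oracle_hyper_tail(k, length(sets[[s]]), 20, 10),
      tolerance = 1e-12
    )
  }
  # overlap at its expectation gives a one-sided p of at least 0.5
  expect_gte(res$p[res$process == "spread"], 0.5) # overlap 2 < expected 2.5
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_error(ora_network(network, sets, character()), "universe")
})

test_that("pruning keeps enriched processes, first neighbors and allowed classes", {
  nodes <- data.frame(
    id = c("tx1", "tx2", "tx3", "cg1", "cg2", "mir1"),
    layer = c("transcript", "transcript", "transcript", "CpG", "CpG", "miRNA"),
    is_tf = FALSE, stringsAsFactors = FALSE
  )
  edges <- data.frame(
    node_a = c("cg1", "cg2", "cg1", "tx3", "cg2"),
    node_b = c("tx1", "tx2", "mir1", "mir1", "mir1"),
    pair_class = c(
      "CpG-transcript", "CpG-transcript", "CpG-miRNA",
      "transcript-miRNA", "CpG-miRNA"
    ),
    mi = c(1, 0.9, 0.8, 0.7, 0.6), stringsAsFactors = FALSE
  )
  net <- mi_network(nodes, edges, "toy")
  en <- prune_to_enriched(net, list(P1 = c("tx1", "tx2")))
  # tx1, tx2 seeds; cg1, cg2 first neighbors; mir1/tx3 not adjacent to seeds
  expect_setequal(en$nodes$id, c("tx1", "tx2", "cg1", "cg2"))
  expect_equal(nrow(en$edges), 2) # the CpG-miRNA edge between retained nodes is out
  expect_identical(en$process_nodes, "P1")
  expect_equal(nrow(en$annotation_edges), 2)
  # no represented process: empty result
  en0 <- prune_to_enriched(net, list())
  expect_equal(nrow(en0$nodes), 0)
  expect_equal(nrow(en0$edges), 0)
  # annotated transcripts absent from the network: empty, with a warning
  expect_warning(
    en1 <- prune_to_enriched(net, list(P9 = "not_there")), "empty"
  )
  expect_equal(nrow(en1$nodes), 0)
  # pruning never grows the graph
  expect_lte(nrow(en$nodes), nrow(net$nodes))
  expect_lte(nrow(en$edges), nrow(net$edges))
})

test_that("normal-tissue candidates are the union of subtype-significant processes", {
  mk <- function(procs, qs) {
    data.frame(process = procs, q = qs, stringsAsFactors = FALSE)
  }
  one <- normal_tissue_processes(list(mk(c("A", "B", "C"), c(0.001, 0.5, 0.005))))
  expect_setequal(one, c("A", "C"))
  two <- normal_tissue_processes(list(
    mk(c("A", "B"), c(0.001, 0.002)), mk(c("B", "C"), c(0.003, 0.004))
  ))
  expect_setequal(two, c("A", "B", "C"))
  disjoint <- normal_tissue_processes(list(
    mk(c("A", "B"), c(0.001, 0.001)), mk(c("C", "D", "E"), rep(0.001, 3))
  ))
  expect_length(disjoint, 5)
})
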