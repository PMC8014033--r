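#' Enrichment configuration
#'
#' @param fold_change_null null fold change for the differential ranking
#'   (default 1.5): only fold changes beyond this threshold contribute to
#'   a transcript's statistic.
#' @param gsea_q_max BH-adjusted significance cutoff for gene-set
#'   enrichment (default 0.01).
#' @param ora_q_max BH-adjusted cutoff above which a process is regarded
#'   as non-represented in a network (default 0.05).
#' @param gsea_permutations random gene-set draws for the GSEA null.
#' @param gsea_weight enrichment-score weighting exponent on the ranking
#'   statistic (default 1).
#' @param treat_prior_df prior degrees of freedom for the variance
#'   shrinkage in [treat_rank()] (default 4).
#' @param seed integer seed for the GSEA null draws.
#' @return an `enrichment_config` list.
#' @export
enrichment_config <- function(fold_change_null = 1.5, gsea_q_max = 0.01,
                              ora_q_max = 0.05, gsea_permutations = 1000,
                              gsea_weight = 1, treat_prior_df = 4,
                              seed = 1) {
  cfg <- list(
    fold_change_null = fold_change_null, gsea_q_max = gsea_q_max,
    ora_q_max = ora_q_max, gsea_permutations = as.integer(gsea_permutations),
    gsea_weight = gsea_weight, treat_prior_df = treat_prior_df,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$fold_change_null >= 1,
    cfg$gsea_q_max > 0, cfg$gsea_q_max < 1,
    cfg$ora_q_max > 0, cfg$ora_q_max < 1,
    cfg$gsea_permutations >= 1, cfg$gsea_weight >= 0,
    cfg$treat_prior_df >= 0
  )
  structure(cfg, class = "enrichment_config")
}

#' Fold-change-threshold moderated differential ranking
#'
#' Per transcript, the log2 fold change between two sample groups is
#' tested against a null fold change rather than against zero:
#' `stat = sign(logFC) * max(0, |logFC| - log2(fold_change_null)) / SE`,
#' where the standard error uses a moderated variance shrinking each
#' gene's pooled variance toward the across-gene mean with prior weight
#' `treat_prior_df`. Fold changes inside the null band score exactly 0.
#' The complete descending ranking is returned, ties broken by feature
#' id.
#'
#' @param expr log2 expression matrix.
#' @param group_a,group_b character vectors of sample ids (each >= 3).
#' @param config an [enrichment_config()].
#' @return named numeric vector sorted in decreasing order.
#' @export
treat_rank <- function(expr, group_a, group_b,
                       config = enrichment_config()) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    stopf("each group needs at least 3 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing)) stopf("unknown sample id '%s'", missing[1])
  xa <- expr[, group_a, drop = FALSE]
  xb <- expr[, group_b, drop = FALSE]
  na <- ncol(xa)
  nb <- ncol(xb)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  df <- na + nb - 2
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / df
  d0 <- config$treat_prior_df
  s2_mod <- (d0 * mean(s2) + df * s2) / (d0 + df)
  se <- sqrt(s2_mod * (1 / na + 1 / nb))
  lfc <- ma - mb
  stat <- sign(lfc) * pmax(0, abs(lfc) - log2(config$fold_change_null)) / se
  names(stat) <- rownames(expr)
  stat[order(-stat, names(stat))]
}

#' Preranked gene-set enrichment
#'
#' Walks the descending ranking accumulating `|stat|^weight` (normalized
#' over set members) at member positions and `-1/(N - set size)`
#' elsewhere; the enrichment score is the maximum deviation of the
#' running sum. The null distribution comes from seeded random
#' member-set draws of equal size; NES divides ES by the mean null ES of
#' matching sign, and p-values use the matching-sign tail with add-one
#' correction, BH-adjusted across all sets tested. Computation is
#' delegated to fgsea's set-permutation implementation.
#'
#' Sets with no member in the ranking are dropped with a message; a set
#' covering every ranked gene is an error (the down-step is undefined).
#'
#' @param ranking named statistic vector from [treat_rank()].
#' @param sets named list of transcript-id vectors.
#' @param config an [enrichment_config()].
#' @return data frame: `process`, `size`, `es`, `nes`, `p`, `q`,
#'   `direction` (sign of ES), `nes_defined`.
#' @export
gsea_preranked <- function(ranking, sets, config = enrichment_config()) {
  stopifnot(length(ranking) > 1, !is.null(names(ranking)))
  if (length(sets) == 0) stopf("no gene sets supplied")
  if (is.null(names(sets))) stopf("gene sets must be named")
  sets_f <- lapply(sets, intersect, names(ranking))
  empty <- names(sets_f)[vapply(sets_f, length, integer(1)) == 0]
  if (length(empty)) {
    msgf(
      "dropping %d set(s) with no member in the ranking: %s",
      length(empty), paste(head(empty, 5), collapse = ", ")
    )
    sets_f <- sets_f[setdiff(names(sets_f), empty)]
  }
  if (length(sets_f) == 0) stopf("no gene set overlaps the ranking")
  full <- vapply(sets_f, length, integer(1)) == length(ranking)
  if (any(full)) {
    stopf(
      "set '%s' covers every ranked gene; enrichment is undefined",
      names(sets_f)[full][1]
    )
  }
  res <- with_seed(config$seed, {
    suppressWarnings(fgsea::fgseaSimple(
      pathways = sets_f, stats = ranking,
      nperm = config$gsea_permutations,
      gseaParam = config$gsea_weight,
      minSize = 1, maxSize = length(ranking)
    ))
  })
  res <- as.data.frame(res)
  out <- data.frame(
    process = res$pathway, size = res$size, es = res$ES, nes = res$NES,
    p = res$pval, q = res$padj, direction = sign(res$ES),
    nes_defined = !is.na(res$NES), stringsAsFactors = FALSE
  )
  out[order(match(out$process, names(sets_f))), , drop = FALSE]
}

#' Network over-representation of gene sets
#'
#' One-sided hypergeometric test for the overlap between each process's
#' members and the transcripts present in a network, with BH correction
#' across all processes tested. A process is represented iff its
#' q-value is at most `q_max`.
#'
#' @param network_transcripts transcript ids present in the network.
#' @param process_sets named list of member-id vectors (subsets of
#'   `universe`).
#' @param universe all transcript ids eligible (e.g. every transcript
#'   surviving preprocessing).
#' @param q_max represented/non-represented boundary (default 0.05).
#' @return data frame: `process`, `overlap`, `set_size`, `network_size`,
#'   `p`, `q`, `represented`.
#' @export
ora_network <- function(network_transcripts, process_sets, universe,
                        q_max = 0.05) {
  if (length(universe) == 0) stopf("empty universe")
  network_transcripts <- intersect(network_transcripts, universe)
  N <- length(universe)
  s <- length(network_transcripts)
  rows <- lapply(names(process_sets), function(pr) {
    members <- intersect(process_sets[[pr]], universe)
    m <- length(members)
    k <- length(intersect(members, network_transcripts))
    p <- if (m == 0) 1 else phyper(k - 1, m, N - m, s, lower.tail = FALSE)
    data.frame(
      process = pr, overlap = k, set_size = m, network_size = s,
      p = p, stringsAsFactors = FALSE
    )
  })
  out <- rbind_rows(c(rows))
  out$q <- p.adjust(out$p, method = "BH")
  out$represented <- out$q <= q_max
  out
}

#' Processes submitted to over-representation for the normal tissue
#'
#' The union of processes passing the GSEA significance cutoff in any
#' subtype; this union is the candidate set for over-representation on
#' the Normal network.
#'
#' @param subtype_results named list of [gsea_preranked()] result data
#'   frames (one per subtype).
#' @param q_max GSEA q-value cutoff (default 0.01).
#' @return character vector of process ids.
#' @export
normal_tissue_processes <- function(subtype_results, q_max = 0.01) {
  stopifnot(length(subtype_results) >= 1)
  sort(unique(unlist(lapply(subtype_results, function(r) {
    r$process[!is.na(r$q) & r$q <= q_max]
  }))))
}

#' Construct an enriched (multipartite) network object
#'
#' @param nodes node data frame (`id`, `layer`, `is_tf`) of the retained
#'   MI subgraph.
#' @param edges retained MI edges.
#' @param process_nodes character vector of process ids.
#' @param annotation_edges data frame (`process`, `transcript`).
#' @param group group label.
#' @return an `enriched_network`.
#' @export
enriched_network <- function(nodes, edges, process_nodes,
                             annotation_edges, group = NA_character_) {
  stopifnot(
    all(c("process", "transcript") %in% colnames(annotation_edges)),
    all(annotation_edges$process %in% process_nodes)
  )
  structure(
    list(
      nodes = nodes, edges = edges, process_nodes = process_nodes,
      annotation_edges = annotation_edges, group = group
    ),
    class = "enriched_network"
  )
}

#' @export
print.enriched_network <- function(x, ...) {
  cat(sprintf(
    "enriched_network (%s): %d nodes, %d MI edges, %d processes, %d annotation edges\n",
    x$group, nrow(x$nodes), nrow(x$edges), length(x$process_nodes),
    nrow(x$annotation_edges)
  ))
  invisible(x)
}

# MI edge classes permitted in an enriched network
.enriched_classes <- c("CpG-transcript", "transcript-miRNA", "transcript-transcript")

#' Prune an MI network to its enriched processes
#'
#' Seed nodes are the transcripts annotated to at least one represented
#' process; the retained subgraph is the seeds plus their MI first
#' neighbors. MI edges survive iff both endpoints are retained AND the
#' edge class is CpG-transcript, transcript-miRNA or
#' transcript-transcript. Process nodes are added with annotation edges
#' to their retained member transcripts.
#'
#' @param network an [mi_network()].
#' @param represented named list: process id -> member transcript ids
#'   (only represented processes).
#' @return an [enriched_network()].
#' @export
prune_to_enriched <- function(network, represented) {
  stopifnot(inherits(network, "mi_network"))
  node_ids <- network$nodes$id
  seeds <- intersect(unique(unlist(represented)), node_ids)
  if (length(seeds) == 0) {
    if (length(represented) > 0) {
      warnf("no annotated transcript found in the network; result is empty")
    }
    return(enriched_network(
      network$nodes[0, , drop = FALSE], network$edges[0, , drop = FALSE],
      character(),
      data.frame(
        process = character(), transcript = character(),
        stringsAsFactors = FALSE
      ),
      network$group
    ))
  }
  e <- network$edges
  touch <- e$node_a %in% seeds | e$node_b %in% seeds
  retained <- union(seeds, unique(c(e$node_a[touch], e$node_b[touch])))
  keep <- e$node_a %in% retained & e$node_b %in% retained &
    e$pair_class %in% .enriched_classes
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- network$nodes[network$nodes$id %in% retained, , drop = FALSE]
  rownames(nodes) <- NULL
  ann <- do.call(rbind, lapply(names(represented), function(pr) {
    tx <- intersect(represented[[pr]], seeds)
    if (length(tx) == 0) {
      return(NULL)
    }
    data.frame(process = pr, transcript = tx, stringsAsFactors = FALSE)
  }))
  if (is.null(ann)) {
    ann <- data.frame(
      process = character(), transcript = character(),
      stringsAsFactors = FALSE
    )
  }
  enriched_network(
    nodes, edges, sort(unique(ann$process)), ann, network$group
  )
}

#' @export
as_igraph.enriched_network <- function(x) {
  mi_e <- x$edges
  if (nrow(mi_e) > 0) {
    mi_e <- data.frame(
      from = mi_e$node_a, to = mi_e$node_b, kind = "MI",
      pair_class = mi_e$pair_class, mi = mi_e$mi, stringsAsFactors = FALSE
    )
  } else {
    mi_e <- data.frame(
      from = character(), to = character(), kind = character(),
      pair_class = character(), mi = numeric(), stringsAsFactors = FALSE
    )
  }
  ann_e <- x$annotation_edges
  if (nrow(ann_e) > 0) {
    ann_e <- data.frame(
      from = ann_e$process, to = ann_e$transcript, kind = "annotation",
      pair_class = NA_character_, mi = NA_real_, stringsAsFactors = FALSE
    )
  } else {
    ann_e <- mi_e[0, , drop = FALSE]
  }
  vertices <- rbind(
    data.frame(
      name = x$nodes$id, layer = x$nodes$layer, is_tf = x$nodes$is_tf,
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = x$process_nodes,
      layer = rep("process", length(x$process_nodes)),
      is_tf = rep(FALSE, length(x$process_nodes)),
      stringsAsFactors = FALSE
    )
  )
  igraph::graph_from_data_frame(
    rbind(mi_e, ann_e),
    directed = FALSE, vertices = vertices
  )
}

#' Write an enriched network as TSV (nodes + both edge kinds)
#' @param net an `enriched_network`.
#' @param prefix path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv` (annotation rows have `kind = "annotation"`).
#' @return the two paths, invisibly.
#' @export
write_enriched_network <- function(net, prefix) {
  nodes <- rbind(
    net$nodes,
    data.frame(
      id = net$process_nodes,
      layer = rep("process", length(net$process_nodes)),
      is_tf = rep(FALSE, length(net$process_nodes)),
      stringsAsFactors = FALSE
    )
  )
  mi_e <- data.frame(
    node_a = net$edges$node_a, node_b = net$edges$node_b, kind = "MI",
    pair_class = net$edges$pair_class, mi = net$edges$mi,
    stringsAsFactors = FALSE
  )
  ann_e <- data.frame(
    node_a = net$annotation_edges$process,
    node_b = net$annotation_edges$transcript,
    kind = "annotation", pair_class = NA_character_, mi = NA_real_,
    stringsAsFactors = FALSE
  )
  np <- paste0(prefix, "_nodes.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rbind(mi_e, ann_e), ep,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(np, ep))
}

#' Read an enriched network written by [write_enriched_network()]
#' @param prefix path prefix.
#' @param group group label.
#' @return an [enriched_network()].
#' @export
read_enriched_network <- function(prefix, group = NA_character_) {
  nodes <- read.delim(paste0(prefix, "_nodes.tsv"), stringsAsFactors = FALSE)
  edges <- read.delim(paste0(prefix, "_edges.tsv"), stringsAsFactors = FALSE)
  procs <- nodes$id[nodes$layer == "process"]
  mi_e <- edges[edges$kind == "MI", c("node_a", "node_b", "pair_class", "mi"),
    drop = FALSE
  ]
  rownames(mi_e) <- NULL
  ann <- edges[edges$kind == "annotation", , drop = FALSE]
  ann <- data.frame(
    process = ann$node_a, transcript = ann$node_b, stringsAsFactors = FALSE
  )
  enriched_network(
    nodes[nodes$layer != "process", , drop = FALSE], mi_e, procs, ann, group
  )
}
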