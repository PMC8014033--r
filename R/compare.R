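# Regulator layers considered throughout the comparisons.
.regulator_types <- c("CpG", "TF-gene", "miRNA")

# Regulator type of a node given its layer and TF flag; transcripts that
# are not TF-genes are targets, not regulators (NA).
node_regulator_type <- function(layer, is_tf) {
  ifelse(layer == "CpG", "CpG",
    ifelse(layer == "miRNA", "miRNA",
      ifelse(layer == "transcript" & is_tf, "TF-gene", NA_character_)
    )
  )
}

#' Potential-regulator profiles per biological process
#'
#' For every process node, the regulators of each type (CpG, TF-gene,
#' miRNA) are the nodes of that type adjacent by an MI edge to at least
#' one transcript annotated to the process. TF-flagged transcripts count
#' as TF-genes. Counts are set sizes; proportions divide by the total
#' number of regulators of the process (flagged undefined when the total
#' is 0).
#'
#' @param net an [enriched_network()] with at least one process node.
#' @return a `regulator_profiles` object: named list (per process) of
#'   lists with `counts`, `proportions`, `regulator_ids`; see also
#'   [as.data.frame.regulator_profiles()].
#' @export
regulator_profiles <- function(net) {
  stopifnot(inherits(net, "enriched_network"))
  if (length(net$process_nodes) == 0) stopf("network has no process node")
  type_of <- setNames(
    node_regulator_type(net$nodes$layer, net$nodes$is_tf), net$nodes$id
  )
  e <- net$edges
  profiles <- lapply(net$process_nodes, function(pr) {
    tx <- net$annotation_edges$transcript[net$annotation_edges$process == pr]
    inc_a <- e$node_a %in% tx
    inc_b <- e$node_b %in% tx
    nb <- unique(c(e$node_b[inc_a], e$node_a[inc_b]))
    nb_type <- type_of[nb]
    ids <- lapply(.regulator_types, function(tp) {
      sort(nb[!is.na(nb_type) & nb_type == tp])
    })
    names(ids) <- .regulator_types
    counts <- vapply(ids, length, integer(1))
    total <- sum(counts)
    props <- if (total > 0) counts / total else setNames(
      rep(NA_real_, length(counts)), names(counts)
    )
    list(
      process = pr, counts = counts, proportions = props,
      regulator_ids = ids, total = total
    )
  })
  names(profiles) <- net$process_nodes
  structure(profiles, class = "regulator_profiles", group = net$group)
}

#' Flatten regulator profiles to a data frame
#' @param x a `regulator_profiles` object.
#' @param ... unused.
#' @return long data frame (`process`, `type`, `count`, `proportion`).
#' @export
as.data.frame.regulator_profiles <- function(x, ...) {
  rbind_rows(c(unname(lapply(x, function(p) {
    data.frame(
      process = p$process, type = names(p$counts),
      count = unname(p$counts), proportion = unname(p$proportions),
      stringsAsFactors = FALSE
    )
  }))))
}

#' One-tailed Fisher enrichment of regulator types vs the normal tissue
#'
#' For each process with regulators of any type in both networks, each
#' regulator type is tested on the 2x2 table
#' `[[count_type, count_other_types], [count_type_normal,
#' count_other_types_normal]]` with a one-tailed Fisher exact test -
#' alternative "greater" for CpG and "less" for TF-genes and miRNAs
#' (the null is set opposite to the expected trends). BH correction runs
#' across all (process, type) tests performed; skipped processes are
#' recorded with NA.
#'
#' @param subtype_profiles,normal_profiles `regulator_profiles` of the
#'   subtype and normal networks.
#' @return data frame: `process`, `type`, counts, `alternative`, `p`,
#'   `q`, `tested`.
#' @export
fisher_regulator_enrichment <- function(subtype_profiles, normal_profiles) {
  procs <- intersect(names(subtype_profiles), names(normal_profiles))
  alts <- c(CpG = "greater", `TF-gene` = "less", miRNA = "less")
  rows <- list()
  for (pr in procs) {
    ps <- subtype_profiles[[pr]]
    pn <- normal_profiles[[pr]]
    tested <- ps$total > 0 && pn$total > 0
    for (tp in .regulator_types) {
      a <- ps$counts[[tp]]
      b <- ps$total - a
      c_ <- pn$counts[[tp]]
      d <- pn$total - c_
      p <- NA_real_
      if (tested) {
        p <- fisher.test(
          matrix(c(a, b, c_, d), 2, byrow = TRUE),
          alternative = alts[[tp]]
        )$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        process = pr, type = tp, count_subtype = a, other_subtype = b,
        count_normal = c_, other_normal = d, alternative = alts[[tp]],
        p = p, tested = tested, stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind_rows(c(rows))
  if (is.null(out)) stopf("no process shared between the two networks")
  out$q <- NA_real_
  out$q[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  out
}

#' Node topology of the MI subgraph
#'
#' Computed on MI edges only (process nodes and annotation edges are
#' excluded): per-node degree, per-layer degree distributions, the
#' distribution of finite shortest-path lengths (unweighted hop counts,
#' each unordered pair once), connected-component count, and the
#' unreachable-target fraction per regulator layer - for each regulator
#' node, the share of transcript nodes it cannot reach, averaged over
#' the regulator nodes of the layer.
#'
#' @param net an [enriched_network()] or [mi_network()].
#' @return a `topology_summary`: `degrees` (data frame `node`, `layer`,
#'   `is_tf`, `degree`), `path_lengths`, `n_components`, `unreachable`
#'   (data frame `layer`, `fraction`, `n_regulators`).
#' @export
topology_stats <- function(net) {
  nodes <- net$nodes
  if (nrow(net$edges) == 0) stopf("MI subgraph is empty")
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = nodes$id
  )
  deg <- igraph::degree(g)
  degrees <- data.frame(
    node = names(deg), layer = nodes$layer[match(names(deg), nodes$id)],
    is_tf = nodes$is_tf[match(names(deg), nodes$id)],
    degree = unname(deg), stringsAsFactors = FALSE
  )
  D <- igraph::distances(g)
  ut <- D[upper.tri(D)]
  path_lengths <- ut[is.finite(ut) & ut >= 1]
  comp <- igraph::components(g)$no
  reg_type <- node_regulator_type(degrees$layer, degrees$is_tf)
  targets <- degrees$node[degrees$layer == "transcript"]
  unreach <- do.call(rbind, lapply(.regulator_types, function(tp) {
    regs <- degrees$node[!is.na(reg_type) & reg_type == tp]
    if (length(regs) == 0 || length(targets) == 0) {
      return(data.frame(
        layer = tp, fraction = NA_real_, n_regulators = length(regs),
        stringsAsFactors = FALSE
      ))
    }
    fr <- vapply(regs, function(r) {
      tg <- setdiff(targets, r)
      if (length(tg) == 0) {
        return(NA_real_)
      }
      mean(!is.finite(D[r, tg]))
    }, numeric(1))
    data.frame(
      layer = tp, fraction = mean(fr, na.rm = TRUE),
      n_regulators = length(regs), stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      degrees = degrees, path_lengths = path_lengths,
      n_components = comp, unreachable = unreach
    ),
    class = "topology_summary"
  )
}

#' Compare topology distributions across layers and networks
#'
#' Two-sample Wilcoxon rank-sum tests (normal approximation with
#' continuity correction): degree distributions for every layer pair
#' within a network and every network pair within a layer, plus
#' path-length distributions for every network pair. BH correction runs
#' over all tests; distributions with fewer than 2 values are skipped
#' with a message.
#'
#' @param summaries named list of [topology_stats()] results.
#' @return data frame: `metric`, `scope`, `network_a`, `network_b`,
#'   `layer_a`, `layer_b`, `statistic`, `p`, `q`.
#' @export
compare_node_distributions <- function(summaries) {
  stopifnot(length(summaries) >= 1, !is.null(names(summaries)))
  deg_dists <- lapply(summaries, function(s) {
    split(s$degrees$degree, s$degrees$layer)
  })
  rows <- list()
  add <- function(metric, scope, na, nb, la, lb, x, y) {
    if (length(x) < 2 || length(y) < 2) {
      msgf("skipping %s %s/%s vs %s/%s: fewer than 2 values", metric, na, la, nb, lb)
      return()
    }
    wt <- suppressWarnings(
      wilcox.test(x, y, correct = TRUE, exact = FALSE)
    )
    rows[[length(rows) + 1]] <<- data.frame(
      metric = metric, scope = scope, network_a = na, network_b = nb,
      layer_a = la, layer_b = lb, statistic = unname(wt$statistic),
      p = wt$p.value, stringsAsFactors = FALSE
    )
  }
  for (nw in names(deg_dists)) {
    layers <- sort(names(deg_dists[[nw]]))
    if (length(layers) >= 2) {
      for (pair in combn(layers, 2, simplify = FALSE)) {
        add(
          "degree", "within_network", nw, nw, pair[1], pair[2],
          deg_dists[[nw]][[pair[1]]], deg_dists[[nw]][[pair[2]]]
        )
      }
    }
  }
  if (length(summaries) >= 2) {
    for (pair in combn(sort(names(summaries)), 2, simplify = FALSE)) {
      shared <- intersect(
        names(deg_dists[[pair[1]]]), names(deg_dists[[pair[2]]])
      )
      for (la in sort(shared)) {
        add(
          "degree", "between_networks", pair[1], pair[2], la, la,
          deg_dists[[pair[1]]][[la]], deg_dists[[pair[2]]][[la]]
        )
      }
      add(
        "path_length", "between_networks", pair[1], pair[2], "all", "all",
        summaries[[pair[1]]]$path_lengths, summaries[[pair[2]]]$path_lengths
      )
    }
  }
  out <- rbind_rows(c(rows))
  if (is.null(out)) {
    return(data.frame(
      metric = character(), scope = character(), network_a = character(),
      network_b = character(), layer_a = character(), layer_b = character(),
      statistic = numeric(), p = numeric(), q = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Jaccard index of two id sets
#'
#' `|intersection| / |union|`; when both sets are empty the index is
#' undefined and `NA` is returned with attribute `undefined`.
#'
#' @param a,b character vectors (treated as sets).
#' @return numeric in \[0,1\], or flagged NA.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  length(intersect(a, b)) / length(u)
}

#' Intra-network regulator sharing between processes
#'
#' Per regulator type: the node-set Jaccard index for every pair of
#' processes, and a one-tailed Fisher test of exclusivity - each
#' regulator is exclusive (appears in exactly one process) or shared
#' (two or more); the 2x2 table is `[[exclusive_type, shared_type],
#' [exclusive_other, shared_other]]` with alternative "greater" for CpG
#' sites and "less" for TF-genes and miRNAs, BH-corrected across types.
#'
#' @param profiles a `regulator_profiles` object (one network).
#' @return list with `jaccard` (data frame `type`, `process_a`,
#'   `process_b`, `jaccard`, `size_a`, `size_b`) and `fisher` (data
#'   frame per type).
#' @export
intra_subtype_sharing <- function(profiles) {
  stopifnot(inherits(profiles, "regulator_profiles"))
  procs <- names(profiles)
  alts <- c(CpG = "greater", `TF-gene` = "less", miRNA = "less")
  jrows <- list()
  if (length(procs) >= 2) {
    for (pair in combn(procs, 2, simplify = FALSE)) {
      for (tp in .regulator_types) {
        sa <- profiles[[pair[1]]]$regulator_ids[[tp]]
        sb <- profiles[[pair[2]]]$regulator_ids[[tp]]
        jrows[[length(jrows) + 1]] <- data.frame(
          type = tp, process_a = pair[1], process_b = pair[2],
          jaccard = as.numeric(jaccard(sa, sb)),
          size_a = length(sa), size_b = length(sb),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  jdf <- rbind_rows(c(jrows))
  if (is.null(jdf)) {
    jdf <- data.frame(
      type = character(), process_a = character(), process_b = character(),
      jaccard = numeric(), size_a = integer(), size_b = integer(),
      stringsAsFactors = FALSE
    )
  }
  # exclusive/shared classification per regulator, per type
  counts <- lapply(.regulator_types, function(tp) {
    all_ids <- unlist(lapply(profiles, function(p) p$regulator_ids[[tp]]))
    tab <- table(all_ids)
    c(exclusive = sum(tab == 1), shared = sum(tab >= 2))
  })
  names(counts) <- .regulator_types
  frows <- lapply(.regulator_types, function(tp) {
    a <- counts[[tp]][["exclusive"]]
    b <- counts[[tp]][["shared"]]
    oth <- Reduce(`+`, counts[setdiff(.regulator_types, tp)])
    p <- fisher.test(
      matrix(c(a, b, oth[["exclusive"]], oth[["shared"]]), 2, byrow = TRUE),
      alternative = alts[[tp]]
    )$p.value
    data.frame(
      type = tp, exclusive = a, shared = b,
      exclusive_other = oth[["exclusive"]], shared_other = oth[["shared"]],
      alternative = alts[[tp]], p = p, stringsAsFactors = FALSE
    )
  })
  fdf <- rbind_rows(c(frows))
  fdf$q <- p.adjust(fdf$p, method = "BH")
  list(jaccard = jdf, fisher = fdf)
}

# Regulator-incident MI edge keys of one process in one network, per type.
process_edge_sets <- function(net, process) {
  tx <- net$annotation_edges$transcript[net$annotation_edges$process == process]
  type_of <- setNames(
    node_regulator_type(net$nodes$layer, net$nodes$is_tf), net$nodes$id
  )
  e <- net$edges
  inc_a <- e$node_a %in% tx
  inc_b <- e$node_b %in% tx
  other <- ifelse(inc_a, e$node_b, e$node_a)
  sel <- inc_a | inc_b
  out <- lapply(.regulator_types, function(tp) {
    pick <- sel & !is.na(type_of[other]) & type_of[other] == tp
    unique(edge_key(e$node_a[pick], e$node_b[pick], e$pair_class[pick]))
  })
  names(out) <- .regulator_types
  out
}

#' Inter-network sharing of regulator interactions
#'
#' For each process present in both networks of a pair and each
#' regulator type, the Jaccard index over the sets of regulator-incident
#' MI edges (edge identity = unordered endpoint pair + pair class)
#' touching the process's annotated transcripts. The per-(network pair,
#' type) Jaccard distributions over processes are then compared with
#' two-sample KS tests between every pair of distributions,
#' BH-corrected.
#'
#' @param nets named list of [enriched_network()] objects (at least two,
#'   sharing at least one process).
#' @return list with `jaccard` (data frame `network_a`, `network_b`,
#'   `process`, `type`, `jaccard`, `size_a`, `size_b`) and `ks` (data
#'   frame `dist_a`, `dist_b`, `statistic`, `p`, `q`).
#' @export
inter_subtype_sharing <- function(nets) {
  stopifnot(length(nets) >= 2, !is.null(names(nets)))
  jrows <- list()
  for (pair in combn(sort(names(nets)), 2, simplify = FALSE)) {
    na <- pair[1]
    nb <- pair[2]
    shared <- intersect(nets[[na]]$process_nodes, nets[[nb]]$process_nodes)
    for (pr in sort(shared)) {
      ea <- process_edge_sets(nets[[na]], pr)
      eb <- process_edge_sets(nets[[nb]], pr)
      for (tp in .regulator_types) {
        jrows[[length(jrows) + 1]] <- data.frame(
          network_a = na, network_b = nb, process = pr, type = tp,
          jaccard = as.numeric(jaccard(ea[[tp]], eb[[tp]])),
          size_a = length(ea[[tp]]), size_b = length(eb[[tp]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  jdf <- rbind_rows(c(jrows))
  if (is.null(jdf)) stopf("the networks share no process")
  dists <- split(
    jdf$jaccard[!is.na(jdf$jaccard)],
    paste(jdf$network_a, jdf$network_b, jdf$type, sep = "|")[!is.na(jdf$jaccard)]
  )
  dists <- dists[vapply(dists, length, integer(1)) >= 2]
  krows <- list()
  if (length(dists) >= 2) {
    for (pair in combn(sort(names(dists)), 2, simplify = FALSE)) {
      kt <- suppressWarnings(ks.test(dists[[pair[1]]], dists[[pair[2]]]))
      krows[[length(krows) + 1]] <- data.frame(
        dist_a = pair[1], dist_b = pair[2],
        statistic = unname(kt$statistic), p = kt$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  kdf <- rbind_rows(c(krows))
  if (is.null(kdf)) {
    kdf <- data.frame(
      dist_a = character(), dist_b = character(), statistic = numeric(),
      p = numeric(), q = numeric(), stringsAsFactors = FALSE
    )
  } else {
    kdf$q <- p.adjust(kdf$p, method = "BH")
  }
  list(jaccard = jdf, ks = kdf)
}

#' Cross-reference regulator-incident edges against a reference table
#'
#' Labels every MI edge with at least one regulator endpoint with exactly
#' one of: `validated` (present in the reference with evidence class
#' "validated"), `mapped` (a CpG endpoint whose annotated `mapped_gene`
#' is the other endpoint), `same-chromosome` (a CpG endpoint on the same
#' chromosome as the other endpoint), `predicted` (present in the
#' reference under any other evidence class), or `unsupported`.
#' Reference rows match an edge regardless of orientation. Regulator
#' endpoints absent from the feature metadata are counted unsupported
#' with a warning.
#'
#' @param net an [enriched_network()] or [mi_network()].
#' @param reference data frame (`regulator`, `target`, `evidence_class`);
#'   may be NULL or empty.
#' @param feature_meta feature metadata with `feature_id`, `chromosome`,
#'   `mapped_gene`.
#' @return list with `edges` (labeled edge table) and `fractions`
#'   (per pair class, fraction of each label; fractions sum to 1).
#' @export
cross_reference_edges <- function(net, reference, feature_meta) {
  e <- net$edges
  type_of <- setNames(
    node_regulator_type(net$nodes$layer, net$nodes$is_tf), net$nodes$id
  )
  has_reg <- !is.na(type_of[e$node_a]) | !is.na(type_of[e$node_b])
  e <- e[has_reg, , drop = FALSE]
  if (nrow(e) == 0) stopf("no regulator-incident MI edge in the network")
  meta_idx <- match(e$node_a, feature_meta$feature_id)
  meta_idx_b <- match(e$node_b, feature_meta$feature_id)
  if (anyNA(meta_idx) || anyNA(meta_idx_b)) {
    warnf("some edge endpoints are absent from feature_meta; labeled unsupported")
  }
  ref_keys_valid <- character()
  ref_keys_other <- character()
  if (!is.null(reference) && nrow(reference) > 0) {
    cls <- reference$evidence_class %||% rep("predicted", nrow(reference))
    k <- paste(
      pmin(reference$regulator, reference$target),
      pmax(reference$regulator, reference$target),
      sep = "|"
    )
    ref_keys_valid <- k[cls == "validated"]
    ref_keys_other <- k[cls != "validated"]
  }
  ekey <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b), sep = "|")
  chrom <- setNames(feature_meta$chromosome, feature_meta$feature_id)
  mapped <- setNames(feature_meta$mapped_gene, feature_meta$feature_id)
  layer <- setNames(feature_meta$layer, feature_meta$feature_id)
  label <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    a <- e$node_a[i]
    b <- e$node_b[i]
    # orient the CpG endpoint (if any) as the site whose annotation is used
    cpg <- if (!is.na(layer[a]) && layer[a] == "CpG") {
      a
    } else if (!is.na(layer[b]) && layer[b] == "CpG") {
      b
    } else {
      NA_character_
    }
    other <- if (is.na(cpg)) NA_character_ else setdiff(c(a, b), cpg)[1]
    label[i] <- if (ekey[i] %in% ref_keys_valid) {
      "validated"
    } else if (!is.na(cpg) && !is.na(mapped[cpg]) && identical(
      unname(mapped[cpg]), other
    )) {
      "mapped"
    } else if (!is.na(cpg) && !is.na(chrom[cpg]) && !is.na(chrom[other]) &&
      chrom[cpg] == chrom[other]) {
      "same-chromosome"
    } else if (ekey[i] %in% ref_keys_other) {
      "predicted"
    } else {
      "unsupported"
    }
  }
  e$label <- label
  labels <- c("validated", "mapped", "same-chromosome", "predicted", "unsupported")
  fr <- do.call(rbind, lapply(split(e, e$pair_class), function(d) {
    data.frame(
      pair_class = d$pair_class[1], label = labels,
      fraction = as.numeric(table(factor(d$label, levels = labels))) / nrow(d),
      n = as.integer(table(factor(d$label, levels = labels))),
      stringsAsFactors = FALSE
    )
  }))
  rownames(fr) <- NULL
  list(edges = e, fractions = fr)
}
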