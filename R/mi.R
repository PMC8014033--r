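#' Mutual-information network configuration
#'
#' Houses the kernel bandwidth rule, per-class top-k size, permutation
#' and subsampling parameters, and the excluded pair classes.
#'
#' The default bandwidth presets are keyed by sample size and correspond
#' to the five cohort sizes the pipeline was designed around: h =
#' 0.165024 (n = 125, Basal), 0.211612 (n = 45, Her2+), 0.12527 (n = 395,
#' LumA), 0.16567 (n = 128, LumB) and 0.18679 (n = 75, normal tissue).
#' For other sample sizes "auto" interpolates a power law fitted to the
#' presets (see [resolve_bandwidth()]).
#'
#' @param bandwidth positive numeric, or "auto".
#' @param top_k edges retained per pair class (default 10000).
#' @param n_permutations permutations for [permutation_pvalue()].
#' @param n_subsamples,subsample_size subsampling scheme for
#'   [subsample_zscores()] (default 100 subsamples of size 45).
#' @param excluded_classes pair classes never scored (default CpG-CpG).
#' @param seed integer seed for permutation and subsampling draws.
#' @param bandwidth_presets named numeric vector, names are sample sizes.
#' @param n_pvalue_edges in [run_pipeline()], number of top edges per
#'   class given permutation p-values and subsampling z-scores.
#' @return an `mi_config` list.
#' @export
mi_config <- function(bandwidth = "auto", top_k = 10000,
                      n_permutations = 1000, n_subsamples = 100,
                      subsample_size = 45,
                      excluded_classes = "CpG-CpG", seed = 1,
                      bandwidth_presets = c(
                        `45` = 0.211612, `75` = 0.18679, `125` = 0.165024,
                        `128` = 0.16567, `395` = 0.12527
                      ),
                      n_pvalue_edges = 100) {
  cfg <- list(
    bandwidth = bandwidth, top_k = as.integer(top_k),
    n_permutations = as.integer(n_permutations),
    n_subsamples = as.integer(n_subsamples),
    subsample_size = as.integer(subsample_size),
    excluded_classes = excluded_classes, seed = as.integer(seed),
    bandwidth_presets = bandwidth_presets,
    n_pvalue_edges = as.integer(n_pvalue_edges)
  )
  stopifnot(
    identical(cfg$bandwidth, "auto") ||
      (is.numeric(cfg$bandwidth) && cfg$bandwidth > 0),
    cfg$top_k >= 1, cfg$n_permutations >= 1, cfg$n_subsamples >= 1,
    cfg$subsample_size >= 5,
    all(cfg$excluded_classes %in% pair_classes()),
    length(cfg$bandwidth_presets) >= 2, all(cfg$bandwidth_presets > 0)
  )
  structure(cfg, class = "mi_config")
}

#' Copula (rank) transform
#'
#' Replaces values by `rank/(n+1)` with average ranks for ties, giving a
#' near-uniform marginal on (0,1). The output is invariant under any
#' strictly monotone transform of the input, which lets a single fixed
#' kernel bandwidth serve omics with disparate dynamic ranges. A constant
#' input maps to all 0.5 and is flagged with attribute `degenerate`.
#'
#' @param values numeric vector, length at least 2.
#' @return numeric vector in (0,1).
#' @export
copula_transform <- function(values) {
  n <- length(values)
  if (n < 2) stopf("copula transform needs at least 2 values")
  r <- rank(values, ties.method = "average") / (n + 1)
  if (length(unique(values)) == 1L) attr(r, "degenerate") <- TRUE
  r
}

#' Resolve the kernel bandwidth for a sample size
#'
#' A numeric `bandwidth` in the config is returned as-is. Under "auto",
#' an exact preset match for `n_samples` is returned if present;
#' otherwise the bandwidth follows the power law `a * n^b` fitted by
#' least squares on `log h ~ log n` over the presets (for the default
#' presets: a = 0.5295839, b = -0.2408892).
#'
#' @param n_samples sample size (at least 5).
#' @param config an [mi_config()].
#' @return positive bandwidth.
#' @export
resolve_bandwidth <- function(n_samples, config = mi_config()) {
  stopifnot(n_samples >= 5)
  if (is.numeric(config$bandwidth)) {
    return(config$bandwidth)
  }
  presets <- config$bandwidth_presets
  hit <- match(as.character(n_samples), names(presets))
  if (!is.na(hit)) {
    return(unname(presets[hit]))
  }
  ns <- as.numeric(names(presets))
  fit <- lm(log(presets) ~ log(ns))
  unname(exp(coef(fit)[1]) * n_samples^coef(fit)[2])
}

#' Kernel mutual information of one pair
#'
#' Plug-in resubstitution estimate in nats,
#' `MI = (1/n) sum_i log( f2(x_i, y_i) / (f1(x_i) f1(y_i)) )`,
#' with `f1` a 1-D Gaussian kernel density of bandwidth `h` and `f2` the
#' 2-D product kernel with diagonal bandwidth (h, h), both averaged over
#' all n kernels. Negative estimates (which occur near independence) are
#' clamped to 0; the raw value is kept in attribute `raw`. The estimate
#' is exactly symmetric in (x, y).
#'
#' @param x,y copula-transformed vectors of equal length (n >= 5).
#' @param h kernel bandwidth (> 0).
#' @return MI in nats (>= 0), with attribute `raw`.
#' @export
mi_pair <- function(x, y, h) {
  if (length(x) != length(y)) stopf("x and y must have the same length")
  if (length(x) < 5) stopf("MI estimation needs at least 5 samples")
  stopifnot(h > 0)
  raw <- mi_pair_cpp(as.numeric(x), as.numeric(y), h)
  structure(max(raw, 0), raw = raw)
}

#' Score every admissible feature pair by mutual information
#'
#' Computes kernel MI for every unordered pair of features whose pair
#' class is not excluded (by default CpG-CpG pairs are never scored; no
#' chromosome or motif restriction is applied). Each layer's rows are
#' copula-transformed, and the bandwidth is resolved once from the
#' common sample size.
#'
#' @param data a `normalized_dataset` (or any list with sample-aligned
#'   matrices `cpg_m`, `transcript_expr`, `mirna_expr`; any may be NULL)
#'   and optionally `feature_meta`.
#' @param config an [mi_config()].
#' @return data frame of edge candidates (`node_a`, `node_b`,
#'   `pair_class`, `mi`, `mi_raw`), with node layer/TF metadata attached
#'   as attributes `node_layers` and `node_is_tf`.
#' @export
mi_all_pairs <- function(data, config = mi_config()) {
  layers <- list(
    CpG = data$cpg_m, transcript = data$transcript_expr,
    miRNA = data$mirna_expr
  )
  layers <- layers[!vapply(layers, is.null, logical(1))]
  if (length(layers) == 0) stopf("no omic matrices supplied")
  ns <- vapply(layers, ncol, integer(1))
  if (length(unique(ns)) != 1) stopf("matrices are not sample-aligned")
  n <- ns[[1]]
  if (n < 5) stopf("MI estimation needs at least 5 samples")
  h <- resolve_bandwidth(n, config)

  U <- lapply(layers, function(m) {
    u <- t(apply(m, 1, copula_transform))
    dimnames(u) <- dimnames(m)
    u
  })

  combos <- list()
  layer_names <- names(layers)
  for (i in seq_along(layer_names)) {
    for (j in i:length(layer_names)) {
      cls <- pair_class_of(layer_names[i], layer_names[j])
      if (cls %in% config$excluded_classes) next
      combos[[cls]] <- c(layer_names[i], layer_names[j])
    }
  }

  out <- list()
  for (cls in names(combos)) {
    la <- combos[[cls]][1]
    lb <- combos[[cls]][2]
    if (la == lb) {
      m <- U[[la]]
      if (nrow(m) < 2) next
      mi <- mi_cross_cpp(m, m, h, TRUE)
      idx <- which(upper.tri(mi), arr.ind = TRUE)
      a <- rownames(m)[idx[, 1]]
      b <- rownames(m)[idx[, 2]]
      swap <- b < a
      ea <- ifelse(swap, b, a)
      eb <- ifelse(swap, a, b)
      vals <- mi[idx]
    } else {
      ma <- U[[la]]
      mb <- U[[lb]]
      if (nrow(ma) == 0 || nrow(mb) == 0) next
      mi <- mi_cross_cpp(ma, mb, h, FALSE)
      ea <- rownames(ma)[row(mi)]
      eb <- rownames(mb)[col(mi)]
      vals <- as.vector(mi)
    }
    out[[cls]] <- data.frame(
      node_a = ea, node_b = eb, pair_class = cls,
      mi = pmax(vals, 0), mi_raw = vals, stringsAsFactors = FALSE
    )
  }
  cand <- if (length(out)) {
    rbind_rows(c(out))
  } else {
    data.frame(
      node_a = character(), node_b = character(),
      pair_class = character(), mi = numeric(), mi_raw = numeric(),
      stringsAsFactors = FALSE
    )
  }
  node_layers <- unlist(lapply(names(layers), function(l) {
    setNames(rep(l, nrow(layers[[l]])), rownames(layers[[l]]))
  }))
  is_tf <- setNames(rep(FALSE, length(node_layers)), names(node_layers))
  meta <- data$feature_meta
  if (!is.null(meta)) {
    hit <- intersect(names(is_tf), meta$feature_id[meta$is_tf])
    is_tf[hit] <- TRUE
  }
  attr(cand, "node_layers") <- node_layers
  attr(cand, "node_is_tf") <- is_tf
  attr(cand, "bandwidth") <- h
  attr(cand, "n_samples") <- n
  cand
}

#' Construct an MI network object
#'
#' @param nodes data frame with columns `id`, `layer`, `is_tf`.
#' @param edges data frame with columns `node_a`, `node_b`, `pair_class`,
#'   `mi` (further columns kept).
#' @param group group label the network belongs to.
#' @return an `mi_network`.
#' @export
mi_network <- function(nodes, edges, group = NA_character_) {
  stopifnot(
    all(c("id", "layer", "is_tf") %in% colnames(nodes)),
    all(c("node_a", "node_b", "pair_class", "mi") %in% colnames(edges))
  )
  if (any(edges$node_a == edges$node_b)) stopf("self-edges are not allowed")
  if (anyDuplicated(edge_key(edges$node_a, edges$node_b, edges$pair_class))) {
    stopf("duplicate unordered edge")
  }
  if (anyDuplicated(nodes$id)) stopf("duplicate node ids")
  structure(
    list(nodes = nodes, edges = edges, group = group),
    class = "mi_network"
  )
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf(
    "mi_network (%s): %d nodes, %d edges in %d pair classes\n",
    x$group, nrow(x$nodes), nrow(x$edges),
    length(unique(x$edges$pair_class))
  ))
  invisible(x)
}

#' Select the top-k edges of every pair class
#'
#' Within each pair class independently, retains the `top_k` candidates
#' with the highest MI (all of them when fewer exist). Ties at the cutoff
#' break deterministically by lexicographic (node_a, node_b). Classes are
#' never pooled.
#'
#' @param candidates candidate data frame from [mi_all_pairs()].
#' @param top_k edges retained per class.
#' @param group group label for the resulting network.
#' @return an [mi_network()].
#' @export
select_top_k <- function(candidates, top_k = 10000, group = NA_character_) {
  stopifnot(top_k >= 1)
  picked <- lapply(split(candidates, candidates$pair_class), function(d) {
    o <- order(-d$mi, d$node_a, d$node_b)
    d[o[seq_len(min(top_k, nrow(d)))], , drop = FALSE]
  })
  edges <- rbind_rows(c(unname(picked)))
  if (is.null(edges)) {
    edges <- candidates[0, , drop = FALSE]
  }
  o <- order(edges$pair_class, -edges$mi, edges$node_a, edges$node_b)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  ids <- unique(c(edges$node_a, edges$node_b))
  layers <- attr(candidates, "node_layers")
  is_tf <- attr(candidates, "node_is_tf")
  nodes <- data.frame(
    id = ids,
    layer = if (is.null(layers)) NA_character_ else unname(layers[ids]),
    is_tf = if (is.null(is_tf)) FALSE else unname(is_tf[ids]),
    stringsAsFactors = FALSE
  )
  mi_network(nodes, edges, group)
}

#' Permutation p-value for one pair's MI
#'
#' `p = (1 + #{permutations with MI >= observed}) / (n_permutations + 1)`,
#' permuting `y` with a seeded generator. Comparison uses the raw
#' (unclamped) estimates.
#'
#' @param x,y copula-transformed vectors.
#' @param h bandwidth.
#' @param n_permutations number of permutations.
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(x, y, h, n_permutations = 1000, seed = 1) {
  obs <- attr(mi_pair(x, y, h), "raw")
  n <- length(x)
  perms <- with_seed(seed, {
    matrix(
      unlist(lapply(seq_len(n_permutations), function(i) sample.int(n))),
      nrow = n
    )
  })
  null <- mi_perm_cpp(as.numeric(x), as.numeric(y), h, perms)
  (1 + sum(null >= obs)) / (n_permutations + 1)
}

#' Subsampling z-scores for network edges
#'
#' For each edge, MI is recomputed on `n_subsamples` seeded subsamples of
#' `subsample_size` samples drawn without replacement (the bandwidth is
#' re-resolved at the subsample size, so a preset size such as 45 uses
#' its preset bandwidth), and
#' `z = (MI_full - mean(MI_sub)) / sd(MI_sub)`. A zero subsample standard
#' deviation yields `NA` with `z_defined = FALSE` rather than an error.
#'
#' @param data a `normalized_dataset` (raw per-feature values are pulled
#'   from its matrices by feature id).
#' @param edges data frame with `node_a`, `node_b` columns.
#' @param config an [mi_config()]; uses `n_subsamples`,
#'   `subsample_size`, `seed` and the bandwidth rule.
#' @return `edges` with columns `mi_full`, `mi_sub_mean`, `mi_sub_sd`,
#'   `z`, `z_defined` appended.
#' @export
subsample_zscores <- function(data, edges, config = mi_config()) {
  mats <- list(data$cpg_m, data$transcript_expr, data$mirna_expr)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  all_rows <- do.call(rbind, mats)
  n <- ncol(all_rows)
  m <- config$subsample_size
  if (m >= n) stopf("subsample_size (%d) must be below the group size (%d)", m, n)
  missing_ids <- setdiff(c(edges$node_a, edges$node_b), rownames(all_rows))
  if (length(missing_ids)) stopf("unknown feature id '%s'", missing_ids[1])

  h_full <- resolve_bandwidth(n, config)
  h_sub <- resolve_bandwidth(m, config)
  subs <- with_seed(config$seed, {
    lapply(seq_len(config$n_subsamples), function(i) sample.int(n, m))
  })

  ne <- nrow(edges)
  mi_full <- numeric(ne)
  mu <- numeric(ne)
  sdv <- numeric(ne)
  for (e in seq_len(ne)) {
    xa <- all_rows[edges$node_a[e], ]
    xb <- all_rows[edges$node_b[e], ]
    mi_full[e] <- mi_pair(copula_transform(xa), copula_transform(xb), h_full)
    reps <- vapply(subs, function(cols) {
      as.numeric(mi_pair(
        copula_transform(xa[cols]), copula_transform(xb[cols]), h_sub
      ))
    }, numeric(1))
    mu[e] <- mean(reps)
    sdv[e] <- sd(reps)
  }
  z <- ifelse(sdv > 0, (mi_full - mu) / sdv, NA_real_)
  cbind(edges,
    mi_full = mi_full, mi_sub_mean = mu, mi_sub_sd = sdv,
    z = z, z_defined = sdv > 0
  )
}

#' Compare MI distributions across pair classes and networks
#'
#' Two-sample Kolmogorov-Smirnov tests for every pair of classes within a
#' network and every pair of networks within a class, with
#' Benjamini-Hochberg correction across all tests performed.
#' Distributions with fewer than 2 edges are excluded with a message.
#'
#' @param networks list of [mi_network()] objects (names used as labels).
#' @return data frame with columns `scope`, `network_a`, `network_b`,
#'   `class_a`, `class_b`, `statistic`, `p`, `q`.
#' @export
compare_mi_distributions <- function(networks) {
  if (inherits(networks, "mi_network")) networks <- list(networks)
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    names(networks) <- vapply(seq_along(networks), function(i) {
      g <- networks[[i]]$group
      if (is.na(g)) paste0("network", i) else g
    }, character(1))
  }
  dists <- lapply(networks, function(nw) {
    split(nw$edges$mi, nw$edges$pair_class)
  })
  n_classes <- length(unique(unlist(lapply(dists, names))))
  if (length(networks) < 2 && n_classes < 2) {
    stopf("need at least two networks or two pair classes to compare")
  }
  usable <- function(v) length(v) >= 2
  rows <- list()
  add <- function(scope, na, nb, ca, cb, x, y) {
    if (!usable(x) || !usable(y)) {
      msgf(
        "skipping %s vs %s / %s vs %s: fewer than 2 edges", na, nb, ca, cb
      )
      return()
    }
    kt <- suppressWarnings(ks.test(x, y))
    rows[[length(rows) + 1]] <<- data.frame(
      scope = scope, network_a = na, network_b = nb,
      class_a = ca, class_b = cb,
      statistic = unname(kt$statistic), p = kt$p.value,
      stringsAsFactors = FALSE
    )
  }
  for (nw in names(dists)) {
    cls <- names(dists[[nw]])
    if (length(cls) >= 2) {
      for (pair in combn(sort(cls), 2, simplify = FALSE)) {
        add(
          "within_network", nw, nw, pair[1], pair[2],
          dists[[nw]][[pair[1]]], dists[[nw]][[pair[2]]]
        )
      }
    }
  }
  if (length(dists) >= 2) {
    for (pair in combn(sort(names(dists)), 2, simplify = FALSE)) {
      shared <- intersect(names(dists[[pair[1]]]), names(dists[[pair[2]]]))
      for (cl in sort(shared)) {
        add(
          "between_networks", pair[1], pair[2], cl, cl,
          dists[[pair[1]]][[cl]], dists[[pair[2]]][[cl]]
        )
      }
    }
  }
  out <- rbind_rows(c(rows))
  if (is.null(out)) {
    return(data.frame(
      scope = character(), network_a = character(), network_b = character(),
      class_a = character(), class_b = character(), statistic = numeric(),
      p = numeric(), q = numeric(), stringsAsFactors = FALSE
    ))
  }
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Convert a network to igraph
#' @param x an `mi_network` or `enriched_network`.
#' @return an igraph graph; MI edges carry `mi`, `pair_class` and
#'   `kind = "MI"`; enriched networks add process nodes
#'   (`layer = "process"`) and `kind = "annotation"` edges.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.mi_network <- function(x) {
  edges <- x$edges
  edges$kind <- "MI"
  igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b", "pair_class", "mi", "kind")],
    directed = FALSE,
    vertices = data.frame(
      name = x$nodes$id, layer = x$nodes$layer, is_tf = x$nodes$is_tf,
      stringsAsFactors = FALSE
    )
  )
}

#' Write a network edge list in SIF format (node_a, class, node_b)
#' @param net an `mi_network`.
#' @param path output path.
#' @export
write_sif <- function(net, path) {
  e <- net$edges
  writeLines(paste(e$node_a, e$pair_class, e$node_b, sep = "\t"), path)
  invisible(path)
}

#' Write a network (nodes + extended edge table) as TSV
#'
#' Produces `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`; the edge table
#' keeps any significance columns present (`p_value`, `z`).
#'
#' @param net an `mi_network`.
#' @param prefix path prefix.
#' @return the two paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  np <- paste0(prefix, "_nodes.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  write.table(net$nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(net$edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(np, ep))
}

#' Read a network written by [write_network()]
#' @param prefix path prefix.
#' @param group group label.
#' @return an [mi_network()].
#' @export
read_network <- function(prefix, group = NA_character_) {
  nodes <- read.delim(paste0(prefix, "_nodes.tsv"), stringsAsFactors = FALSE)
  edges <- read.delim(paste0(prefix, "_edges.tsv"), stringsAsFactors = FALSE)
  mi_network(nodes, edges, group)
}

#' Write a network as GraphML
#' @param net an `mi_network` or `enriched_network`.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
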