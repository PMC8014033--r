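#' End-to-end pipeline configuration
#'
#' Validates input paths and bundles the per-stage configurations. All
#' referenced files must exist at validation time.
#'
#' @param cpg_beta,transcript_counts,mirna_counts paths to the three
#'   feature-by-sample matrices.
#' @param sample_sheet path to the sample sheet (sample_id, group).
#' @param feature_meta path to the feature metadata table.
#' @param gene_sets path to the gene-set GMT.
#' @param reference optional path to a regulator-target reference table.
#' @param out_dir output directory.
#' @param preprocess,mi,enrichment stage configurations.
#' @param normal_group label of the reference (non-tumor) group.
#' @param seed global seed; stage seeds derive deterministically from it.
#' @param compute_significance if TRUE, permutation p-values and
#'   subsampling z-scores are computed for the top `mi$n_pvalue_edges`
#'   edges per class of each network.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cpg_beta, transcript_counts, mirna_counts,
                            sample_sheet, feature_meta, gene_sets,
                            reference = NULL, out_dir,
                            preprocess = preprocess_config(),
                            mi = mi_config(),
                            enrichment = enrichment_config(),
                            normal_group = "Normal", seed = 1,
                            compute_significance = TRUE) {
  paths <- c(
    cpg_beta = cpg_beta, transcript_counts = transcript_counts,
    mirna_counts = mirna_counts, sample_sheet = sample_sheet,
    feature_meta = feature_meta, gene_sets = gene_sets
  )
  if (!is.null(reference)) paths <- c(paths, reference = reference)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stopf("input file not found: %s (%s)", missing[1], names(missing)[1])
  }
  stopifnot(
    inherits(preprocess, "preprocess_config"),
    inherits(mi, "mi_config"),
    inherits(enrichment, "enrichment_config")
  )
  structure(
    list(
      paths = as.list(paths), out_dir = out_dir, preprocess = preprocess,
      mi = mi, enrichment = enrichment, normal_group = normal_group,
      seed = as.integer(seed),
      compute_significance = isTRUE(compute_significance)
    ),
    class = "pipeline_config"
  )
}

#' Run the full multilayer analysis pipeline
#'
#' Stages: read inputs, preprocess, per-group MI network construction
#' (bandwidth resolved per group size), MI-distribution comparisons,
#' per-subtype differential ranking + GSEA + network
#' over-representation + functional pruning (the normal group's
#' candidate processes are the union of subtype-significant ones), and
#' the multilayer regulator comparisons. Every intermediate artifact is
#' written under `out_dir` and listed with an MD5 checksum in
#' `manifest.json`. A stage failure aborts with the stage name; files
#' already written are retained.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (also written as JSON), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  log <- list()
  note <- function(stage, fmt, ...) {
    txt <- sprintf(fmt, ...)
    msgf("[%s] %s", stage, txt)
    log[[length(log) + 1]] <<- list(stage = stage, message = txt)
  }
  emit <- function(rel) {
    files <<- c(files, rel)
    file.path(out_dir, rel)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  # ---- read ----
  dataset <- run_stage("read", {
    ds <- structure(
      list(
        cpg_beta = read_matrix(config$paths$cpg_beta),
        transcript_counts = read_matrix(config$paths$transcript_counts),
        mirna_counts = read_matrix(config$paths$mirna_counts),
        sample_groups = read_sample_sheet(config$paths$sample_sheet),
        feature_meta = read_feature_meta(config$paths$feature_meta),
        gene_sets = read_gmt(config$paths$gene_sets),
        config = NULL
      ),
      class = "omics_dataset"
    )
    samp <- colnames(ds$cpg_beta)
    if (!identical(samp, colnames(ds$transcript_counts)) ||
      !identical(samp, colnames(ds$mirna_counts))) {
      stopf("matrices do not share an identical ordered sample list")
    }
    if (!all(samp %in% names(ds$sample_groups))) {
      stopf("samples missing from the sample sheet")
    }
    sizes <- table(ds$sample_groups[samp])
    if (any(sizes < 5)) {
      stopf(
        "group '%s' has %d samples; at least 5 are required for MI estimation",
        names(sizes)[which.min(sizes)], min(sizes)
      )
    }
    if (!(config$normal_group %in% names(sizes))) {
      stopf("normal group '%s' absent from the sample sheet", config$normal_group)
    }
    note("read", "%d samples in %d groups", length(samp), length(sizes))
    ds
  })

  # ---- preprocess ----
  norm <- run_stage("preprocess", {
    nd <- preprocess_dataset(dataset, config$preprocess)
    write_matrix(nd$cpg_m, emit("cpg_m.tsv"))
    write_matrix(nd$transcript_expr, emit("transcript_expr.tsv"))
    write_matrix(nd$mirna_expr, emit("mirna_expr.tsv"))
    prov <- nd$provenance
    jsonlite::write_json(
      prov, emit("provenance.json"),
      auto_unbox = TRUE, pretty = TRUE, na = "string"
    )
    note(
      "preprocess", "features out: %d CpG / %d transcript / %d miRNA",
      nrow(nd$cpg_m), nrow(nd$transcript_expr), nrow(nd$mirna_expr)
    )
    nd
  })

  groups <- sort(unique(norm$sample_groups[colnames(norm$cpg_m)]))
  subtypes <- setdiff(groups, config$normal_group)

  # ---- mi networks per group ----
  networks <- run_stage("mi_network", {
    nets <- list()
    for (g in groups) {
      cols <- names(norm$sample_groups[colnames(norm$cpg_m)])[
        norm$sample_groups[colnames(norm$cpg_m)] == g
      ]
      sub <- list(
        cpg_m = norm$cpg_m[, cols, drop = FALSE],
        transcript_expr = norm$transcript_expr[, cols, drop = FALSE],
        mirna_expr = norm$mirna_expr[, cols, drop = FALSE],
        feature_meta = norm$feature_meta
      )
      cand <- mi_all_pairs(sub, config$mi)
      net <- select_top_k(cand, config$mi$top_k, group = g)
      if (config$compute_significance) {
        net <- add_edge_significance(net, sub, config$mi,
          seed = stage_seed(config$seed, match(g, groups))
        )
      }
      slug <- gsub("[^A-Za-z0-9]", "", g)
      write_network(net, file.path(out_dir, paste0("network_", slug)))
      emit(paste0("network_", slug, "_nodes.tsv"))
      emit(paste0("network_", slug, "_edges.tsv"))
      write_sif(net, emit(paste0("network_", slug, ".sif")))
      write_graphml(net, emit(paste0("network_", slug, ".graphml")))
      note(
        "mi_network", "%s: %d nodes, %d edges (h = %.5f, n = %d)",
        g, nrow(net$nodes), nrow(net$edges),
        attr(cand, "bandwidth"), attr(cand, "n_samples")
      )
      nets[[g]] <- net
    }
    nets
  })

  run_stage("mi_distributions", {
    tab <- compare_mi_distributions(networks)
    write.table(tab, emit("mi_distribution_tests.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    note("mi_distributions", "%d KS tests", nrow(tab))
  })

  # ---- enrichment ----
  enr <- run_stage("enrichment", {
    universe <- rownames(norm$transcript_expr)
    normal_samples <- names(norm$sample_groups)[
      norm$sample_groups == config$normal_group
    ]
    normal_samples <- intersect(normal_samples, colnames(norm$transcript_expr))
    gsea_results <- list()
    represented <- list()
    enriched <- list()
    for (g in subtypes) {
      cols <- names(norm$sample_groups)[norm$sample_groups == g]
      cols <- intersect(cols, colnames(norm$transcript_expr))
      ranking <- treat_rank(
        norm$transcript_expr, cols, normal_samples, config$enrichment
      )
      ecfg <- config$enrichment
      ecfg$seed <- stage_seed(config$seed, 100 + match(g, subtypes))
      gs <- gsea_preranked(ranking, norm$gene_sets, ecfg)
      slug <- gsub("[^A-Za-z0-9]", "", g)
      write.table(gs, emit(paste0("gsea_", slug, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      gsea_results[[g]] <- gs
      sig <- gs$process[!is.na(gs$q) & gs$q <= config$enrichment$gsea_q_max]
      note("enrichment", "%s: %d GSEA-significant processes", g, length(sig))
      represented[[g]] <- sig
    }
    normal_cand <- normal_tissue_processes(
      gsea_results, config$enrichment$gsea_q_max
    )
    ora_candidates <- c(
      represented, setNames(list(normal_cand), config$normal_group)
    )
    for (g in groups) {
      cand_procs <- ora_candidates[[g]]
      slug <- gsub("[^A-Za-z0-9]", "", g)
      if (length(cand_procs) == 0) {
        note("enrichment", "%s: no candidate process; empty network", g)
        enriched[[g]] <- NULL
        next
      }
      net_tx <- networks[[g]]$nodes$id[networks[[g]]$nodes$layer == "transcript"]
      ora <- ora_network(
        net_tx, norm$gene_sets[cand_procs], universe,
        config$enrichment$ora_q_max
      )
      write.table(ora, emit(paste0("ora_", slug, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      rep_sets <- norm$gene_sets[ora$process[ora$represented]]
      if (length(rep_sets) == 0) {
        note("enrichment", "%s: no represented process after ORA", g)
        next
      }
      en <- prune_to_enriched(networks[[g]], rep_sets)
      write_enriched_network(en, file.path(out_dir, paste0("enriched_", slug)))
      emit(paste0("enriched_", slug, "_nodes.tsv"))
      emit(paste0("enriched_", slug, "_edges.tsv"))
      write_graphml(en, emit(paste0("enriched_", slug, ".graphml")))
      note(
        "enrichment", "%s: enriched network with %d processes, %d MI edges",
        g, length(en$process_nodes), nrow(en$edges)
      )
      enriched[[g]] <- en
    }
    list(gsea = gsea_results, enriched = enriched)
  })

  # ---- multilayer comparison ----
  run_stage("compare", {
    enriched <- enr$enriched
    usable <- names(enriched)[!vapply(enriched, is.null, logical(1))]
    usable <- usable[vapply(
      usable, function(g) length(enriched[[g]]$process_nodes) > 0, logical(1)
    )]
    if (length(usable) == 0) {
      note("compare", "no enriched network; comparison stage skipped")
    } else {
    profiles <- lapply(enriched[usable], regulator_profiles)
    prof_df <- rbind_rows(lapply(usable, function(g) {
      cbind(network = g, as.data.frame(profiles[[g]]))
    }))
    write.table(prof_df, emit("regulator_profiles.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    if (config$normal_group %in% usable) {
      fish <- rbind_rows(lapply(
        setdiff(usable, config$normal_group),
        function(g) {
          cbind(
            network = g,
            fisher_regulator_enrichment(
              profiles[[g]], profiles[[config$normal_group]]
            )
          )
        }
      ))
      if (!is.null(fish)) {
        write.table(fish, emit("fisher_regulators.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
      }
    }
    topo <- lapply(enriched[usable], topology_stats)
    topo_tests <- compare_node_distributions(topo)
    write.table(topo_tests, emit("topology_tests.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    unreach <- rbind_rows(lapply(usable, function(g) {
      cbind(network = g, topo[[g]]$unreachable)
    }))
    write.table(unreach, emit("unreachable_targets.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    intra <- rbind_rows(lapply(usable, function(g) {
      sh <- intra_subtype_sharing(profiles[[g]])
      cbind(network = g, sh$fisher)
    }))
    write.table(intra, emit("intra_sharing_fisher.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    if (length(usable) >= 2) {
      inter <- inter_subtype_sharing(enriched[usable])
      write.table(inter$jaccard, emit("inter_sharing_jaccard.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      write.table(inter$ks, emit("inter_sharing_ks.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    if (!is.null(config$paths$reference)) {
      ref <- read_edge_table(config$paths$reference)
      if (!("evidence_class" %in% colnames(ref))) {
        ref$evidence_class <- "validated"
      }
      xr <- rbind_rows(lapply(usable, function(g) {
        cbind(
          network = g,
          cross_reference_edges(
            enriched[[g]], ref, norm$feature_meta
          )$fractions
        )
      }))
      write.table(xr, emit("cross_reference.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    note("compare", "comparison tables written for %d networks", length(usable))
    }
  })

  # ---- manifest ----
  full <- file.path(out_dir, files)
  manifest <- list(
    package = "mionet",
    version = as.character(packageVersion("mionet")),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = list(
      paths = config$paths, normal_group = config$normal_group,
      preprocess = unclass(config$preprocess),
      mi = as.list(unclass(config$mi)),
      enrichment = unclass(config$enrichment),
      compute_significance = config$compute_significance
    ),
    files = as.list(setNames(unname(tools::md5sum(full)), files)),
    log = log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, na = "string", digits = NA
  )
  invisible(manifest)
}

#' Attach permutation p-values and subsampling z-scores to top edges
#'
#' For the `n_pvalue_edges` highest-MI edges of each pair class,
#' computes the seeded permutation p-value; when `subsample_size` is
#' below the group size, subsampling z-scores are added for the same
#' edges (otherwise they are skipped with a message).
#'
#' @param net an [mi_network()].
#' @param data the sample-aligned matrices the network was built from.
#' @param config an [mi_config()].
#' @param seed integer seed.
#' @return the network with `p_value` (and possibly `z`) columns.
#' @export
add_edge_significance <- function(net, data, config = mi_config(), seed = 1) {
  mats <- list(data$cpg_m, data$transcript_expr, data$mirna_expr)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  all_rows <- do.call(rbind, mats)
  n <- ncol(all_rows)
  h <- resolve_bandwidth(n, config)
  e <- net$edges
  top <- unlist(lapply(split(seq_len(nrow(e)), e$pair_class), function(idx) {
    idx[seq_len(min(config$n_pvalue_edges, length(idx)))]
  }), use.names = FALSE)
  e$p_value <- NA_real_
  for (i in top) {
    xa <- copula_transform(all_rows[e$node_a[i], ])
    xb <- copula_transform(all_rows[e$node_b[i], ])
    e$p_value[i] <- permutation_pvalue(
      xa, xb, h, config$n_permutations,
      seed = stage_seed(seed, i)
    )
  }
  if (config$subsample_size < n) {
    zcfg <- config
    zcfg$seed <- stage_seed(seed, 999983)
    zs <- subsample_zscores(data, e[top, , drop = FALSE], zcfg)
    e$z <- NA_real_
    e$z[top] <- zs$z
  } else {
    msgf(
      "subsample_size (%d) >= group size (%d); z-scores skipped",
      config$subsample_size, n
    )
  }
  net$edges <- e
  net
}
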