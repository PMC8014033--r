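#' Configuration for the synthetic multi-omics generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: three
#' omic layers with disparate dynamic ranges (bounded methylation beta
#' values, overdispersed transcript and miRNA counts), planted monotone
#' (optionally nonlinear) regulator-target dependencies within and between
#' layers, group-specific shifts in gene-set activity, and missing values
#' in the methylation layer.
#'
#' @param n_cpg,n_transcripts,n_mirna number of features per layer.
#' @param n_tf number of transcripts flagged as TF-genes (must not exceed
#'   `n_transcripts`).
#' @param group_sizes named integer vector of samples per group. The
#'   default mirrors the five breast-tissue cohorts the analysis was
#'   designed around: Basal 125, Her2+ 45, LumA 395, LumB 128, Normal 75.
#' @param n_processes,genes_per_process number and size of synthetic
#'   biological-process gene sets (transcripts only).
#' @param planted_edges_per_class number of regulator-target dependencies
#'   planted in each admissible pair class (CpG-CpG is never planted).
#' @param dependence_strength real in \[0,1\]; 0 gives statistically
#'   independent "planted" pairs, 1 a noise-free monotone link.
#' @param shift_effect log2-scale expression shift added to member
#'   transcripts of a shifted (group, process) pair, relative to Normal.
#' @param missing_rate fraction of methylation entries masked as missing.
#' @param seed integer; all randomness flows from this single seed.
#' @param nonlinear_links if TRUE planted links are drawn among identity,
#'   cubic and saturating monotone shapes; if FALSE all links are linear.
#' @param shifts_per_group number of processes with a planted activity
#'   shift in each non-Normal group (alternating up/down).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cpg = 300, n_transcripts = 200, n_tf = 30,
                             n_mirna = 80,
                             group_sizes = c(
                               Basal = 125, `Her2+` = 45, LumA = 395,
                               LumB = 128, Normal = 75
                             ),
                             n_processes = 20, genes_per_process = 15,
                             planted_edges_per_class = 30,
                             dependence_strength = 0.8, shift_effect = 1,
                             missing_rate = 0.05, seed = 1,
                             nonlinear_links = TRUE, shifts_per_group = 2) {
  cfg <- list(
    n_cpg = as.integer(n_cpg), n_transcripts = as.integer(n_transcripts),
    n_tf = as.integer(n_tf), n_mirna = as.integer(n_mirna),
    group_sizes = group_sizes, n_processes = as.integer(n_processes),
    genes_per_process = as.integer(genes_per_process),
    planted_edges_per_class = as.integer(planted_edges_per_class),
    dependence_strength = dependence_strength, shift_effect = shift_effect,
    missing_rate = missing_rate, seed = as.integer(seed),
    nonlinear_links = isTRUE(nonlinear_links),
    shifts_per_group = as.integer(shifts_per_group)
  )
  stopifnot(
    cfg$n_cpg > 0, cfg$n_transcripts > 0, cfg$n_mirna > 0, cfg$n_tf >= 0,
    cfg$n_tf <= cfg$n_transcripts,
    length(cfg$group_sizes) >= 1, all(cfg$group_sizes > 0),
    !is.null(names(cfg$group_sizes)), !any(names(cfg$group_sizes) == ""),
    cfg$dependence_strength >= 0, cfg$dependence_strength <= 1,
    cfg$missing_rate >= 0, cfg$missing_rate <= 1,
    cfg$n_processes >= 0, cfg$genes_per_process > 0,
    cfg$genes_per_process <= cfg$n_transcripts,
    cfg$planted_edges_per_class >= 0
  )
  structure(cfg, class = "synthetic_config")
}

# Regulator/target layer plan for the five admissible pair classes.
.planted_classes <- list(
  "CpG-transcript" = c(reg = "CpG", tgt = "transcript"),
  "CpG-miRNA" = c(reg = "CpG", tgt = "miRNA"),
  "transcript-transcript" = c(reg = "TF", tgt = "transcript"),
  "transcript-miRNA" = c(reg = "miRNA", tgt = "transcript"),
  "miRNA-miRNA" = c(reg = "miRNA", tgt = "miRNA")
)

# Monotone link shapes for planted dependencies (all increasing; tails
# kept bounded so exponentiation into counts cannot produce pathological
# library sizes).
.link_funs <- list(
  identity = function(z) z,
  cuberoot = function(z) sign(z) * abs(z)^(1 / 3),
  saturating = function(z) tanh(1.5 * z)
)

#' Generate a synthetic multi-omics dataset with ground truth
#'
#' Draws latent Gaussian signals per feature and sample; planted targets
#' are standardized monotone functions of their regulator's latent signal
#' mixed with independent noise weighted by `1 - dependence_strength`.
#' Transcript and miRNA counts arise by deterministic monotone
#' quantization of latent log2 expression (`round(2^latent)`), giving
#' overdispersed count-like marginals while preserving planted rank
#' dependencies exactly at `dependence_strength = 1`. CpG beta values are
#' a logistic squashing of the latent signal, clipped to
#' `[1e-3, 1 - 1e-3]` so the M-transform stays finite, with
#' `missing_rate` of entries masked at random. Member transcripts of
#' shifted (group, process) pairs receive a signed `shift_effect` on the
#' log2 scale in that group's samples only.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `dataset` (class `omics_dataset`: matrices
#'   `cpg_beta`, `transcript_counts`, `mirna_counts`, named vector
#'   `sample_groups`, data frame `feature_meta`, list `gene_sets`, and the
#'   generating `config`) and `truth` (class `ground_truth`: data frames
#'   `planted_edges` and `shifted_sets`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    cpg_ids <- sprintf("cg%05d", seq_len(config$n_cpg))
    tx_ids <- sprintf("tx%04d", seq_len(config$n_transcripts))
    mir_ids <- sprintf("mir%03d", seq_len(config$n_mirna))
    tf_ids <- sort(sample(tx_ids, config$n_tf))

    groups <- rep(names(config$group_sizes), times = config$group_sizes)
    sample_ids <- paste0(
      gsub("[^A-Za-z0-9]", "", groups), "_",
      unlist(lapply(config$group_sizes, seq_len), use.names = FALSE)
    )
    names(groups) <- sample_ids
    n <- length(sample_ids)

    # chromosomes (a few sex-chromosome CpGs exercise the metadata filter)
    chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
    chrom_w <- c(rep(1, 22), 0.5, 0.1)
    tx_chrom <- sample(chroms, config$n_transcripts, TRUE, prob = chrom_w)
    mir_chrom <- sample(chroms, config$n_mirna, TRUE, prob = chrom_w)
    cpg_mapped <- ifelse(
      runif(config$n_cpg) < 0.7, sample(tx_ids, config$n_cpg, TRUE), NA
    )
    cpg_chrom <- ifelse(
      is.na(cpg_mapped),
      sample(chroms, config$n_cpg, TRUE, prob = chrom_w),
      tx_chrom[match(cpg_mapped, tx_ids)]
    )

    # gene sets over transcripts
    gene_sets <- list()
    if (config$n_processes > 0) {
      gene_sets <- lapply(seq_len(config$n_processes), function(i) {
        sort(sample(tx_ids, config$genes_per_process))
      })
      names(gene_sets) <- sprintf("P%03d", seq_len(config$n_processes))
    }

    # planted gene-set activity shifts (relative to the Normal group)
    shifted <- data.frame(
      group = character(), process = character(), direction = integer(),
      stringsAsFactors = FALSE
    )
    shift_groups <- setdiff(names(config$group_sizes), "Normal")
    if (config$n_processes > 0 && config$shifts_per_group > 0 &&
      length(shift_groups) > 0) {
      k <- min(config$shifts_per_group, config$n_processes)
      shifted <- do.call(rbind, lapply(shift_groups, function(g) {
        procs <- sample(names(gene_sets), k)
        data.frame(
          group = g, process = procs,
          direction = rep_len(c(1L, -1L), k), stringsAsFactors = FALSE
        )
      }))
    }

    # planted regulator-target edges: targets are drawn without
    # replacement (each target has one regulator); regulators may repeat
    # but never coincide with a target of their layer.
    ppc <- config$planted_edges_per_class
    planted <- data.frame(
      regulator = character(), target = character(), pair_class = character(),
      stringsAsFactors = FALSE
    )
    tx_pool <- tx_ids
    mir_pool <- mir_ids
    if (ppc > 0) {
      rows <- list()
      # reserve all targets first so regulator pools exclude them
      need_tx <- 3L * ppc # CpG-transcript, transcript-transcript, transcript-miRNA
      need_mir <- 2L * ppc # CpG-miRNA, miRNA-miRNA
      if (need_tx > length(tx_pool)) {
        stopf(
          "planted_edges_per_class = %d needs %d transcript targets but only %d transcripts exist (classes CpG-transcript, transcript-transcript, transcript-miRNA)",
          ppc, need_tx, length(tx_pool)
        )
      }
      if (need_mir > length(mir_pool)) {
        stopf(
          "planted_edges_per_class = %d needs %d miRNA targets but only %d miRNAs exist (classes CpG-miRNA, miRNA-miRNA)",
          ppc, need_mir, length(mir_pool)
        )
      }
      # transcript targets are drawn preferentially from gene-set members,
      # so planted regulatory wiring attaches to annotated processes (as
      # the downstream regulator-profile statistics assume); within each
      # tier non-TF transcripts go first so TF-genes stay available as
      # transcript-transcript regulators
      members <- intersect(unique(unlist(gene_sets)), tx_pool)
      tiers <- list(
        setdiff(members, tf_ids), setdiff(tx_pool, c(members, tf_ids)),
        intersect(members, tf_ids), intersect(setdiff(tx_pool, members), tf_ids)
      )
      tx_order <- unlist(lapply(tiers, sample))
      tx_tgt <- tx_order[seq_len(need_tx)]
      mir_tgt <- sample(mir_pool, need_mir)
      tgt_by_class <- list(
        "CpG-transcript" = tx_tgt[seq_len(ppc)],
        "transcript-transcript" = tx_tgt[ppc + seq_len(ppc)],
        "transcript-miRNA" = tx_tgt[2L * ppc + seq_len(ppc)],
        "CpG-miRNA" = mir_tgt[seq_len(ppc)],
        "miRNA-miRNA" = mir_tgt[ppc + seq_len(ppc)]
      )
      orig_pools <- list(
        CpG = cpg_ids,
        TF = setdiff(tf_ids, tx_tgt),
        miRNA = setdiff(mir_ids, mir_tgt)
      )
      reg_pools <- orig_pools
      for (cls in names(.planted_classes)) {
        plan <- .planted_classes[[cls]]
        pool <- reg_pools[[plan[["reg"]]]]
        # one target per regulator while the pool lasts (reusing a
        # regulator would wire its targets to each other indirectly);
        # small feature pools fall back to reuse
        if (length(pool) >= ppc) {
          regs <- sample(pool, ppc)
          reg_pools[[plan[["reg"]]]] <- setdiff(pool, regs)
        } else {
          full <- orig_pools[[plan[["reg"]]]]
          if (length(full) == 0) {
            stopf(
              "no %s regulators available to plant class %s edges (all candidates are planted targets)",
              plan[["reg"]], cls
            )
          }
          regs <- sample(full, ppc, replace = TRUE)
        }
        rows[[cls]] <- data.frame(
          regulator = regs,
          target = tgt_by_class[[cls]],
          pair_class = cls, stringsAsFactors = FALSE
        )
      }
      planted <- do.call(rbind, rows)
      rownames(planted) <- NULL
      # half of the planted CpG-transcript regulators map to their target,
      # so the cross-reference "mapped" label has ground-truth instances
      ct <- planted$pair_class == "CpG-transcript"
      map_it <- ct & rbinom(nrow(planted), 1, 0.5) == 1
      cpg_mapped[match(planted$regulator[map_it], cpg_ids)] <-
        planted$target[map_it]
      idx <- match(cpg_mapped, tx_ids)
      cpg_chrom[!is.na(idx)] <- tx_chrom[idx[!is.na(idx)]]
    }

    # latent Gaussian signals, one row per feature
    all_ids <- c(cpg_ids, tx_ids, mir_ids)
    Z <- matrix(rnorm(length(all_ids) * n), nrow = length(all_ids),
      dimnames = list(all_ids, sample_ids)
    )
    if (nrow(planted) > 0) {
      link_names <- if (config$nonlinear_links) {
        sample(names(.link_funs), nrow(planted), TRUE)
      } else {
        rep("identity", nrow(planted))
      }
      s <- config$dependence_strength
      for (e in seq_len(nrow(planted))) {
        g <- .link_funs[[link_names[e]]](Z[planted$regulator[e], ])
        g <- (g - mean(g)) / sd(g)
        Z[planted$target[e], ] <- s * g + (1 - s) * Z[planted$target[e], ]
      }
    }

    # group/process activity shifts on the log2 scale
    shift_mat <- matrix(0, config$n_transcripts, n,
      dimnames = list(tx_ids, sample_ids)
    )
    if (nrow(shifted) > 0) {
      for (r in seq_len(nrow(shifted))) {
        members <- gene_sets[[shifted$process[r]]]
        cols <- groups == shifted$group[r]
        shift_mat[members, cols] <- shift_mat[members, cols] +
          shifted$direction[r] * config$shift_effect
      }
    }

    # counts: deterministic monotone quantization of latent log2 expression
    tx_mu <- runif(config$n_transcripts, 3, 9)
    tx_sd <- runif(config$n_transcripts, 0.8, 1.5)
    transcript_counts <- round(2^(tx_mu + tx_sd * Z[tx_ids, , drop = FALSE] +
      shift_mat))
    mir_mu <- runif(config$n_mirna, 2, 8)
    mir_sd <- runif(config$n_mirna, 0.8, 1.5)
    mirna_counts <- round(2^(mir_mu + mir_sd * Z[mir_ids, , drop = FALSE]))
    storage.mode(transcript_counts) <- "integer"
    storage.mode(mirna_counts) <- "integer"

    # methylation betas: logistic squashing, clipped away from 0/1
    cpg_alpha <- rnorm(config$n_cpg, 0, 1.5)
    cpg_beta <- plogis(cpg_alpha + Z[cpg_ids, , drop = FALSE])
    cpg_beta <- pmin(pmax(cpg_beta, 1e-3), 1 - 1e-3)
    if (config$missing_rate > 0) {
      mask <- matrix(
        runif(length(cpg_beta)) < config$missing_rate,
        nrow = nrow(cpg_beta)
      )
      cpg_beta[mask] <- NA_real_
    }

    feature_meta <- data.frame(
      feature_id = all_ids,
      layer = rep(c("CpG", "transcript", "miRNA"),
        times = c(config$n_cpg, config$n_transcripts, config$n_mirna)
      ),
      is_tf = all_ids %in% tf_ids,
      chromosome = c(cpg_chrom, tx_chrom, mir_chrom),
      mapped_gene = c(cpg_mapped, rep(NA_character_,
        config$n_transcripts + config$n_mirna
      )),
      stringsAsFactors = FALSE
    )

    dataset <- structure(
      list(
        cpg_beta = cpg_beta, transcript_counts = transcript_counts,
        mirna_counts = mirna_counts, sample_groups = groups,
        feature_meta = feature_meta, gene_sets = gene_sets, config = config
      ),
      class = "omics_dataset"
    )
    truth <- structure(
      list(planted_edges = planted, shifted_sets = shifted),
      class = "ground_truth"
    )
    list(dataset = dataset, truth = truth)
  })
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf(
    "omics_dataset: %d CpGs, %d transcripts (%d TF), %d miRNAs x %d samples (%d groups), %d gene sets\n",
    nrow(x$cpg_beta), nrow(x$transcript_counts), sum(x$feature_meta$is_tf),
    nrow(x$mirna_counts), length(x$sample_groups),
    length(unique(x$sample_groups)), length(x$gene_sets)
  ))
  invisible(x)
}

#' Simulate an enriched network with prescribed regulator wiring
#'
#' Builds an `enriched_network` whose per-process regulator counts are
#' Poisson draws around the supplied means - one annotated transcript
#' per process, with CpG, TF-gene and miRNA regulators wired to it by MI
#' edges. Used to study the regulator-type comparison statistics under
#' controlled abundance shifts (e.g. a subtype with inflated CpG wiring
#' against a normal tissue without it).
#'
#' @param n_processes number of process nodes.
#' @param means named numeric vector of expected regulator counts per
#'   process, names among "CpG", "TF-gene", "miRNA".
#' @param seed integer seed.
#' @param group group label.
#' @return an [enriched_network()].
#' @export
simulate_regulator_wiring <- function(n_processes,
                                      means = c(
                                        CpG = 10, `TF-gene` = 8, miRNA = 8
                                      ),
                                      seed = 1, group = "sim") {
  stopifnot(n_processes >= 1, all(means >= 0))
  with_seed(seed, {
    procs <- sprintf("P%03d", seq_len(n_processes))
    tx <- sprintf("tx_%s_%s", group, procs)
    nodes <- list(data.frame(
      id = tx, layer = "transcript", is_tf = FALSE, stringsAsFactors = FALSE
    ))
    edges <- list()
    for (i in seq_len(n_processes)) {
      counts <- vapply(names(means), function(tp) stats::rpois(1, means[[tp]]),
        integer(1)
      )
      if (sum(counts) == 0) counts[1] <- 1L
      for (tp in names(counts)) {
        k <- counts[[tp]]
        if (k == 0) next
        prefix <- switch(tp, CpG = "cg", `TF-gene` = "tf", miRNA = "mir")
        ids <- sprintf("%s_%s_%s_%03d", prefix, group, procs[i], seq_len(k))
        cls <- switch(tp,
          CpG = "CpG-transcript", `TF-gene` = "transcript-transcript",
          miRNA = "transcript-miRNA"
        )
        a <- if (tp == "CpG") ids else rep(tx[i], k)
        b <- if (tp == "CpG") rep(tx[i], k) else ids
        if (tp == "TF-gene") {
          swap <- b < a
          tmp <- a[swap]
          a[swap] <- b[swap]
          b[swap] <- tmp
        }
        edges[[length(edges) + 1]] <- data.frame(
          node_a = a, node_b = b, pair_class = cls, mi = 1,
          stringsAsFactors = FALSE
        )
        nodes[[length(nodes) + 1]] <- data.frame(
          id = ids,
          layer = switch(tp, CpG = "CpG", miRNA = "miRNA", "transcript"),
          is_tf = tp == "TF-gene", stringsAsFactors = FALSE
        )
      }
    }
    enriched_network(
      rbind_rows(nodes),
      rbind_rows(edges) %||% data.frame(
        node_a = character(), node_b = character(),
        pair_class = character(), mi = numeric(), stringsAsFactors = FALSE
      ),
      procs,
      data.frame(process = procs, transcript = tx, stringsAsFactors = FALSE),
      group
    )
  })
}

#' Write a synthetic dataset and its ground truth as plain-text fixtures
#'
#' Emits the tab-delimited matrix, sample-sheet, feature-metadata, GMT and
#' ground-truth formats consumed by the package readers, plus a JSON
#' manifest listing the files (with MD5 checksums) and the generating
#' seed. The files round-trip losslessly through [read_fixtures()].
#'
#' @param dataset an `omics_dataset`.
#' @param truth the matching `ground_truth`.
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_fixtures <- function(dataset, truth, dir) {
  stopifnot(inherits(dataset, "omics_dataset"), inherits(truth, "ground_truth"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory '%s'", dir)
  }
  paths <- c(
    cpg_beta = "cpg_beta.tsv",
    transcript_counts = "transcript_counts.tsv",
    mirna_counts = "mirna_counts.tsv",
    sample_sheet = "sample_sheet.tsv",
    feature_meta = "feature_meta.tsv",
    gene_sets = "gene_sets.gmt",
    ground_truth_edges = "ground_truth_edges.tsv",
    shifted_sets = "shifted_sets.tsv"
  )
  full <- file.path(dir, paths)
  names(full) <- names(paths)
  write_matrix(dataset$cpg_beta, full["cpg_beta"])
  write_matrix(dataset$transcript_counts, full["transcript_counts"])
  write_matrix(dataset$mirna_counts, full["mirna_counts"])
  write_sample_sheet(dataset$sample_groups, full["sample_sheet"])
  write_feature_meta(dataset$feature_meta, full["feature_meta"])
  write_gmt(dataset$gene_sets, full["gene_sets"])
  write_edge_table(truth$planted_edges, full["ground_truth_edges"])
  write.table(truth$shifted_sets, full["shifted_sets"],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest <- list(
    seed = dataset$config$seed %||% NA_integer_,
    files = as.list(setNames(unname(paths), names(paths))),
    md5 = as.list(setNames(unname(tools::md5sum(full)), names(paths)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param dir directory containing the fixture files.
#' @return list with `dataset` and `truth`, as in [generate_dataset()].
#' @export
read_fixtures <- function(dir) {
  dataset <- structure(
    list(
      cpg_beta = read_matrix(file.path(dir, "cpg_beta.tsv")),
      transcript_counts = read_matrix(file.path(dir, "transcript_counts.tsv")),
      mirna_counts = read_matrix(file.path(dir, "mirna_counts.tsv")),
      sample_groups = read_sample_sheet(file.path(dir, "sample_sheet.tsv")),
      feature_meta = read_feature_meta(file.path(dir, "feature_meta.tsv")),
      gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
      config = NULL
    ),
    class = "omics_dataset"
  )
  truth <- structure(
    list(
      planted_edges = read_edge_table(
        file.path(dir, "ground_truth_edges.tsv")
      ),
      shifted_sets = read.delim(file.path(dir, "shifted_sets.tsv"),
        stringsAsFactors = FALSE
      )
    ),
    class = "ground_truth"
  )
  list(dataset = dataset, truth = truth)
}
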