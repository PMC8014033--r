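# Small in-code fixtures shared across test files.

small_config <- function(...) {
  defaults <- list(
    n_cpg = 40, n_transcripts = 50, n_tf = 8, n_mirna = 15,
    group_sizes = c(TumorA = 20, Normal = 20), n_processes = 5,
    genes_per_process = 8, planted_edges_per_class = 3,
    dependence_strength = 0.9, shift_effect = 1, missing_rate = 0.05,
    seed = 42
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# A tiny deterministic normalized dataset (no generator involved).
toy_normalized <- function(n = 12, seed = 5) {
  set.seed(seed)
  mk <- function(p, prefix) {
    m <- matrix(rnorm(p * n), p, n,
      dimnames = list(
        sprintf("%s%02d", prefix, seq_len(p)),
        sprintf("s%02d", seq_len(n))
      )
    )
    m
  }
  list(
    cpg_m = mk(4, "cg"), transcript_expr = mk(5, "tx"),
    mirna_expr = mk(3, "mir"),
    feature_meta = data.frame(
      feature_id = c(sprintf("cg%02d", 1:4), sprintf("tx%02d", 1:5),
        sprintf("mir%02d", 1:3)),
      layer = rep(c("CpG", "transcript", "miRNA"), c(4, 5, 3)),
      is_tf = c(rep(FALSE, 4), TRUE, rep(FALSE, 4), rep(FALSE, 3)),
      chromosome = "chr1", mapped_gene = NA_character_,
      stringsAsFactors = FALSE
    )
  )
}

# Hand-built enriched network: helper for the comparison-module tests.
# wiring: named list process -> list(CpG=..., `TF-gene`=..., miRNA=...)
# of regulator ids wired to that process's (single) annotated transcript.
build_enriched <- function(wiring, group = "net") {
  procs <- names(wiring)
  tx <- sprintf("tx_%s", procs)
  ann <- data.frame(process = procs, transcript = tx, stringsAsFactors = FALSE)
  edges <- list()
  nodes <- list()
  for (i in seq_along(procs)) {
    w <- wiring[[i]]
    for (tp in names(w)) {
      for (r in w[[tp]]) {
        cls <- switch(tp,
          CpG = "CpG-transcript",
          `TF-gene` = "transcript-transcript",
          miRNA = "transcript-miRNA"
        )
        ed <- if (tp == "CpG") {
          c(r, tx[i])
        } else if (tp == "miRNA") {
          c(tx[i], r)
        } else {
          sort(c(r, tx[i]))
        }
        edges[[length(edges) + 1]] <- data.frame(
          node_a = ed[1], node_b = ed[2], pair_class = cls, mi = 1,
          stringsAsFactors = FALSE
        )
        nodes[[length(nodes) + 1]] <- data.frame(
          id = r,
          layer = switch(tp, CpG = "CpG", miRNA = "miRNA", "transcript"),
          is_tf = tp == "TF-gene", stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- unique(do.call(rbind, edges))
  nodes <- unique(do.call(rbind, c(nodes, list(data.frame(
    id = tx, layer = "transcript", is_tf = FALSE, stringsAsFactors = FALSE
  )))))
  enriched_network(nodes, edges, procs, ann, group)
}
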