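#!/usr/bin/env Rscript
# Stage 4: functional enrichment - fold-change-threshold differential
# ranking of each tumor group against normal tissue, preranked GSEA,
# network over-representation, and pruning to enriched multipartite
# networks. Thresholds are demonstration-scale (see the methods
# vignette): a handful of 12-gene sets cannot reach the q-values a
# genome-wide ontology yields.

suppressMessages(library(mionet))

norm_expr <- read_matrix("results/preprocess/transcript_expr.tsv")
groups <- read_sample_sheet("results/fixtures/sample_sheet.tsv")
gene_sets <- read_gmt("results/fixtures/gene_sets.gmt")
ecfg <- enrichment_config(
  gsea_permutations = 2000, gsea_q_max = 0.25, ora_q_max = 0.6, seed = 2026
)

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
normal_samples <- intersect(
  names(groups)[groups == "Normal"], colnames(norm_expr)
)
subtypes <- setdiff(sort(unique(groups)), "Normal")
gsea_results <- list()
for (g in subtypes) {
  cols <- intersect(names(groups)[groups == g], colnames(norm_expr))
  rk <- treat_rank(norm_expr, cols, normal_samples, ecfg)
  res <- gsea_preranked(rk, gene_sets, ecfg)
  write.table(res, file.path(out, paste0("gsea_", g, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  gsea_results[[g]] <- res
  sig <- res[!is.na(res$q) & res$q <= ecfg$gsea_q_max, ]
  cat(sprintf(
    "%s vs Normal: %d/%d sets significant (q <= %.2f): %s\n",
    g, nrow(sig), nrow(res), ecfg$gsea_q_max,
    paste(sprintf("%s(%+d)", sig$process, sig$direction), collapse = " ")
  ))
}

candidates <- lapply(gsea_results, function(r) {
  r$process[!is.na(r$q) & r$q <= ecfg$gsea_q_max]
})
candidates$Normal <- normal_tissue_processes(gsea_results, ecfg$gsea_q_max)
universe <- rownames(norm_expr)

for (g in names(candidates)) {
  if (length(candidates[[g]]) == 0) {
    cat(sprintf("%s: no candidate process\n", g))
    next
  }
  net <- read_network(file.path("results/networks", paste0("network_", g)), g)
  ora <- ora_network(
    net$nodes$id[net$nodes$layer == "transcript"],
    gene_sets[candidates[[g]]], universe, ecfg$ora_q_max
  )
  write.table(ora, file.path(out, paste0("ora_", g, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  rep_sets <- gene_sets[ora$process[ora$represented]]
  if (length(rep_sets) == 0) {
    cat(sprintf("%s: no represented process after ORA\n", g))
    next
  }
  en <- prune_to_enriched(net, rep_sets)
  write_enriched_network(en, file.path(out, paste0("enriched_", g)))
  write_graphml(en, file.path(out, paste0("enriched_", g, ".graphml")))
  cat(sprintf(
    "%s: enriched network keeps %d/%d nodes, %d MI edges, %d processes\n",
    g, nrow(en$nodes), nrow(net$nodes), nrow(en$edges),
    length(en$process_nodes)
  ))
}
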