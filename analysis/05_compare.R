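#!/usr/bin/env Rscript
# Stage 5: multilayer comparison of the enriched networks - potential
# regulators per process, one-tailed Fisher directionality against
# normal tissue, node topology, regulator sharing (node Jaccard within a
# network, edge Jaccard between networks), and cross-referencing of
# regulator edges against the planted ground truth.

suppressMessages(library(mionet))

groups <- read_sample_sheet("results/fixtures/sample_sheet.tsv")
meta <- read_feature_meta("results/fixtures/feature_meta.tsv")
truth <- read_edge_table("results/fixtures/ground_truth_edges.tsv")
truth$evidence_class <- "validated"

nets <- list()
for (g in sort(unique(groups))) {
  prefix <- file.path("results/enrichment", paste0("enriched_", g))
  if (file.exists(paste0(prefix, "_nodes.tsv"))) {
    nets[[g]] <- read_enriched_network(prefix, g)
  }
}
stopifnot(length(nets) >= 1)
out <- "results/compare"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

profiles <- lapply(nets, regulator_profiles)
prof_df <- do.call(rbind, lapply(names(profiles), function(g) {
  cbind(network = g, as.data.frame(profiles[[g]]))
}))
write.table(prof_df, file.path(out, "regulator_profiles.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat("mean regulator proportions per network:\n")
print(aggregate(proportion ~ network + type, prof_df, mean), row.names = FALSE)

if ("Normal" %in% names(nets)) {
  for (g in setdiff(names(nets), "Normal")) {
    fish <- fisher_regulator_enrichment(profiles[[g]], profiles$Normal)
    write.table(fish, file.path(out, paste0("fisher_", g, "_vs_normal.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    sig <- fish[!is.na(fish$q) & fish$q < 0.05, ]
    cat(sprintf(
      "%s vs Normal: %d/%d directional regulator tests at q < 0.05\n",
      g, nrow(sig), sum(fish$tested)
    ))
  }
}

topo <- lapply(nets, topology_stats)
topo_tests <- compare_node_distributions(topo)
write.table(topo_tests, file.path(out, "topology_tests.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
for (g in names(topo)) {
  un <- topo[[g]]$unreachable
  cat(sprintf(
    "%s: %d components; unreachable-target fraction CpG %.2f / miRNA %.2f\n",
    g, topo[[g]]$n_components,
    un$fraction[un$layer == "CpG"], un$fraction[un$layer == "miRNA"]
  ))
}

intra <- do.call(rbind, lapply(names(profiles), function(g) {
  cbind(network = g, intra_subtype_sharing(profiles[[g]])$fisher)
}))
write.table(intra, file.path(out, "intra_sharing_fisher.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)

if (length(nets) >= 2) {
  inter <- inter_subtype_sharing(nets)
  write.table(inter$jaccard, file.path(out, "inter_sharing_jaccard.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(inter$ks, file.path(out, "inter_sharing_ks.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  cat(sprintf(
    "inter-network edge Jaccard: mean %.3f over %d (pair, process, type) cells\n",
    mean(inter$jaccard$jaccard, na.rm = TRUE), nrow(inter$jaccard)
  ))
}

for (g in names(nets)) {
  xr <- cross_reference_edges(nets[[g]], truth, meta)
  write.table(xr$fractions, file.path(out, paste0("cross_reference_", g, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  v <- xr$fractions[xr$fractions$label == "validated", ]
  cat(sprintf(
    "%s: validated (planted) edge fraction by class: %s\n",
    g, paste(sprintf("%s %.2f", v$pair_class, v$fraction), collapse = ", ")
  ))
}
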