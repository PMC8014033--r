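#!/usr/bin/env Rscript
# Stage 2: per-omic preprocessing - low-count and missingness filters,
# TMM scaling, log2 CPM, kNN imputation and the beta-to-M transform.

suppressMessages(library(mionet))

fx <- read_fixtures("results/fixtures")
nd <- preprocess_dataset(fx$dataset, preprocess_config())

out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_matrix(nd$cpg_m, file.path(out, "cpg_m.tsv"))
write_matrix(nd$transcript_expr, file.path(out, "transcript_expr.tsv"))
write_matrix(nd$mirna_expr, file.path(out, "mirna_expr.tsv"))
jsonlite::write_json(nd$provenance, file.path(out, "provenance.json"),
  auto_unbox = TRUE, pretty = TRUE, na = "string"
)

print(nd)
prov <- nd$provenance
cat(sprintf(
  "removed: %d transcripts (low CPM), %d miRNAs (low counts), %d CpGs (sex chromosomes), %d CpGs (missingness)\n",
  length(prov$transcripts_low_cpm_removed),
  length(prov$mirna_low_count_removed),
  length(prov$cpg_sex_chromosome_removed),
  length(prov$cpg_missing_removed)
))
cat(sprintf(
  "TMM factors span %.3f-%.3f (transcripts)\n",
  min(prov$transcript_tmm_factors), max(prov$transcript_tmm_factors)
))
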