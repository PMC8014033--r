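# Shared fixture for the pipeline tests: written once per test run.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) {
      return(cache)
    }
    g <- generate_dataset(synthetic_config(
      n_cpg = 80, n_transcripts = 100, n_tf = 12, n_mirna = 25,
      group_sizes = c(TumorA = 30, Normal = 30), n_processes = 6,
      genes_per_process = 10, planted_edges_per_class = 6,
      dependence_strength = 0.9, shift_effect = 1.5, missing_rate = 0.05,
      seed = 11
    ))
    dir <- file.path(tempdir(), "mionet-pipeline-fixture")
    if (!dir.exists(dir)) write_fixtures(g$dataset, g$truth, dir)
    cache <<- list(dir = dir, truth = g$truth)
    cache
  }
})

fixture_config <- function(out_dir, seed = 3, ...) {
  fx <- pipeline_fixture()
  d <- fx$dir
  pipeline_config(
    cpg_beta = file.path(d, "cpg_beta.tsv"),
    transcript_counts = file.path(d, "transcript_counts.tsv"),
    mirna_counts = file.path(d, "mirna_counts.tsv"),
    sample_sheet = file.path(d, "sample_sheet.tsv"),
    feature_meta = file.path(d, "feature_meta.tsv"),
    gene_sets = file.path(d, "gene_sets.gmt"),
    reference = file.path(d, "ground_truth_edges.tsv"),
    out_dir = out_dir,
    mi = mi_config(
      top_k = 40, n_permutations = 50, n_subsamples = 20,
      subsample_size = 15, n_pvalue_edges = 10
    ),
    enrichment = enrichment_config(
      gsea_permutations = 300, gsea_q_max = 0.25, ora_q_max = 0.6
    ),
    seed = seed, ...
  )
}

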