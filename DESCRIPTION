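Package: mionet
Title: Multilayer Multi-Omics Mutual Information Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic multilayer network analysis of transcriptional
    regulation across DNA-methylation (CpG), transcript, transcription-factor
    and miRNA layers. Provides kernel-density mutual information estimation on
    copula-transformed profiles, per-pair-class top-k co-expression network
    construction with permutation significance and subsampling z-scores,
    count/methylation preprocessing (CPM and low-count filters, TMM scaling
    factors, beta to M-value transform, kNN imputation), fold-change-threshold
    differential ranking with preranked gene-set enrichment and network
    over-representation, functional pruning into multipartite networks, and
    comparative regulator statistics (Fisher directionality, topology,
    Jaccard sharing) across phenotype groups. Includes a synthetic multi-omic
    data generator with planted regulator-target dependencies and gene-set
    activity shifts for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    edgeR,
    limma,
    fgsea,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
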