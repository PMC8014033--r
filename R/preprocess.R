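#' Preprocessing configuration
#'
#' Thresholds for the per-omic filtering, normalization and transformation
#' steps. Defaults follow the filtering rules the pipeline was designed
#' around: transcripts with mean CPM below 10 are dropped; miRNAs with
#' fewer than 5 counts in at least 25% of samples of every group are
#' dropped; CpG sites with over 75% missing values are dropped and the
#' rest imputed with k = 10 site neighbors; TMM uses 30%/5% M/A trims.
#'
#' @param cpm_min minimum mean counts-per-million for transcripts.
#' @param mirna_min_count,mirna_sample_frac miRNA low-count rule: a miRNA
#'   is removed when, in every group, at least `mirna_sample_frac` of that
#'   group's samples have counts below `mirna_min_count`.
#' @param cpg_missing_max maximum tolerated missing fraction per CpG site
#'   (strictly-greater fractions are removed).
#' @param knn_k number of neighbor sites for imputation.
#' @param tmm_trim_m,tmm_trim_a trim fractions for log-ratios (M) and
#'   average log intensities (A) in TMM.
#' @param remove_sex_chromosomes drop CpG sites on chrX/chrY (requires
#'   feature metadata with chromosomes).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(cpm_min = 10, mirna_min_count = 5,
                              mirna_sample_frac = 0.25,
                              cpg_missing_max = 0.75, knn_k = 10,
                              tmm_trim_m = 0.30, tmm_trim_a = 0.05,
                              remove_sex_chromosomes = TRUE) {
  cfg <- list(
    cpm_min = cpm_min, mirna_min_count = mirna_min_count,
    mirna_sample_frac = mirna_sample_frac,
    cpg_missing_max = cpg_missing_max, knn_k = as.integer(knn_k),
    tmm_trim_m = tmm_trim_m, tmm_trim_a = tmm_trim_a,
    remove_sex_chromosomes = isTRUE(remove_sex_chromosomes)
  )
  stopifnot(
    cfg$cpm_min >= 0, cfg$mirna_min_count >= 0,
    cfg$mirna_sample_frac >= 0, cfg$mirna_sample_frac <= 1,
    cfg$cpg_missing_max >= 0, cfg$cpg_missing_max <= 1,
    cfg$knn_k >= 1, cfg$tmm_trim_m >= 0, cfg$tmm_trim_m < 0.5,
    cfg$tmm_trim_a >= 0, cfg$tmm_trim_a < 0.5
  )
  structure(cfg, class = "preprocess_config")
}

#' Filter transcripts with low counts per million
#'
#' A transcript is removed iff its mean CPM across all samples is strictly
#' below `cpm_min` ("less than"); a transcript at exactly the threshold is
#' retained. Retained rows are returned unchanged.
#'
#' @param counts count matrix (features x samples).
#' @param cpm_min threshold on the mean CPM.
#' @return list with `counts` (filtered matrix) and `removed` (ids).
#' @export
filter_transcripts_low_cpm <- function(counts, cpm_min = 10) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stopf("library sizes must be positive")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep <- rowMeans(cpm) >= cpm_min
  if (!any(keep)) stopf("all transcripts removed by the CPM filter")
  list(
    counts = counts[keep, , drop = FALSE],
    removed = rownames(counts)[!keep]
  )
}

#' Filter miRNAs with low counts in every group
#'
#' A miRNA is removed iff in EVERY group the fraction of that group's
#' samples with counts below `min_count` is at least `sample_frac`
#' (the all-groups reading of "low counts in 25% or more of the samples
#' for every subtype").
#'
#' @param counts count matrix.
#' @param min_count,sample_frac low-count rule parameters.
#' @param groups named group vector covering every sample column.
#' @return list with `counts` and `removed`.
#' @export
filter_mirna_low_counts <- function(counts, min_count = 5,
                                    sample_frac = 0.25, groups) {
  if (!all(colnames(counts) %in% names(groups))) {
    stopf("every sample must have a group assignment")
  }
  g <- groups[colnames(counts)]
  low_frac <- sapply(unique(g), function(gr) {
    cols <- which(g == gr)
    if (length(cols) == 0) stopf("group '%s' has zero samples", gr)
    rowMeans(counts[, cols, drop = FALSE] < min_count)
  })
  low_frac <- matrix(low_frac, nrow = nrow(counts))
  remove <- apply(low_frac >= sample_frac, 1, all)
  list(
    counts = counts[!remove, , drop = FALSE],
    removed = rownames(counts)[remove]
  )
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Library-composition normalization factors for count data: the
#' reference sample is the one whose 75th-percentile CPM is closest to
#' the mean 75th percentile; gene-wise log2 CPM ratios (M) and average
#' log2 CPM (A) against the reference are doubly trimmed (`trim_m` on M,
#' `trim_a` on A) over genes positive in both samples, and each factor is
#' 2 to the precision-weighted mean of the surviving M values, rescaled
#' so the factors' geometric mean is 1. Computation is delegated to
#' edgeR's TMM implementation.
#'
#' @param counts count matrix with at least two samples.
#' @param trim_m,trim_a trim fractions.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2) stopf("TMM needs at least two samples")
  if (any(colSums(counts) <= 0)) stopf("library sizes must be positive")
  f <- edgeR::calcNormFactors(counts,
    method = "TMM",
    logratioTrim = trim_m, sumTrim = trim_a
  )
  if (any(!is.finite(f))) {
    stopf("TMM factor undefined: a sample shares no positive gene with the reference")
  }
  setNames(f, colnames(counts))
}

#' Log2 normalized counts per million
#'
#' `log2((count + prior) / (library_size * factor) * 1e6)`.
#'
#' @param counts count matrix.
#' @param factors per-sample scaling factors (positive).
#' @param prior prior count added before the log (default 0.5).
#' @return expression matrix on the log2 scale.
#' @export
log_cpm <- function(counts, factors = rep(1, ncol(counts)), prior = 0.5) {
  if (any(factors <= 0)) stopf("scaling factors must be positive")
  lib <- colSums(counts) * factors
  log2(sweep(counts + prior, 2, lib, "/") * 1e6)
}

#' Filter CpG sites by missing fraction
#'
#' A site is removed iff its missing fraction is strictly over
#' `max_missing`.
#'
#' @param beta beta-value matrix with optional NAs.
#' @param max_missing maximum tolerated missing fraction.
#' @return list with `beta` and `removed`.
#' @export
filter_cpg_missing <- function(beta, max_missing = 0.75) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- rowMeans(is.na(beta))
  keep <- frac <= max_missing
  list(
    beta = beta[keep, , drop = FALSE],
    removed = rownames(beta)[!keep]
  )
}

#' Impute missing methylation values from nearest neighbor sites
#'
#' Each missing entry (site s, sample j) is replaced by the mean value in
#' sample j of the k sites nearest to s, where distance is the root mean
#' squared difference over samples observed in both sites, and only sites
#' observed in sample j are candidate neighbors. If fewer than k
#' candidates exist all available ones are used, with a warning; if none
#' exist the site's own mean is used, with a warning. Observed entries
#' are untouched.
#'
#' @param beta beta-value matrix with NAs; every site needs at least one
#'   observed value.
#' @param k number of neighbor sites.
#' @return complete matrix.
#' @export
knn_impute <- function(beta, k = 10) {
  stopifnot(k >= 1)
  if (any(rowSums(!is.na(beta)) == 0)) {
    stopf("every site needs at least one observed value")
  }
  if (!anyNA(beta)) {
    return(beta)
  }
  p <- nrow(beta)
  obs <- !is.na(beta)
  B0 <- beta
  B0[!obs] <- 0
  # pairwise mean squared difference over commonly observed samples
  common <- obs %*% t(obs)
  sq <- B0^2
  cross <- sq %*% t(obs) + obs %*% t(sq) - 2 * (B0 %*% t(B0))
  d2 <- cross / common
  d2[common == 0] <- Inf
  diag(d2) <- Inf

  out <- beta
  short <- FALSE
  isolated <- FALSE
  for (s in which(rowSums(!obs) > 0)) {
    ord <- order(d2[s, ], rownames(beta)) # deterministic tie-break
    ord <- ord[is.finite(d2[s, ord])]
    for (j in which(!obs[s, ])) {
      cand <- ord[obs[ord, j]]
      if (length(cand) == 0) {
        isolated <- TRUE
        out[s, j] <- mean(beta[s, ], na.rm = TRUE)
      } else {
        if (length(cand) < k) short <- TRUE
        use <- cand[seq_len(min(k, length(cand)))]
        out[s, j] <- mean(beta[use, j])
      }
    }
  }
  if (short) warnf("fewer than k = %d neighbor sites available; used all", k)
  if (isolated) warnf("some entries had no observed neighbor; used the site mean")
  out
}

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))` elementwise. Entries must lie strictly
#' inside (0, 1).
#'
#' @param beta matrix of beta values in (0,1), no missing entries.
#' @return M-value matrix.
#' @export
beta_to_m <- function(beta) {
  if (anyNA(beta)) stopf("beta matrix contains missing values; impute first")
  if (any(beta <= 0 | beta >= 1)) {
    stopf("beta values must lie strictly in (0, 1)")
  }
  log2(beta / (1 - beta))
}

#' Inverse of the M-value transform
#' @param m M-value matrix.
#' @return beta values in (0,1).
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Run the full per-omic preprocessing
#'
#' Transcripts: mean-CPM filter, TMM factors, log2 CPM. miRNAs: grouped
#' low-count filter, TMM factors, log2 CPM. CpGs: optional sex-chromosome
#' removal, missing-value filter, kNN imputation, beta-to-M transform.
#' Batch correction and GC/length normalization are intentionally not
#' applied; the provenance record says so explicitly.
#'
#' @param dataset an `omics_dataset` (see [generate_dataset()] or
#'   [read_fixtures()]).
#' @param config a [preprocess_config()].
#' @return a `normalized_dataset`: matrices `cpg_m`, `transcript_expr`,
#'   `mirna_expr` (all sample-aligned with the input), `sample_groups`,
#'   `feature_meta` restricted to surviving features, `gene_sets`, and a
#'   `provenance` record of every step.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "omics_dataset"))
  prov <- list(
    arsyn_batch_correction = "not applied",
    gc_length_normalization = "not applied"
  )

  tx <- filter_transcripts_low_cpm(dataset$transcript_counts, config$cpm_min)
  prov$transcripts_low_cpm_removed <- tx$removed
  tf_tx <- tmm_factors(tx$counts, config$tmm_trim_m, config$tmm_trim_a)
  transcript_expr <- log_cpm(tx$counts, tf_tx)
  prov$transcript_tmm_factors <- tf_tx

  mir <- filter_mirna_low_counts(
    dataset$mirna_counts, config$mirna_min_count,
    config$mirna_sample_frac, dataset$sample_groups
  )
  prov$mirna_low_count_removed <- mir$removed
  tf_mir <- tmm_factors(mir$counts, config$tmm_trim_m, config$tmm_trim_a)
  mirna_expr <- log_cpm(mir$counts, tf_mir)
  prov$mirna_tmm_factors <- tf_mir

  beta <- dataset$cpg_beta
  if (config$remove_sex_chromosomes) {
    meta <- dataset$feature_meta
    sex <- meta$feature_id[meta$layer == "CpG" &
      meta$chromosome %in% c("chrX", "chrY", "X", "Y")]
    drop <- intersect(rownames(beta), sex)
    beta <- beta[setdiff(rownames(beta), drop), , drop = FALSE]
    prov$cpg_sex_chromosome_removed <- drop
  } else {
    prov$cpg_sex_chromosome_removed <- character()
  }
  bm <- filter_cpg_missing(beta, config$cpg_missing_max)
  prov$cpg_missing_removed <- bm$removed
  beta <- knn_impute(bm$beta, config$knn_k)
  cpg_m <- beta_to_m(beta)

  keep_ids <- c(rownames(cpg_m), rownames(transcript_expr), rownames(mirna_expr))
  meta <- dataset$feature_meta[dataset$feature_meta$feature_id %in% keep_ids, ,
    drop = FALSE
  ]
  rownames(meta) <- NULL
  prov$features_in <- c(
    CpG = nrow(dataset$cpg_beta),
    transcript = nrow(dataset$transcript_counts),
    miRNA = nrow(dataset$mirna_counts)
  )
  prov$features_out <- c(
    CpG = nrow(cpg_m), transcript = nrow(transcript_expr),
    miRNA = nrow(mirna_expr)
  )

  structure(
    list(
      cpg_m = cpg_m, transcript_expr = transcript_expr,
      mirna_expr = mirna_expr, sample_groups = dataset$sample_groups,
      feature_meta = meta, gene_sets = dataset$gene_sets, provenance = prov
    ),
    class = "normalized_dataset"
  )
}

#' @export
print.normalized_dataset <- function(x, ...) {
  cat(sprintf(
    "normalized_dataset: %d CpG M-values, %d transcripts, %d miRNAs x %d samples\n",
    nrow(x$cpg_m), nrow(x$transcript_expr), nrow(x$mirna_expr),
    ncol(x$cpg_m)
  ))
  invisible(x)
}
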