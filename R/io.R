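#' Read a feature-by-sample matrix from tab-delimited text
#'
#' The expected format is a header row of sample ids preceded by a
#' `feature_id` column name, then one row per feature. Duplicate feature
#' or sample ids and ragged rows are rejected.
#'
#' @param path file path.
#' @return numeric matrix with feature row names and sample column names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("'%s': expected a feature_id column plus samples", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stopf(
      "'%s': duplicated feature id '%s'", path, ids[duplicated(ids)][1]
    )
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stopf(
      "'%s': duplicated sample id '%s'", path,
      samples[duplicated(samples)][1]
    )
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("'%s': non-numeric entries in matrix body", path)
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix as tab-delimited text
#'
#' Full double precision is kept so matrices round-trip through
#' [read_matrix()]; missing values are written as `NA`.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(feature_id = rownames(m), m,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (sample_id, group)
#' @param path file path.
#' @return named character vector mapping sample id to group label.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df))) {
    stopf("'%s': expected columns sample_id and group", path)
  }
  if (anyDuplicated(df$sample_id)) {
    stopf(
      "'%s': duplicated sample id '%s'", path,
      df$sample_id[duplicated(df$sample_id)][1]
    )
  }
  setNames(as.character(df$group), df$sample_id)
}

#' Write a sample sheet
#' @param groups named character vector (sample id to group).
#' @param path output path.
#' @export
write_sample_sheet <- function(groups, path) {
  write.table(
    data.frame(sample_id = names(groups), group = unname(groups)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a feature metadata table
#'
#' Columns: `feature_id`, `layer` (CpG/transcript/miRNA), `is_tf`,
#' `chromosome`, `mapped_gene`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_feature_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "layer", "is_tf", "chromosome", "mapped_gene")
  if (!all(need %in% colnames(df))) {
    stopf(
      "'%s': expected columns %s", path, paste(need, collapse = ", ")
    )
  }
  if (anyDuplicated(df$feature_id)) {
    stopf(
      "'%s': duplicated feature id '%s'", path,
      df$feature_id[duplicated(df$feature_id)][1]
    )
  }
  df$is_tf <- as.logical(df$is_tf)
  df$mapped_gene <- as.character(df$mapped_gene)
  df$chromosome <- as.character(df$chromosome)
  df
}

#' Write a feature metadata table
#' @param meta data frame as returned by [read_feature_meta()].
#' @param path output path.
#' @export
write_feature_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `set_id<TAB>description<TAB>member1<TAB>member2...`.
#' Lines with fewer than one member after the description are rejected
#' with their line number. An empty file yields an empty list.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(setNames(list(), character()))
  }
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stopf("'%s' line %d: GMT record needs at least one member", path, i)
    }
    ids[i] <- parts[1]
    out[[i]] <- parts[-(1:2)]
  }
  if (anyDuplicated(ids)) {
    stopf("'%s': duplicated set id '%s'", path, ids[duplicated(ids)][1])
  }
  setNames(out, ids)
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulator-target edge table
#'
#' Used for ground-truth planted edges (columns `regulator`, `target`,
#' `pair_class`) and for external reference tables (columns `regulator`,
#' `target`, `evidence_class`).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_edge_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target") %in% colnames(df))) {
    stopf("'%s': expected columns regulator and target", path)
  }
  df
}

#' Write a regulator-target edge table
#' @param edges data frame with at least `regulator` and `target` columns.
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
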