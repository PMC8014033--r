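#' @useDynLib mionet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif plogis rbinom sd cor lm coef p.adjust
#'   phyper fisher.test ks.test wilcox.test quantile setNames complete.cases
#' @importFrom utils read.delim write.table head combn packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the previous RNG state afterwards so surrounding code is not
#' perturbed. All stochastic operations in the package route their
#' randomness through this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Deterministic per-stage seed derived from a global seed; stays < 2^31.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 31L + stage * 7919) %% 2147483647)
}

# Canonical layer ordering used for pair-class labels and edge keys.
.layer_order <- c("CpG", "transcript", "miRNA")

#' Pair class of an unordered feature pair
#'
#' The pair class is a pure function of the two endpoint layers, with
#' layers ordered canonically (CpG, transcript, miRNA), e.g. a
#' transcript/CpG pair is always "CpG-transcript".
#'
#' @param layer_a,layer_b layer labels, each one of "CpG", "transcript",
#'   "miRNA".
#' @return character pair-class label.
#' @export
pair_class_of <- function(layer_a, layer_b) {
  ia <- match(layer_a, .layer_order)
  ib <- match(layer_b, .layer_order)
  if (anyNA(ia) || anyNA(ib)) stop("unknown layer label")
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  paste(.layer_order[lo], .layer_order[hi], sep = "-")
}

#' All admissible pair classes
#' @return character vector of the six pair-class labels.
#' @export
pair_classes <- function() {
  c(
    "CpG-CpG", "CpG-transcript", "CpG-miRNA",
    "transcript-transcript", "transcript-miRNA", "miRNA-miRNA"
  )
}

# Canonicalize edge endpoints: cross-layer edges put the canonically earlier
# layer first; within-layer edges sort endpoint ids lexicographically.
canonical_edges <- function(node_a, node_b, layer_a, layer_b) {
  ia <- match(layer_a, .layer_order)
  ib <- match(layer_b, .layer_order)
  swap <- ib < ia | (ia == ib & node_b < node_a)
  data.frame(
    node_a = ifelse(swap, node_b, node_a),
    node_b = ifelse(swap, node_a, node_b),
    stringsAsFactors = FALSE
  )
}

# Unique string identity of an edge (endpoints + class, MI ignored).
edge_key <- function(node_a, node_b, pair_class) {
  lo <- pmin(node_a, node_b)
  hi <- pmax(node_a, node_b)
  paste(lo, hi, pair_class, sep = "|")
}

# rbind a list of data frames; NULL (not a degenerate matrix) when empty.
rbind_rows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
msgf <- function(...) message(sprintf(...))
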