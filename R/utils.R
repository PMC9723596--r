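# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing stochastic functions funnel through this so
# that identical (seed, inputs) always give identical outputs.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  } else {
    force(code)
  }
}

# Deterministic derivation of a child seed from a root seed and a stream
# label; keeps results invariant to how many draws earlier stages consumed.
child_seed <- function(seed, stream) {
  stream <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647)
}

# Row-wise minima of a numeric matrix via max.col (C speed, no extra deps).
row_mins <- function(m) {
  if (ncol(m) == 1L) return(as.numeric(m))
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

#' Validate a sample-by-sample dissimilarity matrix
#'
#' Checks symmetry, zero diagonal and finiteness, and returns the matrix
#' with harmonized dimnames. Accepts a `dist` object or a square matrix.
#'
#' @param d a `dist` object or square numeric matrix.
#' @param ids optional identifiers overriding existing dimnames.
#' @return a symmetric numeric matrix with a zero diagonal.
#' @export
as_distance_matrix <- function(d, ids = NULL) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  if (is.null(rownames(m))) {
    ids <- paste0("s", seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  }
  if (any(!is.finite(m))) stop("distance matrix contains non-finite values")
  if (any(abs(m - t(m)) > 1e-8)) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  m[] <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Alignment used inside the phylogenetic metrics: table taxa absent from
# the tree are an error; tree tips absent from the table are pruned
# quietly (the usual case with a large insertion tree); all-zero taxa are
# dropped quietly. Null models downstream therefore shuffle across the
# taxa observed in the dataset.
align_for_metric <- function(table, tree) {
  table <- suppressMessages(validate_community_table(table))
  tree <- validate_phylogeny(tree)
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("table taxa absent from the tree: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, colnames(table))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  list(table = table[, tree$tip.label, drop = FALSE], tree = tree)
}

# Variant for rooted metrics (Faith's PD and its effect size): the
# supplied tree is kept whole so paths to its root are preserved, and
# all-zero taxon columns are retained so the tip-shuffle null ranges over
# every taxon of the dataset.
align_keep_tree <- function(table, tree) {
  table <- validate_community_table(table, drop_empty_taxa = FALSE)
  tree <- validate_phylogeny(tree)
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("table taxa absent from the tree: ", paste(missing, collapse = ", "))
  list(table = table, tree = tree)
}

# Alignment for the pool-scale null models (NTI, beta-NTI, Raup-Crick):
# every table column — including all-zero taxa — stays in, because the
# columns define the regional pool the null shuffles across; the tree is
# pruned to the table's columns (patristic distances are unaffected).
align_pool <- function(table, tree) {
  table <- validate_community_table(table, drop_empty_taxa = FALSE)
  tree <- validate_phylogeny(tree)
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("table taxa absent from the tree: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, colnames(table))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  list(table = table[, tree$tip.label, drop = FALSE], tree = tree)
}

# all unordered sample pairs of a character vector, as a 2-column matrix
sample_pairs <- function(ids) {
  t(utils::combn(ids, 2L))
}
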