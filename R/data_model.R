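# Domain containers and readers: community table (samples x taxa matrix),
# rooted phylogeny (ape::phylo), sample metadata (data.frame).

#' Validate a community abundance table
#'
#' The canonical community table is a numeric matrix with samples as rows,
#' taxa as columns, unique dimnames, and non-negative finite entries.
#' Samples with zero total abundance are rejected; taxa with zero total
#' abundance are dropped with a message (they carry no information and
#' distort presence/absence metrics).
#'
#' @param x numeric matrix (samples x taxa) with dimnames.
#' @param drop_empty_taxa drop all-zero taxon columns (default `TRUE`).
#' @return the validated matrix.
#' @export
validate_community_table <- function(x, drop_empty_taxa = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) stop("community table must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("community table must carry sample (row) and taxon (column) names")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) stop("duplicate sample identifiers: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup)) stop("duplicate taxon identifiers: ", paste(dup, collapse = ", "))
  if (any(!is.finite(x))) stop("community table contains non-finite entries")
  if (any(x < 0)) stop("community table contains negative entries")
  if (any(rowSums(x) <= 0))
    stop("samples with zero total abundance: ",
         paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  if (drop_empty_taxa && any(colSums(x) == 0)) {
    n0 <- sum(colSums(x) == 0)
    message("dropping ", n0, " taxa with zero total abundance")
    x <- x[, colSums(x) > 0, drop = FALSE]
  }
  x
}

#' Read a community table from TSV
#'
#' Supports a plain TSV (header row = taxon IDs, first column = sample IDs)
#' and a dense BIOM-style TSV (taxa as rows, `#OTU ID` header, optional
#' leading `#` comment lines), which is transposed to the canonical
#' samples-as-rows orientation.
#'
#' @param path path to the file.
#' @param format `"tsv"` (samples as rows) or `"dense-biom"` (taxa as rows).
#' @param transpose transpose after reading (for TSVs stored taxa-as-rows).
#' @return a validated community matrix, samples as rows.
#' @export
read_community_table <- function(path, format = c("tsv", "dense-biom"),
                                 transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense-biom") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#(?!OTU)", lines, perl = TRUE)]
    lines[1] <- sub("^#OTU ID", "taxon_id", lines[1])
    df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            check.names = FALSE, stringsAsFactors = FALSE)
    transpose <- TRUE
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  hdr <- names(df)[-1]
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup)) stop("duplicate identifiers in header: ",
                        paste(dup, collapse = ", "))
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate identifiers in first column: ",
                        paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance entries in ", path)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  validate_community_table(m)
}

#' Write a community table to TSV
#'
#' Inverse of [read_community_table()] (plain `"tsv"` layout); the
#' write/read round trip preserves values and identifier order.
#'
#' @param x community matrix, samples as rows.
#' @param path output path.
#' @export
write_community_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream phylogenetic
#' metrics require: the tree must parse, be rooted, and carry a branch
#' length on every edge. Missing branch lengths are an error, never imputed.
#'
#' @param path path to a Newick file.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e) NULL)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for use in phylogenetic diversity metrics
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly validated.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("phylogeny has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("phylogeny has negative branch lengths")
  if (tree$Nnode > 1 && !ape::is.rooted(tree)) stop("phylogeny must be rooted")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  tree
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `sample_type`, `site`, `cage` (a
#' `replicate` column is kept when present) and checks factor levels
#' against declared vocabularies, which default to the gradient-transfer
#' incubation design (three substrate types plus two water fractions,
#' four sites along a salinity gradient, transferred vs stationary cages)
#' and are extensible.
#'
#' @param path path to a TSV file.
#' @param sample_types,sites,cages allowed factor levels.
#' @return a data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path,
                                 sample_types = c("HDPE", "TW", "Wood", "Water3", "Water02"),
                                 sites = c("Bremen", "Brake", "Bremerhaven", "Helgoland"),
                                 cages = c("Transfer", "Stationary")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(df, sample_types = sample_types, sites = sites, cages = cages)
}

#' @rdname read_sample_metadata
#' @param meta a metadata data.frame to validate in place.
#' @export
validate_sample_metadata <- function(meta,
                                     sample_types = c("HDPE", "TW", "Wood", "Water3", "Water02"),
                                     sites = c("Bremen", "Brake", "Bremerhaven", "Helgoland"),
                                     cages = c("Transfer", "Stationary")) {
  need <- c("sample_id", "sample_type", "site", "cage")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "))
  chk <- function(values, allowed, what) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad)) stop("unknown ", what, ": ", paste(bad, collapse = ", "))
  }
  chk(meta$sample_type, sample_types, "sample_type")
  chk(meta$site, sites, "site")
  chk(meta$cage, cages, "cage")
  meta
}

#' Harmonize a community table, phylogeny and metadata
#'
#' Reconciles the taxon sets of the table and the tree and the sample sets
#' of the table and the metadata. In strict mode any mismatch is an error
#' listing the offending identifiers; otherwise the tree is pruned to the
#' table's taxa, table taxa absent from the tree are dropped, and both
#' events are reported via warnings. Taxon ordering of the table is
#' harmonized to the tree's tip order.
#'
#' @param table community matrix (samples x taxa).
#' @param tree a `phylo` object, or `NULL` to skip the taxon checks.
#' @param meta metadata data.frame, or `NULL` to skip the sample checks.
#' @param strict error on any mismatch instead of pruning.
#' @return `list(table, tree, meta)` with harmonized identifier sets.
#' @export
align_inputs <- function(table, tree = NULL, meta = NULL, strict = FALSE) {
  table <- validate_community_table(table)
  if (!is.null(tree)) {
    tree <- validate_phylogeny(tree)
    only_table <- setdiff(colnames(table), tree$tip.label)
    only_tree <- setdiff(tree$tip.label, colnames(table))
    if (strict && (length(only_table) || length(only_tree)))
      stop("taxon sets differ between table and tree; table-only: [",
           paste(only_table, collapse = ", "), "], tree-only: [",
           paste(only_tree, collapse = ", "), "]")
    if (length(only_table)) {
      warning("dropping ", length(only_table), " table taxa absent from the tree")
      table <- validate_community_table(table[, setdiff(colnames(table), only_table),
                                              drop = FALSE])
    }
    if (length(only_tree)) {
      warning("pruning ", length(only_tree), " tree tips absent from the table")
      tree <- ape::drop.tip(tree, only_tree)
    }
    table <- table[, tree$tip.label, drop = FALSE]
  }
  if (!is.null(meta)) {
    miss <- setdiff(rownames(table), meta$sample_id)
    if (length(miss)) stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    extra <- setdiff(meta$sample_id, rownames(table))
    if (length(extra)) {
      if (strict) stop("metadata samples absent from table: ", paste(extra, collapse = ", "))
      meta <- meta[meta$sample_id %in% rownames(table), , drop = FALSE]
    }
    meta <- meta[match(rownames(table), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  list(table = table, tree = tree, meta = meta)
}
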