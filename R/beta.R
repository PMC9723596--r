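# Pairwise dissimilarities, the Baselga turnover/nestedness partition of
# the Jaccard index, SIMPER, and shared-taxon intersection counts.

#' Pairwise taxonomic dissimilarities
#'
#' Bray-Curtis on abundances, `sum|x - y| / sum(x + y)`, or Jaccard on
#' presence/absence, `1 - |intersection| / |union|`.
#'
#' @param table community matrix (samples x taxa), row sums > 0.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return symmetric sample-by-sample dissimilarity matrix in `[0, 1]`.
#' @export
pairwise_dissimilarity <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  table <- suppressMessages(validate_community_table(table))
  d <- switch(metric,
    bray_curtis = vegan::vegdist(table, method = "bray"),
    jaccard = vegan::vegdist(table, method = "jaccard", binary = TRUE))
  as_distance_matrix(d, rownames(table))
}

#' UniFrac phylogenetic dissimilarities
#'
#' Unweighted UniFrac is the fraction of branch length unique to either
#' sample's spanned subtree over the branch length spanned by their union;
#' weighted UniFrac moves relative abundance along branches,
#' `sum(b_i |p_iA - p_iB|)`, normalized to `[0, 1]` by default.
#'
#' @param table community matrix; all taxa must be tips of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @param weighted use abundance-weighted UniFrac.
#' @param normalized normalize the weighted variant to `[0, 1]` (ignored
#'   for unweighted, which is normalized by construction).
#' @return symmetric dissimilarity matrix.
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  al <- align_for_metric(table, tree)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(al$table, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(al$tree))
  d <- phyloseq::UniFrac(ps, weighted = weighted, normalized = normalized,
                         parallel = FALSE, fast = TRUE)
  m <- as.matrix(d)[rownames(al$table), rownames(al$table)]
  if (!weighted || normalized) as_distance_matrix(m) else {
    if (any(abs(diag(m)) > 1e-12)) stop("unexpected nonzero UniFrac diagonal")
    m
  }
}

#' Baselga partition of pairwise Jaccard dissimilarity
#'
#' Decomposes the Jaccard dissimilarity of every sample pair into a
#' turnover (species replacement) and a nestedness-resultant (species
#' loss/gain) component. With `a` shared taxa and `b`, `c` uniques:
#' `beta_jac = (b + c) / (a + b + c)`,
#' `beta_jtu = 2 min(b,c) / (a + 2 min(b,c))`,
#' `beta_jne = beta_jac - beta_jtu`.
#'
#' @param table community matrix; presence/absence is derived from `> 0`.
#' @return `list(jac, jtu, jne)` of symmetric matrices with
#'   `jac = jtu + jne` to machine precision.
#' @export
baselga_partition <- function(table) {
  table <- suppressMessages(validate_community_table(table))
  x <- (table > 0) * 1
  a <- x %*% t(x)                      # shared
  rich <- rowSums(x)
  b <- matrix(rich, nrow(x), nrow(x)) - a          # unique to row sample
  cc <- t(b)
  mn <- pmin(b, cc)
  jac <- (b + cc) / (a + b + cc)
  jtu <- ifelse(a + 2 * mn > 0, 2 * mn / (a + 2 * mn), 0)
  diag(jac) <- diag(jtu) <- 0
  jne <- jac - jtu
  ids <- rownames(table)
  list(jac = as_distance_matrix(jac, ids),
       jtu = as_distance_matrix(jtu, ids),
       jne = as_distance_matrix(jne, ids))
}

#' Similarity percentage analysis (SIMPER)
#'
#' Attributes the average between-group Bray-Curtis dissimilarity to
#' individual taxa: the contribution of taxon `t` to a sample pair
#' `(x, y)` is `|x_t - y_t| / sum(x + y)`, averaged over all between-group
#' pairs. Operates on relative abundances by default (each sample summing
#' to 1), as in the reference implementation; per-taxon contributions sum
#' to the mean between-group Bray-Curtis dissimilarity.
#'
#' @param table community matrix (samples x taxa).
#' @param groups group label per sample.
#' @param relative normalize samples to relative abundance first.
#' @return named list (one element per group pair, `"G1 vs G2"`) of
#'   data.frames with `taxon`, `average` contribution, `percent` and
#'   `cumulative` percent, sorted by decreasing contribution; the mean
#'   between-group dissimilarity is attached as attribute `overall`.
#' @export
simper <- function(table, groups, relative = TRUE) {
  table <- validate_community_table(table, drop_empty_taxa = FALSE)
  groups <- as.factor(groups)
  if (length(groups) != nrow(table)) stop("one group label per sample required")
  if (any(table(groups) < 1)) stop("every group needs at least one sample")
  if (relative) table <- table / rowSums(table)
  lv <- levels(droplevels(groups))
  out <- list()
  for (pair in utils::combn(lv, 2, simplify = FALSE)) {
    gi <- which(groups == pair[1]); gj <- which(groups == pair[2])
    contrib <- numeric(ncol(table))
    for (i in gi) for (j in gj) {
      denom <- sum(table[i, ] + table[j, ])
      contrib <- contrib + abs(table[i, ] - table[j, ]) / denom
    }
    contrib <- contrib / (length(gi) * length(gj))
    overall <- sum(contrib)
    ord <- order(contrib, decreasing = TRUE)
    df <- data.frame(taxon = colnames(table)[ord], average = contrib[ord],
                     percent = 100 * contrib[ord] / overall,
                     row.names = NULL, stringsAsFactors = FALSE)
    df$cumulative <- cumsum(df$percent)
    attr(df, "overall") <- overall
    out[[paste(pair, collapse = " vs ")]] <- df
  }
  out
}

#' Shared-taxon intersection counts between groups (UpSet semantics)
#'
#' A taxon belongs to a group if it is detected (abundance > 0) in any of
#' the group's samples. Reports the exclusive count of every non-empty
#' combination of groups (each taxon counted once, in its exact
#' membership set) and the fraction of each group's taxa unique to it.
#'
#' @param table community matrix (samples x taxa).
#' @param groups group label per sample.
#' @return `list(intersections, unique_fraction)`: a data.frame of
#'   exclusive counts per group-set (sets as `"A&B"` labels) and a named
#'   vector of per-group unique fractions.
#' @export
shared_taxa_intersections <- function(table, groups) {
  table <- suppressMessages(validate_community_table(table))
  groups <- as.factor(groups)
  if (length(groups) != nrow(table)) stop("one group label per sample required")
  lv <- levels(droplevels(groups))
  present <- sapply(lv, function(g)
    colSums(table[groups == g, , drop = FALSE] > 0) > 0)  # taxa x groups
  detected <- rowSums(present) > 0
  pattern <- apply(present[detected, , drop = FALSE], 1, function(z)
    paste(lv[z], collapse = "&"))
  counts <- table(pattern)
  inter <- data.frame(groups = names(counts), count = as.integer(counts),
                      row.names = NULL, stringsAsFactors = FALSE)
  inter <- inter[order(-inter$count), , drop = FALSE]
  rownames(inter) <- NULL
  uniq <- sapply(lv, function(g) {
    rich <- sum(present[, g])
    if (rich == 0) return(NA_real_)
    sum(present[, g] & rowSums(present) == 1) / rich
  })
  list(intersections = inter, unique_fraction = uniq)
}
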