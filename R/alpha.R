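# Library-size normalization (scaling with ranked subsampling) and
# taxonomic/phylogenetic alpha diversity.

#' Normalize library sizes by scaling with ranked subsampling (SRS)
#'
#' Each sample's counts are scaled by `c_min / total`; the integer parts
#' are kept and the remaining deficit is distributed one count each to the
#' taxa ranked by descending fractional part, ties broken by a seeded
#' random draw among the tied taxa. Every retained sample therefore sums
#' to exactly `c_min`. Samples with totals below `c_min` are dropped with
#' a warning.
#'
#' @param table community count matrix (samples x taxa).
#' @param c_min target library size; defaults to the minimum sample total.
#' @param seed RNG seed used only to break fractional-part ties.
#' @return a matrix of normalized counts, every row summing to `c_min`.
#' @export
srs_normalize <- function(table, c_min = min(rowSums(table)), seed = 1L) {
  table <- validate_community_table(table, drop_empty_taxa = FALSE)
  if (c_min <= 0) stop("c_min must be a positive integer")
  c_min <- as.integer(c_min)
  totals <- rowSums(table)
  if (any(totals < c_min)) {
    warning("dropping ", sum(totals < c_min), " samples with totals below c_min")
    table <- table[totals >= c_min, , drop = FALSE]
    if (nrow(table) == 0) stop("no samples left at c_min = ", c_min)
    totals <- rowSums(table)
  }
  local_seed(seed, {
    out <- table
    for (i in seq_len(nrow(table))) {
      scaled <- table[i, ] * c_min / totals[i]
      ints <- floor(scaled)
      deficit <- c_min - sum(ints)
      if (deficit > 0) {
        frac <- scaled - ints
        ord <- order(-frac, sample.int(length(frac)))  # random tie-break
        ints[ord[seq_len(deficit)]] <- ints[ord[seq_len(deficit)]] + 1
      }
      out[i, ] <- ints
    }
    out
  })
}

#' Shannon and Gini-Simpson diversity per sample
#'
#' Shannon entropy in nats, `-sum(p log p)`, and the Gini-Simpson index
#' `1 - sum(p^2)`, with `p` the within-sample relative abundances. Both
#' are invariant to the sample's total abundance.
#'
#' @param table community matrix (samples x taxa), row sums > 0.
#' @return data.frame with `sample_id`, `shannon`, `gini_simpson`.
#' @export
taxonomic_alpha <- function(table) {
  table <- validate_community_table(table, drop_empty_taxa = FALSE)
  data.frame(sample_id = rownames(table),
             shannon = as.numeric(vegan::diversity(table, index = "shannon")),
             gini_simpson = as.numeric(vegan::diversity(table, index = "simpson")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Faith's phylogenetic diversity per sample
#'
#' Total branch length of the minimal subtree spanning each sample's
#' present taxa; with `include_root = TRUE` (the default convention) the
#' path to the root is included.
#'
#' @param table community matrix; all taxa must be tips of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @param include_root include the path from the spanning subtree to the root.
#' @return named numeric vector of PD values (branch-length units).
#' @export
faith_pd <- function(table, tree, include_root = TRUE) {
  al <- align_keep_tree(table, tree)
  if (any(rowSums(al$table > 0) == 0)) stop("sample with zero taxa present")
  res <- picante::pd(al$table, al$tree, include.root = include_root)
  stats::setNames(res$PD, rownames(al$table))
}

# shared machinery for tip-shuffle standardized effect sizes
ses_table <- function(obs, null_mat) {
  mu <- rowMeans(null_mat)
  sd_null <- apply(null_mat, 1, stats::sd)
  undef <- sd_null < .Machine$double.eps^0.5
  z <- (obs - mu) / sd_null
  z[undef] <- NA_real_
  list(z = z, mean_null = mu, sd_null = sd_null, undefined = undef)
}

#' Standardized effect size of Faith's PD (ses.PD)
#'
#' `(PD_obs - mean(PD_null)) / sd(PD_null)` with a null built by shuffling
#' taxa labels across the tips of the supplied tree (`n_reps` shuffles;
#' richness preserved). Negative values indicate less lineage diversity
#' than expected by chance. Pairs where the null has zero spread (e.g., a
#' sample spanning every tip) are flagged undefined (`NA`), never reported
#' as 0.
#'
#' @inheritParams faith_pd
#' @param n_reps number of null shuffles (default 999).
#' @param seed RNG seed.
#' @return data.frame with `sample_id`, `pd_obs`, `pd_null_mean`,
#'   `pd_null_sd`, `ses_pd`, `undefined`.
#' @export
ses_pd <- function(table, tree, n_reps = 999, seed = 1L, include_root = TRUE) {
  al <- align_keep_tree(table, tree)
  if (any(rowSums(al$table > 0) < 2)) stop("ses_pd requires >= 2 taxa per sample")
  tab <- al$table
  single <- nrow(tab) == 1L
  if (single) tab <- rbind(tab, `..dup` = tab[1, ])
  res <- local_seed(seed,
    picante::ses.pd(tab, al$tree, null.model = "taxa.labels",
                    runs = n_reps, include.root = include_root))
  if (single) res <- res[1, , drop = FALSE]
  undef <- !is.finite(res$pd.obs.z) | res$pd.rand.sd < .Machine$double.eps^0.5
  z <- res$pd.obs.z
  z[undef] <- NA_real_
  data.frame(sample_id = rownames(al$table), pd_obs = res$pd.obs,
             pd_null_mean = res$pd.rand.mean, pd_null_sd = res$pd.rand.sd,
             ses_pd = z, undefined = undef,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Nearest taxon index (NTI) per sample
#'
#' The mean nearest taxon distance (MNTD) — abundance-weighted by default —
#' is compared against `n_reps` tip-label shuffles across the supplied
#' tree; `NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null)`, so that
#' phylogenetic clustering yields positive NTI. Degenerate nulls (zero
#' spread, e.g., a star phylogeny) are flagged undefined.
#'
#' @inheritParams ses_pd
#' @param abundance_weighted weight each taxon's nearest-neighbour distance
#'   by its relative abundance.
#' @return data.frame with `sample_id`, `mntd_obs`, `mntd_null_mean`,
#'   `mntd_null_sd`, `nti`, `undefined`.
#' @export
nti <- function(table, tree, n_reps = 999, seed = 1L, abundance_weighted = TRUE) {
  al <- align_pool(table, tree)
  if (any(rowSums(al$table > 0) < 2)) stop("nti requires >= 2 taxa per sample")
  tab <- al$table
  single <- nrow(tab) == 1L
  if (single) tab <- rbind(tab, `..dup` = tab[1, ])
  res <- local_seed(seed,
    picante::ses.mntd(tab, stats::cophenetic(al$tree),
                      null.model = "taxa.labels", runs = n_reps,
                      abundance.weighted = abundance_weighted))
  if (single) res <- res[1, , drop = FALSE]
  undef <- !is.finite(res$mntd.obs.z) | res$mntd.rand.sd < .Machine$double.eps^0.5
  z <- -res$mntd.obs.z
  z[undef] <- NA_real_
  data.frame(sample_id = rownames(al$table), mntd_obs = res$mntd.obs,
             mntd_null_mean = res$mntd.rand.mean, mntd_null_sd = res$mntd.rand.sd,
             nti = z, undefined = undef,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' All alpha-diversity metrics in one table
#'
#' Convenience wrapper combining [taxonomic_alpha()], [faith_pd()],
#' [ses_pd()] and [nti()].
#'
#' @inheritParams ses_pd
#' @inheritParams nti
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(table, tree, n_reps = 999, seed = 1L,
                            include_root = TRUE, abundance_weighted = TRUE) {
  tax <- taxonomic_alpha(table)
  pd <- faith_pd(table, tree, include_root = include_root)
  sp <- ses_pd(table, tree, n_reps = n_reps, seed = child_seed(seed, "sespd"),
               include_root = include_root)
  nt <- nti(table, tree, n_reps = n_reps, seed = child_seed(seed, "nti"),
            abundance_weighted = abundance_weighted)
  data.frame(tax, faith_pd = unname(pd[tax$sample_id]),
             ses_pd = sp$ses_pd, nti = nt$nti,
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis and Dunn post-hoc comparison of a metric between groups
#'
#' Thin reporting utility: a Kruskal-Wallis rank-sum test across groups
#' followed by Dunn's pairwise z tests (with tie correction) and
#' Benjamini-Hochberg adjustment.
#'
#' @param values numeric vector of a per-sample metric.
#' @param groups group label per value.
#' @return `list(kruskal = htest, dunn = data.frame)` where `dunn` has one
#'   row per group pair with `z`, `p`, `p_adj`.
#' @export
alpha_group_test <- function(values, groups) {
  groups <- as.factor(groups)
  kw <- stats::kruskal.test(values, groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_corr
  lv <- levels(groups)
  prs <- utils::combn(lv, 2)
  dunn <- apply(prs, 2, function(p) {
    i <- groups == p[1]; j <- groups == p[2]
    z <- (mean(r[i]) - mean(r[j])) / sqrt(v0 * (1 / sum(i) + 1 / sum(j)))
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group_1 = prs[1, ], group_2 = prs[2, ],
                    z = dunn["z", ], p = dunn["p", ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p)
  list(kruskal = kw, dunn = out)
}
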