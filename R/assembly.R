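# Null-model inference of community assembly processes: phylogenetic
# signal testing, beta-MNTD / beta-NTI, the Raup-Crick (Bray-Curtis)
# null, classification of sample pairs into the five-process vocabulary,
# and relative process contributions per stratum.

#' Abundance-weighted niche optima of taxa
#'
#' The niche optimum of a taxon is its abundance-weighted mean environment
#' across samples, `sum_s n[s,t] env[s] / sum_s n[s,t]`. Taxa with zero
#' total abundance are excluded with a warning.
#'
#' @param table community matrix (samples x taxa).
#' @param env named numeric vector of the environmental variable, one
#'   value per sample (names matching sample ids, or in table row order).
#' @return named numeric vector of niche optima per taxon.
#' @export
estimate_niche_optima <- function(table, env) {
  table <- validate_community_table(table, drop_empty_taxa = FALSE)
  if (!is.null(names(env))) {
    miss <- setdiff(rownames(table), names(env))
    if (length(miss)) stop("env missing for samples: ", paste(miss, collapse = ", "))
    env <- env[rownames(table)]
  } else if (length(env) != nrow(table)) {
    stop("need one env value per sample")
  }
  tot <- colSums(table)
  if (any(tot == 0)) {
    warning("excluding ", sum(tot == 0), " taxa with zero total abundance")
    table <- table[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  colSums(table * env) / tot
}

#' Mantel correlogram of phylogenetic signal
#'
#' Tests, per phylogenetic-distance class, the Mantel correlation between
#' niche (trait) distances and membership in the class, with permutation
#' p-values and progressive multiple-test correction across classes —
#' the standard check that close relatives have similar niches, which the
#' beta-NTI framework presupposes. Distance classes are equal-frequency by
#' default (equal-width behind the flag).
#'
#' @param d_trait taxon-by-taxon niche distance matrix (e.g.
#'   `abs(outer(opt, opt, "-"))`).
#' @param d_phylo taxon-by-taxon patristic distance matrix over the same taxa.
#' @param n_classes number of distance classes (default: Sturges' rule).
#' @param n_reps permutations per class (default 999).
#' @param seed RNG seed.
#' @param equal_freq equal-frequency class boundaries (default) rather
#'   than equal-width.
#' @return data.frame with one row per class: `class_index`, `midpoint`,
#'   `n_pairs`, `mantel_r`, `p`, `p_adj` (progressive correction; `NA`
#'   rows are classes beyond the correlogram cutoff).
#' @export
mantel_correlogram <- function(d_trait, d_phylo, n_classes = NULL,
                               n_reps = 999, seed = 1L, equal_freq = TRUE) {
  d_trait <- as_distance_matrix(d_trait)
  d_phylo <- as_distance_matrix(d_phylo)
  if (!identical(dim(d_trait), dim(d_phylo)))
    stop("trait and phylogenetic distance matrices must share taxa")
  v <- d_phylo[lower.tri(d_phylo)]
  if (is.null(n_classes)) n_classes <- ceiling(1 + log2(length(v)))
  breaks <- if (equal_freq) {
    b <- unique(signif(stats::quantile(v, probs = seq(0, 1, length.out = n_classes + 1)), 10))
    if (length(b) < 3) stop("too few distinct phylogenetic distances for classes")
    # rounding must never leave a pair outside the outermost classes
    b[1] <- min(v) - 1e-8
    b[length(b)] <- max(v) + 1e-8
    b
  } else {
    seq(min(v), max(v), length.out = n_classes + 1)
  }
  res <- local_seed(seed,
    vegan::mantel.correlog(as.dist(d_trait), D.geo = as.dist(d_phylo),
                           break.pts = breaks, cutoff = FALSE,
                           nperm = n_reps, mult = "holm", progressive = TRUE))
  m <- as.data.frame(res$mantel.res)
  data.frame(class_index = seq_len(nrow(m)),
             midpoint = m[, "class.index"], n_pairs = m[, "n.dist"],
             mantel_r = m[, "Mantel.cor"], p = m[, "Pr(Mantel)"],
             p_adj = m[, "Pr(corrected)"], row.names = NULL)
}

# core beta-MNTD kernel: idx/weights per sample, patristic matrix `dmat`
# (optionally viewed through the taxon permutation `perm`)
bmntd_pair <- function(ia, ib, wa, wb, dmat, perm = NULL) {
  if (!is.null(perm)) { ia <- perm[ia]; ib <- perm[ib] }
  sub <- dmat[ia, ib, drop = FALSE]
  0.5 * (sum(wa * row_mins(sub)) + sum(wb * row_mins(t(sub))))
}

sample_support <- function(table, abundance_weighted) {
  lapply(seq_len(nrow(table)), function(i) {
    idx <- which(table[i, ] > 0)
    w <- if (abundance_weighted) table[i, idx] / sum(table[i, idx])
         else rep(1 / length(idx), length(idx))
    list(idx = idx, w = w)
  })
}

#' Between-sample mean nearest taxon distance (beta-MNTD)
#'
#' For samples A and B,
#' `0.5 * (sum_t f_tA min_u d(t, u in B) + sum_u f_uB min_t d(u, t in A))`
#' with `f` the relative abundances (or `1/richness` unweighted): the
#' average phylogenetic distance of each taxon to its closest relative in
#' the other community.
#'
#' @param table community matrix; all taxa must be tips of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @param abundance_weighted weight by relative abundance (default `TRUE`).
#' @return symmetric sample-by-sample matrix of beta-MNTD values.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  al <- align_pool(table, tree)
  dmat <- stats::cophenetic(al$tree)[colnames(al$table), colnames(al$table)]
  sup <- sample_support(al$table, abundance_weighted)
  n <- nrow(al$table)
  out <- matrix(0, n, n, dimnames = list(rownames(al$table), rownames(al$table)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- bmntd_pair(sup[[i]]$idx, sup[[j]]$idx,
                                         sup[[i]]$w, sup[[j]]$w, dmat)
  }
  out
}

#' Beta nearest taxon index (beta-NTI)
#'
#' Standardized effect size of beta-MNTD against a null that shuffles
#' taxa labels across the regional pool — every taxon column of the
#' table, observed or not, so supplying the full pool widens the null
#' beyond the taxa the samples happen to contain — preserving each
#' community's richness and abundances:
#' `betaNTI = (obs - mean_null) / sd_null` per sample pair. Values above 2
#' indicate variable selection, below -2 homogeneous selection. Pairs with
#' a degenerate null (zero spread, e.g. on a star phylogeny) are `NA` and
#' flagged in the `undefined` attribute.
#'
#' @inheritParams beta_mntd
#' @param n_reps number of null shuffles (default 999).
#' @param seed RNG seed.
#' @return symmetric matrix of beta-NTI z-scores with attributes
#'   `bmntd_obs` (observed beta-MNTD matrix) and `undefined` (logical
#'   matrix marking degenerate-null pairs).
#' @export
beta_nti <- function(table, tree, n_reps = 999, seed = 1L,
                     abundance_weighted = TRUE) {
  al <- align_pool(table, tree)
  ntax <- ncol(al$table)
  dmat <- stats::cophenetic(al$tree)[colnames(al$table), colnames(al$table)]
  sup <- sample_support(al$table, abundance_weighted)
  n <- nrow(al$table)
  prs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  obs <- apply(prs, 1, function(p)
    bmntd_pair(sup[[p[1]]]$idx, sup[[p[2]]]$idx,
               sup[[p[1]]]$w, sup[[p[2]]]$w, dmat))
  nulls <- local_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      perm <- sample.int(ntax)  # one tip shuffle shared by all pairs
      apply(prs, 1, function(p)
        bmntd_pair(sup[[p[1]]]$idx, sup[[p[2]]]$idx,
                   sup[[p[1]]]$w, sup[[p[2]]]$w, dmat, perm))
    }, numeric(nrow(prs)))
  })
  nulls <- matrix(nulls, nrow = nrow(prs))
  st <- ses_table(obs, nulls)
  ids <- rownames(al$table)
  z <- ob <- matrix(0, n, n, dimnames = list(ids, ids))
  un <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  z[prs] <- st$z; z[prs[, 2:1, drop = FALSE]] <- st$z
  ob[prs] <- obs; ob[prs[, 2:1, drop = FALSE]] <- obs
  un[prs] <- st$undefined; un[prs[, 2:1, drop = FALSE]] <- st$undefined
  structure(z, bmntd_obs = ob, undefined = un)
}

# one Raup-Crick null community: fix richness and total abundance,
# draw taxa by occupancy, give each drawn taxon one individual, then
# allocate the remaining individuals by regional relative abundance
rc_null_community <- function(richness, total, occupancy, regional_p) {
  idx <- sample.int(length(occupancy), richness, prob = occupancy)
  counts <- numeric(length(occupancy))
  counts[idx] <- 1
  if (total > richness) {
    extra <- stats::rmultinom(1, total - richness, prob = regional_p[idx])
    counts[idx] <- counts[idx] + extra
  }
  counts
}

#' Raup-Crick dissimilarity on Bray-Curtis (RC_bray)
#'
#' For each sample pair, `n_reps` pairs of null communities are assembled
#' from the regional pool: each null community draws the observed richness
#' of taxa with probability proportional to occupancy (fraction of samples
#' occupied), then allocates the observed total abundance across the drawn
#' taxa with probability proportional to regional relative abundance (one
#' individual is placed on every drawn taxon first, so richness is kept).
#' The observed Bray-Curtis dissimilarity is located within the null
#' distribution, ties counted at half weight, and rescaled to `[-1, 1]`:
#' `RC = 2 * ((#(null < obs) + 0.5 #(null = obs)) / n_reps - 0.5)`.
#' Values above 0.95 indicate dispersal limitation, below -0.95
#' homogenizing dispersal.
#'
#' @param table community count matrix (integer counts, samples x taxa).
#' @param n_reps null replicates per pair (default 999).
#' @param seed RNG seed.
#' @return symmetric matrix of RC_bray values in `[-1, 1]`.
#' @export
raup_crick_bray <- function(table, n_reps = 999, seed = 1L) {
  table <- validate_community_table(table, drop_empty_taxa = FALSE)
  if (ncol(table) < 2) stop("regional pool of one taxon")
  if (nrow(table) < 2) stop("need at least two samples")
  if (any(abs(table - round(table)) > 1e-8))
    stop("raup_crick_bray requires integer counts")
  occupancy <- colSums(table > 0) / nrow(table)
  regional_p <- colSums(table) / sum(table)
  rich <- rowSums(table > 0)
  tot <- round(rowSums(table))
  n <- nrow(table)
  ids <- rownames(table)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  obs_bc <- as.matrix(vegan::vegdist(table, method = "bray"))
  local_seed(seed, {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      null_bc <- vapply(seq_len(n_reps), function(r) {
        a <- rc_null_community(rich[i], tot[i], occupancy, regional_p)
        b <- rc_null_community(rich[j], tot[j], occupancy, regional_p)
        sum(abs(a - b)) / sum(a + b)
      }, numeric(1))
      frac <- (sum(null_bc < obs_bc[i, j] - 1e-12) +
                 0.5 * sum(abs(null_bc - obs_bc[i, j]) <= 1e-12)) / n_reps
      out[i, j] <- out[j, i] <- 2 * (frac - 0.5)
    }
  })
  out
}

#' Classify sample pairs into assembly processes
#'
#' The standard two-step decision: `betaNTI > 2` is variable selection,
#' `betaNTI < -2` homogeneous selection; otherwise selection is discounted
#' and `RC_bray > 0.95` indicates dispersal limitation, `RC_bray < -0.95`
#' homogenizing dispersal, and values within both null envelopes drift.
#'
#' @param bnti beta-NTI value(s).
#' @param rc RC_bray value(s), same length.
#' @return factor of process labels (`NA` where `bnti` is undefined).
#' @export
classify_assembly <- function(bnti, rc) {
  if (length(bnti) != length(rc)) stop("bnti and rc lengths differ")
  lv <- c("variable_selection", "homogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal", "drift")
  lab <- ifelse(bnti > 2, "variable_selection",
         ifelse(bnti < -2, "homogeneous_selection",
         ifelse(rc > 0.95, "dispersal_limitation",
         ifelse(rc < -0.95, "homogenizing_dispersal", "drift"))))
  factor(lab, levels = lv)
}

#' Per-pair assembly inference
#'
#' Runs [beta_nti()] and [raup_crick_bray()] on a dataset and classifies
#' every unordered sample pair.
#'
#' @inheritParams beta_nti
#' @return data.frame with one row per unordered sample pair:
#'   `sample_1`, `sample_2`, `beta_mntd`, `beta_nti`, `rc_bray`, `process`.
#' @export
infer_assembly <- function(table, tree, n_reps = 999, seed = 1L,
                           abundance_weighted = TRUE) {
  z <- beta_nti(table, tree, n_reps = n_reps,
                seed = child_seed(seed, "bnti"),
                abundance_weighted = abundance_weighted)
  rc <- raup_crick_bray(table, n_reps = n_reps, seed = child_seed(seed, "rc"))
  ids <- rownames(z)
  prs <- sample_pairs(ids)
  bnti_v <- z[prs]
  undef <- attr(z, "undefined")[prs]
  bnti_v[undef] <- NA_real_
  data.frame(sample_1 = prs[, 1], sample_2 = prs[, 2],
             beta_mntd = attr(z, "bmntd_obs")[prs],
             beta_nti = bnti_v, rc_bray = rc[prs],
             process = classify_assembly(bnti_v, rc[prs]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative contributions of assembly processes per stratum
#'
#' Percent of classified sample pairs bearing each process label within
#' each stratum (e.g., a sample type or a site transition). Pairs with an
#' undefined beta-NTI are excluded and counted; empty strata are omitted
#' with a warning.
#'
#' @param process vector/factor of process labels per pair (`NA` = excluded).
#' @param strata stratum label per pair (default: one overall stratum).
#' @return data.frame `stratum` x `process` with `percent` summing to 100
#'   within each stratum; the number of excluded pairs is attached as
#'   attribute `n_excluded`.
#' @export
process_contributions <- function(process,
                                  strata = rep("all", length(process))) {
  if (length(process) != length(strata)) stop("process and strata lengths differ")
  lv <- c("variable_selection", "homogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal", "drift")
  process <- factor(process, levels = lv)
  keep <- !is.na(process)
  n_excluded <- sum(!keep)
  process <- process[keep]; strata <- strata[keep]
  out <- list()
  for (s in unique(strata)) {
    p <- process[strata == s]
    if (!length(p)) { warning("empty stratum omitted: ", s); next }
    tab <- table(p)
    out[[s]] <- data.frame(stratum = s, process = names(tab),
                           n_pairs = as.integer(tab),
                           percent = 100 * as.numeric(tab) / length(p),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, n_excluded = n_excluded)
}
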