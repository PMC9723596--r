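# Synthetic communities assembled under known ecological processes.
#
# The generator emulates a sequential gradient-transfer incubation: a
# regional pool of taxa evolves niche optima on a phylogeny (Brownian
# motion, so closely related taxa have similar niches), and communities at
# each site recruit from the pool under a declared assembly regime. The
# regimes map onto the five-process vocabulary of the null-model framework
# so that downstream inference can be validated by process recovery.

#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) tree with `n_taxa` tips, rescaled to unit root-to-tip
#' depth so that phylogenetic effect sizes are comparable across scenarios.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed RNG seed.
#' @return an ultrametric `phylo` with tips `t1..tn` and total depth 1.
#' @export
simulate_phylogeny <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  tree <- local_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

#' Evolve niche optima along a phylogeny
#'
#' Brownian-motion trait at each tip: independent normal increments per
#' branch with variance `sigma^2 * branch_length`, root value 0. This is
#' the mechanism that guarantees phylogenetic signal — the relationship
#' between relatedness and niche similarity that the beta-NTI framework
#' presupposes.
#'
#' @param tree a `phylo` with branch lengths.
#' @param sigma Brownian rate (per square-root unit branch length); > 0.
#' @param seed RNG seed.
#' @return named numeric vector of niche optima, one per tip.
#' @export
evolve_traits <- function(tree, sigma = 1, seed = 1L) {
  validate_phylogeny(tree)
  if (sigma <= 0) stop("sigma must be > 0")
  local_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma,
                                   ancestor = FALSE, root.value = 0))
}

#' Define a synthetic assembly scenario
#'
#' Defaults describe a four-site sequential gradient (the sites spaced
#' monotonically across niche space, as along a salinity gradient from
#' freshwater to coastal-marine conditions) with three replicate
#' communities per site, a truncated Gaussian environmental filter, and
#' niche optima conserved within recent radiations. `process` gives the
#' regime governing each between-site transition (scalar recycled); site 1
#' is governed by the first element.
#'
#' @param n_pool_taxa regional pool size.
#' @param tree_seed,community_seed independent seeds for the phylogeny and
#'   the community assembly stage.
#' @param trait_sigma Brownian rate for niche evolution (environment units).
#' @param niche_conservatism conservation depth in (0, 1]: niche optima
#'   evolve by Brownian motion only down to this fraction of the tree
#'   depth and are frozen afterwards, so taxa that diverged more recently
#'   share a niche (1 = plain Brownian motion). An environmental filter
#'   therefore admits whole groups of close relatives.
#' @param env_values one environment value per site (monotone gradient).
#' @param env_scale `"absolute"`: `env_values` are in trait units;
#'   `"quantile"`: each value in (0, 1) is mapped to that quantile of the
#'   realized niche-optimum distribution, placing sites onto occupied
#'   regions of niche space whatever the particular tree and trait draw.
#' @param site_names site labels (length as `env_values`).
#' @param selection_strength inverse squared width of the Gaussian filter
#'   `exp(-strength * (optimum - env)^2)`; 0 disables selection.
#' @param filter_breadth fraction of the pool admitted by the selection
#'   regimes (fundamental-niche cutoff): taxa outside the best-matched
#'   fraction cannot establish, whatever their Gaussian weight.
#' @param process one of `"homogeneous_selection"`, `"variable_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"drift"`;
#'   scalar or one per transition.
#' @param n_replicates replicate communities per site.
#' @param reads_per_sample sequencing depth (fixed library size).
#' @param mixing_fraction for dispersal limitation: fraction of recruitment
#'   drawn from the global pool rather than the site subpool (m << 1).
#' @param homogenization_noise for homogenizing dispersal: fraction of each
#'   sample's reads exchanged against the pool rather than copied from the
#'   shared realized metacommunity.
#' @param drift_richness_fraction fraction of the pool each sample
#'   recruits in the membership lottery (all regimes except homogenizing
#'   dispersal, whose samples copy the realized metacommunity), so that
#'   community membership — not only abundance — is stochastic.
#' @return a `scenario` list.
#' @export
scenario <- function(n_pool_taxa = 64L,
                     tree_seed = 1L,
                     community_seed = 1L,
                     trait_sigma = 1,
                     niche_conservatism = 0.6,
                     env_values = c(0.1, 0.37, 0.63, 0.9),
                     env_scale = c("quantile", "absolute"),
                     site_names = paste0("site", seq_along(env_values)),
                     selection_strength = 1000,
                     filter_breadth = 0.3,
                     process = "variable_selection",
                     n_replicates = 3L,
                     reads_per_sample = 2000L,
                     mixing_fraction = 0.02,
                     homogenization_noise = 0.02,
                     drift_richness_fraction = 0.25) {
  env_scale <- match.arg(env_scale)
  if (env_scale == "quantile" && any(env_values <= 0 | env_values >= 1))
    stop("quantile env_values must lie strictly in (0, 1)")
  procs <- c("homogeneous_selection", "variable_selection",
             "dispersal_limitation", "homogenizing_dispersal", "drift")
  if (!all(process %in% procs))
    stop("unknown process label(s): ", paste(setdiff(process, procs), collapse = ", "))
  n_sites <- length(env_values)
  if (n_sites < 1) stop("need at least one site")
  if (length(site_names) != n_sites) stop("site_names and env_values lengths differ")
  n_trans <- max(1L, n_sites - 1L)
  if (!length(process) %in% c(1L, n_trans))
    stop("process must be scalar or one per transition (", n_trans, ")")
  process <- rep_len(process, n_trans)
  stopifnot(n_pool_taxa >= 2, trait_sigma > 0,
            niche_conservatism > 0, niche_conservatism <= 1,
            selection_strength >= 0,
            filter_breadth > 0, filter_breadth <= 1,
            n_replicates >= 1, reads_per_sample >= 1,
            mixing_fraction >= 0, mixing_fraction <= 1,
            homogenization_noise >= 0, homogenization_noise <= 1,
            drift_richness_fraction > 0, drift_richness_fraction <= 1)
  structure(list(n_pool_taxa = as.integer(n_pool_taxa),
                 tree_seed = as.integer(tree_seed),
                 community_seed = as.integer(community_seed),
                 trait_sigma = trait_sigma,
                 niche_conservatism = niche_conservatism,
                 env_values = env_values,
                 env_scale = env_scale,
                 site_names = site_names,
                 selection_strength = selection_strength,
                 filter_breadth = filter_breadth,
                 process = process,
                 n_replicates = as.integer(n_replicates),
                 reads_per_sample = as.integer(reads_per_sample),
                 mixing_fraction = mixing_fraction,
                 homogenization_noise = homogenization_noise,
                 drift_richness_fraction = drift_richness_fraction),
            class = "scenario")
}

# Niche-conservatism rescaling of branch lengths for trait evolution:
# trait variance accrues only on the part of each branch deeper than the
# conservation depth `t_star` (tree depth 1), so lineages that diverged
# more recently than `t_star` inherit identical niche optima — recent
# radiations form guilds of close relatives sharing a niche, which is the
# signal structure the beta-NTI framework presupposes. Used only for
# trait evolution; all phylogenetic distances downstream use the
# untransformed tree. `t_star = 1` leaves plain Brownian motion.
conserve_niches <- function(tree, t_star) {
  if (t_star >= 1) return(tree)
  if (t_star <= 0) stop("conservation depth must lie in (0, 1]")
  depth <- ape::node.depth.edgelength(tree)
  t0 <- depth[tree$edge[, 1]]
  t1 <- t0 + tree$edge.length
  tree$edge.length <- (pmin(t1, t_star) - pmin(t0, t_star)) / t_star
  tree
}

# Recruitment weights over the pool for one site under one regime.
# Computed in log space so extreme filters never underflow to all-zero.
site_weights <- function(regime, env_site, env_mean, traits, pool_p,
                         subpool, strength, m, breadth = 0.3) {
  logp <- log(pool_p)
  lw <- switch(regime,
    variable_selection = -strength * (traits - env_site)^2 + logp,
    homogeneous_selection = -strength * (traits - env_mean)^2 + logp,
    drift = logp,
    homogenizing_dispersal = logp,
    dispersal_limitation = {
      w_sub <- ifelse(subpool, pool_p / sum(pool_p[subpool]), 0)
      return((1 - m) * w_sub + m * pool_p)
    },
    stop("unknown regime ", regime))
  w <- exp(lw - max(lw))
  if (strength > 0 && regime %in% c("variable_selection", "homogeneous_selection")) {
    # fundamental-niche cutoff: only the `breadth` fraction of the pool
    # best matched to the environment can establish at all; establishment
    # odds among those stay Gaussian in trait distance. A fixed admitted
    # fraction keeps the strength of selection comparable across trees,
    # which a pure weight floor does not (admitted-set sizes then swing
    # with the realized trait spread).
    keep <- rank(-w, ties.method = "first") <= max(2L, ceiling(breadth * length(w)))
    w[!keep] <- 0
  }
  w / sum(w)
}

# Recruitment lottery: a sample's membership is a weighted draw (without
# replacement) of k taxa from the pool, and its reads are then allocated
# multinomially among the drawn taxa. Community membership — not only
# abundance — is therefore stochastic, as in real amplicon data where no
# sample holds the whole regional pool. Under uniform weights this is
# drift (turnover matches the null expectation); under filter or subpool
# weights it adds the demographic noise on top of selection or dispersal.
# Weighted sampling without replacement via exponential keys
# (Efraimidis-Spirakis). base::sample's sequential algorithm loses
# probability mass to floating-point cancellation when weights span many
# orders of magnitude (a hard environmental filter), and then recruits
# zero-weight taxa; the key construction is exact for any weight range.
weighted_draw <- function(k, w) {
  keys <- rep(-Inf, length(w))
  pos <- w > 0
  keys[pos] <- log(stats::runif(sum(pos))) / w[pos]
  order(keys, decreasing = TRUE)[seq_len(k)]
}

draw_lottery_sample <- function(n_pool, reads, richness_fraction, w) {
  k <- min(max(2L, round(richness_fraction * n_pool)), sum(w > 0))
  idx <- weighted_draw(k, w)
  counts <- numeric(n_pool)
  counts[idx] <- 1
  counts[idx] <- counts[idx] +
    stats::rmultinom(1, reads - k, prob = rep(1 / k, k))
  counts
}

# Homogenizing dispersal (mass effects): every sample is a near-copy of
# one realized, well-mixed metacommunity; only a small fraction of reads
# is exchanged against the pool, so samples are far more similar than
# independent draws could be.
perturb_metacommunity <- function(meta_counts, noise, w) {
  reads <- sum(meta_counts)
  n_swap <- stats::rbinom(1, reads, noise)
  if (n_swap > 0) {
    removed <- tabulate(sample(rep.int(seq_along(meta_counts), meta_counts),
                               n_swap), nbins = length(meta_counts))
    meta_counts <- meta_counts - removed +
      as.vector(stats::rmultinom(1, n_swap, w))
  }
  meta_counts
}

#' Assemble a synthetic dataset under a scenario
#'
#' Per site and replicate, a community of `reads_per_sample` individuals is
#' recruited from the regional pool under the regime governing the site:
#' a Gaussian environmental filter times pool abundance for the selection
#' regimes (toward each site's own environment for variable selection,
#' toward the gradient-wide mean environment for homogeneous selection);
#' site-biased nearly disjoint subpools (mixing fraction `m`) for
#' dispersal limitation; a recruitment lottery over a random pool subset
#' for drift (no selection, no barrier — membership and abundance both
#' stochastic); and, for homogenizing dispersal, near-copies of a single
#' realized well-mixed metacommunity with a small read-exchange fraction,
#' emulating mass effects.
#'
#' A single root seed spawns per-stage and per-sample child streams, so
#' adding replicates or sites never perturbs earlier draws.
#'
#' @param scn a [scenario()].
#' @return `list(table, meta, tree, traits)`: counts matrix (samples x
#'   taxa, every row summing to `reads_per_sample`), metadata data.frame,
#'   the pool phylogeny, and the niche-optimum trait map.
#' @export
assemble_dataset <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  n_sites <- length(scn$env_values)
  tree <- simulate_phylogeny(scn$n_pool_taxa, scn$tree_seed)
  traits <- evolve_traits(conserve_niches(tree, scn$niche_conservatism),
                          scn$trait_sigma,
                          child_seed(scn$tree_seed, "traits"))
  pool_p <- rep(1 / scn$n_pool_taxa, scn$n_pool_taxa)  # even regional pool
  env <- if (scn$env_scale == "quantile") {
    as.numeric(stats::quantile(traits, probs = scn$env_values))
  } else scn$env_values
  env_mean <- mean(env)

  # regime governing each site = regime of the transition into it
  site_regime <- scn$process[c(1L, seq_len(n_sites - 1L))][seq_len(n_sites)]

  # global structures shared across sites
  subpool_of <- local_seed(child_seed(scn$community_seed, "subpools"),
                           sample(rep_len(seq_len(n_sites), scn$n_pool_taxa)))
  metacommunity <- local_seed(child_seed(scn$community_seed, "metacommunity"),
                              draw_lottery_sample(scn$n_pool_taxa, scn$reads_per_sample,
                                                  scn$drift_richness_fraction, pool_p))

  samples <- list()
  meta <- list()
  for (k in seq_len(n_sites)) {
    w <- site_weights(site_regime[k], env[k], env_mean, traits,
                      pool_p, subpool_of == k, scn$selection_strength,
                      scn$mixing_fraction, scn$filter_breadth)
    for (r in seq_len(scn$n_replicates)) {
      sid <- sprintf("%s_r%d", scn$site_names[k], r)
      s <- child_seed(scn$community_seed, sid)
      counts <- if (site_regime[k] == "homogenizing_dispersal") {
        local_seed(s, perturb_metacommunity(metacommunity,
                                            scn$homogenization_noise, w))
      } else {
        local_seed(s, draw_lottery_sample(scn$n_pool_taxa, scn$reads_per_sample,
                                          scn$drift_richness_fraction, w))
      }
      samples[[sid]] <- counts
      meta[[sid]] <- data.frame(sample_id = sid, site = scn$site_names[k],
                                env = env[k], replicate = r,
                                regime = site_regime[k],
                                stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, samples)
  colnames(table) <- tree$tip.label
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  list(table = table, meta = meta, tree = tree, traits = traits)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `table.tsv`, `tree.nwk`, `metadata.tsv` and `traits.tsv` into a
#' directory, in the formats the readers of this package accept.
#'
#' @param dataset result of [assemble_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_community_table(dataset$table, file.path(dir, "table.tsv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.table(dataset$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(taxon_id = names(dataset$traits),
                                niche_optimum = unname(dataset$traits)),
                     file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
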