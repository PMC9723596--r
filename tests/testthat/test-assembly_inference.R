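test_that("niche optima are abundance-weighted mean environments", {
  m <- rbind(s1 = c(t1 = 1, t2 = 1), s2 = c(t1 = 3, t2 = 0))
  expect_equal(unname(estimate_niche_optima(m, c(s1 = 0, s2 = 4))),
               c(3, 0))
  only5 <- rbind(s1 = c(t1 = 2), s2 = c(t1 = 3))
  expect_equal(unname(estimate_niche_optima(only5, c(s1 = 5, s2 = 5))), 5)
  const <- estimate_niche_optima(random_counts(4, 6, seed = 1), rep(2.5, 4))
  expect_true(all(const == 2.5))
  withzero <- cbind(random_counts(3, 4, seed = 2), dead = 0)
  expect_warning(estimate_niche_optima(withzero, 1:3), "zero total")
})

test_that("Mantel correlogram detects signal and is invariant to joint relabeling", {
  tree <- simulate_phylogeny(30, seed = 2)
  dp <- stats::cophenetic(tree)
  res <- mantel_correlogram(dp, dp, n_reps = 199, seed = 1)
  expect_gt(res$mantel_r[1], 0)
  expect_lte(res$p[1], 0.05)
  expect_true(all(diff(res$midpoint) >= 0))

  perm <- sample(nrow(dp))
  tr <- evolve_traits(tree, sigma = 1, seed = 3)[rownames(dp)]
  dt <- abs(outer(tr, tr, "-"))
  r1 <- mantel_correlogram(dt, dp, n_reps = 99, seed = 5)
  r2 <- mantel_correlogram(dt[perm, perm], dp[perm, perm], n_reps = 99, seed = 5)
  expect_equal(r1$mantel_r, r2$mantel_r)

  expect_error(mantel_correlogram(dt[1:10, 1:10], dp), "share taxa")
})

test_that("beta-MNTD reproduces hand values and the brute-force oracle", {
  tree <- toy_tree()
  m <- rbind(s1 = c(A = 1, B = 0, C = 0, D = 0), s2 = c(A = 0, B = 0, C = 1, D = 0))
  expect_equal(beta_mntd(m, tree)["s1", "s2"], 4)
  same <- rbind(s1 = c(A = 2, B = 1, C = 0, D = 0), s2 = c(A = 2, B = 1, C = 0, D = 0))
  expect_equal(beta_mntd(same, tree)["s1", "s2"], 0)

  for (s in 1:5) {
    tr <- simulate_phylogeny(16, seed = s)
    tab <- random_counts(4, 16, seed = s, lambda = 1.2)
    colnames(tab) <- tr$tip.label
    tab[, 1] <- pmax(tab[, 1], 1)
    for (aw in c(TRUE, FALSE))
      expect_equal(beta_mntd(tab, tr, abundance_weighted = aw),
                   bmntd_oracle(tab, tr, abundance_weighted = aw),
                   tolerance = 1e-10)
  }
})

test_that("beta-MNTD agrees with picante's comdistnt", {
  tree <- simulate_phylogeny(20, seed = 6)
  tab <- random_counts(5, 20, seed = 6, lambda = 1)
  colnames(tab) <- tree$tip.label
  tab[, 2] <- pmax(tab[, 2], 1)
  mine <- beta_mntd(tab, tree, abundance_weighted = TRUE)
  ref <- as.matrix(picante::comdistnt(tab, stats::cophenetic(tree),
                                      abundance.weighted = TRUE))
  ref <- ref[rownames(mine), colnames(mine)]
  diag(ref) <- 0
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("beta-NTI is deterministic, relabeling-invariant and flags degenerate nulls", {
  tree <- simulate_phylogeny(16, seed = 3)
  tab <- random_counts(4, 16, seed = 7, lambda = 1.5)
  colnames(tab) <- tree$tip.label
  tab[, 3] <- pmax(tab[, 3], 1)
  z1 <- beta_nti(tab, tree, n_reps = 99, seed = 11)
  z2 <- beta_nti(tab, tree, n_reps = 99, seed = 11)
  expect_identical(z1, z2)

  # reordering samples permutes the result without changing values
  ord <- c(3, 1, 4, 2)
  z3 <- beta_nti(tab[ord, ], tree, n_reps = 99, seed = 11)
  expect_equal(unclass(z3)[rownames(z1), colnames(z1)], unclass(z1)[, ],
               ignore_attr = TRUE)

  # column order is harmonized to the tree, so shuffling columns changes nothing
  z4 <- beta_nti(tab[, sample(16)], tree, n_reps = 99, seed = 11)
  expect_identical(z1, z4)

  star <- ape::stree(8, type = "star")
  star$edge.length <- rep(1, 8)
  star$tip.label <- paste0("t", 1:8)
  stab <- rbind(s1 = c(1, 1, 1, 0, 0, 0, 0, 0), s2 = c(0, 0, 0, 1, 1, 1, 0, 0))
  colnames(stab) <- star$tip.label
  zs <- beta_nti(stab, star, n_reps = 99, seed = 1)
  expect_true(attr(zs, "undefined")["s1", "s2"])
  expect_true(is.na(zs["s1", "s2"]))
})

test_that("communities confined to one clade give negative beta-NTI", {
  neg <- vapply(1:10, function(s) {
    tree <- simulate_phylogeny(32, seed = s)
    sizes <- vapply(33:(32 + tree$Nnode), function(nd)
      length(ape::extract.clade(tree, nd)$tip.label), numeric(1))
    clade <- ape::extract.clade(tree, (33:(32 + tree$Nnode))[which.min(abs(sizes - 12))])$tip.label
    set.seed(s)
    tab <- matrix(0, 2, 32, dimnames = list(c("s1", "s2"), tree$tip.label))
    tab[1, sample(clade, 6)] <- 1
    tab[2, sample(clade, 6)] <- 1
    z <- beta_nti(tab, tree, n_reps = 199, seed = s + 100)
    z["s1", "s2"]
  }, numeric(1))
  expect_gte(sum(neg < 0, na.rm = TRUE), 8)
})

test_that("abundance-weighted beta-NTI is invariant to count scaling", {
  tree <- simulate_phylogeny(16, seed = 9)
  tab <- random_counts(3, 16, seed = 10, lambda = 2)
  colnames(tab) <- tree$tip.label
  tab[, 1] <- pmax(tab[, 1], 1)
  expect_identical(beta_nti(tab, tree, n_reps = 99, seed = 5),
                   beta_nti(tab * 2, tree, n_reps = 99, seed = 5))
  expect_equal(pairwise_dissimilarity(tab, "bray_curtis"),
               pairwise_dissimilarity(tab * 2, "bray_curtis"))
})

test_that("Raup-Crick spans its bounds at the two extremes", {
  pool <- random_counts(2, 30, seed = 1, lambda = 4)
  pool[2, ] <- pool[1, ]
  expect_lte(raup_crick_bray(pool, n_reps = 199, seed = 1)[1, 2], -0.9)

  set.seed(2)
  disj <- matrix(0, 2, 40, dimnames = list(c("s1", "s2"), paste0("t", 1:40)))
  disj[1, 1:20] <- rpois(20, 5) + 1
  disj[2, 21:40] <- rpois(20, 5) + 1
  expect_gte(raup_crick_bray(disj, n_reps = 199, seed = 3)[1, 2], 0.9)

  m <- random_counts(5, 25, seed = 4)
  rc <- raup_crick_bray(m, n_reps = 99, seed = 5)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_identical(rc, raup_crick_bray(m, n_reps = 99, seed = 5))

  expect_error(raup_crick_bray(m[, 1, drop = FALSE]), "one taxon")
  expect_error(raup_crick_bray(m / 3), "integer")
})

test_that("classification follows the published thresholds", {
  expect_equal(as.character(classify_assembly(2.5, 0)), "variable_selection")
  expect_equal(as.character(classify_assembly(-2.5, 0)), "homogeneous_selection")
  expect_equal(as.character(classify_assembly(1.0, 0.97)), "dispersal_limitation")
  expect_equal(as.character(classify_assembly(0, -0.97)), "homogenizing_dispersal")
  expect_equal(as.character(classify_assembly(0, 0)), "drift")
  expect_equal(as.character(classify_assembly(1.99, 0.94)), "drift")
  expect_true(is.na(classify_assembly(NA, 0.5)))
  expect_error(classify_assembly(1, c(0, 1)), "lengths differ")
})

test_that("process contributions are percentages that sum to 100 per stratum", {
  p <- c("variable_selection", "variable_selection", "drift", "dispersal_limitation")
  res <- process_contributions(p)
  expect_equal(res$percent[res$process == "variable_selection"], 50)
  expect_equal(res$percent[res$process == "drift"], 25)
  expect_equal(sum(res$percent), 100)

  allsame <- process_contributions(rep("drift", 7))
  expect_equal(allsame$percent[allsame$process == "drift"], 100)
  expect_equal(sum(allsame$percent), 100)

  mixed <- process_contributions(c(p, NA), strata = c(rep("x", 4), "x"))
  expect_equal(attr(mixed, "n_excluded"), 1L)
  expect_equal(sum(mixed$percent), 100)
})

test_that("infer_assembly ties the pieces together consistently", {
  scn <- scenario(n_pool_taxa = 24, tree_seed = 2, community_seed = 3,
                  env_values = c(0.3, 0.7), site_names = c("a", "b"),
                  n_replicates = 2, reads_per_sample = 300, process = "drift")
  ds <- assemble_dataset(scn)
  res <- infer_assembly(ds$table, ds$tree, n_reps = 99, seed = 4)
  expect_equal(nrow(res), choose(4, 2))
  ok <- !is.na(res$beta_nti)
  expect_equal(as.character(res$process[ok]),
               as.character(classify_assembly(res$beta_nti[ok], res$rc_bray[ok])))
})
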