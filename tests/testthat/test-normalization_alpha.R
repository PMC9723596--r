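test_that("SRS normalization reproduces hand computations and the identity case", {
  m <- matrix(c(6, 3, 3), 1, dimnames = list("s", c("a", "b", "c")))
  expect_equal(unname(srs_normalize(m, 4)[1, ]), c(2, 1, 1))

  m2 <- matrix(c(7, 3, 2), 1, dimnames = list("s", c("a", "b", "c")))
  out <- srs_normalize(m2, 6, seed = 1)
  expect_equal(sum(out), 6)
  # scaled (3.5, 1.5, 1.0): integer parts (3, 1, 1), one unit to a tied taxon
  expect_true(all(out[1, ] == c(4, 1, 1)) || all(out[1, ] == c(3, 2, 1)))

  m3 <- random_counts(3, 8, seed = 2)
  expect_equal(srs_normalize(m3, min(rowSums(m3)) * 0 + rowSums(m3)[1],
                             seed = 1)[1, ], m3[1, ])
  expect_error(srs_normalize(m3, 0), "positive")
  expect_warning(srs_normalize(rbind(m3, low = c(1, rep(0, 7))), 10), "dropping")
})

test_that("SRS output sums to c_min, never exceeds ceilings, and is seed-free without ties", {
  for (s in 1:25) {
    m <- random_counts(4, 12, seed = s, lambda = 8)
    cmin <- min(rowSums(m))
    out <- srs_normalize(m, cmin, seed = s)
    expect_true(all(rowSums(out) == cmin))
    scaled <- m * cmin / rowSums(m)
    expect_true(all(out <= ceiling(scaled) + 1e-9))
    expect_true(all(out >= floor(scaled) - 1e-9))
  }
  # no fractional-part ties: result independent of the seed
  m <- matrix(c(13, 5, 2), 1, dimnames = list("s", c("a", "b", "c")))
  expect_identical(srs_normalize(m, 10, seed = 1), srs_normalize(m, 10, seed = 99))
})

test_that("Shannon and Gini-Simpson match closed forms and are scale invariant", {
  m <- matrix(rep(1, 4), 1, dimnames = list("s", letters[1:4]))
  a <- taxonomic_alpha(m)
  expect_equal(a$shannon, log(4))
  expect_equal(a$gini_simpson, 0.75)

  single <- matrix(c(9, 0), 1, dimnames = list("s", c("a", "b")))
  a1 <- taxonomic_alpha(single)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$gini_simpson, 0)

  m2 <- random_counts(3, 6, seed = 3)
  expect_equal(taxonomic_alpha(m2)[, -1], taxonomic_alpha(m2 * 10)[, -1])
})

test_that("Faith's PD spans the minimal subtree with the root path convention", {
  tree <- toy_tree()
  tab <- rbind(ab = c(A = 1, B = 1, C = 0, D = 0),
               all = c(A = 1, B = 1, C = 1, D = 1),
               a = c(A = 1, B = 0, C = 0, D = 0))
  pd <- faith_pd(tab, tree, include_root = TRUE)
  expect_equal(unname(pd), c(3, 6, 2))
})

test_that("Faith's PD is monotone under taxon addition", {
  tree <- simulate_phylogeny(24, seed = 8)
  for (s in 1:20) {
    set.seed(s)
    pres <- rbinom(24, 1, 0.4)
    pres[sample(24, 2)] <- 1
    add <- pres
    add[sample(which(pres == 0), 1)] <- 1
    tab <- rbind(base = pres, more = add)
    colnames(tab) <- tree$tip.label
    pd <- faith_pd(tab, tree)
    expect_gte(pd["more"], pd["base"])
  }
})

test_that("ses.PD flags degenerate nulls and is seed-reproducible", {
  tree <- toy_tree()
  tab <- rbind(full = c(A = 1, B = 1, C = 1, D = 1),
               half = c(A = 1, B = 1, C = 0, D = 0))
  res <- ses_pd(tab, tree, n_reps = 99, seed = 1)
  expect_true(res$undefined[res$sample_id == "full"])
  expect_true(is.na(res$ses_pd[res$sample_id == "full"]))
  expect_false(res$undefined[res$sample_id == "half"])

  r1 <- ses_pd(tab, tree, n_reps = 199, seed = 42)
  r2 <- ses_pd(tab, tree, n_reps = 199, seed = 42)
  expect_identical(r1, r2)
})

test_that("a clustered sister pair has negative ses.PD", {
  # comb tree: two sister tips span far less branch length than random pairs
  comb <- ape::read.tree(text = "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5):0;")
  tab <- rbind(s = c(A = 1, B = 1, C = 0, D = 0, E = 0, F = 0))
  res <- ses_pd(tab, comb, n_reps = 499, seed = 7)
  expect_lt(res$ses_pd, 0)
})

test_that("NTI has the published sign convention and handles degenerate nulls", {
  tree <- toy_tree()
  # unweighted MNTD for {A, C}: each tip's nearest present neighbour is the other
  res <- nti(rbind(s = c(A = 1, B = 0, C = 1, D = 0),
                   s2 = c(A = 1, B = 1, C = 0, D = 0)),
             tree, n_reps = 99, seed = 1, abundance_weighted = FALSE)
  expect_equal(res$mntd_obs[res$sample_id == "s"], 4)
  expect_equal(res$mntd_obs[res$sample_id == "s2"], 2)

  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, 6)
  star$tip.label <- paste0("t", 1:6)
  tabs <- rbind(s = c(1, 1, 1, 0, 0, 0))
  colnames(tabs) <- star$tip.label
  res2 <- nti(tabs, star, n_reps = 99, seed = 1)
  expect_true(res2$undefined)
  expect_true(is.na(res2$nti))
})

test_that("null replicate count does not bias ses estimates (999 vs 9999)", {
  tree <- simulate_phylogeny(20, seed = 11)
  tab <- matrix(0, 1, 20, dimnames = list("s", tree$tip.label))
  tab[1, 1:6] <- c(5, 3, 2, 1, 1, 1)
  a <- nti(tab, tree, n_reps = 999, seed = 1)
  b <- nti(tab, tree, n_reps = 9999, seed = 2)
  se <- a$mntd_null_sd / sqrt(999)
  expect_lt(abs(a$mntd_null_mean - b$mntd_null_mean), 3 * se)
  expect_lt(abs(a$nti - b$nti), 0.5)
})

test_that("Kruskal-Wallis/Dunn utility agrees with the base test and separates groups", {
  set.seed(1)
  vals <- c(rnorm(8, 0), rnorm(8, 0), rnorm(8, 5))
  grp <- rep(c("a", "b", "c"), each = 8)
  res <- alpha_group_test(vals, grp)
  expect_equal(res$kruskal$p.value,
               stats::kruskal.test(vals, factor(grp))$p.value)
  dn <- res$dunn
  expect_lt(dn$p_adj[dn$group_1 == "a" & dn$group_2 == "c"], 0.01)
  expect_gt(dn$p_adj[dn$group_1 == "a" & dn$group_2 == "b"], 0.1)
  # z is antisymmetric in the group ordering
  res2 <- alpha_group_test(vals, factor(grp, levels = c("c", "b", "a")))
  expect_equal(abs(res2$dunn$z[res2$dunn$group_1 == "c" & res2$dunn$group_2 == "a"]),
               abs(dn$z[dn$group_1 == "a" & dn$group_2 == "c"]))
})
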