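# fixtures built in code; no data files

toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
}

toy_table <- function() {
  m <- rbind(s1 = c(5, 0, 2), s2 = c(1, 1, 1))
  colnames(m) <- c("A", "B", "C")
  m
}

# random count table with guaranteed positive row sums
random_counts <- function(n_samples, n_taxa, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("t", seq_len(n_taxa))))
  m[rowSums(m) == 0, 1] <- 1
  m
}

# random presence/absence pair with non-empty supports
random_pa_pair <- function(n_taxa, seed) {
  set.seed(seed)
  x <- stats::rbinom(n_taxa, 1, 0.5)
  y <- stats::rbinom(n_taxa, 1, 0.5)
  if (sum(x) == 0) x[1] <- 1
  if (sum(y) == 0) y[n_taxa] <- 1
  m <- rbind(s1 = x, s2 = y)
  colnames(m) <- paste0("t", seq_len(n_taxa))
  m
}

# brute-force beta-MNTD oracle: explicit double loop over taxa
bmntd_oracle <- function(table, tree, abundance_weighted = TRUE) {
  d <- stats::cophenetic(tree)[colnames(table), colnames(table)]
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ta <- which(table[a, ] > 0); tb <- which(table[b, ] > 0)
    wa <- if (abundance_weighted) table[a, ta] / sum(table[a, ta]) else
      rep(1 / length(ta), length(ta))
    wb <- if (abundance_weighted) table[b, tb] / sum(table[b, tb]) else
      rep(1 / length(tb), length(tb))
    s <- 0
    for (k in seq_along(ta)) {
      best <- Inf
      for (l in seq_along(tb)) best <- min(best, d[ta[k], tb[l]])
      s <- s + wa[k] * best / 2
    }
    for (l in seq_along(tb)) {
      best <- Inf
      for (k in seq_along(ta)) best <- min(best, d[tb[l], ta[k]])
      s <- s + wb[l] * best / 2
    }
    out[a, b] <- out[b, a] <- s
  }
  out
}

# independent one-way PERMANOVA F from within-group distances
# (Anderson's identity: no Gower matrix, no hat matrices)
pseudo_f_oracle <- function(dmat, groups) {
  n <- length(groups)
  tot <- sum(dmat[lower.tri(dmat)]^2) / n
  within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dmat[idx, idx, drop = FALSE]
    within <- within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((tot - within) / (a - 1)) / (within / (n - a))
}
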