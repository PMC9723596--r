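# Ordination and permutation statistics: PCoA, one-/two-way PERMANOVA
# (distance-based pseudo-F with permutation of residuals under the
# reduced model, and an exact enumeration fallback), PERMDISP, and
# Benjamini-Hochberg adjustment.

#' Principal coordinate analysis
#'
#' Classical scaling of the double-centered squared-distance matrix. Axes
#' are ordered by eigenvalue; no negative-eigenvalue correction is applied
#' and explained variation is reported relative to the positive-eigenvalue
#' total, with the negative-eigenvalue mass reported alongside.
#'
#' @param d a `dist` or symmetric dissimilarity matrix over >= 3 samples.
#' @return `list(coordinates, explained, eigenvalues, negative_mass)`:
#'   sample x axis coordinates, percent explained per retained axis,
#'   all eigenvalues, and the percent of total eigenvalue magnitude that
#'   is negative.
#' @export
pcoa <- function(d) {
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (n < 3) stop("pcoa requires at least 3 samples")
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coordinates = coords,
       explained = 100 * eig[pos] / sum(eig[pos]),
       eigenvalues = eig,
       negative_mass = 100 * sum(abs(eig[eig < 0])) / sum(abs(eig)))
}

# Gower-centered inner-product matrix of a dissimilarity matrix
gower_center <- function(m) {
  a <- -0.5 * m^2
  n <- nrow(a)
  cm <- colMeans(a)
  a - matrix(cm, n, n, byrow = TRUE) - matrix(rowMeans(a), n, n) + mean(a)
}

hat_matrix <- function(X) {
  q <- qr.Q(qr(X))
  tcrossprod(q)
}

# all distinct arrangements of a label vector (multiset permutations),
# each returned as a character vector assigning a label to every sample
multiset_permutations <- function(labels) {
  out <- list()
  rec <- function(pool, acc) {
    if (!length(pool)) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (u in unique(pool)) {
      rec(pool[-match(u, pool)], c(acc, u))
    }
  }
  rec(labels, character(0))
  out
}

# sample permutation q with labels[i] == arrangement[q[i]], so that
# G[q, q] under the original design realizes the arrangement
arrangement_permutation <- function(labels, arrangement) {
  q <- integer(length(labels))
  for (u in unique(labels)) q[labels == u] <- which(arrangement == u)
  q
}

n_multiset_permutations <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

#' Distance-based permutational multivariate analysis of variance
#'
#' Partitions the distance-based sums of squares over the terms of a one-
#' or two-way crossed design (with optional interaction) and tests each
#' term's pseudo-F by permutation. One-way designs permute raw
#' observations — exactly, by full enumeration of the distinct label
#' arrangements, when their number is at most `exact_limit`; two-way terms
#' use permutation of residuals under the reduced model excluding the
#' term (Freedman-Lane on the Gower-centered matrix). Term sums of squares
#' are sequential in the order given (identical to marginal for balanced
#' designs).
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param design data.frame of factors, rows matching the samples of `d`.
#' @param factors column names of the factors to model (1 or 2).
#' @param interaction include the interaction term (two-way only).
#' @param n_perm permutations (default 9999).
#' @param seed RNG seed.
#' @param exact_limit enumerate all arrangements when the one-way
#'   permutation space is at most this size (default 10000).
#' @return data.frame with one row per term plus `Residual` and `Total`:
#'   `term`, `df`, `SS`, `pseudo_F`, `p`, `p_adj` (BH across tested
#'   terms), and attribute `exact` saying whether enumeration was used.
#' @export
permanova <- function(d, design, factors, interaction = length(factors) > 1,
                      n_perm = 9999, seed = 1L, exact_limit = 10000) {
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (!all(factors %in% names(design))) stop("factors absent from design")
  if (nrow(design) != n) stop("design rows must match distance matrix")
  if (!length(factors) %in% 1:2) stop("one or two factors supported")
  fct <- lapply(design[factors], function(f) droplevels(as.factor(f)))
  if (any(vapply(fct, nlevels, 1L) < 2)) stop("each factor needs >= 2 levels")
  if (anyNA(unlist(fct, use.names = FALSE))) stop("unassigned samples in design")
  if (length(factors) == 2 && interaction) {
    cells <- table(fct[[1]], fct[[2]])
    if (any(cells == 0)) {
      bad <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop("empty cell in crossed design: ", rownames(cells)[bad[1]],
           " x ", colnames(cells)[bad[2]])
    }
  }
  G <- gower_center(m)
  dat <- as.data.frame(fct)
  names(dat) <- factors
  terms <- factors
  if (length(factors) == 2 && interaction)
    terms <- c(terms, paste(factors, collapse = ":"))
  # hat matrices of the nested model sequence (intercept-only first)
  forms <- Reduce(function(acc, t) c(acc, paste(acc[length(acc)], t, sep = " + ")),
                  terms[-1], paste("~", terms[1]))
  Xs <- lapply(forms, function(f) stats::model.matrix(stats::as.formula(f), dat))
  Hs <- c(list(matrix(1 / n, n, n)), lapply(Xs, hat_matrix))
  H_full <- Hs[[length(Hs)]]
  ss_total <- sum(diag(G))
  ss_terms <- vapply(seq_along(terms), function(k)
    sum(diag((Hs[[k + 1]] - Hs[[k]]) %*% G)), numeric(1))
  ss_res <- sum(diag((diag(n) - H_full) %*% G))
  df_terms <- vapply(seq_along(terms), function(k)
    qr(Xs[[k]])$rank - qr(if (k == 1) matrix(1, n, 1) else Xs[[k - 1]])$rank,
    numeric(1))
  df_res <- n - qr(Xs[[length(Xs)]])$rank
  if (df_res < 1) stop("no residual degrees of freedom")
  f_obs <- (ss_terms / df_terms) / (ss_res / df_res)

  one_way <- length(terms) == 1
  exact <- FALSE
  if (one_way) {
    labels <- as.character(fct[[1]])
    f_stat <- function(perm) {
      Gp <- G[perm, perm]
      sst <- sum(diag((Hs[[2]] - Hs[[1]]) %*% Gp))
      (sst / df_terms) / ((sum(diag(Gp)) - sst) / df_res)
    }
    if (n_multiset_permutations(labels) <= exact_limit) {
      exact <- TRUE
      # enumerate every distinct assignment of labels to samples
      arrangements <- multiset_permutations(labels)
      f_all <- vapply(arrangements, function(a)
        f_stat(arrangement_permutation(labels, a)), numeric(1))
      p <- mean(f_all >= f_obs - 1e-12)
    } else {
      f_perm <- local_seed(seed, vapply(seq_len(n_perm), function(r)
        f_stat(sample.int(n)), numeric(1)))
      p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    }
  } else {
    # Freedman-Lane: for each term, permute residuals of the model
    # holding all other terms
    p <- numeric(length(terms))
    for (k in seq_along(terms)) {
      others <- terms[-k]
      X_red <- stats::model.matrix(
        stats::as.formula(paste("~", paste(others, collapse = " + "))), dat)
      H_red <- hat_matrix(X_red)
      X_aug <- stats::model.matrix(
        stats::as.formula(paste("~", paste(c(others, terms[k]), collapse = " + "))), dat)
      H_aug <- hat_matrix(X_aug)
      df_k <- qr(X_aug)$rank - qr(X_red)$rank
      R <- diag(n) - H_red
      f_obs_k <- (sum(diag((H_aug - H_red) %*% G)) / df_k) / (ss_res / df_res)
      f_perm <- local_seed(child_seed(seed, terms[k]), {
        vapply(seq_len(n_perm), function(r) {
          M <- H_red + R[sample.int(n), , drop = FALSE]
          Gp <- M %*% G %*% t(M)
          sst <- sum(diag((H_aug - H_red) %*% Gp))
          ssr <- sum(diag((diag(n) - H_full) %*% Gp))
          (sst / df_k) / (ssr / df_res)
        }, numeric(1))
      })
      p[k] <- (sum(f_perm >= f_obs_k - 1e-12) + 1) / (n_perm + 1)
    }
  }
  out <- data.frame(term = c(terms, "Residual", "Total"),
                    df = c(df_terms, df_res, n - 1),
                    SS = c(ss_terms, ss_res, ss_total),
                    pseudo_F = c(f_obs, NA, NA),
                    p = c(p, NA, NA),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adj <- c(bh_adjust(p), NA, NA)
  structure(out, exact = exact)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Distances of samples to their group centroid in principal-coordinate
#' space (negative eigenvalues handled by the imaginary-part correction),
#' followed by a one-way F test on those distances with a permutation
#' p-value.
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups of >= 2 samples).
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return `list(F, p, distances, model)` where `distances` are the
#'   per-sample distances to group centroids.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = 1L) {
  m <- as_distance_matrix(d)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("permdisp requires >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  mod <- vegan::betadisper(stats::as.dist(m), groups, type = "centroid")
  pt <- local_seed(seed, vegan::permutest(mod, permutations = n_perm))
  list(F = pt$tab$F[1], p = pt$tab[1, "Pr(>F)"],
       distances = mod$distances, model = mod)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: sorted `p_i * m / i` with a
#' running minimum from the largest rank, capped at 1, returned in input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
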