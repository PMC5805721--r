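## Community-assembly inference: rarefaction, abundance-weighted beta mean
## nearest taxon distance (betaMNTD), a taxa-shuffle randomization null,
## the beta nearest taxon index (betaNTI), assembly-regime classification,
## Mantel tests, and the betaNTI ~ Sorensen distance regression.

#' Rarefy an OTU table to fixed depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (via [vegan::rrarefy()]).  Samples whose total falls below `depth` are
#' dropped with a warning; OTUs left with zero abundance across all samples
#' are removed.
#'
#' @param counts OTU x sample integer matrix.
#' @param depth rarefaction depth (default 977).
#' @param seed RNG seed for the subsampling.
#' @return rarefied OTU x sample matrix; dropped sample ids are attached as
#'   the `dropped` attribute.
#' @export
rarefy_counts <- function(counts, depth = 977, seed = 1L) {
  stopifnot(depth >= 1)
  totals <- colSums(counts)
  drop <- totals < depth
  if (all(drop)) stop("all samples are below the rarefaction depth", call. = FALSE)
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[drop], collapse = ", "), call. = FALSE)
  }
  kept <- counts[, !drop, drop = FALSE]
  # vegan notes whenever counts look unusual; the depth contract is ours
  rar <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(t(kept), depth)))
  out <- t(rar)
  out <- out[rowSums(out) > 0, , drop = FALSE]
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- colnames(counts)[drop]
  out
}

# Relative-abundance matrix (samples x OTUs) aligned to tree tip order.
rel_abund <- function(counts, tree) {
  m <- match_tree_table(counts, tree)
  totals <- colSums(m$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total abundance: ",
         paste(colnames(m$counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  P <- t(m$counts) / totals  # samples x OTUs
  list(P = P, tree = m$tree)
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For each sample pair, the mean patristic distance from every taxon in one
#' community to its nearest taxon in the other, weighted by relative
#' abundance and averaged over both directions.  Taxa present in both
#' communities contribute distance zero.  The unweighted variant gives every
#' present taxon equal weight.
#'
#' @param counts OTU x sample count matrix.
#' @param tree phylogeny covering the OTUs (matched/pruned internally).
#' @param weighted abundance-weight the taxa (default `TRUE`).
#' @return symmetric sample x sample betaMNTD matrix.
#' @export
bmntd <- function(counts, tree, weighted = TRUE) {
  ra <- rel_abund(counts, tree)
  P <- ra$P
  if (!weighted) {
    pres <- P > 0
    P <- pres / rowSums(pres)
  }
  D <- ape::cophenetic.phylo(ra$tree)
  D <- D[colnames(P), colnames(P)]
  out <- cpp_bmntd(P, D, seq_len(ncol(P)))
  dimnames(out) <- list(rownames(P), rownames(P))
  out
}

#' betaNTI from a taxa-shuffle randomization null
#'
#' Generates a null betaMNTD distribution for every sample pair by shuffling
#' OTU identities across all tips of the phylogeny (`n_reps` randomizations,
#' implemented as label permutations of the precomputed patristic distance
#' matrix -- identical results to re-shuffling the tree, at a fraction of the
#' cost).  The beta nearest taxon index is the standardized effect size
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD_{null}}) /
#'   sd(\beta MNTD_{null})}
#' Pairs with zero null standard deviation (e.g., a star phylogeny) get
#' `NA` betaNTI and are flagged.
#'
#' @param counts OTU x sample count matrix.
#' @param tree phylogeny covering the OTUs.
#' @param n_reps number of randomizations (default 999).
#' @param seed RNG seed for the permutations.
#' @param weighted abundance-weight the taxa (default `TRUE`).
#' @return list of symmetric matrices `bmntd_obs`, `null_mean`, `null_sd`,
#'   `bnti`, plus `n_reps` and `degenerate_pairs` (count of flagged pairs).
#' @export
null_bnti <- function(counts, tree, n_reps = 999, seed = 1L, weighted = TRUE) {
  stopifnot(n_reps >= 2)
  ra <- rel_abund(counts, tree)
  P <- ra$P
  if (!weighted) {
    pres <- P > 0
    P <- pres / rowSums(pres)
  }
  D <- ape::cophenetic.phylo(ra$tree)
  D <- D[colnames(P), colnames(P)]
  n_otu <- ncol(P)
  obs <- cpp_bmntd(P, D, seq_len(n_otu))
  perms <- withr::with_seed(seed, {
    replicate(n_reps, sample.int(n_otu), simplify = FALSE)
  })
  sum1 <- matrix(0, nrow(obs), ncol(obs))
  sum2 <- matrix(0, nrow(obs), ncol(obs))
  for (perm in perms) {
    nb <- cpp_bmntd(P, D, perm)
    sum1 <- sum1 + nb
    sum2 <- sum2 + nb * nb
  }
  null_mean <- sum1 / n_reps
  null_var <- pmax(sum2 / n_reps - null_mean^2, 0) * n_reps / (n_reps - 1)
  null_sd <- sqrt(null_var)
  bnti <- (obs - null_mean) / null_sd
  off <- row(obs) != col(obs)
  degen <- off & (null_sd == 0)
  bnti[degen] <- NA_real_
  diag(bnti) <- NA_real_
  ids <- rownames(P)
  dimnames(obs) <- dimnames(null_mean) <- dimnames(null_sd) <-
    dimnames(bnti) <- list(ids, ids)
  list(bmntd_obs = obs, null_mean = null_mean, null_sd = null_sd,
       bnti = bnti, n_reps = n_reps, degenerate_pairs = sum(degen) / 2)
}

#' Classify the assembly regime from betaNTI
#'
#' betaNTI below -2 indicates consistent selection pressures (homogeneous
#' selection); above +2, shifting pressures (variable selection); in between,
#' composition differences not dominated by selection.
#'
#' @param bnti numeric betaNTI value(s).
#' @return character vector of `"homogeneous_selection"`,
#'   `"variable_selection"`, or `"not_dominated_by_selection"` (`NA` in,
#'   `NA` out).
#' @export
classify_assembly <- function(bnti) {
  out <- rep(NA_character_, length(bnti))
  out[!is.na(bnti) & bnti < -2] <- "homogeneous_selection"
  out[!is.na(bnti) & bnti > 2] <- "variable_selection"
  out[!is.na(bnti) & bnti >= -2 & bnti <= 2] <- "not_dominated_by_selection"
  out
}

#' Permutation-based Mantel test
#'
#' Pearson correlation between the off-diagonal elements of two distance
#' matrices, with significance from simultaneous row/column permutations of
#' one matrix (one-tailed for positive association).  Backed by
#' [vegan::mantel()].
#'
#' @param mat_a,mat_b symmetric matrices over the same samples.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `r` and `p_value`.
#' @export
mantel_test <- function(mat_a, mat_b, n_perm = 999, seed = 1L) {
  if (nrow(mat_a) < 3L) stop("Mantel test needs at least 3 samples", call. = FALSE)
  if (!identical(dim(mat_a), dim(mat_b))) stop("matrix dimensions differ", call. = FALSE)
  if (sd(mat_a[lower.tri(mat_a)]) == 0 || sd(mat_b[lower.tri(mat_b)]) == 0) {
    stop("constant distance matrix: Mantel correlation undefined", call. = FALSE)
  }
  res <- withr::with_seed(seed, vegan::mantel(as.dist(mat_a), as.dist(mat_b),
                                              permutations = n_perm))
  list(r = unname(res$statistic), p_value = res$signif)
}

#' Regression of betaNTI on Sorensen dissimilarity over selected pairs
#'
#' OLS of pairwise betaNTI on pairwise DOC-profile Sorensen dissimilarity,
#' restricted to the sample pairs selected by `pair_filter` (e.g., river vs
#' nearshore hyporheic comparisons only).  Because pairwise values are not
#' independent, significance comes from a Mantel-style permutation: sample
#' labels of the Sorensen matrix are permuted and the correlation over the
#' same filtered pairs recomputed.
#'
#' @param bnti_matrix symmetric betaNTI matrix.
#' @param sorensen_matrix symmetric Sorensen matrix over the same sample ids.
#' @param pair_filter function of two sample ids returning `TRUE` for pairs
#'   to include, or `NULL` for all pairs.
#' @param n_perm permutations for the significance test (default 999).
#' @param seed RNG seed.
#' @return list with `slope`, `intercept`, `r_squared`, `mantel_p`, `n_pairs`.
#' @export
bnti_sorensen_regression <- function(bnti_matrix, sorensen_matrix,
                                     pair_filter = NULL, n_perm = 999,
                                     seed = 1L) {
  ids <- rownames(bnti_matrix)
  common <- intersect(ids, rownames(sorensen_matrix))
  if (length(common) < 3L) stop("matrices share fewer than 3 samples", call. = FALSE)
  B <- bnti_matrix[common, common]
  S <- sorensen_matrix[common, common]
  n <- length(common)
  pairs <- which(upper.tri(B), arr.ind = TRUE)
  if (!is.null(pair_filter)) {
    keep <- mapply(function(i, j) isTRUE(pair_filter(common[i], common[j])),
                   pairs[, 1L], pairs[, 2L])
    pairs <- pairs[keep, , drop = FALSE]
  }
  ok <- !is.na(B[pairs]) & !is.na(S[pairs])
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 3L) stop("fewer than 3 selected pairs", call. = FALSE)
  y <- B[pairs]
  x <- S[pairs]
  fit <- lm(y ~ x)
  r_obs <- suppressWarnings(stats::cor(x, y))
  perm_r <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      ord <- sample.int(n)
      Sp <- S[ord, ord]
      suppressWarnings(stats::cor(Sp[pairs], y))
    }, numeric(1))
  })
  p <- (sum(perm_r >= r_obs, na.rm = TRUE) + 1) / (n_perm + 1)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       mantel_p = p,
       n_pairs = nrow(pairs))
}
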