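test_that("rarefaction hits the exact depth, drops shallow samples, prunes empty OTUs", {
  set.seed(7)
  counts <- matrix(rpois(40 * 6, 60), 40, 6,
                   dimnames = list(paste0("o", 1:40), paste0("s", 1:6)))
  counts[, 6] <- 0L
  counts[1, 6] <- 900L  # total 900 < 977
  expect_warning(rar <- rarefy_counts(counts, depth = 977, seed = 1), "s6")
  expect_equal(unname(colSums(rar)), rep(977, 5))
  expect_equal(attr(rar, "dropped"), "s6")
  expect_true(all(rowSums(rar) > 0))
  # boundary depth 1: one read per sample
  r1 <- rarefy_counts(counts[, 1:5], depth = 1, seed = 1)
  expect_equal(unname(colSums(r1)), rep(1, 5))
  expect_error(rarefy_counts(counts, depth = 10000), "below")
})

test_that("betaMNTD ground truths: identical communities and two singletons", {
  tree <- tiny_tree()
  counts <- matrix(c(3L, 2L, 1L, 3L, 2L, 1L), nrow = 3,
                   dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(bmntd(counts, tree)["s1", "s2"], 0)
  singles <- matrix(c(5L, 0L, 0L, 0L, 4L, 0L), nrow = 3,
                    dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  # d(A,B) = 2 on this tree
  expect_equal(bmntd(singles, tree)["s1", "s2"], 2)
})

test_that("betaMNTD agrees with a brute-force oracle on random instances", {
  for (seed in 1:10) {
    rc <- random_community(5, 4, seed)
    fast <- bmntd(rc$counts, rc$tree)
    slow <- brute_bmntd(rc$counts, rc$tree)
    expect_lt(max(abs(fast - slow[rownames(fast), colnames(fast)])), 1e-10)
  }
})

test_that("betaMNTD cross-checks against the reference picante implementation", {
  skip_if_not_installed("picante")
  rc <- random_community(12, 5, 99)
  ours <- bmntd(rc$counts, rc$tree)
  ref <- as.matrix(picante::comdistnt(t(rc$counts),
                                      ape::cophenetic.phylo(rc$tree),
                                      abundance.weighted = TRUE))
  expect_lt(max(abs(ours - ref[rownames(ours), colnames(ours)])), 1e-10)
})

test_that("unweighted betaMNTD gives every present taxon equal weight", {
  rc <- random_community(6, 3, 5)
  fast <- bmntd(rc$counts, rc$tree, weighted = FALSE)
  slow <- brute_bmntd(rc$counts, rc$tree, weighted = FALSE)
  expect_lt(max(abs(fast - slow[rownames(fast), colnames(fast)])), 1e-10)
})

test_that("betaNTI standardizes observed betaMNTD against the null exactly", {
  # Eq. arithmetic: observed 0.8 against null mean 0.5 and sd 0.1 gives 3
  expect_equal((0.8 - 0.5) / 0.1, 3)
  rc <- random_community(10, 4, 3)
  nb <- null_bnti(rc$counts, rc$tree, n_reps = 99, seed = 1)
  ix <- which(upper.tri(nb$bnti) & nb$null_sd > 0, arr.ind = TRUE)
  expect_equal(nb$bnti[ix],
               (nb$bmntd_obs[ix] - nb$null_mean[ix]) / nb$null_sd[ix])
})

test_that("degenerate nulls are flagged instead of reported", {
  # identical communities: betaMNTD is 0 under every taxa shuffle
  tree <- tiny_tree()
  counts <- matrix(c(3L, 2L, 1L, 3L, 2L, 1L), nrow = 3,
                   dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  nb <- null_bnti(counts, tree, n_reps = 19, seed = 1)
  expect_true(is.na(nb$bnti["s1", "s2"]))
  expect_equal(nb$degenerate_pairs, 1)
})

test_that("betaNTI is stable across null-model seeds", {
  rc <- random_community(30, 6, 11)
  vals <- sapply(1:5, function(s) {
    nb <- null_bnti(rc$counts, rc$tree, n_reps = 999, seed = s)
    nb$bnti[upper.tri(nb$bnti)]
  })
  spread <- apply(vals, 1, function(v) max(v) - min(v))
  expect_lt(max(spread, na.rm = TRUE), 0.4)  # +/- 0.2 around the mean
})

test_that("assembly classification follows the +/-2 cuts", {
  expect_equal(classify_assembly(c(-2.5, 2.5, 0, -2, 2, NA)),
               c("homogeneous_selection", "variable_selection",
                 "not_dominated_by_selection", "not_dominated_by_selection",
                 "not_dominated_by_selection", NA))
})

test_that("Mantel test: identity, constant-matrix error, type-I control", {
  set.seed(21)
  n <- 10
  x <- matrix(runif(n * n), n, n); x <- x + t(x); diag(x) <- 0
  rownames(x) <- colnames(x) <- paste0("s", 1:n)
  m <- mantel_test(x, x, n_perm = 99, seed = 1)
  expect_equal(m$r, 1)
  expect_lte(m$p_value, 0.05)
  cst <- matrix(1, n, n); diag(cst) <- 0
  dimnames(cst) <- dimnames(x)
  expect_error(mantel_test(x, cst), "constant")
  # independent matrices: rejection rate near the nominal level
  rejections <- sapply(1:100, function(s) {
    set.seed(1000 + s)
    y <- matrix(runif(n * n), n, n); y <- y + t(y); diag(y) <- 0
    z <- matrix(runif(n * n), n, n); z <- z + t(z); diag(z) <- 0
    dimnames(y) <- dimnames(z) <- dimnames(x)
    mantel_test(y, z, n_perm = 99, seed = s)$p_value <= 0.05
  })
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.12)
})

test_that("betaNTI~Sorensen regression needs pairs and detects broken linkage", {
  set.seed(31)
  n <- 12
  ids <- paste0("s", 1:n)
  base <- matrix(runif(n * n), n, n); base <- base + t(base); diag(base) <- 0
  dimnames(base) <- list(ids, ids)
  linked <- 2 * base + matrix(rnorm(n * n, sd = 0.01), n, n)
  linked <- (linked + t(linked)) / 2; diag(linked) <- 0
  dimnames(linked) <- list(ids, ids)
  r <- bnti_sorensen_regression(linked, base, n_perm = 199, seed = 1)
  expect_gt(r$slope, 0)
  expect_lt(r$mantel_p, 0.05)
  expect_error(bnti_sorensen_regression(linked, base,
                                        pair_filter = function(a, b) FALSE),
               "fewer than 3")
})
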