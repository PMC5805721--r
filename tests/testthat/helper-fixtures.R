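# Shared fixtures and independent oracles, built in code.

# Minimal valid chemistry table: two events, one river + one hyporheic +
# two wells each.
tiny_chem <- function() {
  data.frame(
    sample_id = c("r1", "h1", "w1", "w2", "r2", "h2", "w3", "w4"),
    location_class = rep(c("river", "hyporheic", "well", "well"), 2),
    event = rep(1:2, each = 4),
    cl = c(1.5, 3.4, 19, 21, 1.5, 5.2, 18.5, 20.5),
    doc = c(1.4, 0.9, 0.36, 0.35, 1.5, 1.0, 0.37, 0.34),
    dic = c(5, 5.5, 8, 8.1, 5.2, 5.6, 7.9, 8.0),
    no3 = c(0.5, 2.1, 9.9, 10.2, 0.55, 3.0, 10.0, 10.3),
    stringsAsFactors = FALSE
  )
}

# Three-tip tree with known patristic distances: d(A,B)=2, d(A,C)=d(B,C)=4.
tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Independent brute-force betaMNTD oracle: direct double loop over the
# definition, no shared code with the package implementation.
brute_bmntd <- function(counts, tree, weighted = TRUE) {
  D <- ape::cophenetic.phylo(tree)
  otus <- rownames(counts)
  ns <- ncol(counts)
  out <- matrix(0, ns, ns, dimnames = list(colnames(counts), colnames(counts)))
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      pa <- counts[, a] / sum(counts[, a])
      pb <- counts[, b] / sum(counts[, b])
      in_a <- otus[counts[, a] > 0]
      in_b <- otus[counts[, b] > 0]
      if (!weighted) {
        pa <- (counts[, a] > 0) / length(in_a)
        pb <- (counts[, b] > 0) / length(in_b)
        names(pa) <- names(pb) <- otus
      }
      sa <- 0
      for (i in in_a) sa <- sa + pa[[i]] * min(D[i, in_b])
      sb <- 0
      for (j in in_b) sb <- sb + pb[[j]] * min(D[j, in_a])
      out[a, b] <- out[b, a] <- 0.5 * (sa + sb)
    }
  }
  out
}

# Random community + tree pair for oracle comparisons.
random_community <- function(n_otu, n_sample, seed) {
  withr::with_seed(seed, {
    tree <- ape::rtree(n_otu)
    counts <- matrix(rpois(n_otu * n_sample, 3), n_otu, n_sample,
                     dimnames = list(tree$tip.label,
                                     paste0("s", seq_len(n_sample))))
    # ensure no empty community
    counts[1, colSums(counts) == 0] <- 1
    list(counts = counts, tree = tree)
  })
}

# Aligned peak table from bare identity vectors, for set-mechanics tests.
peaks_from_ids <- function(sample_id, ids) {
  data.frame(sample_id = sample_id, mz = ids, aligned_mz = ids,
             C = NA_integer_, H = NA_integer_, N = NA_integer_,
             O = NA_integer_, P = NA_integer_, S = NA_integer_,
             charge = 0L, stringsAsFactors = FALSE)
}
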