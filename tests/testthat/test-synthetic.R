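test_that("the same seed reproduces every dataset bit-for-bit", {
  p <- generator_params(seed = 5)
  expect_identical(generate_chemistry(p), generate_chemistry(p))
  expect_identical(generate_formula_library(p), generate_formula_library(p))
  chem <- generate_chemistry(p)
  expect_identical(generate_ftms_samples(p, chem),
                   generate_ftms_samples(p, chem))
  c1 <- generate_communities(p, chem)
  c2 <- generate_communities(p, chem)
  expect_identical(c1$counts, c2$counts)
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(c2$tree))
})

test_that("noise-free chemistry sits exactly on the conservative mixing lines", {
  p <- generator_params(seed = 6, noise_cv = 0)
  chem <- generate_chemistry(p)
  f <- attr(chem, "truth")$f_true
  cl_line <- f * p$gw_cl + (1 - f) * p$rw_cl
  no3_line <- f * p$no3_gw_over_rw * p$rw_no3 + (1 - f) * p$rw_no3
  expect_lt(max(abs(chem$cl - cl_line)), 1e-12)
  expect_lt(max(abs(chem$no3 - no3_line)), 1e-12)
  # pure groundwater end member: DOC equals gw_doc exactly at f = 1
  pure <- which(abs(f - 1) < 1e-9)
  if (length(pure) > 0) {
    expect_lt(max(abs(chem$doc[pure] - p$gw_doc)), 1e-12)
  }
})

test_that("respiration is carbon-balanced and shaped by the protection threshold", {
  p <- generator_params(seed = 7, noise_cv = 0)
  chem <- generate_chemistry(p)
  tr <- attr(chem, "truth")
  f <- tr$f_true
  dic_line <- f * p$gw_dic + (1 - f) * p$rw_dic
  # every mg of DOC lost shows up as a mg of DIC
  expect_lt(max(abs((chem$dic - dic_line) - tr$doc_loss)), 1e-12)
  # river samples never react
  expect_true(all(tr$doc_loss[chem$location_class == "river"] == 0))
  # DOC never driven below the protection threshold by respiration
  reacted <- tr$doc_loss > 0
  expect_true(all(chem$doc[reacted] >= p$doc_protection_threshold - 1e-12))
})

test_that("per-event design: one river, one hyporheic, n_wells wells", {
  p <- generator_params(seed = 8, n_events = 5, n_wells = 7)
  chem <- generate_chemistry(p)
  per_event <- table(chem$event, chem$location_class)
  expect_true(all(per_event[, "river"] == 1))
  expect_true(all(per_event[, "hyporheic"] == 1))
  expect_true(all(per_event[, "well"] == 7))
})

test_that("the formula library honours its pool contracts", {
  p <- generator_params(seed = 9)
  lib <- generate_formula_library(p)
  expect_true(all(lib$C >= 1))
  expect_true(all(lib$N[lib$pool == "river"] == 0))     # CHO only
  expect_true(all(lib$N[lib$pool == "gw"] >= 1))        # CHON
  # groundwater pool is more thermodynamically favorable (lower dG),
  # by roughly the configured offset
  shift <- median(lib$dg[lib$pool == "gw"]) - median(lib$dg[lib$pool == "river"])
  expect_lt(shift, 0)
  expect_lt(abs(shift - p$dg_gw_shift), 6)
  # no duplicate formulas
  expect_false(any(duplicated(lib[, c("C", "H", "N", "O", "P", "S")])))
})

test_that("synthetic peak sets respect the observed count bounds and replicate structure", {
  p <- generator_params(seed = 10)
  chem <- generate_chemistry(p)
  peaks <- generate_ftms_samples(p, chem)
  tr <- attr(peaks, "truth")
  expect_true(all(tr$n_peaks >= 211 & tr$n_peaks <= 3499))
  expect_equal(sort(unique(peaks$replicate)), 1:3)
  # every chemistry sample got three replicates
  expect_setequal(unique(peaks$sample_id), chem$sample_id)
})

test_that("without dropout the replicates are identical and union equals each", {
  p <- generator_params(seed = 10, replicate_dropout = 0)
  chem <- generate_chemistry(p)
  peaks <- generate_ftms_samples(p, chem)
  one <- peaks[peaks$sample_id == chem$sample_id[1], ]
  sizes <- table(one$replicate)
  expect_equal(length(unique(sizes)), 1L)
  expect_equal(length(unique(one$mz)), unname(sizes[1]))
})

test_that("median Gibbs energy tracks the latent groundwater fraction", {
  p <- generator_params(seed = 2)
  chem <- generate_chemistry(p)
  peaks <- generate_ftms_samples(p, chem)
  aligned <- align_peaks(peaks)
  merged <- do.call(rbind, lapply(split(aligned, aligned$sample_id),
                                  merge_replicates))
  prof <- sample_median_dg(merged)
  tr <- attr(peaks, "truth")
  f <- tr$f_true[match(prof$sample_id, tr$sample_id)]
  expect_lt(cor(f, prof$median_dg, method = "spearman"), -0.5)
})

test_that("EC series: untouched cells keep baseline, intruded cells reach the end member", {
  p <- generator_params(seed = 3)
  ec <- generate_ec_series(p)
  expect_equal(ec$rw, 0.5 * ec$baseline)
  last <- ec$snapshots[[length(ec$snapshots)]]
  f <- ec$truth[[length(ec$truth)]]
  # fully intruded cells sit at the river end member
  full <- f > 0.9999
  expect_gt(sum(full), 0)
  expect_lt(max(abs(last[full] - ec$rw[full])), 0.01)
  # effectively never-intruded cells stay at baseline
  none <- f < 1e-3
  expect_gt(sum(none), 0)
  expect_lt(max(abs(last[none] - ec$baseline[none])), 0.05)
  # recovery through the end-member transform is exact
  fr <- rw_fraction(last, ec$baseline, ec$rw)
  expect_lt(max(abs(fr$f_rw - f)), 1e-9)
})

test_that("a generated bundle round-trips through the file formats", {
  p <- generator_params(seed = 4, n_events = 3, n_wells = 3,
                        n_otus = 64L, n_samples_community = 9L)
  dir <- withr::local_tempdir()
  generate_all(p, dir)
  chem <- read_chemistry(file.path(dir, "chemistry.csv"))
  expect_equal(nrow(chem), 3 * (3 + 2))
  peaks <- read_peaks(file.path(dir, "peaks.csv"))
  expect_gt(nrow(peaks), 0)
  counts <- read_otu_table(file.path(dir, "otu_table.tsv"))
  tree <- read_tree(file.path(dir, "tree.nwk"))
  m <- match_tree_table(counts, tree)
  expect_equal(sort(rownames(m$counts)), sort(m$tree$tip.label))
  ec <- read_ec_series(file.path(dir, "ec"))
  expect_length(ec$snapshots, p$n_snapshots)
  expect_true(file.exists(file.path(dir, "truth", "chemistry.csv")))
})
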