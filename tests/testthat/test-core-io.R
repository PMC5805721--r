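test_that("chemistry tables round-trip through CSV", {
  chem <- tiny_chem()
  path <- withr::local_tempfile(fileext = ".csv")
  write_chemistry(chem, path)
  back <- read_chemistry(path)
  expect_equal(back$sample_id, chem$sample_id)
  expect_equal(back$cl, chem$cl, tolerance = 1e-6)
  expect_equal(back$doc, chem$doc, tolerance = 1e-6)
  expect_equal(back$event, chem$event)
})

test_that("chemistry schema and value validation reject documented malformations", {
  chem <- tiny_chem()
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(chem[, setdiff(names(chem), "cl")], path, row.names = FALSE)
  expect_error(read_chemistry(path), "cl")

  bad <- chem
  bad$doc[3] <- -0.2
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_chemistry(path), "row")

  bad <- chem
  bad$doc <- as.character(bad$doc)
  bad$doc[2] <- "oops"
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_chemistry(path), "unparseable")

  dup <- chem
  dup$sample_id[2] <- dup$sample_id[1]
  expect_error(validate_chemistry(dup), "duplicated")
})

test_that("missing concentrations survive a round trip as NA, not zero", {
  chem <- tiny_chem()
  chem$no3[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_chemistry(chem, path)
  back <- read_chemistry(path)
  expect_true(is.na(back$no3[2]))
})

test_that("peak tables parse formulas, keep formula-less peaks, merge duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,mz,C,H,N,O,P,S,charge",
    "s1,180.0634,6,12,0,6,0,0,0",
    "s1,121.01,,,,,,,",
    "s1,180.0634,6,12,0,6,0,0,0",
    "s2,59.013,2,3,0,2,0,0,0"
  ), path)
  peaks <- read_peaks(path)
  expect_equal(nrow(peaks), 3L)  # duplicate (s1, 180.0634) merged
  expect_equal(sum(has_formula(peaks)), 2L)
  glc <- peaks[peaks$mz == 180.0634 & peaks$sample_id == "s1", ]
  expect_equal(glc$C, 6L)
  expect_equal(glc$O, 6L)
  # the assigned mass matches the monoisotopic mass within assignment error
  expect_lt(abs(formula_mass(glc) - glc$mz), 1e-3)
})

test_that("peak element counts must be non-negative integers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,mz,C,H,N,O,P,S,charge",
               "s1,100.1,2.5,4,0,1,0,0,0"), path)
  expect_error(read_peaks(path), "integer")
})

test_that("newick trees read with known patristic distances", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_tree(path)
  expect_equal(sort(tree$tip.label), c("A", "B", "C"))
  D <- ape::cophenetic.phylo(tree)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)

  writeLines("((A:1,B:0):1,C:2);", path)  # zero-length branch accepted
  expect_silent(read_tree(path))

  writeLines("((A:1,B:1):1", path)
  suppressWarnings(expect_error(read_tree(path), "parse|newick"))
})

test_that("match_tree_table prunes both sides and drops zero-total OTUs", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  counts <- matrix(c(5L, 3L, 0L, 2L, 1L, 0L), nrow = 3,
                   dimnames = list(c("A", "B", "Z"), c("s1", "s2")))
  m <- match_tree_table(counts, tree)
  expect_setequal(m$tree$tip.label, c("A", "B"))
  expect_setequal(rownames(m$counts), c("A", "B"))

  disjoint <- matrix(1L, 1, 1, dimnames = list("Q", "s1"))
  expect_error(match_tree_table(disjoint, tree), "share no")
})

test_that("EC series reader enforces manifest and shape contracts", {
  dir <- withr::local_tempdir()
  base <- matrix(10, 4, 5)
  write_ec_grid(base, file.path(dir, "base.txt"))
  write_ec_grid(base * 0.5, file.path(dir, "rw.txt"))
  write_ec_grid(base * 0.8, file.path(dir, "t1.txt"))
  write_ec_grid(base * 0.7, file.path(dir, "t2.txt"))
  manifest <- data.frame(role = c("baseline", "rw", "snapshot", "snapshot"),
                         filename = c("base.txt", "rw.txt", "t1.txt", "t2.txt"),
                         time = c(0, 0, 2, 1))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ec <- read_ec_series(dir)
  expect_length(ec$snapshots, 2L)
  # ordered by time: t2.txt (time 1) first
  expect_equal(attr(ec$snapshots[[1]], "time"), 1)
  expect_equal(ec$snapshots[[1]][1, 1], 7)

  write_ec_grid(matrix(1, 4, 4), file.path(dir, "t1.txt"))
  expect_error(read_ec_series(dir), "t1.txt")

  manifest$role[1] <- "snapshot"
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_ec_series(dir), "baseline")
})
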