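#' @useDynLib hyporheos, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median lm coef t.test quantile pt rnorm runif rmultinom
#'   rlnorm smooth.spline predict complete.cases sd setNames residuals
#'   as.dist dist plogis cor
#' @importFrom utils read.csv write.csv read.delim write.table
"_PACKAGE"

LOCATION_CLASSES <- c("river", "hyporheic", "well")

CHEM_COLUMNS <- c("sample_id", "location_class", "event", "cl", "doc", "dic", "no3")
SOLUTES <- c("doc", "dic", "no3")
PEAK_COLUMNS <- c("sample_id", "mz", "C", "H", "N", "O", "P", "S", "charge")
ELEMENTS <- c("C", "H", "N", "O", "P", "S")

# Monoisotopic atomic masses (Da)
ATOMIC_MASS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

`%||%` <- function(a, b) if (is.null(a)) b else a

## ------------------------------------------------------------------
## Aqueous chemistry tables
## ------------------------------------------------------------------

#' Validate an aqueous-chemistry table
#'
#' Checks the column contract, location classes, uniqueness of sample ids,
#' presence of an event for every row and non-negativity of concentrations.
#' Missing concentrations (empty cells / `NA`) are allowed and are excluded
#' from downstream means rather than imputed.
#'
#' @param chem data frame with columns `sample_id`, `location_class`
#'   (one of `"river"`, `"hyporheic"`, `"well"`), `event` (integer event
#'   index), and concentrations `cl`, `doc`, `dic`, `no3` in mg/l.
#' @return the validated data frame, invisibly classed as `chem_table`.
#' @export
validate_chemistry <- function(chem) {
  missing_cols <- setdiff(CHEM_COLUMNS, names(chem))
  if (length(missing_cols) > 0L) {
    stop("chemistry table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_class <- !chem$location_class %in% LOCATION_CLASSES
  if (any(bad_class)) {
    stop("unknown location_class in row(s) ",
         paste(which(bad_class), collapse = ", "),
         " (expected river/hyporheic/well)", call. = FALSE)
  }
  if (anyDuplicated(chem$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(chem$sample_id[duplicated(chem$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(chem$event))) {
    stop("every sample must have an event; missing in row(s) ",
         paste(which(is.na(chem$event)), collapse = ", "), call. = FALSE)
  }
  for (col in c("cl", SOLUTES)) {
    v <- chem[[col]]
    neg <- !is.na(v) & v < 0
    if (any(neg)) {
      stop("negative ", col, " concentration in row(s) ",
           paste(which(neg), collapse = ", "), call. = FALSE)
    }
  }
  class(chem) <- unique(c("chem_table", class(chem)))
  invisible(chem)
}

#' Read an aqueous-chemistry CSV
#'
#' Expected header: `sample_id, location_class, event, cl, doc, dic, no3`.
#' Unparseable numeric cells are an error, never a silent `NA`; genuinely
#' empty cells become `NA` ("absent") and are excluded from means downstream.
#'
#' @param path CSV file path.
#' @return a validated `chem_table` data frame.
#' @export
read_chemistry <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing_cols <- setdiff(CHEM_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("chemistry file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- is.na(out) & !(is.na(x) | x == "")
    if (any(bad)) {
      stop("unparseable ", col, " value ", dQuote(x[which(bad)[1L]]),
           " in row ", which(bad)[1L], call. = FALSE)
    }
    out
  }
  chem <- data.frame(
    sample_id = raw$sample_id,
    location_class = raw$location_class,
    event = as.integer(parse_num("event")),
    cl = parse_num("cl"),
    doc = parse_num("doc"),
    dic = parse_num("dic"),
    no3 = parse_num("no3"),
    stringsAsFactors = FALSE
  )
  validate_chemistry(chem)
  class(chem) <- unique(c("chem_table", class(chem)))
  chem
}

#' Write an aqueous-chemistry CSV
#'
#' Inverse of [read_chemistry()]; numeric values are printed at full precision
#' so a read/write cycle round-trips.
#'
#' @param chem validated chemistry table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chemistry <- function(chem, path) {
  validate_chemistry(chem)
  write.csv(chem[, CHEM_COLUMNS], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

## ------------------------------------------------------------------
## FTICR-MS peak tables
## ------------------------------------------------------------------

#' Read an FTICR-MS peak table
#'
#' Expected header: `sample_id, mz, C, H, N, O, P, S, charge`.  Element
#' columns may be empty for peaks without an assigned molecular formula; such
#' peaks are retained (they still carry mass-difference information) but are
#' excluded from thermodynamic calculations.  Duplicate `(sample_id, mz)` rows
#' collapse to a single peak (presence/absence semantics).
#'
#' @param path CSV file path.
#' @return a `peak_table` data frame, one row per peak.
#' @export
read_peaks <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing_cols <- setdiff(PEAK_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("peak file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(raw$mz))
  if (any(is.na(mz) | mz <= 0)) {
    stop("peak m/z must be a positive number; offending row ",
         which(is.na(mz) | mz <= 0)[1L], call. = FALSE)
  }
  parse_count <- function(col) {
    x <- raw[[col]]
    empty <- is.na(x) | x == ""
    out <- suppressWarnings(as.numeric(x))
    bad <- !empty & (is.na(out) | out %% 1 != 0 | out < 0)
    if (any(bad)) {
      stop("element count ", col, " must be a non-negative integer; row ",
           which(bad)[1L], " has ", dQuote(x[which(bad)[1L]]), call. = FALSE)
    }
    out[empty] <- NA_real_
    as.integer(out)
  }
  peaks <- data.frame(
    sample_id = raw$sample_id,
    mz = mz,
    C = parse_count("C"), H = parse_count("H"), N = parse_count("N"),
    O = parse_count("O"), P = parse_count("P"), S = parse_count("S"),
    charge = {
      z <- suppressWarnings(as.numeric(raw$charge))
      z[is.na(raw$charge) | raw$charge == ""] <- 0
      as.integer(z)
    },
    stringsAsFactors = FALSE
  )
  # formula present only when all six element counts are given
  has_f <- stats::complete.cases(peaks[, ELEMENTS])
  if (any(has_f & peaks$C < 1)) {
    stop("assigned formulas must contain at least one carbon; row ",
         which(has_f & peaks$C < 1)[1L], call. = FALSE)
  }
  peaks <- peaks[!duplicated(peaks[, c("sample_id", "mz")]), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- unique(c("peak_table", class(peaks)))
  peaks
}

#' Write an FTICR-MS peak table
#'
#' @param peaks `peak_table` data frame as returned by [read_peaks()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  write.csv(peaks[, PEAK_COLUMNS], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Does each peak carry an assigned molecular formula?
#'
#' @param peaks `peak_table` data frame.
#' @return logical vector, one element per row.
#' @export
has_formula <- function(peaks) {
  stats::complete.cases(peaks[, ELEMENTS, drop = FALSE])
}

#' Monoisotopic mass of molecular formulas
#'
#' Neutral monoisotopic mass from the C, H, N, O, P, S columns of a formula
#' or peak table, using exact atomic masses (12C = 12 Da).
#'
#' @param formulas data frame with integer columns `C,H,N,O,P,S`.
#' @return numeric vector of masses in Da (`NA` where the formula is absent).
#' @export
formula_mass <- function(formulas) {
  m <- rep(0, nrow(formulas))
  for (el in ELEMENTS) m <- m + formulas[[el]] * ATOMIC_MASS[[el]]
  unname(m)
}

## ------------------------------------------------------------------
## OTU table + phylogeny
## ------------------------------------------------------------------

#' Read an OTU count table
#'
#' TSV with first column `otu_id` and one column of non-negative integer
#' counts per sample.
#'
#' @param path TSV file path.
#' @return integer matrix, OTUs in rows, samples in columns.
#' @export
read_otu_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "otu_id") {
    stop("OTU table must have first column 'otu_id'", call. = FALSE)
  }
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyNA(counts) || any(counts < 0) || any(counts %% 1 != 0)) {
    stop("OTU counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$otu_id
  counts
}

#' Write an OTU count table
#'
#' @param counts OTU x sample integer matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phylogeny from a newick file
#'
#' @param path newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("could not parse newick file ", path, call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree in ", path, " has no branch lengths", call. = FALSE)
  }
  tree
}

#' Match an OTU table against a phylogeny
#'
#' Prunes the tree to OTUs present in the table, restricts the table to tree
#' tips, and removes OTUs with zero abundance across all samples (as after
#' rarefaction).  Mirrors the classic `match.phylo.data` contract.
#'
#' @param counts OTU x sample count matrix.
#' @param tree [ape::phylo] tree whose tip labels are OTU ids.
#' @return list with elements `counts` and `tree`, consistently subset.
#' @export
match_tree_table <- function(counts, tree) {
  nonzero <- rowSums(counts) > 0
  counts <- counts[nonzero, , drop = FALSE]
  shared <- intersect(rownames(counts), tree$tip.label)
  if (length(shared) == 0L) {
    stop("OTU table and tree share no OTU ids", call. = FALSE)
  }
  tree <- ape::keep.tip(tree, shared)
  counts <- counts[tree$tip.label, , drop = FALSE]
  list(counts = counts, tree = tree)
}

## ------------------------------------------------------------------
## Electrical-conductivity image series
## ------------------------------------------------------------------

#' Read a time-lapse EC image series
#'
#' A directory holding whitespace-delimited text grids plus a `manifest.tsv`
#' with columns `role` (`baseline`, `rw`, or `snapshot`), `filename`, and
#' `time` (ordinal snapshot index; ignored for the two end members).  All
#' grids must share the baseline's shape.
#'
#' @param dir directory path.
#' @return list with `baseline` and `rw` matrices and `snapshots`, a list of
#'   matrices ordered by time (each carrying a `time` attribute).
#' @export
read_ec_series <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.tsv in ", dir, call. = FALSE)
  }
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("role", "filename", "time")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns role, filename, time", call. = FALSE)
  }
  read_grid <- function(fn) {
    g <- as.matrix(read.table(file.path(dir, fn)))
    dimnames(g) <- NULL
    if (!all(is.finite(g))) stop("non-finite EC values in ", fn, call. = FALSE)
    g
  }
  base_row <- manifest[manifest$role == "baseline", , drop = FALSE]
  rw_row <- manifest[manifest$role == "rw", , drop = FALSE]
  if (nrow(base_row) != 1L) stop("manifest must name exactly one baseline grid", call. = FALSE)
  if (nrow(rw_row) != 1L) stop("manifest must name exactly one rw end-member grid", call. = FALSE)
  baseline <- read_grid(base_row$filename)
  rw <- read_grid(rw_row$filename)
  snaps <- manifest[manifest$role == "snapshot", , drop = FALSE]
  snaps <- snaps[order(snaps$time), , drop = FALSE]
  check_shape <- function(g, fn) {
    if (!identical(dim(g), dim(baseline))) {
      stop("EC grid ", fn, " has shape ", paste(dim(g), collapse = "x"),
           " but baseline is ", paste(dim(baseline), collapse = "x"),
           call. = FALSE)
    }
    g
  }
  check_shape(rw, rw_row$filename)
  snapshots <- lapply(seq_len(nrow(snaps)), function(i) {
    g <- check_shape(read_grid(snaps$filename[i]), snaps$filename[i])
    attr(g, "time") <- snaps$time[i]
    g
  })
  list(baseline = baseline, rw = rw, snapshots = snapshots)
}

#' Write an EC grid as a plain-text matrix
#'
#' @param grid numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ec_grid <- function(grid, path) {
  write.table(format(grid, digits = 10, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
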