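## Biochemical-transformation inference from exact mass differences.  The
## ultra-high mass accuracy of FTICR-MS lets a mass difference between two
## peaks be matched against the monoisotopic masses of common biochemical
## gains/losses (e.g., 2.0156 Da = hydrogenation, 71.0371 Da = loss of one
## alanine residue), without needing assigned formulas.

#' Load the biochemical-transformation database
#'
#' Returns the packaged 82-entry library of commonly observed biochemical
#' transformations (amino-acid residues, nucleobases, glycosyl units, and
#' functional-group gains/losses).  Each entry carries element-count deltas;
#' the monoisotopic `delta_mass` is recomputed from those deltas and exact
#' atomic masses at load time, so the table is internally mass-consistent by
#' construction.  The shipped list is a synthetic stand-in for the study's
#' supplementary inventory and can be replaced via `path`.
#'
#' @param path optional CSV with columns
#'   `name,d_c,d_h,d_n,d_o,d_p,d_s,n_kind`; defaults to the packaged file.
#' @return data frame with columns `name`, element deltas `C,H,N,O,P,S`,
#'   `delta_mass` (Da), `has_n`, and `n_kind`
#'   (`"organic"`, `"inorganic"`, `"none"`).
#' @export
build_transform_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "transformation_db_synthetic.csv",
                        package = "hyporheos", mustWork = TRUE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  db <- data.frame(
    name = raw$name,
    C = raw$d_c, H = raw$d_h, N = raw$d_n,
    O = raw$d_o, P = raw$d_p, S = raw$d_s,
    n_kind = raw$n_kind,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(db$name)) stop("transformation names must be unique", call. = FALSE)
  db$delta_mass <- formula_mass(db)
  if (any(db$delta_mass <= 0)) stop("transformation masses must be positive", call. = FALSE)
  db$has_n <- db$N > 0
  db
}

#' Count biochemical transformations in a peak set
#'
#' For every unordered pair of peaks in one sample, the absolute m/z
#' difference is compared against every database mass; each match within
#' `tol_da` increments that transformation's count.  A pair may match more
#' than one entry (all matches count).  Matching uses an absolute Da
#' tolerance because mass differences, not masses, are being compared.
#'
#' @param mz numeric vector of peak m/z values for one sample (a
#'   `peak_table` for one sample also works).
#' @param db transformation database from [build_transform_db()].
#' @param tol_da matching tolerance in Da (default 0.001).
#' @return a `transform_profile` data frame with `name` and `count`
#'   (zero-count transformations retained), total count as an attribute.
#' @export
infer_transformations <- function(mz, db, tol_da = 0.001) {
  if (is.data.frame(mz)) mz <- mz$mz
  mz <- sort(unique(mz))
  counts <- setNames(integer(nrow(db)), db$name)
  if (length(mz) >= 2L) {
    d <- sort(as.vector(stats::dist(mz)))  # all pairwise |mz_i - mz_j|
    # count pair differences with |d - delta_mass| <= tol_da per entry
    lo <- findInterval(db$delta_mass - tol_da * (1 + 1e-9), d)
    hi <- findInterval(db$delta_mass + tol_da * (1 + 1e-9), d)
    counts[] <- hi - lo
  }
  out <- data.frame(name = db$name, count = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(out$count)
  class(out) <- unique(c("transform_profile", class(out)))
  out
}

#' Normalize a transformation profile to fractional contributions
#'
#' Converts counts into fractions of the total number of observed
#' transformations in the data set, akin to relative abundances.
#'
#' @param profile `transform_profile` data frame from
#'   [infer_transformations()].
#' @return the profile with a `fraction` column summing to 1.
#' @export
normalize_profile <- function(profile) {
  total <- sum(profile$count)
  if (total == 0) {
    stop("profile has zero total transformations; fractions undefined", call. = FALSE)
  }
  profile$fraction <- profile$count / total
  profile
}

#' Differential representation of transformations between two data sets
#'
#' Per-transformation difference in normalized representation, with the sign
#' convention positive = overrepresented in the first (river) data set and
#' negative = overrepresented in the second (hyporheic zone).
#' Transformations absent from a profile contribute fraction 0.
#'
#' @param profile_river,profile_hz normalized profiles
#'   (see [normalize_profile()]).
#' @return data frame with `name`, `fraction_river`, `fraction_hz`, and
#'   `difference` (`fraction_river - fraction_hz`), carrying over `n_kind`
#'   and `has_n` when present in either profile.
#' @export
differential_representation <- function(profile_river, profile_hz) {
  if (is.null(profile_river$fraction) || is.null(profile_hz$fraction)) {
    stop("profiles must be normalized (see normalize_profile)", call. = FALSE)
  }
  nm <- union(profile_river$name, profile_hz$name)
  fr <- setNames(rep(0, length(nm)), nm)
  fh <- fr
  fr[profile_river$name] <- profile_river$fraction
  fh[profile_hz$name] <- profile_hz$fraction
  out <- data.frame(name = nm,
                    fraction_river = unname(fr),
                    fraction_hz = unname(fh),
                    difference = unname(fr - fh),
                    stringsAsFactors = FALSE)
  for (col in c("n_kind", "has_n")) {
    src <- if (!is.null(profile_river[[col]])) profile_river else profile_hz
    if (!is.null(src[[col]])) out[[col]] <- src[[col]][match(out$name, src$name)]
  }
  out
}

#' Filter differential representations by magnitude
#'
#' Retains transformations whose absolute representation difference meets
#' `min_abs` (the display threshold used when reporting the river vs
#' hyporheic-zone contrast).
#'
#' @param differences output of [differential_representation()].
#' @param min_abs minimum |difference| to retain (default 0.1).
#' @return the retained subset, with attributes `n_retained` and `n_dropped`.
#' @export
filter_by_magnitude <- function(differences, min_abs = 0.1) {
  keep <- abs(differences$difference) >= min_abs
  out <- differences[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
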