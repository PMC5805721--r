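## Peak-set mechanics: cross-sample m/z alignment, replicate merging,
## Van Krevelen classification, Sorensen dissimilarity and unique-peak-set
## construction.  All downstream use is presence/absence; intensities are
## never consulted.

#' Align peaks across samples on a shared mass grid
#'
#' Single-linkage clustering of m/z values pooled across all samples: sorted
#' masses are chained while consecutive gaps stay within `tol_ppm`; any
#' resulting cluster wider than `tol_ppm` overall is split recursively at its
#' largest internal gap.  Each cluster becomes one aligned identity whose
#' reference mass is the cluster mean.
#'
#' @param peaks `peak_table` data frame (any number of samples/replicates).
#' @param tol_ppm alignment tolerance in parts per million (default 1, the
#'   typical mass accuracy of the instrument).
#' @return the peak table with an `aligned_mz` column; within a sample,
#'   peaks collapsing onto one identity are merged.
#' @export
align_peaks <- function(peaks, tol_ppm = 1.0) {
  stopifnot(tol_ppm > 0)
  mz <- sort(unique(peaks$mz))
  if (length(mz) == 0L) stop("no peaks to align", call. = FALSE)
  split_cluster <- function(idx) {
    v <- mz[idx]
    if ((v[length(v)] - v[1L]) / mean(v) * 1e6 <= tol_ppm || length(v) == 1L) {
      return(list(idx))
    }
    gaps <- diff(v)
    cut <- which.max(gaps)
    c(split_cluster(idx[seq_len(cut)]),
      split_cluster(idx[(cut + 1L):length(idx)]))
  }
  # chain while consecutive gaps are within tolerance
  gap_ok <- c(FALSE, diff(mz) <= tol_ppm * 1e-6 * mz[-length(mz)])
  cluster_id <- cumsum(!gap_ok)
  clusters <- unlist(lapply(split(seq_along(mz), cluster_id), split_cluster),
                     recursive = FALSE)
  ref <- numeric(length(mz))
  for (cl in clusters) ref[cl] <- mean(mz[cl])
  peaks$aligned_mz <- ref[match(peaks$mz, mz)]
  dup <- duplicated(peaks[, c("sample_id", "aligned_mz")])
  peaks <- peaks[!dup, , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Merge replicate peak sets into one sample profile
#'
#' Replicates of a sample are collapsed by retaining every aligned peak
#' observed in any replicate (set union), giving a more complete sampling of
#' DOC species.
#'
#' @param reps `peak_table` rows for the replicates of one sample; all rows
#'   must share `sample_id` and carry `aligned_mz` (see [align_peaks()]).
#' @param replicate_col optional column distinguishing replicates (ignored in
#'   the union; present for interface symmetry).
#' @return a `peak_table` with one row per aligned identity.
#' @export
merge_replicates <- function(reps, replicate_col = "replicate") {
  if (length(unique(reps$sample_id)) != 1L) {
    stop("merge_replicates expects replicates of a single sample; got ids: ",
         paste(unique(reps$sample_id), collapse = ", "), call. = FALSE)
  }
  if (is.null(reps$aligned_mz)) {
    stop("peaks must be aligned (aligned_mz) before merging replicates", call. = FALSE)
  }
  out <- reps[!duplicated(reps$aligned_mz), , drop = FALSE]
  out[[replicate_col]] <- NULL
  rownames(out) <- NULL
  out
}

# Van Krevelen class rectangles in (O:C, H:C) space, checked in order; the
# first match wins.  Standard literature boundaries; amino sugar is checked
# before protein because the regions overlap.
VK_CLASSES <- data.frame(
  klass = c("lipid", "amino_sugar", "protein", "carbohydrate", "lignin",
            "condensed_aromatic"),
  oc_min = c(0.00, 0.55, 0.30, 0.67, 0.10, 0.00),
  oc_max = c(0.30, 0.70, 0.67, 1.20, 0.67, 1.20),
  hc_min = c(1.50, 1.50, 1.50, 1.50, 0.70, 0.20),
  hc_max = c(2.00, 2.20, 2.20, 2.40, 1.50, 0.70),
  stringsAsFactors = FALSE
)

#' Van Krevelen coordinates and compound-class labels
#'
#' Molar O:C and H:C ratios for every formula-bearing peak, classified into
#' biochemical compound classes by a rectangle decision table in
#' (O:C, H:C) space with a documented priority order (`VK_CLASSES`); ratios
#' matching no rectangle are `"other"`.
#'
#' @param peaks `peak_table` data frame (or any data frame with C,H,O counts).
#' @return data frame with `oc`, `hc`, and `klass` columns appended; rows
#'   without formulas get `NA` coordinates and class.
#' @export
vankrevelen <- function(peaks) {
  ok <- has_formula(peaks)
  peaks$oc <- ifelse(ok, peaks$O / peaks$C, NA_real_)
  peaks$hc <- ifelse(ok, peaks$H / peaks$C, NA_real_)
  klass <- rep(NA_character_, nrow(peaks))
  klass[ok] <- "other"
  for (i in rev(seq_len(nrow(VK_CLASSES)))) {
    r <- VK_CLASSES[i, ]
    hit <- ok & peaks$oc >= r$oc_min & peaks$oc <= r$oc_max &
      peaks$hc >= r$hc_min & peaks$hc <= r$hc_max
    klass[hit] <- r$klass  # earlier rows overwrite later ones
  }
  peaks$klass <- klass
  peaks
}

#' Sorensen dissimilarity between aligned peak sets
#'
#' Presence/absence Sorensen dissimilarity
#' `D(A, B) = 1 - 2|A intersect B| / (|A| + |B|)` between every pair of
#' samples, on aligned peak identities.
#'
#' @param peaks aligned `peak_table` covering two or more samples.
#' @return symmetric dissimilarity matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
peak_sorensen <- function(peaks) {
  if (is.null(peaks$aligned_mz)) {
    stop("peaks must be aligned (aligned_mz) before Sorensen", call. = FALSE)
  }
  sets <- lapply(split(peaks$aligned_mz, peaks$sample_id), unique)
  if (length(sets) < 2L || any(lengths(sets) == 0L)) {
    stop("Sorensen needs at least two non-empty peak sets", call. = FALSE)
  }
  ids <- names(sets)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      d <- 1 - 2 * shared / (length(sets[[i]]) + length(sets[[j]]))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Peaks unique to each of two sample groups
#'
#' Pools the aligned peaks of each group (union within group), intersects the
#' pooled sets, and returns the peaks unique to each group along with the
#' shared set, so that `|uniqueX| = |pooledX| - |shared|`.
#'
#' @param peaks_a,peaks_b aligned `peak_table` rows for the two groups (e.g.,
#'   river vs hyporheic-zone samples).
#' @return list with numeric vectors `unique_a`, `unique_b`, `shared` of
#'   aligned identities, plus pooled sizes `n_pooled_a`, `n_pooled_b`.
#' @export
unique_peak_sets <- function(peaks_a, peaks_b) {
  pa <- unique(if (is.data.frame(peaks_a)) peaks_a$aligned_mz else peaks_a)
  pb <- unique(if (is.data.frame(peaks_b)) peaks_b$aligned_mz else peaks_b)
  shared <- intersect(pa, pb)
  list(unique_a = setdiff(pa, shared),
       unique_b = setdiff(pb, shared),
       shared = shared,
       n_pooled_a = length(pa),
       n_pooled_b = length(pb))
}
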