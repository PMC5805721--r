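## DOC thermodynamics: NOSC and the Gibbs free energy of the carbon
## oxidation half reaction, per-sample median profiles, and the
## regression/threshold analyses relating thermodynamic favorability to
## groundwater fraction and DOC concentration.

#' Nominal oxidation state of carbon (NOSC)
#'
#' NOSC of a molecular formula CaHbNcOdPeSf with net charge Z:
#' \deqn{NOSC = -\frac{-Z + 4a + b - 3c - 2d + 5e - 2f}{a} + 4}
#' Values outside the physical range \[-4, 4\] trigger a warning (exotic
#' hetero-rich formulas can exceed it) but are returned unchanged.
#'
#' @param C,H,N,O,P,S integer element counts (vectorized).
#' @param Z net charge (default 0: formulas are assigned as neutral
#'   molecules even under negative-mode electrospray).
#' @return numeric vector of NOSC values.
#' @examples
#' nosc(C = 6, H = 12, O = 6)   # glucose: 0
#' nosc(C = 1, H = 4)           # methane: -4
#' nosc(C = 1, O = 2)           # CO2: +4
#' @export
nosc <- function(C, H = 0, N = 0, O = 0, P = 0, S = 0, Z = 0) {
  if (any(is.na(C)) || any(C < 1)) {
    stop("NOSC requires at least one carbon atom (C >= 1)", call. = FALSE)
  }
  out <- -((-Z + 4 * C + H - 3 * N - 2 * O + 5 * P - 2 * S) / C) + 4
  oob <- is.finite(out) & (out < -4 | out > 4)
  if (any(oob)) {
    warning(sum(oob), " NOSC value(s) outside [-4, 4]", call. = FALSE)
  }
  out
}

#' Gibbs free energy of the carbon oxidation half reaction
#'
#' Standard-state Gibbs free energy per mole of carbon, from the empirical
#' linear relation \eqn{\Delta G^0_{Cox} = 60.3 - 28.5 \cdot NOSC}
#' (kJ (mol C)^-1).  Higher values are less thermodynamically favorable
#' to oxidize.
#'
#' @param nosc NOSC value(s).
#' @return numeric vector in kJ (mol C)^-1.
#' @export
delta_g_cox <- function(nosc) {
  60.3 - 28.5 * nosc
}

#' Per-peak NOSC and Gibbs energy for a peak table
#'
#' Computes NOSC and delta G for every formula-bearing peak; formula-less
#' peaks get `NA` and are counted in the `n_without_formula` attribute.
#'
#' @param peaks `peak_table` data frame.
#' @param Z net charge override (default 0 for all peaks).
#' @return the peak table with `nosc` and `dg` columns added.
#' @export
peak_thermo <- function(peaks, Z = 0) {
  ok <- has_formula(peaks)
  peaks$nosc <- NA_real_
  peaks$dg <- NA_real_
  if (any(ok)) {
    peaks$nosc[ok] <- nosc(peaks$C[ok], peaks$H[ok], peaks$N[ok],
                           peaks$O[ok], peaks$P[ok], peaks$S[ok], Z = Z)
    peaks$dg[ok] <- delta_g_cox(peaks$nosc[ok])
  }
  attr(peaks, "n_without_formula") <- sum(!ok)
  peaks
}

#' Per-sample median Gibbs energy profile
#'
#' The thermodynamic profile of each sample is the median delta G over its
#' formula-bearing peaks, on presence/absence (each distinct peak counts
#' once; intensities are never used).  The median, not the mean, is used
#' because within-sample delta G distributions can be skewed.
#'
#' @param peaks `peak_table` data frame covering one or more samples.
#' @param Z net charge override passed to [peak_thermo()].
#' @return data frame with `sample_id`, `n_peaks` (formula-bearing),
#'   `median_nosc`, and `median_dg`.
#' @export
sample_median_dg <- function(peaks, Z = 0) {
  peaks <- peak_thermo(peaks, Z = Z)
  ok <- !is.na(peaks$dg)
  if (!any(ok)) stop("no formula-bearing peaks; median delta G undefined", call. = FALSE)
  sub <- peaks[ok, , drop = FALSE]
  ids <- unique(peaks$sample_id)
  absent <- setdiff(ids, unique(sub$sample_id))
  if (length(absent) > 0L) {
    stop("sample(s) without any formula-bearing peak: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(sub, sub$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1L],
               n_peaks = nrow(d),
               median_nosc = median(d$nosc),
               median_dg = median(d$dg),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[match(ids, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Regression of median Gibbs energy on groundwater fraction
#'
#' Ordinary least squares of the per-sample median delta G on the
#' groundwater fraction from the mixing model.  A negative slope means DOC
#' becomes more thermodynamically favorable with increasing groundwater
#' influence.
#'
#' @param profiles output of [sample_median_dg()].
#' @param mix `mixing_result` data frame (needs `sample_id`, `f_gw`).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
dg_vs_gwfraction <- function(profiles, mix) {
  m <- merge(profiles, mix[, c("sample_id", "f_gw")], by = "sample_id")
  unmatched <- setdiff(profiles$sample_id, mix$sample_id)
  if (length(unmatched) > 0L) {
    stop("profiles have no mixing result for sample(s): ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  if (nrow(m) < 3L) stop("need at least 3 matched samples", call. = FALSE)
  fit <- lm(median_dg ~ f_gw, data = m)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2L, 4L],
       n = nrow(m))
}

#' Compare median Gibbs energy across a DOC concentration threshold
#'
#' Two-sample t-test (Welch by default) of per-sample median delta G between
#' samples whose DOC exceeds `threshold` and those at or below it.
#'
#' @param profiles output of [sample_median_dg()].
#' @param chem chemistry table with `sample_id` and `doc` (mg/l).
#' @param threshold DOC concentration cut in mg/l (default 0.4).
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return list with `t`, `df`, `p_value`, per-group `n`, means and medians.
#' @export
dg_threshold_test <- function(profiles, chem, threshold = 0.4,
                              var_equal = FALSE) {
  m <- merge(profiles, chem[, c("sample_id", "doc")], by = "sample_id")
  m <- m[!is.na(m$doc), , drop = FALSE]
  high <- m$doc > threshold
  if (!any(high) || all(high)) {
    stop("both DOC groups must be non-empty at threshold ", threshold,
         " (sizes ", sum(high), " / ", sum(!high), ")", call. = FALSE)
  }
  x <- m$median_dg[high]
  y <- m$median_dg[!high]
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate variance: identical groups carry no evidence by symmetry;
    # perfectly separated constant groups are an infinite-t split
    tt <- list(statistic = if (mean(x) == mean(y)) 0 else
                 sign(mean(x) - mean(y)) * Inf,
               parameter = length(x) + length(y) - 2,
               p.value = if (mean(x) == mean(y)) 1 else 0)
  } else {
    tt <- t.test(x, y, var.equal = var_equal)
  }
  list(t = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       n_high = sum(high), n_low = sum(!high),
       mean_high = mean(m$median_dg[high]),
       mean_low = mean(m$median_dg[!high]),
       median_high = median(m$median_dg[high]),
       median_low = median(m$median_dg[!high]))
}

#' Scan DOC thresholds for the strongest Gibbs-energy contrast
#'
#' Evaluates [dg_threshold_test()] at every candidate threshold on a regular
#' grid between the 10th and 90th percentiles of DOC and returns the
#' candidate maximizing |t|.  Ties break toward the smaller threshold.
#'
#' @param profiles output of [sample_median_dg()].
#' @param chem chemistry table with `sample_id` and `doc`.
#' @param grid_step grid spacing in mg/l (default 0.05).
#' @return list with `threshold` (the |t|-maximizing candidate) and `scan`,
#'   a data frame of every candidate with its t statistic, p value and group
#'   sizes.
#' @export
threshold_scan <- function(profiles, chem, grid_step = 0.05) {
  m <- merge(profiles, chem[, c("sample_id", "doc")], by = "sample_id")
  m <- m[!is.na(m$doc), , drop = FALSE]
  if (nrow(m) < 4L) stop("need at least 4 samples for a threshold scan", call. = FALSE)
  q <- quantile(m$doc, c(0.1, 0.9), names = FALSE)
  if (diff(q) < grid_step) {
    stop("degenerate DOC range: 10th-90th percentile spread below one grid step",
         call. = FALSE)
  }
  grid <- seq(ceiling(q[1L] / grid_step) * grid_step,
              floor(q[2L] / grid_step) * grid_step, by = grid_step)
  rows <- lapply(grid, function(thr) {
    high <- m$doc > thr
    if (sum(high) < 2L || sum(!high) < 2L) return(NULL)
    tt <- tryCatch(t.test(m$median_dg[high], m$median_dg[!high]),
                   error = function(e) NULL)  # zero-variance candidates
    if (is.null(tt)) return(NULL)
    data.frame(threshold = thr, t = unname(tt$statistic),
               p_value = tt$p.value, n_high = sum(high), n_low = sum(!high))
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || nrow(scan) == 0L) {
    stop("no candidate threshold left both groups with >= 2 samples", call. = FALSE)
  }
  best <- scan$threshold[which.max(abs(scan$t))]  # which.max takes the first
  list(threshold = best, scan = scan)
}
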