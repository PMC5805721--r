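## End-member transform of time-lapse electrical-conductivity images into
## river-water / groundwater fraction fields, and projection of the
## DOC ~ groundwater-fraction relationship across the imaged domain.
## Bulk EC is a linear function of pore-water EC, so the two-end-member
## algebra applies cell-wise.

#' River-water fraction image from an EC snapshot
#'
#' Cell-wise linear un-mixing of an EC image between the baseline (pure
#' groundwater) and river-water end members:
#' `F_rw = (EC_t - EC_0) / (EC_rw - EC_0)`.  Fractions are not clamped by
#' default; values slightly outside \[0, 1\] arise legitimately from noise.
#'
#' @param ec_t EC snapshot matrix.
#' @param ec0 baseline EC matrix (pure groundwater conditions).
#' @param ecrw river-water end-member EC matrix.
#' @return list of matrices `f_rw` and `f_gw` (`f_gw = 1 - f_rw`), carrying
#'   the snapshot's `time` attribute when present.
#' @export
rw_fraction <- function(ec_t, ec0, ecrw) {
  if (!identical(dim(ec_t), dim(ec0)) || !identical(dim(ecrw), dim(ec0))) {
    stop("EC grids must share one shape", call. = FALSE)
  }
  denom <- ecrw - ec0
  bad <- which(denom == 0)
  if (length(bad) > 0L) {
    stop("EC end members coincide (EC_rw == EC_0) at cell index(es) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  f_rw <- (ec_t - ec0) / denom
  out <- list(f_rw = f_rw, f_gw = 1 - f_rw)
  attr(out, "time") <- attr(ec_t, "time")
  class(out) <- "fraction_image"
  out
}

# Clip a fraction field into the curve domain [0, 1], counting clips.
clip_to_domain <- function(f_gw) {
  clipped <- sum(f_gw < 0 | f_gw > 1)
  list(f = pmin(pmax(f_gw, 0), 1), n_clipped = clipped)
}

#' Project DOC across a fraction image
#'
#' Evaluates a fitted DOC ~ groundwater-fraction curve (see
#' [fit_doc_curve()]) at every cell of a fraction image.  Groundwater
#' fractions outside \[0, 1\] are clipped into the curve domain and the clip
#' count is reported rather than erroring, because fractions beyond the end
#' members occur legitimately.
#'
#' @param frac `fraction_image` from [rw_fraction()].
#' @param doc_curve `doc_curve` function from [fit_doc_curve()].
#' @return matrix of projected normalized DOC (fraction of river DOC), with
#'   attribute `n_clipped`.
#' @export
project_doc <- function(frac, doc_curve) {
  if (!inherits(doc_curve, "doc_curve")) {
    stop("doc_curve must be a fitted curve from fit_doc_curve()", call. = FALSE)
  }
  cl <- clip_to_domain(frac$f_gw)
  proj <- matrix(suppressWarnings(doc_curve(as.vector(cl$f))),
                 nrow = nrow(frac$f_gw))
  attr(proj, "n_clipped") <- cl$n_clipped
  attr(proj, "time") <- attr(frac, "time")
  proj
}

#' Project mixing-model deviations across a fraction image
#'
#' Same machinery as [project_doc()] but for a curve fitted to the DOC
#' deviation (negative values = DOC consumed relative to conservative
#' mixing).
#'
#' @param frac `fraction_image` from [rw_fraction()].
#' @param dev_curve `doc_curve` fitted with `what = "doc_dev"`.
#' @return matrix of projected deviations with attribute `n_clipped`.
#' @export
project_deviation <- function(frac, dev_curve) {
  project_doc(frac, dev_curve)
}

#' Area fraction below a groundwater-fraction cut, per snapshot
#'
#' For each snapshot in a series, the fraction of cells whose groundwater
#' fraction falls below `f_cut` — a quantitative expression of how much of
#' the imaged domain has crossed into the reactive low-GW mixing regime.
#'
#' @param frac_series list of `fraction_image` objects.
#' @param f_cut groundwater-fraction cut (default 0.10).
#' @return data frame with `time` and `area_fraction`.
#' @export
threshold_summary <- function(frac_series, f_cut = 0.10) {
  if (length(frac_series) == 0L) stop("empty fraction series", call. = FALSE)
  rows <- lapply(seq_along(frac_series), function(i) {
    fr <- frac_series[[i]]
    data.frame(time = attr(fr, "time") %||% i,
               area_fraction = mean(fr$f_gw < f_cut))
  })
  do.call(rbind, rows)
}
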