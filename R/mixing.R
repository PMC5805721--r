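## Conservative-tracer end-member mixing.  Chloride is treated as a
## conserved tracer of groundwater-river water mixing; reactive solutes
## (NO3, DOC, DIC) are normalized within each sampling event to the river
## concentration, linear two-end-member predictions are computed from the
## groundwater fraction, and deviations from those predictions diagnose
## reaction (DOC loss coupled to DIC gain).

#' Normalize reactive solutes to the river concentration per event
#'
#' Because river concentrations drift over a long sampling campaign, a single
#' mixing model cannot be fit to raw concentrations.  Every reactive solute
#' (DOC, DIC, NO3) is instead divided by the river concentration measured in
#' the same sampling event, so river samples sit at exactly 1.  Chloride, the
#' conservative tracer, is left unnormalized.
#'
#' @param chem validated chemistry table.
#' @return the table with added columns `doc_norm`, `dic_norm`, `no3_norm`.
#' @export
normalize_to_river <- function(chem) {
  validate_chemistry(chem)
  out <- chem
  for (col in paste0(SOLUTES, "_norm")) out[[col]] <- NA_real_
  for (ev in unique(chem$event)) {
    rows <- chem$event == ev
    river <- rows & chem$location_class == "river"
    if (sum(river) == 0L) {
      stop("event ", ev, " has no river sample to normalize against", call. = FALSE)
    }
    if (sum(river) > 1L) {
      stop("event ", ev, " has more than one river sample", call. = FALSE)
    }
    for (sol in SOLUTES) {
      ref <- chem[[sol]][river]
      if (is.na(ref) || ref == 0) {
        stop("river ", sol, " concentration in event ", ev,
             " is zero or missing; cannot normalize", call. = FALSE)
      }
      out[[paste0(sol, "_norm")]][rows] <- chem[[sol]][rows] / ref
    }
  }
  out
}

#' Estimate mixing end members from the tracer
#'
#' Samples with chloride above `cl_pure_threshold` are defined as pure
#' groundwater; their mean chloride is the 100%-GW tracer concentration.  The
#' mean chloride of river samples is the 0%-GW concentration.  Normalized
#' reactive-solute end members for groundwater are the means of the
#' event-normalized values over the same pure-GW sample set (river end
#' members are 1 by construction).
#'
#' @param chem_norm output of [normalize_to_river()].
#' @param cl_pure_threshold chloride concentration (mg/l) above which a sample
#'   counts as pure groundwater (default 17.5).
#' @return an `endmembers` list: `cl_gw`, `cl_rw`, `gw_norm` (named numeric,
#'   one entry per solute), `n_pure`, `cl_pure_threshold`.
#' @export
estimate_endmembers <- function(chem_norm, cl_pure_threshold = 17.5) {
  if (is.null(chem_norm$doc_norm)) {
    stop("normalize_to_river() must be applied before estimating end members",
         call. = FALSE)
  }
  pure <- !is.na(chem_norm$cl) & chem_norm$cl > cl_pure_threshold
  river <- chem_norm$location_class == "river"
  if (!any(pure)) {
    stop("no sample has Cl above ", cl_pure_threshold,
         " mg/l; lower cl_pure_threshold or check the tracer data", call. = FALSE)
  }
  if (!any(river)) stop("no river samples", call. = FALSE)
  gw_norm <- vapply(SOLUTES, function(sol) {
    mean(chem_norm[[paste0(sol, "_norm")]][pure], na.rm = TRUE)
  }, numeric(1))
  em <- list(cl_gw = mean(chem_norm$cl[pure], na.rm = TRUE),
             cl_rw = mean(chem_norm$cl[river], na.rm = TRUE),
             gw_norm = gw_norm,
             n_pure = sum(pure),
             cl_pure_threshold = cl_pure_threshold)
  if (em$cl_gw <= em$cl_rw) {
    stop("degenerate end members: mean pure-GW Cl (", signif(em$cl_gw, 4),
         ") is not above mean river Cl (", signif(em$cl_rw, 4), ")",
         call. = FALSE)
  }
  class(em) <- "endmembers"
  em
}

#' Groundwater fraction from the chloride tracer
#'
#' Linear two-end-member un-mixing: `f = (cl - cl_rw) / (cl_gw - cl_rw)`.
#' The fraction is deliberately not clamped: because 100% GW corresponds to a
#' mean chloride concentration, fractions above 1 (and slightly below 0) are
#' legitimate.
#'
#' @param cl chloride concentration(s) in mg/l.
#' @param em `endmembers` object.
#' @return numeric groundwater fraction(s).
#' @export
gw_fraction <- function(cl, em) {
  if (em$cl_gw == em$cl_rw) stop("degenerate end members (cl_gw == cl_rw)", call. = FALSE)
  (cl - em$cl_rw) / (em$cl_gw - em$cl_rw)
}

#' Linear mixing-model prediction for a normalized solute
#'
#' @param f groundwater fraction(s).
#' @param gw_norm normalized groundwater end-member concentration of the
#'   solute (the river end member is 1 by construction).
#' @return predicted normalized concentration `f * gw_norm + (1 - f)`.
#' @export
mixing_prediction <- function(f, gw_norm) {
  f * gw_norm + (1 - f)
}

#' Full mixing-model table: fractions, predictions, deviations
#'
#' Computes the groundwater fraction for every sample, the linear mixing
#' prediction for every normalized reactive solute, and the deviation
#' `observed - predicted`.  The sign convention makes DOC consumption
#' negative and DIC production positive.
#'
#' @param chem_norm output of [normalize_to_river()].
#' @param em `endmembers` object; estimated from the data when `NULL`.
#' @param exclude_events event indices to drop before fitting (the study
#'   convention of removing outlier events is exposed as an option, never
#'   hard-coded).
#' @param cl_pure_threshold passed to [estimate_endmembers()] when `em` is
#'   estimated here.
#' @return a `mixing_result` data frame with columns `sample_id`,
#'   `location_class`, `event`, `f_gw`, and per solute `<sol>_norm`,
#'   `<sol>_pred`, `<sol>_dev`; the end members are attached as the
#'   `endmembers` attribute.
#' @export
mixing_model <- function(chem_norm, em = NULL, exclude_events = integer(),
                         cl_pure_threshold = 17.5) {
  if (length(exclude_events) > 0L) {
    chem_norm <- chem_norm[!chem_norm$event %in% exclude_events, , drop = FALSE]
  }
  if (is.null(em)) em <- estimate_endmembers(chem_norm, cl_pure_threshold)
  out <- chem_norm[, c("sample_id", "location_class", "event")]
  out$f_gw <- gw_fraction(chem_norm$cl, em)
  for (sol in SOLUTES) {
    obs <- chem_norm[[paste0(sol, "_norm")]]
    pred <- mixing_prediction(out$f_gw, em$gw_norm[[sol]])
    out[[paste0(sol, "_norm")]] <- obs
    out[[paste0(sol, "_pred")]] <- pred
    out[[paste0(sol, "_dev")]] <- obs - pred
  }
  attr(out, "endmembers") <- em
  attr(out, "exclude_events") <- exclude_events
  class(out) <- unique(c("mixing_result", class(out)))
  out
}

#' Regress DIC deviations on DOC deviations in the low-GW-fraction window
#'
#' Within the narrow mixing window (groundwater fraction below `f_max`),
#' aerobic respiration consumes DOC and produces DIC, so DIC deviations
#' should decrease with DOC deviations (negative slope).
#'
#' @param mix `mixing_result` data frame.
#' @param f_max upper groundwater-fraction bound of the window (default 0.10).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
deviation_regression <- function(mix, f_max = 0.10) {
  sub <- mix[!is.na(mix$f_gw) & mix$f_gw < f_max &
               !is.na(mix$doc_dev) & !is.na(mix$dic_dev), , drop = FALSE]
  if (nrow(sub) < 3L) {
    stop("fewer than 3 samples with f_gw below ", f_max, call. = FALSE)
  }
  fit <- lm(dic_dev ~ doc_dev, data = sub)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2L, 4L],
       n = nrow(sub))
}

#' Fit a smooth curve of normalized DOC against groundwater fraction
#'
#' Cubic smoothing spline (smoothing chosen by generalized cross-validation
#' unless `spar` is given) of normalized DOC on groundwater fraction.  The
#' returned object is callable on \[0, 1\]; evaluation outside the fitted
#' range warns about extrapolation.
#'
#' @param mix `mixing_result` data frame.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @param what column to model (default `"doc_norm"`; use `"doc_dev"` for the
#'   deviation curve used in spatial projection).
#' @return a function of class `doc_curve` mapping `f_gw` to the fitted value.
#' @export
fit_doc_curve <- function(mix, spar = NULL, what = "doc_norm") {
  ok <- !is.na(mix$f_gw) & !is.na(mix[[what]])
  f <- mix$f_gw[ok]
  y <- mix[[what]][ok]
  if (length(f) < 10L) stop("need at least 10 samples to fit the curve", call. = FALSE)
  if (min(f) > 0.05 || max(f) < 0.95) {
    stop("samples must span the groundwater-fraction range [0, 1] ",
         "(observed ", signif(min(f), 3), " to ", signif(max(f), 3), ")",
         call. = FALSE)
  }
  fit <- if (is.null(spar)) smooth.spline(f, y) else smooth.spline(f, y, spar = spar)
  rng <- range(f)
  curve <- function(fgw) {
    if (any(fgw < rng[1L] - 1e-9 | fgw > rng[2L] + 1e-9)) {
      warning("evaluating DOC curve outside the fitted range [",
              signif(rng[1L], 3), ", ", signif(rng[2L], 3),
              "]: extrapolating", call. = FALSE)
    }
    predict(fit, fgw)$y
  }
  attr(curve, "fit") <- fit
  attr(curve, "range") <- rng
  attr(curve, "what") <- what
  class(curve) <- c("doc_curve", "function")
  curve
}

#' Two-segment changepoint in the DOC deviation vs groundwater fraction
#'
#' Fits a continuous two-segment piecewise-linear model (a hinge) of the DOC
#' deviation on the groundwater fraction for every candidate breakpoint on a
#' regular grid and returns the breakpoint minimizing the residual sum of
#' squares.  When the hinge barely improves on a single line (relative RSS
#' reduction below `min_improvement`) the estimate carries a low-confidence
#' flag: the data are consistent with no breakpoint at all.
#'
#' @param mix `mixing_result` data frame.
#' @param grid_step breakpoint grid spacing in fraction units (default 0.01).
#' @param min_improvement relative RSS improvement over a single straight
#'   line below which the fit is flagged low-confidence (default 0.1).
#' @return list with `f_star` (the breakpoint), `low_confidence` flag, `rss`,
#'   `rss_single` and the full `scan` data frame.
#' @export
changepoint_estimate <- function(mix, grid_step = 0.01, min_improvement = 0.1) {
  ok <- !is.na(mix$f_gw) & !is.na(mix$doc_dev)
  f <- mix$f_gw[ok]
  y <- mix$doc_dev[ok]
  if (length(f) < 5L) stop("too few samples for a changepoint fit", call. = FALSE)
  single <- lm(y ~ f)
  rss_single <- sum(residuals(single)^2)
  lo <- ceiling((min(f) + grid_step) / grid_step) * grid_step
  hi <- floor((max(f) - grid_step) / grid_step) * grid_step
  grid <- seq(lo, hi, by = grid_step)
  rss <- vapply(grid, function(cp) {
    hinge <- pmax(cp - f, 0)  # active below the breakpoint
    sum(residuals(lm(y ~ f + hinge))^2)
  }, numeric(1))
  best <- which.min(rss)  # ties resolve to the smaller breakpoint
  f_star <- grid[best]
  improvement <- if (rss_single > 0) 1 - rss[best] / rss_single else 0
  list(f_star = f_star,
       low_confidence = improvement < min_improvement,
       rss = rss[best],
       rss_single = rss_single,
       scan = data.frame(f = grid, rss = rss))
}
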