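## End-to-end orchestration: one configuration object, one call running
## generate -> mixing -> thermo -> ftms -> transforms -> ecology -> project,
## one machine-readable report.

#' Pipeline configuration
#'
#' Collects every stage's thresholds, replicate counts and seeds in one
#' list.  Defaults are the study conventions (17.5 mg/l pure-GW chloride,
#' 0.4 mg/l DOC threshold, 10% GW window, betaNTI cuts at +/-2, 0.1
#' differential-representation filter, 999 randomizations).  The object
#' round-trips through YAML via [write_config()] / [read_config()].
#'
#' @param cl_pure_threshold chloride cut for pure groundwater (mg/l).
#' @param doc_threshold DOC concentration threshold (mg/l).
#' @param f_max groundwater-fraction window for the deviation regression.
#' @param bnti_cut absolute betaNTI cut for selection regimes.
#' @param diff_min magnitude filter for differential representation.
#' @param null_reps,mantel_perms randomization counts.
#' @param rarefaction_depth reads per sample after rarefaction.
#' @param align_tol_ppm peak-alignment tolerance (ppm).
#' @param transform_tol_da transformation mass-matching tolerance (Da).
#' @param exclude_events event indices to drop from the mixing analysis.
#' @param seed base seed for all stochastic stages.
#' @param generator `generator_params` for synthetic input generation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cl_pure_threshold = 17.5,
                            doc_threshold = 0.4,
                            f_max = 0.10,
                            bnti_cut = 2,
                            diff_min = 0.1,
                            null_reps = 999L,
                            mantel_perms = 999L,
                            rarefaction_depth = 977L,
                            align_tol_ppm = 1.0,
                            transform_tol_da = 0.001,
                            exclude_events = integer(),
                            seed = 1L,
                            generator = generator_params(seed = seed)) {
  cfg <- as.list(environment())
  stopifnot(cfg$cl_pure_threshold > 0, cfg$doc_threshold > 0,
            cfg$f_max > 0, cfg$bnti_cut > 0, cfg$null_reps >= 2)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg `pipeline_config` object.
#' @param path YAML file path.
#' @return `path` (write) or the reconstructed `pipeline_config` (read).
#' @export
write_config <- function(cfg, path) {
  plain <- unclass(cfg)
  plain$generator <- unclass(plain$generator)
  plain$generator$selection_regimes <-
    as.list(plain$generator$selection_regimes)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- raw$generator
  gen$selection_regimes <- unlist(gen$selection_regimes)
  raw$generator <- do.call(generator_params, gen)
  raw$exclude_events <- as.integer(unlist(raw$exclude_events))
  do.call(pipeline_config, raw)
}

#' Run the full inference chain on synthetic inputs
#'
#' Generates all inputs at the configured parameters and runs every stage:
#' mixing model (fractions, deviations, deviation coupling, DOC curve,
#' changepoint), thermodynamics (median Gibbs energy profiles, regression on
#' groundwater fraction, DOC threshold test and scan), peak mechanics
#' (alignment, replicate union, Sorensen), transformation profiling (river
#' vs hyporheic differential representation), ecology (rarefaction, betaNTI,
#' regime classification, betaNTI ~ Sorensen), and EC projection (fraction
#' images, DOC projection, area-threshold summary).
#'
#' @param config `pipeline_config` object.
#' @param out_dir optional directory; when given, the generated inputs and a
#'   JSON report are written there.
#' @return a nested list report with one block per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  gen <- config$generator
  report <- list(config = list(seed = config$seed,
                               exclude_events = config$exclude_events))

  ## generate
  chem <- generate_chemistry(gen)
  peaks <- generate_ftms_samples(gen, chem)
  comm <- generate_communities(gen, chemistry = chem)
  ec <- generate_ec_series(gen)
  report$generate <- list(n_samples = nrow(chem),
                          n_peak_rows = nrow(peaks),
                          n_otus = nrow(comm$counts),
                          n_snapshots = length(ec$snapshots))

  ## mixing
  chem_norm <- normalize_to_river(chem)
  mix <- mixing_model(chem_norm, exclude_events = config$exclude_events,
                      cl_pure_threshold = config$cl_pure_threshold)
  dev_reg <- deviation_regression(mix, f_max = config$f_max)
  cp <- changepoint_estimate(mix)
  doc_curve <- fit_doc_curve(mix)
  dev_curve <- fit_doc_curve(mix, what = "doc_dev")
  em <- attr(mix, "endmembers")
  report$mixing <- list(endmembers = list(cl_gw = em$cl_gw, cl_rw = em$cl_rw,
                                          gw_norm = as.list(em$gw_norm)),
                        excluded_events = config$exclude_events,
                        deviation_regression = dev_reg,
                        changepoint = list(f_star = cp$f_star,
                                           low_confidence = cp$low_confidence))

  ## ftms mechanics
  aligned <- align_peaks(peaks, tol_ppm = config$align_tol_ppm)
  merged <- do.call(rbind, lapply(split(aligned, aligned$sample_id),
                                  merge_replicates))
  rownames(merged) <- NULL
  sorensen <- peak_sorensen(merged)
  report$ftms <- list(n_aligned_identities = length(unique(aligned$aligned_mz)),
                      n_samples = nrow(sorensen))

  ## thermo
  profiles <- sample_median_dg(merged)
  # the mixing table may exclude events; regress on its sample set
  prof_mix <- profiles[profiles$sample_id %in% mix$sample_id, , drop = FALSE]
  dg_reg <- dg_vs_gwfraction(prof_mix, mix)
  thr_test <- dg_threshold_test(profiles, chem,
                                threshold = config$doc_threshold)
  scan <- threshold_scan(profiles, chem)
  report$thermo <- list(dg_vs_f = dg_reg,
                        threshold_test = thr_test[c("t", "df", "p_value",
                                                    "n_high", "n_low")],
                        threshold_scan = list(threshold = scan$threshold))

  ## ecology
  rar <- suppressWarnings(rarefy_counts(comm$counts,
                                        depth = config$rarefaction_depth,
                                        seed = config$seed))
  matched <- match_tree_table(rar, comm$tree)
  nb <- null_bnti(matched$counts, matched$tree, n_reps = config$null_reps,
                  seed = config$seed)
  meta <- comm$metadata
  compartment_of <- setNames(meta$compartment, meta$sample_id)
  ids <- rownames(nb$bnti)
  pair_ix <- which(upper.tri(nb$bnti), arr.ind = TRUE)
  ca <- compartment_of[ids[pair_ix[, 1L]]]
  cb <- compartment_of[ids[pair_ix[, 2L]]]
  v <- nb$bnti[pair_ix]
  within_mean <- mean(v[ca == cb], na.rm = TRUE)
  rh <- (ca == "river" & cb == "hyporheic") | (ca == "hyporheic" & cb == "river")
  river_hz_mean <- mean(v[rh], na.rm = TRUE)
  regimes <- table(classify_assembly(v))
  report$ecology <- list(n_samples = length(ids),
                         dropped = attr(rar, "dropped"),
                         within_compartment_mean_bnti = within_mean,
                         river_vs_hz_mean_bnti = river_hz_mean,
                         regimes = as.list(regimes))

  ## Mantel test of betaNTI against changes in the conservative tracer,
  ## over subsurface (non-river) communities only
  sub_ids <- ids[compartment_of[ids] != "river"]
  if (length(sub_ids) >= 3L) {
    cl_of <- setNames(chem$cl, chem$sample_id)
    dcl <- as.matrix(stats::dist(cl_of[sub_ids]))
    dimnames(dcl) <- list(sub_ids, sub_ids)
    b_sub <- nb$bnti[sub_ids, sub_ids]
    b_sub[is.na(b_sub)] <- 0  # diagonal; dist ignores it
    diag(b_sub) <- 0
    report$ecology$bnti_vs_delta_cl <-
      tryCatch(mantel_test(b_sub, dcl, n_perm = config$mantel_perms,
                           seed = config$seed),
               error = function(e) list(error = conditionMessage(e)))
  }

  ## betaNTI ~ Sorensen (river vs hyporheic pairs); the FTICR samples map to
  ## community samples via compartment labels, so use compartment medians of
  ## the peak Sorensen to select pairs in synthetic data: here both matrices
  ## are over community samples only when ids match, so guard accordingly.
  shared_ids <- intersect(rownames(nb$bnti), rownames(sorensen))
  if (length(shared_ids) >= 3L) {
    filt <- function(a, b) {
      xor(compartment_of[[a]] == "river", compartment_of[[b]] == "river") &&
        "hyporheic" %in% c(compartment_of[[a]], compartment_of[[b]])
    }
    report$ecology$bnti_sorensen <-
      bnti_sorensen_regression(nb$bnti, sorensen, filt,
                               n_perm = config$mantel_perms,
                               seed = config$seed)
  }

  ## transforms: river vs hyporheic unique peak sets
  db <- build_transform_db()
  hz_ids <- chem$sample_id[chem$location_class == "hyporheic"]
  rw_ids <- chem$sample_id[chem$location_class == "river"]
  ups <- unique_peak_sets(merged[merged$sample_id %in% rw_ids, ],
                          merged[merged$sample_id %in% hz_ids, ])
  prof_rw <- normalize_profile(infer_transformations(ups$unique_a, db,
                                                     config$transform_tol_da))
  prof_hz <- normalize_profile(infer_transformations(ups$unique_b, db,
                                                     config$transform_tol_da))
  prof_rw$n_kind <- db$n_kind
  diffs <- differential_representation(prof_rw, prof_hz)
  kept <- filter_by_magnitude(diffs, min_abs = config$diff_min)
  report$transforms <- list(n_unique_river = length(ups$unique_a),
                            n_unique_hz = length(ups$unique_b),
                            n_shared = length(ups$shared),
                            n_retained = attr(kept, "n_retained"),
                            n_dropped = attr(kept, "n_dropped"))

  ## ERT projection
  fracs <- lapply(ec$snapshots, rw_fraction, ec0 = ec$baseline, ecrw = ec$rw)
  proj_last <- project_doc(fracs[[length(fracs)]], doc_curve)
  dev_last <- project_deviation(fracs[[length(fracs)]], dev_curve)
  area <- threshold_summary(fracs, f_cut = config$f_max)
  report$project <- list(n_snapshots = length(fracs),
                         n_clipped_last = attr(proj_last, "n_clipped"),
                         doc_range_last = range(proj_last),
                         deviation_min_last = min(dev_last),
                         area_below_cut = area$area_fraction)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    generate_all(gen, file.path(out_dir, "inputs"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  report
}
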