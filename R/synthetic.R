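## Seeded synthetic-data generator.  The study's field data are unreleased,
## so every pipeline input is emulated with the statistical structure the
## downstream analyses assume: a river / hyporheic / groundwater-well
## three-compartment design over repeated sampling events; conservative
## chloride and nitrate mixing; a respiration signal (DOC loss, matched DIC
## gain) confined to groundwater fractions below 10% and shut off below a
## DOC protection threshold of 0.4 mg/l; FTICR-MS formula pools whose
## thermodynamic favorability increases with groundwater influence;
## trait-selected communities on a Brownian-trait phylogeny; and a
## river-intrusion EC image series with EC_rw = 0.5 x EC_gw.  Latent truths
## are returned alongside every dataset for recovery tests.

#' Synthetic-generator parameters
#'
#' Defaults encode the study conditions: groundwater DOC ~0.35 mg/l against
#' 1.4 mg/l river DOC (so GW/RW ~ 0.25), groundwater chloride ~20 mg/l vs
#' 1.5 mg/l with 17.5 mg/l defining pure groundwater, nitrate 20x the river
#' concentration in groundwater, respiration confined below 10% groundwater
#' fraction with a 0.4 mg/l DOC protection threshold, 5% concentration
#' noise, and a river-water EC end member at 50% of baseline.
#'
#' @param seed base RNG seed; every generator derives its stream from it.
#' @param n_events number of sampling events.
#' @param n_wells groundwater wells sampled per event.
#' @param rw_doc,gw_doc river / groundwater DOC end members (mg/l).
#' @param rw_cl,gw_cl river / groundwater chloride end members (mg/l).
#' @param gw_cl_pure_threshold chloride cut defining pure groundwater (mg/l).
#' @param rw_no3 river nitrate (mg/l); groundwater nitrate is
#'   `no3_gw_over_rw` times larger.
#' @param no3_gw_over_rw groundwater-to-river nitrate ratio.
#' @param rw_dic,gw_dic river / groundwater DIC end members (mg/l).
#' @param mixing_threshold_f groundwater fraction below which respiration
#'   operates.
#' @param doc_protection_threshold DOC concentration (mg/l) below which DOC
#'   escapes respiration.
#' @param respiration_strength maximal fraction of unprotected DOC oxidized.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   measurement noise on concentrations.
#' @param dg_gw_shift offset (kJ (mol C)^-1, negative) of the groundwater
#'   formula pool's expected Gibbs energy relative to the river pool.
#' @param n_river_formulas,n_gw_formulas,n_shared_formulas formula-library
#'   pool sizes.
#' @param peak_range min/max peaks drawn per sample (kept within the
#'   observed 211-3499 range).
#' @param replicate_dropout per-replicate probability of missing a drawn
#'   peak (makes the replicate union meaningful).
#' @param n_otus,n_samples_community community dimensions.
#' @param selection_regimes named trait optima per compartment.
#' @param selection_sigma width of the Gaussian trait filter (trait units;
#'   traits are standardized to unit variance).
#' @param hz_width_boost extra filter width granted to hyporheic samples
#'   with little groundwater influence: their filter width is
#'   `selection_sigma + hz_width_boost * (1 - min(f/hz_f_max, 1))`, so
#'   selection tightens as groundwater (and its favorable DOC) mixes in —
#'   the coupling that makes betaNTI rise with DOC-profile dissimilarity
#'   across river vs hyporheic pairs.
#' @param hz_f_max upper bound of the hyporheic latent groundwater fraction.
#' @param optimum_jitter standard deviation of per-sample jitter around the
#'   compartment optimum (0 keeps selection strictly homogeneous within a
#'   compartment; positive values push within-compartment pairs toward the
#'   variable-selection regime).
#' @param abundance_noise_sdlog lognormal noise on expected abundances.
#' @param depth_range community sequencing-depth range (one sample is forced
#'   below 977 so rarefaction dropping is exercised).
#' @param ec_dim EC grid dimensions (rows, columns).
#' @param ec_base baseline groundwater EC magnitude (mS/m).
#' @param n_snapshots EC snapshots in the intruding series.
#' @return a `generator_params` list.
#' @export
generator_params <- function(seed = 1L,
                             n_events = 12L,
                             n_wells = 10L,
                             rw_doc = 1.4, gw_doc = 0.35,
                             rw_cl = 1.5, gw_cl = 20,
                             gw_cl_pure_threshold = 17.5,
                             rw_no3 = 0.5, no3_gw_over_rw = 20,
                             rw_dic = 5, gw_dic = 8,
                             mixing_threshold_f = 0.10,
                             doc_protection_threshold = 0.4,
                             respiration_strength = 0.8,
                             noise_cv = 0.05,
                             dg_gw_shift = -15,
                             n_river_formulas = 2000L,
                             n_gw_formulas = 2000L,
                             n_shared_formulas = 1000L,
                             peak_range = c(211L, 3499L),
                             replicate_dropout = 0.1,
                             n_otus = 1024L,
                             n_samples_community = 30L,
                             selection_regimes = c(river = -1, hyporheic = 1,
                                                   well = 0),
                             selection_sigma = 0.25,
                             hz_width_boost = 0.55,
                             hz_f_max = 0.25,
                             optimum_jitter = 0,
                             abundance_noise_sdlog = 1,
                             depth_range = c(1000L, 5000L),
                             ec_dim = c(20L, 40L),
                             ec_base = 30,
                             n_snapshots = 6L) {
  p <- as.list(environment())
  stopifnot(p$mixing_threshold_f > 0, p$mixing_threshold_f <= 1,
            p$respiration_strength >= 0, p$respiration_strength <= 1,
            p$replicate_dropout >= 0, p$replicate_dropout < 1,
            p$noise_cv >= 0, p$gw_cl > p$rw_cl, p$dg_gw_shift <= 0,
            p$peak_range[1] >= 211, p$peak_range[2] <= 3499)
  class(p) <- "generator_params"
  p
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic aqueous chemistry
#'
#' Per event: one river sample (groundwater fraction 0), one hyporheic
#' sample (low fraction), and `n_wells` well samples whose latent fractions
#' span the mixing gradient, with 40% of wells near-pure groundwater (their
#' fractions may slightly exceed 1, as with a mean-defined end member).
#' Chloride and nitrate are conservative; DOC follows the mixing line and
#' then loses `respiration_strength * w(f) * (DOC_mix - protection)+` with
#' a matched 1:1 (mg C) DIC gain, where the respiration weight
#' `w(f) = min(f / mixing_threshold_f, 1)` ramps up across the narrow
#' mixing window and saturates above it.  DOC deviations from the mixing
#' line therefore grow increasingly negative from the river anchor (zero
#' deviation at f = 0) to the 10%-GW breakpoint and then relax linearly
#' back toward the mixing expectation from 10% to 100% GW, while measured
#' DOC changes little above the breakpoint — the nonlinear DOC ~ f shape
#' the projections rely on.  Lognormal noise with CV `noise_cv` is applied
#' to all measured concentrations.
#'
#' @param params `generator_params`.
#' @return a `chem_table`; latent truths (true fraction, DOC loss) attached
#'   as the `truth` attribute.
#' @export
generate_chemistry <- function(params = generator_params()) {
  withr::with_seed(params$seed + 1L, {
    nw <- params$n_wells
    n_shallow <- max(1L, round(0.2 * nw))
    n_mid1 <- max(1L, round(0.2 * nw))
    n_mid2 <- max(1L, round(0.2 * nw))
    n_pure <- nw - n_shallow - n_mid1 - n_mid2
    rows <- list()
    for (ev in seq_len(params$n_events)) {
      f_wells <- c(runif(n_shallow, 0.02, 0.30),
                   runif(n_mid1, 0.30, 0.60),
                   runif(n_mid2, 0.60, 0.90),
                   runif(n_pure, 0.88, 1.04))
      rows[[ev]] <- data.frame(
        sample_id = c(sprintf("e%02d_river", ev),
                      sprintf("e%02d_hz", ev),
                      sprintf("e%02d_w%02d", ev, seq_len(nw))),
        location_class = c("river", "hyporheic", rep("well", nw)),
        event = ev,
        f_true = c(0, runif(1, 0, params$hz_f_max), f_wells),
        stringsAsFactors = FALSE
      )
    }
    chem <- do.call(rbind, rows)
    f <- chem$f_true
    is_river <- chem$location_class == "river"

    cl <- f * params$gw_cl + (1 - f) * params$rw_cl
    no3 <- f * (params$no3_gw_over_rw * params$rw_no3) + (1 - f) * params$rw_no3
    doc_mix <- f * params$gw_doc + (1 - f) * params$rw_doc
    dic_mix <- f * params$gw_dic + (1 - f) * params$rw_dic
    w <- pmin(f / params$mixing_threshold_f, 1)
    loss <- params$respiration_strength * w *
      pmax(doc_mix - params$doc_protection_threshold, 0)
    loss[is_river] <- 0  # the river end member is unreacted by definition
    doc <- doc_mix - loss
    dic <- dic_mix + loss  # 1:1 molar C transfer, both measured as mg C / l

    n <- nrow(chem)
    out <- data.frame(
      sample_id = chem$sample_id,
      location_class = chem$location_class,
      event = chem$event,
      cl = cl * ln_noise(n, params$noise_cv),
      doc = doc * ln_noise(n, params$noise_cv),
      dic = dic * ln_noise(n, params$noise_cv),
      no3 = no3 * ln_noise(n, params$noise_cv),
      stringsAsFactors = FALSE
    )
    validate_chemistry(out)
    attr(out, "truth") <- data.frame(sample_id = chem$sample_id,
                                     f_true = f,
                                     doc_mix = doc_mix,
                                     doc_loss = loss,
                                     stringsAsFactors = FALSE)
    class(out) <- unique(c("chem_table", class(out)))
    out
  })
}

# Integer molecular formula from target C count and molar ratios; H parity
# is adjusted so the double-bond equivalent stays integral.
build_formulas <- function(C, hc, oc, N) {
  H <- round(hc * C)
  O <- round(oc * C)
  H <- H + ((H - N) %% 2)  # H == N (mod 2)
  data.frame(C = C, H = H, N = N, O = O, P = 0L, S = 0L)
}

#' Generate the synthetic molecular-formula library
#'
#' Two overlapping formula pools: a river-enriched CHO pool in the
#' lignin-like Van Krevelen region, a groundwater/hyporheic-enriched CHON
#' pool in the amino-sugar-like region, and a shared CHO pool.  The
#' groundwater pool's H:C center is placed analytically so its expected
#' Gibbs energy sits `dg_gw_shift` kJ (mol C)^-1 below the river pool's
#' (more negative = more thermodynamically favorable).
#'
#' @param params `generator_params`.
#' @return data frame of unique formulas with columns `C,H,N,O,P,S`,
#'   `charge`, `mz` (neutral monoisotopic mass), `pool`, `nosc`, `dg`.
#' @export
generate_formula_library <- function(params = generator_params()) {
  withr::with_seed(params$seed + 2L, {
    # integer rounding collapses nearby (C, ratio) draws onto the same
    # formula, so oversample each pool and keep the unique survivors
    over <- 4L
    # river pool: CHO, lignin-like box
    nr <- params$n_river_formulas * over
    river <- build_formulas(sample(8:40, nr, TRUE),
                            runif(nr, 0.85, 1.45), runif(nr, 0.15, 0.60), 0L)
    river$pool <- "river"
    e_nosc_river <- 2 * mean(c(0.15, 0.60)) - mean(c(0.85, 1.45))

    # groundwater pool: CHON, amino-sugar-like box; H:C center solves for
    # the requested expected Gibbs-energy offset (NOSC = 2*O:C - H:C + 3*N:C
    # for CHON formulas)
    ng <- params$n_gw_formulas * 10L  # small Van Krevelen box: oversample more
    C_g <- sample(6:40, ng, TRUE)
    N_g <- pmax(1L, as.integer(round(0.2 * C_g)))
    nc_expect <- mean(pmax(1, round(0.2 * (6:40))) / (6:40))
    target_nosc_gw <- e_nosc_river - params$dg_gw_shift / 28.5
    hc_center <- 2 * mean(c(0.55, 0.70)) + 3 * nc_expect - target_nosc_gw
    hc_g <- pmin(pmax(runif(ng, hc_center - 0.2, hc_center + 0.2), 1.5), 2.2)
    gw <- build_formulas(C_g, hc_g, runif(ng, 0.55, 0.70), N_g)
    gw$pool <- "gw"

    # shared pool: CHO formulas of intermediate thermodynamic favorability,
    # present in both waters
    ns <- params$n_shared_formulas * over
    shared <- build_formulas(sample(8:35, ns, TRUE),
                             runif(ns, 0.95, 1.40), runif(ns, 0.35, 0.65), 0L)
    shared$pool <- "shared"

    take_unique <- function(d, n) {
      d <- d[!duplicated(d[, c("C", "H", "N", "O", "P", "S")]), , drop = FALSE]
      d[seq_len(min(n, nrow(d))), , drop = FALSE]
    }
    lib <- rbind(take_unique(river, params$n_river_formulas),
                 take_unique(gw, params$n_gw_formulas),
                 take_unique(shared, params$n_shared_formulas))
    lib <- lib[!duplicated(lib[, c("C", "H", "N", "O", "P", "S")]), ,
               drop = FALSE]
    lib$charge <- 0L
    lib$mz <- formula_mass(lib)
    lib$nosc <- suppressWarnings(nosc(lib$C, lib$H, lib$N, lib$O, lib$P, lib$S))
    lib$dg <- delta_g_cox(lib$nosc)
    # fixed prevalence threshold per formula: a formula is present in a
    # sample when its pool-and-state inclusion probability exceeds this,
    # so samples in the same chemical state share nearly the same peaks
    lib$prevalence_u <- runif(nrow(lib))
    rownames(lib) <- NULL
    lib
  })
}

#' Generate synthetic FTICR-MS peak sets (3 replicates per sample)
#'
#' Each water sample's peak set is determined by its chemical state: the
#' groundwater-pool weight `w` rises with the latent groundwater fraction
#' and jumps when DOC falls below the protection threshold.  A library
#' formula is present when its inclusion probability — `0.95 - 0.9 w` for
#' river-pool formulas, `0.05 + 0.9 w` for groundwater-pool formulas, a
#' constant `0.8` for the shared pool, all scaled by a per-sample retention
#' factor — exceeds the formula's fixed prevalence threshold.  Presence is
#' therefore near-deterministic given the state: samples in similar states
#' share most peaks, and peak-set dissimilarity tracks the compositional
#' difference rather than sampling noise.  Per-sample median Gibbs energy
#' decreases with groundwater fraction and drops across the DOC threshold.
#' Three replicates are produced with independent random peak dropout;
#' merging replicates by union approximates the sample's full set.
#'
#' @param params `generator_params`.
#' @param chemistry output of [generate_chemistry()] (its `truth` attribute
#'   supplies the latent fractions).
#' @return a `peak_table` with an extra `replicate` column; latent truths
#'   (fraction, pool weight, peak count) attached as `truth`.
#' @export
generate_ftms_samples <- function(params = generator_params(),
                                  chemistry = generate_chemistry(params)) {
  lib <- generate_formula_library(params)
  truth_chem <- attr(chemistry, "truth")
  f <- truth_chem$f_true[match(chemistry$sample_id, truth_chem$sample_id)]
  withr::with_seed(params$seed + 3L, {
    w_gw <- pmin(pmax(0.1 + 0.45 * pmin(pmax(f, 0), 1) +
                        0.25 * (chemistry$doc < params$doc_protection_threshold),
                      0.05), 0.95)
    retention <- runif(nrow(chemistry), 0.75, 0.98)
    res <- vector("list", nrow(chemistry))
    n_peaks <- integer(nrow(chemistry))
    for (i in seq_len(nrow(chemistry))) {
      p_incl <- switch_pool_prob(lib$pool, w_gw[i]) * retention[i]
      present <- which(lib$prevalence_u < p_incl)
      n_peaks[i] <- length(present)
      if (n_peaks[i] < params$peak_range[1] ||
          n_peaks[i] > params$peak_range[2]) {
        stop("generated peak count ", n_peaks[i], " for sample ",
             chemistry$sample_id[i], " falls outside the study range [",
             params$peak_range[1], ", ", params$peak_range[2], "]",
             call. = FALSE)
      }
      reps <- lapply(1:3, function(r) {
        keep <- if (params$replicate_dropout > 0) {
          runif(length(present)) > params$replicate_dropout
        } else rep(TRUE, length(present))
        if (!any(keep)) keep[1L] <- TRUE
        d <- lib[present[keep], c("C", "H", "N", "O", "P", "S", "mz")]
        data.frame(sample_id = chemistry$sample_id[i], replicate = r, d,
                   charge = 0L, stringsAsFactors = FALSE)
      })
      res[[i]] <- do.call(rbind, reps)
    }
    peaks <- do.call(rbind, res)
    rownames(peaks) <- NULL
    attr(peaks, "truth") <- data.frame(sample_id = chemistry$sample_id,
                                       f_true = f, w_gw = w_gw,
                                       retention = retention,
                                       n_peaks = n_peaks,
                                       stringsAsFactors = FALSE)
    class(peaks) <- unique(c("peak_table", class(peaks)))
    peaks
  })
}

# Pool- and state-dependent inclusion probability for library formulas.
switch_pool_prob <- function(pool, w) {
  ifelse(pool == "river", 0.95 - 0.9 * w,
         ifelse(pool == "gw", 0.05 + 0.9 * w, 0.8))
}

#' Generate synthetic communities under trait-based selection
#'
#' A random pure-birth phylogeny over `n_otus` OTUs, with branch lengths
#' homogenized to one unit per edge, carries one Brownian-evolved trait
#' (standardized to unit variance), so trait similarity is phylogenetically
#' conserved — the condition under which betaMNTD-based inference responds
#' to selection.  Each sample filters OTUs through a Gaussian trait filter
#' centered on its compartment's optimum (width `selection_sigma`), with
#' lognormal abundance noise, and is multinomially sampled at a
#' heterogeneous depth; one sample is forced below depth 977 so rarefaction
#' dropping is exercised.  Compartments sharing an optimum come out under
#' homogeneous selection (mean betaNTI < -2) and river vs hyporheic
#' comparisons under variable selection (mean betaNTI > +2).  Hyporheic
#' samples with little groundwater influence get a broader filter
#' (see `hz_width_boost`), so river-vs-hyporheic betaNTI grows with the
#' latent groundwater fraction, mirroring the link between DOC-profile
#' shifts and selection.
#'
#' @param params `generator_params`.
#' @param chemistry optional output of [generate_chemistry()]; when given,
#'   community samples take their ids from chemistry samples (compartment =
#'   location class), so community and DOC-profile analyses can be linked
#'   pairwise.  Otherwise free-standing sample ids are invented.
#' @return list with `counts` (OTU x sample), `tree`, and `metadata`
#'   (`sample_id`, `compartment`); latent truths (traits, optima, depths)
#'   attached as `truth`.
#' @export
generate_communities <- function(params = generator_params(),
                                 chemistry = NULL) {
  withr::with_seed(params$seed + 4L, {
    # pure-birth topology; branch lengths homogenized to one unit per edge
    # so patristic distance equals nodal distance.  Nearest-taxon distances
    # are then tightly concentrated for random taxon sets, which is the
    # regime in which the betaMNTD null model has power.
    tree <- ape::rphylo(params$n_otus, birth = 1, death = 0)
    tree$edge.length <- rep(1, nrow(tree$edge))
    tree$tip.label <- sprintf("otu%04d", seq_len(params$n_otus))
    trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    trait <- (trait - mean(trait)) / sd(trait)

    comps <- names(params$selection_regimes)
    per <- rep(floor(params$n_samples_community / length(comps)),
               length(comps))
    per[1L] <- params$n_samples_community - sum(per[-1L])
    if (is.null(chemistry)) {
      ids <- unlist(mapply(function(cp, k) sprintf("c_%s_%02d", cp, 1:k),
                           comps, per, SIMPLIFY = FALSE))
    } else {
      lc <- c(river = "river", hyporheic = "hyporheic", well = "well")
      ids <- unlist(mapply(function(cp, k) {
        pool <- chemistry$sample_id[chemistry$location_class == lc[[cp]]]
        if (length(pool) < k) {
          stop("chemistry has only ", length(pool), " ", cp,
               " samples but ", k, " were requested", call. = FALSE)
        }
        pool[seq_len(k)]
      }, comps, per, SIMPLIFY = FALSE))
    }
    meta <- data.frame(
      sample_id = ids,
      compartment = rep(comps, per),
      stringsAsFactors = FALSE
    )
    # latent groundwater fraction per community sample: taken from the
    # chemistry truth when linked, otherwise drawn per compartment
    if (is.null(chemistry)) {
      f <- ifelse(meta$compartment == "river", 0,
                  ifelse(meta$compartment == "hyporheic",
                         runif(nrow(meta), 0, params$hz_f_max),
                         runif(nrow(meta), 0.88, 1.04)))
    } else {
      tr <- attr(chemistry, "truth")
      f <- tr$f_true[match(meta$sample_id, tr$sample_id)]
    }
    width <- rep(params$selection_sigma, nrow(meta))
    hz <- meta$compartment == "hyporheic"
    width[hz] <- params$selection_sigma + params$hz_width_boost *
      (1 - pmin(f[hz] / params$hz_f_max, 1))

    depths <- sample(params$depth_range[1]:params$depth_range[2],
                     nrow(meta), replace = TRUE)
    depths[nrow(meta)] <- 900L  # one sample under the 977 rarefaction depth

    counts <- sapply(seq_len(nrow(meta)), function(s) {
      mu <- params$selection_regimes[[meta$compartment[s]]] +
        if (params$optimum_jitter > 0) rnorm(1, 0, params$optimum_jitter) else 0
      lambda <- exp(-(trait - mu)^2 / (2 * width[s]^2)) *
        rlnorm(length(trait), 0, params$abundance_noise_sdlog)
      rmultinom(1, depths[s], prob = lambda)[, 1L]
    })
    dimnames(counts) <- list(tree$tip.label, meta$sample_id)
    storage.mode(counts) <- "integer"
    out <- list(counts = counts, tree = tree, metadata = meta)
    attr(out, "truth") <- list(trait = trait,
                               optima = params$selection_regimes,
                               sigma = params$selection_sigma,
                               f = setNames(f, meta$sample_id),
                               filter_width = setNames(width, meta$sample_id),
                               depths = setNames(depths, meta$sample_id))
    out
  })
}

#' Generate a synthetic EC image series with a moving intrusion front
#'
#' The baseline grid is pure-groundwater EC increasing smoothly with depth;
#' the river-water end member is exactly half the baseline.  Snapshots
#' interpolate toward the river end member behind a sigmoidal intrusion
#' front that advances monotonically from the river boundary (column 1), so
#' per-cell river-water fractions are non-decreasing through the series.
#'
#' @param params `generator_params`.
#' @return list with `baseline`, `rw`, `snapshots` (list of EC matrices with
#'   `time` attributes) and `truth` (list of latent river-water fraction
#'   matrices).
#' @export
generate_ec_series <- function(params = generator_params()) {
  nr <- params$ec_dim[1L]
  nc <- params$ec_dim[2L]
  depth <- matrix(seq_len(nr) / nr, nr, nc)
  baseline <- params$ec_base * (1 + 0.15 * depth)
  rw <- 0.5 * baseline
  front <- seq(2, 0.6 * nc, length.out = params$n_snapshots)
  col_ix <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  snapshots <- vector("list", params$n_snapshots)
  truth <- vector("list", params$n_snapshots)
  for (t in seq_len(params$n_snapshots)) {
    f_rw <- stats::plogis((front[t] - col_ix) / 2)
    ec_t <- baseline + f_rw * (rw - baseline)
    attr(ec_t, "time") <- t
    snapshots[[t]] <- ec_t
    truth[[t]] <- f_rw
  }
  list(baseline = baseline, rw = rw, snapshots = snapshots, truth = truth)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates chemistry, peaks, communities and the EC series at the given
#' parameters and writes them in the package's file formats, with latent
#' truths under `truth/`.
#'
#' @param params `generator_params`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
generate_all <- function(params = generator_params(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  dir.create(file.path(dir, "ec"), showWarnings = FALSE)

  chem <- generate_chemistry(params)
  write_chemistry(chem, file.path(dir, "chemistry.csv"))
  write.csv(attr(chem, "truth"), file.path(dir, "truth", "chemistry.csv"),
            row.names = FALSE)

  peaks <- generate_ftms_samples(params, chem)
  out_peaks <- peaks
  out_peaks$sample_id <- paste0(peaks$sample_id, "_r", peaks$replicate)
  write_peaks(out_peaks, file.path(dir, "peaks.csv"))
  write.csv(attr(peaks, "truth"), file.path(dir, "truth", "peaks.csv"),
            row.names = FALSE)

  comm <- generate_communities(params)
  write_otu_table(comm$counts, file.path(dir, "otu_table.tsv"))
  ape::write.tree(comm$tree, file.path(dir, "tree.nwk"))
  write.csv(comm$metadata, file.path(dir, "sample_metadata.csv"),
            row.names = FALSE)
  write.csv(data.frame(otu_id = names(attr(comm, "truth")$trait),
                       trait = unname(attr(comm, "truth")$trait)),
            file.path(dir, "truth", "traits.csv"), row.names = FALSE)

  ec <- generate_ec_series(params)
  write_ec_grid(ec$baseline, file.path(dir, "ec", "baseline.txt"))
  write_ec_grid(ec$rw, file.path(dir, "ec", "rw.txt"))
  manifest <- data.frame(role = c("baseline", "rw"),
                         filename = c("baseline.txt", "rw.txt"),
                         time = c(0L, 0L), stringsAsFactors = FALSE)
  for (t in seq_along(ec$snapshots)) {
    fn <- sprintf("snapshot_%02d.txt", t)
    write_ec_grid(ec$snapshots[[t]], file.path(dir, "ec", fn))
    write_ec_grid(ec$truth[[t]],
                  file.path(dir, "truth", sprintf("f_rw_%02d.txt", t)))
    manifest <- rbind(manifest, data.frame(role = "snapshot", filename = fn,
                                           time = t))
  }
  write.table(manifest, file.path(dir, "ec", "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
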