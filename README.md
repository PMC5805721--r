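# hyporheos

Groundwater–river mixing, dissolved organic carbon (DOC) thermodynamics,
and microbiome assembly in the hyporheic corridor.

River corridors host a subsurface mixing zone — the hyporheic corridor —
where river water (RW) intrudes into groundwater (GW). Mixing brings
together two protected carbon pools: thermodynamically unfavorable
river DOC and concentration-limited but favorable groundwater DOC, and
their contact stimulates microbial respiration within a narrow window of
mixing conditions. `hyporheos` implements the full inference chain used
to study this system:

- **End-member mixing** (`mixing_model()`): chloride as a conservative
  tracer, with reactive solutes (DOC, DIC, NO3) normalized per sampling
  event to the river concentration. The groundwater fraction of a sample
  is `f = (Cl - Cl_rw) / (Cl_gw - Cl_rw)`; deviations of observed
  normalized concentrations from the linear mixing prediction
  `f·C_gw + (1 - f)·1` diagnose reaction. A two-segment changepoint fit
  (`changepoint_estimate()`) locates the groundwater fraction below which
  DOC deviations grow increasingly negative, and
  `deviation_regression()` tests the DOC-loss/DIC-gain coupling.
- **DOC thermodynamics** (`nosc()`, `delta_g_cox()`,
  `sample_median_dg()`): for a molecular formula C_aH_bN_cO_dP_eS_f with
  net charge Z,
  `NOSC = -((-Z + 4a + b - 3c - 2d + 5e - 2f)/a) + 4`, and the Gibbs free
  energy of the carbon oxidation half reaction is
  `dG0_Cox = 60.3 - 28.5·NOSC` kJ (mol C)^-1 (higher = less favorable).
  Samples are profiled by their median over formula-bearing FTICR-MS
  peaks, on presence/absence. `threshold_scan()` finds the DOC
  concentration at which the thermodynamic profile shifts.
- **Peak-set mechanics** (`align_peaks()`, `merge_replicates()`,
  `vankrevelen()`, `peak_sorensen()`, `unique_peak_sets()`): ppm-level
  m/z alignment, replicate union, Van Krevelen compound classes, and
  Sorensen dissimilarity `1 - 2|A∩B|/(|A|+|B|)`.
- **Biochemical transformations** (`build_transform_db()`,
  `infer_transformations()`): exact mass differences between peak pairs
  matched to an 82-entry library of biochemical gains/losses (e.g.
  2.0156 Da = hydrogenation, 71.0371 Da = alanine), with normalized
  profiles and river-vs-hyporheic differential representation.
- **Community assembly** (`rarefy_counts()`, `bmntd()`, `null_bnti()`,
  `classify_assembly()`): abundance-weighted beta mean nearest taxon
  distance, a taxa-shuffle randomization null, and the beta nearest
  taxon index `betaNTI = (betaMNTD_obs - mean_null)/sd_null`;
  betaNTI < -2 indicates homogeneous selection, > +2 variable selection.
- **Spatial projection** (`rw_fraction()`, `project_doc()`): time-lapse
  electrical-conductivity images converted to river-water fraction
  fields by `F_rw = (EC_t - EC_0)/(EC_rw - EC_0)` and combined with the
  fitted DOC ~ groundwater-fraction curve to project DOC across the
  imaged domain.

Because the study's field data are unreleased, the package ships a
seeded synthetic-data generator (`generator_params()`,
`generate_chemistry()`, `generate_ftms_samples()`,
`generate_communities()`, `generate_ec_series()`, `generate_all()`)
that reproduces the statistical structure of all inputs, with latent
truths for recovery testing. `run_pipeline()` runs every stage end to
end from one configuration.

## Worked example

```r
library(hyporheos)

params <- generator_params(seed = 1)
chem   <- generate_chemistry(params)
mix    <- mixing_model(normalize_to_river(chem))

attr(mix, "endmembers")$cl_gw        # 19.31  mean Cl- of pure-GW samples (mg/l)
changepoint_estimate(mix)$f_star     # 0.10   GW fraction where DOC deviations break
deviation_regression(mix)$slope      # -0.31  DIC gain per unit DOC loss (negative)

peaks  <- generate_ftms_samples(params, chem)
merged <- do.call(rbind, lapply(split(align_peaks(peaks), ~ sample_id),
                                merge_replicates))
prof   <- sample_median_dg(merged)
dg_vs_gwfraction(prof, mix)$slope    # -7.79  kJ (mol C)^-1 per unit GW fraction
threshold_scan(prof, chem)$threshold # 0.4    mg/l DOC threshold of the dG shift
```

The numbers above are what the code prints at seed 1: the mixing
changepoint sits at a 10% groundwater fraction, DOC loss is coupled to
DIC gain below it, median Gibbs energy falls (DOC becomes more
favorable) toward pure groundwater, and the thermodynamic regime shifts
at a DOC concentration of 0.4 mg/l.

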