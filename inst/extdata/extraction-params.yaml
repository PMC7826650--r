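# Extraction settings used throughout the repeatability analysis.
# These mirror the package defaults; pass this file to `radrep run` configs
# or read it with yaml::read_yaml() to keep extraction parameters auditable.
extraction:
  dimensionality: 3D
  filters: none                # features are computed on unfiltered images
  discretisation:
    type: fixed_bin_width
    bin_width: 5               # intensity units; bin edges anchored at ROI min
  normalisation:
    enabled_variants: [false, true]
    target_mean: 0
    target_sd: 100
    scope: volume              # statistics over the whole volume, not ROI-only
  texture:
    glcm_distance: 1
    directions: 13             # unique 3D direction pairs, symmetrised
    direction_aggregation: average_feature_values
    connectivity: 26           # GLSZM / GLDM / NGTDM neighbourhoods
    gldm_alpha: 0
statistics:
  icc: "ICC(1,1), one-way random effects, exact F confidence intervals"
  rc: "1.96 * sqrt(2) * within-subject SD, chi-square confidence intervals"
  gaussianity_gate:
    test: shapiro_wilk
    alpha: 0.05
    bonferroni_denominator: 105
  boxcox:
    lambda_criterion: ppcc     # probability-plot correlation; mle available
    lambda_bounds: [-5, 5]
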