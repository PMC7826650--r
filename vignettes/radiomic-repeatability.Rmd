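---
title: "Assessing test-retest repeatability of MRI radiomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing test-retest repeatability of MRI radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrep)
```

## The measurement model

A test-retest study measures each lesion twice under nominally identical
conditions. For a single radiomic feature, `radrep` models the value of
lesion $i$ at visit $j$ as

$$x_{ij} = \mu + b_i + e_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad e_{ij} \sim N(0, \sigma_w^2),$$

a one-way random-effects model: $\sigma_b^2$ is the genuine between-lesion
spread of the feature in the cohort and $\sigma_w^2$ is the measurement
(test-retest) variance. Two complementary summaries follow:

* **ICC(1,1)** $= \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ — the fraction of
  observed variability that is real signal. Estimated from the one-way ANOVA
  mean squares as $(MS_B - MS_W)/(MS_B + (k-1) MS_W)$, with an exact
  confidence interval from the $F$-ratio $MS_B/MS_W$ on
  $(n-1,\; n(k-1))$ degrees of freedom. The ICC is dimensionless and
  cohort-dependent: a feature that varies little across lesions can have a
  low ICC even when measured precisely.
* **Repeatability coefficient (RC)** $= 1.96\sqrt{2}\,\sigma_w$ — the bound
  that the absolute difference between two repeat measurements stays within
  for 95% of lesions. Estimated from $\widehat{\sigma}_w = \sqrt{MS_W}$
  (for $k = 2$ this is $\sqrt{\sum_i d_i^2 / 2n}$ over the paired
  differences $d_i$), with a confidence interval from the exact
  $\chi^2_{n(k-1)}$ distribution of the scaled within-subject variance. RC
  carries the feature's units and does not depend on the cohort's
  between-lesion spread, which makes it the natural yardstick for deciding
  whether a longitudinal change in an individual patient is real.

The one-way (rather than two-way) model treats visits as exchangeable: there
is no systematic visit effect to estimate, which matches a short-interval
repeat-scan design in which nothing distinguishes visit 1 from visit 2.
Negative ICC estimates are reported as computed; clamping them at zero would
distort the estimator's sampling distribution and invalidate the interval
coverage that the package's acceptance checks verify.

Lesions are treated as independent sampling units even though several may
come from one patient. This mirrors common per-lesion practice and keeps the
model honest to what the data identify, but it is a documented limitation:
with strong patient-level clustering the effective sample size is smaller
than the lesion count and intervals will be somewhat anticonservative.

## Gaussianity gating and Box-Cox transformation

Both the $F$ interval for the ICC and the $\chi^2$ interval for the RC
assume Gaussian feature distributions, and many radiomic features are
heavily skewed. `classify_features()` therefore applies, per feature, on
values pooled across both visits:

1. A **Shapiro-Wilk gate** at the Bonferroni-corrected threshold
   $p < \alpha/m$ (default $0.05/105$, $m$ being the number of features
   tested). Features that pass are analysed untransformed
   (`gaussian_pre`).
2. For the rest, a **Box-Cox transformation**
   $y = (x^\lambda - 1)/\lambda$ ($\log x$ at $\lambda = 0$), with
   $\lambda$ chosen to maximise the probability-plot correlation
   coefficient (PPCC) over $\lambda \in [-5, 5]$ — a coarse 41-point grid
   locates the basin, then bounded scalar optimisation refines it, making
   the search deterministic. A Gaussian profile-likelihood criterion is
   available (`method = "mle"`); the two agree closely on cleanly
   transformable data, and PPCC is the default because it is the quantity
   displayed on Box-Cox normality plots and is robust to mild outliers.
3. A **re-gate** of the transformed values, classifying the feature
   `gaussian_post` or `never`. `never` features are still analysed on the
   transformed scale: even when the gate still fails, the transformation
   moves the distribution substantially closer to Gaussian, which is
   preferable to knowingly analysing raw skewed values.

One $\lambda$ is fitted per feature per dataset and applied identically to
both visits, so the transformation cannot manufacture spurious
between-visit differences. Because Box-Cox is strictly increasing, ranks —
and hence Spearman correlations — are unchanged.

Features that can be non-positive (skewness, cluster shade) are shifted by
$-\min(x) + \varepsilon$ (with $\varepsilon$ scaled to the data range)
before transformation; the shift is recorded in the per-feature record.
This choice is not canonical — alternatives such as Yeo-Johnson exist —
so it is surfaced explicitly rather than hidden.

## ICC comparisons across datasets

To compare the same feature's repeatability between two datasets (two MR
sequences, with/without intensity normalisation, with/without Box-Cox),
`compare_iccs()` uses Fisher's Z-test: $z = \tfrac12\ln\frac{1+r}{1-r}$
stabilises the variance of correlation-type statistics, and the difference
$z_a - z_b$ is referred to a normal distribution. The per-cohort variance
uses Fisher's small-sample form for intraclass correlations from paired
measurements, $1/(n - 3/2)$, with the classic product-moment $1/(n-3)$
available by flag; the choice matters little at $n \gtrsim 50$ but the
intraclass form is the theoretically matched one for $k = 2$. Cohorts are
treated as independent even when the same lesions appear in both datasets —
an unpaired comparison that is typically conservative under the positive
dependence induced by shared lesions, and a documented simplification.

Significance is gated at $\alpha/m$ with $m$ equal to the number of
features (the dominant multiplicity), not the number of dataset pairs;
additional adjustment across pairs is left to the study design.

## Upstream image computation

**T1 mapping.** The variable-flip-angle SPGR signal
$S(\alpha) = M_0 \sin\alpha\,(1-E)/(1-E\cos\alpha)$, $E = e^{-TR/T_1}$, is
fitted voxelwise for $(M_0, T_1)$ by Levenberg-Marquardt damped least
squares, vectorised across voxels (the damped 2x2 normal equations are
solved in closed form for all voxels simultaneously, so whole volumes fit
in seconds). Initialisation uses the linearised DESPOT1 regression of
$S/\sin\alpha$ on $S/\tan\alpha$, whose slope is $E$ — a closed form that
removes any dependence on arbitrary starting values and doubles as an
independent cross-check: on noiseless data the two routes agree to solver
tolerance, and the nonlinear fit matches an external per-voxel
Levenberg-Marquardt implementation to four decimals in tests. Voxels whose
signals are all numerically zero, whose fit fails, or whose $T_1$ lands
outside the default (1, 10000) ms bounds are flagged `fit_ok = FALSE`
(never clamped) and carry `NA` in the maps. No B1 correction is applied;
flip angles are taken at face value.

**Normalisation and discretisation.** Weighted-image intensities have
arbitrary units, so images can be linearly normalised to mean 0 / SD 100
before extraction. Statistics are computed over the whole volume by
default — matching the convention of standard extraction software — with an
ROI-restricted option (`scope = "roi"`), since published workflows are
often silent on this point. Grey levels are discretised with a fixed bin
width (default 5 intensity units) and bin edges anchored at the ROI
minimum: level $= \lfloor (x - \min)/w \rfloor + 1$. Fixed bin width (as
opposed to fixed bin count) keeps the intensity resolution constant across
lesions, and the median bin count across lesions is reported as the
standard summary of effective grey-level resolution.

**Mask resampling** between resolutions (e.g. applying a low-resolution
qT1-map mask to a higher-resolution weighted image) is nearest-neighbour in
world coordinates, which guarantees a binary result without a thresholding
convention. Round-trip fidelity is good for lesion-scale masks (tests
verify >= 90% overlap for convex masks >= 20 voxels across) but degrades
for structures only a few voxels wide, where any nearest-neighbour scheme
loses boundary voxels.

## Radiomic features

The extractor implements every feature the repeatability analysis names,
plus exemplars of each texture class, rather than a full 100+ catalogue:
the statistics stack is feature-agnostic, so breadth adds nothing to the
method. `feature_provenance()` lists each feature's class, formula and
parameters; the same information can be embedded as a commented header in
exported tables.

Choices worth knowing about:

* **Mesh volume and surface area** come from a closed triangulated
  isosurface: the binary mask is box-averaged onto the dual lattice
  (anti-aliasing the staircase boundary, without which the area of a
  digitised sphere is overestimated by 20-30%), then contoured at the 0.5
  level through the six Freudenthal tetrahedra per cell, within which the
  field is linear and the level set an exact plane. A digitised
  radius-8-voxel ball yields sphericity 0.978 (analytic limit 1), and area
  and volume within a few percent of the analytic values. Masks under two
  voxels thick have no usable isosurface and return `NA` mesh features.
* **Texture matrices** use the 13 unique 3D directions at distance 1 (GLCM
  symmetrised; GLRLM runs broken by ROI gaps) and 26-connected
  neighbourhoods (GLSZM zones, GLDM with dependence threshold
  $\alpha = 0$, NGTDM). Per-direction features are averaged over
  directions — not computed on merged matrices — a convention choice that
  is recorded in the provenance table because published pipelines differ.
* **NGTDM coarseness** is $1/\sum_i p_i s_i$, capped at $10^6$ for a
  perfectly homogeneous ROI where the denominator vanishes.
* **First-order skewness** uses population moments (Fisher-Pearson) and is
  `NA` below three voxels.

All texture matrices are verified exactly against exhaustive brute-force
neighbour enumeration on random ROIs, and every derived feature against a
direct evaluation of its formula — the implementation and its oracle share
no code.

## The synthetic-data generator

`simulate_feature_table()` draws feature tables from the one-way model
above, with an optional inverse Box-Cox warp (`lambda_skew`) so that the
generative truth survives on a known transformed scale: applying the
forward Box-Cox with the same $\lambda$ restores exact Gaussianity.
Out-of-domain warps are rejected, never clipped — clipping would silently
bias the generative variance components that every recovery test relies
on. `simulate_vfa_phantom()` builds SPGR flip-angle volumes from a known
$T_1$/$M_0$ phantom — a uniform background (default 500 ms, liver
parenchyma at 1.5 T) with an ellipsoidal lesion (default 1000 ms,
reflecting the prolonged $T_1$ of metastases), acquired at flip angles
2/10/20 degrees with TR 4 ms, the protocol geometry the statistical
defaults are matched to — plus additive Gaussian noise.

What the generator deliberately does **not** emulate: patient-level
clustering of lesions, visit effects (scanner drift, contrast-agent
timing), motion and breathing artefacts, B0/B1 inhomogeneity, anatomical
texture, and segmentation variability. Passing recovery tests therefore
demonstrate that the statistical machinery is correct and well calibrated
under its stated model — not that real-world features meet the model's
assumptions; that is exactly what the Gaussianity gate and the per-study
analysis are for.

## Numerical and design choices

* Box-Cox transforms are computed as `expm1(lambda * log x)/lambda`,
  continuous through $\lambda = 0$ to machine precision.
* The RC multiplier is `sqrt(2) * qnorm(0.975)` (2.7718...), the quantity
  conventionally quoted as 1.96-root-2.
* All randomness in `run_study()` flows from one top-level seed;
  synthetic datasets consume sequential blocks of the RNG stream, so
  identical configurations reproduce byte-identical reports.
* Degenerate inputs are flagged rather than silently repaired: constant
  images cannot be normalised, constant features fail the gate with a
  degenerate flag, zero-signal voxels are `fit_ok = FALSE`, constant
  features have undefined Spearman correlations.
* Validation problem sizes were chosen to make Monte-Carlo error small
  relative to the tolerance being asserted: 2000 cohorts of 50 lesions for
  interval coverage (binomial SE ~ 0.5 percentage points), 100,000 subject
  pairs for RC containment, and 5000-lesion tables for variance-component
  recovery at 3-SE sharpness.

## Known limitations

* Per-lesion (not per-patient) inference; see above.
* The unpaired Fisher-Z comparison ignores lesion sharing between
  datasets.
* The feature subset omits filtered (wavelet/LoG) feature maps and 2D
  extraction by design.
* `shapiro.test()` accepts at most 5000 values, bounding the pooled sample
  size per feature; two-visit cohorts up to 2500 lesions are covered.
* Nearest-neighbour mask resampling is inaccurate for masks only a few
  voxels across.
* Maximum 3D diameter uses surface-voxel centres, not mesh vertices, so it
  underestimates by up to one voxel diagonal relative to mesh-based
  definitions.
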