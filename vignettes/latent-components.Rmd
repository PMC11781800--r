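---
title: "Multimodal brain-behavior latent components: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal brain-behavior latent components: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsmosaic)
```

## The scientific problem

Dimensional psychiatry asks how broad symptom dimensions in children --
a general psychopathology ("p") factor, internalizing versus
externalizing contrasts, neurodevelopmental symptoms -- map onto brain
structure and intrinsic functional organization. plsmosaic implements a
complete analysis chain for this question: it relates a
subjects-by-items matrix of parent-rated ordinal symptom scores (0/1/2)
to multimodal imaging features (cortical surface area, thickness and
volume per parcel, plus vectorized region-pair resting-state functional
connectivity) in large multi-site pediatric cohorts, and
contextualizes the resulting brain maps against the sensory-to-transmodal
cortical gradient.

## The core model: PLS correlation

Let $Y$ ($n \times q$, symptom items) and $X_{pca}$ ($n \times p$,
concatenated per-modality PCA scores) be z-scored across subjects.
The cross-covariance
$$R = Y^\top X_{pca}$$
is decomposed by SVD, $R = U S V^\top$. Each *latent component* (LC) is
a pair of singular vectors -- behavioral saliences $u_k$ and imaging
saliences $v_k$ -- with singular value $s_k$. Composite scores are the
projections $L_X = X_{pca} V$ and $L_Y = Y U$; they maximize the sample
covariance between the two blocks among orthonormal weight systems. The
interpretable output is not the saliences but the *loadings*: Pearson
correlations between each original variable and the matching composite
score. Covariance explained by component $k$ is
$s_k^2 / \sum_j s_j^2$, computed over the full singular spectrum.

Assumptions worth stating: the method is linear and symmetric (no
outcome/predictor asymmetry), treats ordinal 0/1/2 items as numeric
after z-scoring, and identifies components only up to sign. We fix
signs so that the largest-magnitude behavior loading of each component
is positive, which makes "all items load positively on the p-factor
component" a reproducible readout.

## The pipeline around the model

1. **Confound residualization** (`residualize`). Age, age squared, sex,
   site and ethnicity are regressed out of every feature and every
   item; thickness and volume are additionally adjusted for
   intracranial volume, surface area for total surface area, and
   connectivity for head motion (mean FD) and image intensity (mean
   DVARS). Coefficients are fitted on the full sample for the main
   pipeline; the transfer analysis refits them on discovery subjects
   only, since out-of-sample scoring may use nothing from the
   replication arm. Residualization is idempotent and leaves residuals
   orthogonal to the design to numerical precision.
2. **Matched split** (`matched_split`). Subjects are stratified by site,
   sex, ethnicity, age quartile and overall-psychopathology quartile
   (first principal component of the items, signed positively with the
   item total), and each cell is split 2:1. Cells below three subjects
   are merged upward by dropping stratification variables in reverse
   order of importance. Continuous matching variables are binned at
   quartiles; the split is deterministic given the seed.
3. **Dimensionality reduction** (`fit_pca`, `concatenate_scores`). PCA
   per modality on centered (not variance-standardized) features,
   keeping the smallest number of components whose cumulative explained
   variance reaches the threshold (default 0.5). Features within a
   modality share units, which is why standardization is off by
   default; a switch exposes it. The per-modality scores are
   concatenated in fixed order (area, thickness, volume, rsfc).
   Balancing modalities through a common variance threshold, rather
   than concatenating raw features, keeps the far larger connectivity
   block from dominating the decomposition.
4. **Inference** (`permutation_test`, `bootstrap_within_site`).
   Significance of the leading components is assessed by permuting
   behavior rows *within acquisition site* and comparing each observed
   singular value against its same-index null (add-one p-values, BH-FDR
   across the tested components, default five). Loading stability uses
   a within-site bootstrap: each resample refits the decomposition,
   components are sign-aligned to the original by the sign of
   $u_k^\top u_k^{(0)}$ (never re-ordered), and Z = loading /
   bootstrap SD, converted to two-sided normal p-values with BH-FDR.
   Connectivity loadings are averaged within and between networks
   before Z-scoring to limit multiple comparisons; an 18-network
   partition yields 171 blocks.
5. **Weight transfer** (`fit_transfer_model`, `transfer_scores`).
   Replication data are pushed through the discovery PCA coefficients,
   normalized by discovery means and SDs, and multiplied by the
   discovery saliences. Out-of-sample loadings correlate these
   cross-validated scores with the normalized replication data. Items
   invariant in the replication arm are dropped from both $U$ and $Y$,
   with the remaining salience columns renormalized.
6. **Gradients** (`build_affinity`, `diffusion_embed`). The group-mean
   connectivity matrix is row-thresholded to its top 10% entries
   (diagonal excluded), converted to cosine similarities (negatives
   clamped to zero), and embedded by diffusion maps with $\alpha = 0.5$
   and $t = 0$. Gradient variance fractions are eigenvalue ratios over
   the retained nontrivial spectrum. `procrustes_align` rotates the
   embedding onto a reference gradient set (orthogonal rotation,
   reflections allowed, no scaling).
7. **Spatial nulls** (`spin_permutation`, `spin_correlation`).
   Correlations between cortical loading maps and the principal
   gradient are tested against spin permutations: uniform random
   rotations applied to the left-hemisphere centroid sphere and
   x-mirrored to the right, with greedy nearest-neighbor reassignment
   (duplicates allowed). Subcortical parcels are excluded from spins.

## Permutation of residuals

Permuting residualized rows is subtly anticonservative: the observed
residuals are exactly orthogonal to the confound design while permuted
rows are not, so observed cross-covariances are systematically compared
against a mismatched null. At $n = 300$ with a ~12-column design this
inflates the type-I rate of the leading-component test from 5% to
roughly 7-8%. `permutation_test` therefore accepts the confound design
(`covariates`, `terms`) and re-residualizes every permuted draw before
the null decomposition, which restores the nominal rate (measured 5.3%
over 300 null replicates). The uncorrected path remains available by
omitting the design.

## The synthetic cohort generator

`generate_dataset` draws a multi-site cohort in which *all*
imaging-behavior covariance is carried by a small number of planted
latent components, so every stage of the pipeline can be validated
against known ground truth:

- **Subject factors and saliences.** Each subject has `n_latent`
  standard-normal factor scores. Behavior saliences are orthonormal with
  an all-positive dominant column (a p-factor analogue); structural
  saliences are spatially smooth orthonormal maps per block.
- **Strength convention.** `latent_strength[k]` is the signal-to-noise
  of component $k$ on the composite scale: projecting the data onto the
  planted salience gives signal of SD `latent_strength[k]` against
  unit noise. The defaults (5, 3, 2) give a clearly detectable but not
  degenerate three-component structure at $n$ in the hundreds.
- **Ordinal items.** A Gaussian propensity loading on the factors is
  standardized and cut at two thresholds per item (defaults 0.8 and
  1.8), making "0" the modal response, as in right-skewed community
  symptom scales.
- **Connectivity.** Per subject, $C_i = B \Lambda_i B^\top + D$ with
  shared orthonormalized columns $B$: leading eigenvectors of a
  Laplacian kernel along the (rank-uniformized) planted cortical
  gradient, then network indicator columns, then dense noise columns.
  Subject factor strengths $\Lambda_i$ vary around column-specific
  baselines (gradient columns scale with `gradient_strength`), receive
  the planted latent perturbations on disjoint network-column supports,
  and are clipped at zero -- so every subject matrix is positive
  semi-definite by construction. Edge noise is consequently low-rank
  (rank at most the number of columns of $B$), which is the price of
  exact PSD; the PCA step absorbs this structure.
- **Planted truth scale.** Because the analysis z-scores features,
  recorded imaging saliences are expressed in the standardized feature
  space (raw signal directions rescaled by realized feature SDs, then
  re-orthonormalized). This makes the stored truth directly comparable
  with recovered saliences and loading maps.
- **Confounds.** Age, age squared, sex, site and ethnicity shifts
  (plus motion for connectivity, volume proxies for structure) are
  injected additively with magnitude `confound_strength`; for
  connectivity they enter through $\Lambda$ so PSD is preserved. Site
  effects are additive mean shifts -- the simplest mechanism that makes
  site-restricted permutation consequential.

What the generator does *not* emulate: realistic item psychometrics
beyond ordinal marginals and factor structure, fMRI timeseries or
scanner physics, family structure, missingness, or full-rank
subject-level edge noise. Passing tests on this generator therefore
demonstrate correctness of the estimation machinery and calibration of
the resampling inference under the stated generative model, not
real-data effect sizes: headline statistics from any particular cohort
(composite correlations, covariance-explained percentages, gradient
variance fractions) are data-bound and are not reproduction targets.

## Numerical choices and conventions

- Z-scoring uses the sample ($n-1$) SD; the choice cancels in all
  correlations and covariance fractions.
- Edge vectorization is lower-triangle, row-major, diagonal excluded;
  419 regions give 87,571 edges.
- PCA is computed from the eigendecomposition of the smaller Gram
  matrix (features or subjects), with component signs fixed so the
  largest-|loading| feature is positive. Retention uses a closed
  boundary (cumulative ratio $\ge$ threshold).
- The diffusion eigenproblem is solved densely on the symmetrically
  conjugated operator -- deterministic, no randomized solvers; at $t=0$
  gradients are unscaled eigenvectors, with eigenvector signs fixed by
  the largest-|entry| rule.
- Permutation and bootstrap p-values use add-one smoothing and so are
  never exactly zero; with 10,000 permutations the attainable floor is
  about $10^{-4}$.
- Undefined correlations (zero-variance composites, zero bootstrap
  SDs) are reported as 0 or $\pm\infty$ with explicit flags rather
  than NaN; bootstrap SDs below $10^{-12}$ are treated as zero.
- The permutation null uses same-index singular values without
  realignment by default; a Procrustes-aligned null is available as a
  sensitivity switch.

## Design decisions where the design was open

- **Residualization scope.** Coefficients are fitted on the full sample
  before splitting for the main pipeline; the transfer path refits on
  discovery only. Both orders are exposed, since the correct choice
  depends on whether the replication arm must remain strictly unseen.
- **Covariance-explained denominator.** The full singular spectrum,
  not a truncated one; with hundreds of imaging dimensions this leaves
  a long tail of small components, so leading-component fractions are
  conservative.
- **Within/between-network parcel maps.** The per-parcel summaries
  correlated with the gradient are signed means over each parcel's
  within- and between-network edges; absolute means are available via
  a switch.
- **Spin construction.** Parcel-level centroid rotation rather than
  vertex-level projection, since loadings live on parcels here.
  Duplicates from nearest-neighbor reassignment are accepted; roughly
  half to two-thirds of the value multiset survives a spin, which is
  inherent to non-bijective reassignment at any parcel density.
- **Composite-score orthogonality.** Saliences are exactly orthonormal;
  composite scores are only approximately uncorrelated (their
  covariance is $V^\top \hat\Sigma_X V$, not diagonal). Tests assert
  the exact property for saliences and a small-magnitude bound for
  composites.

## Validation protocol and problem sizes

The test suite validates each stage against independent oracles
(closed-form eigenstructure, brute-force correlation loops, dense
eigensolvers, planted ground truth) and calibrates the resampling
machinery at these scales, chosen to make stochastic checks stable
while keeping the default run in the minutes range: salience recovery
at $n = 2000$ subjects, 100 cortical parcels, 60 items; permutation
type-I calibration over 500 null replicates at $n = 300$ with 99
permutations; bootstrap CI coverage over 100 replicates at $n = 1000$
with 200 resamples; spin calibration over 200 replicates with 99 spins
on 100 parcels. `scripts/acceptance.R` re-runs the same computations
from scratch and writes the resulting quantities as JSON.

## Known limitations

- PLS correlation captures linear covariance only, and component
  identity can rotate under resampling when singular values are close;
  the bootstrap sign-aligns but deliberately never re-orders
  components.
- The generator's PSD-by-construction connectivity implies low-rank
  subject-level edge noise; calibration results for edge-loading
  inference should be read with that in mind.
- Spin tests require a spherical parcel geometry and exclude
  subcortex; conclusions about subcortical loadings rely on the
  bootstrap machinery alone.
- Ordinal items are analyzed as numeric after z-scoring, matching
  common practice for 0/1/2 symptom scales; no graded-response
  measurement model is fitted.
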