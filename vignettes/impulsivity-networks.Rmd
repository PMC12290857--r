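---
title: "From activation coordinates to brain-network communities: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From activation coordinates to brain-network communities: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alenet)
```

`alenet` implements a complete inference chain for characterising the brain
networks underlying a cognitive construct from the published literature:
coordinate-based meta-analysis (ALE) of reported activation foci, permutation
contrasts and conjunctions between meta-analyses, extraction of network nodes
from the resulting statistic maps, node-based resting-state functional
connectivity, consensus community detection with graph metrics, gradient
decomposition of seed-to-voxel connectivity profiles, and a spatially
constrained random-network null for correlating node metrics with volumetric
annotation maps such as PET receptor-density atlases. The worked context
throughout is the impulsivity network — 21 meta-analytically derived nodes
spanning delayed-consequence sensitivity (delay discounting) and response
inhibition task domains — whose coordinates ship with the package.

This vignette is the package's own account of each model, its assumptions,
the tunable parameters, the synthetic data used to validate it, and the
numerical choices made where the method leaves details open.

## 1. ALE meta-analysis

### Model

Each reported activation focus is a noisy observation of a true activation
location. The modelled-activation (MA) map of one experiment places an
isotropic 3D Gaussian at each focus whose standard deviation combines two
variance components,

$$\mathrm{sd}(n) \;=\; \sqrt{\sigma_{\mathrm{template}}^2 +
  \sigma_{\mathrm{subject}}^2 / n},$$

so experiments with more subjects (`n`) contribute spatially sharper
evidence. The defaults (`kernel_spec()`) correspond to the widely used
empirical calibration of between-template (FWHM 5.7 mm) and between-subject
(FWHM 11.6 mm, single subject) uncertainty; both are configurable because
the calibration is an empirical input, not part of the algorithm. Within an
experiment, per-focus kernels are combined by the voxel-wise **maximum**:
several nearby foci reported by one experiment represent one underlying
activation and must not inflate its evidence. Across experiments, the ALE
score is the union probability

$$\mathrm{ALE}(v) \;=\; 1 - \prod_i \bigl(1 - \mathrm{MA}_i(v)\bigr),$$

the probability that at least one experiment truly activates voxel $v$ under
independence.

Kernels are evaluated on the voxel lattice (foci snapped to the nearest
voxel centre), spherically truncated at 4 kernel standard deviations, and
normalised to unit discrete mass, so each focus deposits probability 1 on an
unmasked grid.

### The analytic null and its assumptions

Under the null of random spatial association, an experiment's MA value at a
voxel is an exchangeable draw from that experiment's MA histogram over the
mask. The exact null distribution of ALE is therefore the sequential
combination of the per-experiment histograms under the union rule,
re-binned at `bin_width` (default 1e-5). Two numerical details matter:

* the far tail (survival below `tail_floor`, default 1e-10) is folded into
  a single bin — survival values above the fold are exact, and p values
  below 1e-10 are never interpretable at realistic grid sizes anyway;
* p values for continuous observed scores interpolate the binned survival
  function linearly between bins. Snapping to the nearest atom instead
  biases tail p values by up to half a bin.

The null assumes spatial **stationarity**: every voxel shares the pooled MA
histogram. Voxels near the mask boundary violate this (fewer kernel
placements can reach them), so on masks that are small relative to the
kernel the voxel-level threshold is slightly anti-conservative. On a
30×36×30-voxel toy mask the measured false-positive fraction at p < 0.001
is ≈ 0.0011; at 50×60×50 (kernel radius ≈ 10 mm against ≈ 50 mm semi-axes,
the regime of a real MNI brain mask) it is ≈ 0.001. The calibration checks
therefore run in the large-mask regime; the boundary effect is a property
of the analytic ALE null itself, shared with the reference implementations.

### Cluster-level family-wise error

Voxels passing the cluster-inclusion threshold (default p < 0.001) are
grouped into connected components (26-neighbourhood by default; 6 and 18
available). The Monte-Carlo null of the maximum component size redraws every
experiment's foci uniformly within the mask — same focus counts, same sample
sizes, hence same kernels — recomputes ALE, applies the same voxel-level ALE
cutoff, and records the largest suprathreshold component. Observed clusters
survive iff larger than the `1 - p_cluster` empirical quantile (default
0.05); per-cluster p values use the add-one estimator $(b+1)/(n+1)$.
`n_iter` defaults to 1000; 200 iterations already resolve the 0.05 quantile
and are used in the validation suite.

## 2. Contrasts, conjunctions, subsampling

The contrast statistic is the voxel-wise difference of two groups' ALE
scores. Its null pools all experiments and redraws groups of the original
sizes (default 25,000 permutations; the validation suite uses 500, which
resolves p = 0.05 comfortably). p values use the add-one estimator, are
thresholded at 0.05, and surviving voxels must form components of at least
5 voxels. Two design choices:

* **Restriction mask.** Standard practice evaluates ALE contrasts inside
  the union of the two analyses' cluster-FWE-significant regions. The
  contrast function takes this region as an explicit `restrict_mask`
  argument rather than recomputing two cluster-FWE Monte Carlos internally;
  passing `NULL` evaluates the whole mask (used by the calibration checks).
* **Calibration regime.** At voxels covered by only a few experiments'
  kernels the permutation distribution is atomic (many relabellings yield
  identical differences), which makes the test conservative there. This is
  intrinsic to permutation tests on sparse corpora. The calibration check
  uses corpora dense enough (12 experiments × 10 foci on a small grid) that
  every voxel receives mass from many experiments and the statistic is
  effectively continuous; measured voxel-wise false-positive rate ≈ 0.05.

Conjunctions are the voxel-wise intersection of two thresholded maps with
the same ≥ 5-voxel extent filter. When one meta-analysis has many more
experiments than the other (the response-inhibition corpus is 96 vs 26),
`balanced_contrast()` repeats the contrast on random size-matched subsets of
the larger set (default 25 subsamples) and keeps voxels significant in at
least `agreement_fraction` (default 0.5) of them. The published record of
this subsampling procedure is in supplementary material that does not state
the counts; the defaults here are a reconstruction, exposed as arguments,
and should not be attributed to the original authors.

## 3. Node extraction

Peaks are local maxima (≥ all 26 neighbours; on a plateau the first voxel in
linear index order wins) of a thresholded z map within grey matter, selected
greedily in descending z with a minimum inter-peak distance of 15 mm. When
peaks from different maps (e.g. a conjunction and a contrast) fall within
15 mm, the higher-z peak is kept; z ties go to the earlier-listed map, then
lexicographic coordinate order — deterministic by construction. The bundled
node table (`inst/extdata/impulsivity_nodes.tsv`) contains the 21 nodes of
the impulsivity network in this Table-style schema
(region/hemisphere/x/y/z); note that the two ventral-striatum nodes are
√332 ≈ 18.2 mm apart and so both survive the 15 mm rule.

## 4. Functional connectivity

Subjects are excluded on mean framewise displacement (Power convention: sum
of absolute frame-to-frame differences of the six rigid-body parameters,
rotations converted to mm on a 50 mm sphere), with the boundary kept
(mean FD ≤ threshold). Denoising follows the listed order: confound
regression (white matter, CSF, global signal, with intercept; collinear
columns dropped with a warning), linear detrend, zero-phase band-pass
0.01–0.1 Hz (Butterworth order 2, forwards and backwards — the filter
family is a package choice, the band is the method's), then spatial Gaussian
smoothing at FWHM 5 mm.

Node time series average grey-matter voxels within **5 mm radius** spheres;
node-to-node FC is the per-subject Pearson correlation, Fisher
z-transformed with |r| clipped at 1 − 1e−7 (a guard for degenerate,
perfectly correlated series), then averaged element-wise across subjects.
The diagonal is set to 0: self-connections are undefined and all downstream
graph measures ignore them. Seed-to-voxel maps are per-subject correlations
between each node's sphere series and every grey-matter voxel, Fisher
z-transformed before group averaging.

Note an intentional asymmetry: annotation-map sampling (section 6) uses
**5 mm diameter** spheres (radius 2.5 mm). The two conventions mirror the
method's two phrasings for the two analysis stages; both radii are
arguments.

## 5. Communities, node roles, gradients

### Signed Louvain with fine-tuning

Community detection maximises modularity Q by the Louvain algorithm on the
modularity matrix. Group-averaged Fisher-z FC matrices contain negative
edges; the default treatment is the asymmetric signed extension, in which
positive weights carry full modularity weight and negative weights enter
with reduced weight $1/(s^+ + s^-)$ — negative edges should discourage, but
not dominate, co-assignment. A positive-only mode is available; the
original analysis fed signed matrices to a Louvain routine without stating
the option, so both are exposed. Resolution γ defaults to 1.

After one Louvain pass (greedy local moving plus community aggregation),
the algorithm is re-run with the current partition as initialisation until
Q stops increasing (tolerance 1e-10) — the fine-tuning loop. Because greedy
local moving is stochastic (node visiting order), the procedure is repeated
(default 1000 times) to build an **agreement matrix** — the fraction of runs
co-assigning each node pair — and the reported consensus is the **modal**
label-invariant solution with its frequency. The method's published record
reports the agreement matrix but not an explicit consensus rule; the modal
rule is this package's default (deterministic, reportable), with an
iterative agreement-matrix re-clustering option. On ≤ 10-node graphs the
implementation provably attains the exhaustive-search optimum (checked in
the test suite), and it matches igraph's independent Louvain on positive
graphs.

### Node roles

The participation coefficient $P_i = 1 - \sum_c (s_{ic}/s_i)^2$ (computed
on positive weights by default) measures between-community integration; the
within-module degree z-score standardises a node's within-community
strength over its community (sample sd; singleton or zero-spread modules
get z = 0 by documented convention).

### Gradients

The node-by-node similarity matrix correlates vectorised group-mean
seed-to-voxel maps. Each row is sparsified to its top `sparsity` fraction
of off-diagonal entries (default 0.20 — i.e. the top 20% of similarities
retained, as in the source analysis; 0.3 and 0.4 are exercised as
robustness settings), then decomposed by PCA (rows as observations) or by
diffusion-map embedding with anisotropic-diffusion parameter α (default
0.05, following the source analysis). Components are sign-aligned so the
first node's loading is non-negative — pure reporting stability, since
eigenvector signs are arbitrary.

## 6. Annotation (receptor-density) association

Annotation maps are resampled to the analysis grid by trilinear
interpolation (nearest-neighbour available for label maps), linearly
rescaled to min 0 / max 100 over the mask, and sampled at the nodes with
5 mm diameter spheres. Node metrics (P, z within) are screened against each
map by Spearman correlation in **two** datasets (discovery and
replication); a map passes at |ρ| > 0.3 in both with matching sign.
Survivors are tested against a spatial null: 1000 random 21-node sets
rejection-sampled from grey-matter voxel centres, accepted iff their
minimum, mean and maximum pairwise distances each fall within one standard
deviation of the empirical network's values. "One standard deviation" is
read as the SD of the empirical network's pairwise-distance distribution —
the natural scale available from the data; an explicit mm band is accepted
as an argument since the original definition is not recorded. Sampling at
voxel centres (not continuous mm) matches the mask's granularity; both
reconstructions are flagged in the function documentation.

The test is one-sided in the direction of the empirical correlation:
significant iff the empirical ρ exceeds the 95th percentile of the null
(mirrored for negative ρ), with add-one permutation p values.

## 7. Synthetic data: what it emulates, what it does not

The generators supply inputs with exactly the statistical structure each
stage assumes, so recovery of planted structure is a meaningful end-to-end
check:

* `gen_foci_corpus()` plants spatial convergence: each experiment hits each
  planted centre with probability 0.9, contributing 3 foci jittered at
  5 mm sd (the scale of ALE spatial uncertainty) plus 5 uniform noise foci,
  sample sizes uniform on 15–30 — a corpus of the shape and density of a
  moderate meta-analysis. Foci are rejection-sampled into the mask.
* `gen_bold()` plants block communities: node latent signals drawn from a
  block correlation matrix (positive semi-definiteness checked by
  eigendecomposition), sphere voxels carry their node's latent plus white
  noise, everything else is noise. The latent model is the simplest that
  achieves exact target block correlations. Motion traces are i.i.d.
  half-normal FD values so the exclusion filter is testable.
* `gen_annotation_map()` plants a rank coupling between node-sphere means
  and a node metric, with a construction loop that redraws until the
  achieved Spearman ρ is within 0.15 of the target.

None of these emulate haemodynamics, spatial autocorrelation of real BOLD,
scanner artefacts, or the anatomical covariance of real receptor maps.
Passing the validation suite therefore demonstrates that the inference
chain is correct and calibrated under its own model assumptions — not that
those assumptions hold in any particular empirical dataset.

## 8. Validation problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) uses sizes chosen so every check runs at meaningful
Monte-Carlo resolution on a single CPU:

* analytic-null accuracy: 5 experiments, 30×36×30 grid, 10⁶ oracle draws
  (agreement to < 0.005 everywhere);
* voxel calibration: 20 random-foci experiments × 200 replicates on
  50×60×50 (see section 1 for why the large mask);
* planted-cluster recovery: the generator's default corpus on 40×48×40,
  200 cFWE iterations, plus 20 plant-free seeds;
* contrast calibration: 10 replicate pairs of 12-experiment corpora × 500
  permutations;
* community recovery: 21 nodes / 4 planted blocks, within-r 0.5, between-r
  0.05, 300 timepoints × 3 subjects, 100 consensus repetitions, 20 seeds —
  the planted contrast is strong enough that recovery is exact (ARI 1),
  which is the point: failures would indicate implementation error, not
  statistical noise;
* receptor null: one 1000-network ensemble, 100 coupling-0 maps for
  calibration, 20 coupling-0.8 maps for power.

## 9. Known limitations

* Foci are snapped to voxel centres before kernel placement; sub-voxel
  kernel placement would change MA values by a fraction of a (2 mm) voxel.
* The analytic null's stationarity assumption makes voxel thresholds
  slightly anti-conservative on masks small relative to the kernel
  (section 1).
* The subsampling balancer and the distance-band definition of the random
  network null are reconstructions of procedures whose published record is
  incomplete; both are parameterised rather than hard-coded.
* The pipeline consumes registered, minimally preprocessed volumes;
  registration, distortion correction and surface processing are out of
  scope, as is any coordinate-space conversion (inputs are assumed MNI).
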