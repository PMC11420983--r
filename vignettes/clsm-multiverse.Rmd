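---
title: "The CLSM multiverse: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CLSM multiverse: models, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsmverse)
```

## The scientific problem

Connectome-based lesion-symptom mapping (CLSM) asks how disruption of
structural brain connectivity relates to behavioural deficits after stroke.
In practice the analyst faces a cascade of processing choices: whether
connectivity damage is measured *directly* from each patient's diffusion
imaging or *indirectly* by overlaying the lesion mask on a normative white
matter atlas; whether the network is the *whole brain* or a *language-related
subset* of parcels; and which of many *measures* is used — tract-level
summaries (lesion percentage, disconnection percentage, tract volume,
streamline count, mean FA/MD/AD/RD), parcel-pair streamline counts, or global
graph-theory statistics. A multiverse analysis runs all of these variants
jointly and reports the full pattern, so that the robustness (or fragility)
of any single-pipeline conclusion becomes visible.

`clsmverse` implements that multiverse as a tested pipeline: the geometric
kernels (voxel traversal of streamlines, endpoint-to-parcel assignment), the
tract and connectome measures, the graph-metric chain, and the statistical
engine (add-one ΔR² grids, rank-correlation similarity, sparse CCA with
cross-validation). A synthetic cohort generator with planted ground truth
makes every stage testable without imaging downloads.

## Coordinate and geometry conventions

* Voxel indices are 0-based; `world = affine %*% c(i, j, k, 1)` in
  millimetres, as in NIfTI headers. Streamlines are stored in world mm
  regardless of the on-disk dialect (TRK, TCK or a plain JSON-lines polyline
  format used as the human-readable test fixture).
* A point belongs to the voxel whose centre is nearest under a half-open
  rule: continuous voxel coordinate `v` maps to index `floor(v + 0.5)`, so a
  point exactly on a `+0.5` boundary belongs to the higher-index voxel. This
  removes boundary ambiguity from all overlap counts.
* `streamline_traversal()` computes the *exact* set of voxel cells a
  polyline intersects, by locating every parametric crossing of a voxel face
  and classifying interval midpoints (implemented in C++). A streamline is
  severed by a lesion iff its traversal contains at least one lesioned voxel
  — a binary pass criterion with no partial-volume weighting. Tests compare
  the traversal against two independent oracles: a dense point-sampling
  classifier (which can only miss corner-grazing cells, and must always be a
  subset) and an exact segment/box clipping oracle (which must agree
  exactly).

## Tract and connectome measures

For a tract `T` with voxel set `V(T)` and streamline set `S(T)`:

* lesion percentage `LP = 100 |V(T) ∩ lesion| / |V(T)|`;
* disconnection percentage `DP = 100 (severed streamlines) / |S(T)|`;
* tract volume `= |V(T)| ×` voxel volume; streamline count `SN`;
* mean FA/MD/AD/RD over `V(T)`.

Percentages are reported on a 0–100 scale throughout. Direct metrics of the
synthetic cohort are measured on the *post-lesion* bundle (severed
streamlines removed, mask recomputed), emulating per-participant
tractography; `build_metric_matrix(..., direct_on = "atlas")` switches to
the intact bundle. A tract whose streamlines are all severed is flagged
fully disconnected and its direct metrics are missing (never zero); all
downstream statistics are per-metric complete-case, so each metric keeps its
own N, and nested models are always compared on identical rows.

The DP denominator uses the atlas bundle's streamline count by default
(`dp_denominator = "participant"` is available); in the synthetic cohort the
two coincide because the participant bundle is exactly the surviving subset.

Parcel connectomes use the *end* criterion: a streamline contributes to edge
`(i, j)` iff its two endpoint voxels carry labels `i ≠ j`. The indirect
connectome counts atlas streamlines that avoid the lesion entirely. The
direct connectome optionally corrects counts for parcel distance and volume.
The correction formula is not standardized across toolchains, so it is an
explicit switch: `off`, `volume` (`w = count / sqrt(v_i v_j)`) or `full`
(`w = count · d_ij / sqrt(v_i v_j)`, centroid distance in mm, volumes in
voxels). `full` is the default because it removes the two dominant size
biases transparently; no fidelity to any particular tool is claimed.

## Graph metrics

All six global metrics run on the chain *normalize → length → distance*:
weights are divided by their maximum, lengths are inverse weights, and
distances are all-pairs shortest paths (Dijkstra per source). Then:

* characteristic path length: mean over *finite* off-diagonal distances.
  Lesioned indirect networks fragment, so unreachable pairs are excluded
  (and counted in the log) rather than propagating `Inf`;
* strength: mean nodal row sum;
* transitivity: `Σ (w_ij w_jk w_ki)^{1/3} / Σ k_i (k_i − 1)` with binary
  degrees `k`, in [0, 1] for normalized weights;
* modularity: `Q = Σ_c (e_c − γ a_c²)` maximized by multi-level greedy node
  moving (Louvain; engine from igraph), γ = 1, 20 seeded restarts, best Q
  kept. Restarts make the stochastic optimizer reproducible and near-exact:
  on random graphs with ≤ 8 nodes it attains the exhaustive-partition
  maximum in ≥ 95% of cases;
* rich club: for each degree level `k`, total weight among nodes with binary
  degree > k divided by the sum of the same number of largest weights
  anywhere in the graph; averaged over all defined levels. The degree levels
  to average over are a genuinely open choice; averaging over every level
  with a surviving edge is the least arbitrary option;
* small-worldness: the σ ratio `(C/⟨C₀⟩)/(CPL/⟨CPL₀⟩)` against 100 null
  networks that preserve the binary degree sequence (edge rewiring) with the
  observed weights shuffled onto the rewired topology. "Small-world
  propensity" in the Muldoon sense is a different estimator; the σ ratio was
  chosen because it needs no lattice reference construction on weighted
  graphs, and the choice is surfaced here rather than hidden.

Every metric is invariant to positive rescaling of the weights (the
normalization absorbs it) and to node permutation; both properties are
tested. Undefined metrics (empty graphs, no surviving rich-club level, zero
null clustering) are reported as `NA`, never silently dropped.

## The statistical engine

**Similarity.** Tract-measure agreement uses Kendall's τ-b (tie-corrected;
an O(n log n) implementation because whole-brain vectors have 13 695 edges),
with pairwise-complete observations. Direct-vs-indirect connectome
similarity is τ-b over the vectorized upper triangle per participant, and
the two network scales are compared with a two-sided paired t-test across
participants. Pearson correlations are available via `method = "pearson"`
where a linear-scale view is wanted.

**Add-one ΔR² grid.** The base model is OLS:
`score ~ lesion_volume + scanner` (dummy-coded, reference level). Each
metric is added singly; the cell records `ΔR² = R²_full − R²_base` on the
metric's complete rows and the F-test p-value of the added term (the
standard nested-model test; its p equals the added coefficient's t-test
p-value, which is verified numerically). No familywise correction is
applied — the object of interest is the *pattern* of cells, not any single
association. Cells are classed significant (p < 0.05), marginal
(0.05 ≤ p < 0.1) or ns.

**Sparse CCA.** Connectome edges are high-dimensional (91 or 13 695 columns
for 50 rows), so the edge–behaviour association uses a sparse canonical
vector on the edge side against the residualized outcome (lesion volume and
scanner regressed out). With a univariate behavioural side the unpenalized
canonical direction is the least-squares solution; the sparse direction
soft-thresholds it to an L1 budget `1 + sparsity·(√p − 1)` and renormalizes
to unit L2 norm (`sparsity = 1` recovers least squares exactly, small values
give few active edges; the default 0.1 keeps between a handful and ~20% of
edges active, depending on the correlation structure of the edge matrix).
Internal sparseness optimization as done by some neuroimaging toolboxes is
deliberately not emulated — the sparsity is an explicit argument. Fit is
judged by 4-fold cross-validation with seeded fold assignment; test-fold
predictions are pooled into a single observed-vs-predicted correlation
(pooling is stabler than averaging per-fold r at n = 50/4; a per-fold
variant would be a trivial change), tested one-sided because only positive
predictive correlation is evidence of fit. Under the null this test rejects
at close to the nominal 5% rate, which the acceptance suite verifies with
200 null replicates.

## The synthetic cohort generator

The generator emulates a chronic left-hemisphere stroke aphasia study at
desk scale. Its defaults are the study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| participants | 50 | typical CLSM sample |
| scanner levels | 3, sampled 25/18/7 | three acquisition protocols |
| grid | 64³ voxels at 2 mm | ~900 cc brain ellipsoid |
| parcels | 166, spheres on a jittered lattice | whole-brain parcellation scale |
| language subset | 14 parcels nearest the peri-sylvian zone | ROI-scale analyses |
| tracts | AF, FAT, SLF3, ILF, IFOF, UF; 50 streamlines each | six language bundles |
| background streamlines | 1200, distance-decaying pairs | whole-brain tractogram |
| lesion volume | lognormal, mean 91 cc, SD 65, truncated 2–263 cc | stroke volumetrics |
| naming score | mean 34, max 60; slope −0.185/cc, noise SD 15 | r(lesion, naming) ≈ −0.5…−0.6 |
| Token score | mean 24, max 45; slope −0.13/cc, noise SD 9.5 | r ≈ −0.5…−0.6 |
| FA / MD / AD / RD | 0.45 / 8e-4 / 1.2e-3 / 6e-4, lesion factors 0.45 / 1.8 / 1.15 / 2.0 | FA drops, diffusivities rise in lesions |

Lesions are unions of overlapping spheres centred near the language zone
(centre SD 22 mm), clipped to the brain ellipsoid; the sphere-volume factor
0.9 compensates the expected clipping loss so realized volumes track the
target distribution. Lesions are *not* anatomically realistic — only the
overlap/severance topology matters to the methods under test. Bundles arch
away from the brain centre by a per-tract random factor, so severance rates
vary across tracts; because bundles are compact corridors and lesions are
large, disconnection percentages come out strongly bimodal (most mass near
0 or 100), and complete disconnection — hence missing direct metrics —
occurs at rates comparable to the harder-to-track tracts of real cohorts
(roughly a third of tract-participant cells; real studies report up to
~half for the worst tract). Scores are rounded and clipped to the test
ranges; the generator warns when more than 10% of scores clip.

The simulated *direct* connectome is a negative-binomial-like model around
the lesion-filtered atlas counts: per-edge lognormal variability (SD 0.8)
for anatomy and tracking, plus a distance-decaying Poisson background
(`direct_bg = 3` at zero distance, 30 mm decay) because probabilistic
tractography yields dense connectomes with spurious connections. These two
parameters control how weakly direct and indirect connectomes agree; the
defaults land the per-participant τ in the weak range, reproducing the
method's headline phenomenon without being tuned to any printed value.

**Planted effects.** An effect spec adds `c·z` to one outcome, where `z` is
the standardized residual of the target metric after the base covariates and
`c = sd_noise · √(pr²/(1−pr²))` delivers a chosen partial R². Because
clipped scores are insensitive to the effect, the coefficient is scaled by
`1/√(1 − clip fraction)` so the *delivered* partial R² matches its target —
the generator's contract is the effect size in the data as analysed.
`resample_behavior()` redraws behaviour (and the planted effect) on a fixed
imaging cohort, which is what makes 500-replicate power and 2000-cell
calibration loops affordable: the imaging stage is simulated once, the
behavioural stage per replicate.

**Determinism.** Every generator is a pure function of (spec, seed);
sub-stages derive their seeds from the cohort seed, and seeded metrics
(modularity, small-world nulls, CV folds) save and restore the caller's RNG
state.

## What passing tests do and do not show

The cohort exercises the pipeline's geometry, missingness handling,
calibration and power behaviour under known ground truth. It does not
emulate registration error, scanner-specific noise physics, anatomically
shaped lesions, crossing-fibre tractography failures, or pre-stroke
individual anatomy; conclusions about how *real* direct and indirect
measures diverge cannot be read off the synthetic defaults. The quantities
the paper-scale dataset determines empirically (e.g. the exact median τ
between real direct and indirect connectomes) are not reproducible from
synthetic data and are not claimed.

## Problem sizes used by tests and the acceptance script

Unit and property tests run on a reduced cohort (n = 10, 32³ grid, 24
parcels, 12 streamlines per bundle) chosen so the full suite stays fast;
the acceptance checks that concern cohort-level behaviour (calibration,
power, phenomena) run at the study scale (n = 50, 166 parcels). The
acceptance script runs the complete pipeline at study scale with the
default 100-network null ensemble and 20 modularity restarts.
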