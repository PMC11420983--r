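# clsmverse

Multiverse analysis of connectome-based lesion-symptom mapping (CLSM).

After a stroke, behavioural deficits can be related not only to the damaged
grey matter but to the disruption of white matter connections. CLSM
quantifies that disruption — but it can be done in many ways: damage can be
measured **directly** from each patient's diffusion imaging or **indirectly**
by overlaying the lesion mask on a normative tract atlas; the network can be
the **whole brain** or a **language-related subset** of parcels; and the
measure can be tract-based (lesion percentage LP, disconnection percentage
DP, tract volume, streamline count, mean FA/MD/AD/RD), parcel-based
(streamline-count connectomes) or network-based (graph-theory metrics).
`clsmverse` implements the whole grid of these choices as one tested
pipeline, so the *pattern* of results across pipelines — the multiverse —
can be computed and inspected. It is aimed at lesion-symptom-mapping
methodologists and at anyone who needs a ground-truth testbed for
disconnection measures.

## What it computes

For a tract `T` with voxel set `V(T)` and streamline set `S(T)`, lesion `L`:

- `LP = 100·|V(T) ∩ V(L)| / |V(T)|`, `DP = 100·|{s ∈ S(T): s crosses L}| / |S(T)|`,
  volume `|V(T)|·v_mm³`, streamline count, and mean FA/MD/AD/RD over `V(T)`.
  A streamline crosses the lesion iff its exact voxel traversal (computed by
  an analytic grid-crossing kernel in C++) contains a lesioned voxel.
- Parcel connectomes `w_ij` = streamline counts between parcels under the
  endpoint criterion, either preserved counts after lesion filtering
  (indirect) or tractography counts with optional distance/volume correction
  `w_ij = n_ij·d_ij/√(v_i v_j)` (direct); whole-brain (166 parcels, 13 695
  edges) and language subset (14 parcels, 91 edges).
- Six global graph metrics on the chain *normalize → inverse-weight length →
  shortest-path distance*: characteristic path length, mean strength,
  weighted transitivity, modularity `Q = Σ_c (e_c − γ a_c²)` (Louvain with
  iterated-local-search refinement), mean weighted rich-club coefficient,
  and small-worldness `σ = (C/⟨C₀⟩)/(CPL/⟨CPL₀⟩)` against degree-preserving
  null networks.
- The statistical multiverse: Kendall τ-b similarity of measures and
  connectomes; add-one OLS grids `score ~ lesion volume + scanner (+ metric)`
  with ΔR² and the F-test of the added term, classed at p < 0.05 / < 0.1;
  and sparse CCA of connectome edges against residualized behaviour with
  4-fold cross-validation.
- A synthetic stroke cohort generator (`cohort_spec()` / `make_cohort()`)
  with planted ground truth: lesions 2–263 cc near a language zone, naming
  and Token scores negatively correlated with lesion volume, bimodal DP,
  complete-disconnection missingness, and an optional planted metric effect
  with a configurable partial R².

## Worked example

```r
library(clsmverse)

spec   <- cohort_spec(seed = 1)          # n = 50, 166 parcels, 6 tracts
cohort <- make_cohort(spec)
p      <- cohort$participants

cor(p$lesion_cc, p$naming)
#> [1] -0.4581782

# tract-based multiverse: 6 tracts x 8 measures x 2 outcomes = 96 cells
cells <- multiverse_grid(cohort$metrics, p)
table(cells$class)
#>
#>    marginal          ns significant
#>           3          86           7

subset(cells, outcome == "naming" & class == "significant")
#>    outcome  metric  n  delta_r2     p_value       class
#> 12  naming  FAT_MD 34 0.1380292 0.025028368 significant
#> 35  naming IFOF_FA 33 0.1986221 0.007962545 significant
#> 41  naming  UF_VOL 41 0.1339960 0.014808919 significant
#> 42  naming   UF_SN 41 0.1283516 0.017279735 significant
```

This cohort is null (no planted effect), so the seven "significant" cells
of 96 are the false-positive pattern an uncorrected multiverse displays by
design — the point of the method is to read the pattern, not any single
cell (note also the per-metric N: direct metrics of fully disconnected
tracts are missing, shrinking some cells to n ≈ 33–41). Direct-vs-indirect
similarity per participant:

```r
conns <- lapply(1:50, function(i) participant_connectomes(cohort, i))
connectome_similarity(conns, ids = p$id)$summary
#>   scale n_edges    median       min       max
#> 1 whole   13695 0.2255060 0.1563749 0.2619559
#> 2   roi      91 0.3357077 0.1089863 0.4976515
```

Weak agreement (τ ≈ 0.2–0.3) between the two imaging approaches at both
network scales — the central methodological caution the multiverse makes
visible.

The numbered scripts under `analysis/` run the full sequence (cohort →
tract similarity → connectomes → multiverse grids → sparse CCA) and write
tidy tables under `results/`.

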