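---
title: "Discriminating cartilage state from multiplex secretome responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating cartilage state from multiplex secretome responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartstate)
```

## The problem

An ex vivo model of osteoarthritic cartilage degradation compares how
healthy and enzymatically degraded (collagenase-II-treated) cartilage
explants respond to a broad panel of protein stimulations. Each explant is
stimulated with one of 55 perturbations — 13 single cytokines/growth
factors, or one of the 6 × 7 cross-group pairs formed from a
pro-inflammatory/catabolic group and an anti-inflammatory/anabolic group —
and the proteins it releases into the supernatant are measured with a
26-plex bead-array (xMAP) immunoassay as median fluorescence intensities
(MFIs). `cartstate` implements the full analysis chain on such plates:
preprocessing to a normalized response matrix, effect-size ranking of
baseline releases, unsupervised state assignment, supervised discriminant
projections, and an exhaustive search for the protein *pair* whose joint
response best separates the two tissue states.

## Preprocessing model

Raw wells go through four steps, per plate and tissue state:

1. **Blank filtering.** Duplicate reagent-only blanks define a per-protein
   background (their arithmetic mean, per plate). Measurements strictly
   below it carry no signal above experimental noise and are set to
   missing.
2. **Self-channel masking.** A well stimulated with a recombinant protein
   rails at the saturation ceiling on that protein's own channel, because a
   sandwich assay cannot distinguish the spiked-in stimulus from tissue
   release. The self-channel(s) — both members for pair stimuli — are set
   to missing.
3. **Nearest-neighbour imputation** on the raw MFIs. A missing entry
   (well, protein) is replaced by the mean of that protein over the `k`
   nearest wells that observe it (`k = 1` by default, the classical
   single-neighbour rule). Row distance is Euclidean over mutually observed
   coordinates, rescaled by `sqrt(n_total / n_observed)` so rows with
   different missingness patterns are comparable, with ties broken by row
   order — all deterministic and therefore testable against a brute-force
   oracle. Imputation precedes normalization so the bounded transform below
   always sees positive MFIs; the reverse order would impute already-bounded
   values and could not restore a meaningful raw scale.
4. **Normalized difference.** Every stimulated well is compared with the
   plate's unstimulated control well: `D = (F - F_c) / (F + F_c)`. `D` is 0
   when stimulation changes nothing, approaches +1 (−1) when the stimulated
   signal dwarfs (vanishes against) the control, and is bounded in
   [−1, +1], making responses comparable across proteins and plates with
   very different dynamic ranges.

Per-protein replicate precision is summarised by `assay_cv()` (sample
sd/mean across matched wells, n−1 denominator); proteins at or above 25%
CV are flagged as failing the usual bead-array precision expectation.

## Baseline effect sizes

`rank_baseline_releases()` compares raw (not normalized) MFIs between a
treated and a control group per protein: an unpaired two-sided Student
t-test (pooled variance, consistent with the pooled-sd effect size; Welch
is available via `var_equal = FALSE`) and Cohen's
`d = (m_treated − m_control) / s_pooled`, so positive `d` means more
release in treated tissue. Proteins with `p < 0.05` (raw p-values by
default — no multiplicity correction, mirroring common practice in small
screening experiments; Benjamini–Hochberg is available via `adjust`) are
retained and sorted by decreasing `d`.

## Unsupervised state assignment

`state_pca()` performs covariance PCA (column-mean-centered, no
unit-variance scaling: all inputs already share the bounded [−1, 1] scale,
and rescaling would inflate the influence of unresponsive proteins).
Component signs follow a fixed convention — the largest-magnitude loading
of each component is positive — so loading reports are reproducible.
`cluster_states()` runs k-means with `k = 2` on the first four components
(50 restarts, seedable) and maps clusters to tissue states by the majority
of true labels within each cluster; an exact tie is an error rather than an
arbitrary choice. The confusion counts quantify how often unsupervised
structure alone recovers the tissue state. `pc1_loading_report()` ranks
proteins by their first-component loading and states which tissue state an
increasing score moves a response toward.

## Supervised projections (OOS-DA)

`fit_oosda()` builds an optimal orthonormal system for discriminant
analysis: sequential linear projections, each maximising Fisher's
separation criterion `w'S_b w / w'S_w w`, each constrained to the
orthogonal complement of the previous directions. The deflation is done by
solving the generalized symmetric eigenproblem restricted to an explicit
orthonormal basis of the complement, which guarantees `W'W = I` to machine
precision instead of relying on re-orthogonalisation. Conventions: the
within-class scatter weights each class by `1/N_k` and the between-class
scatter uses the unweighted mean of class means (`1/K`), matching the
separation score below; `S_w` carries a relative ridge
(`ridge * trace(S_w)/d`, default `1e-8`) so the criterion stays defined
when samples are fewer than features. For two classes the first direction
coincides with the closed-form Fisher discriminant `S_w^{-1}(m_1 − m_2)`,
which the test suite uses as an independent oracle.

## Exhaustive pair search

The separation score of a feature subset is `J = s_b / s_w` with

- `s_w = Σ_k (1/N_k) Σ_{n∈k} ||x_n − m_k||²` (within-class spread),
- `s_b = (1/K) Σ_k ||m_k − m||²`, `m` the unweighted mean of class means.

`exhaustive_pair_search()` scores all `p(p−1)/2` protein pairs — 325 for
the 26-plex panel — on their two-column submatrices. To temper the
dependence on any particular stimulus set, each pair's reported score is
the **maximum** of `J` over 100 random subsets containing 80% of the
stimuli. Two details matter:

- **Paired subsampling.** A stimulus is kept or dropped in both tissue
  states together: stimuli are the experimental unit shared by the two
  class blocks, so unpaired subsampling would compare responses to
  different perturbation sets.
- **Shared subsets.** All 325 pairs are scored on the same subset sequence
  (drawn once from the seed), so scores are directly comparable and a
  per-pair `resampled_score()` call with the same seed reproduces them
  bit for bit.

The maximum over resamples is kept as the default because it is the
method as published; it is anti-conservative (a maximum grows with the
number of resamples), and `summary = "median"` or `"min"` are provided as
more conservative alternatives. Degenerate subsets (`s_w = 0`) are skipped,
not zero-filled. Ties in the ranking break lexicographically by pair name.
The top pair's 2-D linear decision boundary is the Fisher direction
`(S_w + ridge I)^{-1}(m_1 − m_2)` with the offset at the midpoint of the
projected class means.

## The synthetic plate generator

Because raw plates for this kind of experiment are rarely deposited, the
package ships a generator (`simulate_plate()`) whose draws have the
statistical structure the analysis assumes:

- **Lognormal multiplicative noise**, parameterised by the median and a
  natural-scale CV (default 0.15, the middle of the 10–25% range typical
  of bead arrays): MFIs are positive and right-skewed.
- **Baselines** log-uniform over 500–20000 MFI, a **blank level** of 50
  MFI, and a **saturation ceiling** of 32000 MFI with hard clipping; these
  are configuration values representing a plausible instrument window, not
  claims about any particular assay.
- **Duplicate blanks** and one unstimulated control per plate, mirroring
  the plate layout the preprocessing expects.
- **Self-channel saturation** applied after noise: a well's own stimulating
  protein(s) rail at the ceiling.
- **Response structure**: `default_generator_config()` adds a low-rank
  latent model (three latent programmes) plus independent
  per-(stimulus, protein) heterogeneity shared by both states — this is
  what gives simulated response matrices a few dominant principal
  components, as real secretome panels show — and an optional per-protein
  modulation of the degrading state's responses so the states differ along
  a diffuse direction, not only in a planted pair.
- **Plantable discriminative pair**: `plant_discriminative_pair()` gives
  two proteins opposite, state-antisymmetric response shifts (factor
  `2^shift` in healthy, `2^-shift` in degrading tissue), emulating the
  joint pattern where one protein's stimulated release rises in healthy and
  falls in degrading tissue while its partner does the reverse.
- `simulate_baseline_release()` plants per-protein standardized mean
  differences for the effect-size stage; the treated median factor is
  calibrated by fixed-point iteration so the *expected pooled Cohen's d on
  the raw scale* equals the requested value despite the sd scaling with
  the mean.

What the generator does **not** emulate: bead-level fluorescence
distributions and bead counts, standard-curve (5PL) calibration,
plate-position effects, cross-reactivity between antibodies, and
biological correlation between a stimulus's identity and which proteins it
induces. Passing tests therefore demonstrate that the analysis chain is
correct and recovers structure it is designed for — not that real cartilage
data will be as well behaved.

## Recovery experiments and their problem sizes

The test suite and `scripts/acceptance.R` rerun the full chain on
generated data:

- **Planted-pair recovery**: 100 runs of two 55-stimulus plates (one per
  state, cv 0.15) with a single planted pair (shift ±1.5 log2, a gap of
  several within-class sds after normalization) as the only state
  difference; the exhaustive search must rank the planted pair first in at
  least 95 runs. With the configuration above it does so in all 100.
- **Effect-size recovery**: 11 planted baseline shifts among 26 proteins at
  magnitudes between |d| = 1.3 and 5.7, n = 3 control vs 6 treated wells.
  At these sample sizes the weakest planted effects have two-sided t-test
  power of only ~0.35, so the probability that a single run retains all 11
  is a few percent — the corresponding strict acceptance check fails by
  design of the statistics, and the suite documents the measured rate
  rather than weakening the criterion. With large planted shifts (d ≈ 6)
  the same procedure recovers the planted set almost always, which is what
  the unit test asserts. Under the null, per-protein false retention sits
  at the nominal 5%.
- **Unsupervised assignment**: on demo data with a planted pair plus
  diffuse state modulation, k-means on four components typically assigns
  all responses correctly; with exchangeable states it mixes them at
  chance, often up to an exact majority tie (which the mapping reports as
  an error rather than resolving arbitrarily).

## Known limitations

- The separation score sums per-protein spreads without per-feature
  normalization, so a pair's `J` can be raised by swapping a genuinely
  discriminative but high-variance partner for a "quiet" low-variance
  protein with a small incidental gap. When per-protein within-class
  spreads are very heterogeneous, the top-ranked pair should be read
  together with its neighbours in the ranking, not as a unique answer.
- The max-over-resamples score is anti-conservative; use the median/min
  summaries for a stability-selection-style reading.
- With a single control well per plate, control-well noise shifts all
  normalized differences of that plate and protein coherently; this is a
  real design property of such experiments and is visible in the generator
  as small spurious between-state gaps for unresponsive proteins.
- k-means with two centers on leading components is a coarse state model;
  it is kept because it is the reference workflow, not because it is
  optimal — the supervised stages exist precisely because it misassigns
  borderline responses.

## A worked run

```{r demo, eval = FALSE}
run <- run_pipeline(seed = 1)
run
glance(run$pca)
glance(run$clusters)
head(tidy(run$pairs), 5)
autoplot(run$pairs)
```
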