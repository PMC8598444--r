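---
title: "Methods: the HTA index, its null model and its p-values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the HTA index, its null model and its p-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hta)
```

## The model

The package analyses a *trait-combination matrix*: a dense 2D or 3D
lattice in which each position either manifests exactly one non-empty
subset of `t` binary traits (its "combination", one of `C` labels) or is
empty ("None") — because no spot was measured there or because no trait
was called present.  In spatial transcriptomics the traits are genes
dichotomised at their median expression across spots; in imaging they can
be thresholded signal channels; the statistic itself is agnostic to the
origin of the labels.

Heterogeneity is measured at two levels.  Within a region, the
HeTerogeneity Index is base-`C` Shannon entropy of the combination
proportions among occupied positions, `HTI = -Σ p_c log_C p_c`, which the
log base confines to `[0, 1]`.  Across a grid partition, the
HeTerogeneity Average weights each retained (non-empty) region's HTI by
its share of occupied positions: `HTA = Σ_r (n_r/n) HTI(M_r)`.  A single
whole-matrix region makes HTA the global HTI; refining the grid can only
decrease HTA (conditioning never increases entropy), which gives a known
ordering when scanning region sizes.

### Assumptions

* Spot coordinates are integer lattice indices; the package anchors them
  at the per-axis minimum.  No hexagonal-to-square re-gridding of
  platform-specific spot geometry is attempted: a spot table with hex
  offsets will be treated as the integer lattice it literally encodes.
* Trait calls are binary and fixed before analysis; the statistic does
  not model measurement noise in the underlying continuous values.
* Inference treats region HTIs as independent under the null; the
  residual dependence induced by permuting without replacement across
  regions is ignored (it vanishes as the number of regions grows).

## Parameters that matter

* **`region_size`** (positions per axis; the single substantive
  parameter).  Scalars broadcast to all axes; anisotropic sizes such as
  `c(8, 8, 1)` versus `c(8, 8, 3)` let 3D analyses treat z-slices
  separately or jointly.  Because HTA is monotone under refinement, users
  should read results across sizes as a profile, not pick one post hoc.
* **`c_mode`** (`"observed"`, default, or `"full"`): whether the entropy
  log base counts the combinations actually present or all `2^t − 1`
  subsets.  `"observed"` makes the deterministic balanced construction
  attain HTA = 1 exactly and is self-calibrating for sparse trait sets;
  `"full"` fixes the scale across samples with different combination
  censuses (7 traits ⇒ `C = 127`).  Both are exposed; the choice changes
  the scale of HTA but not the permutation p-values' validity.
* **`threshold`** (`"median"` default): a trait is present where its
  value is *strictly greater* than the per-trait median.  Values tied at
  the median are called absent — the literal reading of
  "above the median" — and the rule is deliberately rank-based, so any
  strictly monotone transform of a trait column leaves the calls
  unchanged.  A fixed numeric threshold can be substituted.
* **`n_permutations`** (default 1000): Monte-Carlo precision of the
  per-region null moments.  100 permutations already reproduce p-values
  to within an order of magnitude on strongly structured maps (see the
  robustness discussion below).
* **`seed`**: one integer seed drives all permutations through a single
  serial RNG stream; every result object records it.

## The null model and p-values

The null hypothesis is that the observed trait combinations carry no
spatial organisation: labels are rearranged uniformly at random over the
occupied positions, preserving the label multiset and the occupancy mask
exactly.  Permuting *combinations* rather than individual traits keeps
the sample's combination census intact — a tissue expressing only one
co-expression pattern should not sprout subsets it never exhibited.

Because occupancies `n_r` differ across regions, the per-region HTIs are
independent but not identically distributed under this null, so the
package uses the Lyapunov CLT on the weighted sum: with per-region null
moments `(μ_r, σ_r)`,

```
z = (HTA − Σ w_r μ_r) / sqrt(Σ w_r² σ_r²),   w_r = n_r / n .
```

The weights are constants of the test (the mask never changes), which is
what licenses applying them to the moments of the per-region HTIs.  The
lower tail `P(Z ≤ z)` tests homogeneity, the upper tail heterogeneity,
and the overall significance doubles the smaller tail (capped at 1).
Both one-sided values are always reported alongside the doubled one.

`μ_r, σ_r` are estimated from `n_permutations` permutations (population
standard deviation; at 1000 draws the sample/population distinction is
far below Monte-Carlo noise).  Single-entry regions have HTI identically
0, hence moments (0, 0); they are retained in HTA but counted and
surfaced in the result (`n_single_entry_regions`) because an unbounded
proportion of them would undermine the CLT argument.  A warning is
emitted for `R < 30` regions; results are still returned, since the
approximation degrades gradually and the empirical calibration below
already holds at `R = 16`.

### Exact moments for small regions

For small regions the null distribution of HTI is computed exactly under
the generative per-cell model: each of `t` traits independently present
with probability ½, i.e. each cell uniform over all `2^t` states
including the empty one; empty cells are excluded from the counts, empty
regions are discarded (moments are conditioned on at least one occupied
cell), and the log base is `C = 2^t − 1`.  The implementation enumerates
per-state count vectors weighted by their multinomial probabilities,
which visits every one of the `(2^t)^cells` equally likely configurations
exactly once while evaluating only `choose(cells + 2^t − 1, 2^t − 1)`
distinct entropies; a guard (~10⁷ configurations) routes larger problems
to the permutation path.  For two traits this yields region-HTI nulls of
mean 0.57, sd 0.31 (2×2 regions) and mean 0.83, sd 0.17 (3×3 regions);
the test suite pins both against an independent brute-force enumeration
and a Monte-Carlo cross-check.

### Numerical choices and degenerate inputs

* Entropy terms with `p_c = 0` contribute 0; `C = 1` or a single
  occupied entry give HTI = 0 by definition, not by limit evaluation.
* An all-`NA` matrix, all-zero counts, or `C` smaller than the number of
  combinations present are input errors; a single observed label makes
  the null variance zero and p-values are refused rather than returned
  as 0/1.
* Tail probabilities are computed with `pnorm(..., lower.tail = FALSE)`
  on the appropriate side, so p-values of order 10⁻³⁰⁰ remain accurate.
* Ragged trailing regions (shape not divisible by the region size) are
  retained — discarding measured entries would bias `n`; only all-empty
  regions are dropped.  Oversized region extents clamp to one region per
  axis with a warning.
* Nearest-neighbour resizing uses the pixel-centre mapping
  `src = floor((i + 0.5) · n_in / n_out)`, guaranteeing label-set
  closure; it is applied to label maps as a whole, not per-trait.

## What the generators emulate — and what they do not

The synthetic generators reproduce the canonical study conditions used
throughout the package's tests: `random_uniform_map` (each trait present
with probability 0.5 per position — the null, and exactly the per-cell
model of the exact-moment path), `region_homogeneous_map` /
`region_heterogeneous_map` (deterministic constructions pinning the HTA
bounds 0 and 1 at a 32×32 / region-8 geometry, using two mutually
exclusive traits so 64-cell regions can be balanced exactly), and
`layered_z_map` (a (32, 32, 3) volume whose z-layers carry distinct
combinations, separating region sizes `(8, 8, 1)` and `(8, 8, 3)`).
The balanced construction cycles labels deterministically within each
region; HTA depends only on counts, so the arrangement is immaterial.

These maps lack several features of real data: spatial autocorrelation
of expression noise, platform spot geometry, tissue boundaries and
irregular occupancy masks, and correlated traits.  Passing tests
therefore validate the statistic and its null machinery, not the
biological preprocessing; on real data the median threshold and the
integer-lattice assumption are the places to scrutinise.

## Simulation study sizes

The suite's calibration study uses 200 independent null maps (32×32, two
traits, presence probability 0.5) at region size 8 with 1000
permutations each, checking the overall p-value's rejection rate at
α = 0.05 against a 3-standard-error binomial band; a pre-registered pilot
at 300 maps gave empirical rates 0.047 (region 8) and 0.053 (region 2).
Refinement monotonicity is property-checked on 100 fully occupied random
maps across nested region sizes 2 | 8 | 16.  These sizes make the whole
suite run in well under a minute while keeping binomial tolerances
meaningful.

## Design choices where the design was open

* **Log base of the regional entropy.**  The weighted-average definition
  is used with base `C` throughout; this is what keeps HTA in `[0, 1]`
  and reproduces the exact null moments above.
* **Heterogeneity tails are compressed at coarse grids.**  A perfectly
  balanced map has HTA = 1, but a random permutation of a balanced label
  multiset over 64-cell regions already achieves near-maximal entropy
  (null mean ≈ 0.989, sd ≈ 0.004 at C = 2), so the largest attainable
  z is only ≈ 3 and the sharpest possible one-sided heterogeneity
  p-value at region size 8 is ~10⁻³.  Significant-heterogeneity claims
  are therefore asserted at the construction's finest balanced grid
  (region size 2, where z ≈ 90 and p underflows), and users scanning
  region sizes should expect heterogeneity significance to sharpen as
  grids refine.  The homogeneity tail has no such compression.
* **Robustness fixture.**  The 100-vs-1000-permutation comparison uses a
  region-pure map with 85% of entries reshuffled (overall p ≈ 4·10⁻⁷).
  At far more extreme significance the comparison stops being
  informative about permutation count: `log10 p` scales with `z²`, so
  percent-level Monte-Carlo noise in the variance estimate moves
  extremely small p-values by several orders of magnitude regardless of
  how many permutations either side uses.
* **Moment weighting.**  Per-region HTI moments are combined with the
  fixed weights (`Σ w_r μ_r`, `Σ w_r² σ_r²`); subtracting unweighted
  region means would be dimensionally inconsistent with the weighted
  statistic.
* **RNG.**  All permutations of one moment estimate come from a single
  serial stream seeded once; runs are exactly reproducible given the
  seed.  (Per-permutation counter-derived streams would enable
  parallelism, but serial estimation already takes ~0.1 s per thousand
  permutations on a 32×32 map, so the simpler scheme wins.)
* **`observed` as the default `C`.**  It is the only convention under
  which the deterministic balanced construction attains HTA = 1 exactly,
  and it avoids an arbitrary dependence of the scale on traits that
  never co-occur.

## Known limitations

* The normal approximation needs a reasonable number of regions; below
  ~30 the package warns.  No empirical (rank-based) permutation p-value
  is offered as primary output, though `simulate()` on a fitted test
  exposes the null HTA draws for cross-checking.
* The trait-combination representation scales as `2^t`; beyond a dozen
  traits, aggregate meta-traits before encoding.
* No automatic region-size selection and no cross-scale summary
  statistic; results should be read as a profile over region sizes.
* The permutation null is global; locality-preserving nulls (permuting
  within neighbourhoods) are out of scope.
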