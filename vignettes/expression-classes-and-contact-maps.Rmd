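---
title: "Expression classes, cluster composition and contact maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression classes, cluster composition and contact maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbscape)
```

`limbscape` analyses how the deletion of a single enhancer redistributes
a developmental gene's expression across limb-bud cell populations. This
vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
underlying analysis left the design open.

## Three-class expression calling

Per-cell counts are normalized as `v = ln(1 + count/total * scale)`.
The scale factor defaults to 10,000 counts per cell — the documented
default of the standard single-cell toolkits — and is an argument of
`log_normalize()`. Cells are assigned to three classes:

| class | rule | interpretation |
|---|---|---|
| non/low | `v <= 0.3` | locus effectively inactive |
| intermediate | `0.3 < v <= 1.45` | distal-type moderate expression |
| high | `v > 1.45` | proximal-type strong expression |

Both boundaries belong to the **lower** class. The figure-legend
convention (`<=`) is used rather than the strict `<` that sometimes
appears in prose descriptions of such analyses; on real data the
difference affects only cells sitting exactly on a threshold.

The thresholds ship frozen in `expression_thresholds()` because they are
the operative definition of the classes: re-deriving them from data makes
classification depend on KDE settings. Re-derivation is available as an
explicit mode: `estimate_density()` on each population, then
`find_intersection()` over a search window.

### Density estimation and intersection

`estimate_density()` evaluates the exact Gaussian kernel sum
`f(g) = (1/(n*bw)) * sum_i dnorm((g - v_i)/bw)` at every point of an even
grid spanning `[min - 3 bw, max + 3 bw]` (default 512 points). It is a
direct summation, not an FFT-binned approximation, so it matches a
brute-force oracle to floating-point accuracy; this exactness is what the
test suite asserts. The automatic bandwidth is Silverman's rule of thumb
(`bw.nrd0`); both bandwidth and grid size are exposed because density
plots give no universal default.

`find_intersection()` interpolates the second curve onto the first grid,
forms the difference and locates sign changes by linear interpolation
between bracketing grid points. When several crossings fall in the search
window the smallest is returned and all are reported — the deterministic
tie-break needed because named intersection points are single numbers.
Identical curves (difference identically zero) raise a "no intersection"
error rather than returning an arbitrary point.

## QC filtering

`qc_filter()` keeps cells with at least 200 detected genes and a
mitochondrial fraction within [1%, 15%]. The removal bounds are
exclusive (a cell at exactly 15% survives); the high bound removes dying
cells, the low bound removes blood-like contaminants. A per-rule removal
log is attached to the result.

## Differential proportion analysis

`dpa_test()` asks whether cluster composition differs between two
conditions. The observed statistic per cluster is the difference of
within-condition proportions. The null distribution is generated by
drawing, each iteration, a full label multiset for every condition from
the mixture `p_mix * own-condition proportions + (1 - p_mix) * pooled
proportions` (a multinomial of the condition's size), and recomputing the
statistic. Defaults are `n_perm = 100,000` and `p_mix = 0.1`, the
settings used by published applications of the method; the suite uses
`n_perm = 2,000` for runtime.

Two design points deserve a note:

* **Null calibration.** An alternative reading of the "mixing
  proportion" mechanism — perturbing only a fraction `p_mix` of each
  condition's labels per iteration — leaves the null statistic with
  roughly a tenth of the observed statistic's sampling variance, so the
  test would essentially never reject on null data. The full-redraw
  mixture used here keeps the null variance equal to the observed one
  and yields a type-I error of ~4.5% at the nominal 5% (the suite checks
  the [3%, 7%] band over 200 null replicates). The residual weight
  `p_mix` on the condition's own proportions makes the test very mildly
  conservative under the alternative.
* **Exact swap symmetry.** The two conditions are processed in a
  canonical alphabetical order internally and the statistic is
  sign-corrected to the caller's argument order, so swapping arguments
  under the same seed negates every statistic and reproduces identical
  p-values bit for bit.

The empirical p-value uses add-one smoothing, `(1 + #{|null| >= |obs|}) /
(n_perm + 1)`, and therefore never reaches exactly zero. Raw p-values are
reported without multiplicity correction, matching the convention of
flagging `p < 0.01` per cluster. `pairwise_dpa()` derives one seed per
unordered pair (`seed + pair index`) so any single comparison can be
reproduced in isolation.

## Contact-map post-processing

Coordinates are 1-based inclusive externally (`genomic_interval()`,
presets such as `region_preset("pitx1-mm9")`), 0-based half-open
internally; `pos_to_bin()` maps the first position of a region to bin 0
exactly, and the bedGraph writer converts back exactly.

* `bin_pairs()` fills a symmetric matrix; upper-triangle mass equals the
  pair count.
* `kr_balance()` is an R implementation of the Knight–Ruiz balancing
  algorithm (outer Newton steps, conjugate-gradient inner solves). Bins
  with a zero marginal are masked first and re-inserted afterwards, as
  balancing requires support. The bias is rescaled so the balanced
  matrix preserves the raw total mass; convergence failures raise an
  error rather than returning a partial result. The test oracle is an
  independent Sinkhorn alternating-scaling implementation run to 1e-12;
  the two agree entrywise to better than 1e-6 on random matrices because
  the doubly stochastic scaling of a positive symmetric matrix is
  unique.
* `subdiagonal_scale()` formalizes "scaling two maps together across
  their subdiagonals" as per-offset mean matching to the two-map
  average: at each diagonal offset `d` both maps are multiplied by
  `t(d)/m_x(d)` with `t(d) = (m_a(d)+m_b(d))/2`. The convention is
  symmetric in the inputs, leaves identical maps untouched, and removes
  distance-decay imbalance — the purpose of the step. Offsets with a
  zero mean in either map are flagged and left unscaled. Exact
  recovery of the authors' scaling is not claimed; this one is
  documented and tested.
* `subtract_maps()` refuses (by default) inputs that have not been
  scaled together, because a subtraction of unscaled maps confounds loop
  differences with decay differences.
* `truncate_percentile()` clips displays at a linear-interpolation
  quantile of the unmasked upper-triangle entries (default 99th
  percentile).
* `virtual_4c()` counts pairs with **exactly one** mate in the viewpoint
  (both-in-viewpoint pairs are self-interactions and contribute
  nothing), bins the outside mate at a fine raw resolution (default
  1 kb) and averages over 5 kb intervals. Real fragment-based profiles
  count per restriction fragment; a fixed raw bin stands in because
  synthetic data has no fragment map, preserving the two-scale
  count-then-average structure. Raw counts are reported by default, with
  a per-million option, since profile normalization conventions vary.

## The synthetic-data generators

The generators define the conditions every test runs under; their
defaults were fixed once, from the study design, and are not tuned.

**Cells** (`gen_cells()`): four conditions (wildtype fore- and hindlimb,
enhancer-deleted hindlimb, knockout hindlimb) x nine mesenchymal clusters
(ICT, TP, PPP, PC proximal; DP, DPP, EDC, LDC distal; Ms unassigned),
2,000 cells per condition by default. Each cell draws a latent class from
per-(condition, cluster) weights, an expression value from that class's
component, and a log-normal library (median 10^4 total UMIs, a typical
droplet scale); the integer count is reconstructed as
`round((e^v - 1) * total / scale)` so the downstream pathway is exercised
end to end, rounding included. The default weights echo the published
fractions: ~21/40/39% classes in the wildtype hindlimb, non/low rising to
~36% under the deletion with 3.5x in ICT and 2x in PPP, near-silent
forelimb and knockout; the deletion also shifts population shares from
ICT to PPP (the delayed-differentiation phenotype the composition test
should detect).

Component shapes are conventions, flagged as such: non/low is a point
mass at zero (q = 0.8) plus a uniform tail on (0, 0.2]; intermediate is
normal(1.0, 0.22) truncated to (0.3, 1.45]; high is normal(2.3, 0.5)
truncated above 1.45. The locations sit away from the class boundaries
deliberately: at a median library of 10^4 the count grid near `v = 0.3`
is coarse (0 or 1 UMI), and components hugging a boundary would let
rounding flip a few percent of cells across it, biasing weight recovery.
With these defaults the flip mass is below half a binomial standard error
at n = 5,000. What the generator does **not** emulate: full
transcriptomes, doublets, ambient RNA, batch effects, or any clustering
uncertainty — cluster labels are ground truth. Passing tests therefore
validate the arithmetic of the pipeline, not the upstream clustering of
real data.

**Contacts** (`gen_contacts()`): one mate uniform in the region, a
separation from a power law with exponent -1 (the standard Hi-C decay)
truncated below at 20 kb (short-range products are dominated by
self-ligation artefacts), random direction, out-of-region proposals
rejected — so the realized distance density carries the `(L - d)` edge
factor, which the goodness-of-fit oracle integrates explicitly. Loops
over-sample anchor pairs by rejection with weight equal to the
enrichment.

### Fixture sizes

The subtraction-pipeline and virtual-4C checks run on a 600 kb region at
10 kb bins with a 5x loop at 150 kb separation (20 kb anchors) and 10^5
pairs per condition; the signal at the anchor after per-offset scaling is
then ~3x the per-offset mean against a maximal near-diagonal Poisson
fluctuation of ~2x, a margin chosen by a signal/noise calculation at the
design stage. Threshold-recovery checks use 10^5 draws per population
from equal-sd normal mixtures whose analytic crossing is the target
threshold; with sd 0.4 the KDE crossing's sampling error (~0.003) is an
order of magnitude below the `max(grid step, bw/2)` tolerance. The DPA
calibration uses 200 null replicates of 2,000 cells over nine clusters at
`n_perm = 2,000`.

## Numerical choices and degenerate inputs

* KDE: at least two finite values; zero variance with automatic
  bandwidth is an error (a fixed bandwidth is fine).
* Intersection: no sign change in the window is an explicit error;
  exact zeros of the difference count as crossings only when flanked by
  opposite signs.
* KR: tolerance is the residual norm on unit row sums (default 1e-8);
  matrices without total support fail loudly.
* Quantile type 7 (linear interpolation) for percentile truncation.
* Proportion tables: empty groups are omitted with a warning; fractions
  always sum to 1 per row; fold changes against a zero reference are
  flagged undefined, never reported as numbers.
* z-scores use the sample (n-1) standard deviation by default
  (population sd available); constant genes are returned as `NA` rows,
  flagged, never divided.
* log2 fold changes add a 0.01 RPKM pseudocount by default, exposed as
  an argument, purely to guard against division by zero.

## Known limitations

* The DPA null mechanism is a documented reconstruction of the cited
  method's mixing idea, not a transcription of its source code.
* Virtual 4C uses fixed raw bins, not restriction fragments; absolute
  profile values differ from fragment-based ones although interval
  averages are comparable.
* The subdiagonal scaling convention, while symmetric and idempotent, is
  one of several defensible formalizations.
* Synthetic cluster labels are noiseless; real pipelines inherit
  clustering uncertainty that these tests do not measure.
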