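---
title: "VR-thresholded connectomes: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VR-thresholded connectomes: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrconn)
```

## The procedure

The pipeline turns per-subject streamlines into binarized structural
networks through a per-fiber robustness score. Deterministic tracking with
a fractional-anisotropy stopping threshold (FAT) is conceptually repeated
as the threshold sweeps upward from 0 in steps of 0.01; a fiber that still
spans the 30 mm fiber-length threshold (FLT) at threshold `t` but not at
`t + 0.01` has `fa_max = t`. The subject's largest such value is `FAT_max`,
and each fiber's visualized ratio is `VR = fa_max / FAT_max x 100`.
Fibers with VR >= 25% and VR >= 50% feed five matrices per subject — whole
brain, left and right hemisphere, and the subject's positive / negative
stimulation-mapping region sets — binarized at more than three fibers per
region pair. Average degree, global efficiency and local efficiency are
computed per matrix and threshold, together with the low-minus-high
threshold differences.

Two readings of the per-fiber quantity are possible: the maximal pointwise
FA along the fiber, or the maximal threshold the fiber *survives* with the
length criterion enforced. We implement the survival semantics, because
the quantity is defined inside the incremental-threshold procedure and the
length threshold participates in it. `famax_by_sweep()` computes it in a
single pass: the largest grid threshold `t` such that some contiguous run
of points with FA >= `t` spans at least 30 mm, equivalently the grid floor
of the best min-over-window FA over windows of length >= FLT (extending a
window can only lower its minimum, so minimal windows suffice). The
literal repeated-tracking procedure remains available as
`famax_by_retracking()` and pins the sweep down on phantoms: the two agree
within one 0.01 grid step for more than 95% of seeds, the residual
disagreement coming from seeds that sit outside their fiber's best
suprathreshold run (retracking grows the run containing the seed, the
sweep may use a different stretch of the same fiber).

Thresholds live on an exact 0.01 grid and are manipulated as integer
hundredths, so `VR = 100 * ih / ih_max` is exact; the fiber attaining
`FAT_max` has VR exactly 100 and survives every selection. Selection is
inclusive (`VR >= threshold`): the boundary rule is deterministic and the
threshold-defining fiber is never discarded.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `flt_mm` | 30 | fiber length threshold (mm); fibers that cannot span it at any FA threshold are dropped before any matrix is built |
| `grid_step` | 0.01 | FA threshold grid |
| `vr_thresholds` | 25, 50 | VR selection thresholds (percent), inclusive |
| `min_fiber_count` | 3 | region pairs need strictly more fibers to count as connected |
| `search_radius_mm` | 5 | nearest-label fallback for stimulation points (sites sit on the cortical surface and may fall in background after registration) |
| tracker `step_mm`, angle | 1 mm, 60 deg | conventional deterministic-tracking defaults; only the retracking reference depends on them |

Point-to-region assignment uses the containing voxel, falling back to the
nearest labeled voxel center within the search radius, distance ties going
to the smaller region id. A region may be both positively and negatively
mapped for one subject (at least one point of each polarity assigns to
it); `pos_precedence = TRUE` removes positive regions from the negative
set, since published mapping counts do not disambiguate the two
conventions. Fibers enter the count matrix by their two endpoints only;
pass-through counting would inflate hub connectivity. Metrics of a 0- or
1-node matrix (possible for small mapping sets) are defined as 0.

All coordinates are exchanged in world mm (RAS); voxel indices are
0-based; world-to-voxel uses the inverse affine with nearest-voxel
rounding for labels and trilinear interpolation for FA (the interpolation
scheme is our choice; out-of-bounds FA evaluates to 0). Inputs must be
pre-co-registered — a shape or affine mismatch between FA and label
volumes is a hard error, and no resampling is attempted.

## The synthetic cohort

`make_cohort()` generates everything the pipeline consumes. A block
parcellation halves the grid at the world-x midline and tiles each half
with 45 contiguous rectangular regions. Bundles are straight tubes between
region centroids; inside a tube FA is the bundle peak plus uniform
per-voxel jitter (half-width 0.02) and the direction field follows the
tangent, outside FA stays below 0.1. Default bundle peaks descend from
0.55, so realized per-fiber maxima (which sit a jitter below the peak)
anchor `FAT_max` near 0.53 with the 0.531 +/- 0.065 range of clinical
subjects in mind, and the ladder's lower rungs (0.28, 0.22) straddle the
50% VR cut so the two thresholds genuinely separate the bundle population.
Fibers are jittered copies of centerlines with FA sampled from the
phantom; the transverse offset is capped at 0.3 of the tube radius so the
trilinear support of fiber points stays inside the tube.

The two-group structure: 30 + 30 subjects; tumor sizes drawn per group
(2.4 +/- 2.6 vs 4.7 +/- 4.3 cm^3, truncated at 0); GIA subjects keep each
left-hemisphere bundle independently with probability `deficit` (default
0.6); the ordinal aphasia level (0 for every NA subject, 1-5 for GIA) is
constructed to rise with the fraction of left bundles lost, plus noise, so
it correlates negatively with realized left connectivity by construction
— a modeling choice that makes recovery testable, not a claim about the
clinical relationship, which is not quantified anywhere we could source.
Positive/negative mapping sets are drawn over left-hemisphere regions
only; bundle-endpoint regions get elevated probabilities (0.55 / 0.75
versus 0.19 / 0.37 elsewhere) so the mapping-region networks have edges,
and mean counts land near 10 positive vs 19 negative of 45 — positive
rarer than negative, as observed clinically (8.4 vs 16.6). Two designated
non-endpoint regions have their positive probability raised to 0.4 in the
GIA group, mirroring the reported supplementary-motor-area/angular-gyrus
contrast.

The deficit default of 0.6 deserves a note: desk-scale phantoms carry ~5
left bundles where a brain carries thousands of streamlines, so each
dropped bundle moves the left metrics far more than any clinical effect
would. A keep-probability of 0.6 produces a left average-degree reduction
that 30 + 30 subjects detect reliably — the emulation preserves the
*direction and testability* of the group difference, not its clinical
magnitude. Consequently passing recovery tests demonstrates that the
pipeline propagates a known ground-truth difference through VR selection,
counting, binarization and ANCOVA; it says nothing about sensitivity at
clinical effect sizes. The phantom also omits: curved and crossing fiber
geometry (tubes are straight and kept from crossing in the default
layouts), realistic DWI noise and CSD fitting (upstream of this package's
scope), lesion mass effects (tumor size is a covariate, not geometry —
an optional future lesion flag was considered and dropped as out of
scope), and registration error.

## Statistics

ANCOVA is the linear model `value ~ group + tumor size` fit by least
squares; the reported statistic is the group coefficient's t with n - 3
degrees of freedom (matching the T-value convention for adjusted group
contrasts), with the equivalent F = t^2 alongside. The nonparametric
mapping-count comparison is Mann-Whitney U (exact when sizes allow and no
ties). The aphasia correlation defaults to Spearman because the level is
ordinal; Pearson is available. FDR correction is Benjamini-Hochberg, with
all comparisons of one output table treated as one family (the family
structure is otherwise unspecified, and one-table-one-family is the most
conservative reading that keeps tables self-contained). Degenerate
comparisons — a metric constant across all subjects, which happens at
desk scale when an edge is deterministic — yield NA rows rather than
fabricated statistics.

## Numerical and testing choices

Graph metrics use a vectorized Floyd-Warshall inside the package (the
replicate suites evaluate ~10^5 tiny graphs, where per-graph object
construction in graph libraries dominates); tests verify them to 1e-12
against definitional BFS brute force on hundreds of random graphs and
against igraph shortest paths. Calibration runs 200 replicate null
cohorts (no deficit, equal tumor distributions) and checks that ANCOVA,
t, U and correlation each reject at 5% within a three-sigma binomial
band; recovery runs 100 default-deficit replicates and requires the left
AD and EG differences (correct direction) and the negative pooled
aphasia-efficiency correlation in at least 80%. These replicate studies
use an 8-region phantom with regions at the corners of a 40 mm square per
hemisphere and bundles along non-crossing square edges laid down in
ascending peak order — tube overlaps at shared corners then only ever
*raise* FA briefly, which a min-over-window `fa_max` ignores, whereas
low-FA contamination would corrupt it. One bundle per hemisphere is
marginal at each VR cut, so subject networks vary stochastically and the
group tests see genuine sampling noise. Acceptance-scale problem sizes
(a ~2,200-seed phantom for the sweep-vs-retracking comparison, 200 + 100
replicate cohorts) were chosen as the smallest sizes at which the
binomial bands are meaningful.

## Known limitations

- TRK support covers version-2 headers with the voxel-to-world transform
  present; scalars are skipped on read, not preserved.
- The tracker is a fixed-step principal-direction follower on a smooth
  synthetic direction field; it is the in-package reference for the
  threshold procedure, not a general-purpose tractography replacement.
- Local efficiency of sparse desk-scale networks is dominated by a few
  triangles and is accordingly coarse; its threshold difference is not
  sign-constrained (unlike AD-diff and EG-diff under nested edge sets),
  and both signs occur in practice.
- The generator draws mapping regions independently per region; spatial
  correlation of stimulation sites is not modeled.
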