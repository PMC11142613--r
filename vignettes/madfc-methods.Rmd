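---
title: "Mirrored axis distortion for fold-change visualization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirrored axis distortion for fold-change visualization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(madfc)
```

## The problem

A fold change is the ratio of an experiment group's mean to a control
group's mean: a positive real number where 1 means no change. Plotting fold
changes raw (a linear axis) compresses every down-regulation into the
interval (0, 1) while up-regulations occupy (1, ∞), so a 4-fold decrease
(fold change 1/4) sits a fraction of the distance from "no change" that a
4-fold increase does. The usual fix, a log axis, restores symmetry but
destroys proportionality: equal display distances no longer correspond to
equal numbers of fold changes, so point clouds and interval widths are
distorted relative to their actual effect sizes.

This package implements an alternative display transform, mirrored axis
distortion of fold change (MAD-FC), and the toolkit around it: a labelled
axis scale, a diverging color normalization, six plot builders, numeric
property audits, and synthetic fixture generators.

## The transform

Define *fold change units* (FCU) as the signed number of fold changes from
the point of no change:

$$f_U(x) = \begin{cases} x - 1 & x \ge 1 \\ 1 - 1/x & 0 < x < 1, \end{cases}$$

so fold changes (2, 1/2, 3, 1/3) encode as (1, −1, 2, −2). The MAD-FC
transform reaches the same coordinates in two steps. A *mirror* transform
sends sub-unit fold changes to their negated reciprocals,

$$f_M(x) = \begin{cases} x & x \ge 1 \\ -1/x & 0 < x < 1, \end{cases}$$

making reciprocal pairs sign-symmetric but leaving an empty band over
\[−1, 1). A *contraction* then pulls both branches one unit toward zero,

$$f_C(m) = \begin{cases} m - 1 & m \ge 1 \\ m + 1 & m < -1, \end{cases}$$

closing the gap. The composition $f_C \circ f_M$ is continuous, strictly
increasing, maps 1 to 0 exactly, and is numerically identical to $f_U$ — a
provable identity that the test suite checks on a 10^4-point log-spaced
grid over $[2^{-10}, 2^{10}]$ at 1e−12 relative tolerance. The exact
inverse composes the case-wise inverses $f_C^{-1}(y) = y \pm 1$ and
$f_M^{-1}(m) = m$ or $-1/m$, giving $y + 1$ for $y \ge 0$ and $1/(1-y)$
for $y < 0$; it is defined on all reals, which is what lets axis tick
labels be back-transformed anywhere.

The half-open case boundaries are kept literally as written above (branch
membership at $m = -1$ and $y = 0$), because that choice makes the
forward/inverse pair exact at the point of no change rather than merely
close.

A MAD axis is always *labelled*: tick text shows the back-transformed raw
fold change (`1/6 … 6` rather than `−5 … 5`), because a raw MAD axis would
force the reader to invert the transform mentally. The package never emits
raw MAD tick labels from its public scale.

### Out-of-domain inputs

Fold changes must be positive; the transform is undefined at or below
zero. Two policies are offered: `strict` (the default for the scalar
transform functions) raises an error naming the offending values, and
`propagate` (the default throughout the table/plot pipeline) maps them to
`NA` positionally, so a single degenerate feature does not abort a
5,000-gene volcano plot. A fold change of exactly 0 (complete loss) has no
defined display position; we deliberately do not invent a pseudocount for
it — it errors or propagates like any other out-of-domain value.

## Properties and the audit

Four properties frame the design: *readability* (values recoverable from
positions and labels), *proportionality* (display distance from no change
linear in FCU, per direction), *symmetry* (a fold change and its
reciprocal equidistant from no change), and *dynamic range* (how many
doublings stay visually separable in a fixed pixel budget).

`audit_fc_transforms()` scores any strictly increasing display transform:

- **Proportionality** draws the line from the point of no change to the
  most extreme probe in each direction (in FCU vs display coordinates) and
  reports the largest residual, normalized by the branch's display span.
  The probe grid defaults to the 11 fold changes at integer FCU −5…5.
- **Symmetry** reports the largest difference between the display
  distances of $m$ and $1/m$ from the point of no change, normalized by
  the probe display span, for magnitudes 2…6.
- **Dynamic range** maps the dyadic ladder $2^0 \dots 2^k$ onto a 600 px
  axis and finds the largest $k$ keeping every adjacent pair ≥ 2 px apart.
  The search is capped at the budget's own limit (axis_px / min_gap_px).

Pass thresholds for the first two are 1e−9 of display span: transforms
satisfying the law exactly pass despite floating-point noise, while the
linear scale's asymmetry (~0.71 of span on the default probes) and the
log scale's non-proportionality (~0.21 per branch; the linear scale's
negative branch reaches ~0.4) are many orders of magnitude above it. The pixel-budget defaults (600 px, 2 px) are one deliberate
operationalization of "typically distinguishable"; under them the linear
and MAD scales separate 8 doublings ($2^k - 1 \le 300$ gives $k = 8$) and
the log scale is limited only by the budget cap. Readability is not
numerically scored: it is a label-semantics contract, enforced instead by
the tick invariant that parsing any emitted label and re-applying the
forward transform reproduces the tick position to 1e−9.

```{r audit}
audit_fc_transforms()
```

## Tick placement and labels

No tick algorithm follows from the transform itself, so the scale uses
integer-FCU candidates: every integer display position in range, thinned —
when they exceed `max_ticks` — to multiples of the smallest stride that
fits. Multiples of a stride always include 0, so the point-of-no-change
tick survives thinning whenever it is in range. Ranges with fewer than two
integer FCU positions (all data within one fold change of no change) fall
back to five evenly spaced positions with decimal back-transformed labels,
snapping one tick to 0 when in range. Fraction labels are ASCII `1/k`;
exponent style renders `b^p` (base 2 by default) when exact and falls back
to decimals otherwise.

```{r ticks}
madfc_ticks(-5, 5, max_ticks = 11)
```

## Color normalization

`normalize_fc()` maps fold change to [0, 1] for a diverging palette:
transform, rescale between the transformed bounds, clip. With
`symmetric = TRUE` (the default, and the data-driven default bounds in
`plot_heatmap()`) the bounds are replaced by ±max magnitude about the
transform's point of no change, so fold change 1 always sits at the
palette midpoint and, under the MAD transform, equal FCU steps get equal
color steps with `normalize_fc(x) + normalize_fc(1/x) = 1`. Out-of-range
cells clip to the palette ends rather than erroring, since heatmaps
routinely contain outliers. Perceptual nonuniformity of color is out of
scope: the normalization makes the *numeric* color positions
proportional, not the perceived differences.

## Plot builders

Each builder returns the ggplot plus an assertable spec record (display
positions, tick placement, classifications, summary geometry) so figure
content is testable without rendering pixels.

- **Volcano / MA**: x (or y) is the chosen display transform of fold
  change; significance classes (`Up` red / `Down` blue / `NS` black)
  require both adjusted p < `padj_max` (default 0.1) and |log2 fold
  change| > `lfc_min` (default 1). The magnitude threshold is read in
  log2 units by default — the convention of mainstream volcano tooling —
  with `lfc_unit = "fcu"` available since "greater than ±1 fold change"
  admits both readings. Classification never depends on the display
  scale. The MA x-axis is log10(base mean + 0.5); the pseudocount keeps
  zero-count features plottable and is configurable.
- **Interval plots** transform interval *endpoints*, never widths. Under
  MAD, an interval spanning ±h FCU around any center renders with display
  half-width exactly h — identical-dispersion fixtures are visibly
  identical, which is the transform's selling point for uncertainty
  display.
- **Box plots** compute quartiles on raw fold changes with type-7
  (order-statistic interpolation) quantiles and transform them for
  display. When quartile probabilities land on order statistics (sample
  sizes 4k+1, which the box fixture generator guarantees), this commutes
  exactly with any monotone display transform. Whiskers are Tukey
  1.5·IQR evaluated in display space, matching mainstream boxplot
  defaults.
- **Violin plots** estimate the kernel density *in display space*
  (densities do not commute with monotone transforms): Gaussian kernel,
  Scott's bandwidth, 256-point grid extending 3 bandwidths past the data.
  Display-space estimation is what makes "same distribution shape under
  MAD" literally true for FCU-translated groups, since both the bandwidth
  rule and the grid are translation-equivariant.
- **Heatmaps** color cells by the normalization above and label the
  colorbar with back-transformed fold changes via the same tick algebra.

Rendering is deterministic: no jitter, seeded generators, byte-identical
spec JSON for identical inputs.

## Synthetic fixtures

The generators produce the study conditions the plots are demonstrated
on; they replace any external datasets, and all are seeded and
deterministic.

- `gen_dyadic_ladder()`: fold changes $2^0 \dots 2^9$ (the dynamic-range
  probe).
- `gen_fcu_span()`: fold changes at integer FCU −5…5, i.e. 1/6…6.
- `gen_interval_groups()`: 11 groups at integer FCU centers −5…5, ±2 FCU
  half-width. The group count and centers are declared defaults (the
  reference layout is visual only), overridable.
- `gen_box_groups()`: medians swept over integer FCU −8…8 (fold changes
  1/9…9) with quartile boundaries 2 FCU apart, placed deterministically
  by piecewise-linear filling between quartile anchors at sample size
  4k+1 so type-7 quartiles are exact; "2-fold change unit spacing" is
  read as FCU spacing of the quartile boundaries (the raw-FC reading
  would contradict the construction's symmetry in MAD space). Optional
  Gaussian FCU jitter for less stylized samples.
- `gen_violin_groups()`: one base sample (standard normal truncated to
  ±3, scaled by `scale_fcu = 1` FCU, n = 200 per group) translated to
  each center — groups differ *only* by an FCU translation.
- `gen_de_results()`: a synthetic stand-in for a DESeq2-style results
  table. Spike-and-slab log2 effects (80% nulls; non-null effects
  N(0, 1.5²) log2 units — a typical spread of real differential calls),
  log-normal base means (median 100, 1.5 log-sd), observed log2 fold
  changes with constant standard error 0.25 (a typical shrunken-estimate
  magnitude), two-sided normal p-values, Benjamini–Hochberg adjustment.
  Null p-values are uniform by construction (KS-checked in the tests).
  It emulates the *schema and statistical shape* of differential
  results — it is not a count-level RNA-seq simulator, models no
  mean–dispersion trend, and its noise is exactly Gaussian, so passing
  tests demonstrate the visualization pipeline's correctness on tables
  of this shape, not robustness to real count noise.

## Problem sizes and numerical choices

The identity and round-trip checks run on 10^4-point grids; the symmetry
property on 10^4 random draws; violin fixtures at 150–200 points per
group; the synthetic results tables at 300–5,000 features. These sizes
make every law testable well below a second while leaving no corner of
the piecewise domain unprobed. Round-trip equality is asserted at 1e−12
relative (1/x is inexact in binary floating point); tick readback and
geometry claims at 1e−9; audit pass thresholds at 1e−9 of span as above.
Values astronomically far from 1 are transformed as-is — no clamping;
dynamic-range concerns are the audit's job, not the transform's.

## Known limitations

- Signed "fold change" conventions where negative values encode
  down-regulation (±ratio encoding) are not supported; convert to
  positive ratios first.
- Dual-axis (raw + labelled) rendering is excluded on purpose; raw MAD
  coordinates are never labelled.
- The MAD scale inherits the linear scale's limited dynamic range
  (about 8 log2 units under the default pixel budget); datasets spanning
  much more than that are better served by a log display, and the audit
  quantifies exactly that trade-off.
- Minor ticks between fold-change units are not generated.
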