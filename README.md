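# madfc

Fold-change visualization with mirrored axis distortion (MAD-FC), for
anyone plotting differential expression or differential abundance results:
volcano and MA plots, interval estimates, box and violin plots, and
heatmaps where the display is **readable** (axis labels are raw fold
changes), **proportional** (display distance from "no change" is linear in
fold-change units, in each direction), and **symmetric** (a fold change
and its reciprocal are equidistant from no change).

## The transform

A fold change *x* > 0 is the ratio experiment / control; *x* = 1 is the
point of no change. *Fold change units* encode it linearly as distance
from no change:

    f_U(x) = x − 1        for x ≥ 1
    f_U(x) = 1 − 1/x      for 0 < x < 1

so (2, ½, 3, ⅓) encode as (1, −1, 2, −2). MAD-FC reaches the same
coordinate by *mirroring* sub-unit fold changes to negated reciprocals
(f_M(x) = −1/x on (0, 1), identity above 1) and *contracting* both
branches one unit toward zero (f_C(m) = m ∓ 1). The composition is
continuous, strictly increasing, fixes f(1) = 0, equals f_U identically,
and has the exact inverse y + 1 (y ≥ 0), 1/(1 − y) (y < 0). Axis ticks are
drawn at integer fold-change-unit positions and labelled with the
back-transformed raw fold change — a "labelled MAD plot". Compared with a
log axis, MAD keeps proportionality at the price of a linear scale's
dynamic range (about 8 log2 units within a 600-px / 2-px pixel budget).

## Worked example

```r
library(madfc)

fold_change_units(c(2, 1/2, 3, 1/3))
#> [1]  1 -1  2 -2

madfc_ticks(-5, 5, max_ticks = 11)
#> # A tibble: 11 × 3
#>    position    fc label
#>       <dbl> <dbl> <chr>
#>  1       -5 0.167 1/6
#>  2       -4 0.2   1/5
#> ...
#>  6        0 1     1
#> ...
#> 11        5 6     6
```

The tick table is the readability contract made concrete: positions −5…5
are equally spaced display coordinates, and their labels 1/6…6 are the raw
fold changes, so reciprocal ticks pair off symmetrically about the "1"
anchor. Build a volcano plot from a synthetic DESeq2-style results table:

```r
de <- gen_de_results(n_genes = 2000, seed = 42)
v  <- plot_volcano(de, scale = "madfc")   # autoplot(v) or print(v) to draw
table(plot_spec(v)$class_labels)
#> Down   NS   Up
#>  102 1786  112
head(plot_spec(v)$point_positions, 5)
#> [1]  8.96018352  0.50316633 -0.07307509  0.21275863  0.21330320
```

`plot_spec()` exposes what the figure actually encodes: each point
position is exactly the MAD transform of that feature's fold change (the
first gene, at fold change ≈ 9.96, sits 8.96 fold-change units above no
change), and the Up/Down/NS classes follow the padj < 0.1, |log2FC| > 1
rule independent of the display scale. `plot_ma()`, `plot_interval()`,
`plot_box()`, `plot_violin()`, and `plot_heatmap()` return the same kind
of figure-plus-spec pair; `scale_x_madfc()` / `scale_y_madfc()` attach the
MAD axis to any ggplot.

Audit any display transform for the three numeric properties:

```r
audit_fc_transforms()
#> Fold-change transform audit (tol 1.0e-09, axis 600 px, min gap 2 px)
#>  transform  proportional symmetric  dynamic_range
#>     linear positive only        no   8 log2 units
#>       log2            no       yes 299 log2 units
#>      madfc           yes       yes   8 log2 units
```

A command-line surface wraps the same functions
(`inst/scripts/madfc`): `simulate`, `transform`, `volcano`, `ma`, `box`,
`violin`, `heatmap`, and `audit` subcommands with `--scale`,
`--label-style`, `--padj-max`, `--lfc-min`, `--seed`, and `--out` flags.

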