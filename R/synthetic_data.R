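# Seeded synthetic fixtures: the probe datasets the figures are built from
# (dyadic ladder, integer-FCU span, interval/box/violin groups constructed
# in fold-change-unit space) and a generator that emulates the statistical
# shape of a DESeq2-style differential results table. Identical arguments
# and seed give identical output.

# Run code under a fixed RNG state without disturbing the caller's.
with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Dyadic ladder of positive fold changes
#'
#' The dynamic-range probe set: fold changes `2^0, 2^1, ..., 2^max_log2`
#' (default up to 512), used to illustrate how far up the doubling ladder a
#' scale keeps adjacent values distinguishable.
#'
#' @param max_log2 Largest exponent (default 9).
#' @return Numeric vector of `max_log2 + 1` increasing fold changes.
#' @examples
#' gen_dyadic_ladder()
#' @export
gen_dyadic_ladder <- function(max_log2 = 9) {
  stopifnot(max_log2 >= 0)
  2^(0:max_log2)
}

#' Fold changes at integer fold-change-unit positions
#'
#' The inverse MAD transform of each integer in `[lo_fcu, hi_fcu]`. The
#' defaults give the canonical 11-point probe grid from 1/6 to 6 (fold
#' change units -5 to 5) used throughout the property audits.
#'
#' @param lo_fcu,hi_fcu Integer fold-change-unit bounds.
#' @return Numeric vector of raw fold changes.
#' @examples
#' gen_fcu_span()
#' @export
gen_fcu_span <- function(lo_fcu = -5, hi_fcu = 5) {
  stopifnot(lo_fcu <= hi_fcu)
  madfc_inverse(seq(lo_fcu, hi_fcu))
}

#' Interval-estimate groups with identical width in fold-change units
#'
#' One interval per center: the point estimate sits at `center_fcu` fold
#' change units and the interval spans `center_fcu ± half_width_fcu`, both
#' endpoints mapped back to raw fold change. Under a MAD display every
#' group's interval has exactly the same width (`2 * half_width_fcu`);
#' linear and log2 displays distort the widths group by group.
#'
#' @param centers_fcu Interval centers in fold-change units (default the 11
#'   integers -5 to 5).
#' @param half_width_fcu Half-width in fold-change units (default 2).
#' @return A tibble with columns `group`, `center_fcu`, `half_width_fcu`,
#'   `center_fc`, `lower_fc`, `upper_fc` (all fold changes positive).
#' @examples
#' gen_interval_groups()
#' @export
gen_interval_groups <- function(centers_fcu = -5:5, half_width_fcu = 2) {
  stopifnot(half_width_fcu >= 0)
  tibble(
    group = factor(seq_along(centers_fcu)),
    center_fcu = as.numeric(centers_fcu),
    half_width_fcu = half_width_fcu,
    center_fc = madfc_inverse(centers_fcu),
    lower_fc = madfc_inverse(centers_fcu - half_width_fcu),
    upper_fc = madfc_inverse(centers_fcu + half_width_fcu)
  )
}

#' Box-plot groups with exact quartile geometry in fold-change units
#'
#' For each requested median `m` (in fold-change units), builds a sample
#' whose order-statistic quartiles (minimum, lower quartile, median, upper
#' quartile, maximum under type-7 interpolation) sit exactly at
#' `m + c(-2, -1, 0, 1, 2) * quartile_gap_fcu`, then maps the values back
#' to raw fold change. Placement is deterministic (piecewise-linear filling
#' between quartile anchors); optional Gaussian jitter in FCU space can be
#' added for less stylized samples. Defaults sweep the median over integer
#' FCU from -8 to 8, i.e. fold changes 1/9 to 9, with quartile boundaries
#' 2 FCU apart.
#'
#' @param medians_fcu Group medians in fold-change units.
#' @param quartile_gap_fcu Spacing between adjacent quartile boundaries in
#'   fold-change units (default 2).
#' @param n_per_group Sample size per group; rounded up to `4k + 1` so the
#'   quartiles land on order statistics exactly (default 21).
#' @param jitter_sd Standard deviation of optional FCU-space jitter
#'   (default 0: exact placement).
#' @param seed RNG seed used only when `jitter_sd > 0`.
#' @return A long tibble with columns `group`, `median_fcu`, `fc`.
#' @examples
#' gen_box_groups(medians_fcu = 0)
#' @export
gen_box_groups <- function(medians_fcu = -8:8, quartile_gap_fcu = 2,
                           n_per_group = 21, jitter_sd = 0, seed = 1) {
  k <- max(1L, ceiling((n_per_group - 1) / 4))
  build <- function(m) {
    anchors <- m + c(-2, -1, 0, 1, 2) * quartile_gap_fcu
    fcu <- unlist(lapply(1:4, function(j) {
      seq(anchors[j], anchors[j + 1], length.out = k + 1)[seq_len(k)]
    }))
    c(fcu, anchors[5])
  }
  out <- purrr::map_dfr(seq_along(medians_fcu), function(i) {
    tibble(group = factor(i, levels = seq_along(medians_fcu)),
           median_fcu = medians_fcu[i],
           fcu = build(medians_fcu[i]))
  })
  if (jitter_sd > 0) {
    out$fcu <- with_rng_seed(seed,
      out$fcu + rnorm(nrow(out), sd = jitter_sd))
  }
  out$fc <- madfc_inverse(out$fcu)
  out[c("group", "median_fcu", "fc")]
}

#' Violin-plot groups with identical dispersion in fold-change units
#'
#' Draws each group from the same base distribution in fold-change-unit
#' space (standard normal truncated to ±3, scaled by `scale_fcu`),
#' translates it to the group's center, and maps back to raw fold change.
#' Groups therefore differ only by a translation in FCU space, so their
#' density shapes are identical under a MAD display and distorted under
#' linear or log2 displays.
#'
#' @param centers_fcu Group centers in fold-change units (default -5 to 5).
#' @param scale_fcu Dispersion scale in fold-change units (default 1).
#' @param n Sample size per group (default 200).
#' @param seed RNG seed (default 1).
#' @return A long tibble with columns `group`, `center_fcu`, `fc`.
#' @examples
#' gen_violin_groups(centers_fcu = c(-2, 2), n = 50)
#' @export
gen_violin_groups <- function(centers_fcu = -5:5, scale_fcu = 1, n = 200,
                              seed = 1) {
  stopifnot(n >= 2, scale_fcu > 0)
  base <- with_rng_seed(seed,
    qnorm(runif(n, pnorm(-3), pnorm(3))) * scale_fcu)
  purrr::map_dfr(seq_along(centers_fcu), function(i) {
    tibble(group = factor(i, levels = seq_along(centers_fcu)),
           center_fcu = centers_fcu[i],
           fc = madfc_inverse(base + centers_fcu[i]))
  })
}

#' Synthetic differential-expression results table
#'
#' Emulates the statistical shape of a DESeq2-style results table without
#' any count-level simulation: spike-and-slab log2 effects (a fraction of
#' features are true nulls), log-normal base means, observed log2 fold
#' changes with Gaussian estimation noise, two-sided normal (Wald-like)
#' p-values, and Benjamini-Hochberg adjusted p-values. Null features have
#' uniformly distributed p-values by construction. This is a synthetic
#' stand-in with the schema and null behavior of real differential results,
#' not a realistic RNA-seq count simulator.
#'
#' @param n_genes Number of features (default 5000).
#' @param frac_null Fraction of true-null features (default 0.8).
#' @param effect_sd_log2 Standard deviation of true non-null log2 effects
#'   (default 1.5).
#' @param se_log2 Standard error of the observed log2 fold change
#'   (default 0.25).
#' @param seed RNG seed (default 1).
#' @return A tibble with columns `feature_id`, `base_mean`, `fc`, `log2fc`,
#'   `pvalue`, `padj`, and the truth column `true_log2fc`.
#' @examples
#' gen_de_results(n_genes = 100)
#' @export
gen_de_results <- function(n_genes = 5000, frac_null = 0.8,
                           effect_sd_log2 = 1.5, se_log2 = 0.25, seed = 1) {
  stopifnot(n_genes >= 1, frac_null >= 0, frac_null <= 1)
  with_rng_seed(seed, {
    is_null <- runif(n_genes) < frac_null
    true_lfc <- ifelse(is_null, 0, rnorm(n_genes, sd = effect_sd_log2))
    obs_lfc <- true_lfc + rnorm(n_genes, sd = se_log2)
    z <- obs_lfc / se_log2
    p <- 2 * pnorm(-abs(z))
    tibble(
      feature_id = sprintf("gene_%05d", seq_len(n_genes)),
      base_mean = rlnorm(n_genes, meanlog = log(100), sdlog = 1.5),
      fc = 2^obs_lfc,
      log2fc = obs_lfc,
      pvalue = p,
      padj = p.adjust(p, method = "BH"),
      true_log2fc = true_lfc
    )
  })
}
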