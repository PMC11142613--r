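# Builders for the six figure types (volcano, MA, interval, box, violin,
# heatmap), each renderable under a linear, log2, or MAD display scale.
# Every builder returns a `madfc_plot`: the ggplot plus an assertable spec
# record (display positions, tick placement, significance classes, summary
# geometry) so the figures' computed content can be tested and serialized
# without rendering pixels.

new_madfc_plot <- function(plot, spec, type) {
  structure(list(plot = plot, spec = c(list(type = type), spec)),
            class = "madfc_plot")
}

#' @export
print.madfc_plot <- function(x, ...) {
  print(x$plot, ...)
  invisible(x)
}

#' Extract the ggplot from a built plot
#'
#' @param object A `madfc_plot`.
#' @param ... Unused.
#' @return The stored ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot madfc_plot
#' @export
autoplot.madfc_plot <- function(object, ...) object$plot

#' @export
ggplot2::autoplot

#' Extract the assertable spec record from a built plot
#'
#' @param x A `madfc_plot` returned by one of the `plot_*()` builders.
#' @return A list: `type`, `scale_name`, computed display positions /
#'   summary geometry, `tick_spec`, and (for volcano/MA) `class_labels`.
#' @examples
#' p <- plot_interval(gen_interval_groups())
#' names(plot_spec(p))
#' @export
plot_spec <- function(x) {
  stopifnot(inherits(x, "madfc_plot"))
  x$spec
}

#' Serialize a plot spec (or audit) to JSON
#'
#' @param x A `madfc_plot` or `fc_audit`.
#' @param path Optional file to write; when `NULL`, the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
spec_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "madfc_plot")) plot_spec(x) else as_tibble(x)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

sig_palette <- c(Up = "#B2182B", Down = "#2166AC", NS = "black")

#' Classify features as up, down, or not significant
#'
#' Applies the standard volcano-plot rule: `Up` requires adjusted p below
#' `padj_max` and log2 fold change above `lfc_min`; `Down` requires the
#' adjusted-p criterion and log2 fold change below `-lfc_min`; everything
#' else (including features with missing adjusted p) is `NS`. The defaults
#' (`padj_max = 0.1`, `lfc_min = 1`) follow common differential-expression
#' practice where the magnitude threshold is read in log2 units;
#' `lfc_unit = "fcu"` applies it to fold-change units instead. When no
#' `padj` column is present the raw p-value is used with a warning. The
#' classification depends only on the thresholds, never on the display
#' scale.
#'
#' @param data A results data frame with `fc` or `log2fc`, `pvalue`, and
#'   optionally `padj` columns (see [as_results_table()]).
#' @param padj_max Adjusted-p threshold (default 0.1).
#' @param lfc_min Fold-change magnitude threshold (default 1).
#' @param lfc_unit Units of `lfc_min`: `"log2"` (default) or `"fcu"`.
#' @return The input as a tibble with a `significance` factor column
#'   (levels `Up`, `Down`, `NS`).
#' @examples
#' classify_significance(gen_de_results(n_genes = 50))
#' @export
classify_significance <- function(data, padj_max = 0.1, lfc_min = 1,
                                  lfc_unit = c("log2", "fcu")) {
  lfc_unit <- match.arg(lfc_unit)
  t <- as_results_table(data)
  if (all(is.na(t$padj))) {
    warn("no adjusted p-values available; falling back to raw p-values")
    t$padj <- t$pvalue
  }
  eff <- if (lfc_unit == "log2") t$log2fc else
    fold_change_units(t$fc, policy = "propagate")
  sig <- !is.na(t$padj) & t$padj < padj_max & !is.na(eff)
  cls <- dplyr::case_when(
    sig & eff > lfc_min ~ "Up",
    sig & eff < -lfc_min ~ "Down",
    .default = "NS"
  )
  t$significance <- factor(cls, levels = c("Up", "Down", "NS"))
  t
}

# Shared axis helper: ticks for a display-space data range.
spec_ticks <- function(disp, scale, max_ticks, style) {
  rng <- range(disp, na.rm = TRUE)
  if (!all(is.finite(rng))) abort("no finite display positions",
                                  class = "madfc_domain_error")
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  fc_scale_ticks(rng[1], rng[2], scale, max_ticks, style)
}

fc_axis_label <- function(scale) {
  switch(scale, madfc = "fold change (MAD scale)",
         log2 = "fold change (log2 scale)", linear = "fold change")
}

#' Volcano plot under a linear, log2, or MAD fold-change scale
#'
#' Scatter of -log10 p-value against the chosen display transform of fold
#' change, with features colored by significance class (Up red, Down blue,
#' NS black). MAD and log2 axes carry back-transformed fold-change tick
#' labels, never raw transform coordinates.
#'
#' @inheritParams classify_significance
#' @param scale Display scale: `"madfc"` (default), `"log2"`, `"linear"`.
#' @param style Tick label style (see [format_fc_label()]).
#' @param max_ticks Maximum number of fold-change axis ticks.
#' @return A `madfc_plot`; its spec carries `point_positions` (display x),
#'   `neg_log10_p`, `class_labels`, and `tick_spec`.
#' @examples
#' plot_volcano(gen_de_results(n_genes = 200))
#' @export
plot_volcano <- function(data, scale = c("madfc", "log2", "linear"),
                         padj_max = 0.1, lfc_min = 1,
                         lfc_unit = c("log2", "fcu"),
                         style = "fraction", max_ticks = 7) {
  scale <- match.arg(scale)
  if (!nrow(data)) abort("results table is empty",
                         class = "madfc_config_error")
  t <- classify_significance(data, padj_max, lfc_min, lfc_unit)
  x <- fc_display(t$fc, scale, policy = "propagate")
  if (all(is.na(x))) {
    abort("no fold change is in the transform's domain",
          class = "madfc_domain_error")
  }
  y <- -log10(t$pvalue)
  ticks <- spec_ticks(x, scale, max_ticks, style)
  df <- tibble(x = x, y = y, significance = t$significance)
  gg <- ggplot2::ggplot(df[!is.na(df$x), ],
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$significance)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = sig_palette, drop = FALSE) +
    ggplot2::scale_x_continuous(breaks = ticks$position,
                                labels = ticks$label) +
    ggplot2::labs(x = fc_axis_label(scale), y = "-log10 p-value",
                  colour = NULL) +
    ggplot2::theme_minimal()
  new_madfc_plot(gg, list(
    scale_name = scale, point_positions = x, neg_log10_p = y,
    class_labels = as.character(t$significance), tick_spec = ticks
  ), "volcano")
}

#' MA plot under a linear, log2, or MAD fold-change scale
#'
#' Bland-Altman-style scatter of the display transform of fold change
#' against log10 mean abundance. Zero base means are placed at the
#' pseudocount position.
#'
#' @inheritParams plot_volcano
#' @param pseudocount Added to `base_mean` before the log10 x-axis
#'   (default 0.5), so zero-count features remain plottable.
#' @return A `madfc_plot`; its spec carries `point_positions` (display y),
#'   `mean_positions` (log10 mean), `class_labels`, and `tick_spec`.
#' @examples
#' plot_ma(gen_de_results(n_genes = 200))
#' @export
plot_ma <- function(data, scale = c("madfc", "log2", "linear"),
                    padj_max = 0.1, lfc_min = 1,
                    lfc_unit = c("log2", "fcu"), pseudocount = 0.5,
                    style = "fraction", max_ticks = 7) {
  scale <- match.arg(scale)
  t <- classify_significance(data, padj_max, lfc_min, lfc_unit)
  if (all(is.na(t$base_mean))) {
    abort("MA plot requires a base_mean column",
          class = "madfc_config_error")
  }
  y <- fc_display(t$fc, scale, policy = "propagate")
  x <- log10(t$base_mean + pseudocount)
  ticks <- spec_ticks(y, scale, max_ticks, style)
  df <- tibble(x = x, y = y, significance = t$significance)
  gg <- ggplot2::ggplot(df[!is.na(df$y), ],
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$significance)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = sig_palette, drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = ticks$position,
                                labels = ticks$label) +
    ggplot2::labs(x = "log10 mean abundance", y = fc_axis_label(scale),
                  colour = NULL) +
    ggplot2::theme_minimal()
  new_madfc_plot(gg, list(
    scale_name = scale, point_positions = y, mean_positions = x,
    class_labels = as.character(t$significance), tick_spec = ticks
  ), "ma")
}

#' Interval-estimate plot with endpoints transformed, never widths
#'
#' Renders one point estimate with an interval per group. Interval
#' endpoints are transformed to display space individually (the
#' transform-the-endpoints rule); widths are never transformed as lengths.
#' Under the MAD scale a group whose interval spans `±h` fold-change units
#' around its center renders with display half-width exactly `h`, for every
#' group, which is what makes identical-dispersion fixtures visibly
#' identical.
#'
#' @param groups A data frame with one row per group: either `center_fc`
#'   plus `half_width_fcu`, or explicit `lower_fc`/`upper_fc` endpoints
#'   (plus `center_fc`). An optional `group` column labels the x-axis.
#' @inheritParams plot_volcano
#' @return A `madfc_plot`; its spec carries `center_positions`,
#'   `lower_positions`, `upper_positions`, and `tick_spec`.
#' @examples
#' plot_interval(gen_interval_groups(), scale = "madfc")
#' @export
plot_interval <- function(groups, scale = c("madfc", "log2", "linear"),
                          style = "fraction", max_ticks = 7) {
  scale <- match.arg(scale)
  g <- as_tibble(groups)
  if (!nrow(g)) abort("no interval groups", class = "madfc_config_error")
  if (!"center_fc" %in% names(g)) {
    abort("interval groups need a center_fc column",
          class = "madfc_config_error")
  }
  if (!all(c("lower_fc", "upper_fc") %in% names(g))) {
    if (!"half_width_fcu" %in% names(g)) {
      abort("supply either lower_fc/upper_fc or half_width_fcu",
            class = "madfc_config_error")
    }
    c_fcu <- madfc_forward(g$center_fc, policy = "propagate")
    g$lower_fc <- madfc_inverse(c_fcu - g$half_width_fcu)
    g$upper_fc <- madfc_inverse(c_fcu + g$half_width_fcu)
  }
  bad <- !is.na(g$lower_fc) & !is.na(g$upper_fc) &
    !(g$lower_fc < g$center_fc & g$center_fc < g$upper_fc) &
    (g$lower_fc != g$upper_fc)
  if (any(bad)) {
    abort("interval endpoints must bracket the center",
          class = "madfc_config_error")
  }
  if (!"group" %in% names(g)) g$group <- factor(seq_len(nrow(g)))
  center <- fc_display(g$center_fc, scale, policy = "propagate")
  lower <- fc_display(g$lower_fc, scale, policy = "propagate")
  upper <- fc_display(g$upper_fc, scale, policy = "propagate")
  ticks <- spec_ticks(c(lower, upper, center), scale, max_ticks, style)
  df <- tibble(group = g$group, y = center, ymin = lower, ymax = upper)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$y,
                                         ymin = .data$ymin,
                                         ymax = .data$ymax,
                                         colour = .data$group)) +
    ggplot2::geom_pointrange(show.legend = FALSE) +
    ggplot2::scale_y_continuous(breaks = ticks$position,
                                labels = ticks$label) +
    ggplot2::labs(x = "group", y = fc_axis_label(scale)) +
    ggplot2::theme_minimal()
  new_madfc_plot(gg, list(
    scale_name = scale, center_positions = center,
    lower_positions = lower, upper_positions = upper, tick_spec = ticks
  ), "interval")
}

# Display-space box geometry: quartiles on raw fold changes (monotone
# transforms commute with order-statistic quantiles), Tukey 1.5 IQR
# whiskers computed in display space.
box_geometry <- function(fc, scale) {
  q_raw <- quantile(fc, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
  disp <- fc_display(fc, scale, policy = "propagate")
  qd <- fc_display(q_raw, scale, policy = "propagate")
  iqr <- qd[3] - qd[1]
  in_lo <- disp[!is.na(disp) & disp >= qd[1] - 1.5 * iqr]
  in_hi <- disp[!is.na(disp) & disp <= qd[3] + 1.5 * iqr]
  tibble(lower = qd[1], middle = qd[2], upper = qd[3],
         ymin = min(in_lo), ymax = max(in_hi))
}

#' Box plots of per-group fold changes
#'
#' Quartiles are computed on the raw fold changes and then transformed for
#' display (equivalently, computed in display space: monotone transforms
#' commute with order-statistic quantiles). Whiskers follow the Tukey
#' 1.5 IQR rule evaluated in display space, matching mainstream boxplot
#' defaults. Under MAD the per-group boxes of the identical-dispersion
#' fixture are symmetric and equally sized; under log2/linear they distort.
#'
#' @param samples A long data frame with columns `group` and `fc`
#'   (each group needs at least 5 values).
#' @inheritParams plot_volcano
#' @return A `madfc_plot`; its spec carries `summary_geometry` (per-group
#'   `lower`, `middle`, `upper`, `ymin`, `ymax` in display coordinates)
#'   and `tick_spec`.
#' @examples
#' plot_box(gen_box_groups(medians_fcu = c(-2, 0, 2)))
#' @export
plot_box <- function(samples, scale = c("madfc", "log2", "linear"),
                     style = "fraction", max_ticks = 7) {
  scale <- match.arg(scale)
  s <- as_tibble(samples)
  stopifnot(all(c("group", "fc") %in% names(s)))
  sizes <- table(s$group[!is.na(s$fc)])
  if (any(sizes < 5)) {
    abort("each box group needs at least 5 fold changes",
          class = "madfc_config_error")
  }
  geom <- s |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(box_geometry(.data$fc, scale))
  ticks <- spec_ticks(c(geom$ymin, geom$ymax), scale, max_ticks, style)
  gg <- ggplot2::ggplot(geom, ggplot2::aes(x = .data$group,
                                           fill = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$ymin, lower = .data$lower,
                   middle = .data$middle, upper = .data$upper,
                   ymax = .data$ymax),
      stat = "identity", show.legend = FALSE) +
    ggplot2::scale_y_continuous(breaks = ticks$position,
                                labels = ticks$label) +
    ggplot2::labs(x = "group", y = fc_axis_label(scale)) +
    ggplot2::theme_minimal()
  new_madfc_plot(gg, list(
    scale_name = scale, summary_geometry = geom, tick_spec = ticks
  ), "box")
}

#' Violin plots of per-group fold changes
#'
#' Kernel densities are estimated in display space (densities, unlike
#' quantiles, do not commute with monotone transforms): Gaussian kernel,
#' Scott's bandwidth rule, a 256-point grid extending 3 bandwidths past the
#' data. Under MAD, groups that differ only by a translation in fold-change
#' units produce identical density shapes.
#'
#' @param samples A long data frame with columns `group` and `fc`
#'   (each group needs at least 10 values).
#' @inheritParams plot_volcano
#' @param n_grid Number of density grid points (default 256).
#' @return A `madfc_plot`; its spec carries `summary_geometry` (per-group
#'   grid `y` and `density` in display coordinates) and `tick_spec`.
#' @examples
#' plot_violin(gen_violin_groups(centers_fcu = c(-2, 2), n = 50))
#' @export
plot_violin <- function(samples, scale = c("madfc", "log2", "linear"),
                        style = "fraction", max_ticks = 7, n_grid = 256) {
  scale <- match.arg(scale)
  s <- as_tibble(samples)
  stopifnot(all(c("group", "fc") %in% names(s)))
  sizes <- table(s$group[!is.na(s$fc)])
  if (any(sizes < 10)) {
    abort("each violin group needs at least 10 fold changes",
          class = "madfc_config_error")
  }
  geom <- s |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe({
      disp <- fc_display(.data$fc, scale, policy = "propagate")
      disp <- disp[is.finite(disp)]
      d <- density(disp, bw = stats::bw.nrd(disp), n = n_grid, cut = 3)
      tibble(y = d$x, density = d$y)
    })
  ticks <- spec_ticks(geom$y, scale, max_ticks, style)
  poly <- geom |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe({
      gx <- as.numeric(.data$group[1])
      w <- 0.4 * .data$density / max(.data$density)
      yy <- .data$y
      tibble(x = c(gx - w, rev(gx + w)), y = c(yy, rev(yy)))
    })
  gg <- ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y,
                                           group = .data$group,
                                           fill = .data$group)) +
    ggplot2::geom_polygon(show.legend = FALSE, alpha = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq_along(levels(s$group)),
                                labels = levels(s$group)) +
    ggplot2::scale_y_continuous(breaks = ticks$position,
                                labels = ticks$label) +
    ggplot2::labs(x = "group", y = fc_axis_label(scale)) +
    ggplot2::theme_minimal()
  new_madfc_plot(gg, list(
    scale_name = scale, summary_geometry = geom, tick_spec = ticks
  ), "violin")
}

#' Fold-change heatmap with a transform-aware diverging color scale
#'
#' Cell colors come from a diverging palette applied to
#' [normalize_fc()] of each cell, so the color spacing follows the chosen
#' transform (under a symmetric MAD spec, equal fold-change-unit steps get
#' equal color steps and fold change 1 sits at the palette midpoint). The
#' colorbar ticks are placed by the MAD tick algebra and labelled with raw
#' fold changes.
#'
#' @param mat A numeric matrix of raw fold changes (features x groups),
#'   with optional dimnames, or a long data frame with columns `row`,
#'   `col`, `fc`.
#' @param spec A [color_norm_spec()]; default is data-driven symmetric MAD
#'   bounds at the largest observed magnitude in fold-change units.
#' @inheritParams plot_volcano
#' @return A `madfc_plot`; its spec carries `normalized` (long tibble of
#'   `row`, `col`, `fc`, `value` in `[0, 1]`) and `tick_spec` for the
#'   colorbar.
#' @examples
#' m <- matrix(c(1/4, 1, 2, 4), 2, dimnames = list(c("a", "b"), c("g1", "g2")))
#' plot_heatmap(m)
#' @export
plot_heatmap <- function(mat, spec = NULL, style = "fraction",
                         max_ticks = 7) {
  if (is.matrix(mat)) {
    long <- tibble(
      row = factor(rep(rownames(mat) %||% seq_len(nrow(mat)),
                       times = ncol(mat)),
                   levels = rev(rownames(mat) %||% seq_len(nrow(mat)))),
      col = factor(rep(colnames(mat) %||% seq_len(ncol(mat)),
                       each = nrow(mat)),
                   levels = colnames(mat) %||% seq_len(ncol(mat))),
      fc = as.numeric(mat)
    )
  } else {
    long <- as_tibble(mat)
    stopifnot(all(c("row", "col", "fc") %in% names(long)))
  }
  spec <- spec %||% color_norm_spec_from_data(long$fc)
  long$value <- normalize_fc(long$fc, spec)
  lo_d <- fc_display(spec$vmin_fc, spec$transform)
  hi_d <- fc_display(spec$vmax_fc, spec$transform)
  if (spec$symmetric) {
    noc <- if (spec$transform == "linear") 1 else 0
    half <- max(abs(lo_d - noc), abs(hi_d - noc))
    lo_d <- noc - half
    hi_d <- noc + half
  }
  ticks <- fc_scale_ticks(lo_d, hi_d, spec$transform, max_ticks, style)
  tick_norm <- normalize_fc(ticks$fc, spec)
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$col, .data$row,
                                           fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("#2166AC", "white", "#B2182B"), limits = c(0, 1),
      breaks = tick_norm, labels = ticks$label, na.value = "grey70",
      name = "fold change") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  new_madfc_plot(gg, list(
    scale_name = spec$transform, normalized = long, tick_spec = ticks
  ), "heatmap")
}
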