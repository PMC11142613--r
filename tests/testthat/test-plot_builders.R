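test_that("significance classification follows the two-criterion rule", {
  t <- tibble::tibble(
    log2fc = c(2, 0, 3, -2, 1.5),
    pvalue = c(1e-5, 1e-5, 0.4, 1e-4, 1e-4),
    padj = c(0.05, 0.05, 0.5, 0.01, NA)
  )
  cls <- classify_significance(t)$significance
  expect_identical(as.character(cls), c("Up", "NS", "NS", "Down", "NS"))
  # scale choice never affects classification
  d <- gen_de_results(n_genes = 300, seed = 2)
  specs <- lapply(c("linear", "log2", "madfc"), function(s)
    plot_spec(plot_volcano(d, scale = s))$class_labels)
  expect_identical(specs[[1]], specs[[2]])
  expect_identical(specs[[2]], specs[[3]])
})

test_that("missing padj falls back to pvalue with a warning", {
  t <- tibble::tibble(log2fc = c(3, 0), pvalue = c(1e-6, 0.9))
  expect_warning(out <- classify_significance(t), "adjusted p")
  expect_identical(as.character(out$significance), c("Up", "NS"))
})

test_that("the fcu threshold reading is available", {
  # log2fc = 1.2 passes |log2fc| > 1 but FCU = 2^1.2 - 1 = 1.30 also > 1;
  # log2fc = 0.8 fails log2 but FCU = 0.74 < 1 fails too; use 0.95:
  # FCU = 2^0.95 - 1 = 0.93 < 1 (NS in fcu units), |log2fc| < 1 (NS) — so
  # separate with lfc_min = 0.9: log2 reading Up, fcu reading NS.
  t <- tibble::tibble(log2fc = 0.95, pvalue = 1e-6, padj = 1e-6)
  up_log2 <- classify_significance(t, lfc_min = 0.9)$significance
  up_fcu <- classify_significance(t, lfc_min = 0.95,
                                  lfc_unit = "fcu")$significance
  expect_identical(as.character(up_log2), "Up")
  expect_identical(as.character(up_fcu), "NS")
})

test_that("volcano positions are the chosen transform of fold change", {
  t <- toy_results()
  expect_equal(plot_spec(plot_volcano(t, "madfc"))$point_positions,
               c(3, -3, 0))
  expect_equal(plot_spec(plot_volcano(t, "log2"))$point_positions,
               c(2, -2, 0))
  expect_equal(plot_spec(plot_volcano(t, "linear"))$point_positions,
               c(4, 0.25, 1))
  expect_error(plot_volcano(t[0, ]), class = "madfc_config_error")
  bad <- tibble::tibble(fc = c(-1, 0), pvalue = c(0.1, 0.1),
                        padj = c(0.5, 0.5))
  expect_error(plot_volcano(bad), class = "madfc_domain_error")
})

test_that("MA plots mirror volcano on the y-axis and place zero means", {
  t <- toy_results()
  sp <- plot_spec(plot_ma(t, "madfc"))
  expect_equal(sp$point_positions, c(3, -3, 0))
  expect_equal(sp$mean_positions, log10(c(100.5, 50.5, 0.5)))
  tk <- sp$tick_spec
  expect_true(all(diff(tk$position) > 0))
  expect_equal(madfc_forward(parse_fc_label(tk$label)), tk$position,
               tolerance = 1e-9)
  no_mean <- tibble::tibble(fc = 2, pvalue = 0.1, padj = 0.5)
  expect_error(plot_ma(no_mean), class = "madfc_config_error")
})

test_that("interval endpoints transform, widths are preserved under MAD", {
  g <- gen_interval_groups()
  sp <- plot_spec(plot_interval(g, "madfc"))
  widths <- sp$upper_positions - sp$lower_positions
  expect_equal(stats::sd(widths), 0, tolerance = 1e-9)
  expect_equal(widths[1], 4)
  expect_equal(sp$upper_positions - sp$center_positions, rep(2, 11))
  # a single group centered at FC 4 with half-width 2 spans display [1, 5]
  one <- tibble::tibble(center_fc = 4, half_width_fcu = 2)
  sp1 <- plot_spec(plot_interval(one, "madfc"))
  expect_equal(c(sp1$lower_positions, sp1$upper_positions), c(1, 5))
  # centered at no change: symmetric about 0 under MAD, asymmetric linear
  noc <- tibble::tibble(center_fc = 1, half_width_fcu = 2)
  spm <- plot_spec(plot_interval(noc, "madfc"))
  expect_equal(c(spm$lower_positions, spm$upper_positions), c(-2, 2))
  spl <- plot_spec(plot_interval(noc, "linear"))
  expect_equal(c(spl$lower_positions, spl$upper_positions), c(1/3, 3))
})

test_that("box quartiles commute with monotone display transforms", {
  set.seed(9)
  fc <- exp(stats::rnorm(101, 0, 1.2))
  s <- tibble::tibble(group = factor(1), fc = fc)
  for (scale in c("linear", "log2", "madfc")) {
    geom <- plot_spec(plot_box(s, scale))$summary_geometry
    direct <- stats::quantile(
      madfc:::fc_display(fc, scale), c(0.25, 0.5, 0.75), type = 7)
    expect_equal(unname(unlist(geom[c("lower", "middle", "upper")])),
                 unname(direct), tolerance = 1e-9, info = scale)
  }
})

test_that("box fixture geometry is exact under MAD and distorted under log2", {
  b <- gen_box_groups(medians_fcu = c(-4, 0, 4))
  gm <- plot_spec(plot_box(b, "madfc"))$summary_geometry
  expect_equal(gm$upper - gm$middle, rep(2, 3))
  expect_equal(gm$middle - gm$lower, rep(2, 3))
  gl <- plot_spec(plot_box(b, "log2"))$summary_geometry
  expect_gt(max(abs((gl$upper - gl$middle) - (gl$middle - gl$lower))), 0.1)
  # degenerate: one value repeated gives a zero-height box at its transform
  flat <- tibble::tibble(group = factor(1), fc = rep(3, 8))
  gf <- plot_spec(plot_box(flat, "madfc"))$summary_geometry
  expect_equal(unname(unlist(gf[c("lower", "middle", "upper",
                                  "ymin", "ymax")])), rep(2, 5))
  expect_error(plot_box(tibble::tibble(group = factor(1), fc = c(1, 2))),
               class = "madfc_config_error")
})

test_that("violin densities are translation-equal under MAD only", {
  v <- gen_violin_groups(centers_fcu = c(-3, 2), n = 150, seed = 5)
  gm <- plot_spec(plot_violin(v, "madfc"))$summary_geometry
  d1 <- gm[gm$group == 1, ]
  d2 <- gm[gm$group == 2, ]
  expect_equal(d1$y + 5, d2$y, tolerance = 1e-9)
  expect_lt(max(abs(d1$density - d2$density)), 0.02 * max(d1$density))
  gl <- plot_spec(plot_violin(v, "linear"))$summary_geometry
  l1 <- gl[gl$group == 1, ]
  l2 <- gl[gl$group == 2, ]
  expect_gt(max(abs(l1$density - l2$density)), 0.1 * max(l1$density))
  expect_error(
    plot_violin(tibble::tibble(group = factor(1), fc = rep(2, 3))),
    class = "madfc_config_error")
})

test_that("heatmap cells follow the color normalization and tick invariants", {
  m <- matrix(c(1, 1, 1, 1), 2)
  sp <- plot_spec(plot_heatmap(m))
  expect_true(all(sp$normalized$value == 0.5))
  spec <- color_norm_spec("madfc", 1/5, 5)
  m2 <- matrix(c(1/4, 5, 4, 1), 2)
  sp2 <- plot_spec(plot_heatmap(m2, spec))
  expect_equal(sp2$normalized$value[sp2$normalized$fc == 5], 1)
  long <- sp2$normalized
  expect_equal(long$value[long$fc == 4] + long$value[long$fc == 1/4], 1)
  tk <- sp2$tick_spec
  expect_equal(madfc_forward(parse_fc_label(tk$label)), tk$position,
               tolerance = 1e-9)
})

test_that("plot objects print, autoplot, and serialize", {
  p <- plot_interval(gen_interval_groups())
  expect_s3_class(autoplot(p), "ggplot")
  js <- spec_json(p)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(parsed$type, "interval")
  expect_equal(parsed$center_positions, -5:5)
  f <- tempfile(fileext = ".json")
  spec_json(p, f)
  expect_true(file.exists(f))
  unlink(f)
})
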