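test_that("label formatting covers fraction, decimal, and exponent styles", {
  expect_identical(format_fc_label(c(1/6, 1/3, 1, 2, 6), "fraction"),
                   c("1/6", "1/3", "1", "2", "6"))
  expect_identical(format_fc_label(1, "decimal"), "1")
  expect_identical(format_fc_label(0.4, "fraction"), "0.4")
  expect_identical(format_fc_label(c(1/4, 8), "exponent"),
                   c("2^-2", "2^3"))
  expect_identical(format_fc_label(3, "exponent"), "3")
  expect_error(format_fc_label(-1), class = "madfc_domain_error")
})

test_that("label parsing inverts every formatting style", {
  fcs <- c(1/6, 1/3, 1, 2.5, 4, 8)
  for (style in c("fraction", "decimal", "exponent")) {
    expect_equal(parse_fc_label(format_fc_label(fcs, style)), fcs,
                 tolerance = 1e-9, info = style)
  }
})

test_that("full-range ticks sit at integer FCU with back-transformed labels", {
  tk <- madfc_ticks(-5, 5, max_ticks = 11, style = "fraction")
  expect_identical(tk$position, as.numeric(-5:5))
  expect_identical(tk$label,
                   c("1/6", "1/5", "1/4", "1/3", "1/2", "1",
                     "2", "3", "4", "5", "6"))
  expect_identical(attr(tk, "anchor_index"), 6L)
})

test_that("tick thinning keeps the point-of-no-change tick", {
  tk <- madfc_ticks(-5, 5, max_ticks = 5)
  expect_identical(tk$position, c(-4, -2, 0, 2, 4))
  tk7 <- madfc_ticks(-9.5, 9.5, max_ticks = 7)
  expect_true(0 %in% tk7$position)
  expect_lte(nrow(tk7), 7)
  expect_true(all(diff(tk7$position) > 0))
})

test_that("sub-unit ranges fall back to evenly spaced decimal ticks", {
  tk <- madfc_ticks(-0.5, 0.5, max_ticks = 5, style = "decimal")
  expect_identical(nrow(tk), 5L)
  expect_true(any(tk$position == 0 & tk$label == "1"))
  expect_error(madfc_ticks(2, 2), class = "madfc_range_error")
})

test_that("tick labels read back to their positions (readability contract)", {
  for (tk in list(madfc_ticks(-5, 5, 11), madfc_ticks(-0.7, 0.9, 5),
                  madfc_ticks(-12, 30, 9))) {
    readback <- madfc_forward(parse_fc_label(tk$label))
    expect_equal(readback, tk$position, tolerance = 1e-9)
    # equal spacing of consecutive integer-FCU ticks
    if (nrow(tk) > 2 && all(tk$position == round(tk$position))) {
      expect_equal(stats::sd(diff(tk$position)), 0)
    }
  }
})

test_that("mirror tick pairs carry reciprocal labels", {
  tk <- madfc_ticks(-5, 5, 11)
  for (k in 1:5) {
    up <- tk$fc[tk$position == k]
    down <- tk$fc[tk$position == -k]
    expect_equal(up * down, 1)
  }
})

test_that("the ggplot2 madfc transform round-trips and labels raw fold change", {
  tr <- madfc_trans(max_ticks = 11)
  expect_identical(tr$name, "madfc")
  x <- c(1/6, 1/2, 1, 3, 6)
  expect_equal(tr$transform(x), fold_change_units(x))
  expect_equal(tr$inverse(tr$transform(x)), x, tolerance = 1e-12)
  expect_true(is.na(tr$transform(-2)))
  # default formatter emits back-transformed labels, never raw coordinates
  brks <- tr$breaks(c(1/6, 6))
  expect_equal(sort(brks), sort(madfc_inverse(-5:5)), tolerance = 1e-12)
  expect_identical(tr$format(c(1/6, 6)), c("1/6", "6"))
  # idempotent re-creation
  tr2 <- madfc_trans()
  expect_identical(tr2$transform(x), tr$transform(x))
})

test_that("madfc position scales attach to a ggplot and set labelled breaks", {
  df <- data.frame(fc = c(1/6, 1, 6), y = 1:3)
  p <- ggplot2::ggplot(df, ggplot2::aes(fc, y)) + ggplot2::geom_point() +
    scale_x_madfc(max_ticks = 11)
  b <- ggplot2::ggplot_build(p)
  labs <- b$layout$panel_params[[1]]$x$get_labels()
  expect_true(all(c("1/6", "1", "6") %in% labs))
  # display coordinates span [-5, 5] in transform space
  expect_equal(range(b$data[[1]]$x), c(-5, 5))
})
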