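test_that("proportionality residuals separate the three canonical transforms", {
  pr_mad <- assess_proportionality(fc_transform("madfc"))
  expect_equal(pr_mad$max_residual, c(0, 0), tolerance = 1e-12)
  pr_lin <- assess_proportionality(fc_transform("linear"))
  expect_equal(pr_lin$max_residual[pr_lin$branch == "positive"], 0,
               tolerance = 1e-12)
  expect_gt(pr_lin$max_residual[pr_lin$branch == "negative"], 0.1)
  pr_log <- assess_proportionality(fc_transform("log2"))
  expect_true(all(pr_log$max_residual > 0.1))
})

test_that("symmetry deviation is zero for madfc/log2 and large for linear", {
  expect_equal(assess_symmetry(fc_transform("madfc")), 0, tolerance = 1e-12)
  expect_equal(assess_symmetry(fc_transform("log2")), 0, tolerance = 1e-12)
  expect_gt(assess_symmetry(fc_transform("linear")), 0.1)
  expect_error(assess_symmetry(fc_transform("madfc"), magnitudes = c(0.5)),
               class = "madfc_config_error")
})

test_that("dynamic range under the default pixel budget orders log2 above linear", {
  k_lin <- estimate_dynamic_range(fc_transform("linear"))
  k_log <- estimate_dynamic_range(fc_transform("log2"))
  k_mad <- estimate_dynamic_range(fc_transform("madfc"))
  expect_identical(k_lin, 8L)
  expect_gt(k_log, k_lin)
  expect_lte(abs(k_mad - k_lin), 1)
  # closed-form oracle for the linear scale: the tightest gap is the first
  # ladder rung, so k is the largest k with (2^k - 1) <= axis_px / gap_px
  expect_identical(k_lin, max(which(2^(1:12) - 1 <= 300)))
})

test_that("audit reproduces the canonical verdict pattern", {
  a <- audit_fc_transforms()
  row <- function(tr) a[a$transform == tr, ]
  expect_false(row("linear")$symmetric)
  expect_true(row("log2")$symmetric)
  expect_true(row("madfc")$symmetric)
  expect_true(row("linear")$proportional_pos)
  expect_false(row("linear")$proportional_neg)
  expect_false(row("log2")$proportional_pos)
  expect_false(row("log2")$proportional_neg)
  expect_true(row("madfc")$proportional)
  expect_gt(row("log2")$dynamic_range_log2, row("linear")$dynamic_range_log2)
  # readability is a label contract, not a numeric score
  expect_false(any(grepl("readab", names(a), ignore.case = TRUE)))
})

test_that("scores are invariant to affine rescaling of the display transform", {
  scaled <- fc_transform("madfc2", forward = function(x)
    7 * madfc_forward(x, "propagate") + 3)
  expect_equal(assess_symmetry(scaled), 0, tolerance = 1e-12)
  expect_equal(assess_proportionality(scaled)$max_residual, c(0, 0),
               tolerance = 1e-12)
  expect_identical(estimate_dynamic_range(scaled),
                   estimate_dynamic_range(fc_transform("madfc")))
})

test_that("degenerate transforms are handled", {
  # identity transform on raw fold change is just the linear scale
  ident <- fc_transform("identity", forward = function(x) x,
                        point_of_no_change = 1)
  expect_gt(assess_symmetry(ident), 0.1)
  # a constant transform violates the monotonicity precondition
  expect_error(fc_transform("const", forward = function(x) rep(1, length(x))),
               class = "madfc_config_error")
})

test_that("tidy and glance summarize the audit", {
  a <- audit_fc_transforms()
  td <- tidy(a)
  expect_identical(nrow(td), 12L)
  expect_true(all(c("transform", "property", "score", "pass") %in% names(td)))
  expect_true(all(is.na(td$pass[td$property == "dynamic_range_log2"])))
  g <- glance(a)
  expect_identical(g$n_transforms, 3L)
  expect_identical(g$axis_px, 600)
})
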