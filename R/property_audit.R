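# Property audit: score any candidate fold-change display transform on
# proportionality (display distance from the point of no change linear in
# fold-change units, per direction), symmetry (reciprocal pairs equidistant
# from the point of no change), and pixel-budget dynamic range (how far up
# the dyadic ladder adjacent rungs stay visually separable). Readability is
# a label-semantics contract carried by the axis scale, not a numeric score,
# so it deliberately has no column here.

#' Describe a fold-change display transform for auditing
#'
#' Wraps a display transform so the audit functions can probe it: its name,
#' the forward map from raw fold change to display coordinate, and the
#' display value of the point of no change (fold change 1). The built-in
#' names `"linear"`, `"log2"`, and `"madfc"` need no other arguments; pass
#' `forward` and `point_of_no_change` to audit a custom transform.
#'
#' @param name Transform name; one of the built-ins, or any string when
#'   `forward` is supplied.
#' @param forward Optional function mapping positive fold changes to display
#'   coordinates; must be strictly increasing.
#' @param point_of_no_change Display coordinate of fold change 1; defaults
#'   to `forward(1)`.
#' @return An object of class `fc_transform`.
#' @examples
#' fc_transform("madfc")
#' fc_transform("sqrt", forward = sqrt)
#' @export
fc_transform <- function(name, forward = NULL, point_of_no_change = NULL) {
  if (is.null(forward)) {
    name <- match.arg(name, c("linear", "log2", "madfc"))
    forward <- switch(name,
      linear = function(x) check_fc_domain(x, "propagate"),
      log2 = function(x) fc_to_log2(x, "propagate"),
      madfc = function(x) madfc_forward(x, "propagate")
    )
    point_of_no_change <- if (name == "linear") 1 else 0
  }
  point_of_no_change <- point_of_no_change %||% forward(1)
  probe <- forward(2^seq(-4, 4, by = 0.5))
  if (any(diff(probe) <= 0)) {
    abort("forward must be strictly increasing on positive fold changes",
          class = "madfc_config_error")
  }
  structure(list(name = name, forward = forward,
                 point_of_no_change = point_of_no_change),
            class = "fc_transform")
}

#' @export
print.fc_transform <- function(x, ...) {
  cat(sprintf("<fc_transform> %s (no-change display value %g)\n",
              x$name, x$point_of_no_change))
  invisible(x)
}

#' Proportionality residuals of a display transform
#'
#' For each fold-change direction, draws the line from the point of no
#' change to the most extreme probe (in fold-change units vs display
#' coordinate) and measures the largest deviation of the remaining probes
#' from that line, normalized by the branch's display span. A transform is
#' proportional in a direction when the residual is (numerically) zero: all
#' probes fall on the line. The slopes of the two branches need not match —
#' that is symmetry's job.
#'
#' @param t An [fc_transform()].
#' @param probe_fcs Raw fold changes to probe; needs at least 3 on each side
#'   of 1. Default is the integer fold-change-unit grid from -5 to 5
#'   (fold changes 1/6 to 6).
#' @return A tibble with `branch` (`"positive"`/`"negative"`) and
#'   `max_residual` (normalized display units).
#' @examples
#' assess_proportionality(fc_transform("madfc"))
#' assess_proportionality(fc_transform("log2"))
#' @export
assess_proportionality <- function(t, probe_fcs = gen_fcu_span()) {
  stopifnot(inherits(t, "fc_transform"))
  probe_fcs <- check_fc_domain(probe_fcs, "strict", what = "probe fold change")
  branch_residual <- function(fcs) {
    if (length(fcs) < 3) {
      abort("need at least 3 probe fold changes on each side of 1",
            class = "madfc_config_error")
    }
    u <- fold_change_units(fcs)
    d <- t$forward(fcs)
    extreme <- which.max(abs(u))
    span <- abs(d[extreme] - t$point_of_no_change)
    slope <- (d[extreme] - t$point_of_no_change) / u[extreme]
    line <- t$point_of_no_change + slope * u
    max(abs(d - line)) / span
  }
  tibble(
    branch = c("positive", "negative"),
    max_residual = c(branch_residual(probe_fcs[probe_fcs > 1]),
                     branch_residual(probe_fcs[probe_fcs < 1]))
  )
}

#' Symmetry deviation of a display transform
#'
#' For each fold-change magnitude `m > 1`, compares the display distance of
#' `m` and of `1/m` from the point of no change; the score is the largest
#' absolute difference, normalized by the display span of the probe set. A
#' symmetric transform (MAD, log2) scores zero; the linear scale does not,
#' because sub-unit fold changes are compressed into (0, 1).
#'
#' @inheritParams assess_proportionality
#' @param magnitudes Fold-change magnitudes, all `> 1`.
#' @return The maximum normalized deviation (scalar).
#' @examples
#' assess_symmetry(fc_transform("linear"))
#' @export
assess_symmetry <- function(t, magnitudes = 2:6) {
  stopifnot(inherits(t, "fc_transform"))
  if (any(magnitudes <= 1)) {
    abort("magnitudes must all exceed 1", class = "madfc_config_error")
  }
  up <- t$forward(magnitudes)
  down <- t$forward(1 / magnitudes)
  span <- max(c(up, down)) - min(c(up, down))
  max(abs(abs(up - t$point_of_no_change) -
            abs(down - t$point_of_no_change))) / span
}

#' Pixel-budget dynamic range of a display transform
#'
#' Maps the dyadic ladder `2^0, 2^1, ..., 2^k` onto an axis of `axis_px`
#' pixels (linear rescaling of the display coordinates) and finds the
#' largest `k` for which every adjacent rung pair remains at least
#' `min_gap_px` pixels apart. Reported in log2 units: the number of
#' doublings the scale keeps visually separable within the pixel budget.
#' The search is capped at `axis_px / min_gap_px`, the budget's own limit.
#'
#' @inheritParams assess_proportionality
#' @param axis_px Axis length in pixels (default 600).
#' @param min_gap_px Minimum separable gap in pixels (default 2).
#' @return Largest separable `k`, in log2 units (integer).
#' @examples
#' estimate_dynamic_range(fc_transform("linear"))
#' @export
estimate_dynamic_range <- function(t, axis_px = 600, min_gap_px = 2) {
  stopifnot(inherits(t, "fc_transform"))
  if (!(axis_px > min_gap_px && min_gap_px > 0)) {
    abort("need axis_px > min_gap_px > 0", class = "madfc_config_error")
  }
  cap <- floor(axis_px / min_gap_px)
  best <- 0L
  for (k in seq_len(cap)) {
    d <- t$forward(2^(0:k))
    px <- (d - d[1]) / (d[k + 1] - d[1]) * axis_px
    if (min(diff(px)) >= min_gap_px) best <- k else break
  }
  best
}

#' Audit fold-change display transforms
#'
#' Runs the proportionality, symmetry, and dynamic-range assessments for a
#' set of transforms and derives pass/fail verdicts at the configured
#' tolerances. For the built-in trio this reproduces the canonical verdict
#' pattern: the linear scale is proportional on the positive branch only and
#' asymmetric; log2 is symmetric but proportional in neither direction; MAD
#' is proportional in both directions and symmetric; and the dynamic-range
#' ordering is log2 > linear ~ madfc. Readability is a label contract of
#' the axis scale and is not scored.
#'
#' @param transforms Character vector of built-in names and/or a list of
#'   [fc_transform()] objects.
#' @param probe_fcs Probe fold changes for proportionality.
#' @param magnitudes Probe magnitudes for symmetry.
#' @param tol Normalized tolerance below which a residual or deviation
#'   counts as a pass (default 1e-9: exact-law transforms pass, log/linear
#'   violations are many orders of magnitude larger).
#' @inheritParams estimate_dynamic_range
#' @return A tibble of class `fc_audit`, one row per transform, with scores
#'   (`prop_residual_pos`, `prop_residual_neg`, `symmetry_deviation`,
#'   `dynamic_range_log2`) and verdicts (`proportional_pos`,
#'   `proportional_neg`, `proportional`, `symmetric`).
#' @examples
#' audit_fc_transforms()
#' @export
audit_fc_transforms <- function(transforms = c("linear", "log2", "madfc"),
                                probe_fcs = gen_fcu_span(),
                                magnitudes = 2:6, tol = 1e-9,
                                axis_px = 600, min_gap_px = 2) {
  tlist <- purrr::map(transforms, function(tr) {
    if (inherits(tr, "fc_transform")) tr else fc_transform(tr)
  })
  rows <- purrr::map_dfr(tlist, function(t) {
    pr <- assess_proportionality(t, probe_fcs)
    tibble(
      transform = t$name,
      prop_residual_pos = pr$max_residual[pr$branch == "positive"],
      prop_residual_neg = pr$max_residual[pr$branch == "negative"],
      symmetry_deviation = assess_symmetry(t, magnitudes),
      dynamic_range_log2 = estimate_dynamic_range(t, axis_px, min_gap_px)
    )
  })
  out <- dplyr::mutate(rows,
    proportional_pos = .data$prop_residual_pos <= tol,
    proportional_neg = .data$prop_residual_neg <= tol,
    proportional = .data$proportional_pos & .data$proportional_neg,
    symmetric = .data$symmetry_deviation <= tol
  )
  attr(out, "tol") <- tol
  attr(out, "axis_px") <- axis_px
  attr(out, "min_gap_px") <- min_gap_px
  class(out) <- c("fc_audit", class(out))
  out
}

#' @export
print.fc_audit <- function(x, ...) {
  cat("Fold-change transform audit",
      sprintf("(tol %.1e, axis %d px, min gap %d px)\n",
              attr(x, "tol"), as.integer(attr(x, "axis_px")),
              as.integer(attr(x, "min_gap_px"))))
  verdict <- function(b) ifelse(b, "yes", "no")
  tab <- data.frame(
    transform = x$transform,
    proportional = ifelse(x$proportional, "yes",
                          ifelse(x$proportional_pos, "positive only", "no")),
    symmetric = verdict(x$symmetric),
    dynamic_range = paste0(x$dynamic_range_log2, " log2 units")
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tidy an audit into one row per transform and property
#'
#' @param x An `fc_audit` from [audit_fc_transforms()].
#' @param ... Unused.
#' @return A tibble with columns `transform`, `property`, `score`, `pass`
#'   (`NA` for dynamic range, which is an estimate rather than a verdict).
#' @method tidy fc_audit
#' @export
tidy.fc_audit <- function(x, ...) {
  tol <- attr(x, "tol")
  tidyr::pivot_longer(
    as_tibble(x)[c("transform", "prop_residual_pos", "prop_residual_neg",
                   "symmetry_deviation", "dynamic_range_log2")],
    -"transform", names_to = "property", values_to = "score"
  ) |>
    dplyr::mutate(pass = dplyr::if_else(
      .data$property == "dynamic_range_log2", NA,
      .data$score <= tol))
}

#' One-row summary of an audit
#'
#' @inheritParams tidy.fc_audit
#' @return A one-row tibble: number of transforms, tolerance, pixel budget.
#' @method glance fc_audit
#' @export
glance.fc_audit <- function(x, ...) {
  tibble(n_transforms = nrow(x), tol = attr(x, "tol"),
         axis_px = attr(x, "axis_px"), min_gap_px = attr(x, "min_gap_px"))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
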