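# Diverging color normalization: map fold change to [0, 1] so that, under
# the MAD transform, equal steps in fold-change units get equal steps in
# color and reciprocal fold changes sit symmetrically about the palette
# midpoint.

#' Specify a fold-change color normalization
#'
#' Describes how raw fold changes are mapped to the unit interval for a
#' diverging colormap: which transform sets the spacing (`madfc`, `log2`,
#' or `linear`), the fold-change bounds, and whether the bounds are
#' symmetrized in transform space so that a fold change of 1 always maps to
#' exactly 0.5 (the palette midpoint).
#'
#' @param transform One of `"madfc"`, `"log2"`, `"linear"`.
#' @param vmin_fc,vmax_fc Positive fold-change bounds, `vmin_fc < vmax_fc`.
#' @param symmetric If `TRUE` (default) the bounds in transform space are
#'   replaced by `±max(|t(vmin_fc)|, |t(vmax_fc)|)` about the transform's
#'   point of no change.
#' @return An object of class `fc_color_norm_spec`.
#' @examples
#' color_norm_spec("madfc", vmin_fc = 1/5, vmax_fc = 5)
#' @export
color_norm_spec <- function(transform = c("madfc", "log2", "linear"),
                            vmin_fc, vmax_fc, symmetric = TRUE) {
  transform <- match.arg(transform)
  if (!is.numeric(vmin_fc) || !is.numeric(vmax_fc) ||
      vmin_fc <= 0 || vmax_fc <= 0 || vmin_fc >= vmax_fc) {
    abort("need positive fold-change bounds with vmin_fc < vmax_fc",
          class = "madfc_config_error")
  }
  structure(
    list(transform = transform, vmin_fc = vmin_fc, vmax_fc = vmax_fc,
         symmetric = isTRUE(symmetric)),
    class = "fc_color_norm_spec"
  )
}

#' @export
print.fc_color_norm_spec <- function(x, ...) {
  cat(sprintf(
    "<fc_color_norm_spec> transform=%s bounds=[%g, %g] symmetric=%s\n",
    x$transform, x$vmin_fc, x$vmax_fc, x$symmetric))
  invisible(x)
}

# Symmetric data-driven default: bounds at the data's largest |FCU|.
color_norm_spec_from_data <- function(fc, transform = "madfc") {
  u <- fold_change_units(fc, policy = "propagate")
  m <- max(abs(u), na.rm = TRUE)
  if (!is.finite(m) || m == 0) m <- 1
  color_norm_spec(transform, madfc_inverse(-m), madfc_inverse(m),
                  symmetric = TRUE)
}

#' Normalize fold changes to the unit interval for color mapping
#'
#' Applies the spec's transform to `x`, linearly rescales between the
#' transformed bounds (symmetrized about the point of no change when the
#' spec says so), and clips to `[0, 1]` — heatmaps routinely contain
#' outliers, so out-of-range values saturate rather than error. Under a
#' symmetric MAD spec, `normalize_fc(x) + normalize_fc(1/x) == 1` and equal
#' fold-change-unit steps get equal color steps.
#'
#' @param x Numeric vector of raw fold changes.
#' @param spec An [color_norm_spec()].
#' @inheritParams fold_change_units
#' @return Numeric vector in `[0, 1]` (with `NA` where the policy
#'   propagated out-of-domain inputs).
#' @examples
#' sp <- color_norm_spec("madfc", 1/5, 5)
#' normalize_fc(c(1/5, 1, 5), sp)
#' @export
normalize_fc <- function(x, spec, policy = c("propagate", "strict")) {
  policy <- match.arg(policy)
  if (!inherits(spec, "fc_color_norm_spec")) {
    abort("spec must be created by color_norm_spec()",
          class = "madfc_config_error")
  }
  tf <- function(v) fc_display(v, spec$transform, policy = "propagate")
  t <- fc_display(x, spec$transform, policy = policy)
  noc <- if (spec$transform == "linear") 1 else 0
  t0 <- tf(spec$vmin_fc)
  t1 <- tf(spec$vmax_fc)
  if (spec$symmetric) {
    half <- max(abs(t0 - noc), abs(t1 - noc))
    t0 <- noc - half
    t1 <- noc + half
  }
  pmin(pmax((t - t0) / (t1 - t0), 0), 1)
}
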