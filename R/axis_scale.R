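# Axis scale: tick placement at integer fold-change-unit positions with
# labels back-transformed to raw fold change, plus a registered ggplot2
# transform so any axis can adopt the MAD scale. A MAD axis always carries
# back-transformed labels: the raw transform coordinates are never exposed
# as tick text.

#' Format a raw fold change as an axis tick label
#'
#' Renders a positive fold change in one of three styles. `"fraction"` emits
#' `1/k` when the value is (within 1e-9) a unit fraction and an integer
#' string when it is an integer; `"exponent"` emits `b^p` when the value is
#' an exact integer power of `base`; both fall back to a decimal rendering
#' otherwise. `"decimal"` always renders decimals.
#'
#' @param x Numeric vector of raw fold changes, all `> 0`.
#' @param style One of `"fraction"`, `"decimal"`, `"exponent"`.
#' @param base Base used by the exponent style (default 2).
#' @param digits Significant digits for the decimal rendering.
#' @return Character vector of labels.
#' @examples
#' format_fc_label(c(1/3, 1, 6), style = "fraction")
#' format_fc_label(c(1/4, 8), style = "exponent")
#' @export
format_fc_label <- function(x, style = c("fraction", "decimal", "exponent"),
                            base = 2, digits = 10) {
  style <- match.arg(style)
  x <- check_fc_domain(x, "strict", what = "label value")
  dec <- function(v) {
    ifelse(abs(v - round(v)) < 1e-9,
      format(round(v), scientific = FALSE, trim = TRUE),
      vapply(v, function(vi) format(signif(vi, digits), digits = digits,
                                    scientific = FALSE, trim = TRUE),
             character(1))
    )
  }
  if (style == "decimal") return(dec(x))
  if (style == "fraction") {
    inv <- 1 / x
    is_int <- abs(x - round(x)) < 1e-9
    is_unit_frac <- !is_int & x < 1 & abs(inv - round(inv)) < 1e-9
    out <- dec(x)
    out[is_int] <- format(round(x[is_int]), trim = TRUE)
    out[is_unit_frac] <- paste0("1/", format(round(inv[is_unit_frac]),
                                             trim = TRUE))
    return(out)
  }
  # exponent style
  p <- log(x, base)
  is_pow <- abs(p - round(p)) < 1e-9
  out <- dec(x)
  out[is_pow] <- paste0(base, "^", round(p[is_pow]))
  out
}

#' Parse an axis tick label back to a raw fold change
#'
#' Inverse of [format_fc_label()]: understands `1/k` fractions, `b^p`
#' exponents, and plain decimals. Used to verify the readability contract
#' (label text reproduces tick position under the forward transform).
#'
#' @param label Character vector of labels.
#' @return Numeric vector of raw fold changes.
#' @examples
#' parse_fc_label(c("1/6", "2^3", "1.5"))
#' @export
parse_fc_label <- function(label) {
  vapply(as.character(label), function(s) {
    if (grepl("^\\s*1\\s*/\\s*[0-9]+\\s*$", s)) {
      k <- as.numeric(sub("^\\s*1\\s*/\\s*([0-9]+)\\s*$", "\\1", s))
      return(1 / k)
    }
    if (grepl("^\\s*[0-9.]+\\^-?[0-9]+\\s*$", s)) {
      parts <- strsplit(trimws(s), "^", fixed = TRUE)[[1]]
      return(as.numeric(parts[1])^as.numeric(parts[2]))
    }
    as.numeric(s)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Tick positions and back-transformed labels for a MAD axis
#'
#' Places candidate ticks at every integer fold-change-unit position inside
#' `[lo, hi]` (display coordinates). If there are more candidates than
#' `max_ticks`, they are thinned to multiples of the smallest integer stride
#' that fits, which always retains the point-of-no-change tick at 0 when it
#' is in range. Each label is the inverse MAD transform of its position
#' rendered with [format_fc_label()], so a position `-k` is labelled
#' `1/(k+1)` and a position `k` is labelled `k+1`. Ranges containing fewer
#' than two integer positions fall back to five evenly spaced positions with
#' decimal labels (snapping one tick to 0 when in range).
#'
#' @param lo,hi Axis range in MAD display coordinates, `lo < hi`.
#' @param max_ticks Maximum number of ticks (at least 3).
#' @param style Label style passed to [format_fc_label()].
#' @return A tibble of class `madfc_ticks` with columns `position` (display
#'   coordinate), `fc` (back-transformed raw fold change), and `label`.
#'   The attribute `anchor_index` gives the row of the point-of-no-change
#'   tick, or `NA` if 0 is out of range.
#' @examples
#' madfc_ticks(-5, 5, max_ticks = 11)
#' @export
madfc_ticks <- function(lo, hi, max_ticks = 11,
                        style = c("fraction", "decimal", "exponent")) {
  style <- match.arg(style)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort("tick range requires finite lo < hi", class = "madfc_range_error")
  }
  if (max_ticks < 3) abort("max_ticks must be at least 3")
  cand <- seq(ceiling(lo), floor(hi))
  if (length(cand) >= 2) {
    if (length(cand) > max_ticks) {
      stride <- 2
      while (sum(cand %% stride == 0) > max_ticks) stride <- stride + 1
      cand <- cand[cand %% stride == 0]
    }
    pos <- as.numeric(cand)
    fc <- madfc_inverse(pos)
    labels <- format_fc_label(fc, style)
  } else {
    # sub-unit range: fewer than two integer FCU positions available
    pos <- seq(lo, hi, length.out = 5)
    if (lo <= 0 && hi >= 0) pos[which.min(abs(pos))] <- 0
    fc <- madfc_inverse(pos)
    labels <- format_fc_label(fc, "decimal")
  }
  out <- tibble(position = pos, fc = fc, label = labels)
  anchor <- which(out$position == 0)
  attr(out, "anchor_index") <- if (length(anchor)) anchor[1] else NA_integer_
  class(out) <- c("madfc_ticks", class(out))
  out
}

# Per-scale tick generation used by the plot builders; every scale's labels
# are readable raw fold changes (MAD and log2 axes are "labeled", never raw).
fc_scale_ticks <- function(lo, hi, scale = c("madfc", "log2", "linear"),
                           max_ticks = 11,
                           style = c("fraction", "decimal", "exponent")) {
  scale <- match.arg(scale)
  style <- match.arg(style)
  if (scale == "madfc") return(madfc_ticks(lo, hi, max_ticks, style))
  if (scale == "log2") {
    cand <- seq(ceiling(lo), floor(hi))
    if (length(cand) >= 2) {
      if (length(cand) > max_ticks) {
        stride <- 2
        while (sum(cand %% stride == 0) > max_ticks) stride <- stride + 1
        cand <- cand[cand %% stride == 0]
      }
      pos <- as.numeric(cand)
    } else {
      pos <- seq(lo, hi, length.out = 5)
      if (lo <= 0 && hi >= 0) pos[which.min(abs(pos))] <- 0
    }
    fc <- 2^pos
    sty <- if (length(cand) >= 2) style else "decimal"
    return(tibble(position = pos, fc = fc,
                  label = format_fc_label(fc, sty)))
  }
  pos <- pretty(c(lo, hi), n = max_ticks)
  pos <- pos[pos >= lo & pos <= hi & pos > 0]
  if (!length(pos)) pos <- seq(max(lo, .Machine$double.eps), hi,
                               length.out = 5)
  tibble(position = pos, fc = pos, label = format_fc_label(pos, "decimal"))
}

#' The "madfc" coordinate transform for ggplot2 scales
#'
#' A registered [scales::trans_new()] transformation named `"madfc"`:
#' display coordinates are [madfc_forward()] of the data, the inverse is
#' [madfc_inverse()], breaks sit at integer fold-change-unit positions, and
#' labels are back-transformed raw fold changes. Data at or below zero is
#' masked to `NA` (propagate policy). Calling it repeatedly returns an
#' equivalent object; registration is idempotent.
#'
#' @inheritParams madfc_ticks
#' @return A transformation object usable as `transform`/`trans` in any
#'   ggplot2 continuous scale.
#' @examples
#' tr <- madfc_trans()
#' tr$transform(c(1/6, 6))
#' @export
madfc_trans <- function(style = c("fraction", "decimal", "exponent"),
                        max_ticks = 7) {
  style <- match.arg(style)
  scales::trans_new(
    name = "madfc",
    transform = function(x) madfc_forward(x, policy = "propagate"),
    inverse = function(y) madfc_inverse(y),
    breaks = function(x, n = max_ticks) {
      rng <- madfc_forward(range(x, na.rm = TRUE), policy = "propagate")
      if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
      madfc_ticks(rng[1], rng[2], max(n, 3), style)$fc
    },
    format = function(x) format_fc_label(x, style),
    domain = c(.Machine$double.xmin, Inf)
  )
}

#' MAD fold-change position scales for ggplot2
#'
#' Continuous x/y scales using the `"madfc"` transform, with tick labels
#' back-transformed to raw fold change. These are the labelled-MAD-axis
#' entry points for composing your own ggplots; the bundled plot builders
#' use the same tick algebra.
#'
#' @inheritParams madfc_ticks
#' @param ... Passed to [ggplot2::scale_x_continuous()] /
#'   [ggplot2::scale_y_continuous()].
#' @return A ggplot2 scale object.
#' @examples
#' ggplot2::ggplot(data.frame(fc = c(1/6, 1, 6), y = 1:3)) +
#'   ggplot2::aes(fc, y) + ggplot2::geom_point() + scale_x_madfc()
#' @export
scale_x_madfc <- function(..., style = "fraction", max_ticks = 7) {
  ggplot2::scale_x_continuous(..., trans = madfc_trans(style, max_ticks))
}

#' @rdname scale_x_madfc
#' @export
scale_y_madfc <- function(..., style = "fraction", max_ticks = 7) {
  ggplot2::scale_y_continuous(..., trans = madfc_trans(style, max_ticks))
}
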