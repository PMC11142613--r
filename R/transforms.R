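#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile density setNames p.adjust pnorm qnorm rlnorm
#'   rnorm runif
NULL

# Out-of-domain handling shared by every transform that requires a positive
# raw fold change. "strict" errors and names the offending values; "propagate"
# maps them to NA positionally so one bad feature does not kill a whole plot.
check_fc_domain <- function(x, policy = c("strict", "propagate"),
                            what = "raw fold change") {
  policy <- match.arg(policy)
  x <- as.numeric(x)
  bad <- !is.finite(x) | x <= 0
  bad[is.na(x)] <- TRUE
  if (any(bad)) {
    if (policy == "strict") {
      offenders <- unique(x[bad])
      abort(sprintf(
        "%s must be a positive finite number; offending value(s): %s",
        what, paste(utils::head(format(offenders), 5L), collapse = ", ")
      ), class = "madfc_domain_error")
    }
    x[bad] <- NA_real_
  }
  x
}

#' Fold change units: the linear encoding of fold change
#'
#' Encodes a raw fold change \eqn{x > 0} as its signed distance, in "fold
#' changes", from the point of no change (\eqn{x = 1}): \eqn{x - 1} for
#' \eqn{x \ge 1} and \eqn{1 - 1/x} for \eqn{0 < x < 1}. Raw fold changes
#' (2, 1/2, 3, 1/3) map to (1, -1, 2, -2) fold change units. This encoding is
#' numerically identical to the composed MAD-FC transform
#' ([madfc_forward()]), which is what makes MAD axes proportional in
#' fold-change units.
#'
#' @param x Numeric vector of raw fold changes (positive ratios,
#'   experiment / control).
#' @param policy Out-of-domain policy for `x <= 0` or non-finite values:
#'   `"strict"` (default) raises an error naming the offending values,
#'   `"propagate"` maps them to `NA` positionally.
#' @return Numeric vector of fold change units, same length as `x`.
#' @examples
#' fold_change_units(c(2, 1/2, 3, 1/3))
#' fold_change_units(1/6)
#' @seealso [madfc_forward()], [madfc_inverse()]
#' @export
fold_change_units <- function(x, policy = c("strict", "propagate")) {
  x <- check_fc_domain(x, policy)
  ifelse(x >= 1, x - 1, 1 - 1 / x)
}

#' The mirror transform
#'
#' Maps sub-unit fold changes to their negated reciprocals (\eqn{-1/x} for
#' \eqn{0 < x < 1}; identity for \eqn{x \ge 1}) so that reciprocal pairs
#' become sign-symmetric about zero. Its range has a gap over \eqn{[-1, 1)}
#' that the contraction transform ([contract_fc()]) closes.
#'
#' @inheritParams fold_change_units
#' @return Numeric vector in \eqn{(-\infty, -1) \cup [1, \infty)}.
#' @examples
#' mirror_fc(c(2, 1/3))
#' @export
mirror_fc <- function(x, policy = c("strict", "propagate")) {
  x <- check_fc_domain(x, policy)
  ifelse(x >= 1, x, -1 / x)
}

#' The contraction transform
#'
#' Translates both branches of mirrored fold changes one unit toward zero
#' (\eqn{m - 1} for \eqn{m \ge 1}, \eqn{m + 1} for \eqn{m < -1}), closing the
#' mirror transform's empty region. Mirror then contraction is the MAD-FC
#' transform.
#'
#' @param m Numeric vector in the mirror transform's range: \eqn{m \ge 1} or
#'   \eqn{m < -1}. Values inside \eqn{[-1, 1)} are outside the transform's
#'   domain and raise an error; `NA`s pass through.
#' @return Numeric vector of MAD-FC display coordinates.
#' @examples
#' contract_fc(c(3, -3))
#' @export
contract_fc <- function(m) {
  m <- as.numeric(m)
  bad <- !is.na(m) & m >= -1 & m < 1
  if (any(bad)) {
    abort(sprintf(
      "contraction is undefined on [-1, 1); offending value(s): %s",
      paste(utils::head(format(unique(m[bad])), 5L), collapse = ", ")
    ), class = "madfc_domain_error")
  }
  ifelse(m >= 1, m - 1, m + 1)
}

#' The MAD-FC transform (mirror then contract)
#'
#' The mirrored-axis-distortion transform of fold change: the composition of
#' [mirror_fc()] and [contract_fc()]. It is continuous and strictly
#' increasing on \eqn{(0, \infty)}, maps the point of no change to 0 exactly,
#' and equals [fold_change_units()] for every defined input.
#'
#' @inheritParams fold_change_units
#' @return Numeric vector of MAD display coordinates (fold change units).
#' @examples
#' madfc_forward(c(1/6, 1/2, 1, 2, 6))
#' @export
madfc_forward <- function(x, policy = c("strict", "propagate")) {
  contract_fc(mirror_fc(x, policy))
}

#' Inverse of the contraction transform
#'
#' \eqn{y + 1} for \eqn{y \ge 0}, \eqn{y - 1} for \eqn{y < 0}; moves the
#' point of no change from 0 back to 1. Defined on all reals.
#'
#' @param y Numeric vector of MAD display coordinates.
#' @return Numeric vector in the mirror transform's range.
#' @examples
#' contract_inverse(c(0, 2, -2))
#' @export
contract_inverse <- function(y) {
  y <- as.numeric(y)
  ifelse(y >= 0, y + 1, y - 1)
}

#' Inverse of the mirror transform
#'
#' Identity for \eqn{m \ge 1}, \eqn{-1/m} for \eqn{m < -1}; undefined on
#' \eqn{[-1, 1)}.
#'
#' @inheritParams contract_fc
#' @return Numeric vector of raw fold changes.
#' @examples
#' mirror_inverse(c(3, -3))
#' @export
mirror_inverse <- function(m) {
  m <- as.numeric(m)
  bad <- !is.na(m) & m >= -1 & m < 1
  if (any(bad)) {
    abort(sprintf(
      "mirror inverse is undefined on [-1, 1); offending value(s): %s",
      paste(utils::head(format(unique(m[bad])), 5L), collapse = ", ")
    ), class = "madfc_domain_error")
  }
  ifelse(m >= 1, m, -1 / m)
}

#' Inverse MAD-FC transform
#'
#' Maps a MAD display coordinate back to the raw fold change:
#' \eqn{y + 1} for \eqn{y \ge 0}, \eqn{1 / (1 - y)} for \eqn{y < 0}. Exact
#' two-sided inverse of [madfc_forward()]; defined on all reals, so axis
#' labels can be back-transformed anywhere on the axis.
#'
#' @param y Numeric vector of MAD display coordinates (fold change units).
#' @return Numeric vector of raw fold changes.
#' @examples
#' madfc_inverse(-5:5)
#' @export
madfc_inverse <- function(y) {
  mirror_inverse(contract_inverse(y))
}

#' Convert between log2 fold change and raw fold change
#'
#' Differential-expression tables usually carry `log2FoldChange`; the MAD
#' transform family works on raw positive ratios. These helpers convert
#' between the two encodings and are mutual inverses.
#'
#' @param l Numeric vector of log2 fold changes.
#' @inheritParams fold_change_units
#' @return `log2_to_fc()`: raw fold changes; `fc_to_log2()`: log2 fold
#'   changes.
#' @examples
#' log2_to_fc(c(-1, 0, 1))
#' fc_to_log2(1/6)
#' @export
log2_to_fc <- function(l) 2^as.numeric(l)

#' @rdname log2_to_fc
#' @export
fc_to_log2 <- function(x, policy = c("strict", "propagate")) {
  log2(check_fc_domain(x, policy))
}

# Display transform for the three scales the builders understand.
fc_display <- function(x, scale = c("madfc", "log2", "linear"),
                       policy = "propagate") {
  scale <- match.arg(scale)
  switch(scale,
    madfc = madfc_forward(x, policy),
    log2 = fc_to_log2(x, policy),
    linear = check_fc_domain(x, policy)
  )
}

fc_display_inverse <- function(y, scale = c("madfc", "log2", "linear")) {
  scale <- match.arg(scale)
  switch(scale,
    madfc = madfc_inverse(y),
    log2 = 2^y,
    linear = as.numeric(y)
  )
}
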