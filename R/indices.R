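# Better/worse coefficients and the importance-satisfaction quadrant matrix.

#' Round half away from zero
#'
#' Display rounding used for reported indices (so that e.g. -0.615 prints as
#' -0.62, matching how survey tables are conventionally typeset), as opposed
#' to [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Satisfaction ("better") coefficient
#'
#' SI = (A + O) / (A + O + M + I). Closer to 1 means fulfilling the item
#' raises satisfaction more. Reverse and questionable counts are ignored.
#'
#' @param counts named numeric vector with (at least) names M, O, A, I.
#' @return SI in \[0, 1\], at full precision.
#' @export
#' @examples
#' satisfaction_index(c(M = 282, O = 235, A = 725, I = 322))  # 960/1564
satisfaction_index <- function(counts) {
  .index_parts(counts, which = "si")
}

#' Importance ("worse") coefficient
#'
#' DSI = -(O + M) / (A + O + M + I). Closer to -1 means the item's absence
#' hurts satisfaction more, i.e. the item is more important.
#'
#' @inheritParams satisfaction_index
#' @return DSI in \[-1, 0\], at full precision.
#' @export
#' @examples
#' importance_index(c(M = 699, O = 272, A = 291, I = 301))  # -971/1563
importance_index <- function(counts) {
  .index_parts(counts, which = "dsi")
}

.index_parts <- function(counts, which) {
  need <- c("M", "O", "A", "I")
  x <- stats::setNames(numeric(4), need)
  common <- intersect(names(counts), need)
  x[common] <- counts[common]
  den <- sum(x)
  if (is.na(den) || den <= 0) {
    stop("undefined index: A + O + M + I must be positive", call. = FALSE)
  }
  if (which == "si") (x[["A"]] + x[["O"]]) / den else -(x[["O"]] + x[["M"]]) / den
}

#' Origin of the importance-satisfaction matrix
#'
#' The matrix origin is the per-axis mean over items: x0 = mean |DSI|
#' (importance magnitude), y0 = mean SI. Computed from full-precision
#' per-item values by default; pass 2-dp rounded indices to replicate a
#' published table's display arithmetic (both conventions give identical
#' quadrant memberships on the bundled nurse-demand data).
#'
#' @param si numeric vector of per-item satisfaction indices.
#' @param dsi numeric vector of per-item importance indices (non-positive).
#' @return Named numeric vector \code{c(x0 = mean |DSI|, y0 = mean SI)}.
#' @export
kano_origin <- function(si, dsi) {
  stopifnot(length(si) == length(dsi))
  if (length(si) == 0L) stop("need at least one item to place the origin", call. = FALSE)
  c(x0 = mean(abs(dsi)), y0 = mean(si))
}

.quadrant_strategies <- c(
  "I" = "predominance",
  "II" = "improving",
  "III" = "secondary improving",
  "IV" = "reserving"
)

#' Assign items to strategy quadrants
#'
#' Places each item in the importance-satisfaction plane at
#' (x, y) = (|DSI|, SI) and splits the plane at the origin:
#' \describe{
#'   \item{I (predominance)}{x >= x0 and SI >= y0: important and
#'     satisfaction-sensitive; priority needs.}
#'   \item{II (improving)}{x < x0 and SI >= y0: satisfaction-sensitive but
#'     less important; key improvement candidates.}
#'   \item{III (secondary improving)}{x < x0 and SI < y0: low on both axes;
#'     observation items.}
#'   \item{IV (reserving)}{x >= x0 and SI < y0: important but low
#'     satisfaction gain; maintain the status quo.}
#' }
#' Boundary ties go to the higher-importance / higher-satisfaction side (>=),
#' so a point exactly at the origin falls in quadrant I.
#'
#' @param si,dsi numeric vectors of per-item indices.
#' @param origin origin as returned by [kano_origin()].
#' @return Factor of quadrant labels with levels I, II, III, IV.
#' @export
assign_quadrant <- function(si, dsi, origin) {
  x <- abs(dsi)
  hi_x <- x >= origin[["x0"]]
  hi_y <- si >= origin[["y0"]]
  q <- ifelse(hi_x & hi_y, "I",
       ifelse(!hi_x & hi_y, "II",
       ifelse(!hi_x, "III", "IV")))
  factor(q, levels = names(.quadrant_strategies))
}

#' Strategy names of the four quadrants
#'
#' @return Named character vector mapping quadrant labels I..IV to their
#'   strategy names (predominance, improving, secondary improving, reserving).
#' @export
quadrant_strategies <- function() {
  .quadrant_strategies
}
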