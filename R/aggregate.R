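# Per-item tabulation of pair classifications and modal attribute assignment.

#' Tabulate Kano category frequencies for one item
#'
#' Counts how many respondents' answer pairs fall in each of the six Kano
#' categories. All respondents with a complete valid pair are counted,
#' including those classified reverse (R) or questionable (Q); R and Q are
#' only excluded later, in the SI/DSI denominators.
#'
#' @param functional,dysfunctional equal-length integer vectors of Likert
#'   codes (1..5) for the item.
#' @param item_id identifier for the item (used in error messages).
#' @return A named integer vector of counts over c(M, O, A, I, R, Q) with
#'   attribute \code{n_total} equal to its sum.
#' @export
#' @examples
#' tabulate_item(c(1, 1, 1, 1), c(5, 5, 5, 1))  # O:3, Q:1
tabulate_item <- function(functional, dysfunctional, item_id = NULL) {
  if (length(functional) == 0L) {
    stop(sprintf("no responses for item %s",
                 if (is.null(item_id)) "<unnamed>" else item_id), call. = FALSE)
  }
  tags <- classify_pair(functional, dysfunctional)
  counts <- stats::setNames(integer(6), .kano_tags)
  tb <- table(factor(tags, levels = .kano_tags))
  counts[names(tb)] <- as.integer(tb)
  attr(counts, "n_total") <- sum(counts)
  counts
}

#' Modal Kano category of a frequency row
#'
#' Assigns an item's final Kano attribute as the most frequent category among
#' its respondents. Ties are broken by the fixed precedence
#' M > O > A > I > R > Q (categories with larger dissatisfaction impact
#' dominate); the tie event is reported so callers can flag items whose
#' assignment rests on the tie-break.
#'
#' @param counts named numeric vector of category counts; names must cover
#'   M, O, A, I, R, Q (missing names are treated as zero).
#' @param precedence character vector giving the tie-break order; the default
#'   is the conservative convention above.
#' @return A list with elements \code{category} (tag), \code{is_tie}
#'   (logical) and \code{tied} (character vector of the maximising tags, in
#'   precedence order).
#' @export
#' @examples
#' modal_category(c(M = 282, O = 235, A = 725, I = 322, R = 2, Q = 5))
#' modal_category(c(M = 10, O = 10, A = 3, I = 0, R = 0, Q = 0))  # tie -> M
modal_category <- function(counts, precedence = c("M", "O", "A", "I", "R", "Q")) {
  stopifnot(setequal(precedence, .kano_tags))
  x <- stats::setNames(numeric(6), precedence)
  common <- intersect(names(counts), precedence)
  x[common] <- counts[common]
  if (any(x < 0) || any(is.na(x))) {
    stop("category counts must be non-negative numbers", call. = FALSE)
  }
  if (sum(x) == 0) stop("all category counts are zero", call. = FALSE)
  tied <- precedence[x == max(x)]
  list(category = tied[[1L]], is_tie = length(tied) > 1L, tied = tied)
}
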