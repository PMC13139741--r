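#' @keywords internal
"_PACKAGE"

# Canonical five-point Likert coding for Kano questionnaires:
# 1 = like, 2 = must-be, 3 = neutral, 4 = live-with, 5 = dislike.
.likert_labels <- c("like", "must-be", "neutral", "live-with", "dislike")

# The six Kano categories, in the tie-break precedence order used throughout:
# categories with larger dissatisfaction impact dominate.
.kano_tags <- c("M", "O", "A", "I", "R", "Q")
.kano_names <- c(
  M = "must-be", O = "one-dimensional", A = "attractive",
  I = "indifferent", R = "reverse", Q = "questionable"
)

#' Likert answer labels for Kano questionnaires
#'
#' The fixed five-point coding used by paired functional/dysfunctional Kano
#' questions: 1 = "like", 2 = "must-be", 3 = "neutral", 4 = "live-with",
#' 5 = "dislike". The direction is fixed; data collected with a reversed
#' scale must be remapped (e.g. via the codebook's \code{likert_mapping})
#' before analysis -- the package never guesses the coding.
#'
#' @return A named character vector of length 5; names are the codes "1".."5".
#' @export
#' @examples
#' likert_labels()
likert_labels <- function() {
  stats::setNames(.likert_labels, as.character(1:5))
}

#' Kano category tags and names
#'
#' @return A named character vector mapping the six category tags
#'   (M, O, A, I, R, Q) to their names (must-be, one-dimensional, attractive,
#'   indifferent, reverse, questionable).
#' @export
#' @examples
#' kano_categories()
kano_categories <- function() {
  .kano_names
}

# Validate Likert codes; returns the codes as integers or signals an error
# naming the offending values (and positions when `what` is given).
validate_likert <- function(code, what = "Likert code") {
  x <- suppressWarnings(as.integer(code))
  bad <- is.na(x) | x < 1L | x > 5L
  if (any(bad)) {
    stop(sprintf(
      "invalid %s: %s (positions %s); codes must be integers in 1..5",
      what,
      paste(utils::head(unique(code[bad]), 5L), collapse = ", "),
      paste(utils::head(which(bad), 5L), collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' The Kano evaluation table
#'
#' Returns the standard 5 x 5 Kano evaluation table as a character matrix:
#' rows index the functional ("if this feature was available") answer, columns
#' the dysfunctional ("if it was not available") answer, both coded
#' 1 = like .. 5 = dislike, and each cell holds the Kano category tag that
#' such an answer pair maps to. The table is stored as data, not as
#' conditionals, so it can be printed and inspected directly. Over the 25
#' cells the category multiset is I:9, R:7, A:3, M:3, Q:2, O:1.
#'
#' @return A 5 x 5 character matrix with dimnames
#'   \code{list(functional = labels, dysfunctional = labels)}.
#' @seealso [classify_pair()]
#' @export
#' @examples
#' kano_evaluation_table()
#' table(kano_evaluation_table())
kano_evaluation_table <- function() {
  m <- matrix(
    c(
      "Q", "A", "A", "A", "O",
      "R", "I", "I", "I", "M",
      "R", "I", "I", "I", "M",
      "R", "I", "I", "I", "M",
      "R", "R", "R", "R", "Q"
    ),
    nrow = 5, byrow = TRUE,
    dimnames = list(functional = .likert_labels, dysfunctional = .likert_labels)
  )
  m
}

#' Classify functional/dysfunctional answer pairs
#'
#' Maps each paired answer to its Kano category via the evaluation table.
#' Vectorised: `functional` and `dysfunctional` are recycled to a common
#' length in the usual way only when one of them has length 1.
#'
#' @param functional integer codes in 1..5 for the functional question
#'   (1 = like .. 5 = dislike).
#' @param dysfunctional integer codes in 1..5 for the dysfunctional question.
#' @return A character vector of category tags ("M", "O", "A", "I", "R", "Q"),
#'   one per pair.
#' @export
#' @examples
#' classify_pair(1, 5)  # like if present, dislike if absent -> "O"
#' classify_pair(3, 5)  # neutral / dislike -> "M"
#' classify_pair(c(1, 5), c(1, 1))  # "Q", "R"
classify_pair <- function(functional, dysfunctional) {
  f <- validate_likert(functional, "functional answer")
  d <- validate_likert(dysfunctional, "dysfunctional answer")
  if (length(f) != length(d)) {
    if (length(f) == 1L) f <- rep(f, length(d))
    else if (length(d) == 1L) d <- rep(d, length(f))
    else stop("functional and dysfunctional must have equal length", call. = FALSE)
  }
  kano_evaluation_table()[cbind(f, d)]
}
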