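# Instrument-development statistics: internal consistency and coder agreement.

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' alpha = k/(k-1) * (1 - sum of item variances / variance of respondent
#' totals), with sample (n-1) variances. Scores are used as given; any
#' reverse-coding must be applied by the caller first.
#'
#' @param m numeric matrix or data.frame, respondents x items; at least two
#'   rows and two columns, no missing cells.
#' @return alpha (<= 1; can be negative for scales worse than noise).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' cronbach_alpha(cbind(x, x))  # duplicated items inflate alpha
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("scores must be numeric", call. = FALSE)
  if (anyNA(m)) stop("missing cells; supply complete cases", call. = FALSE)
  k <- ncol(m)
  if (nrow(m) < 2L || k < 2L) {
    stop("need at least 2 respondents and 2 items", call. = FALSE)
  }
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    stop("zero variance of respondent totals: reliability undefined", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two categorical coders:
#' kappa = (p_o - p_e) / (1 - p_e), with expected agreement p_e from the
#' product of the coders' marginal distributions. Unweighted; the label set
#' is the union of labels either coder used.
#'
#' @param a,b equal-length vectors of categorical codes (character, factor,
#'   or anything coercible to character).
#' @param threshold agreement level reported as "substantial"; the
#'   conventional instrument-development target is 0.80.
#' @return List of class \code{"cohens_kappa"}: \code{kappa}, \code{p_o},
#'   \code{p_e}, \code{n}, and \code{substantial} (kappa >= threshold).
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y", "y"), c("x", "y", "x", "y"))  # kappa = 0
cohens_kappa <- function(a, b, threshold = 0.80) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) stop("coders rated different numbers of units", call. = FALSE)
  n <- length(a)
  if (n < 1L) stop("no rated units", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing codes", call. = FALSE)
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev)) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_e >= 1) {
    stop("both coders used a single identical label: kappa undefined", call. = FALSE)
  }
  kap <- (p_o - p_e) / (1 - p_e)
  structure(
    list(kappa = kap, p_o = p_o, p_e = p_e, n = n,
         substantial = kap >= threshold),
    class = "cohens_kappa"
  )
}

#' @export
print.cohens_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f  (p_o = %.3f, p_e = %.3f, n = %d)%s\n",
              x$kappa, x$p_o, x$p_e, x$n,
              if (x$substantial) "  [substantial agreement]" else ""))
  invisible(x)
}

#' Cronbach's alpha for a paired Kano survey
#'
#' Convenience wrapper selecting the functional columns, the dysfunctional
#' columns, or both from a wide respondent-level table before computing
#' [cronbach_alpha()].
#'
#' @param data wide respondent-level data.frame.
#' @param codebook codebook data.frame (see [kano_codebook()]).
#' @param scale one of "combined", "functional", "dysfunctional".
#' @return alpha for the selected scale.
#' @export
survey_alpha <- function(data, codebook,
                         scale = c("combined", "functional", "dysfunctional")) {
  scale <- match.arg(scale)
  codebook <- as_codebook(codebook, data)
  cols <- switch(scale,
    functional = codebook$functional_column,
    dysfunctional = codebook$dysfunctional_column,
    combined = c(codebook$functional_column, codebook$dysfunctional_column)
  )
  cronbach_alpha(data[, cols, drop = FALSE])
}
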