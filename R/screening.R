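# Pre-analysis data-quality screening and sample-size planning.

#' Screen respondents by logic errors and completion time
#'
#' Applies the two standard exclusions in order: respondents flagged for
#' obvious logical errors are removed first, then, of the remainder, those
#' who completed the questionnaire in less than `min_seconds`. The two
#' exclusion tallies are therefore disjoint and sum with the kept count to
#' the number received. What constitutes a "logical error" is survey-specific
#' (platform consistency checks, straight-lining detectors, ...), so the
#' caller supplies the flag rather than the package inventing a rule.
#'
#' @param data data.frame of respondents, one row each; row order of kept
#'   respondents is preserved.
#' @param min_seconds minimum acceptable completion time in seconds
#'   (default 180, i.e. 3 minutes).
#' @param time_column name of the completion-time column (seconds). `NULL`
#'   skips the time filter.
#' @param logic_column name of a logical column flagging logic errors. `NULL`
#'   skips the logic filter.
#' @return A list of class \code{"kano_screening"}: \code{kept} (the filtered
#'   data.frame) and \code{report}, a list with \code{n_received},
#'   \code{n_logic_excluded}, \code{n_time_excluded}, \code{n_valid} and
#'   \code{response_rate_pct} (full precision; the print method shows 2 dp).
#' @export
#' @examples
#' d <- data.frame(t = c(600, 100, 500), bad = c(FALSE, FALSE, TRUE))
#' screen_respondents(d, time_column = "t", logic_column = "bad")
screen_respondents <- function(data, min_seconds = 180,
                               time_column = "completion_seconds",
                               logic_column = "logic_error") {
  stopifnot(is.data.frame(data), min_seconds >= 0)
  n_received <- nrow(data)
  if (n_received == 0L) stop("no respondents received", call. = FALSE)

  logic_bad <- if (!is.null(logic_column)) {
    if (!logic_column %in% names(data)) {
      stop(sprintf("logic flag column '%s' not found", logic_column), call. = FALSE)
    }
    as.logical(data[[logic_column]]) %in% TRUE
  } else rep(FALSE, n_received)

  after_logic <- data[!logic_bad, , drop = FALSE]
  time_bad <- if (!is.null(time_column)) {
    if (!time_column %in% names(data)) {
      stop(sprintf("completion time column '%s' not found", time_column), call. = FALSE)
    }
    tt <- as.numeric(after_logic[[time_column]])
    if (any(tt < 0, na.rm = TRUE)) stop("negative completion times", call. = FALSE)
    !is.na(tt) & tt < min_seconds
  } else rep(FALSE, nrow(after_logic))

  kept <- after_logic[!time_bad, , drop = FALSE]
  n_valid <- nrow(kept)
  if (n_valid == 0L) warning("screening excluded every respondent", call. = FALSE)
  report <- list(
    n_received = n_received,
    n_logic_excluded = sum(logic_bad),
    n_time_excluded = sum(time_bad),
    n_valid = n_valid,
    response_rate_pct = 100 * n_valid / n_received
  )
  structure(list(kept = kept, report = report), class = "kano_screening")
}

#' @export
print.kano_screening <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("Respondent screening\n",
           "  received:           %d\n",
           "  logic-error drops:  %d\n",
           "  under-time drops:   %d\n",
           "  valid:              %d  (response rate %.2f%%)\n"),
    r$n_received, r$n_logic_excluded, r$n_time_excluded, r$n_valid,
    r$response_rate_pct
  ))
  invisible(x)
}

#' Kendall sample-size rule for survey planning
#'
#' The required sample is 5-10 times the number of independent variables,
#' inflated for anticipated non-response; fractional products are rounded up.
#' With k = 26 items and 20% anticipated non-response (inflation 1.2) the
#' plan is 156-312 respondents.
#'
#' @param k number of independent variables (items); k >= 1.
#' @param inflation non-response inflation factor (>= 1); the default 1.2
#'   corresponds to an anticipated non-response rate of 20%.
#' @return List with \code{k}, \code{inflation}, \code{n_min} (= ceiling of
#'   5 k x inflation) and \code{n_max} (= ceiling of 10 k x inflation).
#' @export
#' @examples
#' kendall_sample_size(26)        # 156 .. 312
#' kendall_sample_size(7, 1.15)   # 41 .. 81
kendall_sample_size <- function(k, inflation = 1.2) {
  stopifnot(length(k) == 1L, k >= 1, k == as.integer(k),
            length(inflation) == 1L, inflation >= 1)
  list(
    k = as.integer(k),
    inflation = inflation,
    n_min = as.integer(ceiling(5 * k * inflation)),
    n_max = as.integer(ceiling(10 * k * inflation))
  )
}
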