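# Synthetic paired-Likert respondents with controlled Kano structure.

#' Define an item's response-pair distribution
#'
#' An item profile is a probability distribution over the 25
#' (functional, dysfunctional) answer cells. Either give the full 5 x 5
#' weight matrix (rows = functional answer 1..5, columns = dysfunctional),
#' or use the shorthand: probability mass `purity` spread uniformly over the
#' cells of `target` category in the evaluation table, and the remaining
#' 1 - purity spread uniformly over all other cells. The uniform spread is
#' the maximum-entropy default; supply explicit `cell_weights` for realistic
#' marginals.
#'
#' @param target a Kano category tag ("M", "O", "A", "I", "R", "Q");
#'   ignored when `cell_weights` is given.
#' @param purity probability mass on the target category, in \[0, 1\].
#' @param cell_weights optional 5 x 5 non-negative matrix of cell weights;
#'   normalised to sum to 1.
#' @return A 5 x 5 probability matrix of class \code{"kano_profile"}.
#' @export
#' @examples
#' kano_profile("A", purity = 0.8)
kano_profile <- function(target = NULL, purity = 1, cell_weights = NULL) {
  if (is.null(cell_weights)) {
    stopifnot(!is.null(target), target %in% .kano_tags,
              purity >= 0, purity <= 1)
    tab <- kano_evaluation_table()
    w <- matrix(0, 5, 5, dimnames = dimnames(tab))
    in_cat <- tab == target
    w[in_cat] <- purity / sum(in_cat)
    w[!in_cat] <- (1 - purity) / sum(!in_cat)
  } else {
    w <- as.matrix(cell_weights)
    stopifnot(identical(dim(w), c(5L, 5L)), all(w >= 0), sum(w) > 0)
    dimnames(w) <- dimnames(kano_evaluation_table())
    w <- w / sum(w)
  }
  if (abs(sum(w) - 1) > 1e-9) stop("profile weights failed to normalise", call. = FALSE)
  structure(w, class = c("kano_profile", "matrix"))
}

#' Profile implied by an observed frequency row
#'
#' Turns a per-item Kano category frequency row into a response-pair
#' distribution: each category receives mass proportional to its observed
#' count, spread uniformly over that category's evaluation-table cells.
#' Lets published aggregate tables seed realistic simulations.
#'
#' @param counts named numeric vector of counts over M, O, A, I, R, Q.
#' @return A \code{"kano_profile"} matrix.
#' @export
#' @examples
#' p <- profile_from_frequencies(c(M = 282, O = 235, A = 725, I = 322, R = 2, Q = 5))
#' profile_category_distribution(p)
profile_from_frequencies <- function(counts) {
  x <- stats::setNames(numeric(6), .kano_tags)
  common <- intersect(names(counts), .kano_tags)
  x[common] <- counts[common]
  if (sum(x) <= 0) stop("counts must have positive total", call. = FALSE)
  tab <- kano_evaluation_table()
  w <- matrix(0, 5, 5)
  for (tag in .kano_tags) {
    cells <- tab == tag
    w[cells] <- x[[tag]] / (sum(x) * sum(cells))
  }
  kano_profile(cell_weights = w)
}

#' Category distribution implied by a profile
#'
#' @param profile a \code{"kano_profile"}.
#' @return Named numeric vector: total probability mass each Kano category
#'   receives under the profile (sums to 1).
#' @export
profile_category_distribution <- function(profile) {
  tab <- kano_evaluation_table()
  vapply(.kano_tags, function(tag) sum(profile[tab == tag]), numeric(1))
}

# Run `expr` under a reproducible, self-contained RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a wide paired-Likert survey dataset
#'
#' Draws `n` respondents; each respondent answers each item independently,
#' with the item's (functional, dysfunctional) pair sampled from that item's
#' profile. Completion times are lognormal and logic-error flags Bernoulli,
#' so the output feeds straight into [screen_respondents()] and [kano()].
#' The defaults emulate a web survey of this length: median completion about
#' 7 minutes with moderate spread, and no logic errors unless requested.
#'
#' @param profiles a named list of [kano_profile()] objects (names become
#'   item ids), or a single profile (recycled over `item_ids`).
#' @param n number of respondents.
#' @param item_ids item identifiers; defaults to \code{names(profiles)}.
#' @param seed optional integer; when given, the dataset is a pure function
#'   of (profiles, n, seed) and the caller's RNG state is left untouched.
#' @param time_meanlog,time_sdlog lognormal parameters of completion time in
#'   seconds (defaults log(420) and 0.5).
#' @param logic_error_rate probability a respondent is flagged for a logic
#'   error, in \[0, 1\] (default 0).
#' @return Wide data.frame: \code{respondent_id}, \code{completion_seconds},
#'   \code{logic_error}, then \code{<item>_func} and \code{<item>_dys}
#'   columns; the matching [kano_codebook()] is attached as attribute
#'   \code{"codebook"}.
#' @export
#' @examples
#' d <- simulate_kano_survey(list(x = kano_profile("M")), n = 5, seed = 1)
#' d
simulate_kano_survey <- function(profiles, n, item_ids = NULL, seed = NULL,
                                 time_meanlog = log(420), time_sdlog = 0.5,
                                 logic_error_rate = 0) {
  if (inherits(profiles, "kano_profile")) profiles <- list(item1 = profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            n >= 1L, logic_error_rate >= 0, logic_error_rate <= 1)
  if (is.null(item_ids)) item_ids <- names(profiles)
  if (is.null(item_ids) || any(!nzchar(item_ids))) {
    item_ids <- paste0("item", seq_along(profiles))
  }
  if (length(item_ids) != length(profiles)) {
    stop("item_ids and profiles lengths differ", call. = FALSE)
  }
  for (p in profiles) {
    if (!inherits(p, "kano_profile")) stop("profiles must be kano_profile objects", call. = FALSE)
  }

  with_seed(seed, {
    out <- data.frame(
      respondent_id = paste0("r", seq_len(n)),
      completion_seconds = stats::rlnorm(n, time_meanlog, time_sdlog),
      logic_error = stats::runif(n) < logic_error_rate,
      stringsAsFactors = FALSE
    )
    for (j in seq_along(profiles)) {
      w <- as.vector(profiles[[j]])  # column-major: cell k -> (f, d)
      cell <- sample.int(25L, n, replace = TRUE, prob = w)
      out[[paste0(item_ids[[j]], "_func")]] <- ((cell - 1L) %% 5L) + 1L
      out[[paste0(item_ids[[j]], "_dys")]] <- ((cell - 1L) %/% 5L) + 1L
    }
    attr(out, "codebook") <- kano_codebook(item_ids)
    out
  })
}
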