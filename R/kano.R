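#' Fit a Kano needs analysis
#'
#' The main entry point. Runs the full pipeline -- optional respondent
#' screening, pair-level classification by the Kano evaluation table,
#' per-item modal attribute assignment, satisfaction (SI) and importance
#' (DSI) coefficients, and the importance-satisfaction quadrant matrix --
#' and returns a single fitted object.
#'
#' Two input shapes are accepted:
#' \describe{
#'   \item{respondent-level}{a wide data.frame (one row per respondent, two
#'     Likert columns per item) together with a `codebook` naming the
#'     columns. If the screening columns are present (see
#'     [screen_respondents()]) respondents are screened first.}
#'   \item{aggregated}{a per-item frequency table with columns \code{item},
#'     \code{label} and category counts \code{M O A I R Q}, as returned by
#'     [read_kano_frequencies()]. No screening applies.}
#' }
#'
#' Per item, the final attribute is the modal category (ties broken by
#' `tie_precedence`), SI = (A+O)/(A+O+M+I) and DSI = -(O+M)/(A+O+M+I) at
#' full precision, and the item is placed in the importance-satisfaction
#' plane at (|DSI|, SI). The plane is split at `origin` (by default the
#' per-axis mean over items) into the four strategy quadrants of
#' [assign_quadrant()].
#'
#' @param x respondent-level data.frame or aggregated frequency table.
#' @param codebook a [kano_codebook()]; required for respondent-level input
#'   unless `x` carries one as an attribute (as [read_kano_survey()] and
#'   [simulate_kano_survey()] outputs do).
#' @param screen logical; screen respondents before classification
#'   (respondent-level input only). Default: screen iff the screening
#'   columns are present.
#' @param min_seconds completion-time threshold passed to
#'   [screen_respondents()].
#' @param tie_precedence tie-break order for [modal_category()].
#' @param origin optional fixed origin \code{c(x0 = , y0 = )}; by default
#'   computed from the fitted full-precision indices via [kano_origin()].
#' @return An object of class \code{"kano"}: a list with components
#'   \code{items} (per-item data.frame: counts, \code{n_total},
#'   \code{category}, \code{is_tie}, \code{si}, \code{dsi},
#'   \code{quadrant}), \code{origin}, \code{attribute_tally},
#'   \code{quadrants} (named list of item ids per quadrant, sorted),
#'   \code{screening} (a [screen_respondents()] result or `NULL`) and
#'   \code{call}.
#' @seealso [summary.kano()], [plot.kano()], [simulate.kano()],
#'   [nurse_demand_frequencies()] for a complete worked dataset.
#' @export
#' @examples
#' fit <- kano(nurse_demand_frequencies())
#' fit
#' coef(fit)[1:3, ]
kano <- function(x, codebook = NULL, screen = NULL, min_seconds = 180,
                 tie_precedence = c("M", "O", "A", "I", "R", "Q"),
                 origin = NULL) {
  cl <- match.call()
  screening <- NULL

  if (is.data.frame(x) && all(.kano_tags %in% names(x)) && is.null(codebook) &&
      is.null(attr(x, "codebook"))) {
    # aggregated per-item frequency table
    if (!all(c("item", "label") %in% names(x))) {
      x$item <- if (is.null(x$item)) seq_len(nrow(x)) else x$item
      x$label <- if (is.null(x$label)) as.character(x$item) else x$label
    }
    freq <- as.matrix(x[, .kano_tags])
    rownames(freq) <- as.character(x$item)
    items <- data.frame(item_id = as.character(x$item), label = x$label,
                        stringsAsFactors = FALSE)
  } else {
    if (is.null(codebook)) codebook <- attr(x, "codebook")
    if (is.null(codebook)) {
      stop("respondent-level input needs a codebook (see kano_codebook())",
           call. = FALSE)
    }
    codebook <- as_codebook(codebook, x)
    do_screen <- if (is.null(screen)) {
      any(c("completion_seconds", "logic_error") %in% names(x))
    } else isTRUE(screen)
    if (do_screen) {
      screening <- screen_respondents(
        x, min_seconds = min_seconds,
        time_column = if ("completion_seconds" %in% names(x)) "completion_seconds" else NULL,
        logic_column = if ("logic_error" %in% names(x)) "logic_error" else NULL
      )
      x <- screening$kept
    }
    freq <- t(vapply(seq_len(nrow(codebook)), function(i) {
      f <- x[[codebook$functional_column[[i]]]]
      d <- x[[codebook$dysfunctional_column[[i]]]]
      ok <- !is.na(f) & !is.na(d)
      if (!any(ok)) {
        stop(sprintf("item '%s' has no complete response pairs",
                     codebook$item_id[[i]]), call. = FALSE)
      }
      tabulate_item(f[ok], d[ok], codebook$item_id[[i]])
    }, stats::setNames(integer(6), .kano_tags)))
    rownames(freq) <- codebook$item_id
    items <- data.frame(item_id = codebook$item_id, label = codebook$label,
                        stringsAsFactors = FALSE)
  }

  modal <- lapply(seq_len(nrow(freq)), function(i) {
    modal_category(freq[i, ], precedence = tie_precedence)
  })
  items <- cbind(items, as.data.frame(freq))
  items$n_total <- as.integer(rowSums(freq))
  items$category <- vapply(modal, `[[`, character(1), "category")
  items$is_tie <- vapply(modal, `[[`, logical(1), "is_tie")
  items$si <- apply(freq, 1, satisfaction_index)
  items$dsi <- apply(freq, 1, importance_index)

  if (is.null(origin)) origin <- kano_origin(items$si, items$dsi)
  stopifnot(all(c("x0", "y0") %in% names(origin)))
  items$quadrant <- assign_quadrant(items$si, items$dsi, origin)

  tally <- table(factor(items$category, levels = .kano_tags))
  quadrants <- lapply(stats::setNames(nm = names(.quadrant_strategies)),
                      function(q) sort_ids(items$item_id[items$quadrant == q]))

  structure(
    list(items = items, origin = origin,
         attribute_tally = stats::setNames(as.integer(tally), .kano_tags),
         quadrants = quadrants, screening = screening, call = cl),
    class = "kano"
  )
}

# Sort item ids numerically when they all look numeric, else lexically.
sort_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) ids[order(num)] else sort(ids)
}

#' @export
print.kano <- function(x, ...) {
  cat(sprintf("Kano needs analysis: %d items", nrow(x$items)))
  if (!is.null(x$screening)) {
    cat(sprintf(", %d valid respondents (of %d received)",
                x$screening$report$n_valid, x$screening$report$n_received))
  }
  cat("\n")
  tally <- x$attribute_tally[x$attribute_tally > 0]
  cat("Attributes: ",
      paste(sprintf("%s:%d", names(tally), tally), collapse = "  "), "\n", sep = "")
  cat(sprintf("Matrix origin: mean |DSI| = %.2f, mean SI = %.2f\n",
              x$origin[["x0"]], x$origin[["y0"]]))
  if (any(x$items$is_tie)) {
    cat("Note: modal-category tie on item(s) ",
        paste(x$items$item_id[x$items$is_tie], collapse = ", "),
        " (tie-break precedence applied)\n", sep = "")
  }
  invisible(x)
}

#' Summarise a Kano analysis
#'
#' @param object a fitted [kano()] object.
#' @param digits decimal places for displayed indices (display only; the
#'   object keeps full precision).
#' @param ... unused.
#' @return An object of class \code{"summary.kano"} whose print method shows
#'   the per-item table (counts, attribute, DSI, SI, quadrant), the origin,
#'   the attribute tally, quadrant memberships and any screening report.
#' @export
summary.kano <- function(object, digits = 2, ...) {
  it <- object$items
  tab <- data.frame(
    item = it$item_id, label = it$label,
    it[, .kano_tags],
    attribute = ifelse(it$is_tie, paste0(it$category, "*"), it$category),
    DSI = round_half_up(it$dsi, digits),
    SI = round_half_up(it$si, digits),
    quadrant = as.character(it$quadrant),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  structure(list(table = tab, origin = object$origin,
                 attribute_tally = object$attribute_tally,
                 quadrants = object$quadrants,
                 screening = object$screening, digits = digits),
            class = "summary.kano")
}

#' @export
print.summary.kano <- function(x, ...) {
  if (!is.null(x$screening)) print(x$screening)
  print(x$table, row.names = FALSE)
  if (any(endsWith(x$table$attribute, "*"))) {
    cat("  (* modal tie, broken by precedence)\n")
  }
  cat(sprintf("\nOrigin: (mean |DSI|, mean SI) = (%.*f, %.*f)\n",
              x$digits, x$origin[["x0"]], x$digits, x$origin[["y0"]]))
  tally <- x$attribute_tally[x$attribute_tally > 0]
  cat("Attribute tally: ",
      paste(sprintf("%s:%d", names(tally), tally), collapse = "  "), "\n", sep = "")
  strat <- quadrant_strategies()
  for (q in names(x$quadrants)) {
    cat(sprintf("Quadrant %-3s (%s): %s\n", q, strat[[q]],
                if (length(x$quadrants[[q]])) paste(x$quadrants[[q]], collapse = ", ")
                else "-"))
  }
  invisible(x)
}

#' Per-item coefficients of a Kano analysis
#'
#' @param object a fitted [kano()] object.
#' @param ... unused.
#' @return Numeric matrix with one row per item and columns \code{si} and
#'   \code{dsi}, at full precision.
#' @export
coef.kano <- function(object, ...) {
  m <- cbind(si = object$items$si, dsi = object$items$dsi)
  rownames(m) <- object$items$item_id
  m
}

#' Importance-satisfaction matrix plot
#'
#' Scatter of the items at (|DSI|, SI) with cross-hairs at the matrix origin
#' and the four strategy quadrants annotated. Base graphics; intended as a
#' quick diagnostic, not a publication figure.
#'
#' @param x a fitted [kano()] object.
#' @param labels item labels to draw; defaults to item ids.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kano <- function(x, labels = x$items$item_id, ...) {
  it <- x$items
  xs <- abs(it$dsi)
  graphics::plot(xs, it$si, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "importance |DSI|", ylab = "satisfaction SI",
                 pch = 19, col = as.integer(it$quadrant) + 1L, ...)
  graphics::abline(v = x$origin[["x0"]], h = x$origin[["y0"]], lty = 2)
  graphics::text(xs, it$si, labels = labels, pos = 3, cex = 0.7)
  corners <- cbind(x = c(0.97, 0.03, 0.03, 0.97), y = c(0.97, 0.97, 0.03, 0.03))
  graphics::text(corners[, "x"], corners[, "y"], names(quadrant_strategies()),
                 col = "grey40")
  invisible(x)
}

#' Simulate survey datasets from a fitted Kano analysis
#'
#' Draws respondent-level datasets whose per-item response-pair
#' distributions are implied by the fitted frequencies (each item's category
#' mass spread uniformly over that category's evaluation-table cells, via
#' [profile_from_frequencies()]). Useful for parametric-bootstrap checks of
#' classification stability.
#'
#' @param object a fitted [kano()] object.
#' @param nsim number of datasets.
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param n respondents per dataset; defaults to the fitted per-item maximum
#'   \code{n_total}.
#' @param ... passed to [simulate_kano_survey()].
#' @return A list of `nsim` wide data.frames (each with a codebook
#'   attribute).
#' @export
#' @examples
#' fit <- kano(nurse_demand_frequencies())
#' sims <- simulate(fit, nsim = 1, seed = 1, n = 50)
#' dim(sims[[1]])
simulate.kano <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  profiles <- lapply(seq_len(nrow(object$items)), function(i) {
    profile_from_frequencies(unlist(object$items[i, .kano_tags]))
  })
  names(profiles) <- object$items$item_id
  if (is.null(n)) n <- max(object$items$n_total)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      simulate_kano_survey(profiles, n = n, ...)
    })
  })
}
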