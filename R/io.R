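# Readers and writers: wide respondent-level CSV + codebook, the aggregated
# per-item frequency dialect, and report emission.

#' Build a codebook for a wide paired-Likert survey table
#'
#' A codebook names the items and says which two columns of the wide table
#' hold each item's functional and dysfunctional answers. The default column
#' naming convention is \code{<item_id>_func} / \code{<item_id>_dys}, which
#' is also what [simulate_kano_survey()] emits.
#'
#' @param item_id character vector of unique item identifiers.
#' @param label human-readable item labels (defaults to `item_id`).
#' @param functional_column,dysfunctional_column column names in the data
#'   file; defaults follow the convention above.
#' @return data.frame of class \code{"kano_codebook"} with one row per item.
#' @export
#' @examples
#' kano_codebook(c("i1", "i2"), c("Mood diary", "White noise"))
kano_codebook <- function(item_id, label = item_id,
                          functional_column = paste0(item_id, "_func"),
                          dysfunctional_column = paste0(item_id, "_dys")) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id)) stop("item ids must be unique", call. = FALSE)
  structure(
    data.frame(item_id = item_id, label = as.character(label),
               functional_column = functional_column,
               dysfunctional_column = dysfunctional_column,
               stringsAsFactors = FALSE),
    class = c("kano_codebook", "data.frame")
  )
}

#' Read a codebook from JSON or YAML
#'
#' The file holds an \code{items} array of objects with fields
#' \code{item_id}, \code{label}, \code{functional_column},
#' \code{dysfunctional_column}, and optionally a \code{likert_mapping}
#' object remapping raw answer codes to the canonical 1..5 coding
#' (1 = like .. 5 = dislike), e.g. \code{{"5": 1, ...}} for a reversed scale.
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{"kano_codebook"} data.frame; any \code{likert_mapping} is
#'   attached as an attribute and applied by [read_kano_survey()].
#' @export
read_codebook <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML codebooks requires the 'yaml' package", call. = FALSE)
    }
    yaml::yaml.load_file(path)
  } else {
    stop("codebook must be .json, .yaml or .yml", call. = FALSE)
  }
  items <- raw$items
  if (is.null(items)) stop("codebook has no 'items' entry", call. = FALSE)
  if (!is.data.frame(items)) {
    items <- do.call(rbind, lapply(items, function(it) as.data.frame(it, stringsAsFactors = FALSE)))
  }
  cb <- kano_codebook(
    items$item_id, items$label,
    items$functional_column, items$dysfunctional_column
  )
  if (!is.null(raw$likert_mapping)) {
    lm <- unlist(raw$likert_mapping)
    attr(cb, "likert_mapping") <- stats::setNames(as.integer(lm), names(lm))
  }
  cb
}

# Coerce/validate a codebook against a data.frame's columns.
as_codebook <- function(codebook, data = NULL) {
  if (!inherits(codebook, "kano_codebook")) {
    codebook <- kano_codebook(codebook$item_id, codebook$label,
                              codebook$functional_column,
                              codebook$dysfunctional_column)
  }
  if (!is.null(data)) {
    need <- c(codebook$functional_column, codebook$dysfunctional_column)
    miss <- setdiff(need, names(data))
    if (length(miss)) {
      stop(sprintf("codebook references missing columns: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  codebook
}

#' Read a wide respondent-level Kano survey CSV
#'
#' One row per respondent; two Likert columns per item, named by the
#' codebook. Every referenced cell is validated to the 1..5 coding; invalid
#' cells are reported with their row number and column name. A
#' \code{likert_mapping} attached to the codebook is applied to the raw codes
#' first.
#'
#' @param path CSV path.
#' @param codebook a [kano_codebook()] (or the result of [read_codebook()]).
#' @return data.frame of validated respondents with the codebook attached as
#'   attribute \code{"codebook"}.
#' @export
read_kano_survey <- function(path, codebook) {
  data <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  codebook <- as_codebook(codebook, data)
  mapping <- attr(codebook, "likert_mapping")
  cols <- c(codebook$functional_column, codebook$dysfunctional_column)
  bad <- character(0)
  for (cl in cols) {
    v <- data[[cl]]
    if (!is.null(mapping)) {
      m <- mapping[as.character(v)]
      v <- ifelse(is.na(m), v, m)
    }
    vi <- suppressWarnings(as.integer(v))
    vn <- suppressWarnings(as.numeric(v))
    ok <- !is.na(vi) & vi >= 1L & vi <= 5L & vi == vn
    if (any(!ok)) {
      bad <- c(bad, sprintf("row %d, column '%s': %s",
                            which(!ok), cl, data[[cl]][!ok]))
    }
    data[[cl]] <- vi
  }
  if (length(bad)) {
    stop("invalid Likert codes (must be integers 1..5):\n  ",
         paste(utils::head(bad, 10L), collapse = "\n  "),
         if (length(bad) > 10L) sprintf("\n  ... and %d more", length(bad) - 10L),
         call. = FALSE)
  }
  attr(data, "codebook") <- codebook
  data
}

#' Read an aggregated per-item Kano frequency table
#'
#' The aggregated dialect has one row per item with columns \code{item},
#' \code{label}, and the six category counts \code{M O A I R Q} (extra
#' columns such as published attribute letters or indices are carried along
#' untouched). Field separator is sniffed from the header (tab or comma),
#' and any Unicode minus signs (common in typeset tables) are normalised to
#' ASCII on read.
#'
#' @param path TSV or CSV path.
#' @return data.frame with one row per item; counts as integers.
#' @export
read_kano_frequencies <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- gsub("−", "-", lines)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  data <- utils::read.table(text = lines, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"")
  need <- c("item", "label", .kano_tags)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("frequency table lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  for (tag in .kano_tags) {
    v <- data[[tag]]
    if (any(is.na(v)) || any(v < 0) || any(v != as.integer(v))) {
      stop(sprintf("column '%s' must hold non-negative integer counts", tag),
           call. = FALSE)
    }
    data[[tag]] <- as.integer(v)
  }
  data
}

#' Nurse digital mental-health demand frequencies
#'
#' Bundled per-item Kano frequency table from a cross-sectional survey of
#' 1,571 tertiary-hospital nurses rating 26 candidate features of a digital
#' mental-health support platform (intelligent emotion monitoring,
#' professional counselling, mindfulness practice, privacy protection, ...).
#' Each row gives the item's counts over the six Kano categories together
#' with the attribute letter and 2-dp DSI/SI values as originally published,
#' so recomputed results can be checked against the published ones.
#'
#' @return data.frame with 26 rows and columns \code{item}, \code{label},
#'   \code{M}, \code{O}, \code{A}, \code{I}, \code{R}, \code{Q},
#'   \code{published_attribute}, \code{published_DSI}, \code{published_SI}.
#' @export
#' @examples
#' head(nurse_demand_frequencies())
nurse_demand_frequencies <- function() {
  path <- system.file("extdata", "nurse_demand_frequencies.tsv",
                      package = "kanor", mustWork = TRUE)
  read_kano_frequencies(path)
}

#' Write a Kano analysis report
#'
#' Emits the per-item results as a TSV (counts, attribute, full-precision
#' SI/DSI, quadrant) and, optionally, a JSON summary (screening report,
#' origin, attribute tally, quadrant memberships). Values are written at
#' full precision; rounding happens only in display methods, so re-reading
#' the TSV reproduces identical downstream results.
#'
#' @param object a fitted [kano()] object.
#' @param tsv path for the per-item table; `NULL` to skip.
#' @param json path for the JSON summary; `NULL` to skip.
#' @return `object`, invisibly.
#' @export
write_kano_report <- function(object, tsv = NULL, json = NULL) {
  stopifnot(inherits(object, "kano"))
  if (!is.null(tsv)) {
    utils::write.table(object$items, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(json)) {
    payload <- list(
      screening = object$screening$report,
      origin = as.list(object$origin),
      attribute_tally = as.list(object$attribute_tally),
      quadrant_membership = object$quadrants
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(object)
}
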