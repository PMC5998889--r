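# Time labels are numeric with an optional trailing unit ("780", "780min",
# "2h", "2 h"); comparisons are on the numeric value only.
parse_time_labels <- function(labels) {
  m <- regmatches(labels,
                  regexec("^\\s*([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(min\\.?|hours?|hrs?|h|m|s)?\\s*$",
                          labels))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("cannot parse time label(s): ",
         paste(shQuote(labels[bad]), collapse = ", "), call. = FALSE)
  }
  data.frame(label = trimws(labels),
             value = vapply(m, function(g) as.numeric(g[2]), numeric(1)),
             unit = vapply(m, function(g) sub("\\.$", "", g[3]), character(1)),
             stringsAsFactors = FALSE)
}

default_time_points <- function(n) {
  data.frame(label = paste0("t", seq_len(n)), value = as.numeric(seq_len(n)),
             unit = rep("", n), stringsAsFactors = FALSE)
}

#' Construct a time-course expression profile
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   time points in columns.
#' @param time_points Data frame with columns `label`, `value`, `unit`, one
#'   row per column of `values` and strictly increasing `value`; or a
#'   character vector of time labels to be parsed. Defaults to unit-spaced
#'   times `t1, t2, ...`.
#' @return An `ExpressionProfile` object.
#' @export
expression_profile <- function(values, time_points = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("expression matrix needs gene ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene ", shQuote(rownames(values)[bad[1]]),
         ", column ", bad[2], call. = FALSE)
  }
  if (is.null(time_points)) time_points <- default_time_points(ncol(values))
  if (is.character(time_points)) time_points <- parse_time_labels(time_points)
  if (nrow(time_points) != ncol(values)) {
    stop("time point table does not match the number of columns", call. = FALSE)
  }
  if (any(diff(time_points$value) <= 0)) stop("time points not increasing", call. = FALSE)
  structure(list(values = values, time_points = time_points),
            class = "ExpressionProfile")
}

#' @export
print.ExpressionProfile <- function(x, ...) {
  tp <- x$time_points
  cat("Expression profile: ", nrow(x$values), " genes x ", nrow(tp),
      " time points (", tp$value[1], "-", tp$value[nrow(tp)],
      if (nzchar(tp$unit[1])) paste0(" ", tp$unit[1]), ")\n", sep = "")
  invisible(x)
}

#' Read a time-course expression table
#'
#' The first row carries the time labels (numeric, optional unit suffix such
#' as `min` or `h`), the first column the gene ids. Replicate columns that
#' share a time label are averaged into a single column. Malformed cells are
#' rejected with their location; silently coercing is never done.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return An `ExpressionProfile`.
#' @export
read_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  tab <- read_numeric_table(path, dialect)
  tp <- parse_time_labels(colnames(tab))
  # average replicate columns sharing a time label
  grp <- match(tp$label, unique(tp$label))
  if (anyDuplicated(grp)) {
    vals <- vapply(split(seq_along(grp), grp),
                   function(ix) rowMeans(tab[, ix, drop = FALSE]),
                   numeric(nrow(tab)))
    vals <- matrix(vals, nrow = nrow(tab),
                   dimnames = list(rownames(tab), NULL))
    tp <- tp[!duplicated(grp), , drop = FALSE]
  } else {
    vals <- tab
  }
  if (any(diff(tp$value) <= 0)) stop("time points not increasing", call. = FALSE)
  expression_profile(vals, tp)
}

# Shared strict reader: character ingest, per-cell numeric validation with
# row/column location in the error message.
read_numeric_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("table needs a gene-id column and >= 1 time column", call. = FALSE)
  ids <- trimws(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- is.na(num) | is.nan(num)
  if (any(bad)) {
    at <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing value ", shQuote(cells[at[1], at[2]]),
         " at row ", at[1] + 1L, " (gene ", shQuote(ids[at[1]]), "), column ",
         at[2] + 1L, call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- colnames(raw)[-1L]
  num
}
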