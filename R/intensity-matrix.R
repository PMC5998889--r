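#' Construct a regulation-intensity matrix
#'
#' `M[g, j]` is signed evidence that the regulation of gene `g` is active at
#' time point `j`: positive when the upstream regulators explain the gene's
#' expression there, negative when they do not.
#'
#' @param values Numeric matrix, regulated genes in rows (rownames = gene
#'   ids), time points in columns; all values finite.
#' @param time_points Optional time-point table (as in
#'   [expression_profile()]) or character labels; defaults to `t1, t2, ...`.
#' @return An `IntensityMatrix` object.
#' @export
intensity_matrix <- function(values, time_points = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in intensity matrix", call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite intensity at gene ", shQuote(rownames(values)[bad[1]]),
         ", column ", bad[2], call. = FALSE)
  }
  if (is.null(time_points)) time_points <- default_time_points(ncol(values))
  if (is.character(time_points)) time_points <- parse_time_labels(time_points)
  if (nrow(time_points) != ncol(values)) {
    stop("time point table does not match the number of columns", call. = FALSE)
  }
  colnames(values) <- time_points$label
  structure(list(values = values, time_points = time_points),
            class = "IntensityMatrix")
}

# Accept either a plain numeric matrix or an IntensityMatrix everywhere.
intensity_values <- function(M) {
  if (inherits(M, "IntensityMatrix")) return(M$values)
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  M
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat("Intensity matrix: ", nrow(x$values), " regulated genes x ",
      ncol(x$values), " time points; ",
      sprintf("%.1f%% positive", 100 * mean(x$values > 0)), "\n", sep = "")
  invisible(x)
}

#' Read an intensity matrix from a TSV/CSV table
#'
#' Same layout as [read_expression()] (header = time labels, first column =
#' gene ids) but without replicate averaging; ragged or non-numeric rows and
#' NaN values are rejected with their location.
#'
#' @inheritParams read_expression
#' @return An `IntensityMatrix`.
#' @export
read_intensity <- function(path, dialect = c("tsv", "csv")) {
  tab <- read_numeric_table(path, match.arg(dialect))
  # non-numeric headers (e.g. "t1") fall back to unit-spaced times
  tp <- tryCatch(parse_time_labels(colnames(tab)), error = function(e) {
    data.frame(label = colnames(tab), value = as.numeric(seq_len(ncol(tab))),
               unit = rep("", ncol(tab)), stringsAsFactors = FALSE)
  })
  intensity_matrix(tab, tp)
}

#' Write an intensity matrix to TSV
#'
#' Values are printed with 17 significant digits, so
#' `read_intensity(write_intensity(M, f))` reproduces `M` exactly.
#'
#' @param M An `IntensityMatrix` or numeric matrix.
#' @param path Output path.
#' @export
write_intensity <- function(M, path) {
  M <- if (inherits(M, "IntensityMatrix")) M else intensity_matrix(M)
  vals <- M$values
  header <- paste(c("gene", M$time_points$label), collapse = "\t")
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
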