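#' Construct a directed gene regulatory network
#'
#' @param edges Data frame with columns `regulator`, `target` and optionally
#'   `sign` (+1 activation, -1 repression, NA unknown). Duplicate
#'   (regulator, target) pairs are collapsed; self-loops are kept but
#'   trigger a warning, and a gene's own expression is never used as a
#'   predictor of itself downstream.
#' @return A `RegulatoryNetwork` object.
#' @export
regulatory_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target") %in% names(edges))) {
    stop("edges need 'regulator' and 'target' columns", call. = FALSE)
  }
  if (is.null(edges$sign)) edges$sign <- NA_integer_
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (any(!is.na(edges$sign) & !edges$sign %in% c(-1L, 1L))) {
    stop("edge sign must be +1, -1 or NA", call. = FALSE)
  }
  edges <- edges[!duplicated(edges[c("regulator", "target")]), , drop = FALSE]
  rownames(edges) <- NULL
  loops <- edges$regulator == edges$target
  if (any(loops)) {
    warning("self-loop(s) on: ", paste(edges$regulator[loops], collapse = ", "),
            " (kept; a gene never predicts itself)", call. = FALSE)
  }
  structure(list(edges = edges), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat("Regulatory network: ", length(network_genes(x)), " genes, ",
      nrow(x$edges), " regulations\n", sep = "")
  invisible(x)
}

#' All gene ids appearing in a network
#' @param network A `RegulatoryNetwork`.
#' @export
network_genes <- function(network) {
  unique(c(network$edges$regulator, network$edges$target))
}

#' Parent set of a gene
#'
#' @param network A `RegulatoryNetwork`.
#' @param gene Gene id.
#' @param exclude_self Drop a self-loop from the parent set (default TRUE:
#'   a gene cannot explain itself).
#' @return Character vector of regulator ids (empty for unregulated genes).
#' @export
parents <- function(network, gene, exclude_self = TRUE) {
  p <- network$edges$regulator[network$edges$target == gene]
  if (exclude_self) p <- setdiff(p, gene)
  unique(p)
}

#' Genes with at least one (non-self) regulator
#' @param network A `RegulatoryNetwork`.
#' @export
regulated_genes <- function(network) {
  tg <- unique(network$edges$target)
  tg[vapply(tg, function(g) length(parents(network, g)) > 0L, logical(1))]
}

#' Convert a network to an igraph graph
#' @param network A `RegulatoryNetwork`.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[c("regulator", "target")],
                                directed = TRUE)
}

SIGN_TOKENS <- c("+" = 1L, "+1" = 1L, "1" = 1L, "activation" = 1L, "activates" = 1L,
                 "-" = -1L, "-1" = -1L, "repression" = -1L, "represses" = -1L,
                 "unknown" = NA_integer_, "?" = NA_integer_, "regulates" = NA_integer_)

#' Read a regulatory network from an edge list or SIF file
#'
#' `tsv_edges`: 2-3 tab-separated columns `regulator target [sign]`, where
#' sign is one of `+`, `-`, `+1`, `-1`, `activation`, `repression`,
#' `unknown`. `sif`: lines `source relation target [target2 ...]`; the
#' relation maps to a sign when recognized, otherwise must be a known token.
#'
#' @param path Path to the file.
#' @param format `"tsv_edges"` (default) or `"sif"`.
#' @return A `RegulatoryNetwork`.
#' @export
read_network <- function(path, format = c("tsv_edges", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)
  parse_sign <- function(token, lineno) {
    token <- tolower(trimws(token))
    if (!token %in% names(SIGN_TOKENS)) {
      stop("unknown sign token ", shQuote(token), " on line ", lineno, call. = FALSE)
    }
    SIGN_TOKENS[[token]]
  }
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    if (format == "tsv_edges") {
      if (length(f) < 2L) stop("line ", i, ": need regulator and target", call. = FALSE)
      sign <- if (length(f) >= 3L) parse_sign(f[3L], i) else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(regulator = f[1L], target = f[2L],
                                              sign = sign)
    } else {
      if (length(f) < 3L) stop("line ", i, ": SIF needs 'source relation target'", call. = FALSE)
      sign <- if (tolower(f[2L]) %in% names(SIGN_TOKENS)) SIGN_TOKENS[[tolower(f[2L])]]
              else NA_integer_
      for (tg in f[-(1:2)]) {
        rows[[length(rows) + 1L]] <- data.frame(regulator = f[1L], target = tg,
                                                sign = sign)
      }
    }
  }
  regulatory_network(do.call(rbind, rows))
}
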