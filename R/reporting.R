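#' Classify which genes are controlled in each period
#'
#' A gene counts as controlled in a period when the mean of its intensity
#' over the period's time points is strictly positive (a mean of exactly
#' zero classifies as not controlled, matching the tie rule of the
#' segmentation). Because the mean and the sum differ by a positive factor,
#' the classification agrees with the best model's activity whenever no
#' period mean is exactly zero.
#'
#' @param M An `IntensityMatrix` or numeric matrix.
#' @param tra Break set defining the periods.
#' @return A `PeriodReport`: `periods` (index, start/end time value),
#'   `mean_intensity` (gene x period), `controlled` (logical gene x period).
#' @export
classify_period_activity <- function(M, tra) {
  vals <- intensity_values(M)
  tp <- if (inherits(M, "IntensityMatrix")) M$time_points
        else default_time_points(ncol(vals))
  periods <- periods_from_breaks(tra, ncol(vals))
  mean_int <- vapply(periods, function(idx) rowMeans(vals[, idx, drop = FALSE]),
                     numeric(nrow(vals)))
  mean_int <- matrix(mean_int, nrow = nrow(vals),
                     dimnames = list(rownames(vals),
                                     paste0("period", seq_along(periods))))
  pdf <- data.frame(
    index = seq_along(periods),
    start_label = tp$label[vapply(periods, `[`, integer(1), 1L)],
    start_value = tp$value[vapply(periods, `[`, integer(1), 1L)],
    end_label = tp$label[vapply(periods, function(ix) ix[length(ix)], integer(1))],
    end_value = tp$value[vapply(periods, function(ix) ix[length(ix)], integer(1))],
    stringsAsFactors = FALSE)
  structure(list(periods = pdf, mean_intensity = mean_int,
                 controlled = mean_int > 0),
            class = "PeriodReport")
}

#' @export
print.PeriodReport <- function(x, ...) {
  cat("Period report: ", nrow(x$periods), " period(s), ",
      nrow(x$controlled), " genes\n", sep = "")
  for (p in seq_len(nrow(x$periods))) {
    cat(sprintf("  period %d [%s .. %s]: %d/%d controlled\n", p,
                x$periods$start_label[p], x$periods$end_label[p],
                sum(x$controlled[, p]), nrow(x$controlled)))
  }
  invisible(x)
}

#' Score-versus-period table of a search result
#'
#' One row per evaluated break count, reported as a period count (k + 1)
#' with the penalized score; the best row is flagged, and rows evaluated
#' only for reference after an early stop are marked.
#'
#' @param result A `SegmentationResult`.
#' @return Data frame with `periods`, `score`, `best`, `reference`.
#' @export
score_table <- function(result) {
  stopifnot(inherits(result, "SegmentationResult"))
  data.frame(
    periods = vapply(result$per_k, function(e) e$k + 1L, integer(1)),
    score = vapply(result$per_k, `[[`, numeric(1), "score"),
    best = vapply(result$per_k, function(e) {
      !e$reference && identical(e$tra, result$best$tra) &&
        e$score == result$best$score
    }, logical(1)),
    reference = vapply(result$per_k, `[[`, logical(1), "reference"))
}

#' Breakpoint time labels of a model
#'
#' The reported label of a break is the time value of the last point of the
#' earlier period; the index and both flanking time values are included.
#'
#' @param tra Break set.
#' @param time_points Time-point table; defaults to unit-spaced times.
#' @param n_time Number of time points (needed only without `time_points`).
#' @export
breakpoint_times <- function(tra, time_points = NULL, n_time = NULL) {
  if (is.null(time_points)) {
    if (is.null(n_time)) stop("need time_points or n_time", call. = FALSE)
    time_points <- default_time_points(n_time)
  }
  tra <- validate_breaks(tra, nrow(time_points))
  data.frame(index = tra,
             label = time_points$label[tra],
             time_before = time_points$value[tra],
             time_after = time_points$value[tra + 1L],
             stringsAsFactors = FALSE)
}

#' Export a result as flat TSV reports
#'
#' Writes `score_table.tsv`, `periods.tsv` and `activity_by_period.tsv`
#' under `dir`.
#'
#' @param result A `SegmentationResult`.
#' @param M The intensity matrix the search ran on.
#' @param dir Output directory (created if missing).
#' @export
export_report <- function(result, M, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- classify_period_activity(M, result$best$tra)
  tsv <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(score_table(result), "score_table.tsv")
  tsv(rep$periods, "periods.tsv")
  act <- data.frame(gene = rownames(rep$controlled),
                    ifelse(rep$controlled, "controlled", "not_controlled"),
                    check.names = FALSE)
  tsv(act, "activity_by_period.tsv")
  invisible(dir)
}

#' Write a segmentation result to JSON
#'
#' The file records the breaks (index and time labels), the periods (start
#' and end time of each), the per-gene per-period activity of the best
#' model, the score-versus-k table and the search settings, in stable key
#' order and at full double precision.
#'
#' @param result A `SegmentationResult`.
#' @param path Output path.
#' @param seed Optional integer recorded under settings.
#' @export
write_result <- function(result, path, seed = NULL) {
  stopifnot(inherits(result, "SegmentationResult"))
  best <- result$best
  tp <- result$time_points
  n_time <- ncol(best$act)
  if (is.null(tp)) tp <- default_time_points(n_time)
  periods <- periods_from_breaks(best$tra, n_time)
  act_periods <- lapply(seq_len(nrow(best$act)), function(i) {
    vapply(periods, function(ix) best$act[i, ix[1L]], numeric(1))
  })
  names(act_periods) <- rownames(best$act) %||% paste0("g", seq_len(nrow(best$act)))
  obj <- list(
    breaks = breakpoint_times(best$tra, tp),
    periods = lapply(periods, function(ix) {
      list(start = tp$value[ix[1L]], end = tp$value[ix[length(ix)]])
    }),
    activity = act_periods,
    score_table = lapply(result$per_k, function(e) {
      list(k = e$k, score = e$score, reference = e$reference)
    }),
    best = list(k = length(best$tra), raw_score = best$raw_score,
                score = best$score),
    settings = list(penalty_factor = result$penalty_factor,
                    penalty_mode = result$penalty_mode,
                    search_mode = result$search_mode,
                    stopped_early = result$stopped_early,
                    seed = seed)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(path)
}
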