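#' Index ranges of the periods induced by a break set
#'
#' A break at index `j` means one period ends at the j-th time point and the
#' next starts at the (j+1)-th, so a break set `tra` of size k partitions
#' `1:n_time` into k + 1 contiguous periods.
#'
#' @param tra Integer vector of break indices, each in `1:(n_time - 1)`.
#' @param n_time Number of time points.
#' @return List of integer vectors, one per period, covering `1:n_time`.
#' @export
periods_from_breaks <- function(tra, n_time) {
  tra <- validate_breaks(tra, n_time)
  starts <- c(1L, tra + 1L)
  ends <- c(tra, n_time)
  mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
}

validate_breaks <- function(tra, n_time) {
  if (length(tra) == 0L) return(integer(0))
  tra <- as.integer(sort(unique(tra)))
  if (any(tra < 1L) || any(tra > n_time - 1L)) {
    stop("break index out of range 1..", n_time - 1L, call. = FALSE)
  }
  tra
}

#' Break set realized by a binary activity matrix
#'
#' A boundary `j` belongs to the transition set whenever at least one gene
#' changes activity between time points `j` and `j + 1`.
#'
#' @param act Binary (0/1) matrix, genes in rows, time points in columns.
#' @return Sorted integer vector of break indices.
#' @export
derive_transitions <- function(act) {
  act <- as.matrix(act)
  if (!all(act %in% c(0, 1))) stop("activity matrix must be 0/1 valued", call. = FALSE)
  n_time <- ncol(act)
  if (n_time <= 1L) return(integer(0))
  changed <- colSums(abs(act[, -1L, drop = FALSE] - act[, -n_time, drop = FALSE])) > 0
  which(changed)
}

#' Penalized activity score of a model
#'
#' Computes the raw score `sum(M * act)` and the penalized score
#' `raw - penalty_factor * |B| * log(G * T)`, where `B` is the set of
#' penalized breaks: the transitions realized by `act` in `"effective"`
#' mode, or the declared break set `tra` in `"declared"` mode. `G` is the
#' number of rows of `M` (regulated genes) and `T` its number of columns.
#'
#' @param M Intensity matrix (numeric, genes x time points).
#' @param act Binary activity matrix of the same shape.
#' @param penalty_factor Nonnegative multiplier `c` of the BIC-style penalty.
#'   `c = 2` matches the search initialization used by the method; `c = 1`
#'   gives the plain one-per-break penalty.
#' @param penalty_mode `"effective"` counts breaks realized by `act`;
#'   `"declared"` counts the supplied `tra`.
#' @param tra Declared break set; required when `penalty_mode = "declared"`.
#' @return List with `raw_score`, `score`, `penalized_breaks`.
#' @export
score_model <- function(M, act, penalty_factor = 2,
                        penalty_mode = c("effective", "declared"), tra = NULL) {
  penalty_mode <- match.arg(penalty_mode)
  M <- intensity_values(M)
  act <- as.matrix(act)
  if (!identical(dim(M), dim(act))) {
    stop("intensity and activity matrices have different shapes", call. = FALSE)
  }
  if (penalty_factor < 0) stop("penalty_factor must be >= 0", call. = FALSE)
  raw <- sum(M * act)
  b <- if (penalty_mode == "effective") {
    derive_transitions(act)
  } else {
    if (is.null(tra)) stop("declared penalty mode needs a break set", call. = FALSE)
    validate_breaks(tra, ncol(M))
  }
  list(raw_score = raw,
       score = raw - penalty_factor * length(b) * log(nrow(M) * ncol(M)),
       penalized_breaks = b)
}

#' Best period-constant activity vector for one gene
#'
#' Among all binary vectors constant within each period of `tra`, the inner
#' product with the intensity row is maximized by switching each period on
#' exactly when its intensity sum is positive (a zero sum ties towards
#' inactive, preferring the sparser model).
#'
#' @param m_row Numeric intensity vector over the time points.
#' @param tra Break set.
#' @return List with the binary vector `v` and its raw contribution
#'   `row_raw = sum over periods of max(0, period sum)`.
#' @export
best_row_activity <- function(m_row, tra) {
  n_time <- length(m_row)
  periods <- periods_from_breaks(tra, n_time)
  v <- numeric(n_time)
  row_raw <- 0
  for (idx in periods) {
    s <- sum(m_row[idx])
    if (s > 0) {
      v[idx] <- 1
      row_raw <- row_raw + s
    }
  }
  list(v = v, row_raw = row_raw)
}

#' Best activity model for a fixed break set
#'
#' Fills each gene's row with [best_row_activity()] and scores the result.
#' In `"effective"` mode the model is canonicalized: the stored break set is
#' reset to the transitions actually realized by the activity matrix.
#'
#' @inheritParams score_model
#' @param tra Break set defining the periods.
#' @return An `ActivityModel`: list with `act`, `tra`, `raw_score`, `score`,
#'   `penalty_factor`, `penalty_mode`.
#' @export
evaluate_segmentation <- function(M, tra, penalty_factor = 2,
                                  penalty_mode = c("declared", "effective")) {
  penalty_mode <- match.arg(penalty_mode)
  vals <- intensity_values(M)
  tra <- validate_breaks(tra, ncol(vals))
  act <- matrix(0, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  raw <- 0
  for (i in seq_len(nrow(vals))) {
    br <- best_row_activity(vals[i, ], tra)
    act[i, ] <- br$v
    raw <- raw + br$row_raw
  }
  stored_tra <- if (penalty_mode == "effective") derive_transitions(act) else tra
  sc <- score_model(vals, act, penalty_factor, penalty_mode, tra = tra)
  new_activity_model(act, stored_tra, sc$raw_score, sc$score,
                     penalty_factor, penalty_mode)
}

new_activity_model <- function(act, tra, raw_score, score,
                               penalty_factor, penalty_mode) {
  structure(list(act = act, tra = tra, raw_score = raw_score, score = score,
                 penalty_factor = penalty_factor, penalty_mode = penalty_mode),
            class = "ActivityModel")
}

#' @export
print.ActivityModel <- function(x, ...) {
  cat("Activity model: ", length(x$tra) + 1L, " period(s), breaks {",
      paste(x$tra, collapse = ", "), "}\n", sep = "")
  cat(sprintf("  raw score %.6g, penalized score %.6g (c = %g, %s mode)\n",
              x$raw_score, x$score, x$penalty_factor, x$penalty_mode))
  invisible(x)
}

# Period sums for every row of the prefix matrix P (G x (T+1)), given
# period start/end indices; the raw score of a break set is
# sum over genes and periods of max(0, period sum).
segment_raw <- function(P, starts, ends) {
  raw <- 0
  for (p in seq_along(starts)) {
    s <- P[, ends[p] + 1L] - P[, starts[p]]
    raw <- raw + sum(s[s > 0])
  }
  raw
}

#' Exhaustive search over break sets
#'
#' For k = 0, 1, 2, ... evaluates every break set of size k, keeping the
#' best-scoring one (ties resolved to the lexicographically smallest set,
#' then to the smallest k). With `early_stop = TRUE` the k-loop terminates
#' as soon as the best score at k does not improve on k - 1 (the method's
#' stopping rule); a few larger k are still evaluated and reported for
#' reference but never selected as the best model.
#'
#' @inheritParams score_model
#' @param max_breaks Largest break count examined; defaults to `T - 1`.
#' @param early_stop Stop the search when the score stops improving.
#' @param reference_k After an early stop at `k`, how many additional break
#'   counts to tabulate for reference (default 2).
#' @return A `SegmentationResult`; see [search_dp()] for the layout.
#' @export
search_exhaustive <- function(M, penalty_factor = 2,
                              penalty_mode = c("declared", "effective"),
                              max_breaks = NULL, early_stop = TRUE,
                              reference_k = 2L) {
  penalty_mode <- match.arg(penalty_mode)
  vals <- intensity_values(M)
  if (nrow(vals) == 0L || ncol(vals) == 0L) stop("empty intensity matrix", call. = FALSE)
  n_time <- ncol(vals)
  if (is.null(max_breaks)) max_breaks <- n_time - 1L
  max_breaks <- min(as.integer(max_breaks), n_time - 1L)
  P <- cbind(0, t(apply(vals, 1L, cumsum)))
  ln_gt <- log(nrow(vals) * n_time)

  per_k <- list()
  stopped_early <- FALSE
  k_stop <- NA_integer_
  for (k in 0:max_breaks) {
    best_score <- -Inf
    best_tra <- NULL
    cands <- if (k == 0L) list(integer(0)) else
      asplit(utils::combn(n_time - 1L, k), 2L)
    for (tra in cands) {
      tra <- as.integer(tra)
      if (penalty_mode == "declared") {
        raw <- segment_raw(P, c(1L, tra + 1L), c(tra, n_time))
        score <- raw - penalty_factor * k * ln_gt
      } else {
        score <- evaluate_segmentation(vals, tra, penalty_factor, "effective")$score
      }
      if (score > best_score) {
        best_score <- score
        best_tra <- tra
      }
    }
    model <- evaluate_segmentation(vals, best_tra, penalty_factor, penalty_mode)
    per_k[[k + 1L]] <- list(k = k, tra = model$tra, act = model$act,
                            raw_score = model$raw_score, score = model$score,
                            reference = FALSE)
    if (early_stop && is.na(k_stop) && k >= 1L &&
        per_k[[k + 1L]]$score <= per_k[[k]]$score) {
      stopped_early <- TRUE
      k_stop <- k
    }
    if (stopped_early) {
      per_k[[k + 1L]]$reference <- k > k_stop
      if (k >= min(max_breaks, k_stop + reference_k)) break
    }
  }
  finish_result(per_k, vals, M, "brute", stopped_early,
                penalty_factor, penalty_mode)
}

finish_result <- function(per_k, vals, M, search_mode, stopped_early,
                          penalty_factor, penalty_mode) {
  eligible <- Filter(function(e) !e$reference, per_k)
  scores <- vapply(eligible, `[[`, numeric(1), "score")
  best_e <- eligible[[which.max(scores)]]  # which.max: first max, smallest k
  best <- new_activity_model(best_e$act, best_e$tra, best_e$raw_score,
                             best_e$score, penalty_factor, penalty_mode)
  structure(list(per_k = per_k, best = best, search_mode = search_mode,
                 stopped_early = stopped_early,
                 penalty_factor = penalty_factor, penalty_mode = penalty_mode,
                 gene_ids = rownames(vals),
                 time_points = if (inherits(M, "IntensityMatrix")) M$time_points),
            class = "SegmentationResult")
}

#' Dynamic-programming search over break sets
#'
#' Equivalent to [search_exhaustive()] in declared mode with early stopping
#' off, but polynomial: the gain of any candidate period is the sum over
#' genes of `max(0, period intensity sum)`, memoized for every (start, end)
#' pair from per-gene prefix sums, and the best split of the first `b` time
#' points into `m` segments satisfies
#' `F(m, b) = max over a of F(m - 1, a - 1) + gain(a, b)`.
#'
#' @inheritParams search_exhaustive
#' @return A `SegmentationResult`: `per_k` holds, for each break count k,
#'   the best break set, activity matrix, raw and penalized scores; `best`
#'   is the overall best `ActivityModel` (ties to the smallest k);
#'   `search_mode`, `stopped_early` and the penalty settings record how the
#'   search was run.
#' @export
search_dp <- function(M, penalty_factor = 2, max_breaks = NULL) {
  vals <- intensity_values(M)
  if (nrow(vals) == 0L || ncol(vals) == 0L) stop("empty intensity matrix", call. = FALSE)
  n_time <- ncol(vals)
  if (is.null(max_breaks)) max_breaks <- n_time - 1L
  max_breaks <- min(as.integer(max_breaks), n_time - 1L)
  P <- cbind(0, t(apply(vals, 1L, cumsum)))
  ln_gt <- log(nrow(vals) * n_time)

  # gain[a, b]: total positive-part intensity of period a..b, all genes
  gain <- matrix(-Inf, n_time, n_time)
  for (a in seq_len(n_time)) {
    seg <- P[, (a + 1L):(n_time + 1L), drop = FALSE] - P[, a]
    seg[seg < 0] <- 0
    gain[a, a:n_time] <- colSums(seg)
  }

  n_seg <- max_breaks + 1L
  F <- matrix(-Inf, n_seg, n_time)
  From <- matrix(NA_integer_, n_seg, n_time)
  F[1L, ] <- gain[1L, ]
  if (n_seg >= 2L) {
    for (m in 2:n_seg) {
      for (b in m:n_time) {
        cand <- F[m - 1L, (m - 1L):(b - 1L)] + gain[m:b, b]
        a_best <- which.max(cand)  # ties: smallest last-segment start
        F[m, b] <- cand[a_best]
        From[m, b] <- a_best + m - 1L
      }
    }
  }

  per_k <- vector("list", max_breaks + 1L)
  for (k in 0:max_breaks) {
    raw <- F[k + 1L, n_time]
    tra <- integer(0)
    b <- n_time
    m <- k + 1L
    while (m > 1L) {
      a <- From[m, b]
      tra <- c(a - 1L, tra)
      b <- a - 1L
      m <- m - 1L
    }
    model <- evaluate_segmentation(vals, tra, penalty_factor, "declared")
    per_k[[k + 1L]] <- list(k = k, tra = tra, act = model$act,
                            raw_score = raw,
                            score = raw - penalty_factor * k * ln_gt,
                            reference = FALSE)
  }
  finish_result(per_k, vals, M, "dp", FALSE, penalty_factor, "declared")
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat("Segmentation (", x$search_mode, " search, c = ", x$penalty_factor,
      ", ", x$penalty_mode, " penalty)\n", sep = "")
  for (e in x$per_k) {
    marker <- if (e$reference) " (reference)"
    else if (identical(e$tra, x$best$tra) && e$score == x$best$score) " <- best"
    else ""
    cat(sprintf("  k = %d: score %.6g%s\n", e$k, e$score, marker))
  }
  if (x$stopped_early) cat("  search stopped early\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
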