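# Write a small expression/intensity-style TSV: first row time labels,
# first column gene ids.
write_tsv_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Enumeration oracle: the best score over ALL binary period-constant
# activity matrices for a fixed break set, by direct enumeration of the
# candidate vector set V (|V| = 2^(k+1) per gene).
enum_best_for_tra <- function(M, tra, penalty_factor, penalty_mode = "declared") {
  n_time <- ncol(M)
  periods <- periods_from_breaks(tra, n_time)
  combos <- expand.grid(rep(list(0:1), length(periods)))
  vectors <- apply(combos, 1L, function(bits) {
    v <- numeric(n_time)
    for (p in seq_along(periods)) v[periods[[p]]] <- bits[p]
    v
  })
  act <- matrix(0, nrow(M), n_time)
  raw <- 0
  for (i in seq_len(nrow(M))) {
    scores <- colSums(M[i, ] * vectors)
    best <- which.max(scores)
    if (scores[best] > 0) {
      act[i, ] <- vectors[, best]
      raw <- raw + scores[best]
    }
  }
  b <- if (penalty_mode == "declared") length(tra) else length(derive_transitions(act))
  list(act = act, raw = raw,
       score = raw - penalty_factor * b * log(nrow(M) * ncol(M)))
}

# Enumeration oracle over every break set up to max_breaks.
enum_search <- function(M, penalty_factor, max_breaks = ncol(M) - 1L) {
  n_time <- ncol(M)
  best <- NULL
  per_k <- numeric(max_breaks + 1L)
  for (k in 0:max_breaks) {
    cands <- if (k == 0L) list(integer(0)) else
      asplit(utils::combn(n_time - 1L, k), 2L)
    sc <- vapply(cands, function(tra) {
      enum_best_for_tra(M, as.integer(tra), penalty_factor)$score
    }, numeric(1))
    per_k[k + 1L] <- max(sc)
    if (is.null(best) || max(sc) > best$score) {
      best <- list(k = k, tra = as.integer(cands[[which.max(sc)]]), score = max(sc))
    }
  }
  list(best = best, per_k = per_k)
}

# Star network: one regulator driving n targets.
star_network <- function(n_targets) {
  regulatory_network(data.frame(regulator = "tf1",
                                target = paste0("tg", seq_len(n_targets))))
}
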