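test_that("derive_transitions returns exactly the boundaries some gene crosses", {
  expect_equal(derive_transitions(rbind(c(1, 1, 1, 1), c(0, 0, 0, 0))), integer(0))
  expect_equal(derive_transitions(rbind(c(1, 1, 0, 0), c(1, 1, 1, 1))), 2L)
  expect_equal(derive_transitions(matrix(c(1, 0, 1), 1)), c(1L, 2L))
  expect_error(derive_transitions(matrix(c(0.5, 1), 1)), "0/1")
})

test_that("score_model evaluates the penalized activity score", {
  M <- rbind(c(1, 2), c(-1, 3))
  act <- rbind(c(1, 1), c(0, 1))
  s <- score_model(M, act, penalty_factor = 1, penalty_mode = "effective")
  expect_equal(s$raw_score, 6)
  expect_equal(s$score, 6 - log(4))

  s2 <- score_model(M, act, penalty_factor = 2, penalty_mode = "effective")
  expect_equal(s2$score, 6 - 2 * log(4))

  z <- score_model(M, matrix(0, 2, 2), penalty_factor = 1,
                   penalty_mode = "effective")
  expect_equal(z$raw_score, 0)
  expect_equal(z$score, 0)

  expect_error(score_model(M, matrix(0, 2, 3), 1), "shape")
})

test_that("best_row_activity matches exhaustive candidate enumeration", {
  r <- best_row_activity(c(2, -1, -3, 4), tra = 2L)
  expect_equal(r$v, c(1, 1, 1, 1))
  expect_equal(r$row_raw, 2)

  expect_equal(best_row_activity(c(-1, -1), integer(0))$v, c(0, 0))
  expect_equal(best_row_activity(c(1, -1), 1L),
               list(v = c(1, 0), row_raw = 1))

  # property: per-period sign rule == argmax over the 2^(k+1) vector set
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:7, 1)
    m <- matrix(runif(n, -1, 1), 1)
    k <- sample(0:(n - 1), 1)
    tra <- sort(sample(n - 1, k))
    got <- best_row_activity(m[1, ], tra)
    oracle <- enum_best_for_tra(m, tra, penalty_factor = 0)
    expect_equal(got$row_raw, oracle$raw)
    expect_equal(got$v, oracle$act[1, ])
  }
})

test_that("evaluate_segmentation fills rows optimally and canonicalizes", {
  M <- matrix(c(5, -5, 5), 1)
  m1 <- evaluate_segmentation(M, c(1L, 2L), penalty_factor = 1,
                              penalty_mode = "declared")
  expect_equal(unname(m1$act[1, ]), c(1, 0, 1))
  expect_equal(m1$raw_score, 10)
  expect_equal(m1$score, 10 - 2 * log(3))

  m0 <- evaluate_segmentation(M, integer(0), penalty_factor = 1)
  expect_equal(unname(m0$act[1, ]), c(1, 1, 1))  # sum 5 > 0
  expect_equal(m0$score, 5)

  neg <- evaluate_segmentation(matrix(-abs(rnorm(8)), 2, 4), c(2L),
                               penalty_factor = 1, penalty_mode = "effective")
  expect_true(all(neg$act == 0))
  expect_equal(neg$tra, integer(0))
  expect_equal(neg$score, 0)

  expect_error(evaluate_segmentation(M, 5L, 1), "out of range")
})

test_that("exhaustive search enumerates break sets and honors early stopping", {
  M <- matrix(c(5, -5, 5), 1)
  full <- search_exhaustive(M, penalty_factor = 1, penalty_mode = "declared",
                            early_stop = FALSE)
  expect_equal(full$best$tra, c(1L, 2L))
  expect_equal(full$best$score, 10 - 2 * log(3))
  expect_false(full$stopped_early)

  # the stopping rule is greedy, not globally optimal: it settles for k = 0
  es <- search_exhaustive(M, penalty_factor = 1, early_stop = TRUE)
  expect_true(es$stopped_early)
  expect_equal(es$best$tra, integer(0))
  expect_equal(es$best$score, 5)

  pos <- matrix(abs(rnorm(12)) + 0.1, 3, 4)
  rp <- search_exhaustive(pos, penalty_factor = 1, early_stop = FALSE)
  expect_equal(rp$best$tra, integer(0))
  expect_true(all(rp$best$act == 1))
  expect_equal(rp$best$score, sum(pos))
})

test_that("exhaustive search matches the independent enumeration oracle", {
  set.seed(5)
  for (i in 1:10) {
    M <- matrix(runif(3 * 5, -1, 1), 3, 5)
    got <- search_exhaustive(M, penalty_factor = 1, early_stop = FALSE)
    oracle <- enum_search(M, penalty_factor = 1)
    expect_equal(got$best$score, oracle$best$score)
    expect_equal(got$best$tra, oracle$best$tra)
    expect_equal(vapply(got$per_k, `[[`, numeric(1), "score"), oracle$per_k)
  }
})

test_that("dynamic program reproduces the exhaustive per-k table", {
  set.seed(7)
  for (i in 1:30) {
    G <- sample(1:6, 1)
    Tn <- sample(2:8, 1)
    M <- matrix(runif(G * Tn, -1, 1), G, Tn)
    brute <- search_exhaustive(M, penalty_factor = 2, early_stop = FALSE)
    dp <- search_dp(M, penalty_factor = 2)
    expect_equal(vapply(dp$per_k, `[[`, numeric(1), "score"),
                 vapply(brute$per_k, `[[`, numeric(1), "score"),
                 tolerance = 1e-12)
    expect_equal(dp$best$score, brute$best$score, tolerance = 1e-12)
    expect_equal(dp$best$tra, brute$best$tra)
  }
})

test_that("single time point admits only the trivial segmentation", {
  r <- search_dp(matrix(c(3, -1), 2, 1), penalty_factor = 2)
  expect_length(r$per_k, 1L)
  expect_equal(r$best$tra, integer(0))
  expect_equal(r$best$raw_score, 3)
})
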