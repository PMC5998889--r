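test_that("planted truths validate their fields and repair unidentifiable plans", {
  tr <- planted_truth(3, 10, tra_true = c(4, 7), seed = 2)
  expect_equal(dim(tr$activity_plan), c(3L, 3L))
  expect_error(planted_truth(3, 10, tra_true = 12), "out of range")
  expect_error(planted_truth(3, 10, 4, mu_act = -1), "mu_act")
  expect_error(planted_truth(3, 10, 4, sigma = 0), "sigma")
  expect_error(planted_truth(2, 6, 3, activity_plan = matrix(1, 3, 2)),
               "activity plan")

  # every break flips at least one gene, for many seeds
  for (s in 1:20) {
    tr <- planted_truth(4, 12, tra_true = c(3, 6, 9), seed = s)
    for (b in 1:3) {
      expect_true(any(tr$activity_plan[, b] != tr$activity_plan[, b + 1]))
    }
  }
})

test_that("generate_intensity is seed-deterministic and near-noiseless instances are recovered exactly", {
  tr <- planted_truth(5, 12, tra_true = c(4, 8), seed = 3)
  a <- generate_intensity(tr)
  b <- generate_intensity(tr)
  expect_identical(a$M$values, b$M$values)
  expect_error(generate_intensity(tr, n_genes = 7), "does not match")

  # noiseless limit: with enough genes flipping at each break, the break
  # gain dwarfs the BIC penalty and the truth is recovered exactly
  tr0 <- planted_truth(20, 12, tra_true = c(4, 8), sigma = 1e-6, seed = 4)
  g <- generate_intensity(tr0)
  res <- search_dp(g$M, penalty_factor = 2)
  expect_equal(res$best$tra, tr0$tra_true)
  period_cols <- c(1, 5, 9)  # first column of each period
  expect_equal(unname(res$best$act[, period_cols]),
               unname(tr0$activity_plan))
})

test_that("generated networks are acyclic with the requested size", {
  net <- generate_network(5, 4, seed = 1)
  expect_equal(nrow(net$edges), 4L)
  expect_true(igraph::is_dag(as_igraph(net)))

  big <- generate_network(31, 50, seed = 7)  # diauxic-shift-sized
  expect_equal(length(network_genes(big)) <= 31, TRUE)
  expect_equal(nrow(big$edges), 50L)
  expect_true(igraph::is_dag(as_igraph(big)))

  expect_error(generate_network(2, 3, seed = 1), "infeasible")
})

test_that("generate_expression is seed-deterministic down to the written TSV", {
  net <- star_network(3)
  tr <- planted_truth(3, 10, tra_true = 6, seed = 5)
  p1 <- generate_expression(net, tr)$profile
  p2 <- generate_expression(net, tr)$profile
  expect_identical(p1$values, p2$values)

  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_intensity(intensity_matrix(p1$values), f1)
  write_intensity(intensity_matrix(p2$values), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cyclic networks are rejected with the offending genes named", {
  cyc <- regulatory_network(data.frame(regulator = c("a", "b", "c"),
                                       target = c("b", "c", "a")))
  tr <- planted_truth(3, 10, 5, seed = 1)
  expect_error(generate_expression(cyc, tr), "cycle.*a.*b.*c|cycle")
})

test_that("an always-active child under a clean signal yields a positive row and k = 0", {
  net <- regulatory_network(data.frame(regulator = "tf1", target = "tg1"))
  tr <- planted_truth(1, 15, tra_true = integer(0),
                      activity_plan = matrix(1, 1, 1), seed = 6)
  sim <- generate_expression(net, tr, sigma_expr = 0.05)
  M <- loo_intensity(sim$profile, net)
  # positive evidence at most points (an occasional large studentized
  # residual is expected even under perfect regulation)
  expect_gt(mean(M$values > 0), 0.6)
  expect_gt(mean(M$values), 0)
  res <- search_dp(M, penalty_factor = 2)
  expect_equal(res$best$tra, integer(0))
  expect_true(all(res$best$act == 1))
})
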