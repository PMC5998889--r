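test_that("exact linear fits recover coefficients with floored scale", {
  x <- c(1, 2, 3, 4, 5)
  fit <- fit_parent_model(2 * x + 1, matrix(x))
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$residual_scale, intensity_config()$sigma_floor)
  expect_false(fit$degenerate)
})

test_that("a constant parent gives a degenerate fit with intercept = mean", {
  y <- c(1, 3, 2, 4, 5)
  fit <- fit_parent_model(y, matrix(rep(2, 5)))
  expect_true(fit$degenerate)
  expect_equal(unname(fit$coefficients[1]), mean(y))
  expect_equal(unname(fit$coefficients[2]), 0)
})

test_that("noisy fits agree with the closed-form OLS oracle", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(100)
    y <- x + rnorm(100)
    fit <- fit_parent_model(y, matrix(x))
    expect_equal(unname(fit$coefficients), unname(coef(lm(y ~ x))),
                 tolerance = 1e-10)
  }
  # unit-noise slope lands near 1 on a seeded instance
  x <- rnorm(100)
  fit <- fit_parent_model(x + rnorm(100), matrix(x))
  expect_gt(fit$coefficients[2], 0.8)
  expect_lt(fit$coefficients[2], 1.2)
})

test_that("too few points for the parent count is an error", {
  expect_error(fit_parent_model(1:3, matrix(rnorm(6), 3, 2)), "too few")
  prof <- expression_profile(rbind(a = c(1, 2, 3), b = c(2, 4, 6)))
  net <- regulatory_network(data.frame(regulator = "a", target = "b"))
  expect_error(loo_intensity(prof, net), "too few time points")
})

test_that("a perfectly regulated child scores lambda at every point", {
  x <- c(0.3, 1.1, 2.7, 3.2, 4.8, 5.9)
  prof <- expression_profile(rbind(p = x, c = 2 * x))
  net <- regulatory_network(data.frame(regulator = "p", target = "c"))
  for (fit in c("mm", "ols")) {
    M <- loo_intensity(prof, net, intensity_config(fit = fit))
    expect_equal(rownames(M$values), "c")  # no row for the unregulated parent
    expect_equal(unname(M$values["c", ]), rep(2, 6), tolerance = 1e-6)
  }
})

test_that("intensities are invariant to affine rescaling of the child", {
  set.seed(32)
  x <- cumsum(rnorm(15))
  y <- x + rnorm(15, 0, 0.3)
  net <- regulatory_network(data.frame(regulator = "p", target = "c"))
  M1 <- loo_intensity(expression_profile(rbind(p = x, c = y)), net)
  M2 <- loo_intensity(expression_profile(rbind(p = x, c = 3.7 * y - 11)), net)
  expect_equal(M1$values, M2$values, tolerance = 1e-8)
})

test_that("missing regulated genes or parents are reported by name", {
  prof <- expression_profile(rbind(a = rnorm(6), b = rnorm(6)))
  net <- regulatory_network(data.frame(regulator = "a", target = "zzz"))
  expect_error(loo_intensity(prof, net), "zzz")
  net2 <- regulatory_network(data.frame(regulator = "ghost", target = "b"))
  expect_error(loo_intensity(prof, net2), "ghost")
})

test_that("a child decoupled from a strongly varying parent scores negative on average", {
  # smaller simulation here; the full 500-run check lives in the acceptance suite
  set.seed(33)
  net <- regulatory_network(data.frame(regulator = "p", target = "c"))
  means <- replicate(40, {
    prof <- expression_profile(rbind(p = seq(0, 10, length.out = 20),
                                     c = rnorm(20)))
    mean(loo_intensity(prof, net)$values)
  })
  expect_lt(mean(means), 0)
})
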