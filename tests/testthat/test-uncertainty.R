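test_that("residuals are observation minus prediction, per row and output", {
  fx <- fixture_bench()
  res <- compute_residuals(fx$model, fx$train)
  expect_equal(nrow(res), nrow(fx$train))
  pred <- t2demu:::.predict_outputs(fx$model, fx$train)
  expect_equal(res$gamma, fx$train$gamma - pred[, "gamma"])

  # a perfectly fit constant table has all-zero residuals
  tab <- constant_table()
  m <- fit_emulator(tab, n_trees = 10, seed = 2)
  expect_true(all(abs(as.matrix(compute_residuals(m, tab)[, 3:5])) < 1e-12))
})

test_that("bands collapse to the center when residuals vanish", {
  tab <- constant_table()
  m <- fit_emulator(tab, n_trees = 10, seed = 2)
  x <- decode_subjects(as.matrix(tab[1, t2demu:::.subject_fields]))
  band <- bootstrap_band(m, tab, x, B = 50, alpha = 0.05, seed = 3)
  expect_equal(band$lower, band$center)
  expect_equal(band$upper, band$center)
  expect_error(bootstrap_band(m, tab, x, B = 1), "B must be")
  expect_error(bootstrap_band(m, tab, x, alpha = 0.7), "alpha")
})

test_that("bands are ordered, nested in alpha and reproducible", {
  fx <- fixture_bench()
  x <- fx$parts$train[5, ]
  b05 <- bootstrap_band(fx$model, fx$train, x, B = 50, alpha = 0.05, seed = 11)
  expect_true(all(b05$lower <= b05$upper))
  expect_true(all(b05$lower <= b05$center & b05$center <= b05$upper))
  expect_equal(attr(b05, "B"), 50L)
  expect_identical(as.data.frame(b05),
                   as.data.frame(bootstrap_band(fx$model, fx$train, x,
                                                B = 50, alpha = 0.05, seed = 11)))
  b01 <- bootstrap_band(fx$model, fx$train, x, B = 50, alpha = 0.01, seed = 11)
  expect_true(all(b01$lower <= b05$lower + 1e-12))
  expect_true(all(b01$upper >= b05$upper - 1e-12))
})

test_that("the refit variant produces valid, narrower bands", {
  grid <- enumerate_grid()
  s <- lhs_sample(grid, 30, seed = 21)
  tab <- generate_dataset(s, simulator_config(), seed = 21)
  m <- fit_emulator(tab, n_trees = 20, seed = 21)
  x <- s[1, ]
  pb <- bootstrap_band(m, tab, x, B = 10, seed = 22, method = "perturb")
  rb <- bootstrap_band(m, tab, x, B = 10, seed = 22, method = "refit")
  expect_true(all(rb$lower <= rb$upper))
  expect_equal(rb$center, pb$center)
  # refit bands track ensemble-mean variability only, so they are narrower
  expect_lt(mean(rb$upper - rb$lower), mean(pb$upper - pb$lower))
})

test_that("coverage probability counts the weeks inside the band", {
  # hand-checkable toy band around a synthetic reference
  ref <- data.frame(t = 1:26, beta = rep(1, 26), gamma = rep(1, 26),
                    tau = rep(1, 26))
  band <- do.call(rbind, lapply(c("beta", "gamma", "tau"), function(h) {
    data.frame(output = h, t = 1:26,
               lower = c(rep(0, 13), rep(2, 13)),
               center = 1,
               upper = c(rep(2, 13), rep(3, 13)))
  }))
  cov <- coverage_probability(band, ref)
  expect_equal(cov$coverage, rep(0.5, 3))

  wide <- band; wide$lower <- -1e9; wide$upper <- 1e9
  expect_equal(coverage_probability(wide, ref)$coverage, rep(1, 3))
  degen <- band; degen$lower <- 5; degen$upper <- 5
  expect_equal(coverage_probability(degen, ref)$coverage, rep(0, 3))
  short <- ref[1:10, ]
  expect_error(coverage_probability(band, short), "different weeks")
})

test_that("multi-subject coverage agrees with per-subject bands", {
  fx <- fixture_bench()
  few <- fx$train[fx$train$subject_id %in% fx$parts$train$subject_id[1:4], ]
  cs <- coverage_study(fx$model, fx$train, few, B = 20, seed = 31)
  expect_equal(cs$n_subjects, 4)
  expect_true(all(cs$mean_coverage >= 0 & cs$mean_coverage <= 1))
  expect_equal(colMeans(cs$per_subject[, c("beta", "gamma", "tau")]),
               cs$mean_coverage)
  # same draws through the single-subject band interface
  x1 <- fx$parts$train[1, ]
  band <- bootstrap_band(fx$model, fx$train, x1, B = 20, seed = 31)
  ref <- few[few$subject_id == x1$subject_id, c("t", "beta", "gamma", "tau")]
  cov1 <- coverage_probability(band, ref)
  expect_equal(cs$per_subject[cs$per_subject$subject_id == x1$subject_id,
                              c("beta", "gamma", "tau")],
               setNames(as.data.frame(t(cov1$coverage)),
                        c("beta", "gamma", "tau")),
               ignore_attr = TRUE)
})

test_that("rmse from the residual set matches the evaluation module", {
  fx <- fixture_bench()
  res <- compute_residuals(fx$model, fx$test)
  sc <- fx$scaling
  curve <- rmse_curve(fx$model, fx$test, sc)
  span <- sc$max - sc$min
  for (h in c("beta", "gamma", "tau")) {
    manual <- vapply(1:26, function(w) {
      sqrt(mean((res[[h]][res$t == w] / span[[h]])^2))
    }, numeric(1))
    expect_equal(curve$E[curve$output == h], manual, tolerance = 1e-12)
  }
})
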