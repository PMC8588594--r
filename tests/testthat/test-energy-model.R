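test_that("REE follows the documented equation and its monotonicities", {
  x <- case_subject()
  cst <- energy_constants()
  # direct evaluation of the Mifflin-St Jeor form as oracle
  w <- 27.5 * 1.75^2
  expect_equal(compute_ree(x), 10 * w + 6.25 * 175 - 5 * 38 + 5)

  older <- x; older$age <- 68
  expect_gt(compute_ree(x), compute_ree(older))

  female <- x; female$sex <- "female"
  # same classes resolve to different heights per sex, so compare via the
  # equation's fixed offset at equal body measures
  wf <- 27.5 * (cst$height_cm$female[["average"]] / 100)^2
  expect_equal(compute_ree(female),
               10 * wf + 6.25 * cst$height_cm$female[["average"]] - 5 * 38 - 161)

  normal <- x; normal$weight_class <- "normal"
  expect_gt(compute_ree(x), compute_ree(normal))
  short <- x; short$height_class <- "short"
  expect_gt(compute_ree(x), compute_ree(short))
})

test_that("AEE is zero when sedentary and linear in sessions and duration", {
  x <- case_subject()
  sedentary <- x
  sedentary$pa_sessions <- 0; sedentary$pa_duration <- 0; sedentary$pa_intensity <- 0
  expect_equal(compute_aee(sedentary), 0)

  two <- x; two$pa_sessions <- 2
  expect_equal(compute_aee(two), 2 * compute_aee(x))
  long <- x; long$pa_duration <- 60
  expect_equal(compute_aee(long), 2 * compute_aee(x))
  easy <- x; easy$pa_intensity <- 40
  expect_lt(compute_aee(easy), compute_aee(x))

  # hand evaluation of the MET formula: 1 session, 30 min, 60 %VO2max
  w <- 27.5 * 1.75^2
  expect_equal(compute_aee(x), 1 * (30 / 60) * (7 - 1) * w / 7)
})

test_that("the energy budget closes as a fixed point of intake", {
  b <- energy_budget(ree = 1500, aee = 300)
  expect_equal(b$balanced_intake, 2000)
  expect_equal(b$tef, 200)
  expect_equal(b$tdee, b$ree + b$aee + b$tef)
  expect_equal(b$tdee, b$balanced_intake)
  expect_equal(b$tef / b$balanced_intake, 0.10)

  # closure across a spread of grid subjects
  grid <- enumerate_grid()
  for (i in seq(1, nrow(grid), length.out = 25)) {
    bi <- energy_budget(grid[round(i), ])
    expect_equal(bi$tdee, bi$ree + bi$aee + bi$tef, tolerance = 1e-12)
    expect_equal(bi$tef, 0.10 * bi$balanced_intake, tolerance = 1e-12)
    expect_gt(bi$ree, 0)
  }
})

test_that("meal macros realize the 50/20/30 split and level multipliers", {
  b <- energy_budget(ree = 1620, aee = 0)  # balanced intake 1800 kcal
  expect_equal(b$balanced_intake, 1800)
  med <- meal_macros(b, c("med", "med", "med"))
  # 600 kcal per meal: 300 kcal carb, 120 kcal protein, 180 kcal fat
  expect_equal(med$carb, 300 / 4)
  expect_equal(med$prot, 120 / 4)
  expect_equal(med$fat, 180 / 9)

  hi <- meal_macros(b, c("high", "high", "high"))
  lo <- meal_macros(b, c("low", "low", "low"))
  for (m in c("carb", "prot", "fat")) {
    expect_identical(hi[[m]] / med[[m]], 1.5)
    expect_identical(lo[[m]] / med[[m]], 0.8)
  }
  expect_error(meal_macros(b, c("med", "med")), "levels")
})

test_that("diet bounds frame a feasible set containing the med diet", {
  x <- case_subject()
  bounds <- diet_bounds(x)
  expect_equal(bounds$u_C / bounds$l_C, 1.5 / 0.8)
  expect_equal(bounds$u_P / bounds$l_P, 1.5 / 0.8)
  expect_equal(bounds$u_F / bounds$l_F, 1.5 / 0.8)

  budget <- energy_budget(x)
  med <- meal_macros(budget, c("med", "med", "med"))
  expect_true(isTRUE(feasible_diet(med, bounds)))

  # enumerate all 27 level combinations: each is inside its boxes, and the
  # total constraint is what decides survival
  combos <- diet_grid()
  for (i in seq_len(27)) {
    g <- meal_macros(budget, unlist(combos[i, ]))
    expect_true(g$carb >= bounds$l_C - 1e-12 && g$carb <= bounds$u_C + 1e-12)
    total <- g$carb + g$prot + g$fat
    expect_equal(isTRUE(feasible_diet(g, bounds)),
                 total >= bounds$l_T - 1e-12 && total <= bounds$u_T + 1e-12)
  }

  # a tight total bound rejects the high/high/high diet but keeps med
  tight <- bounds
  tight$u_T <- sum(med$carb, med$prot, med$fat) * 1.1
  hi <- meal_macros(budget, c("high", "high", "high"))
  expect_false(isTRUE(feasible_diet(hi, tight)))
  expect_true(isTRUE(feasible_diet(med, tight)))
  expect_match(paste(attr(feasible_diet(hi, tight), "violated"), collapse = " "),
               "total")
})
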