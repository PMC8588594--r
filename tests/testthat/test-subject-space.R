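test_that("the full factorial grid matches brute-force enumeration", {
  grid <- enumerate_grid()
  expect_equal(nrow(grid), 46170)
  expect_equal(nrow(grid), brute_force_count(grid_spec()))
  expect_equal(nrow(grid), 90 * 19 * 27)
  expect_equal(grid$subject_id, seq_len(nrow(grid)))
  expect_false(anyDuplicated(grid[, -1]) > 0)

  sedentary <- enumerate_grid(grid_spec(pa_sessions = 0))
  expect_equal(nrow(sedentary), 2430)
  expect_equal(nrow(sedentary), brute_force_count(grid_spec(pa_sessions = 0)))
  expect_true(all(sedentary$pa_duration == 0 & sedentary$pa_intensity == 0))

  single <- enumerate_grid(grid_spec(
    sex = "female", age = 28, weight_class = "normal", height_class = "tall",
    pa_sessions = 2, pa_duration = 60, pa_intensity = 40,
    carb_level = "low", prot_level = "med", fat_level = "high"))
  expect_equal(nrow(single), 1)

  expect_error(grid_spec(sex = character(0)), "empty level list")
  expect_error(grid_spec(weight_class = "obese"), "invalid level")
})

test_that("grid order is deterministic and lexicographic in field order", {
  grid <- enumerate_grid()
  expect_identical(grid, enumerate_grid())
  # sex varies slowest, fat_level fastest
  expect_equal(unique(grid$sex), c("female", "male"))
  expect_equal(grid$fat_level[1:3], c("low", "med", "high"))
  # encoded columns are already rank codes in field order, so lexicographic
  # order of the grid means order() over them is the identity
  enc <- as.data.frame(encode_subjects(grid))
  expect_equal(do.call(order, enc), seq_len(nrow(grid)))
})

test_that("encoding is an invertible coordinate-wise map", {
  grid <- enumerate_grid()
  enc <- encode_subjects(grid)
  expect_equal(dim(enc), c(46170, 10))
  expect_true(is.numeric(enc))
  expect_equal(decode_subjects(enc), as.data.frame(grid)[, colnames(enc)],
               ignore_attr = TRUE)

  x <- case_subject()
  v <- encode_subjects(x)
  expect_equal(as.numeric(v), c(1, 38, 3, 2, 1, 30, 60, 2, 3, 3))
  expect_equal(decode_subjects(v), x, ignore_attr = TRUE)

  y <- x
  y$fat_level <- "low"
  expect_equal(sum(encode_subjects(x) != encode_subjects(y)), 1)

  bad <- x
  bad$sex <- "other"
  expect_error(encode_subjects(bad), "sex")
})

test_that("stratified sampling is balanced, distinct and reproducible", {
  grid <- enumerate_grid()
  for (k in c(500, 5000)) {
    s <- lhs_sample(grid, k, seed = 7)
    expect_equal(nrow(s), k)
    expect_false(anyDuplicated(s$subject_id) > 0)
    expect_identical(as.data.frame(s), as.data.frame(lhs_sample(grid, k, seed = 7)))
    # per-factor marginal counts within one unit of proportional
    facs <- list(s$sex, s$age, s$weight_class, s$height_class,
                 paste(s$pa_sessions, s$pa_duration, s$pa_intensity),
                 s$carb_level, s$prot_level, s$fat_level)
    L <- c(2, 5, 3, 3, 19, 3, 3, 3)
    for (i in seq_along(facs)) {
      counts <- table(facs[[i]])
      expect_equal(length(counts), L[i])
      expect_true(all(counts >= floor(k / L[i]) & counts <= ceiling(k / L[i])))
    }
  }
  expect_error(lhs_sample(grid, nrow(grid) + 1, seed = 1), "between 1 and")
})

test_that("exhaustive and PA-stratified samples hit every combination", {
  grid <- enumerate_grid()
  full <- lhs_sample(grid, nrow(grid), seed = 3)
  expect_equal(sort(full$subject_id), grid$subject_id)

  # a grid whose only multi-level factor is the 19-level PA composite:
  # k = 19 must select each PA pattern exactly once
  pa_grid <- enumerate_grid(grid_spec(
    sex = "male", age = 48, weight_class = "normal", height_class = "short",
    carb_level = "med", prot_level = "med", fat_level = "med"))
  expect_equal(nrow(pa_grid), 19)
  s <- lhs_sample(pa_grid, 19, seed = 11)
  pa <- paste(s$pa_sessions, s$pa_duration, s$pa_intensity)
  expect_equal(length(unique(pa)), 19)
  expect_true(all(table(pa) == 1))
})

test_that("train/test split is a subject-level partition with floor sizes", {
  grid <- enumerate_grid()
  s <- lhs_sample(grid, 5000, seed = 5)
  parts <- split_train_test(s, 0.7, seed = 9)
  expect_equal(nrow(parts$train), 3500)
  expect_equal(nrow(parts$test), 1500)
  expect_length(intersect(parts$train$subject_id, parts$test$subject_id), 0)
  expect_equal(sort(c(parts$train$subject_id, parts$test$subject_id)),
               sort(s$subject_id))
  again <- split_train_test(s, 0.7, seed = 9)
  expect_identical(as.data.frame(parts$train), as.data.frame(again$train))
  expect_error(split_train_test(s, 1.2), "train_fraction")
})
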