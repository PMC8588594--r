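# Shared fixtures, built in code once per test run.

.fix <- new.env(parent = emptyenv())

# a small but heterogeneous benchmark: 120 subjects from the full grid,
# 70/30 split, default surrogate, default emulator
fixture_bench <- function() {
  if (is.null(.fix$model)) {
    grid <- enumerate_grid()
    s <- lhs_sample(grid, 120, seed = 42)
    parts <- split_train_test(s, 0.7, seed = 42)
    cfg <- simulator_config()
    .fix$parts <- parts
    .fix$train <- generate_dataset(parts$train, cfg, seed = 42)
    .fix$test <- generate_dataset(parts$test, cfg, seed = 42)
    .fix$model <- fit_emulator(.fix$train, seed = 42)
    .fix$scaling <- fit_scaling(.fix$train)
  }
  as.list(.fix)
}

# constant-output training table: every tree leaf averages the same value,
# so the fitted forest predicts the constants exactly — a handle for exact
# arithmetic oracles further down the pipeline
constant_table <- function(values = c(beta = 25, gamma = 90, tau = 20),
                           n_subjects = 3, weeks = 26) {
  grid <- enumerate_grid(grid_spec(
    sex = "female", age = 48, height_class = "average",
    pa_sessions = 0, carb_level = "med", prot_level = "med"
  ))
  subjects <- grid[seq_len(n_subjects), , drop = FALSE]
  feats <- encode_subjects(subjects)
  tab <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    cbind(subject_id = subjects$subject_id[i],
          as.data.frame(feats[rep(i, weeks), , drop = FALSE]),
          t = seq_len(weeks),
          beta = values[["beta"]], gamma = values[["gamma"]],
          tau = values[["tau"]])
  }))
  rownames(tab) <- NULL
  class(tab) <- c("training_table", "data.frame")
  tab
}

# one canonical subject: overweight male, 38y, average height, 1 x 30 min
# at 60 %VO2max, med/high/high diet
case_subject <- function() {
  data.frame(
    sex = "male", age = 38, weight_class = "overweight",
    height_class = "average", pa_sessions = 1, pa_duration = 30,
    pa_intensity = 60, carb_level = "med", prot_level = "high",
    fat_level = "high", stringsAsFactors = FALSE
  )
}

# brute-force enumeration of the design-space size by nested loops,
# independent of the package's expand/cross-join machinery
brute_force_count <- function(spec) {
  n <- 0
  for (sx in spec$sex) for (a in spec$age) {
    for (w in spec$weight_class) for (h in spec$height_class) {
      pa <- 0
      for (s in spec$pa_sessions) {
        if (s == 0) pa <- pa + 1
        else pa <- pa + length(spec$pa_duration) * length(spec$pa_intensity)
      }
      n <- n + pa * length(spec$carb_level) * length(spec$prot_level) *
        length(spec$fat_level)
    }
  }
  n
}

# independently coded brute-force diet optimum: loop over all 27 level
# combinations, check feasibility by direct comparisons, sum squared
# pointwise tau predictions, and apply the documented tie-break
brute_force_optimum <- function(model, x, bounds) {
  budget <- energy_budget(x)
  lev <- c("low", "med", "high")
  best <- NULL
  for (cl in lev) for (pl in lev) for (fl in lev) {
    g <- meal_macros(budget, c(cl, pl, fl))
    total <- g$carb + g$prot + g$fat
    ok <- g$carb >= bounds$l_C && g$carb <= bounds$u_C &&
      g$prot >= bounds$l_P && g$prot <= bounds$u_P &&
      g$fat >= bounds$l_F && g$fat <= bounds$u_F &&
      total >= bounds$l_T && total <= bounds$u_T
    if (!ok) next
    xi <- x
    xi$carb_level <- cl; xi$prot_level <- pl; xi$fat_level <- fl
    obj <- 0
    for (w in 1:26) obj <- obj + predict_point(model, xi, w)[["tau"]]^2
    cand <- list(carb_level = cl, prot_level = pl, fat_level = fl,
                 objective = obj, total = total)
    if (is.null(best) || obj < best$objective ||
        (obj == best$objective && total < best$total)) {
      best <- cand
    }
  }
  best
}
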