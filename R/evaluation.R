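# Unit-interval output scaling and per-week RMSE evaluation, including the
# multi-sample-size study design.

#' Fit min-max scaling of the outputs to the unit interval
#'
#' Per-output minima and maxima are taken from the training table only (so
#' the test set cannot leak into the scale); applying the spec maps training
#' outputs into \[0, 1\].
#'
#' @param table a `training_table`.
#' @return A `scaling_spec` list with named `min` and `max` vectors.
#' @export
fit_scaling <- function(table) {
  .check_table(table)
  mn <- vapply(table[.output_names], min, numeric(1))
  mx <- vapply(table[.output_names], max, numeric(1))
  if (any(mx <= mn)) {
    stopf("degenerate scale: constant output column(s): %s",
          paste(.output_names[mx <= mn], collapse = ", "))
  }
  structure(list(min = mn, max = mx), class = "scaling_spec")
}

#' Apply (or invert) a min-max output scaling
#'
#' Values outside the training range map outside \[0, 1\] and are flagged via
#' the `out_of_range` attribute rather than clipped, so downstream error
#' measures are not silently biased.
#'
#' @param y a matrix or data frame with `beta`, `gamma`, `tau` columns.
#' @param scaling a [fit_scaling()] spec.
#' @return The scaled matrix, with attribute `out_of_range` (per-output count
#'   of values outside the unit interval).
#' @export
scale_outputs <- function(y, scaling) {
  y <- as.matrix(as.data.frame(y)[.output_names])
  out <- sweep(sweep(y, 2, scaling$min[.output_names]), 2,
               scaling$max[.output_names] - scaling$min[.output_names], "/")
  attr(out, "out_of_range") <- colSums(out < 0 | out > 1)
  out
}

#' @rdname scale_outputs
#' @export
invert_scaling <- function(y, scaling) {
  y <- as.matrix(as.data.frame(y)[.output_names])
  sweep(sweep(y, 2, scaling$max[.output_names] - scaling$min[.output_names],
              "*"), 2, scaling$min[.output_names], "+")
}

# per-week, per-output root mean square error of scaled predictions;
# obs/pred are n x 3 matrices on the unit scale, t the week of each row
.rmse_table <- function(obs, pred, t) {
  weeks <- sort(unique(t))
  out <- do.call(rbind, lapply(.output_names, function(h) {
    e <- vapply(weeks, function(w) {
      d <- obs[t == w, h] - pred[t == w, h]
      sqrt(mean(d^2))
    }, numeric(1))
    data.frame(output = h, t = weeks, E = e)
  }))
  rownames(out) <- NULL
  out
}

#' Per-week RMSE curves on unit-scaled outputs
#'
#' For each output variable `h` and week `t`, computes
#' \deqn{E^h(t) = \sqrt{\frac{1}{n}\sum_{i=1}^{n}
#'   \big(y^h(x_i,t) - \hat y^h(x_i,t)\big)^2}}
#' over the `n` evaluation subjects, with both observations and predictions
#' min-max scaled to the unit interval so the curves are comparable across
#' outputs.
#'
#' @param model a fitted [fit_emulator()] model.
#' @param test a `training_table` of held-out subjects (a warning is issued
#'   if any subject was in the training set).
#' @param scaling a [fit_scaling()] spec fitted on the training table.
#' @return An `rmse_curve` data frame with columns `output`, `t`, `E`;
#'   attributes `n` (number of evaluation subjects) and `out_of_range`.
#' @export
rmse_curve <- function(model, test, scaling) {
  .check_table(test)
  if (nrow(test) == 0) stopf("empty test table")
  overlap <- intersect(unique(test$subject_id), model$train_subjects)
  if (length(overlap) > 0) {
    warning(sprintf("%d evaluation subject(s) were in the training set",
                    length(overlap)), call. = FALSE)
  }
  obs <- scale_outputs(test[.output_names], scaling)
  pred <- scale_outputs(.predict_outputs(model, test[model$feature_names]),
                        scaling)
  out <- .rmse_table(obs, pred, test$t)
  structure(out, n = length(unique(test$subject_id)),
            out_of_range = attr(obs, "out_of_range"),
            class = c("rmse_curve", "data.frame"))
}

#' Sample-size study: RMSE and coverage across training-set sizes
#'
#' Reproduces the study design at each requested size: draw a stratified
#' Latin-hypercube sample from the grid, split it 70/30 at the subject
#' level, simulate trajectories with the surrogate, fit the forest emulator
#' on the training split, and evaluate per-week RMSE and test-set band
#' coverage. Every stage's seed derives from the master seed and the size,
#' so the whole study is reproducible.
#'
#' @param grid a `subject_grid`.
#' @param sizes training-sample sizes (numbers of subjects before the
#'   split); default `c(500, 1000, 1500, 2000)`, a desk-scale version of the
#'   study's 5000--20000.
#' @param config a [simulator_config()].
#' @param seed master integer seed.
#' @param n_trees trees per forest.
#' @param B bootstrap replicates for the coverage statistic; the study
#'   default of 20 keeps the four-size design tractable.
#' @param alpha band tail probability per side.
#' @param train_fraction training share of each sample.
#' @param method bootstrap band method, see [bootstrap_band()].
#' @return A `sample_size_study` list with tidy data frames: `rmse`
#'   (`size`, `output`, `t`, `E`), `mean_rmse` (`size`, `output`, `E`),
#'   `coverage` (`size`, `output`, `coverage`), and `edge_ratio`
#'   (`size`, `output`, first/last-week RMSE relative to the mid-horizon
#'   mean — the U-shape diagnostic, reported but not asserted).
#' @export
sample_size_study <- function(grid, sizes = c(500, 1000, 1500, 2000),
                              config = simulator_config(), seed = 1L,
                              n_trees = 50L, B = 20L, alpha = 0.05,
                              train_fraction = 0.7,
                              method = c("perturb", "refit")) {
  method <- match.arg(method)
  if (any(sizes > nrow(grid))) stopf("sizes must not exceed the grid size")
  rmse_all <- list(); cov_all <- list(); mean_all <- list(); edge_all <- list()
  for (k in sizes) {
    seed_k <- derive_seed(seed, "size", k)
    sample_k <- lhs_sample(grid, k, seed = seed_k)
    parts <- split_train_test(sample_k, train_fraction, seed = seed_k)
    train_tab <- generate_dataset(parts$train, config, seed = derive_seed(seed_k, "data"))
    test_tab <- generate_dataset(parts$test, config, seed = derive_seed(seed_k, "data"))
    model <- fit_emulator(train_tab, n_trees = n_trees,
                          seed = derive_seed(seed_k, "fit"))
    scaling <- fit_scaling(train_tab)
    curve <- rmse_curve(model, test_tab, scaling)
    covr <- coverage_study(model, train_tab, test_tab, B = B, alpha = alpha,
                           seed = derive_seed(seed_k, "band"), method = method)
    rmse_all[[as.character(k)]] <- cbind(size = k, as.data.frame(curve))
    mean_all[[as.character(k)]] <- data.frame(
      size = k, output = .output_names,
      E = vapply(.output_names, function(h) mean(curve$E[curve$output == h]),
                 numeric(1)))
    cov_all[[as.character(k)]] <- data.frame(
      size = k, output = .output_names,
      coverage = unname(covr$mean_coverage[.output_names]))
    edge_all[[as.character(k)]] <- do.call(rbind, lapply(.output_names, function(h) {
      e <- curve$E[curve$output == h]
      mid <- mean(e[-c(1, length(e))])
      data.frame(size = k, output = h,
                 first_over_mid = e[1] / mid,
                 last_over_mid = e[length(e)] / mid)
    }))
  }
  structure(list(
    rmse = do.call(rbind, rmse_all),
    mean_rmse = do.call(rbind, mean_all),
    coverage = do.call(rbind, cov_all),
    edge_ratio = do.call(rbind, edge_all),
    sizes = sizes, B = as.integer(B), alpha = alpha, method = method,
    seed = as.integer(seed)
  ), class = "sample_size_study")
}

#' @export
print.sample_size_study <- function(x, ...) {
  cat("Sample-size study (training sizes:",
      paste(x$sizes, collapse = ", "), ")\n")
  cat("Mean RMSE over weeks (unit scale):\n")
  print(stats::reshape(x$mean_rmse, idvar = "size", timevar = "output",
                       direction = "wide"), row.names = FALSE)
  cat("Test-set band coverage:\n")
  print(stats::reshape(x$coverage, idvar = "size", timevar = "output",
                       direction = "wide"), row.names = FALSE)
  invisible(x)
}
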