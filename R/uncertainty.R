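# Bootstrap-residual confidence bands and coverage probability.
#
# The band procedure is the fixed-design residual bootstrap: residuals
# e(x_i, t) = y(x_i, t) - yhat(x_i, t) are pooled per output variable and
# resampled with replacement to form B pseudo-trajectories
# y*_b(x, t) = yhat(x, t) + e*_b(x, t); the band at level alpha is the
# pointwise empirical q_alpha / q_{1-alpha} envelope of the B trajectories.
# A "refit" variant that re-trains the emulator on each pseudo-response set
# over the fixed design is available as a configuration switch; it yields a
# confidence band for the ensemble mean rather than a prediction band, and
# is markedly narrower (see the methods vignette).

#' Training residuals of a fitted emulator
#'
#' Computes `observed - predicted` for every row and output of a table, kept
#' with their grouping keys.
#'
#' @param model a fitted [fit_emulator()] model.
#' @param table a `training_table` compatible with the model's schema.
#' @return A `residual_set` data frame with `subject_id`, `t` and the three
#'   per-output residual columns.
#' @export
compute_residuals <- function(model, table) {
  .check_table(table)
  pred <- .predict_outputs(model, table[model$feature_names])
  res <- as.data.frame(as.matrix(table[.output_names]) - pred)
  out <- cbind(table[c("subject_id", "t")], res)
  rownames(out) <- NULL
  class(out) <- c("residual_set", "data.frame")
  out
}

# draw a B-column matrix of pseudo-predictions for each output at `npoints`
# prediction rows; `center` is the npoints x 3 matrix of emulator predictions
.perturb_draws <- function(center, residuals, B, seed) {
  npoints <- nrow(center)
  draws <- lapply(.output_names, function(h) {
    pool <- residuals[[h]]
    m <- matrix(0, npoints, B)
    for (b in seq_len(B)) {
      m[, b] <- center[, h] +
        with_seed(derive_seed(seed, "boot", h, b),
                  sample(pool, npoints, replace = TRUE))
    }
    m
  })
  names(draws) <- .output_names
  draws
}

# refit variant: B re-trainings on pseudo-responses over the fixed design
.refit_draws <- function(model, table, newdata, residuals, B, seed) {
  yhat_train <- .predict_outputs(model, table[model$feature_names])
  n_train <- nrow(table)
  draws <- lapply(.output_names, function(h) matrix(0, nrow(newdata), B))
  names(draws) <- .output_names
  for (b in seq_len(B)) {
    ystar <- yhat_train
    for (h in .output_names) {
      ystar[, h] <- yhat_train[, h] +
        with_seed(derive_seed(seed, "boot", h, b),
                  sample(residuals[[h]], n_train, replace = TRUE))
    }
    for (h in .output_names) {
      fb <- ranger::ranger(
        x = table[model$feature_names], y = ystar[, h],
        num.trees = model$n_trees,
        seed = derive_seed(seed, "refit", h, b),
        num.threads = 1, oob.error = FALSE
      )
      draws[[h]][, b] <- predict(fb, data = newdata, num.threads = 1)$predictions
    }
  }
  draws
}

.band_from_draws <- function(draws, alpha) {
  lapply(draws, function(m) {
    cbind(
      lower = apply(m, 1, stats::quantile, probs = alpha, type = 7),
      upper = apply(m, 1, stats::quantile, probs = 1 - alpha, type = 7)
    )
  })
}

#' Bootstrap-residual confidence band for one subject's trajectory
#'
#' Builds the pointwise `q_alpha`/`q_{1-alpha}` band (default 90 % central
#' band at `alpha = 0.05`) from `B = 50` bootstrap pseudo-trajectories
#' `yhat + e*_b`, with residuals pooled per output variable. Quantiles use
#' the inclusive linear-interpolation convention (R type 7). Replicate
#' seeds derive deterministically from `seed` and the replicate index.
#'
#' @param model a fitted [fit_emulator()] model.
#' @param table the training table the residuals come from.
#' @param x a one-row subject data frame.
#' @param B number of bootstrap replicates, `>= 2`; default 50.
#' @param alpha tail probability per side, in (0, 0.5); default 0.05.
#' @param seed integer seed.
#' @param method `"perturb"` (default): pseudo-trajectories are
#'   `yhat + e*_b`; `"refit"`: each replicate re-trains the emulator on the
#'   pseudo-responses over the fixed design and predicts the subject.
#' @return A `confidence_band` data frame with columns `output`, `t`,
#'   `lower`, `center`, `upper`; attributes `alpha`, `B`, `method`.
#' @export
bootstrap_band <- function(model, table, x, B = 50L, alpha = 0.05, seed = 1L,
                           method = c("perturb", "refit")) {
  method <- match.arg(method)
  if (B < 2) stopf("B must be >= 2 bootstrap replicates")
  if (alpha <= 0 || alpha >= 0.5) stopf("alpha must be in (0, 0.5)")
  residuals <- compute_residuals(model, table)
  t <- seq(model$t_range[1], model$t_range[2])
  newdata <- .subject_rows(x, t)
  center <- .predict_outputs(model, newdata)
  draws <- if (method == "perturb") {
    .perturb_draws(center, residuals, B, seed)
  } else {
    .refit_draws(model, table, newdata, residuals, B, seed)
  }
  q <- .band_from_draws(draws, alpha)
  out <- do.call(rbind, lapply(.output_names, function(h) {
    data.frame(output = h, t = t, lower = q[[h]][, "lower"],
               center = center[, h], upper = q[[h]][, "upper"])
  }))
  rownames(out) <- NULL
  structure(out, alpha = alpha, B = as.integer(B), method = method,
            seed = as.integer(seed),
            class = c("confidence_band", "data.frame"))
}

#' Coverage probability of a band against a reference trajectory
#'
#' The fraction of the 26 time points at which the reference trajectory lies
#' inside the band, per output variable.
#'
#' @param band a [bootstrap_band()] result.
#' @param reference a `trajectory` data frame with `t`, `beta`, `gamma`,
#'   `tau`.
#' @return A `coverage_report` data frame with columns `output` and
#'   `coverage` (each in \[0, 1\]).
#' @export
coverage_probability <- function(band, reference) {
  out <- do.call(rbind, lapply(.output_names, function(h) {
    bh <- band[band$output == h, ]
    idx <- match(bh$t, reference$t)
    if (anyNA(idx)) stopf("band and reference trajectories have different weeks")
    y <- reference[[h]][idx]
    data.frame(output = h,
               coverage = mean(y >= bh$lower & y <= bh$upper))
  }))
  rownames(out) <- NULL
  class(out) <- c("coverage_report", "data.frame")
  out
}

#' Mean band coverage over many subjects
#'
#' Builds bootstrap bands for every subject of an evaluation table (sharing
#' the bootstrap machinery, so the refit variant re-trains only `B` times in
#' total) and scores them against the observed trajectories in that table.
#' This is the coverage-probability statistic reported per output and sample
#' size in the study design.
#'
#' @param model a fitted [fit_emulator()] model.
#' @param table the training table supplying the residual pool.
#' @param eval_table a `training_table` holding the reference trajectories to
#'   score (training rows for a held-in calibration check, test rows for the
#'   study statistic).
#' @inheritParams bootstrap_band
#' @return A list with `mean_coverage` (named per-output vector),
#'   `per_subject` (data frame `subject_id` x outputs) and the band
#'   parameters.
#' @export
coverage_study <- function(model, table, eval_table, B = 50L, alpha = 0.05,
                           seed = 1L, method = c("perturb", "refit")) {
  method <- match.arg(method)
  if (B < 2) stopf("B must be >= 2 bootstrap replicates")
  .check_table(eval_table)
  residuals <- compute_residuals(model, table)
  center <- .predict_outputs(model, eval_table[model$feature_names])
  draws <- if (method == "perturb") {
    .perturb_draws(center, residuals, B, seed)
  } else {
    .refit_draws(model, table, eval_table[model$feature_names],
                 residuals, B, seed)
  }
  q <- .band_from_draws(draws, alpha)
  inside <- vapply(.output_names, function(h) {
    eval_table[[h]] >= q[[h]][, "lower"] & eval_table[[h]] <= q[[h]][, "upper"]
  }, logical(nrow(eval_table)))
  per_subject <- aggregate(inside, by = list(subject_id = eval_table$subject_id),
                           FUN = mean)
  list(
    mean_coverage = colMeans(inside),
    per_subject = per_subject,
    B = as.integer(B), alpha = alpha, method = method,
    n_subjects = nrow(per_subject)
  )
}
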