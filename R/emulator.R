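# Time-as-input ensemble emulator: one random forest per output variable,
# each taking the ten encoded subject features plus the week index and
# returning the equally-weighted average of its trees.

.check_table <- function(table) {
  missing <- setdiff(c(.feature_names, .output_names), names(table))
  if (length(missing) > 0) {
    stopf("training table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  num <- vapply(table[c(.feature_names, .output_names)], is.numeric, logical(1))
  if (!all(num)) {
    stopf("non-numeric column(s): %s",
          paste(names(num)[!num], collapse = ", "))
  }
  if (!all(is.finite(as.matrix(table[.output_names])))) {
    stopf("non-finite output values in training table")
  }
  invisible(table)
}

#' Fit the random-forest trajectory emulator
#'
#' Fits one regression forest per output variable (`beta`, `gamma`, `tau`)
#' on the long-format training table, with the week index `t` as an ordinary
#' eleventh input. The default of 50 trees follows the study design; tree
#' hyperparameters beyond the ensemble size are the conventional regression
#' defaults of \pkg{ranger} unless overridden. Out-of-bag mean-squared
#' errors and the empirical 3x3 covariance of the training residuals are
#' stored on the model.
#'
#' @param table a `training_table` from [generate_dataset()] or
#'   [read_training_table()].
#' @param n_trees trees per forest (`M`), default 50.
#' @param seed integer seed; fits are deterministic under it (forests run
#'   single-threaded).
#' @param mtry,min_node_size optional \pkg{ranger} hyperparameters.
#' @return A `t2d_emulator` list: `forests` (one \pkg{ranger} fit per
#'   output), `n_trees`, `feature_names`, `oob` (per-output OOB MSE),
#'   `residual_cov`, `train_subjects`, `t_range`, `seed`.
#' @export
fit_emulator <- function(table, n_trees = 50L, seed = 1L,
                         mtry = NULL, min_node_size = NULL) {
  .check_table(table)
  if (nrow(table) == 0) stopf("empty training table")
  if (n_trees < 1) stopf("n_trees must be >= 1")
  X <- table[.feature_names]
  forests <- lapply(.output_names, function(h) {
    ranger::ranger(
      x = X, y = table[[h]],
      num.trees = n_trees,
      mtry = mtry,
      min.node.size = min_node_size,
      seed = derive_seed(seed, "forest", h),
      num.threads = 1,
      oob.error = TRUE
    )
  })
  names(forests) <- .output_names
  model <- structure(
    list(
      forests = forests,
      n_trees = as.integer(n_trees),
      feature_names = .feature_names,
      oob = vapply(forests, function(f) f$prediction.error, numeric(1)),
      train_subjects = unique(table$subject_id),
      t_range = range(table$t),
      seed = as.integer(seed)
    ),
    class = "t2d_emulator"
  )
  pred <- .predict_outputs(model, X)
  res <- as.matrix(table[.output_names]) - pred
  model$residual_cov <- stats::cov(res)
  model
}

#' @export
print.t2d_emulator <- function(x, ...) {
  cat(sprintf(
    "Trajectory emulator: 3 forests x %d trees, %d training subjects\n",
    x$n_trees, length(x$train_subjects)))
  cat("OOB mean squared error:\n")
  print(signif(x$oob, 4))
  invisible(x)
}

# predict all three outputs for a data frame of encoded features + t
.predict_outputs <- function(model, newdata) {
  newdata <- as.data.frame(newdata)[model$feature_names]
  out <- vapply(
    .output_names,
    function(h) predict(model$forests[[h]], data = newdata,
                        num.threads = 1)$predictions,
    numeric(nrow(newdata))
  )
  if (nrow(newdata) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, .output_names))
  out
}

# build the emulator input rows for one subject at the given weeks
.subject_rows <- function(x, t) {
  feats <- encode_subjects(as.data.frame(x))
  rows <- as.data.frame(feats[rep(1, length(t)), , drop = FALSE])
  rows$t <- t
  rows
}

#' Predict the three outputs for one subject-week
#'
#' Returns the ensemble-mean prediction \eqn{\hat y(x, t)}: for each output
#' the equally-weighted average of the per-tree predictions. Weeks outside
#' the training horizon are allowed but flagged with a warning, since trees
#' extrapolate by nearest partition.
#'
#' @param model a fitted [fit_emulator()] model.
#' @param x a one-row subject data frame.
#' @param t week index (scalar or vector).
#' @return A named vector `(beta, gamma, tau)` for scalar `t`, otherwise a
#'   matrix with one row per week.
#' @export
predict_point <- function(model, x, t) {
  if (any(t < model$t_range[1] | t > model$t_range[2])) {
    warning(sprintf(
      "week(s) outside the training horizon [%d, %d]; prediction is an extrapolation",
      model$t_range[1], model$t_range[2]), call. = FALSE)
  }
  out <- .predict_outputs(model, .subject_rows(x, t))
  if (length(t) == 1L) out[1, ] else out
}

#' Predict a full 26-week trajectory for one subject
#'
#' Applies [predict_point()] over the training horizon.
#'
#' @inheritParams predict_point
#' @return A `trajectory` data frame with columns `t`, `beta`, `gamma`,
#'   `tau` (plus `subject_id` when present in `x`).
#' @export
predict_trajectory <- function(model, x) {
  t <- seq(model$t_range[1], model$t_range[2])
  out <- cbind(data.frame(t = t), as.data.frame(.predict_outputs(
    model, .subject_rows(x, t))))
  if (!is.null(x$subject_id)) out <- cbind(subject_id = x$subject_id, out)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Out-of-bag error of the emulator
#'
#' Per-output out-of-bag mean-squared error on the training table, as stored
#' at fit time from the bagged forests.
#'
#' @param model a fitted [fit_emulator()] model.
#' @return Named numeric vector of OOB MSEs, all `>= 0`.
#' @export
oob_error <- function(model) {
  if (is.null(model$oob) || anyNA(model$oob)) {
    stopf("out-of-bag error unavailable for this model")
  }
  model$oob
}
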