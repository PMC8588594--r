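# Constrained diet optimization: choose per-meal macronutrient levels that
# minimize the emulated squared-inflammation load sum_t tau_hat(t)^2 subject
# to per-macronutrient and total grams-per-meal bounds.

#' All 27 diet level combinations
#'
#' Lexicographic enumeration (low < med < high, carb slowest) of the
#' per-meal carbohydrate/protein/fat level assignments.
#'
#' @return A 27-row data frame with `carb_level`, `prot_level`, `fat_level`.
#' @export
diet_grid <- function() {
  lev <- c("low", "med", "high")
  out <- expand.grid(fat_level = lev, prot_level = lev, carb_level = lev,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("carb_level", "prot_level", "fat_level")]
  rownames(out) <- NULL
  out
}

#' Squared-inflammation objective for a candidate diet
#'
#' Substitutes the candidate diet levels into the subject descriptor,
#' predicts the 26-week TNF-alpha trajectory with the emulator, and returns
#' \eqn{\sum_t \hat\tau(t)^2}.
#'
#' @param model a fitted [fit_emulator()] model.
#' @param x a one-row subject data frame (its own diet is ignored).
#' @param diet a list/row with `carb_level`, `prot_level`, `fat_level`.
#' @return Non-negative scalar, deterministic given the model.
#' @export
objective_value <- function(model, x, diet) {
  x <- as.data.frame(x)
  x$carb_level <- diet$carb_level
  x$prot_level <- diet$prot_level
  x$fat_level <- diet$fat_level
  sum(predict_trajectory(model, x)$tau^2)
}

#' Feasibility of a diet against per-meal bounds
#'
#' A diet is feasible when the three per-macronutrient gram quantities lie
#' in their boxes and the total grams lie in `[l_T, u_T]`.
#'
#' @param diet a [meal_macros()] result or any list with `carb`, `prot`,
#'   `fat` grams per meal.
#' @param bounds a [diet_bounds()] result.
#' @return Logical scalar, with attribute `violated` naming any failed
#'   constraints.
#' @export
feasible_diet <- function(diet, bounds) {
  total <- diet$carb + diet$prot + diet$fat
  checks <- c(
    carb  = diet$carb >= bounds$l_C && diet$carb <= bounds$u_C,
    prot  = diet$prot >= bounds$l_P && diet$prot <= bounds$u_P,
    fat   = diet$fat >= bounds$l_F && diet$fat <= bounds$u_F,
    total = total >= bounds$l_T && total <= bounds$u_T
  )
  structure(all(checks), violated = names(checks)[!checks])
}

#' Optimize the diet to minimize emulated inflammation
#'
#' Solves
#' \deqn{\min_{C,P,F} \sum_t \hat\tau(t)^2 \quad \mathrm{s.t.}\quad
#'   l_C \le C \le u_C,\; l_P \le P \le u_P,\; l_F \le F \le u_F,\;
#'   l_T \le C+P+F \le u_T}
#' over the per-meal macronutrient assignment. The default method
#' exhaustively enumerates the 27 level combinations, keeps those whose gram
#' realizations satisfy the bounds, evaluates the emulated objective on
#' each, and returns the argmin (ties broken by lowest total grams, then
#' lexicographic level order). A `"continuous"` mode runs a Nelder-Mead
#' search over gram values (snapped to the nearest levels for emulator
#' input) for user-supplied gram-valued bounds.
#'
#' @param model a fitted [fit_emulator()] model.
#' @param x a one-row subject data frame; its own diet levels are the
#'   baseline.
#' @param bounds a [diet_bounds()] result; defaults to the subject's own
#'   bounds.
#' @param method `"exhaustive"` (default) or `"continuous"`.
#' @param constants energy-model constants.
#' @return A `diet_optimization` list: `best` (levels + grams), `objective`,
#'   `baseline` levels, `baseline_objective`, `tau_hat` (26-week series
#'   under the best diet), `feasible_count`, `method`, and the per-candidate
#'   `candidates` table.
#' @export
optimize_diet <- function(model, x, bounds = NULL,
                          method = c("exhaustive", "continuous"),
                          constants = energy_constants()) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  budget <- energy_budget(x, constants = constants)
  if (is.null(bounds)) bounds <- diet_bounds(x, budget, constants)

  combos <- diet_grid()
  grams <- lapply(seq_len(nrow(combos)), function(i) {
    meal_macros(budget, unlist(combos[i, ]), constants)
  })
  feas <- vapply(grams, function(g) isTRUE(feasible_diet(g, bounds)), logical(1))
  if (!any(feas)) {
    probe <- feasible_diet(grams[[which(combos$carb_level == "med" &
                                          combos$prot_level == "med" &
                                          combos$fat_level == "med")]], bounds)
    stopf("no feasible diet under the given bounds (med/med/med violates: %s)",
          paste(attr(probe, "violated"), collapse = ", "))
  }

  candidates <- cbind(
    combos,
    carb = vapply(grams, `[[`, numeric(1), "carb"),
    prot = vapply(grams, `[[`, numeric(1), "prot"),
    fat = vapply(grams, `[[`, numeric(1), "fat"),
    feasible = feas,
    objective = NA_real_
  )
  candidates$total <- candidates$carb + candidates$prot + candidates$fat

  # one batched prediction over 27 x 26 rows, then per-candidate sums
  idx_f <- which(feas)
  rows <- do.call(rbind, lapply(idx_f, function(i) {
    xi <- x
    xi$carb_level <- combos$carb_level[i]
    xi$prot_level <- combos$prot_level[i]
    xi$fat_level <- combos$fat_level[i]
    r <- .subject_rows(xi, seq(model$t_range[1], model$t_range[2]))
    r$candidate <- i
    r
  }))
  tau_hat <- .predict_outputs(model, rows[model$feature_names])[, "tau"]
  obj <- tapply(tau_hat^2, rows$candidate, sum)
  candidates$objective[as.integer(names(obj))] <- as.numeric(obj)

  ord <- order(candidates$objective, candidates$total,
               seq_len(nrow(candidates)), na.last = TRUE)
  best_i <- ord[1]

  if (method == "continuous") {
    best_i <- .continuous_refine(model, x, bounds, budget, candidates,
                                 best_i, constants)
  }

  baseline <- list(carb_level = x$carb_level, prot_level = x$prot_level,
                   fat_level = x$fat_level)
  baseline_objective <- objective_value(model, x, baseline)
  best_x <- x
  best_x$carb_level <- candidates$carb_level[best_i]
  best_x$prot_level <- candidates$prot_level[best_i]
  best_x$fat_level <- candidates$fat_level[best_i]

  structure(list(
    best = candidates[best_i, c("carb_level", "prot_level", "fat_level",
                                "carb", "prot", "fat")],
    objective = candidates$objective[best_i],
    baseline = baseline,
    baseline_objective = baseline_objective,
    tau_hat = predict_trajectory(model, best_x)$tau,
    feasible_count = sum(feas),
    method = method,
    candidates = candidates
  ), class = "diet_optimization")
}

# derivative-free polish over gram values: the emulator's diet input is
# categorical, so gram proposals are snapped to the nearest level grams; the
# search can therefore only rediscover a level combination, which keeps the
# continuous mode consistent with the discrete argmin
.continuous_refine <- function(model, x, bounds, budget, candidates, best_i,
                               constants) {
  med <- meal_macros(budget, c("med", "med", "med"), constants)
  snap <- function(g, med_g) {
    lv <- c("low", "med", "high")
    lv[which.min(abs(g - med_g * constants$level_multiplier[lv]))]
  }
  penalized <- function(par) {
    d <- list(carb = par[1], prot = par[2], fat = par[3])
    if (!isTRUE(feasible_diet(d, bounds))) return(1e12)
    lvl <- list(carb_level = snap(par[1], med$carb),
                prot_level = snap(par[2], med$prot),
                fat_level = snap(par[3], med$fat))
    objective_value(model, x, lvl)
  }
  start <- c(candidates$carb[best_i], candidates$prot[best_i],
             candidates$fat[best_i])
  fit <- stats::optim(start, penalized, method = "Nelder-Mead",
                      control = list(maxit = 200))
  lvl <- c(snap(fit$par[1], med$carb), snap(fit$par[2], med$prot),
           snap(fit$par[3], med$fat))
  hit <- which(candidates$carb_level == lvl[1] &
                 candidates$prot_level == lvl[2] &
                 candidates$fat_level == lvl[3] & candidates$feasible)
  if (length(hit) == 1 && !is.na(candidates$objective[hit]) &&
      candidates$objective[hit] < candidates$objective[best_i]) hit else best_i
}

#' @export
print.diet_optimization <- function(x, ...) {
  cat(sprintf(
    "Optimized diet: carb %s / prot %s / fat %s (%.0f/%.0f/%.0f g per meal)\n",
    x$best$carb_level, x$best$prot_level, x$best$fat_level,
    x$best$carb, x$best$prot, x$best$fat))
  cat(sprintf("objective %.4g vs baseline %.4g (%d feasible diet(s), %s)\n",
              x$objective, x$baseline_objective, x$feasible_count, x$method))
  invisible(x)
}
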