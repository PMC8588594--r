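# Energy-balance model: resting and activity energy expenditure, thermic
# effect of food, per-meal macronutrient quantities and diet bounds.

#' Energy-model constants
#'
#' All tunable constants of the energy model in one place: the 50/20/30
#' carbohydrate/protein/fat calorie shares of a meal, the Atwater energy
#' densities (4/4/9 kcal per gram), the 0.8/1.5 multipliers realizing the
#' low/high macronutrient levels, the thermic-effect-of-food rate (10 % of
#' calories ingested), MET values for the two exercise intensities, and the
#' per-sex representative heights (cm) and per-class representative BMIs used
#' to turn the categorical weight/height classes into numbers.
#'
#' @param ... named overrides of individual constants.
#' @return A named list of constants.
#' @export
energy_constants <- function(...) {
  defaults <- list(
    macro_shares   = c(carb = 0.50, prot = 0.20, fat = 0.30),
    energy_density = c(carb = 4, prot = 4, fat = 9),      # kcal per gram
    level_multiplier = c(low = 0.8, med = 1.0, high = 1.5),
    tef_rate       = 0.10,                                # fraction of intake
    met            = c("40" = 4, "60" = 7),               # by %VO2max
    height_cm      = list(
      female = c(short = 155, average = 162.5, tall = 170),
      male   = c(short = 165, average = 175,   tall = 185)
    ),
    bmi_rep        = c(underweight = 17.5, normal = 22, overweight = 27.5),
    total_bound_multipliers = c(lower = 0.8, upper = 1.5)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    stopf("unknown energy constant(s): %s", paste(unknown, collapse = ", "))
  }
  defaults[names(override)] <- override
  defaults
}

#' Representative body measures for a subject
#'
#' Resolves the categorical weight and height classes into numeric values: a
#' per-sex representative height and a per-class representative BMI, from
#' which the representative weight is `BMI * (height/100)^2`.
#'
#' @param subject a one-row subject data frame.
#' @param constants energy-model constants from [energy_constants()].
#' @return A list with `height_cm`, `bmi` and `weight_kg`.
#' @export
representative_body <- function(subject, constants = energy_constants()) {
  h <- constants$height_cm[[subject$sex]][[subject$height_class]]
  b <- constants$bmi_rep[[subject$weight_class]]
  list(height_cm = h, bmi = b, weight_kg = b * (h / 100)^2)
}

#' Resting energy expenditure (kcal/day)
#'
#' Mifflin-St Jeor equation on the representative weight, height and age:
#' `10 W + 6.25 H - 5 A + 5` for males and `10 W + 6.25 H - 5 A - 161` for
#' females. Increasing in weight and height, decreasing in age, with a fixed
#' 166 kcal/day sex offset at equal body measures.
#'
#' @inheritParams representative_body
#' @return kcal/day, strictly positive.
#' @export
compute_ree <- function(subject, constants = energy_constants()) {
  body <- representative_body(subject, constants)
  offset <- if (subject$sex == "male") 5 else -161
  10 * body$weight_kg + 6.25 * body$height_cm - 5 * subject$age + offset
}

#' Activity energy expenditure (kcal/day)
#'
#' MET-based net cost of the weekly exercise pattern, averaged per day:
#' `sessions * (duration/60) * (MET - 1) * weight / 7`, with MET 4 at
#' 40 %VO2max and MET 7 at 60 %VO2max. Zero for sedentary subjects and
#' linear in sessions and duration.
#'
#' @inheritParams representative_body
#' @return kcal/day, `>= 0`.
#' @export
compute_aee <- function(subject, constants = energy_constants()) {
  if (subject$pa_sessions == 0) return(0)
  met <- constants$met[[as.character(subject$pa_intensity)]]
  body <- representative_body(subject, constants)
  subject$pa_sessions * (subject$pa_duration / 60) * (met - 1) * body$weight_kg / 7
}

#' Daily energy budget under energy balance
#'
#' The total daily energy expenditure is `TDEE = REE + AEE + TEF` where the
#' thermic effect of food is 10 % of the calories ingested. Under energy
#' balance (intake = TDEE) this is a fixed point: the balanced intake solves
#' `intake = REE + AEE + 0.10 * intake`, i.e. `intake = (REE + AEE) / 0.9`.
#'
#' @param subject a one-row subject data frame, or `NULL` when `ree`/`aee`
#'   are supplied directly.
#' @param ree,aee optional kcal/day values overriding the subject-derived
#'   ones.
#' @param constants energy-model constants from [energy_constants()].
#' @return An `energy_budget` list with `ree`, `aee`, `tef`, `tdee` and
#'   `balanced_intake` (all kcal/day, `tdee == balanced_intake`).
#' @export
energy_budget <- function(subject = NULL, ree = NULL, aee = NULL,
                          constants = energy_constants()) {
  if (is.null(ree)) ree <- compute_ree(subject, constants)
  if (is.null(aee)) aee <- compute_aee(subject, constants)
  if (ree <= 0 || aee < 0) stopf("ree must be > 0 and aee >= 0")
  intake <- (ree + aee) / (1 - constants$tef_rate)
  budget <- list(
    ree = ree, aee = aee,
    tef = constants$tef_rate * intake,
    tdee = ree + aee + constants$tef_rate * intake,
    balanced_intake = intake
  )
  class(budget) <- "energy_budget"
  budget
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf(
    "Energy budget (kcal/day): REE %.1f + AEE %.1f + TEF %.1f = TDEE %.1f\n",
    x$ree, x$aee, x$tef, x$tdee))
  invisible(x)
}

#' Per-meal macronutrient grams for a level combination
#'
#' The balanced intake is divided into three equal meals; each meal's
#' calories split 50/20/30 % into carbohydrate, protein and fat, converted
#' to grams with the 4/4/9 kcal/g densities. Those are the `med` quantities;
#' `low` and `high` are 0.8 and 1.5 times `med`.
#'
#' @param budget an [energy_budget()].
#' @param levels length-3 character vector of carb/prot/fat levels
#'   (`"low"`, `"med"`, `"high"`).
#' @param constants energy-model constants.
#' @return A `meal_macros` list with `carb`, `prot`, `fat` grams per meal and
#'   the realized `levels`.
#' @export
meal_macros <- function(budget, levels = c("med", "med", "med"),
                        constants = energy_constants()) {
  levels <- as.character(levels)
  if (length(levels) != 3 || !all(levels %in% names(constants$level_multiplier))) {
    stopf("levels must be three of low/med/high")
  }
  meal_kcal <- budget$balanced_intake / 3
  med <- constants$macro_shares * meal_kcal / constants$energy_density
  mult <- constants$level_multiplier[levels]
  out <- list(
    carb = unname(med["carb"] * mult[1]),
    prot = unname(med["prot"] * mult[2]),
    fat  = unname(med["fat"] * mult[3]),
    levels = stats::setNames(levels, c("carb", "prot", "fat"))
  )
  class(out) <- "meal_macros"
  out
}

#' Per-meal diet bounds for the optimization feasible set
#'
#' Box bounds per macronutrient are the low (0.8 x med) and high (1.5 x med)
#' gram quantities; the total-grams bounds default to the same multipliers
#' applied to the summed med grams, so the med/med/med diet is always
#' strictly feasible.
#'
#' @inheritParams representative_body
#' @param budget optionally, a precomputed [energy_budget()] for the subject.
#' @return A `diet_bounds` list with `l_C`, `u_C`, `l_P`, `u_P`, `l_F`,
#'   `u_F`, `l_T`, `u_T` (grams per meal).
#' @export
diet_bounds <- function(subject, budget = NULL, constants = energy_constants()) {
  if (is.null(budget)) budget <- energy_budget(subject, constants = constants)
  med <- meal_macros(budget, c("med", "med", "med"), constants)
  lo <- constants$level_multiplier[["low"]]
  hi <- constants$level_multiplier[["high"]]
  tot <- med$carb + med$prot + med$fat
  tb <- constants$total_bound_multipliers
  out <- list(
    l_C = lo * med$carb, u_C = hi * med$carb,
    l_P = lo * med$prot, u_P = hi * med$prot,
    l_F = lo * med$fat,  u_F = hi * med$fat,
    l_T = tb[["lower"]] * tot, u_T = tb[["upper"]] * tot
  )
  class(out) <- "diet_bounds"
  out
}

# daily calories of a diet given as level labels, relative to balance:
# share-weighted mean of the level multipliers; 1 means intake == TDEE
.diet_multiplier <- function(carb_level, prot_level, fat_level,
                             constants = energy_constants()) {
  m <- constants$level_multiplier
  s <- constants$macro_shares
  unname(s[["carb"]] * m[carb_level] + s[["prot"]] * m[prot_level] +
           s[["fat"]] * m[fat_level])
}
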