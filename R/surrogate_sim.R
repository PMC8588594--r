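# Stochastic surrogate simulator: weekly 26-week trajectories of BMI (beta),
# fasting glucose (gamma) and TNF-alpha (tau) with the qualitative dynamics
# of the patient-specific simulator being emulated — gamma reacts within a
# week or two, beta drifts slowly with the energy imbalance, tau follows with
# an explicit inflammatory lag and the largest noise.

#' Surrogate-simulator configuration
#'
#' Parameters of the stochastic difference-equation surrogate. Noise scales
#' are per-week standard deviations in output units (kg/m^2 for beta, mg/dl
#' for gamma, arbitrary units for tau). BMI noise perturbs the weekly state
#' update; glucose and TNF-alpha noise are additive on the observed series.
#' By default tau has by far the largest noise both absolutely and relative
#' to its scale, reflecting the short life span of cytokines against the
#' weekly observation grid. `tau_lag` is the inflammatory
#' inertia in weeks: tau tracks a first-order-filtered, `tau_lag`-delayed
#' response to glucose and BMI.
#'
#' @param noise_sd_beta,noise_sd_gamma,noise_sd_tau per-week noise standard
#'   deviations.
#' @param tau_lag inflammatory delay in weeks.
#' @param response named list of response gains: `beta_gain` (relative BMI
#'   equilibrium shift per unit relative energy imbalance), `beta_rate` and
#'   `gamma_rate` and `tau_rate` (first-order filter rates per week),
#'   `gamma_base`, `gamma_age`, `gamma_bmi`, `gamma_carb`, `tau_base`,
#'   `tau_glucose`, `tau_bmi` (response intercepts/slopes).
#' @param t_max trajectory length in weeks.
#' @return A `simulator_config` list.
#' @export
simulator_config <- function(noise_sd_beta = 0.1,
                             noise_sd_gamma = 4.0,
                             noise_sd_tau = 6.0,
                             tau_lag = 3L,
                             response = list(),
                             t_max = 26L) {
  resp <- list(
    beta_gain  = 0.30,   # relative beta equilibrium shift per unit imbalance
    beta_rate  = 0.12,   # per-week approach rate of beta to its equilibrium
    gamma_rate = 0.70,   # fast: glucose settles within ~1-2 weeks
    tau_rate   = 0.45,   # slow resolution of inflammation
    gamma_base = 82,     # mg/dl at age 28, lean
    gamma_age  = 0.08,   # mg/dl per year above 28
    gamma_bmi  = 2.2,    # mg/dl per BMI unit above 22
    gamma_carb = 9,      # mg/dl per unit carb-level multiplier above med
    tau_base   = 15,     # arbitrary units, uninflamed
    tau_glucose = 1.5,   # per mg/dl of glucose above 88
    tau_bmi    = 1.2     # per BMI unit above 22
  )
  unknown <- setdiff(names(response), names(resp))
  if (length(unknown) > 0) {
    stopf("unknown response gain(s): %s", paste(unknown, collapse = ", "))
  }
  resp[names(response)] <- response
  if (noise_sd_tau < max(noise_sd_beta, noise_sd_gamma)) {
    warning("tau is expected to be the high-variability output", call. = FALSE)
  }
  cfg <- list(
    noise_sd_beta = noise_sd_beta, noise_sd_gamma = noise_sd_gamma,
    noise_sd_tau = noise_sd_tau, tau_lag = as.integer(tau_lag),
    response = resp, t_max = as.integer(t_max)
  )
  class(cfg) <- "simulator_config"
  cfg
}

# first-order lag filter with explicit delay: the week-t update tracks the
# target from `lag` weeks earlier at rate `rate`; targets before week 1 are
# held at the initial target (steady pre-study state)
.lagged_filter <- function(target, init, rate, lag) {
  t_max <- length(target)
  out <- numeric(t_max)
  prev <- init
  for (t in seq_len(t_max)) {
    tgt <- if (t - lag >= 1) target[t - lag] else init
    prev <- prev + rate * (tgt - prev)
    out[t] <- prev
  }
  out
}

#' Simulate one subject's 26-week trajectory
#'
#' Generates weekly series of BMI, fasting glucose and TNF-alpha for a
#' virtual subject. BMI starts at the weight-class representative value and
#' relaxes toward an equilibrium shifted in proportion to the relative energy
#' imbalance of the diet (share-weighted level multiplier vs the balanced
#' intake from [energy_budget()]); at exact energy balance and zero noise
#' BMI is constant. Glucose responds within a week or two to current BMI and
#' carbohydrate level; TNF-alpha is a lagged, slowly resolving response to
#' recent glucose and BMI with the largest noise, so a transient glucose
#' peak produces a delayed inflammation peak with slow decline.
#'
#' @param x a one-row subject data frame.
#' @param config a [simulator_config()].
#' @param seed integer seed; trajectories are deterministic under it.
#' @param constants energy-model constants shared with [energy_budget()].
#' @return A `trajectory` data frame with columns `subject_id` (if present in
#'   `x`), `t` (1..26), `beta`, `gamma`, `tau`.
#' @export
simulate_subject <- function(x, config = simulator_config(), seed = 1L,
                             constants = energy_constants()) {
  .check_subjects(as.data.frame(x))
  r <- config$response
  t_max <- config$t_max
  body <- representative_body(x, constants)
  imbalance <- .diet_multiplier(x$carb_level, x$prot_level, x$fat_level,
                                constants) - 1
  carb_mult <- constants$level_multiplier[[x$carb_level]]

  beta0 <- body$bmi
  beta_eq <- beta0 * (1 + r$beta_gain * imbalance)
  gamma_target <- function(beta) {
    r$gamma_base + r$gamma_age * (x$age - 28) +
      r$gamma_bmi * pmax(beta - 22, 0) + r$gamma_carb * (carb_mult - 1)
  }
  tau_target <- function(gamma, beta) {
    r$tau_base + r$tau_glucose * pmax(gamma - 88, 0) +
      r$tau_bmi * pmax(beta - 22, 0)
  }

  with_seed(seed, {
    beta <- numeric(t_max)
    prev <- beta0
    for (t in seq_len(t_max)) {
      prev <- prev + r$beta_rate * (beta_eq - prev) +
        rnorm(1, 0, config$noise_sd_beta)
      beta[t] <- prev
    }
    gamma0 <- r$gamma_base + r$gamma_age * (x$age - 28) +
      r$gamma_bmi * max(beta0 - 22, 0)
    gamma <- .lagged_filter(gamma_target(beta), gamma0, r$gamma_rate, 0) +
      rnorm(t_max, 0, config$noise_sd_gamma)
    tau0 <- tau_target(gamma0, beta0)
    tau <- .lagged_filter(tau_target(gamma, beta), tau0, r$tau_rate,
                          config$tau_lag) +
      rnorm(t_max, 0, config$noise_sd_tau)
    out <- data.frame(t = seq_len(t_max), beta = beta, gamma = gamma, tau = tau)
    if (!is.null(x$subject_id)) out <- cbind(subject_id = x$subject_id, out)
    class(out) <- c("trajectory", "data.frame")
    out
  })
}

#' Generate a long-format training table for a design sample
#'
#' Simulates every subject of the sample and stacks the results into the
#' emulator's long format: one row per (subject, week) with the ten encoded
#' subject features, the week index `t` (the eleventh input) and the three
#' outputs. Row count is `26 * nrow(sample)`. Each subject's trajectory seed
#' derives deterministically from `seed` and its `subject_id`, so the table
#' is reproducible and insensitive to row order.
#'
#' @param sample a `design_sample` (or any subject data frame with
#'   `subject_id`).
#' @param config a [simulator_config()].
#' @param seed master integer seed.
#' @param constants energy-model constants.
#' @return A `training_table` data frame with columns `subject_id`, the ten
#'   feature columns, `t`, `beta`, `gamma`, `tau`.
#' @export
generate_dataset <- function(sample, config = simulator_config(), seed = 1L,
                             constants = energy_constants()) {
  sample <- as.data.frame(sample)
  if (nrow(sample) == 0) stopf("empty design sample")
  if (is.null(sample$subject_id)) sample$subject_id <- seq_len(nrow(sample))
  feats <- encode_subjects(sample)
  t_max <- config$t_max
  n <- nrow(sample)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    traj <- simulate_subject(sample[i, , drop = FALSE], config,
                             seed = derive_seed(seed, "traj", sample$subject_id[i]),
                             constants = constants)
    blocks[[i]] <- cbind(
      subject_id = sample$subject_id[i],
      as.data.frame(feats[rep(i, t_max), , drop = FALSE]),
      traj[, c("t", "beta", "gamma", "tau")]
    )
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("training_table", "data.frame")
  out
}
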