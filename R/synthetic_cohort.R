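# Seeded synthetic inpatient cohort with known ground-truth insulin
# response: a minimal dose-response simulator over the seven-slot grid,
# brute-force per-slot oracle doses, a jittered (deliberately sub-optimal)
# behavior policy, and the degraded-data operations.

POSTMEAL_SLOTS <- c(1L, 3L, 5L)  # post-breakfast, post-lunch, post-dinner

# Injection schedule per regimen: named integer->class map over slots 0..6.
regimen_schedule <- function(regimen) {
  switch(regimen,
    premixed    = c("0" = "premixed", "4" = "premixed"),
    basal_only  = c("6" = "long_acting"),
    basal_bolus = c("0" = "short_rapid", "2" = "short_rapid",
                    "4" = "short_rapid", "6" = "long_acting"),
    stop("unknown regimen: ", regimen))
}

#' Synthetic cohort configuration
#'
#' Defines the generating conditions of the simulated inpatient cohort:
#' cohort size, treatment days (at least 2, matching the study's inclusion
#' rule), the mix of insulin regimens, the hyperpriors of the per-patient
#' latents, the behavior-policy dose jitter, measurement missingness and
#' glucose noise.
#'
#' @param n_patients Number of patients.
#' @param n_days Treatment days per patient (>= 2).
#' @param regimen_mix Named proportions over `premixed`, `basal_only`,
#'   `basal_bolus`; must sum to 1.
#' @param basal_mean,basal_sd Hyperprior of basal (fasting, insulin-naive)
#'   glucose in mmol/L.
#' @param sens_mean,sens_sd Hyperprior of insulin sensitivity, mmol/L
#'   glucose drop per effective unit.
#' @param meal_mean,meal_sd Hyperprior of per-meal post-prandial glucose
#'   rise in mmol/L.
#' @param noise_sd Gaussian measurement/physiology noise sd in mmol/L.
#' @param behavior_policy_noise Sd (units) of the discrete Gaussian jitter
#'   added to oracle doses by the logged behavior policy.
#' @param missing_rate Probability that a slot's glucose is unmeasured.
#' @param target_glucose Glucose target (mmol/L) the oracle doses aim at.
#' @param seed Integer seed; all randomness flows from it through
#'   per-patient substreams.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200, n_days = 3,
                          regimen_mix = c(premixed = 0.4, basal_only = 0.3,
                                          basal_bolus = 0.3),
                          basal_mean = 9.5, basal_sd = 1.2,
                          sens_mean = 0.35, sens_sd = 0.08,
                          meal_mean = 3.5, meal_sd = 0.7,
                          noise_sd = 0.4, behavior_policy_noise = 3,
                          missing_rate = 0.1, target_glucose = 6.5,
                          seed = 1L) {
  if (abs(sum(regimen_mix) - 1) > 1e-9)
    stop("regimen_mix proportions must sum to 1")
  if (n_days < 2) stop("n_days must be >= 2 (patients treated < 2 days are excluded)")
  if (noise_sd < 0 || missing_rate < 0 || missing_rate >= 1)
    stop("invalid noise_sd or missing_rate")
  structure(as.list(environment()), class = "cohort_config")
}

sample_latents <- function(cfg) {
  trunc_norm <- function(n, mean, sd, lo, hi)
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
  list(
    basal_glucose = trunc_norm(1, cfg$basal_mean, cfg$basal_sd, 6.5, 13.5),
    insulin_sensitivity = trunc_norm(1, cfg$sens_mean, cfg$sens_sd, 0.12, 0.6),
    meal_effect = trunc_norm(3, cfg$meal_mean, cfg$meal_sd, 1.5, 6),
    noise_sd = cfg$noise_sd
  )
}

# Additive contribution of one injection to the effective-dose profile.
# Steps are 1-based absolute indices on the 7-slot grid.
# Kinetics (minimal pharmacology for the three regimen families):
#   short/rapid : full effect on the immediately following slot;
#   long-acting : half-weight effect on each of the next 7 slots (next day);
#   premixed    : prandial half on the next slot, basal half spread at
#                 quarter weight over the three slots after that.
dose_contribution <- function(class, step, tau) {
  idx <- switch(class,
    short_rapid = step + 1L,
    long_acting = step + 1:7,
    premixed    = step + 1:4,
    integer(0))
  wts <- switch(class,
    short_rapid = 1.0,
    long_acting = rep(0.5, 7),
    premixed    = c(0.5, 0.25, 0.25, 0.25),
    numeric(0))
  keep <- idx <= tau
  list(idx = idx[keep], wts = wts[keep])
}

# Noise-free glucose response to a full action sequence.
# action_class/dose are per-step vectors of length tau = 7 * n_days.
sim_expected_glucose <- function(latents, action_class, dose, n_days) {
  tau <- 7L * n_days
  slot <- rep(0:6, n_days)
  meal_lift <- numeric(tau)
  for (m in 1:3) meal_lift[slot == POSTMEAL_SLOTS[m]] <- latents$meal_effect[m]
  eff <- numeric(tau)
  for (p in which(action_class != "none")) {
    ct <- dose_contribution(action_class[p], p, tau)
    eff[ct$idx] <- eff[ct$idx] + ct$wts * dose[p]
  }
  pmax(latents$basal_glucose + meal_lift - latents$insulin_sensitivity * eff,
       1.5)
}

#' Brute-force oracle doses for a synthetic patient
#'
#' Walks the regimen's injection events in chronological order and, for
#' each, searches doses 1..40 for the one minimizing the summed absolute
#' deviation of the noise-free glucose response from the target at the
#' slots that injection affects (given all previously fixed doses).
#' Ties prefer the lower dose.
#'
#' @param latents Patient latents as produced by the generator.
#' @param regimen One of `"premixed"`, `"basal_only"`, `"basal_bolus"`.
#' @param n_days Number of treatment days.
#' @param target Target glucose in mmol/L.
#' @return List with per-step `action_class` and integer `dose` vectors
#'   (`NA` dose at non-injection slots).
#' @export
oracle_doses <- function(latents, regimen, n_days, target = 6.5) {
  tau <- 7L * n_days
  slot <- rep(0:6, n_days)
  sched <- regimen_schedule(regimen)
  action_class <- rep("none", tau)
  for (s in names(sched)) action_class[slot == as.integer(s)] <- sched[[s]]
  dose <- rep(NA_integer_, tau)
  for (p in which(action_class != "none")) {
    ct <- dose_contribution(action_class[p], p, tau)
    if (length(ct$idx) == 0) { dose[p] <- 1L; next }
    best <- NULL; best_obj <- Inf
    for (u in 1:40) {
      cand <- dose; cand[p] <- u
      g <- sim_expected_glucose(latents,
                                ifelse(is.na(cand), "none", action_class),
                                ifelse(is.na(cand), 0L, cand), n_days)
      obj <- sum(abs(g[ct$idx] - target))
      if (obj < best_obj - 1e-12) { best <- u; best_obj <- obj }
    }
    dose[p] <- best
  }
  list(action_class = action_class, dose = dose)
}

#' Generate a synthetic inpatient cohort
#'
#' Simulates `n_patients` trajectories over the seven-slot daily grid with
#' per-patient latent insulin sensitivity, basal glucose and meal effects.
#' Logged behavior doses are the brute-force oracle doses plus rounded
#' Gaussian jitter clamped to 1..40 (a deliberately sub-optimal clinician
#' stand-in), glucose follows the closed-form dose-response model plus
#' Gaussian noise, a fraction of measurements is masked, and rewards are
#' the Magni-risk rewards of measured glucose. Deterministic under the
#' config seed via per-patient substreams.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   `trajectories` (list of `trajectory`), `latents` (per-patient list,
#'   including the oracle doses) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_patients
  pseeds <- sample.int(.Machine$integer.max - 1L, n)
  regimens <- sample(names(config$regimen_mix), n, replace = TRUE,
                     prob = config$regimen_mix)
  tau <- 7L * config$n_days
  trajs <- vector("list", n); lats <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(pseeds[i])
    lat <- sample_latents(config)
    orc <- oracle_doses(lat, regimens[i], config$n_days,
                        config$target_glucose)
    lat$oracle_doses <- orc$dose
    lat$regimen <- regimens[i]
    lat$patient_id <- sprintf("P%04d", i)
    inj <- which(orc$action_class != "none")
    beh <- orc$dose
    if (config$behavior_policy_noise > 0)
      beh[inj] <- pmin(40L, pmax(1L, as.integer(round(
        orc$dose[inj] + stats::rnorm(length(inj), 0,
                                     config$behavior_policy_noise)))))
    g <- sim_expected_glucose(lat, orc$action_class, ifelse(is.na(beh), 0L, beh),
                              config$n_days)
    if (config$noise_sd > 0)
      g <- pmax(g + stats::rnorm(tau, 0, config$noise_sd), 1.5)
    g_obs <- g
    if (config$missing_rate > 0)
      g_obs[stats::runif(tau) < config$missing_rate] <- NA_real_
    # normalized covariates: age, sex, BMI, and an HbA1c-like marker
    # correlated with the latent basal glucose (informative for encoders)
    covs <- c(age_z = stats::rnorm(1, 0, 1),
              sex = stats::rbinom(1, 1, 0.5),
              bmi_z = stats::rnorm(1, 0, 1),
              hba1c_z = 0.8 * (lat$basal_glucose - config$basal_mean) /
                config$basal_sd + stats::rnorm(1, 0, 0.6))
    lat$covariates <- covs
    tr <- trajectory(sprintf("P%04d", i),
                     day = rep(seq_len(config$n_days), each = 7L),
                     slot = rep(0:6, config$n_days),
                     glucose = g_obs,
                     action_class = orc$action_class, dose = beh,
                     covariates = covs, regimen = regimens[i])
    trajs[[i]] <- traj_rewards(tr)
    lats[[i]] <- lat
  }
  structure(list(trajectories = trajs, latents = lats, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$trajectories), "patients,",
      x$config$n_days, "days each;",
      "regimens:", paste(names(table(vapply(x$latents, `[[`, "", "regimen"))),
                         collapse = "/"), "\n")
  invisible(x)
}

#' Discard glucose measurements down to k per day
#'
#' Emulates degraded data quality: for each day with more than `k` measured
#' glucose values, uniformly at random retains exactly `k` and masks the
#' rest. Actions and covariates are untouched; rewards at masked slots
#' become undefined. Deterministic under `seed`.
#'
#' @param traj A `trajectory`.
#' @param max_glucose_per_day Non-negative integer `k`.
#' @param seed Integer seed.
#' @return The degraded `trajectory`.
#' @export
degrade_trajectory <- function(traj, max_glucose_per_day, seed = 1L) {
  k <- max_glucose_per_day
  if (k < 0) stop("max_glucose_per_day must be >= 0")
  set.seed(seed)
  for (d in unique(traj$day)) {
    idx <- which(traj$day == d & !is.na(traj$glucose))
    if (length(idx) > k) {
      keep <- if (k > 0) sample(idx, k) else integer(0)
      drop <- setdiff(idx, keep)
      traj$glucose[drop] <- NA_real_
      traj$reward[drop] <- NA_real_
    }
  }
  traj
}

#' Add Gaussian observation noise to measured glucose
#'
#' Adds i.i.d. `N(0, sd^2)` noise to measured glucose values only (masked
#' slots stay masked), floors the result at 0.1 mmol/L and recomputes the
#' rewards of the noised measurements.
#'
#' @param traj A `trajectory`.
#' @param sd Noise standard deviation in mmol/L (>= 0).
#' @param seed Integer seed.
#' @return The noised `trajectory`.
#' @export
add_observation_noise <- function(traj, sd, seed = 1L) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(traj)
  set.seed(seed)
  m <- which(!is.na(traj$glucose))
  traj$glucose[m] <- pmax(traj$glucose[m] + stats::rnorm(length(m), 0, sd), 0.1)
  traj_rewards(traj)
}

# Interactive simulation: roll the response model forward while an agent
# chooses doses at the regimen's injection slots. agent_fn(info) receives
# info = list(step, day, slot, glucose, class, history) where history holds
# the partial per-step vectors up to the current step, and must return an
# integer dose in 1..40. Used for head-to-head policy evaluation on the
# simulator; deterministic under seed given a deterministic agent.
simulate_interactive <- function(latents, config, agent_fn, seed = 1L) {
  set.seed(seed)
  n_days <- config$n_days
  tau <- 7L * n_days
  slot <- rep(0:6, n_days); day <- rep(seq_len(n_days), each = 7L)
  sched <- regimen_schedule(latents$regimen)
  action_class <- rep("none", tau)
  for (s in names(sched)) action_class[slot == as.integer(s)] <- sched[[s]]
  dose <- rep(NA_integer_, tau)
  noise <- stats::rnorm(tau, 0, latents$noise_sd)
  glucose <- rep(NA_real_, tau)
  for (p in seq_len(tau)) {
    g_all <- sim_expected_glucose(latents, action_class,
                                  ifelse(is.na(dose), 0L, dose), n_days)
    glucose[p] <- max(g_all[p] + noise[p], 1.5)
    u <- agent_fn(list(step = p, day = day[p], slot = slot[p],
                       glucose = glucose[p], class = action_class[p],
                       history = list(day = day[seq_len(p)],
                                      slot = slot[seq_len(p)],
                                      glucose = glucose[seq_len(p)],
                                      action_class = action_class[seq_len(p - 1)],
                                      dose = dose[seq_len(p - 1)])))
    if (action_class[p] != "none")
      dose[p] <- as.integer(min(40L, max(1L, u)))
  }
  tr <- trajectory(latents$patient_id %||% "sim", day, slot, glucose,
                   action_class, dose, covariates = latents$covariates,
                   regimen = latents$regimen)
  traj_rewards(tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
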