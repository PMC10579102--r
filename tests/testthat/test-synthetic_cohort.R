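# Synthetic cohort generator: determinism, ground-truth response,
# oracle doses, degradation operations.

# Independent re-implementation of the dose-response model: direct
# per-slot accumulation written without reusing the package's helper.
oracle_response <- function(lat, action_class, dose, n_days) {
  tau <- 7 * n_days
  g <- numeric(tau)
  for (p in 1:tau) {
    slot <- (p - 1) %% 7
    meal <- 0
    if (slot == 1) meal <- lat$meal_effect[1]
    if (slot == 3) meal <- lat$meal_effect[2]
    if (slot == 5) meal <- lat$meal_effect[3]
    eff <- 0
    for (q in 1:tau) {
      if (action_class[q] == "none" || is.na(dose[q])) next
      u <- dose[q]
      if (action_class[q] == "short_rapid" && p == q + 1) eff <- eff + u
      if (action_class[q] == "long_acting" && p >= q + 1 && p <= q + 7)
        eff <- eff + 0.5 * u
      if (action_class[q] == "premixed") {
        if (p == q + 1) eff <- eff + 0.5 * u
        if (p >= q + 2 && p <= q + 4) eff <- eff + 0.25 * u
      }
    }
    g[p] <- max(lat$basal_glucose + meal - lat$insulin_sensitivity * eff, 1.5)
  }
  g
}

test_that("same seed reproduces the cohort exactly; shapes are correct", {
  c1 <- tiny_cohort(n_patients = 10, n_days = 3, seed = 21)
  c2 <- tiny_cohort(n_patients = 10, n_days = 3, seed = 21)
  expect_identical(c1$trajectories, c2$trajectories)
  expect_length(c1$trajectories, 10)
  expect_true(all(vapply(c1$trajectories, length, 0L) == 21L))
  c3 <- tiny_cohort(n_patients = 10, n_days = 3, seed = 22)
  expect_false(identical(c1$trajectories, c3$trajectories))
})

test_that("noiseless, jitter-free glucose matches the independent response oracle", {
  coh <- generate_cohort(cohort_config(n_patients = 6, n_days = 3,
                                       noise_sd = 0, behavior_policy_noise = 0,
                                       missing_rate = 0, seed = 5))
  for (i in seq_along(coh$trajectories)) {
    tr <- coh$trajectories[[i]]
    g <- oracle_response(coh$latents[[i]], tr$action_class, tr$dose, 3)
    expect_equal(tr$glucose, g, tolerance = 1e-10)
  }
})

test_that("generated rewards equal the Magni reward of generated glucose", {
  coh <- tiny_cohort(n_patients = 5, n_days = 2, seed = 9)
  for (tr in coh$trajectories) {
    m <- !is.na(tr$glucose)
    expect_equal(tr$reward[m], magni_reward(mgdl_from_mmol(tr$glucose[m])))
    expect_true(all(is.na(tr$reward[!m])))
  }
})

test_that("dose-response is monotone: more insulin never raises glucose", {
  set.seed(31)
  for (rep in 1:20) {
    lat <- list(basal_glucose = runif(1, 7, 13),
                insulin_sensitivity = runif(1, 0.15, 0.6),
                meal_effect = runif(3, 1.5, 6))
    regimen <- sample(c("premixed", "basal_only", "basal_bolus"), 1)
    orc <- oracle_doses(lat, regimen, 2)
    inj <- which(orc$action_class != "none")
    p <- sample(inj, 1)
    d1 <- orc$dose; d2 <- orc$dose
    d2[p] <- min(40L, d2[p] + sample(1:5, 1))
    g1 <- insulinrl:::sim_expected_glucose(lat, orc$action_class,
                                           ifelse(is.na(d1), 0, d1), 2)
    g2 <- insulinrl:::sim_expected_glucose(lat, orc$action_class,
                                           ifelse(is.na(d2), 0, d2), 2)
    expect_true(all(g2 <= g1 + 1e-12))
  }
})

test_that("stored oracle doses equal an independent brute-force search", {
  set.seed(17)
  lat <- list(basal_glucose = 10.2, insulin_sensitivity = 0.4,
              meal_effect = c(3.1, 3.6, 2.8))
  for (regimen in c("premixed", "basal_only", "basal_bolus")) {
    orc <- oracle_doses(lat, regimen, 2)
    inj <- which(orc$action_class != "none")
    # independent sequential brute force over the independent oracle model
    dd <- rep(NA_integer_, length(orc$action_class))
    for (p in inj) {
      # affected steps of this injection
      aff <- switch(orc$action_class[p],
                    short_rapid = p + 1, long_acting = p + 1:7,
                    premixed = p + 1:4)
      aff <- aff[aff <= length(dd)]
      if (length(aff) == 0) { dd[p] <- 1L; next }
      objs <- sapply(1:40, function(u) {
        cand <- dd; cand[p] <- u
        g <- oracle_response(lat, ifelse(is.na(cand), "none",
                                         orc$action_class), cand, 2)
        sum(abs(g[aff] - 6.5))
      })
      dd[p] <- which.max(-objs)  # first minimum -> lowest dose on ties
    }
    expect_identical(orc$dose, dd)
  }
})

test_that("degrade_trajectory retains exactly k measurements per day", {
  coh <- generate_cohort(cohort_config(n_patients = 2, n_days = 3,
                                       missing_rate = 0, seed = 3))
  tr <- coh$trajectories[[1]]
  expect_identical(degrade_trajectory(tr, 7, seed = 1), tr)
  d2 <- degrade_trajectory(tr, 2, seed = 1)
  for (d in unique(d2$day))
    expect_equal(sum(!is.na(d2$glucose[d2$day == d])), 2)
  # untouched fields
  expect_identical(d2$dose, tr$dose)
  expect_identical(d2$action_class, tr$action_class)
  # same seed -> same surviving set; reapplication keeps survivors
  d2b <- degrade_trajectory(tr, 2, seed = 1)
  expect_identical(d2, d2b)
  d2c <- degrade_trajectory(d2, 2, seed = 99)
  expect_identical(which(!is.na(d2c$glucose)), which(!is.na(d2$glucose)))
})

test_that("observation noise is zero-mean, floored, and mask-preserving", {
  coh <- tiny_cohort(n_patients = 3, n_days = 2, missing = 0.2, seed = 13)
  tr <- coh$trajectories[[1]]
  expect_identical(add_observation_noise(tr, 0), tr)
  noised <- add_observation_noise(tr, 0.5, seed = 8)
  expect_identical(is.na(noised$glucose), is.na(tr$glucose))
  expect_true(all(noised$glucose >= 0.1, na.rm = TRUE))
  expect_error(add_observation_noise(tr, -0.1), ">= 0")
  # Monte-Carlo: mean perturbation within 3 SE of zero
  base <- trajectory("m", rep(1:143, each = 7)[1:1000],
                     rep(0:6, length.out = 1000),
                     rep(8, 1000), rep("none", 1000), rep(NA_integer_, 1000))
  nz <- add_observation_noise(base, 0.5, seed = 4)
  delta <- nz$glucose - base$glucose
  se <- 0.5 / sqrt(1000)
  expect_lt(abs(mean(delta)), 3 * se)
})
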