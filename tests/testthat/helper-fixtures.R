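# Shared fixtures: small in-code cohorts and models used across the suite.

tiny_cohort <- function(n_patients = 6, n_days = 2, noise_sd = 0.3,
                        jitter = 2, missing = 0.1, seed = 7) {
  generate_cohort(cohort_config(
    n_patients = n_patients, n_days = n_days, noise_sd = noise_sd,
    behavior_policy_noise = jitter, missing_rate = missing, seed = seed))
}

# A hand-built two-day trajectory with known values.
toy_trajectory <- function() {
  trajectory(
    patient_id = "T1",
    day = rep(1:2, each = 7), slot = rep(0:6, 2),
    glucose = c(8.1, 11.2, 7.4, 10.8, 7.0, 12.3, 8.5,
                7.2, 10.1, NA, 9.9, 6.8, 11.0, 7.9),
    action_class = rep(c("premixed", "none", "none", "none",
                         "premixed", "none", "none"), 2),
    dose = rep(c(12L, NA, NA, NA, 10L, NA, NA), 2),
    covariates = c(0.1, 1, -0.3, 0.5),
    regimen = "premixed")
}

# Exhaustive enumeration oracle for the planner: depth-first search over
# the same candidate sets the planner sees, scoring complete sequences by
# sum gamma^i r + gamma^K V(terminal).
enumerate_best <- function(pm, policy, state, day, slot, regimen, cfg) {
  best <- -Inf
  recurse <- function(s, rewards, depth) {
    if (depth == cfg$K) {
      v <- sum(cfg$gamma^(seq_along(rewards) - 1) * rewards) +
        cfg$gamma^cfg$K * policy_value(policy, s)
      best <<- max(best, v)
      return(invisible())
    }
    pos <- advance_slot(day, slot, depth + 1)
    cls <- insulinrl:::scheduled_class(regimen, pos$slot)
    P <- policy_forward(policy, s)
    for (tok in insulinrl:::candidate_tokens(P, cls, cfg)) {
      st <- pm_step(pm, s, cls, token_dose(tok))
      recurse(matrix(st$state, 1), c(rewards, st$reward), depth + 1)
    }
  }
  recurse(matrix(state, 1), numeric(0), 0)
  best
}

# Toy 2-state, 2-action MDP for off-policy evaluation checks: the state
# flips when action 2 is taken; reward 1 whenever the state is 2.
toy_mdp_episode <- function(pol, len = 4) {
  s <- 1L
  states <- integer(len); actions <- integer(len); rewards <- numeric(len)
  for (t in seq_len(len)) {
    states[t] <- s
    a <- sample(1:2, 1, prob = pol[s, ])
    actions[t] <- a
    if (a == 2L) s <- 3L - s
    rewards[t] <- as.numeric(s == 2L)
  }
  list(states = states, actions = actions, rewards = rewards)
}

toy_return <- function(rewards, gamma)
  sum(gamma^(seq_along(rewards) - 1) * rewards)

# A tiny untrained patient model + policy for structural/planner tests.
toy_models <- function(hidden_dim = 8, seed = 42) {
  set.seed(seed)
  cfg <- patient_model_config(hidden_dim = hidden_dim, epochs = 1,
                              seed = seed)
  input_dim <- ncol(insulinrl:::traj_features(toy_trajectory()))
  pm <- structure(list(params = insulinrl:::new_patient_model(cfg, input_dim),
                       cfg = cfg, input_dim = input_dim, trained = TRUE),
                  class = "patient_model")
  pol <- structure(list(params = insulinrl:::new_dose_policy(hidden_dim, 1),
                        cfg = policy_config(), mode = "joint",
                        hidden_dim = hidden_dim, trained = TRUE,
                        floor = NULL),
                   class = "dose_policy")
  list(pm = pm, policy = pol)
}
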