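# Off-policy evaluation: ratios, IS/WIS estimates, effective sample
# size, convergence on a toy MDP with known policies.

test_that("importance ratios follow the definition and flag support violations", {
  r <- is_ratios(c(0.5, 0.2), c(0.5, 0.2))
  expect_equal(r$rho, c(1, 1)); expect_equal(r$w, 1)
  # deterministic target agreeing with the log
  r2 <- is_ratios(c(1, 1), c(0.25, 0.5))
  expect_equal(r2$rho, c(4, 2)); expect_equal(r2$w, 8)
  expect_error(is_ratios(c(0.5), c(0)), "support violation")
  set.seed(3)
  p1 <- runif(6); p0 <- runif(6, 0.1, 1)
  expect_equal(is_ratios(p1, p0)$w, prod(p1 / p0))
})

test_that("identical policies give the mean return and full ESS", {
  set.seed(4)
  G <- rnorm(20)
  res <- v_wis(rep(1, 20), G)
  expect_equal(res$v_wis, mean(G))
  expect_equal(res$v_is, mean(G))
  expect_equal(res$ess, 20)
  expect_equal(sum(res$weights), 1)
  # one dominant weight collapses to that trajectory's return
  res2 <- v_wis(c(1e8, rep(1e-8, 9)), c(2.5, rnorm(9)))
  expect_equal(res2$v_wis, 2.5, tolerance = 1e-6)
  expect_lt(res2$ess, 1 + 1e-6)
  expect_error(v_wis(c(0, 0), c(1, 2)), "degenerate")
})

test_that("ESS is bounded by N and attains N only for equal weights", {
  set.seed(5)
  for (i in 1:20) {
    w <- runif(15, 0.01, 5)
    res <- v_wis(w, rnorm(15))
    expect_lte(res$ess, 15 + 1e-9)
  }
  expect_equal(v_wis(rep(3.7, 8), rnorm(8))$ess, 8)
})

test_that("IS and WIS agree with on-policy Monte Carlo on the toy MDP", {
  gamma <- 0.9
  pi0 <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  pi1 <- rbind(c(0.3, 0.7), c(0.7, 0.3))
  # ground truth: direct Monte Carlo under the target policy
  set.seed(11)
  mc <- replicate(10000, toy_return(toy_mdp_episode(pi1)$rewards, gamma))
  truth <- mean(mc); se_mc <- sd(mc) / sqrt(length(mc))
  # off-policy data from the behavior policy
  set.seed(12)
  eps <- replicate(10000, toy_mdp_episode(pi0), simplify = FALSE)
  ws <- vapply(eps, function(e)
    is_ratios(pi1[cbind(e$states, e$actions)],
              pi0[cbind(e$states, e$actions)])$w, 0)
  gs <- vapply(eps, function(e) toy_return(e$rewards, gamma), 0)
  est_is <- v_is(ws, gs)
  res <- v_wis(ws, gs)
  se_is <- sd(ws * gs) / sqrt(length(ws))
  expect_lt(abs(est_is - truth), 3 * (se_is + se_mc))
  expect_lt(abs(res$v_wis - truth), 3 * (se_is + se_mc))
  expect_gt(res$ess, 100)
})

test_that("WIS has lower variance than IS over resamples", {
  gamma <- 0.9
  pi0 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  pi1 <- rbind(c(0.2, 0.8), c(0.8, 0.2))
  set.seed(21)
  eps <- replicate(4000, toy_mdp_episode(pi0), simplify = FALSE)
  ws <- vapply(eps, function(e)
    is_ratios(pi1[cbind(e$states, e$actions)],
              pi0[cbind(e$states, e$actions)])$w, 0)
  gs <- vapply(eps, function(e) toy_return(e$rewards, gamma), 0)
  set.seed(22)
  boots <- replicate(200, {
    idx <- sample(length(ws), 60, replace = TRUE)
    c(is = v_is(ws[idx], gs[idx]), wis = v_wis(ws[idx], gs[idx])$v_wis)
  })
  expect_lt(var(boots["wis", ]), var(boots["is", ]))
})

test_that("IS/WIS converge towards the on-policy value as N grows", {
  gamma <- 0.9
  pi0 <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  pi1 <- rbind(c(0.4, 0.6), c(0.6, 0.4))
  set.seed(31)
  truth <- mean(replicate(20000,
                          toy_return(toy_mdp_episode(pi1)$rewards, gamma)))
  errs <- vapply(c(100, 1000, 10000), function(N) {
    eps <- replicate(N, toy_mdp_episode(pi0), simplify = FALSE)
    ws <- vapply(eps, function(e)
      is_ratios(pi1[cbind(e$states, e$actions)],
                pi0[cbind(e$states, e$actions)])$w, 0)
    gs <- vapply(eps, function(e) toy_return(e$rewards, gamma), 0)
    abs(v_wis(ws, gs)$v_wis - truth)
  }, 0)
  expect_lt(errs[3], 0.05)
  expect_lt(errs[3], errs[1] + 0.02)
})

test_that("cohort-level OPE with a shared encoder produces a coherent report", {
  coh <- tiny_cohort(n_patients = 10, n_days = 2, seed = 41)
  pm <- patient_model(coh, patient_model_config(hidden_dim = 8, epochs = 2,
                                                seed = 2))
  pol <- train_policy(coh, pm, policy_config(epochs = 3, seed = 3),
                      mode = "sl_only")
  pol$floor <- 1e-3
  res <- ope_evaluate(coh, pol, pol, pm)
  # identical behavior and target policies: every ratio is 1
  expect_equal(res$ess, 10)
  gs <- vapply(coh$trajectories, function(tr)
    insulinrl:::traj_return(tr$reward, 0.9), 0)
  expect_equal(res$v_wis, mean(gs))
})
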