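# Patient model: encoding, dynamics, prediction, losses, training.

test_that("encode returns a hidden_dim-wide state, deterministically", {
  m <- toy_models(hidden_dim = 8)
  tr <- toy_trajectory()
  s1 <- encode(m$pm, tr)
  s2 <- encode(m$pm, tr)
  expect_length(s1, 8)
  expect_identical(s1, s2)
  expect_true(all(is.finite(s1)))
  # the paper-scale profile widens the state to 256
  cfg256 <- patient_model_config(hidden_dim = 256, encoder_layers = 3)
  set.seed(1)
  pm256 <- structure(list(params = insulinrl:::new_patient_model(
    cfg256, ncol(insulinrl:::traj_features(tr))), cfg = cfg256),
    class = "patient_model")
  expect_length(encode(pm256, tr), 256)
  expect_error(encode(m$pm, insulinrl:::traj_slice(tr, integer(0))), "empty")
})

test_that("training gradients match finite differences", {
  coh <- tiny_cohort(n_patients = 4, n_days = 2, seed = 7)
  cfg <- patient_model_config(hidden_dim = 6, encoder_layers = 2,
                              rollout_depth = 2, seed = 5)
  set.seed(5)
  params <- insulinrl:::new_patient_model(
    cfg, ncol(insulinrl:::traj_features(coh$trajectories[[1]])))
  bt <- insulinrl:::batch_tensors(coh$trajectories)
  pass <- insulinrl:::pm_batch_pass(params, cfg, bt, TRUE)
  f0 <- pass$losses[["total"]]
  eps <- 1e-5
  set.seed(11)
  for (comp in c("encoder", "dyn", "pred", "rew")) {
    g <- pass$grads[[comp]]
    path <- c()
    node <- g
    while (is.list(node)) {
      i <- sample(length(node), 1); path <- c(path, i); node <- node[[i]]
    }
    j <- sample(length(node), 1)
    p2 <- params
    leaf_expr <- Reduce(function(e, i) call("[[", e, i),
                        path, init = call("[[", quote(p2), comp))
    leaf <- eval(leaf_expr)
    leaf[j] <- leaf[j] + eps
    eval(call("<-", leaf_expr, leaf))
    f1 <- insulinrl:::pm_batch_pass(p2, cfg, bt, FALSE)$losses[["total"]]
    num <- (f1 - f0) / eps
    expect_lt(abs(num - node[j]) / max(1e-8, abs(num) + abs(node[j])), 1e-3)
  }
})

test_that("dynamics steps compose and reward head emits scalars", {
  m <- toy_models()
  s <- encode(m$pm, toy_trajectory())
  states <- list(); rewards <- c()
  for (k in 1:3) {
    st <- pm_step(m$pm, s, "short_rapid", 10L)
    s <- st$state
    states[[k]] <- s; rewards <- c(rewards, st$reward)
  }
  expect_length(states, 3); expect_length(rewards, 3)
  expect_true(all(vapply(states, length, 0L) == 8L))
  expect_error(pm_step(m$pm, s, "mystery", 5L), "unknown insulin class")
  expect_error(pm_step(m$pm, s, "premixed", 50L), "1..40")
})

test_that("status prediction squashes WTR to [0,1] and is a pure function", {
  m <- toy_models()
  set.seed(4)
  S <- matrix(rnorm(10 * 8), 10)
  p1 <- pm_predict(m$pm, S)
  p2 <- pm_predict(m$pm, S)
  expect_true(all(p1$wtr_prob >= 0 & p1$wtr_prob <= 1))
  expect_identical(p1, p2)
})

test_that("consistency loss is the summed squared pair distance", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  expect_equal(consistency_loss(a, b), 0)
  # two pairs with distances d1, d2 -> d1^2 + d2^2
  A <- rbind(c(0, 0, 0), c(1, 1, 1))
  B <- rbind(c(3, 0, 0), c(1, 1, 0))
  expect_equal(consistency_loss(A, B), 9 + 1)
  expect_equal(consistency_loss(A, B), consistency_loss(B, A))
  expect_message(out <- consistency_loss(matrix(0, 0, 3), matrix(0, 0, 3)),
                 "no matching")
  expect_equal(out, 0)
})

test_that("prediction loss decomposes into MSE plus cross-entropy", {
  pred <- list(glucose_mmol = c(5, 8), wtr_prob = c(1 - 1e-12, 0.5))
  truth <- list(glucose_mmol = c(5, 8), wtr = c(TRUE, TRUE))
  # perfect glucose; CE = (-log(1) - log(0.5)) / 2 = log(2)/2
  expect_equal(prediction_loss(pred, truth), log(2) / 2, tolerance = 1e-6)
  truth$glucose_mmol <- c(NA, NA)
  expect_error(prediction_loss(pred, truth), "masked")
  # random batch against a scalar re-computation
  set.seed(6)
  pr <- list(glucose_mmol = rnorm(5, 8), wtr_prob = runif(5))
  tv <- list(glucose_mmol = rnorm(5, 8), wtr = runif(5) > 0.5)
  manual <- mean((pr$glucose_mmol - tv$glucose_mmol)^2) +
    mean(-ifelse(tv$wtr, log(pr$wtr_prob), log(1 - pr$wtr_prob)))
  expect_equal(prediction_loss(pr, tv), manual)
})

test_that("rollout emits K predictions and enforces the action count", {
  m <- toy_models()
  tr <- toy_trajectory()
  acts <- replicate(7, list(class = "none", dose = NA_integer_),
                    simplify = FALSE)
  ro <- pm_rollout(m$pm, tr, acts, K = 7)
  expect_equal(nrow(ro), 7)
  expect_true(all(ro$wtr_prob >= 0 & ro$wtr_prob <= 1))
  expect_error(pm_rollout(m$pm, tr, acts, K = 5), "exactly K")
  # K = 1 equals encode -> step -> predict
  one <- pm_rollout(m$pm, tr, acts[1], K = 1)
  st <- pm_step(m$pm, encode(m$pm, tr), "none", NA_integer_)
  pr <- pm_predict(m$pm, st$state)
  expect_equal(one$glucose_mmol, pr$glucose_mmol)
  expect_equal(one$reward, st$reward)
})

test_that("joint training reduces the loss and mu = 0 drops the consistency term", {
  coh <- tiny_cohort(n_patients = 24, n_days = 2, noise_sd = 0.2,
                     seed = 19)
  cfg <- patient_model_config(hidden_dim = 12, epochs = 10,
                              rollout_depth = 2, seed = 3)
  pm <- patient_model(coh, cfg)
  h <- pm$history
  expect_lt(h$total[10], h$total[1])
  # loss decomposition identity on a batch
  bt <- insulinrl:::batch_tensors(coh$trajectories[1:8])
  pass <- insulinrl:::pm_batch_pass(pm$params, cfg, bt, FALSE)
  expect_equal(pass$losses[["total"]],
               cfg$consistency_weight * pass$losses[["cons"]] +
                 pass$losses[["glu"]] + pass$losses[["tir"]] +
                 cfg$reward_weight * pass$losses[["rew"]])
  cfg0 <- cfg; cfg0$consistency_weight <- 0
  pass0 <- insulinrl:::pm_batch_pass(pm$params, cfg0, bt, FALSE)
  expect_equal(pass0$losses[["total"]],
               pass0$losses[["glu"]] + pass0$losses[["tir"]] +
                 pass0$losses[["rew"]])
})

test_that("encoder is shared: perturbing it changes dynamics and predictions", {
  m <- toy_models()
  tr <- toy_trajectory()
  s <- encode(m$pm, tr)
  pm2 <- m$pm
  pm2$params$encoder[[1]]$W <- pm2$params$encoder[[1]]$W + 0.1
  s2 <- encode(pm2, tr)
  expect_false(isTRUE(all.equal(s, s2)))
  expect_false(isTRUE(all.equal(pm_predict(m$pm, s)$glucose_mmol,
                                pm_predict(pm2, s2)$glucose_mmol)))
})

test_that("checkpoints reproduce identical predictions after reload", {
  coh <- tiny_cohort(n_patients = 8, n_days = 2, seed = 29)
  pm <- patient_model(coh, patient_model_config(hidden_dim = 8, epochs = 2,
                                                seed = 2))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(pm, path)
  pm2 <- load_checkpoint(path)
  tr <- coh$trajectories[[1]]
  expect_identical(predict(pm, tr), predict(pm2, tr))
  expect_error(load_checkpoint("nope.rds"), "not found")
})
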