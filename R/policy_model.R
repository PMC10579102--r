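# Dosing policy pi and value function V over the learned latent states,
# trained with the joint objective L = L_RL1 + eps1 * L_RL2 + eps2 * L_SL:
# an advantage-weighted policy gradient on logged trajectories, a
# model-based policy gradient on roll-outs generated against the patient
# model, and categorical imitation of the clinician's logged doses.

N_TOKENS <- 41L  # token 1 = no injection, tokens 2..41 = doses 1..40

#' Map an insulin action to its policy token (and back)
#'
#' The dose vocabulary is `none` plus integer doses 1..40; the insulin
#' class is taken from the regimen schedule, the policy chooses the token.
#'
#' @param class Insulin class token.
#' @param dose Integer dose, `NA` for `"none"`.
#' @return Integer token in 1..41.
#' @export
action_token <- function(class, dose) {
  ifelse(class == "none", 1L, as.integer(dose) + 1L)
}

#' @rdname action_token
#' @param token Integer token in 1..41.
#' @export
token_dose <- function(token) ifelse(token == 1L, NA_integer_,
                                     as.integer(token) - 1L)

#' Policy training configuration
#'
#' @param layers Hidden layers of the policy and value MLPs.
#' @param gamma Discount factor in (0, 1].
#' @param eps1,eps2 Weights of the model-based policy-gradient loss and of
#'   the supervised imitation loss in the joint objective.
#' @param rollout_depth Depth of the model-based roll-outs.
#' @param n_anchors Roll-out start states sampled per trajectory per epoch.
#' @param epochs,batch_size,lr,weight_decay Optimization settings (Adam).
#' @param advantage Use the learnable value baseline `(R - V(s))` in the
#'   policy-gradient terms (the stable default); `FALSE` uses raw returns.
#' @param warmup_frac Fraction of epochs during which joint training runs
#'   imitation and value regression only, before the policy-gradient
#'   terms switch on. Starting the policy gradient from an
#'   imitation-initialized policy and a fitted value baseline keeps the
#'   advantage estimates low-variance.
#' @param seed Seed for initialization, shuffling and roll-out sampling.
#' @param verbose Print per-epoch loss terms.
#' @return A list of class `policy_config`.
#' @export
policy_config <- function(layers = 2, gamma = 0.9, eps1 = 1, eps2 = 1,
                          rollout_depth = 5, n_anchors = 3, epochs = 80,
                          batch_size = 16, lr = 1e-3, weight_decay = 1e-4,
                          advantage = TRUE, warmup_frac = 0.25, seed = 1L,
                          verbose = FALSE) {
  stopifnot(gamma > 0, gamma <= 1, eps1 >= 0, eps2 >= 0,
            warmup_frac >= 0, warmup_frac < 1)
  structure(as.list(environment()), class = "policy_config")
}

#' Action probabilities of a dosing policy
#'
#' Softmax output of the policy network over the 41-token dose vocabulary;
#' rows are non-negative and sum to 1. If the policy carries a probability
#' floor (behavior-policy estimates), probabilities are mixed with the
#' floor so that every token has mass at least `floor`.
#'
#' @param policy A `dose_policy`.
#' @param states Hidden state vector or (batch x hidden) matrix.
#' @return A (batch x 41) matrix of probabilities.
#' @export
policy_forward <- function(policy, states) {
  S <- if (is.matrix(states)) states else matrix(states, 1)
  P <- softmax_rows(mlp_forward(policy$params$pi, S)$out)
  fl <- policy$floor
  if (!is.null(fl) && fl > 0) P <- (1 - N_TOKENS * fl) * P + fl
  P
}

#' Value function estimate
#'
#' @param policy A `dose_policy`.
#' @param states Hidden state vector or (batch x hidden) matrix.
#' @return Numeric vector of state values.
#' @export
policy_value <- function(policy, states) {
  S <- if (is.matrix(states)) states else matrix(states, 1)
  as.numeric(mlp_forward(policy$params$V, S)$out)
}

#' Discounted returns
#'
#' `R_t = sum_i gamma^i r_{t+i}`, computed by the backward recursion
#' `R_t = r_t + gamma * R_{t+1}` with `R_{tau+1} = 0`. Missing rewards
#' (unmeasured slots) contribute 0.
#'
#' @param rewards Numeric vector of per-step rewards (`NA` allowed).
#' @param gamma Discount factor.
#' @return Numeric vector of the same length.
#' @export
discounted_returns <- function(rewards, gamma) {
  r <- ifelse(is.na(rewards), 0, rewards)
  n <- length(r)
  R <- numeric(n)
  acc <- 0
  for (t in rev(seq_len(n))) {
    acc <- r[t] + gamma * acc
    R[t] <- acc
  }
  R
}

#' Supervised imitation loss
#'
#' Cross-entropy of the clinician's logged action tokens under the policy:
#' `mean(-log pi(a_t | s_t))`.
#'
#' @param policy_probs (n x 41) matrix of action probabilities.
#' @param tokens Integer vector of logged action tokens (1..41).
#' @return Scalar loss.
#' @export
sl_loss <- function(policy_probs, tokens) {
  if (any(tokens < 1 | tokens > N_TOKENS)) stop("action token out of vocabulary")
  p <- policy_probs[cbind(seq_along(tokens), tokens)]
  mean(-log(pmax(p, 1e-12)))
}

#' Policy-gradient loss on a logged trajectory
#'
#' `L_RL1 = -sum_t w_t log pi(a_t | s_t)` where `w_t` is the discounted
#' return `R_t`, or the advantage `R_t - V(s_t)` when values are supplied
#' (the stable default used in training).
#'
#' @param policy_probs (tau x 41) matrix of action probabilities.
#' @param tokens Logged action tokens.
#' @param rewards Logged per-step rewards (`NA` allowed).
#' @param gamma Discount factor.
#' @param values Optional per-step value baseline `V(s_t)`.
#' @return Scalar loss.
#' @export
rl_loss_logged <- function(policy_probs, tokens, rewards, gamma,
                           values = NULL) {
  R <- discounted_returns(rewards, gamma)
  w <- if (is.null(values)) R else R - values
  p <- policy_probs[cbind(seq_along(tokens), tokens)]
  -sum(w * log(pmax(p, 1e-12)))
}

# ---- training ------------------------------------------------------------

new_dose_policy <- function(H, layers) {
  list(pi = mlp_new(c(H, rep(H, layers), N_TOKENS)),
       V = mlp_new(c(H, rep(H, layers), 1L)))
}

# Precompute encoder states, tokens and rewards for every trajectory.
policy_dataset <- function(trajs, pm) {
  lapply(trajs, function(tr) {
    list(states = encode(pm, tr, all_states = TRUE),
         tokens = action_token(tr$action_class, tr$dose),
         rewards = tr$reward,
         day = tr$day, slot = tr$slot, regimen = tr$regimen)
  })
}

# Scheduled insulin class at a (slot) for a regimen; "none" if no injection.
scheduled_class <- function(regimen, slot) {
  sched <- regimen_schedule(regimen)
  cls <- sched[as.character(slot)]
  ifelse(is.na(cls), "none", cls)
}

#' Train the dosing policy
#'
#' Second stage of the two-stage schedule: on top of a trained patient
#' model (whose encoder is frozen and used to embed the logged
#' trajectories), optimizes the joint objective
#' `L = L_RL1 + eps1 * L_RL2 + eps2 * L_SL` over a policy network and a
#' shared value function. `L_RL1` is an advantage-weighted policy gradient
#' on the logged data; `L_RL2` applies the same form to trajectories
#' generated by sampling the policy against the patient model's latent
#' dynamics and reward head; `L_SL` is categorical imitation of the
#' clinician's doses. `mode = "sl_only"` drops both RL terms (pure
#' behavior cloning), which serves as the ablation comparator.
#'
#' @param cohort A `synthetic_cohort` or list of trajectories.
#' @param pm A fitted [patient_model()]; refused if untrained unless
#'   `force = TRUE`.
#' @param cfg A [policy_config()].
#' @param mode `"joint"` (default) or `"sl_only"`.
#' @param force Allow an untrained patient model.
#' @return An object of class `dose_policy` with `params`, `cfg`, `mode`
#'   and a per-epoch `history` of the separate loss terms.
#' @export
train_policy <- function(cohort, pm, cfg = policy_config(),
                         mode = c("joint", "sl_only"), force = FALSE) {
  mode <- match.arg(mode)
  trajs <- if (inherits(cohort, "synthetic_cohort")) cohort$trajectories
           else cohort
  if (!isTRUE(pm$trained) && !force)
    stop("policy training requires a trained patient model (or force = TRUE)")
  set.seed(cfg$seed)
  H <- pm$cfg$hidden_dim
  params <- new_dose_policy(H, cfg$layers)
  opt <- adam_new(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  ds <- policy_dataset(trajs, pm)
  n <- length(ds)
  hist <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    terms <- c(rl1 = 0, rl2 = 0, sl = 0); nb <- 0
    pg_on <- ep > cfg$warmup_frac * cfg$epochs
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      pass <- policy_batch_pass(params, cfg, ds[b], pm, mode, pg_on)
      st <- adam_step(opt, params, pass$grads)
      opt <- st$opt; params <- st$params
      terms <- terms + pass$terms; nb <- nb + 1
    }
    terms <- terms / nb
    hist <- rbind(hist, data.frame(epoch = ep, t(terms),
                                   total = terms["rl1"] +
                                     cfg$eps1 * terms["rl2"] +
                                     cfg$eps2 * terms["sl"]))
    if (cfg$verbose)
      cat(sprintf("epoch %3d  rl1 %.3f  rl2 %.3f  sl %.3f\n", ep,
                  terms["rl1"], terms["rl2"], terms["sl"]))
  }
  structure(list(params = params, cfg = cfg, mode = mode,
                 hidden_dim = H, history = hist, trained = TRUE,
                 floor = NULL),
            class = "dose_policy")
}

policy_batch_pass <- function(params, cfg, batch, pm, mode, pg_on = TRUE) {
  B <- length(batch)
  g_pi <- tree_zeros(params$pi)
  g_V <- tree_zeros(params$V)
  terms <- c(rl1 = 0, rl2 = 0, sl = 0)
  use_rl <- mode == "joint"
  n_sl <- sum(vapply(batch, function(d) length(d$tokens), 0L))
  for (d in batch) {
    S <- d$states
    tau <- nrow(S)
    fpi <- mlp_forward(params$pi, S)
    P <- softmax_rows(fpi$out)
    fV <- mlp_forward(params$V, S)
    V <- as.numeric(fV$out)
    onehot <- matrix(0, tau, N_TOKENS)
    onehot[cbind(seq_len(tau), d$tokens)] <- 1
    # supervised imitation (cross-entropy), averaged over all logged steps
    pa <- P[cbind(seq_len(tau), d$tokens)]
    terms["sl"] <- terms["sl"] + sum(-log(pmax(pa, 1e-12))) / n_sl
    dlog <- cfg$eps2 * (P - onehot) / n_sl
    if (use_rl) {
      R <- discounted_returns(d$rewards, cfg$gamma)
      # value regression towards logged returns (also during warmup)
      dV <- matrix(2 * (V - R) / (tau * B), tau, 1)
      bkV <- mlp_backward(params$V, fV, dV)
      g_V <- tree_add(g_V, bkV$grads)
      if (pg_on) {
        # L_RL1: advantage-weighted policy gradient on the logged data
        adv <- if (cfg$advantage) R - V else R
        terms["rl1"] <- terms["rl1"] - sum(adv * log(pmax(pa, 1e-12))) / B
        dlog <- dlog + (adv / B) * (P - onehot)
      }
    }
    bk <- mlp_backward(params$pi, fpi, dlog)
    g_pi <- tree_add(g_pi, bk$grads)
    if (use_rl && pg_on && cfg$eps1 > 0) {
      mb <- modelbased_grads(params, cfg, d, pm, B)
      g_pi <- tree_add(g_pi, mb$g_pi)
      terms["rl2"] <- terms["rl2"] + mb$loss
    }
  }
  list(grads = list(pi = g_pi, V = g_V), terms = terms)
}

# Model-based roll-outs: sample anchors along the logged trajectory, roll
# the patient model forward under actions sampled from the policy at the
# regimen's scheduled slots, and apply the advantage-weighted policy
# gradient to the generated (state, action, model-reward) tuples.
modelbased_grads <- function(params, cfg, d, pm, B) {
  tau <- nrow(d$states)
  anchors <- sample(seq_len(tau - 1L), min(cfg$n_anchors, tau - 1L))
  g_pi <- tree_zeros(params$pi)
  loss <- 0
  for (t0 in anchors) {
    s <- d$states[t0, , drop = FALSE]
    depth <- min(cfg$rollout_depth, 7L)
    recs <- vector("list", depth)
    for (i in seq_len(depth)) {
      pos <- advance_slot(d$day[t0], d$slot[t0], i - 1L)
      cls <- scheduled_class(d$regimen, pos$slot)
      fpi <- mlp_forward(params$pi, s)
      P <- softmax_rows(fpi$out)
      if (cls == "none") {
        tok <- 1L; grad_step <- FALSE
      } else {
        # sample among dose tokens, renormalized (the schedule mandates
        # an injection here, so the "none" token is excluded)
        pd <- P[1, -1]; pd <- pd / sum(pd)
        tok <- sample(2:N_TOKENS, 1, prob = pd)
        grad_step <- TRUE
      }
      st <- pm_step(pm, s, cls, token_dose(tok))
      recs[[i]] <- list(s = s, fpi = fpi, P = P, tok = tok,
                        grad = grad_step, r = st$reward)
      s <- if (is.matrix(st$state)) st$state else matrix(st$state, 1)
    }
    rew <- vapply(recs, `[[`, 0, "r")
    # bootstrap the tail with the value function (detached)
    vend <- as.numeric(mlp_forward(params$V, s)$out)
    R <- discounted_returns(c(rew, vend), cfg$gamma)[seq_len(depth)]
    for (i in seq_len(depth)) {
      rc <- recs[[i]]
      if (!rc$grad) next
      v0 <- as.numeric(mlp_forward(params$V, rc$s)$out)
      adv <- if (cfg$advantage) R[i] - v0 else R[i]
      pd <- rc$P[1, -1] / sum(rc$P[1, -1])
      loss <- loss - adv * log(max(pd[rc$tok - 1L], 1e-12)) /
        (B * length(anchors))
      # gradient of -adv * log softmax over the renormalized dose tokens
      dlog <- matrix(0, 1, N_TOKENS)
      dlog[1, -1] <- adv * pd / (B * length(anchors))
      dlog[1, rc$tok] <- dlog[1, rc$tok] - adv / (B * length(anchors))
      bk <- mlp_backward(params$pi, rc$fpi, dlog)
      g_pi <- tree_add(g_pi, bk$grads)
    }
  }
  list(g_pi = g_pi, loss = loss)
}

#' Model-based policy-gradient loss (diagnostic form)
#'
#' Generates roll-outs from the supplied start states by alternating
#' policy sampling and patient-model dynamics steps, and returns the
#' advantage-weighted policy-gradient loss
#' `-sum_t (Rhat_t - V(s_t)) log pi(ahat_t | s_t)` over the generated
#' tuples. Reproducible under `seed`.
#'
#' @param pm A fitted `patient_model`.
#' @param policy A `dose_policy`.
#' @param start_states Matrix of roll-out start states (rows).
#' @param day,slot Grid position of each start state (vectors or scalars).
#' @param regimen Regimen whose schedule assigns classes to slots.
#' @param depth Roll-out depth (>= 1).
#' @param gamma Discount factor.
#' @param seed Sampling seed.
#' @return Scalar loss.
#' @export
rl_loss_modelbased <- function(pm, policy, start_states, day, slot, regimen,
                               depth = 5, gamma = 0.9, seed = 1L) {
  set.seed(seed)
  if (is.null(dim(start_states))) start_states <- matrix(start_states, 1)
  day <- rep_len(day, nrow(start_states))
  slot <- rep_len(slot, nrow(start_states))
  loss <- 0
  for (j in seq_len(nrow(start_states))) {
    s <- start_states[j, , drop = FALSE]
    rew <- numeric(depth); logp <- numeric(depth); keep <- logical(depth)
    v0 <- numeric(depth)
    for (i in seq_len(depth)) {
      pos <- advance_slot(day[j], slot[j], i - 1L)
      cls <- scheduled_class(regimen, pos$slot)
      P <- policy_forward(policy, s)
      if (cls == "none") tok <- 1L
      else {
        pd <- P[1, -1] / sum(P[1, -1])
        tok <- sample(2:N_TOKENS, 1, prob = pd)
        logp[i] <- log(max(pd[tok - 1L], 1e-12)); keep[i] <- TRUE
      }
      v0[i] <- policy_value(policy, s)
      if (!all(is.finite(s))) stop("divergent roll-out state (non-finite)")
      st <- pm_step(pm, s, cls, token_dose(tok))
      rew[i] <- st$reward
      s <- matrix(st$state, 1)
    }
    vend <- policy_value(policy, s)
    R <- discounted_returns(c(rew, vend), gamma)[seq_len(depth)]
    loss <- loss - sum(((R - v0) * logp)[keep])
  }
  loss
}

#' @export
print.dose_policy <- function(x, ...) {
  cat("<dose_policy>", x$mode, "| hidden", x$hidden_dim,
      "| vocabulary", N_TOKENS, "tokens (none + 1..40 U)\n")
  invisible(x)
}

#' @export
summary.dose_policy <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("  final-epoch loss terms:\n")
    print(utils::tail(object$history, 1), row.names = FALSE)
  }
  invisible(object)
}

#' Evaluate a dosing policy against the synthetic simulator
#'
#' Rolls the ground-truth response simulator forward for each patient
#' while the policy (argmax over dose tokens at the regimen's scheduled
#' injection slots) chooses doses online from its encoder state. Returns
#' per-patient mean daily reward (summed Magni rewards per day) and mean
#' daily within-target-range ratio.
#'
#' @param policy A `dose_policy`.
#' @param pm The `patient_model` providing the encoder.
#' @param latents_list List of patient latents (from [generate_cohort()]).
#' @param config The [cohort_config()] used for simulation.
#' @param seed Simulation seed (glucose noise).
#' @return A data.frame with `patient_id`, `daily_reward`, `wtr_ratio`.
#' @export
evaluate_policy <- function(policy, pm, latents_list, config, seed = 1L) {
  res <- lapply(seq_along(latents_list), function(i) {
    lat <- latents_list[[i]]
    agent <- policy_agent(policy, pm, lat)
    tr <- simulate_interactive(lat, config, agent, seed = seed + i)
    days <- split(seq_along(tr$day), tr$day)
    dr <- mean(vapply(days, function(ix) {
      r <- tr$reward[ix]; sum(r[!is.na(r)])
    }, 0))
    wtr <- mean(vapply(days, function(ix) {
      g <- tr$glucose[ix]; g <- g[!is.na(g)]
      mean(wtr_label(g))
    }, 0))
    data.frame(patient_id = lat$patient_id, daily_reward = dr,
               wtr_ratio = wtr)
  })
  do.call(rbind, res)
}

# Stateful simulator agent: advances the encoder one step per slot and
# doses by argmax over the policy's dose tokens at injection slots.
policy_agent <- function(policy, pm, lat) {
  env <- new.env()
  env$h <- NULL
  env$prev_class <- "none"; env$prev_dose <- NA_integer_
  L <- length(pm$params$encoder); H <- pm$cfg$hidden_dim
  function(info) {
    slot_oh <- numeric(7); slot_oh[info$slot + 1L] <- 1
    af <- action_features(env$prev_class, env$prev_dose)
    x <- matrix(c(info$glucose / 10, 1, slot_oh, info$day / 7, af,
                  lat$covariates), 1)
    if (is.null(env$h))
      env$h <- replicate(L, matrix(0, 1, H), simplify = FALSE)
    xx <- x
    for (l in seq_len(L)) {
      fc <- gru_cell_forward(pm$params$encoder[[l]], xx, env$h[[l]])
      env$h[[l]] <- fc$h
      xx <- fc$h
    }
    dose <- NA_integer_
    if (info$class != "none") {
      P <- policy_forward(policy, env$h[[L]])
      dose <- which.max(P[1, -1])  # argmax over dose tokens; ties -> lower
    }
    env$prev_class <- info$class
    env$prev_dose <- if (info$class == "none") NA_integer_ else as.integer(dose)
    dose
  }
}
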