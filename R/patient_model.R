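# Learned patient model: a stacked GRU sequence encoder f_R over the
# seven-slot observation stream, a latent dynamics function f_T mapping
# (state, insulin action) to the next state plus a reward estimate, and a
# prediction head f_P emitting a glucose point prediction and a
# within-target-range probability. Trained jointly with a consistency loss
# on latent roll-outs and a supervised prediction loss.

ACTION_FEAT_DIM <- 5L  # is_none, class one-hot (3), dose/40

action_features <- function(class, dose) {
  if (!all(class %in% INSULIN_CLASSES)) stop("unknown insulin class token")
  n <- length(class)
  f <- matrix(0, n, ACTION_FEAT_DIM)
  f[, 1] <- class == "none"
  f[, 2] <- class == "short_rapid"
  f[, 3] <- class == "long_acting"
  f[, 4] <- class == "premixed"
  d <- ifelse(is.na(dose), 0, dose)
  if (any(class != "none" & (d < 1 | d > 40)))
    stop("dose must be in 1..40 for an injection action")
  f[, 5] <- d / 40
  f
}

# Per-step observation features. The action channel carries the *previous*
# step's action, so the state at t never encodes the action chosen at t
# (the policy conditions on s_t when choosing a_t).
traj_features <- function(traj) {
  tau <- length(traj$day)
  g <- traj$glucose
  mask <- as.numeric(!is.na(g))
  gn <- ifelse(is.na(g), 0, g) / 10
  slot_oh <- matrix(0, tau, 7)
  slot_oh[cbind(seq_len(tau), traj$slot + 1L)] <- 1
  prev_class <- c("none", traj$action_class[-tau])
  prev_dose <- c(NA_integer_, traj$dose[-tau])
  af <- action_features(prev_class, prev_dose)
  cbind(gn, mask, slot_oh, traj$day / 7, af, traj$covariates)
}

#' Patient model configuration
#'
#' Architecture and training hyperparameters of the patient model. The
#' defaults are a desk-scale profile (hidden width 32, one encoder layer,
#' 30 epochs) suitable for the bundled synthetic cohorts; `paper_scale()`
#' in the examples shows the full-scale profile (hidden 256, 3 layers,
#' 100 epochs, roll-out depth 7).
#'
#' @param hidden_dim Width of the hidden state.
#' @param encoder_layers Stacked recurrent encoder layers.
#' @param dynamics_layers,predictor_layers Hidden layers of the dynamics
#'   and prediction MLPs.
#' @param consistency_weight Weight mu of the latent consistency loss in
#'   the joint objective `mu * L_T + L_P`.
#' @param reward_weight Weight of the reward-head regression term.
#' @param rollout_depth Teacher-forced roll-out depth used when forming
#'   consistency pairs and multi-step prediction losses during training.
#' @param pad_length Maximum trajectory length consumed by the encoder.
#' @param epochs,batch_size,lr,weight_decay Optimization settings (Adam).
#' @param val_frac Fraction of trajectories held out for validation.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return A list of class `patient_model_config`.
#' @examples
#' patient_model_config()                            # desk-scale default
#' paper_scale <- function() patient_model_config(
#'   hidden_dim = 256, encoder_layers = 3, dynamics_layers = 3,
#'   predictor_layers = 3, rollout_depth = 7, epochs = 100)
#' @export
patient_model_config <- function(hidden_dim = 32, encoder_layers = 1,
                                 dynamics_layers = 2, predictor_layers = 2,
                                 consistency_weight = 0.1, reward_weight = 1,
                                 rollout_depth = 5, pad_length = 128,
                                 epochs = 50, batch_size = 32, lr = 1e-3,
                                 weight_decay = 1e-4, val_frac = 0.2,
                                 seed = 1L, verbose = FALSE) {
  stopifnot(hidden_dim > 0, encoder_layers > 0, rollout_depth >= 1,
            consistency_weight >= 0)
  structure(as.list(environment()), class = "patient_model_config")
}

new_patient_model <- function(cfg, input_dim) {
  H <- cfg$hidden_dim
  list(encoder = gru_new(input_dim, H, cfg$encoder_layers),
       dyn = mlp_new(c(H + ACTION_FEAT_DIM,
                       rep(H, cfg$dynamics_layers), H)),
       pred = mlp_new(c(H, rep(H, cfg$predictor_layers - 1L), 2L)),
       rew = mlp_new(c(H, H, 1L)))
}

#' Encode an observation history into a hidden state
#'
#' Runs the sequence encoder f_R over the trajectory's per-slot features
#' and returns the last hidden vector as the patient state (or the full
#' state sequence with `all_states = TRUE`). Deterministic for fixed
#' weights. Sequences longer than `pad_length` are truncated to their most
#' recent `pad_length` steps.
#'
#' @param model A fitted `patient_model`.
#' @param traj A `trajectory` with at least one observation.
#' @param all_states Return the full tau x hidden matrix instead of the
#'   final row.
#' @return A numeric vector of width `hidden_dim`, or a matrix.
#' @export
encode <- function(model, traj, all_states = FALSE) {
  if (length(traj$day) == 0) stop("cannot encode an empty observation sequence")
  X <- traj_features(traj)
  if (nrow(X) > model$cfg$pad_length)
    X <- X[(nrow(X) - model$cfg$pad_length + 1L):nrow(X), , drop = FALSE]
  xs <- lapply(seq_len(nrow(X)), function(t) X[t, , drop = FALSE])
  fwd <- gru_forward(model$params$encoder, xs)
  if (all_states)
    do.call(rbind, lapply(fwd$states, as.numeric))
  else as.numeric(fwd$states[[length(fwd$states)]])
}

#' One latent dynamics step
#'
#' Applies the dynamics function f_T: maps the current hidden state and an
#' insulin action to the next hidden state and the predicted reward at
#' that next state. Composable for roll-outs.
#'
#' @param model A fitted `patient_model`.
#' @param state Hidden state: numeric vector or (batch x hidden) matrix.
#' @param class Insulin class token (one of [INSULIN_CLASSES]).
#' @param dose Integer dose 1..40, or `NA` when `class == "none"`.
#' @return List with `state` (same shape as input) and `reward` (numeric).
#' @export
pm_step <- function(model, state, class, dose = NA_integer_) {
  v <- !is.matrix(state)
  S <- if (v) matrix(state, 1) else state
  af <- action_features(rep(class, nrow(S)), rep(dose, nrow(S)))
  fc <- mlp_forward(model$params$dyn, cbind(S, af))
  S2 <- S + fc$out  # residual parameterization keeps roll-outs stable
  r <- mlp_forward(model$params$rew, S2)$out
  list(state = if (v) as.numeric(S2) else S2,
       reward = if (v) as.numeric(r) else as.numeric(r))
}

#' Predict patient status from a hidden state
#'
#' The prediction head f_P: a glucose point prediction (mmol/L) and the
#' probability that glucose is within the 3.9-10.0 mmol/L target range.
#' A pure function of the state.
#'
#' @param model A fitted `patient_model`.
#' @param state Hidden state vector or (batch x hidden) matrix.
#' @return List with `glucose_mmol` and `wtr_prob` (vectors).
#' @export
pm_predict <- function(model, state) {
  S <- if (is.matrix(state)) state else matrix(state, 1)
  out <- mlp_forward(model$params$pred, S)$out
  list(glucose_mmol = as.numeric(out[, 1] * 10),
       wtr_prob = as.numeric(sigmoid(out[, 2])))
}

#' Latent consistency loss
#'
#' Sum of squared L2 distances between paired hidden states that land on
#' the same absolute timestep through different (start, roll-out depth)
#' splits. Zero when all matched states coincide; returns 0 with a message
#' when no pairs are supplied.
#'
#' @param states_a,states_b Matrices with one paired state per row (or
#'   vectors for a single pair).
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(states_a, states_b) {
  if (is.null(dim(states_a))) states_a <- matrix(states_a, 1)
  if (is.null(dim(states_b))) states_b <- matrix(states_b, 1)
  if (nrow(states_a) == 0) {
    message("consistency_loss: no matching state pairs; returning 0")
    return(0)
  }
  stopifnot(all(dim(states_a) == dim(states_b)))
  sum((states_a - states_b)^2)
}

#' Status prediction loss
#'
#' `L_P = L_P,GLU + L_P,TIR`: mean squared error of the glucose prediction
#' plus binary cross-entropy of the within-target-range probability,
#' averaged over slots with measured truth.
#'
#' @param pred List with `glucose_mmol` and `wtr_prob` (as returned by
#'   [pm_predict()]).
#' @param truth List with `glucose_mmol` (measured values) and `wtr`
#'   (logical labels).
#' @return Scalar loss; errors if every slot is masked.
#' @export
prediction_loss <- function(pred, truth) {
  m <- !is.na(truth$glucose_mmol)
  if (!any(m)) stop("prediction_loss: all truth values are masked")
  mse <- mean((pred$glucose_mmol[m] - truth$glucose_mmol[m])^2)
  p <- pmin(pmax(pred$wtr_prob[m], 1e-12), 1 - 1e-12)
  y <- as.numeric(truth$wtr[m])
  ce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  mse + ce
}

# ---- joint training ------------------------------------------------------

# Assemble equal-length batch tensors from a list of trajectories.
batch_tensors <- function(trajs) {
  tau <- length(trajs[[1]]$day)
  B <- length(trajs)
  feats <- lapply(trajs, traj_features)
  xs <- lapply(seq_len(tau), function(t)
    do.call(rbind, lapply(feats, function(f) f[t, , drop = FALSE])))
  G <- do.call(rbind, lapply(trajs, `[[`, "glucose"))
  R <- do.call(rbind, lapply(trajs, `[[`, "reward"))
  AC <- do.call(rbind, lapply(trajs, `[[`, "action_class"))
  AD <- do.call(rbind, lapply(trajs, `[[`, "dose"))
  list(xs = xs, G = G, R = R, AC = AC, AD = AD, tau = tau, B = B)
}

# Forward + backward over one batch; returns losses, parameter gradients.
pm_batch_pass <- function(params, cfg, bt, compute_grads = TRUE) {
  tau <- bt$tau; B <- bt$B; H <- cfg$hidden_dim
  fwd <- gru_forward(params$encoder, bt$xs)
  h <- fwd$states
  dstates <- vector("list", tau)
  if (compute_grads) {
    g_enc_extra <- lapply(seq_len(tau), function(t) matrix(0, B, H))
    g_dyn <- tree_zeros(params$dyn)
    g_pred <- tree_zeros(params$pred)
    g_rew <- tree_zeros(params$rew)
  }
  # loss accumulators and counts
  L <- c(glu = 0, tir = 0, rew = 0, cons = 0)
  wtr_truth <- !is.na(bt$G) & bt$G >= 3.9 & bt$G <= 10.0
  n_pred <- sum(!is.na(bt$G[, -1, drop = FALSE])) * 1  # rough scale
  # counts are accumulated exactly below
  cnt <- c(glu = 0, cons = 0)
  # first pass to count masked targets over all (anchor, depth) cells
  depth <- cfg$rollout_depth
  for (t in seq_len(tau - 1L)) {
    ks <- seq_len(min(depth, tau - t))
    for (k in ks) {
      cnt["glu"] <- cnt["glu"] + sum(!is.na(bt$G[, t + k]))
      cnt["cons"] <- cnt["cons"] + B
    }
  }
  if (cnt["glu"] == 0) stop("patient model training: no measured targets in batch")
  inv_glu <- 1 / cnt[["glu"]]; inv_cons <- 1 / cnt[["cons"]]
  mu <- cfg$consistency_weight; rw <- cfg$reward_weight
  for (t in seq_len(tau - 1L)) {
    ks <- seq_len(min(depth, tau - t))
    S <- h[[t]]
    chain <- vector("list", length(ks))  # caches per depth
    dchain <- vector("list", length(ks))
    for (k in ks) {
      a_idx <- t + k - 1L
      af <- action_features(bt$AC[, a_idx], bt$AD[, a_idx])
      Xd <- cbind(S, af)
      fc <- mlp_forward(params$dyn, Xd)
      S2 <- S + fc$out
      pc <- mlp_forward(params$pred, S2)
      rc <- mlp_forward(params$rew, S2)
      gt <- bt$G[, t + k]; m <- !is.na(gt)
      ghat <- pc$out[, 1]; wlog <- pc$out[, 2]
      pwtr <- sigmoid(wlog)
      rt <- bt$R[, t + k]
      # losses (normalized glucose scale g/10 for the MSE)
      if (any(m)) {
        L["glu"] <- L["glu"] + sum((ghat[m] - gt[m] / 10)^2) * inv_glu
        pclip <- pmin(pmax(pwtr[m], 1e-12), 1 - 1e-12)
        yy <- as.numeric(wtr_truth[m, t + k])
        L["tir"] <- L["tir"] - sum(yy * log(pclip) +
                                     (1 - yy) * log(1 - pclip)) * inv_glu
        L["rew"] <- L["rew"] + sum((rc$out[m, 1] - rt[m])^2) * inv_glu
      }
      Dcons <- S2 - h[[t + k]]
      L["cons"] <- L["cons"] + sum(Dcons^2) / H * inv_cons
      if (compute_grads) {
        dS2 <- matrix(0, B, H)
        # prediction head
        dP <- matrix(0, B, 2)
        dP[m, 1] <- 2 * (ghat[m] - gt[m] / 10) * inv_glu
        dP[m, 2] <- (pwtr[m] - as.numeric(wtr_truth[m, t + k])) * inv_glu
        bk <- mlp_backward(params$pred, pc, dP)
        g_pred <- tree_add(g_pred, bk$grads)
        dS2 <- dS2 + bk$dX
        # reward head
        dRh <- matrix(0, B, 1)
        dRh[m, 1] <- rw * 2 * (rc$out[m, 1] - rt[m]) * inv_glu
        bkr <- mlp_backward(params$rew, rc, dRh)
        g_rew <- tree_add(g_rew, bkr$grads)
        dS2 <- dS2 + bkr$dX
        # consistency: into S2 and (negatively) into the encoder target
        dS2 <- dS2 + mu * 2 * Dcons / H * inv_cons
        g_enc_extra[[t + k]] <- g_enc_extra[[t + k]] -
          mu * 2 * Dcons / H * inv_cons
        chain[[k]] <- list(fc = fc)
        dchain[[k]] <- dS2
      }
      S <- S2
    }
    if (compute_grads) {
      # backprop the teacher-forced chain into the anchor state
      dS <- matrix(0, B, H)
      for (k in rev(ks)) {
        dS <- dS + dchain[[k]]
        bk <- mlp_backward(params$dyn, chain[[k]]$fc, dS)
        g_dyn <- tree_add(g_dyn, bk$grads)
        dS <- dS + bk$dX[, seq_len(H), drop = FALSE]  # residual skip
      }
      g_enc_extra[[t]] <- g_enc_extra[[t]] + dS
    }
  }
  total <- mu * L[["cons"]] + L[["glu"]] + L[["tir"]] + rw * L[["rew"]]
  if (!is.finite(total))
    stop("patient model training diverged (non-finite loss)")
  out <- list(losses = c(total = total, cons = L[["cons"]], glu = L[["glu"]],
                         tir = L[["tir"]], rew = L[["rew"]]))
  if (compute_grads) {
    g_encoder <- gru_backward(params$encoder, fwd, g_enc_extra)
    out$grads <- list(encoder = g_encoder, dyn = g_dyn, pred = g_pred,
                      rew = g_rew)
  }
  out
}

#' Fit the patient model
#'
#' Jointly trains the sequence encoder f_R, latent dynamics f_T (with its
#' reward head) and prediction head f_P on logged trajectories by
#' minimizing `mu * L_T + L_P` (plus the reward regression term), where
#' L_T is the latent consistency loss over teacher-forced roll-out pairs
#' and L_P is the glucose MSE plus within-target-range cross-entropy,
#' averaged over measured slots only. Optimization is Adam with weight
#' decay; trajectories are shuffled into equal-length mini-batches each
#' epoch.
#'
#' @param cohort A `synthetic_cohort` or list of `trajectory` objects.
#' @param cfg A [patient_model_config()].
#' @return An object of class `patient_model` with elements `params`,
#'   `cfg`, `history` (per-epoch loss terms and validation one-step-ahead
#'   glucose MAE) and `input_dim`.
#' @export
patient_model <- function(cohort, cfg = patient_model_config()) {
  trajs <- if (inherits(cohort, "synthetic_cohort")) cohort$trajectories
           else cohort
  if (length(trajs) == 0) stop("empty cohort")
  set.seed(cfg$seed)
  input_dim <- ncol(traj_features(trajs[[1]]))
  params <- new_patient_model(cfg, input_dim)
  opt <- adam_new(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  n <- length(trajs)
  n_val <- max(0L, floor(cfg$val_frac * n))
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  hist <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- c(total = 0, cons = 0, glu = 0, tir = 0, rew = 0); nb <- 0
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      bt <- batch_tensors(trajs[b])
      pass <- pm_batch_pass(params, cfg, bt, compute_grads = TRUE)
      st <- adam_step(opt, params, pass$grads)
      opt <- st$opt; params <- st$params
      ep_loss <- ep_loss + pass$losses; nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    val_mae <- NA_real_
    if (n_val > 0) {
      bt <- batch_tensors(trajs[val_idx])
      model_tmp <- structure(list(params = params, cfg = cfg), class = "patient_model")
      val_mae <- one_step_mae(model_tmp, bt)
    }
    hist <- rbind(hist, data.frame(epoch = ep, t(ep_loss), val_mae = val_mae))
    if (cfg$verbose)
      cat(sprintf("epoch %3d  loss %.4f  (cons %.4f glu %.4f tir %.4f rew %.4f)  val MAE %.3f\n",
                  ep, ep_loss["total"], ep_loss["cons"], ep_loss["glu"],
                  ep_loss["tir"], ep_loss["rew"], val_mae))
  }
  structure(list(params = params, cfg = cfg, input_dim = input_dim,
                 history = hist, val_idx = val_idx, trained = TRUE),
            class = "patient_model")
}

one_step_mae <- function(model, bt) {
  fwd <- gru_forward(model$params$encoder, bt$xs)
  errs <- c()
  for (t in seq_len(bt$tau - 1L)) {
    st <- pm_step_batch(model, fwd$states[[t]], bt$AC[, t], bt$AD[, t])
    pr <- pm_predict(model, st$state)
    m <- !is.na(bt$G[, t + 1L])
    errs <- c(errs, abs(pr$glucose_mmol[m] - bt$G[m, t + 1L]))
  }
  mean(errs)
}

# batched dynamics step with per-row action tokens
pm_step_batch <- function(model, S, classes, doses) {
  af <- action_features(classes, doses)
  fc <- mlp_forward(model$params$dyn, cbind(S, af))
  S2 <- S + fc$out
  r <- mlp_forward(model$params$rew, S2)$out
  list(state = S2, reward = as.numeric(r))
}

#' Roll the patient model forward K steps
#'
#' Encodes the observation prefix, then alternates the dynamics function
#' over the supplied K actions, emitting a status prediction and reward
#' estimate at each simulated step (e.g. K = 7 for one day ahead).
#'
#' @param model A fitted `patient_model`.
#' @param traj_prefix A `trajectory` holding the observed history.
#' @param actions List of K actions, each `list(class =, dose =)`.
#' @param K Roll-out depth; must equal `length(actions)`.
#' @return A data.frame with columns `step`, `glucose_mmol`, `wtr_prob`,
#'   `reward`.
#' @export
pm_rollout <- function(model, traj_prefix, actions, K = length(actions)) {
  if (K < 1 || length(actions) != K)
    stop("rollout requires exactly K actions (K >= 1)")
  s <- encode(model, traj_prefix)
  out <- vector("list", K)
  for (i in seq_len(K)) {
    st <- pm_step(model, s, actions[[i]]$class, actions[[i]]$dose)
    s <- st$state
    pr <- pm_predict(model, s)
    out[[i]] <- data.frame(step = i, glucose_mmol = pr$glucose_mmol,
                           wtr_prob = pr$wtr_prob, reward = st$reward)
  }
  do.call(rbind, out)
}

#' @export
print.patient_model <- function(x, ...) {
  cat("<patient_model> hidden", x$cfg$hidden_dim, "| encoder layers",
      x$cfg$encoder_layers, "| trained", x$cfg$epochs, "epochs\n")
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss %.4f; validation 1-step glucose MAE %.3f mmol/L\n",
                last$total, last$val_mae))
  }
  invisible(x)
}

#' @export
summary.patient_model <- function(object, ...) {
  cat("Patient model (sequence encoder + latent dynamics + status head)\n")
  print(object)
  cat("  loss trajectory (first/last 3 epochs):\n")
  h <- object$history
  print(utils::head(h, 3), row.names = FALSE)
  print(utils::tail(h, 3), row.names = FALSE)
  invisible(object)
}

#' Predict the next day's glucose profile from a fitted patient model
#'
#' For each requested trajectory day after the first, encodes the history
#' up to the end of the previous day and unrolls the dynamics over that
#' day's seven logged actions, returning predicted vs observed glucose.
#'
#' @param object A fitted `patient_model`.
#' @param traj A `trajectory`.
#' @param day Day to predict (default: the last day).
#' @param ... Unused.
#' @return A data.frame with `day`, `slot`, `pred_glucose`, `obs_glucose`,
#'   `wtr_prob`.
#' @export
predict.patient_model <- function(object, traj, day = max(traj$day), ...) {
  if (day <= min(traj$day)) stop("cannot predict the first observed day")
  pre <- which(traj$day < day)
  idx <- which(traj$day == day)
  prefix <- traj_slice(traj, pre)
  actions <- lapply(idx, function(i)
    list(class = traj$action_class[i], dose = traj$dose[i]))
  ro <- pm_rollout(object, prefix, actions)
  data.frame(day = day, slot = traj$slot[idx], pred_glucose = ro$glucose_mmol,
             obs_glucose = traj$glucose[idx], wtr_prob = ro$wtr_prob)
}

# subset a trajectory's steps, keeping attributes
traj_slice <- function(traj, idx) {
  trajectory(traj$patient_id, traj$day[idx], traj$slot[idx],
             traj$glucose[idx], traj$action_class[idx], traj$dose[idx],
             reward = traj$reward[idx],
             covariates = traj$covariates[idx, , drop = FALSE],
             regimen = traj$regimen)
}

#' @export
plot.patient_model <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Patient model training", ...)
  invisible(x)
}
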