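# Off-policy evaluation: per-step importance-sampling ratios, ordinary
# and weighted (self-normalized) importance-sampling value estimates, the
# effective sample size, and a supervised behavior-policy estimator.

#' Per-step importance-sampling ratios
#'
#' `rho_t = pi1(a_t | s_t) / pi0(a_t | s_t)` for the logged actions of one
#' trajectory, plus the trajectory weight `w = prod_t rho_t`.
#'
#' @param p1,p0 Numeric vectors of the target- and behavior-policy
#'   probabilities of each logged action.
#' @return List with `rho` (per-step ratios) and `w` (their product).
#' @export
is_ratios <- function(p1, p0) {
  stopifnot(length(p1) == length(p0))
  bad <- which(p0 <= 0)
  if (length(bad))
    stop("behavior policy has zero probability for the logged action at step ",
         bad[1], " (support violation)")
  rho <- p1 / p0
  list(rho = rho, w = prod(rho))
}

traj_return <- function(rewards, gamma) {
  # sum_t gamma^(t-1) r_t, t starting at 1; unmeasured slots contribute 0
  r <- ifelse(is.na(rewards), 0, rewards)
  sum(gamma^(seq_along(r) - 1L) * r)
}

#' Ordinary importance-sampling value estimate
#'
#' `V_IS = sum_i (w_i / N) G_i` with trajectory weights `w_i = prod rho_t`
#' and discounted returns `G_i = sum_t gamma^(t-1) r_{i,t}`.
#'
#' @param weights Per-trajectory importance weights.
#' @param returns Per-trajectory discounted returns.
#' @return Scalar value estimate.
#' @export
v_is <- function(weights, returns) {
  stopifnot(length(weights) == length(returns), length(weights) >= 1)
  mean(weights * returns)
}

#' Weighted (self-normalized) importance-sampling estimate
#'
#' Normalizes the trajectory weights to sum to 1
#' (`w_i = rho_i / sum_j rho_j`), reducing variance, and reports the
#' effective sample size `ESS = (sum rho)^2 / sum rho^2`.
#'
#' @param weights Per-trajectory importance weights (cumulative products).
#' @param returns Per-trajectory discounted returns.
#' @return List of class `ope_result`: `v_wis`, `v_is`, `weights`
#'   (normalized), `ess`, `n`.
#' @export
v_wis <- function(weights, returns) {
  stopifnot(length(weights) == length(returns), length(weights) >= 1)
  s <- sum(weights)
  if (s <= 0) stop("all importance weights are zero (degenerate estimate)")
  wn <- weights / s
  structure(list(v_wis = sum(wn * returns), v_is = v_is(weights, returns),
                 weights = wn, ess = s^2 / sum(weights^2),
                 n = length(weights)),
            class = "ope_result")
}

#' @export
print.ope_result <- function(x, ...) {
  cat(sprintf("<ope_result> N = %d  V_WIS = %.4f  V_IS = %.4f  ESS = %.1f\n",
              x$n, x$v_wis, x$v_is, x$ess))
  invisible(x)
}

#' Off-policy evaluation of a dosing policy on logged trajectories
#'
#' Embeds each logged trajectory with the patient model's encoder, scores
#' every logged action under the behavior and target policies, forms the
#' per-trajectory importance weights and returns IS/WIS value estimates
#' with the effective sample size. Only injection steps contribute ratios
#' (both policies are forced to the no-dose action elsewhere by the
#' regimen schedule).
#'
#' @param cohort A `synthetic_cohort` or list of trajectories.
#' @param behavior,target `dose_policy` objects (pi0 and pi1).
#' @param pm A fitted `patient_model` (shared encoder).
#' @param gamma Discount factor for the returns.
#' @return An `ope_result`.
#' @export
ope_evaluate <- function(cohort, behavior, target, pm, gamma = 0.9) {
  trajs <- if (inherits(cohort, "synthetic_cohort")) cohort$trajectories
           else cohort
  ws <- numeric(length(trajs)); gs <- numeric(length(trajs))
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    S <- encode(pm, tr, all_states = TRUE)
    tok <- action_token(tr$action_class, tr$dose)
    inj <- which(tr$action_class != "none")
    P1 <- policy_forward(target, S[inj, , drop = FALSE])
    P0 <- policy_forward(behavior, S[inj, , drop = FALSE])
    r <- is_ratios(P1[cbind(seq_along(inj), tok[inj])],
                   P0[cbind(seq_along(inj), tok[inj])])
    ws[i] <- r$w
    gs[i] <- traj_return(tr$reward, gamma)
  }
  v_wis(ws, gs)
}

#' Estimate the clinicians' behavior policy from logged data
#'
#' Supervised-only training of a policy network on the logged actions
#' (behavior cloning over the trained encoder's states), with the output
#' probabilities floored at `floor` to guarantee support for importance
#' sampling.
#'
#' @param cohort A `synthetic_cohort` or list of trajectories.
#' @param pm A fitted `patient_model`.
#' @param cfg A [policy_config()] (used with SL-only training).
#' @param floor Minimum action probability (default 1e-3).
#' @return A `dose_policy` with the probability floor attached.
#' @export
fit_behavior_policy <- function(cohort, pm, cfg = policy_config(),
                                floor = 1e-3) {
  stopifnot(floor >= 0, floor < 1 / N_TOKENS)
  pol <- train_policy(cohort, pm, cfg, mode = "sl_only")
  pol$floor <- floor
  pol
}
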