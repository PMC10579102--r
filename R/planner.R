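# Decision-time K-step planning over the learned patient model via beam
# search: partial action sequences are scored by accumulated discounted
# model reward plus a terminal value bootstrap, keeping the top-B
# sequences at each step.

#' Planner configuration
#'
#' @param K Plan horizon in timeslots (default 7, one day ahead).
#' @param B Beam size (default 10).
#' @param gamma Discount factor.
#' @param candidates Candidate actions proposed per expansion: `"topM"`
#'   keeps the M most probable policy tokens, `"all"` expands every dose
#'   token (used by the exhaustive-oracle checks).
#' @param M Number of candidates under `"topM"`.
#' @return A list of class `plan_config`.
#' @export
plan_config <- function(K = 7, B = 10, gamma = 0.9,
                        candidates = c("topM", "all"), M = 5) {
  candidates <- match.arg(candidates)
  if (K < 1 || B < 1) stop("plan horizon K and beam size B must be >= 1")
  structure(list(K = K, B = B, gamma = gamma, candidates = candidates,
                 M = M), class = "plan_config")
}

# Candidate tokens at a scheduled class: the forced "none" token at
# non-injection slots, otherwise dose tokens proposed by the policy.
candidate_tokens <- function(P, cls, cfg) {
  if (cls == "none") return(1L)
  pd <- P[1, -1]
  if (cfg$candidates == "all") return(2:N_TOKENS)
  ord <- order(pd, decreasing = TRUE)[seq_len(min(cfg$M, length(pd)))]
  sort(ord + 1L)
}

#' K-step beam-search plan over the learned patient model
#'
#' Expands each beam entry with candidate dose tokens proposed by the
#' policy, advances the patient model's latent dynamics, scores partial
#' plans by `sum_i gamma^i rhat_{t+i}` plus the value bootstrap
#' `gamma^k V(s_{t+k})` at the current depth, and keeps the top B plans
#' per step. Returns the highest-value complete plan; ties prefer the
#' lexicographically smaller dose sequence (a safety bias toward lower
#' insulin).
#'
#' @param pm A fitted `patient_model`.
#' @param policy A `dose_policy` (proposes candidates and supplies V).
#' @param state Start hidden state (vector).
#' @param day,slot Grid position of the start state; planned actions apply
#'   from the next slot onward.
#' @param regimen Regimen whose schedule fixes the insulin class per slot;
#'   slots with no scheduled injection are forced to the no-dose action.
#' @param cfg A [plan_config()].
#' @return A list of class `plan` with `actions` (data.frame of step,
#'   day, slot, class, dose), `value`, `rewards` and `states`.
#' @export
plan <- function(pm, policy, state, day, slot, regimen,
                 cfg = plan_config()) {
  beams <- list(list(s = matrix(state, 1), rew = numeric(0),
                     toks = integer(0), score = 0))
  for (i in seq_len(cfg$K)) {
    pos <- advance_slot(day, slot, i)
    cls <- scheduled_class(regimen, pos$slot)
    expanded <- list()
    for (bm in beams) {
      P <- policy_forward(policy, bm$s)
      for (tok in candidate_tokens(P, cls, cfg)) {
        st <- pm_step(pm, bm$s, cls, token_dose(tok))
        s2 <- matrix(st$state, 1)
        rew <- c(bm$rew, st$reward)
        expanded[[length(expanded) + 1L]] <- list(
          s = s2, rew = rew, toks = c(bm$toks, tok),
          score = sum(cfg$gamma^(seq_along(rew) - 1L) * rew) +
            cfg$gamma^i * policy_value(policy, s2))
      }
    }
    scores <- vapply(expanded, `[[`, 0, "score")
    # stable tie-break: order by score desc, then lexicographically
    # smaller dose sequence first
    keys <- vapply(expanded, function(e)
      paste(sprintf("%02d", e$toks), collapse = ""), "")
    ord <- order(-scores, keys)
    beams <- expanded[ord[seq_len(min(cfg$B, length(expanded)))]]
  }
  best <- beams[[1]]
  steps <- seq_len(cfg$K)
  pos <- lapply(steps, function(i) advance_slot(day, slot, i))
  actions <- data.frame(
    step = steps,
    day = vapply(pos, `[[`, 0, "day"),
    slot = vapply(pos, `[[`, 0, "slot"),
    class = vapply(steps, function(i)
      scheduled_class(regimen, pos[[i]]$slot), ""),
    dose = token_dose(best$toks))
  structure(list(actions = actions, value = best$score,
                 rewards = best$rew, terminal_state = as.numeric(best$s)),
            class = "plan")
}

#' @export
print.plan <- function(x, ...) {
  cat(sprintf("<plan> %d steps, value %.4f\n", nrow(x$actions), x$value))
  print(x$actions, row.names = FALSE)
  invisible(x)
}

#' Recommend the next day's insulin doses
#'
#' Encodes a trajectory prefix that ends at the pre-bedtime slot, runs a
#' K = 7 beam-search plan over the learned patient model and maps the
#' planned tokens to per-slot (class, dose) recommendations for the next
#' day.
#'
#' @param traj_prefix A `trajectory` ending at slot 6 (pre-bedtime).
#' @param pm A fitted `patient_model`.
#' @param policy A `dose_policy`.
#' @param cfg A [plan_config()]; `K` must be 7.
#' @return A data.frame of 7 rows: `day`, `slot`, `slot_label`, `class`,
#'   `dose`, plus the plan value as attribute `"plan_value"`.
#' @export
recommend_day <- function(traj_prefix, pm, policy, cfg = plan_config()) {
  tau <- length(traj_prefix$day)
  if (traj_prefix$slot[tau] != 6L)
    stop("trajectory prefix must end at the pre-bedtime slot (slot 6)")
  if (cfg$K != 7) stop("recommend_day plans exactly one day (K = 7)")
  s <- encode(pm, traj_prefix)
  pl <- plan(pm, policy, s, traj_prefix$day[tau], 6L,
             traj_prefix$regimen, cfg)
  out <- pl$actions
  out$slot_label <- SLOT_LABELS[out$slot + 1L]
  out <- out[, c("day", "slot", "slot_label", "class", "dose")]
  attr(out, "plan_value") <- pl$value
  out
}
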