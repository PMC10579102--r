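# Magni-risk-based reward, target-range labeling and daily aggregation.

#' Reward parameters
#'
#' Parameters of the clipped, rescaled Magni blood-glucose risk reward and
#' of the glycemic target range. The risk term is
#' `10 * (c0 * ((ln b)^c1 - c2))^2` for glucose `b` in mg/dl, clipped to
#' `[clip_lo, clip_hi]` and divided by `scale`, so that the reward
#' `1 - clipped_risk/scale` lies in `[-1, 1]`; glucose below `hypo_cut`
#' mg/dl scores -1 outright.
#'
#' @param c0,c1,c2 Dimensionless risk coefficients.
#' @param clip_lo,clip_hi Clipping bounds of the risk term.
#' @param scale Risk-to-reward rescaling divisor.
#' @param hypo_cut Hypoglycemia cutoff in mg/dl.
#' @param wtr_lo,wtr_hi Within-target-range bounds in mmol/L (inclusive).
#' @return A list of class `reward_params`.
#' @export
reward_params <- function(c0 = 1.509, c1 = 1.084, c2 = 5.381,
                          clip_lo = 0, clip_hi = 15.5, scale = 7.75,
                          hypo_cut = 70, wtr_lo = 3.9, wtr_hi = 10.0) {
  stopifnot(clip_lo < clip_hi, wtr_lo < wtr_hi)
  structure(list(c0 = c0, c1 = c1, c2 = c2, clip_lo = clip_lo,
                 clip_hi = clip_hi, scale = scale, hypo_cut = hypo_cut,
                 wtr_lo = wtr_lo, wtr_hi = wtr_hi),
            class = "reward_params")
}

#' Clip values to an interval
#'
#' `clip(x, lo, hi) = min(hi, max(lo, x))`, elementwise.
#'
#' @param x Numeric vector.
#' @param lo,hi Interval bounds, `lo <= hi`.
#' @return Clipped vector.
#' @export
clip <- function(x, lo, hi) {
  if (lo > hi) stop("clip: lo must not exceed hi")
  pmin(hi, pmax(lo, x))
}

#' Magni-risk-based per-measurement reward
#'
#' Maps a blood glucose value (mg/dl) to a patient status score in
#' `[-1, 1]`: -1 for hypoglycemia (`b < hypo_cut`), otherwise
#' `1 - clip(10 * (c0 * ((ln b)^c1 - c2))^2, clip_lo, clip_hi) / scale`.
#' With the default parameters the reward peaks near 112.5 mg/dl
#' (zero risk) and saturates at -1 for severe hyperglycemia.
#'
#' The quadratic groups `c2` inside the bracket multiplied by `c0`,
#' following the original risk-index symmetrization, which places the
#' zero-risk glucose in the euglycemic range. `grouping = "literal"`
#' instead computes `(c0 * (ln b)^c1 - c2)^2` (an alternative reading of
#' the typeset formula) for sensitivity analysis.
#'
#' @param b Glucose in mg/dl, `> 0` (vectorized; `NA` passes through).
#' @param params A [reward_params()] object.
#' @param grouping `"literature"` (default) or `"literal"`.
#' @return Rewards in `[-1, 1]`.
#' @examples
#' magni_reward(60)    # hypoglycemic branch: -1
#' magni_reward(112.5) # near the optimum: ~1
#' magni_reward(600)   # saturated hyperglycemia: -1
#' @export
magni_reward <- function(b, params = reward_params(),
                         grouping = c("literature", "literal")) {
  grouping <- match.arg(grouping)
  if (any(b <= 0, na.rm = TRUE)) stop("glucose must be > 0")
  dev <- if (grouping == "literature")
    params$c0 * (log(b)^params$c1 - params$c2)
  else
    params$c0 * log(b)^params$c1 - params$c2
  risk <- clip(10 * dev^2, params$clip_lo, params$clip_hi)
  r <- 1 - risk / params$scale
  r[!is.na(b) & b < params$hypo_cut] <- -1
  r
}

#' Within-target-range label
#'
#' TRUE iff glucose (mmol/L) lies in the inclusive target band
#' `[wtr_lo, wtr_hi]` (3.9-10.0 mmol/L by default).
#'
#' @param g Glucose in mmol/L, `> 0` (vectorized; `NA` passes through).
#' @param params A [reward_params()] object.
#' @return Logical vector.
#' @export
wtr_label <- function(g, params = reward_params()) {
  if (any(g <= 0, na.rm = TRUE)) stop("glucose must be > 0")
  g >= params$wtr_lo & g <= params$wtr_hi
}

#' Daily reward
#'
#' Sum of per-measurement rewards within a day. Slots with missing glucose
#' have no reward and must be excluded by the caller (pass only defined
#' rewards).
#'
#' @param rewards_of_day Non-empty numeric vector of per-slot rewards.
#' @return Their arithmetic sum.
#' @export
daily_reward <- function(rewards_of_day) {
  if (length(rewards_of_day) == 0) stop("daily_reward: empty reward list")
  sum(rewards_of_day)
}

#' Compute rewards for a trajectory's measured glucose
#'
#' Applies [magni_reward()] to each measured glucose value (converted
#' mmol/L to mg/dl); unmeasured slots stay `NA`.
#'
#' @param traj A `trajectory`.
#' @param params A [reward_params()] object.
#' @return The trajectory with its `reward` field populated.
#' @export
traj_rewards <- function(traj, params = reward_params()) {
  r <- rep(NA_real_, length(traj$glucose))
  m <- !is.na(traj$glucose)
  r[m] <- magni_reward(mgdl_from_mmol(traj$glucose[m]), params)
  traj$reward <- r
  traj
}
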