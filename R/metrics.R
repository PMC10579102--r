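# Evaluation statistics: dose/glucose MAE, dose-adjustment agreement,
# glycemic band fractions, coefficient of variation, Noisy-OR daily WTR
# aggregation and the dose-excess-vs-outcome association.

#' Mean absolute error
#'
#' @param pred,truth Aligned numeric vectors (doses or glucose).
#' @return `mean(|pred - truth|)`.
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0)
    stop("mae: inputs must be non-empty and of equal length")
  mean(abs(pred - truth))
}

#' Agreement category of a dose adjustment
#'
#' Compares a predicted dose adjustment with a reference adjustment:
#' `"identical"` if direction and magnitude agree (two zero adjustments
#' are identical); `"clinical"` if the direction agrees and the dose
#' difference is within 20% of the reference; `"none"` otherwise. A zero
#' reference with a nonzero prediction is `"none"`. An identical match
#' also satisfies the clinical criterion.
#'
#' @param pred_delta,ref_delta Signed dose adjustments in units
#'   (vectorized).
#' @return Character vector over `{"identical", "clinical", "none"}`.
#' @export
agreement <- function(pred_delta, ref_delta) {
  mapply(function(p, r) {
    if (p == r) return("identical")
    if (r == 0) return("none")
    if (sign(p) != sign(r)) return("none")
    if (abs(p - r) <= 0.2 * abs(r)) "clinical" else "none"
  }, pred_delta, ref_delta, USE.NAMES = FALSE)
}

#' Glycemic band fractions
#'
#' Fractions of glucose values (mmol/L) in the standard reporting bands
#' `< 3.0`, `3.0-3.8`, `3.9-10.0` (the within-target-range band),
#' `10.1-13.9` and `> 13.9`. Fractions sum to 1.
#'
#' @param glucose Non-empty numeric vector in mmol/L.
#' @return Named numeric vector of five fractions.
#' @export
band_fractions <- function(glucose) {
  g <- glucose[!is.na(glucose)]
  if (length(g) == 0) stop("band_fractions: no measured glucose values")
  f <- c("<3.0" = mean(g < 3.0),
         "3.0-3.8" = mean(g >= 3.0 & g < 3.9),
         "3.9-10.0" = mean(g >= 3.9 & g <= 10.0),
         "10.1-13.9" = mean(g > 10.0 & g <= 13.9),
         ">13.9" = mean(g > 13.9))
  f
}

#' Glycemic variability as coefficient of variation
#'
#' `100 * sd / mean` of the glucose values (sample sd, n - 1 denominator).
#'
#' @param glucose Numeric vector in mmol/L, at least 2 values, mean > 0.
#' @return CV in percent.
#' @export
glycemic_cv <- function(glucose) {
  g <- glucose[!is.na(glucose)]
  if (length(g) < 2) stop("glycemic_cv: need at least 2 measured values")
  m <- mean(g)
  if (m <= 0) stop("glycemic_cv: mean glucose must be > 0")
  100 * stats::sd(g) / m
}

#' Noisy-OR aggregation of per-slot WTR probabilities
#'
#' Aggregates the per-timepoint within-target-range probabilities of a
#' day into a daily probability: `1 - prod(1 - p_i)`. `mode = "all"`
#' instead returns `prod(p_i)` (the probability that every point is in
#' range).
#'
#' @param point_probs Probabilities in `[0, 1]`.
#' @param mode `"noisy_or"` (default) or `"all"`.
#' @return Scalar probability.
#' @export
noisy_or_daily_wtr <- function(point_probs, mode = c("noisy_or", "all")) {
  mode <- match.arg(mode)
  if (any(point_probs < 0 | point_probs > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  p <- point_probs[!is.na(point_probs)]
  if (mode == "noisy_or") 1 - prod(1 - p) else prod(p)
}

#' Daily within-target-range ratio
#'
#' Fraction of a day's measured glucose values inside the 3.9-10.0 mmol/L
#' band; masked points are excluded from the denominator.
#'
#' @param glucose Numeric vector in mmol/L (`NA` allowed).
#' @param params A [reward_params()] object.
#' @return Fraction in `[0, 1]` (`NaN` if nothing measured).
#' @export
daily_wtr_ratio <- function(glucose, params = reward_params()) {
  g <- glucose[!is.na(glucose)]
  mean(wtr_label(g, params))
}

#' Dose excess versus daily outcome association
#'
#' Bins the daily dose excess (given minus model-suggested dose, summed
#' per day) into integer-unit bins and reports the mean daily WTR ratio
#' per bin with percentile bootstrap confidence intervals.
#'
#' @param excess Numeric vector of daily dose excesses (units).
#' @param wtr_ratio Aligned daily WTR ratios.
#' @param bin_width Bin width in units (default 2).
#' @param n_boot Bootstrap resamples per bin (default 200).
#' @param conf Confidence level (default 0.95).
#' @return A data.frame with `bin_center`, `n`, `mean_wtr`, `lo`, `hi`.
#' @export
dose_excess_outcome <- function(excess, wtr_ratio, bin_width = 2,
                                n_boot = 200, conf = 0.95) {
  if (length(excess) == 0 || length(excess) != length(wtr_ratio))
    stop("excess and wtr_ratio must be non-empty and aligned")
  ctr <- bin_width * round(excess / bin_width)
  alpha <- (1 - conf) / 2
  res <- lapply(sort(unique(ctr)), function(b) {
    y <- wtr_ratio[ctr == b]
    ci <- if (length(y) > 1) {
      bs <- replicate(n_boot, mean(sample(y, replace = TRUE)))
      stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE)
    } else c(NA_real_, NA_real_)
    data.frame(bin_center = b, n = length(y), mean_wtr = mean(y),
               lo = ci[1], hi = ci[2])
  })
  do.call(rbind, res)
}
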