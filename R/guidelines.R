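# Traditional guideline/consensus insulin titration rules for the three
# regimen families, exactly as the printed piecewise tables. All tables
# operate on glucose in mg/dl; mmol/L inputs must be converted first
# (see mgdl_from_mmol()).

#' Premixed-regimen dose adjustment
#'
#' Five-branch titration table over the corresponding blood glucose
#' (mg/dl): the pre-breakfast premixed dose is adjusted on the pre-supper
#' glucose and the pre-supper dose on the pre-breakfast glucose.
#' Adjustment in units: -2 (< 80), 0 (80-109), +2 (110-139), +4 (140-179),
#' +6 (>= 180).
#'
#' @param x Glucose in mg/dl (vectorized, > 0).
#' @return Signed adjustment in insulin units.
#' @examples
#' premixed_adjust(c(75, 100, 120, 150, 190))  # -2 0 2 4 6
#' @export
premixed_adjust <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) stop("glucose must be > 0")
  ifelse(x < 80, -2L,
  ifelse(x <= 109, 0L,
  ifelse(x <= 139, 2L,
  ifelse(x <= 179, 4L, 6L))))
}

#' Basal-regimen dose adjustment
#'
#' The basal (long-acting) dose is adjusted on the pre-breakfast/fasting
#' glucose with the same five-branch table as [premixed_adjust()].
#'
#' @param x Fasting glucose in mg/dl (vectorized, > 0).
#' @return Signed adjustment in insulin units.
#' @export
basal_adjust <- function(x) premixed_adjust(x)

#' Supplemental bolus dose from the basal-bolus post-meal table
#'
#' Seven-branch table over post-meal glucose (mg/dl): 4 (141-180),
#' 6 (181-220), 8 (221-260), 10 (261-300), 12 (301-350), 14 (351-400),
#' 16 (> 400). Post-meal glucose at or below 140 mg/dl yields no
#' supplement (0), the conservative reading of a table that starts at 141.
#'
#' @param x Post-meal glucose in mg/dl (vectorized, > 0).
#' @return Supplemental bolus insulin in units.
#' @examples
#' bolus_supplement(375)  # 14
#' @export
bolus_supplement <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) stop("glucose must be > 0")
  ifelse(x <= 140, 0L,
  ifelse(x <= 180, 4L,
  ifelse(x <= 220, 6L,
  ifelse(x <= 260, 8L,
  ifelse(x <= 300, 10L,
  ifelse(x <= 350, 12L,
  ifelse(x <= 400, 14L, 16L)))))))
}

#' Basal-bolus regimen daily adjustment
#'
#' Basal rule: if fasting (or daily mean) glucose exceeds 140 mg/dl with
#' no hypoglycemia, the basal dose increases by 20%; if a hypoglycemic
#' reading (< 70 mg/dl) occurred, it decreases by 20% (hypoglycemia takes
#' precedence when both conditions hold). The new basal is rounded
#' half-away-from-zero to integer units and clamped to 1..40. Bolus rule:
#' the supplemental bolus follows [bolus_supplement()] on the post-meal
#' glucose.
#'
#' @param fasting_or_mean Fasting or daily-mean glucose in mg/dl.
#' @param hypo_event Was any glucose < 70 mg/dl observed that day?
#' @param current_basal Current basal dose in units (> 0).
#' @param postmeal Post-meal glucose in mg/dl (scalar or vector; one
#'   supplement per value).
#' @return List with `new_basal` (integer units, 1..40),
#'   `bolus_supplement` (integer units per post-meal value) and
#'   `rule_fired` (one of "basal_down_20", "basal_up_20", "basal_hold").
#' @examples
#' basal_bolus_adjust(150, FALSE, 10, 375)  # basal 12, supplement 14
#' @export
basal_bolus_adjust <- function(fasting_or_mean, hypo_event, current_basal,
                               postmeal = numeric(0)) {
  if (current_basal <= 0) stop("current_basal must be > 0")
  if (hypo_event) {
    nb <- current_basal * 0.8; rule <- "basal_down_20"
  } else if (fasting_or_mean > 140) {
    nb <- current_basal * 1.2; rule <- "basal_up_20"
  } else {
    nb <- current_basal; rule <- "basal_hold"
  }
  # round half away from zero, then clamp to the dose vocabulary
  nb <- sign(nb) * floor(abs(nb) + 0.5)
  nb <- as.integer(min(40, max(1, nb)))
  list(new_basal = nb,
       bolus_supplement = if (length(postmeal)) bolus_supplement(postmeal)
                          else integer(0),
       rule_fired = rule)
}

#' Guideline titration recommendations for a trajectory
#'
#' Applies the regimen's printed titration rules day by day: premixed
#' doses adjust on the opposite-meal glucose, basal doses on fasting
#' glucose, and basal-bolus regimens combine the 20% basal rule with
#' post-meal bolus supplements. Glucose is converted from mmol/L to mg/dl
#' before any table lookup. Days with the required glucose unmeasured
#' yield no decision.
#'
#' @param traj A `trajectory` with a `regimen` attribute.
#' @return A data.frame of decisions: `day`, `slot`, `insulin_class`,
#'   `current_dose`, `delta_units` (signed adjustment, or the absolute
#'   supplement for boluses), `new_dose`, `rule_fired`.
#' @export
guideline_titration <- function(traj) {
  if (is.null(traj$regimen)) stop("trajectory has no regimen attribute")
  out <- list()
  add <- function(day, slot, cls, cur, delta, new, rule)
    out[[length(out) + 1L]] <<- data.frame(
      day = day, slot = slot, insulin_class = cls, current_dose = cur,
      delta_units = delta, new_dose = new, rule_fired = rule)
  gdl <- function(i) mgdl_from_mmol(traj$glucose[i])
  for (d in setdiff(unique(traj$day), max(traj$day))) {
    di <- which(traj$day == d)
    nxt <- which(traj$day == d + 1L)
    g_fast <- traj$glucose[di[traj$slot[di] == 0L]]
    if (traj$regimen == "premixed") {
      # next-day pre-breakfast dose from today's pre-supper glucose
      g_sup <- traj$glucose[di[traj$slot[di] == 4L]]
      for (tgt in c(0L, 4L)) {
        src <- if (tgt == 0L) g_sup else g_fast
        cur_i <- di[traj$slot[di] == tgt]
        nxt_i <- nxt[traj$slot[nxt] == tgt]
        if (!length(cur_i) || !length(nxt_i) || is.na(src)) next
        cur <- traj$dose[cur_i]
        dl <- premixed_adjust(mgdl_from_mmol(src))
        add(d + 1L, tgt, "premixed", cur, dl,
            as.integer(min(40, max(1, cur + dl))),
            paste0("premixed_", dl))
      }
    } else if (traj$regimen == "basal_only") {
      cur_i <- di[traj$slot[di] == 6L]
      if (length(cur_i) && length(g_fast) && !is.na(g_fast)) {
        cur <- traj$dose[cur_i]
        dl <- basal_adjust(mgdl_from_mmol(g_fast))
        add(d + 1L, 6L, "long_acting", cur, dl,
            as.integer(min(40, max(1, cur + dl))), paste0("basal_", dl))
      }
    } else if (traj$regimen == "basal_bolus") {
      g_day <- traj$glucose[di]
      meas <- g_day[!is.na(g_day)]
      hypo <- any(mgdl_from_mmol(meas) < 70)
      ref <- if (length(g_fast) && !is.na(g_fast)) mgdl_from_mmol(g_fast)
             else if (length(meas)) mean(mgdl_from_mmol(meas)) else NA
      cur_i <- di[traj$slot[di] == 6L]
      if (length(cur_i) && !is.na(ref)) {
        cur <- traj$dose[cur_i]
        bb <- basal_bolus_adjust(ref, hypo, cur)
        add(d + 1L, 6L, "long_acting", cur, bb$new_basal - cur,
            bb$new_basal, bb$rule_fired)
      }
      # bolus supplements: next-day pre-meal bolus from today's post-meal
      for (pm_slot in c(1L, 3L, 5L)) {
        g_pm <- traj$glucose[di[traj$slot[di] == pm_slot]]
        tgt <- pm_slot - 1L
        cur_i <- di[traj$slot[di] == tgt]
        nxt_i <- nxt[traj$slot[nxt] == tgt]
        if (!length(cur_i) || !length(nxt_i) || !length(g_pm) || is.na(g_pm))
          next
        cur <- traj$dose[cur_i]
        sup <- bolus_supplement(mgdl_from_mmol(g_pm))
        add(d + 1L, tgt, "short_rapid", cur, sup,
            as.integer(min(40, max(1, cur + sup))), paste0("bolus_", sup))
      }
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
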