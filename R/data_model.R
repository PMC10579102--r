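# Core trajectory data structures, the seven-slot daily grid, unit
# conversion and interchange I/O (JSON-lines and long CSV).

#' Timeslot labels of the seven-point daily glucose profile
#'
#' Each treatment day is divided into seven ordered timeslots, indexed
#' 0 to 6: pre-breakfast, post-breakfast, pre-lunch, post-lunch,
#' pre-dinner, post-dinner and pre-bedtime.
#'
#' @format Character vector of length 7.
#' @export
SLOT_LABELS <- c("pre-breakfast", "post-breakfast", "pre-lunch",
                 "post-lunch", "pre-dinner", "post-dinner", "pre-bedtime")

#' Insulin action classes
#'
#' The three insulin classes plus the explicit no-injection token.
#' "No injection" is a distinct class, not dose 0, because the dose
#' vocabulary starts at 1 unit.
#'
#' @format Character vector of length 4.
#' @export
INSULIN_CLASSES <- c("none", "short_rapid", "long_acting", "premixed")

#' Conversion factor between mmol/L and mg/dl for glucose
#'
#' Single source of truth for the molar-mass convention: 1 mmol/L of
#' glucose equals 18.0182 mg/dl.
#'
#' @export
MGDL_PER_MMOL <- 18.0182

#' Convert glucose between mmol/L and mg/dl
#'
#' @param g Non-negative glucose values; `mgdl_from_mmol()` takes mmol/L,
#'   `mmol_from_mgdl()` takes mg/dl. `NA` passes through.
#' @return Converted values (mg/dl, respectively mmol/L).
#' @examples
#' mgdl_from_mmol(5.55)   # ~100 mg/dl
#' mmol_from_mgdl(100)    # ~5.55 mmol/L
#' @export
mgdl_from_mmol <- function(g) {
  if (any(g < 0, na.rm = TRUE)) stop("glucose must be non-negative")
  g * MGDL_PER_MMOL
}

#' @rdname mgdl_from_mmol
#' @export
mmol_from_mgdl <- function(g) {
  if (any(g < 0, na.rm = TRUE)) stop("glucose must be non-negative")
  g / MGDL_PER_MMOL
}

#' Advance a (day, slot) position by k timeslots
#'
#' Slot arithmetic on the seven-slot grid: the k-th step after slot `slot`
#' of day `day` (slots 0-6, days from 1).
#'
#' @param day Integer day (>= 1).
#' @param slot Integer slot index in 0..6.
#' @param k Number of steps to advance (non-negative integer).
#' @return List with components `day` and `slot`.
#' @export
advance_slot <- function(day, slot, k) {
  stopifnot(slot >= 0, slot <= 6, k >= 0)
  tot <- slot + k
  list(day = day + tot %/% 7L, slot = tot %% 7L)
}

#' Construct a patient trajectory
#'
#' A trajectory is the ordered sequence of per-timeslot observations,
#' insulin actions and rewards for one patient. All per-step vectors share
#' the same length tau; (day, slot) must advance strictly monotonically on
#' the seven-slot grid. Missing glucose is `NA` (an explicit mask), never 0.
#'
#' @param patient_id Identifier (coerced to character).
#' @param day Integer vector of days (>= 1), length tau.
#' @param slot Integer vector of slot indices 0..6, length tau.
#' @param glucose Numeric vector of glucose in mmol/L, `NA` where unmeasured.
#' @param action_class Character vector over [INSULIN_CLASSES].
#' @param dose Integer doses in 1..40 where an injection occurs, `NA` where
#'   `action_class == "none"`.
#' @param reward Numeric rewards in `[-1, 1]`, `NA` at unmeasured slots.
#'   Defaults to `NA` everywhere.
#' @param covariates Numeric matrix (tau x k) of normalized covariates, or a
#'   single row recycled to all steps. May have zero columns.
#' @param regimen Optional regimen label ("premixed", "basal_only",
#'   "basal_bolus"), stored as an attribute for schedule-aware tools.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(patient_id, day, slot, glucose, action_class, dose,
                       reward = NULL, covariates = NULL, regimen = NULL) {
  tau <- length(day)
  if (is.null(reward)) reward <- rep(NA_real_, tau)
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = tau, ncol = 0)
  if (!is.matrix(covariates)) covariates <- matrix(covariates, nrow = tau,
                                                   ncol = length(covariates),
                                                   byrow = TRUE)
  x <- structure(list(
    patient_id = as.character(patient_id),
    day = as.integer(day), slot = as.integer(slot),
    glucose = as.numeric(glucose),
    action_class = as.character(action_class),
    dose = as.integer(dose), reward = as.numeric(reward),
    covariates = covariates, regimen = regimen
  ), class = "trajectory")
  validate_trajectory(x)
  x
}

#' Validate trajectory invariants
#'
#' Checks aligned lengths, the monotone (day, slot) grid without duplicates,
#' positive finite glucose where measured, dose bounds 1..40, reward bounds
#' and class vocabulary. Errors name the offending patient.
#'
#' @param x A `trajectory`.
#' @return `x`, invisibly, if valid.
#' @export
validate_trajectory <- function(x) {
  id <- x$patient_id
  tau <- length(x$day)
  lens <- c(length(x$slot), length(x$glucose), length(x$action_class),
            length(x$dose), length(x$reward), nrow(x$covariates))
  if (any(lens != tau))
    stop("patient ", id, ": per-step fields have unequal lengths")
  if (any(x$slot < 0 | x$slot > 6))
    stop("patient ", id, ": slot index outside 0..6")
  if (any(x$day < 1)) stop("patient ", id, ": day index below 1")
  key <- x$day * 7L + x$slot
  if (tau > 1 && any(diff(key) <= 0))
    stop("patient ", id, ": timeslots not strictly increasing (day, slot)")
  g <- x$glucose[!is.na(x$glucose)]
  if (any(!is.finite(g) | g <= 0))
    stop("patient ", id, ": measured glucose must be finite and > 0")
  if (!all(x$action_class %in% INSULIN_CLASSES))
    stop("patient ", id, ": unknown insulin class")
  inj <- x$action_class != "none"
  if (any(is.na(x$dose[inj])) || any(x$dose[inj] < 1 | x$dose[inj] > 40))
    stop("patient ", id, ": dose must be an integer in 1..40 when injecting")
  if (any(!is.na(x$dose[!inj])))
    stop("patient ", id, ": dose must be NA when action class is 'none'")
  r <- x$reward[!is.na(x$reward)]
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12))
    stop("patient ", id, ": reward outside [-1, 1]")
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> patient", x$patient_id,
      sprintf("| %d steps over days %d-%d", length(x$day),
              min(x$day), max(x$day)))
  if (!is.null(x$regimen)) cat(" |", x$regimen)
  cat("\n  measured glucose:", sum(!is.na(x$glucose)), "of", length(x$day),
      "slots; injections:", sum(x$action_class != "none"), "\n")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$day)

#' Convert a trajectory (or list of trajectories) to a long data frame
#'
#' One row per timeslot: patient_id, day, slot, glucose_mmol, insulin_class,
#' dose_units, reward, cov_0..cov_k.
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return A `data.frame` in long format.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(patient_id = x$patient_id, day = x$day, slot = x$slot,
                   glucose_mmol = x$glucose, insulin_class = x$action_class,
                   dose_units = x$dose, reward = x$reward,
                   stringsAsFactors = FALSE)
  k <- ncol(x$covariates)
  if (k > 0) {
    cv <- as.data.frame(x$covariates)
    names(cv) <- paste0("cov_", seq_len(k) - 1L)
    df <- cbind(df, cv)
  }
  df
}

traj_from_df <- function(df, regimen = NULL) {
  covc <- grep("^cov_", names(df), value = TRUE)
  cov <- if (length(covc)) as.matrix(df[covc]) else NULL
  trajectory(df$patient_id[1], df$day, df$slot, df$glucose_mmol,
             df$insulin_class, df$dose_units,
             reward = if ("reward" %in% names(df)) df$reward else NULL,
             covariates = cov, regimen = regimen)
}

#' Write trajectories to disk
#'
#' Two interchange formats are supported. `"jsonl"` (canonical) writes one
#' JSON object per patient with nested per-slot records; masked glucose is
#' serialized as an explicit `null`, never 0. `"csv"` writes the long format
#' with one row per timeslot. Both round-trip losslessly through
#' [read_trajectories()].
#'
#' @param trajs A list of `trajectory` objects (a single trajectory is
#'   accepted).
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  lapply(trajs, validate_trajectory)
  if (format == "jsonl") {
    lines <- vapply(trajs, function(tr) {
      slots <- lapply(seq_along(tr$day), function(i) {
        act <- if (tr$action_class[i] == "none") NULL else
          list(class = tr$action_class[i], dose = tr$dose[i])
        list(day = tr$day[i], slot = tr$slot[i],
             glucose_mmol = if (is.na(tr$glucose[i])) NULL else tr$glucose[i],
             reward = if (is.na(tr$reward[i])) NULL else tr$reward[i],
             action = act,
             covariates = if (ncol(tr$covariates)) tr$covariates[i, ] else NULL)
      })
      jsonlite::toJSON(list(patient_id = tr$patient_id,
                            regimen = tr$regimen,
                            days = max(tr$day), slots = slots),
                       auto_unbox = TRUE, null = "null", digits = NA)
    }, character(1))
    writeLines(lines, path)
  } else {
    dfs <- lapply(trajs, function(tr) {
      d <- as.data.frame(tr)
      d$regimen <- if (is.null(tr$regimen)) NA_character_ else tr$regimen
      d
    })
    utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read trajectories from disk
#'
#' Parses the JSON-lines or long-CSV interchange format written by
#' [write_trajectories()], validating every trajectory's invariants.
#' Malformed records raise errors naming the line or patient.
#'
#' @param path Input file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return A list of `trajectory` objects.
#' @export
read_trajectories <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    lapply(seq_along(lines), function(ln) {
      rec <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
                      error = function(e) stop("line ", ln,
                                               ": malformed JSON: ",
                                               conditionMessage(e)))
      if (is.null(rec$patient_id) || is.null(rec$slots))
        stop("line ", ln, ": missing required field patient_id or slots")
      s <- rec$slots
      get_num <- function(field) vapply(s, function(z)
        if (is.null(z[[field]])) NA_real_ else as.numeric(z[[field]]), 0)
      cls <- vapply(s, function(z)
        if (is.null(z$action)) "none" else z$action$class, "")
      dose <- vapply(s, function(z)
        if (is.null(z$action)) NA_integer_ else as.integer(z$action$dose), 0L)
      cov <- t(vapply(s, function(z)
        as.numeric(unlist(z$covariates)), numeric(length(unlist(s[[1]]$covariates)))))
      if (ncol(cov) == 0) cov <- matrix(numeric(0), nrow = length(s), ncol = 0)
      trajectory(rec$patient_id,
                 vapply(s, function(z) as.integer(z$day), 0L),
                 vapply(s, function(z) as.integer(z$slot), 0L),
                 get_num("glucose_mmol"), cls, dose,
                 reward = get_num("reward"), covariates = cov,
                 regimen = rec$regimen)
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
    need <- c("patient_id", "day", "slot", "glucose_mmol",
              "insulin_class", "dose_units")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing required columns: ",
                           paste(miss, collapse = ", "))
    df$insulin_class[is.na(df$insulin_class)] <- "none"
    lapply(split(df, factor(df$patient_id, levels = unique(df$patient_id))),
           function(d) traj_from_df(d, regimen =
             if ("regimen" %in% names(d) && !is.na(d$regimen[1]))
               d$regimen[1] else NULL))
  }
}
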