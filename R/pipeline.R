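# End-to-end orchestration: YAML config, seeding, checkpoints and the
# simulate -> train-patient -> train-policy -> plan -> evaluate -> ope
# pipeline. A thin command-line front-end over these functions lives at
# inst/scripts/titrate.R.

#' Save / load a model checkpoint
#'
#' Single-file archive holding the weights, the full config and the input
#' schema width, so a reloaded model reproduces identical outputs.
#'
#' @param object A `patient_model` or `dose_policy`.
#' @param path Destination file.
#' @return `path` (save), or the restored object (load).
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

default_run_config <- function() {
  list(
    cohort = list(n_patients = 60, n_days = 3, noise_sd = 0.4,
                  behavior_policy_noise = 3, missing_rate = 0.1),
    patient_model = list(hidden_dim = 32, encoder_layers = 1, epochs = 15,
                         rollout_depth = 2),
    policy = list(epochs = 15, rollout_depth = 5, n_anchors = 2),
    plan = list(K = 7, B = 10, M = 5),
    ope = list(floor = 1e-3, gamma = 0.9)
  )
}

apply_cfg <- function(constructor, block, extra = list()) {
  do.call(constructor, c(block, extra))
}

#' Run the dosing pipeline
#'
#' Executes the requested stages in order, each writing versioned
#' artifacts under `out_dir`: `simulate` (cohort JSON-lines + latents),
#' `train_patient` (patient-model checkpoint), `train_policy` (policy
#' checkpoint), `plan` (per-patient next-day recommendation table),
#' `evaluate` (glycemic metrics JSON) and `ope` (off-policy evaluation
#' JSON). Stage dependencies are checked: a stage whose upstream artifact
#' is missing raises an error naming the stage. A manifest recording the
#' seed and a hash of the configuration is written at the end; rerunning
#' with the same seed and config reproduces the deterministic artifacts.
#'
#' @param config A configuration list (blocks `cohort`, `patient_model`,
#'   `policy`, `plan`, `ope`) or path to a YAML file with those blocks;
#'   `NULL` uses the scaled-down default profile.
#' @param stages Character subset of
#'   `c("simulate", "train_patient", "train_policy", "plan", "evaluate",
#'   "ope")`, executed in pipeline order.
#' @param seed Global seed; every stage derives its randomness from it.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the stage artifacts' paths.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("simulate", "train_patient",
                                    "train_policy", "plan", "evaluate",
                                    "ope"),
                         seed = 1L, out_dir = "pipeline_out") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  for (nm in names(config)) base[[nm]] <- utils::modifyList(base[[nm]],
                                                            config[[nm]])
  config <- base
  order_all <- c("simulate", "train_patient", "train_policy", "plan",
                 "evaluate", "ope")
  stages <- order_all[order_all %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(p(f)))
      stop("stage '", stage, "' requires missing artifact ", f,
           " (run its upstream stage first)")
    p(f)
  }
  arts <- list()
  for (stage in stages) {
    if (stage == "simulate") {
      cc <- apply_cfg(cohort_config, config$cohort, list(seed = seed))
      coh <- generate_cohort(cc)
      write_trajectories(coh$trajectories, p("cohort.jsonl"), "jsonl")
      saveRDS(coh, p("cohort.rds"))
      arts$cohort <- p("cohort.jsonl")
    } else if (stage == "train_patient") {
      coh <- readRDS(need("cohort.rds", stage))
      cfg <- apply_cfg(patient_model_config, config$patient_model,
                       list(seed = seed))
      pm <- patient_model(coh, cfg)
      save_checkpoint(pm, p("patient_model.rds"))
      utils::write.csv(pm$history, p("patient_model_history.csv"),
                       row.names = FALSE)
      arts$patient_model <- p("patient_model.rds")
    } else if (stage == "train_policy") {
      coh <- readRDS(need("cohort.rds", stage))
      pm <- load_checkpoint(need("patient_model.rds", stage))
      cfg <- apply_cfg(policy_config, config$policy, list(seed = seed))
      pol <- train_policy(coh, pm, cfg)
      save_checkpoint(pol, p("policy.rds"))
      utils::write.csv(pol$history, p("policy_history.csv"),
                       row.names = FALSE)
      arts$policy <- p("policy.rds")
    } else if (stage == "plan") {
      coh <- readRDS(need("cohort.rds", stage))
      pm <- load_checkpoint(need("patient_model.rds", stage))
      pol <- load_checkpoint(need("policy.rds", stage))
      pc <- apply_cfg(plan_config, config$plan)
      recs <- lapply(coh$trajectories, function(tr) {
        rec <- recommend_day(tr, pm, pol, pc)
        cbind(patient_id = tr$patient_id, rec,
              plan_value = attr(rec, "plan_value"))
      })
      utils::write.csv(do.call(rbind, recs), p("recommendations.csv"),
                       row.names = FALSE)
      arts$plan <- p("recommendations.csv")
    } else if (stage == "evaluate") {
      coh <- readRDS(need("cohort.rds", stage))
      g <- unlist(lapply(coh$trajectories, `[[`, "glucose"))
      rep_out <- list(
        n_patients = length(coh$trajectories),
        band_fractions = as.list(band_fractions(g)),
        glycemic_cv = glycemic_cv(g),
        mean_daily_wtr = mean(vapply(coh$trajectories, function(tr)
          mean(vapply(split(tr$glucose, tr$day), daily_wtr_ratio, 0),
               na.rm = TRUE), 0), na.rm = TRUE))
      jsonlite::write_json(rep_out, p("metrics.json"), auto_unbox = TRUE,
                           digits = NA)
      arts$evaluate <- p("metrics.json")
    } else if (stage == "ope") {
      coh <- readRDS(need("cohort.rds", stage))
      pm <- load_checkpoint(need("patient_model.rds", stage))
      pol <- load_checkpoint(need("policy.rds", stage))
      ocfg <- config$ope
      beh <- fit_behavior_policy(coh, pm,
                                 policy_config(epochs = 10, seed = seed),
                                 floor = ocfg$floor)
      res <- ope_evaluate(coh, beh, pol, pm, gamma = ocfg$gamma)
      jsonlite::write_json(list(V_IS = res$v_is, V_WIS = res$v_wis,
                                ESS = res$ess, N = res$n,
                                floor = ocfg$floor),
                           p("ope.json"), auto_unbox = TRUE, digits = NA)
      arts$ope <- p("ope.json")
    }
  }
  manifest <- list(seed = seed,
                   config_hash = sum(utf8ToInt(paste(
                     utils::capture.output(utils::str(config)),
                     collapse = ""))),
                   stages = stages, artifacts = arts,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(arts)
}
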