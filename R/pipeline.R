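#' Validate and normalize a pipeline configuration
#'
#' Fills defaults for every stage of the pipeline, checks types and
#' ranges, and rejects unknown keys. All violations are reported together.
#' Every clinically meaningful threshold has a named key with its
#' conventional default: complication drops 0.02/0.02/0.04/0.06, a 1.8
#' discharge-readiness score, the 2000 counts/s activity-count split, the
#' level-3 chest activity split, exercise detection at 70% of maximum HR,
#' the 12 bpm abnormal-HRR-1 flag, the 8-day LOS group threshold, 10,000
#' split candidates and a 0.05 elimination alpha.
#'
#' @param document named list (e.g. parsed from YAML/JSON), possibly
#'   empty.
#' @return a normalized `pipeline_config` list.
#' @export
validate_config <- function(document = list()) {
  defaults <- list(
    seed = 1L,
    n_patients = 125L,
    horizon = 21L,
    generator = list(),
    drop = list(magnitude = c(`1` = 0.02, `2` = 0.02, `3` = 0.04, `4` = 0.06),
                lead_days = c(`1` = 1L, `2` = 1L, `3` = 1L, `4` = 2L)),
    split = list(fraction = 2 / 3, n_candidates = 10000L),
    features = list(),
    model = list(),
    screen_top_n = 16L,
    eliminate = TRUE,
    clinical = list(los_threshold = 8, readiness_threshold = 1.8,
                    hrr1_abnormal = 12, decline_k = 3L)
  )
  errors <- character(0)
  bad <- setdiff(names(document), names(defaults))
  if (length(bad)) {
    errors <- c(errors, paste("unknown key(s):", paste(bad, collapse = ", ")))
  }
  for (sub in c("drop", "split", "clinical")) {
    if (!is.null(document[[sub]])) {
      bad <- setdiff(names(document[[sub]]), names(defaults[[sub]]))
      if (length(bad)) {
        errors <- c(errors, sprintf("unknown key(s) in %s: %s", sub,
                                    paste(bad, collapse = ", ")))
      }
    }
  }
  cfg <- utils::modifyList(defaults, document[names(document) %in% names(defaults)])
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    errors <- c(errors, "seed must be a single integer")
  }
  if (any(unlist(cfg$drop$magnitude) <= 0)) {
    errors <- c(errors, "drop$magnitude values must be positive")
  }
  if (any(unlist(cfg$drop$lead_days) < 1)) {
    errors <- c(errors, "drop$lead_days values must be >= 1")
  }
  if (cfg$split$fraction <= 0 || cfg$split$fraction > 1) {
    errors <- c(errors, "split$fraction must be in (0, 1]")
  }
  if (cfg$split$n_candidates < 1) {
    errors <- c(errors, "split$n_candidates must be >= 1")
  }
  if (cfg$clinical$readiness_threshold <= 0) {
    errors <- c(errors, "clinical$readiness_threshold must be positive")
  }
  if (cfg$clinical$decline_k < 2) {
    errors <- c(errors, "clinical$decline_k must be >= 2")
  }
  if (cfg$n_patients < 2) errors <- c(errors, "n_patients must be >= 2")
  if (cfg$horizon < 1) errors <- c(errors, "horizon must be >= 1")
  if (length(errors)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(doc)
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Run the full recovery-score pipeline
#'
#' Executes every stage in order: simulate the cohort, engineer reference
#' profiles, search a balanced train/test split, generate streams and
#' extract daily features for every patient, screen features by Pearson
#' correlation on the training set, tune hyperparameters (5-fold CV),
#' optionally run backward feature elimination (10-fold CV with the
#' Friedman/Nemenyi stop rule), train the final model, predict all
#' patient-days, evaluate on the held-out test patients, and build the
#' short/long-LOS group bands with per-patient assessments. Test-patient
#' data enter no fitting step: standardization, screening, tuning,
#' elimination and training see training patients only.
#'
#' @param config a `pipeline_config` from [validate_config()].
#' @param out_dir optional directory; when given, all artifacts (config,
#'   cohort, profiles, split, features, predictions, metrics, group
#'   profiles, assessments, log) are written there as CSV/JSON.
#' @param quiet suppress progress messages.
#' @return list with every stage's outputs, including `metrics` (test-set
#'   MSE, SRCC, discharge error), `selected_features` and `importance`.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
    if (!quiet) message(msg)
  }
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-10s done in %.1fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  gen_cfg <- do.call(generator_config,
                     c(list(n_patients = config$n_patients,
                            seed = stage_seed(config$seed, 1L)),
                       config$generator))
  feat_cfg <- do.call(feature_config, config$features)
  dspec <- drop_spec(magnitude = unlist(config$drop$magnitude),
                     lead_days = unlist(config$drop$lead_days))
  mod_cfg <- do.call(model_config,
                     utils::modifyList(list(seed = stage_seed(config$seed, 5L)),
                                       config$model))

  cohort <- run_stage("simulate", generate_cohort(gen_cfg))
  profiles <- run_stage("reference",
                        build_reference_profiles(cohort, dspec,
                                                 horizon = config$horizon))
  split <- run_stage("split", balanced_split(
    cohort, fraction = config$split$fraction,
    n_candidates = config$split$n_candidates,
    seed = stage_seed(config$seed, 2L)))

  frames <- run_stage("features", {
    streams_features <- lapply(cohort, function(p) {
      s <- generate_streams(p, profiles[[p$patient_id]], gen_cfg)
      fr <- extract_features(s, age = p$age, days = 0:(config$horizon - 1L),
                             config = feat_cfg)
      cbind(patient_id = p$patient_id, fr, stringsAsFactors = FALSE)
    })
    delta_features(do.call(rbind, streams_features))
  })

  ref <- profiles_frame(profiles)
  frames <- merge(frames, ref, by = c("patient_id", "day"), all.x = TRUE)
  frames <- frames[!is.na(frames$score), ]
  frames <- frames[order(frames$patient_id, frames$day), ]
  target <- frames$score
  frames$score <- NULL

  train_rows <- frames$patient_id %in% split$train_ids
  train_frames <- frames[train_rows, ]
  train_target <- target[train_rows]

  screen <- run_stage("screen", {
    train_profiles <- profiles[split$train_ids]
    r <- pearson_screen(train_frames, train_profiles)
    r[order(-abs(r))]
  })
  candidates <- names(screen)[!is.na(screen)]
  model_features <- utils::head(candidates, config$screen_top_n)

  std <- standardize(train_frames)
  tuned <- run_stage("tune", tune_hyperparameters(std$frames, train_target,
                                                  mod_cfg,
                                                  features = model_features))
  hyper <- tuned[c("eta", "max_depth", "nrounds", "subsample")]

  elim <- NULL
  selected <- model_features
  if (isTRUE(config$eliminate) && length(model_features) >= 2L) {
    elim <- run_stage("eliminate",
                      backward_eliminate(std$frames, train_target, hyper,
                                         config = mod_cfg,
                                         features = model_features))
    selected <- elim$selected
  }

  model <- run_stage("train", train_final(train_frames, train_target, hyper,
                                          features = selected, config = mod_cfg))
  predictions <- run_stage("predict", predict(model, frames))
  test_pred <- predictions[predictions$patient_id %in% split$test_ids, ]
  metrics <- run_stage("evaluate",
                       evaluate_predictions(test_pred, profiles[split$test_ids]))
  train_metrics <- evaluate_predictions(
    predictions[train_rows, ], profiles[split$train_ids])

  clinical <- run_stage("compare", {
    bands <- group_profiles(predictions, cohort,
                            los_threshold = config$clinical$los_threshold)
    assessments <- lapply(split$test_ids, function(pid) {
      pp <- predictions[predictions$patient_id == pid, c("day", "pred")]
      pat <- cohort[[match(pid, vapply(cohort, `[[`, character(1), "patient_id"))]]
      cls <- classify_patient(pp, bands$short_los, bands$long_los)
      rd <- discharge_readiness(pp, config$clinical$readiness_threshold,
                                discharge_day = pat$los)
      list(patient_id = pid, classification = cls, readiness = rd,
           decline = decline_flags(pp, config$clinical$decline_k))
    })
    names(assessments) <- split$test_ids
    list(bands = bands, assessments = assessments)
  })

  say("pipeline complete in %.1fs",
      as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  result <- list(config = config, cohort = cohort, profiles = profiles,
                 split = split, frames = frames, target = target,
                 screen = screen, hyperparams = hyper, elimination = elim,
                 selected_features = selected, model = model,
                 importance = model_importance(model),
                 predictions = predictions, metrics = metrics,
                 train_metrics = train_metrics, clinical = clinical,
                 log = log_lines)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(result$config),
                       file.path(out_dir, "config.json"), auto_unbox = TRUE)
  write_cohort(result$cohort, file.path(out_dir, "cohort.json"))
  utils::write.csv(profiles_frame(result$profiles),
                   file.path(out_dir, "reference_profiles.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(train_ids = result$split$train_ids,
                            test_ids = result$split$test_ids,
                            balance_score = result$split$balance_score,
                            per_variable_p = as.list(result$split$per_variable_p)),
                       file.path(out_dir, "split.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(split_report(result$split, result$cohort),
                   file.path(out_dir, "split_report.csv"), row.names = FALSE)
  utils::write.csv(result$frames, file.path(out_dir, "features.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(data.frame(feature = names(result$screen),
                              pearson_r = unname(result$screen)),
                   file.path(out_dir, "feature_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(result$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(test = result$metrics[c("mse", "srcc",
                                                    "discharge_error",
                                                    "pearson_r", "n")],
                            train = result$train_metrics[c("mse", "srcc",
                                                           "discharge_error",
                                                           "pearson_r", "n")],
                            hyperparams = result$hyperparams,
                            selected_features = result$selected_features,
                            importance = as.list(result$importance)),
                       file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  bands <- rbind(cbind(group = "short_los", result$clinical$bands$short_los),
                 cbind(group = "long_los", result$clinical$bands$long_los))
  utils::write.csv(bands, file.path(out_dir, "group_profiles.csv"),
                   row.names = FALSE)
  writeLines(result$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
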