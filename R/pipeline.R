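MANIFEST_COLS <- c("subject_id", "scan_time_years", "payload_ref", "grade",
                   "age", "sex", "ethnicity", "bmi", "event_time_years")

#' Write a cohort manifest CSV
#'
#' Censored event times are written as empty fields.
#' @param manifest Manifest data.frame.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(MANIFEST_COLS %in% names(manifest)))
  utils::write.csv(manifest[, MANIFEST_COLS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read and validate a cohort manifest CSV
#'
#' Requires the full manifest header; empty `event_time_years` fields parse
#' as censored (`NA`). Row-level validation failures (negative scan time,
#' grade outside 0-4, non-positive BMI) are reported together with their row
#' numbers.
#'
#' @param path Manifest path.
#' @return Manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  missing_cols <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$event_time_years <- suppressWarnings(as.numeric(df$event_time_years))
  bad <- which(!is.finite(df$scan_time_years) | df$scan_time_years < 0 |
                 !df$grade %in% 0:4 | !is.finite(df$bmi) | df$bmi <= 0)
  if (length(bad) > 0) {
    stop("manifest validation failed at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  df[, MANIFEST_COLS]
}

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "progrisk_out",
    simulation = list(),
    preparation = list(horizons = 2, bmi_tolerance = 0.10,
                       age_tolerance = 0, case_window = c(1, 4)),
    training = list(formulations = c("baseline", "riskform2"),
                    margin = 2.0, gamma = 1.0,
                    outer = 7, outer_folds = NULL,
                    hyper = list()),
    evaluation = list(n_boot = 200, level = 0.95, contrasts = NULL))
}

#' Build and validate an experiment configuration
#'
#' Merges user settings (an R list, or a YAML file path) over the defaults
#' and validates the schema; unknown keys raise an error naming them. The
#' `training$formulations` entry may also name the comparator runs
#' `"riskreg"` and `"conreg"`, which train the baseline formulation with the
#' corresponding soft-constraint penalty.
#'
#' @param config A named list, a YAML file path, or `NULL` for defaults.
#' @param ... Top-level overrides (e.g. `seed = 7`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(config = NULL, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  overrides <- list(...)
  config[names(overrides)] <- overrides
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    stop("config schema error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sec in c("simulation", "preparation", "training", "evaluation")) {
    if (!is.null(config[[sec]])) {
      known <- if (sec == "simulation") names(formals(sim_config))
               else names(base[[sec]])
      bad <- setdiff(names(config[[sec]]), known)
      if (length(bad) > 0) {
        stop(sprintf("config schema error in `%s`: unknown key(s): %s",
                     sec, paste(bad, collapse = ", ")), call. = FALSE)
      }
      base[[sec]][names(config[[sec]])] <- config[[sec]]
    }
  }
  for (k in setdiff(names(base), c("simulation", "preparation", "training",
                                   "evaluation"))) {
    if (!is.null(config[[k]])) base[[k]] <- config[[k]]
  }
  stopifnot(length(base$training$formulations) > 0)
  base$seed <- as.integer(base$seed)
  structure(base, class = "experiment_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  unname(tools::md5sum(tmp))
}

formulation_spec <- function(name, margin, gamma) {
  name <- tolower(name)
  if (name %in% FORMULATIONS) {
    list(name = name, formulation = name, reg = regularizer_config())
  } else if (name %in% c("riskreg", "conreg")) {
    list(name = name, formulation = "baseline",
         reg = regularizer_config(margin = margin, gamma = gamma,
                                  mode = name))
  } else {
    stop("unknown formulation: ", name, call. = FALSE)
  }
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact `%s`: run stage '%s' first",
                 path, produced_by), call. = FALSE)
  }
  path
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[progrisk] %-9s %5.1fs  %s", stage,
                  as.numeric(Sys.time()) - t0, sprintf(...)))
}

#' Run the experiment pipeline
#'
#' Executes the requested stage (and, for `"all"`, every stage in dependency
#' order): `simulate` writes the cohort manifest and payloads; `prepare`
#' matches cases to controls, builds horizon-labelled scan pairs and the
#' nested split plan; `train` fits one model per (train, validation, test)
#' assignment, formulation and horizon; `evaluate` writes ensembled
#' scan-level predictions (each outer test fold scored by the ensemble of
#' its six inner models); `report` computes metrics and writes the report
#' JSON/CSV. Each stage is idempotent given the same configuration and seed,
#' and all randomness derives from the configuration seed.
#'
#' @param config An [experiment_config()] (or anything it accepts).
#' @param stage One of `"simulate"`, `"prepare"`, `"train"`, `"evaluate"`,
#'   `"report"`, `"all"`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = experiment_config(),
                         stage = c("all", "simulate", "prepare", "train",
                                   "evaluate", "report")) {
  stage <- match.arg(stage)
  if (!inherits(config, "experiment_config")) {
    config <- experiment_config(config)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "prepare", "train", "evaluate", "report")
  } else stage
  hash <- config_hash(config)
  jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                            config = unclass(config)),
                       file.path(out, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (st in stages) {
    t0 <- as.numeric(Sys.time())
    switch(st,
      simulate = {
        sim_args <- config$simulation
        sim_args$seed <- derive_seed(config$seed, 11L)
        cohort <- do.call(sim_config, sim_args)
        cohort <- simulate_cohort(cohort)
        write_cohort(cohort, file.path(out, "cohort"))
        stage_log(st, t0, "%d scans, %d subjects", nrow(cohort$manifest),
                  length(unique(cohort$manifest$subject_id)))
      },
      prepare = {
        manifest <- read_manifest(require_artifact(
          file.path(out, "cohort", "manifest.csv"), "simulate"))
        subjects <- cohort_subjects(manifest)
        prep <- config$preparation
        matches <- match_case_control(subjects,
                                      bmi_tolerance = prep$bmi_tolerance,
                                      age_tolerance = prep$age_tolerance)
        utils::write.csv(matches, file.path(out, "matches.csv"),
                         row.names = FALSE)
        keep <- c(matches$case_id, matches$control_id)
        manifest_m <- manifest[manifest$subject_id %in% keep, , drop = FALSE]
        for (h in prep$horizons) {
          pairs <- select_training_scans(manifest_m, h,
                                         case_window = prep$case_window)
          utils::write.csv(pairs, file.path(out, sprintf("pairs_h%g.csv", h)),
                           row.names = FALSE, na = "")
        }
        subjects_m <- subjects[subjects$subject_id %in% keep, , drop = FALSE]
        plan <- make_nested_splits(subjects_m$subject_id, subjects_m$is_case,
                                   outer = config$training$outer,
                                   inner = config$training$outer - 1L,
                                   seed = derive_seed(config$seed, 13L))
        utils::write.csv(as.data.frame(plan), file.path(out, "splits.csv"),
                         row.names = FALSE)
        stage_log(st, t0, "%d matched pairs, %d subjects kept",
                  nrow(matches), length(keep))
      },
      train = {
        ctx <- pipeline_context(config)
        dir.create(file.path(out, "models"), showWarnings = FALSE)
        n_models <- 0L
        for (h in config$preparation$horizons) {
          data_all <- ctx$pair_data(h)
          for (fs in ctx$form_specs) {
            for (k in seq_len(nrow(ctx$assignments))) {
              a <- ctx$assignments[k, ]
              mem <- split_members(ctx$plan, a$outer_fold, a$val_fold)
              model <- train_fold(
                subset_pair_set(data_all, mem$train),
                subset_pair_set(data_all, mem$val),
                formulation = fs$formulation, reg = fs$reg,
                hyper = ctx$hyper,
                seed = derive_seed(config$seed,
                                   100L + a$outer_fold * 10L + a$val_fold))
              write_checkpoint(model, file.path(
                out, "models",
                sprintf("h%g_%s_o%d_v%d.json", h, fs$name, a$outer_fold,
                        a$val_fold)),
                fold = list(outer = a$outer_fold, val = a$val_fold))
              n_models <- n_models + 1L
            }
          }
        }
        stage_log(st, t0, "%d models trained", n_models)
      },
      evaluate = {
        ctx <- pipeline_context(config)
        preds <- list()
        for (h in config$preparation$horizons) {
          data_all <- ctx$pair_data(h)
          for (fs in ctx$form_specs) {
            for (o in unique(ctx$assignments$outer_fold)) {
              vals <- ctx$assignments$val_fold[ctx$assignments$outer_fold == o]
              models <- lapply(vals, function(v) {
                read_checkpoint(require_artifact(file.path(
                  out, "models",
                  sprintf("h%g_%s_o%d_v%d.json", h, fs$name, o, v)), "train"))
              })
              test_ids <- ctx$plan$subject_id[ctx$plan$fold == o]
              p <- ensemble_predict(models,
                                    subset_pair_set(data_all, test_ids))
              p$formulation <- fs$name
              p$outer_fold <- o
              preds[[length(preds) + 1L]] <- p
            }
          }
        }
        pred <- do.call(rbind, preds)
        utils::write.csv(pred, file.path(out, "predictions.csv"),
                         row.names = FALSE)
        stage_log(st, t0, "%d scan-level predictions", nrow(pred))
      },
      report = {
        pred <- utils::read.csv(require_artifact(
          file.path(out, "predictions.csv"), "evaluate"),
          stringsAsFactors = FALSE, colClasses = c(subject_id = "character"))
        ev <- config$evaluation
        for (h in unique(pred$horizon)) {
          rep_h <- eval_report(pred[pred$horizon == h, , drop = FALSE],
                               contrasts = ev$contrasts,
                               n_boot = ev$n_boot, level = ev$level,
                               seed = derive_seed(config$seed, 17L))
          rep_h$config_hash <- hash
          rep_h$horizon <- h
          write_eval_report(rep_h,
                            file.path(out, sprintf("report_h%g.json", h)),
                            file.path(out, sprintf("report_h%g.csv", h)))
        }
        stage_log(st, t0, "reports written for %d horizon(s)",
                  length(unique(pred$horizon)))
      })
  }
  invisible(out)
}

# shared state the train/evaluate stages rebuild from disk artifacts
pipeline_context <- function(config) {
  out <- config$out_dir
  cohort <- read_cohort(file.path(out, "cohort"))
  require_artifact(file.path(out, "cohort", "manifest.csv"), "simulate")
  features <- cohort_features(cohort)
  splits <- utils::read.csv(require_artifact(file.path(out, "splits.csv"),
                                             "prepare"),
                            stringsAsFactors = FALSE,
                            colClasses = c(subject_id = "character"))
  plan <- structure(splits, outer = config$training$outer,
                    inner = config$training$outer - 1L,
                    class = c("split_plan", "data.frame"))
  assignments <- split_assignments(plan)
  if (!is.null(config$training$outer_folds)) {
    assignments <- assignments[assignments$outer_fold %in%
                                 config$training$outer_folds, , drop = FALSE]
  }
  form_specs <- lapply(config$training$formulations, formulation_spec,
                       margin = config$training$margin,
                       gamma = config$training$gamma)
  hyper <- do.call(train_hyper, config$training$hyper)
  pair_data <- function(h) {
    path <- require_artifact(file.path(out, sprintf("pairs_h%g.csv", h)),
                             "prepare")
    pairs <- utils::read.csv(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""),
                             colClasses = c(subject_id = "character"))
    pair_tensors(pairs, features)
  }
  list(plan = plan, assignments = assignments, form_specs = form_specs,
       hyper = hyper, pair_data = pair_data)
}

#' Restrict a pair set to a subject subset
#' @param data A `pair_set`.
#' @param subject_ids Character vector of subjects to keep.
#' @return A `pair_set` over the kept subjects.
#' @export
subset_pair_set <- function(data, subject_ids) {
  i <- data$subject_id %in% subject_ids
  structure(list(X1 = data$X1[i, , drop = FALSE],
                 X2 = data$X2[i, , drop = FALSE],
                 y1 = data$y1[i], y2 = data$y2[i], has2 = data$has2[i],
                 subject_id = data$subject_id[i], grade1 = data$grade1[i],
                 grade2 = data$grade2[i], set_id = data$set_id[i],
                 horizon = data$horizon), class = "pair_set")
}
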