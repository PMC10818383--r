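## End-to-end study pipeline: generate -> preprocess -> label ->
## featurize -> classify (LOSO) -> identify therapy parameters -> report.

#' Experiment grid
#'
#' Enumerates the classification experiment combinations: datasets x
#' feature sets x class counts x classifier families (the full default
#' grid has 3 x 2 x 2 x 3 = 36 combinations).
#'
#' @param datasets Subset of `c("ALL", "HEALTHY", "PATIENTS")`.
#' @param feature_sets Subset of `c("SET-OBSERVE", "SET-PREDICT")`.
#' @param n_classes Subset of `c(2, 3)`.
#' @param models Subset of `c("SVM", "RF", "LDA")`.
#' @return Tibble with one row per experiment and a `config_id` string.
#' @export
experiment_grid <- function(datasets = c("ALL", "HEALTHY", "PATIENTS"),
                            feature_sets = c("SET-OBSERVE", "SET-PREDICT"),
                            n_classes = c(2, 3),
                            models = c("SVM", "RF", "LDA")) {
  tidyr::expand_grid(dataset = datasets, feature_set = feature_sets,
                     n_classes = n_classes, model_family = models) %>%
    mutate(config_id = paste(.data$dataset, .data$feature_set,
                             paste0(.data$n_classes, "class"),
                             .data$model_family, sep = "_"))
}

filter_dataset <- function(features, dataset) {
  switch(dataset,
         ALL = features,
         HEALTHY = features %>% filter(.data$group == "healthy"),
         PATIENTS = features %>% filter(.data$group == "patient"),
         stop("unknown dataset: ", dataset, call. = FALSE))
}

#' Run one LOSO classification experiment on a feature table
#'
#' Subsets the requested dataset, selects the feature set and label
#' scheme, and runs [loso_cross_validate()]; the hyperparameter search
#' always uses the 3-class labels, whose chosen setting is reused for the
#' 2-class problem.
#'
#' @param features Feature table from [assemble_feature_table()].
#' @param dataset `"ALL"`, `"HEALTHY"` or `"PATIENTS"`.
#' @param feature_set `"SET-OBSERVE"` or `"SET-PREDICT"`.
#' @param n_classes 2 or 3.
#' @param model_family `"SVM"`, `"RF"` or `"LDA"`.
#' @param search_iterations Random-search iterations (0 = defaults).
#' @param seed Integer seed.
#' @return A `tscs_loso` object whose fold predictions carry the event
#'   keys.
#' @export
run_experiment <- function(features, dataset = "ALL",
                           feature_set = "SET-OBSERVE", n_classes = 3,
                           model_family = "RF", search_iterations = 0,
                           seed = 1L) {
  df <- filter_dataset(features, dataset)
  sel <- select_feature_set(df, feature_set)
  labels <- if (n_classes == 2) sel$label_2 else sel$label_3
  keys <- df %>% select("subject_id", "group", "measurement", "position",
                        "current", "muscle")
  loso_cross_validate(sel$x, labels, sel$subject_id,
                      model_family = model_family,
                      search_iterations = search_iterations,
                      tune_labels = sel$label_3, keys = keys, seed = seed)
}

# Pooled predictions of a LOSO experiment, one row per test event.
loso_predictions <- function(loso) {
  bind_rows(loso$folds$predictions)
}

#' Generate, preprocess, label and featurize a synthetic study
#'
#' Streams over the cohort plan one session at a time (raw signals are
#' dropped as soon as a session is preprocessed) and returns the labeled
#' event table, the feature table, the pooled exclusion report and the
#' generator truth registry.
#'
#' @param spec Cohort specification ([cohort_spec()]).
#' @param seed Integer root seed.
#' @param protocol Base [stimulation_protocol()].
#' @param emg_noise_sd,acc_noise_sd Sensor noise levels.
#' @param max_current_range Discomfort-limit range, mA.
#' @param ... Passed to [preprocess_session()].
#' @return List with `labels` (labeled events without signal columns),
#'   `features`, `exclusions`, `truth`.
#' @export
build_study_tables <- function(spec, seed = 1L,
                               protocol = stimulation_protocol(),
                               emg_noise_sd = 4, acc_noise_sd = 0.03,
                               max_current_range = c(35, 50), ...) {
  plan <- cohort_plan(spec, seed, protocol, max_current_range,
                      emg_noise_sd, acc_noise_sd)
  feats <- list()
  labs <- list()
  for (entry in plan$entries) {
    session <- realize_session(entry)
    pp <- preprocess_session(session, ...)
    labeled <- label_events(pp$events)
    labs[[length(labs) + 1L]] <- labeled %>%
      select(-"emg_double", -"acc_single", -"acc_double", -"acc_diff")
    if (any(labeled$valid))
      feats[[length(feats) + 1L]] <- assemble_feature_table(labeled)
  }
  labels <- bind_rows(labs)
  list(labels = labels,
       features = bind_rows(feats),
       exclusions = list(
         n_events = nrow(labels),
         n_excluded = sum(!labels$valid),
         fraction = mean(!labels$valid),
         similarity_fail = sum(labels$invalid_reason == "similarity_fail"),
         noisy_emg = sum(labels$invalid_reason == "noisy_emg")),
       truth = plan$truth)
}

#' Run the full calibration study pipeline
#'
#' Generates a synthetic cohort, preprocesses and labels it, extracts
#' features, runs the LOSO classification experiment grid, derives
#' EMG-based and classifier-based therapy parameters, and quantifies
#' their agreement. With `out_dir` set, every stage's tables are written
#' (CSV/JSON) and a `summary.json` report is produced; reruns with the
#' same seed are byte-identical.
#'
#' @param spec Cohort specification ([cohort_spec()]).
#' @param experiments Experiment grid ([experiment_grid()]).
#' @param seed Integer root seed; per-stage seeds are derived from it.
#' @param search_iterations Random-search iterations per LOSO fold.
#' @param emg_noise_sd,acc_noise_sd Sensor noise levels.
#' @param protocol Base [stimulation_protocol()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `tables` (see [build_study_tables()]),
#'   `experiments` (the grid with a `loso` list-column and summary
#'   columns), `therapy` (per-experiment comparisons and agreement
#'   proportions, plus the EMG ground-truth parameters), `seed`.
#' @export
run_full_study <- function(spec = cohort_spec(),
                           experiments = experiment_grid(),
                           seed = 1L, search_iterations = 50,
                           emg_noise_sd = 4, acc_noise_sd = 0.03,
                           protocol = stimulation_protocol(),
                           out_dir = NULL) {
  tables <- build_study_tables(spec, seed = seed, protocol = protocol,
                               emg_noise_sd = emg_noise_sd,
                               acc_noise_sd = acc_noise_sd)
  experiments <- experiments %>%
    mutate(loso = purrr::map(row_number(), function(i) {
      run_experiment(tables$features,
                     dataset = experiments$dataset[i],
                     feature_set = experiments$feature_set[i],
                     n_classes = experiments$n_classes[i],
                     model_family = experiments$model_family[i],
                     search_iterations = search_iterations,
                     seed = (seed + 101L * i) %% .Machine$integer.max)
    }))
  experiments <- experiments %>%
    mutate(summary = purrr::map(.data$loso, function(l)
      glance(l) %>% select(-"model_family"))) %>%
    tidyr::unnest("summary")

  # therapy parameters: EMG ground truth per scheme, then one comparison
  # per experiment from its pooled LOSO predictions
  gt_by_scheme <- list(
    "2" = derive_therapy_params(tables$features, "label_2"),
    "3" = derive_therapy_params(tables$features, "label_3"))
  therapy <- experiments %>%
    select("config_id", "dataset", "feature_set", "n_classes",
           model = "model_family") %>%
    mutate(comparison = purrr::map(row_number(), function(i) {
      preds <- loso_predictions(experiments$loso[[i]])
      gt <- gt_by_scheme[[as.character(experiments$n_classes[i])]] %>%
        dplyr::semi_join(preds, by = "subject_id")
      ml <- derive_therapy_params(preds, "pred")
      compare_therapy_params(gt, ml)
    }),
    agreement = purrr::map(.data$comparison, agreement_summary))

  out <- list(tables = tables, experiments = experiments,
              therapy = therapy,
              gt_params = gt_by_scheme, seed = seed)
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  invisible(out)
}

# Serialize the study outputs as plain CSV/JSON files.
write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$tables$features,
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(study$tables$labels,
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(study$tables$exclusions,
                       file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(nrow(study$experiments))) {
    cfg <- study$experiments$config_id[i]
    d <- file.path(out_dir, "results", cfg)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    loso <- study$experiments$loso[[i]]
    utils::write.csv(tidy(loso), file.path(d, "folds.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(confusion_matrices(loso)$summed),
                     file.path(d, "confusion.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(as.list(glance(loso)),
        list(agreement = study$therapy$agreement[[i]])),
      file.path(d, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  params <- bind_rows(
    study$gt_params[["3"]] %>% mutate(source = "EMG_3class", .before = 1),
    study$gt_params[["2"]] %>% mutate(source = "EMG_2class", .before = 1),
    bind_rows(lapply(seq_len(nrow(study$therapy)), function(i) {
      study$therapy$comparison[[i]] %>%
        mutate(source = paste0("ML_", study$therapy$config_id[i]),
               .before = 1)
    })) %>%
      select("source", "subject_id", "group", "measurement",
             position = "pred_position", therapy_current = "pred_current"))
  utils::write.csv(params, file.path(out_dir, "therapy_params.csv"),
                   row.names = FALSE)
  agreement <- lapply(seq_len(nrow(study$therapy)), function(i)
    as.list(study$therapy$agreement[[i]]))
  names(agreement) <- study$therapy$config_id
  jsonlite::write_json(agreement, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = study$seed,
         n_events = study$tables$exclusions$n_events,
         excluded_fraction = study$tables$exclusions$fraction,
         experiments = lapply(seq_len(nrow(study$experiments)), function(i)
           list(config_id = study$experiments$config_id[i],
                mean_balanced_accuracy =
                  study$experiments$mean_balanced_accuracy[i],
                sd_balanced_accuracy =
                  study$experiments$sd_balanced_accuracy[i]))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
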