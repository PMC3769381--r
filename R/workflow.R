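#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the study
#' conditions: 25 bootstraps of 90% of the training profiles, the
#' four-selector ensemble, 10 candidate signature sizes between 2 and 100,
#' and nested 3x3 cross-validation. The configuration round-trips losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param seed root integer seed for all randomness.
#' @param n_bootstraps,in_bag_fraction bootstrap plan parameters.
#' @param methods Stage-1 selector ensemble.
#' @param size_grid candidate signature sizes.
#' @param consensus_size fixed consensus size, or NULL for the median of the
#'   per-selector spline optima.
#' @param cost,delta selector hyperparameters.
#' @param tasks binary tasks to run.
#' @param durations dosing durations (days) to analyze.
#' @param outer_folds,inner_folds,grouping cross-validation plan.
#' @param classifiers Stage-2 classifier kinds.
#' @param run_cv run the nested cross-validated evaluation per setting.
#' @param classify_undefined classify UNDEF compounds with the C_vs_NC and
#'   GC_vs_NGC signatures.
#' @return list of class `toxsig_config`.
#' @export
toxsig_config <- function(seed = 1L, n_bootstraps = 25,
                          in_bag_fraction = 0.9, methods = DEFAULT_METHODS,
                          size_grid = DEFAULT_SIZE_GRID,
                          consensus_size = NULL, cost = 1, delta = 0,
                          tasks = TASKS, durations = c(3L, 14L),
                          outer_folds = 3, inner_folds = 3,
                          grouping = "by_compound",
                          classifiers = CLASSIFIER_KINDS, run_cv = TRUE,
                          classify_undefined = TRUE) {
  structure(list(seed = as.integer(seed), n_bootstraps = n_bootstraps,
                 in_bag_fraction = in_bag_fraction, methods = methods,
                 size_grid = size_grid, consensus_size = consensus_size,
                 cost = cost, delta = delta, tasks = tasks,
                 durations = as.integer(durations),
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 grouping = grouping, classifiers = classifiers,
                 run_cv = run_cv, classify_undefined = classify_undefined),
            class = "toxsig_config")
}

#' Write a configuration to YAML
#' @param config a [toxsig_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from YAML
#' @param path YAML file written by [write_config()] (missing fields take
#'   defaults).
#' @return a `toxsig_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(toxsig_config))
  do.call(toxsig_config, vals[intersect(names(vals), known)])
}

#' Run the full two-stage pipeline and write its artifacts
#'
#' Executes, per task and duration: group fold-change profiling, Stage-1
#' ensemble signature extraction (signature, ROC-vs-size curves, Kuncheva
#' stability tables), optionally the nested cross-validated Stage-2
#' evaluation (per-group confidences and AUC tables), and the classification
#' of undefined compounds. Writes a probeset selection-frequency report over
#' all derived signatures and a YAML manifest of the configuration.
#'
#' @param expression path to a tab-delimited expression table or a numeric
#'   matrix.
#' @param annotations path to a tab-delimited annotation table or a
#'   data.frame.
#' @param out_dir output directory (created if needed).
#' @param config a [toxsig_config()].
#' @return invisibly, a list with `signatures`, `reports`, `undefined`.
#' @export
run_pipeline <- function(expression, annotations, out_dir,
                         config = toxsig_config()) {
  values <- if (is.character(expression)) read_expression_table(expression)
            else expression
  ann <- if (is.character(annotations)) read_annotation_table(annotations)
         else validate_annotations(annotations)
  ds <- expression_dataset(values, ann)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sigs <- list(); reports <- list(); undef <- list()
  for (d in config$durations) {
    profiles <- compute_group_profiles(ds, d)
    for (task in config$tasks) {
      tag <- paste0(task, "_", d, "d")
      y <- task_labels(profiles$info$class_label, task)
      s1 <- run_stage1(profiles, y, methods = config$methods,
                       n_bootstraps = config$n_bootstraps,
                       in_bag_fraction = config$in_bag_fraction,
                       size_grid = config$size_grid,
                       consensus_size = config$consensus_size,
                       cost = config$cost, delta = config$delta,
                       seed = config$seed, task = task, duration_days = d)
      sigs[[tag]] <- s1$signature
      write_signature(s1$signature,
                      file.path(out_dir, paste0("signature_", tag, ".tsv")))
      write_curve_tables(s1, file.path(out_dir, paste0("stage1_", tag)))
      if (config$run_cv) {
        rep <- nested_cv(profiles, y, classifiers = config$classifiers,
                         stage1_args = list(
                           methods = config$methods,
                           n_bootstraps = config$n_bootstraps,
                           in_bag_fraction = config$in_bag_fraction,
                           size_grid = config$size_grid,
                           consensus_size = config$consensus_size,
                           evaluate_performance =
                             is.null(config$consensus_size),
                           cost = config$cost, delta = config$delta,
                           task = task, duration_days = d),
                         seed = config$seed)
        reports[[tag]] <- rep
        utils::write.table(rep$predictions,
                           file.path(out_dir, paste0("predictions_", tag, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(rep$fold_auc,
                           file.path(out_dir, paste0("auc_", tag, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (config$classify_undefined && task %in% c("C_vs_NC", "GC_vs_NGC") &&
          any(profiles$info$class_label == "UNDEF")) {
        cu <- classify_undefined(profiles, y,
                                 signature = s1$signature$probeset_ids,
                                 classifiers = config$classifiers,
                                 seed = config$seed)
        undef[[tag]] <- cu
        utils::write.table(cu$calls,
                           file.path(out_dir, paste0("undefined_calls_", tag, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  freq <- selection_frequency(sigs)
  utils::write.table(freq, file.path(out_dir, "selection_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(config, file.path(out_dir, "manifest.yaml"))
  invisible(list(signatures = sigs, reports = reports, undefined = undef))
}

write_curve_tables <- function(s1, prefix) {
  if (!is.null(s1$curves)) {
    cv <- do.call(rbind, lapply(s1$curves, function(cu)
      data.frame(method = cu$method, size = cu$sizes, mean_roc = cu$mean_roc,
                 optimum_size = cu$optimum_size)))
    utils::write.table(cv, paste0(prefix, "_roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  ki <- do.call(rbind, lapply(s1$stability, function(st)
    data.frame(method = st$method, size = st$sizes, mean_KI = st$per_size_KI)))
  utils::write.table(ki, paste0(prefix, "_ki.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Probeset selection frequency across derived signatures
#'
#' Counts, for every probeset appearing in at least one signature, how many
#' of the supplied signatures contain it (e.g. the 4 tasks x 2 durations =
#' 8 settings).
#'
#' @param signatures list of `ConsensusSignature`s or probeset-id vectors.
#' @return data.frame (`probeset_id`, `count`) sorted by descending count.
#' @export
selection_frequency <- function(signatures) {
  if (length(signatures) < 2) stop("need >= 2 signatures")
  ids <- lapply(signatures, function(s)
    if (inherits(s, "ConsensusSignature")) s$probeset_ids else as.character(s))
  tab <- table(unlist(lapply(ids, unique)))
  out <- data.frame(probeset_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$probeset_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
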