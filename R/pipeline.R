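#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Configurations can also be read from YAML with [read_pipeline_config()];
#' field names are identical.
#'
#' @param cohort_dir existing cohort root (with `annotations.csv`,
#'   `series.csv`, `images/`), or `NULL` to generate a phantom cohort.
#' @param phantom a [phantom_spec()] (used when `cohort_dir` is `NULL`).
#' @param mode `"split"` for one train/test split, `"kfold"` for a
#'   cross-validation plan.
#' @param test_fraction test fraction in split mode.
#' @param k fold count in kfold mode.
#' @param funnel a [funnel_params()].
#' @param target_size export resolution.
#' @param detector a [detector_model()] used to synthesize detections, or
#'   `NULL` to read them from `detections_csv`.
#' @param detections_csv externally produced detections (VOC CSV schema);
#'   required when `detector` is `NULL`.
#' @param tp_threshold patient-level IoU threshold for a true positive.
#' @param export_images whether dataset assembly writes image/XML payloads
#'   (`TRUE` by default in split mode; manifests are always written). In
#'   kfold mode payload export defaults to `FALSE`.
#' @param seed master seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, phantom = phantom_spec(),
                            mode = c("split", "kfold"),
                            test_fraction = 0.2, k = 10L,
                            funnel = funnel_params(), target_size = 448L,
                            detector = detector_model(),
                            detections_csv = NULL, tp_threshold = 0,
                            export_images = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(detector) && is.null(detections_csv))
    stop("either a synthetic `detector` or a `detections_csv` is required",
         call. = FALSE)
  structure(list(cohort_dir = cohort_dir, phantom = phantom, mode = mode,
                 test_fraction = test_fraction, k = as.integer(k),
                 funnel = funnel, target_size = as.integer(target_size),
                 detector = detector, detections_csv = detections_csv,
                 tp_threshold = tp_threshold,
                 export_images = export_images %||% (mode == "split"),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; the nested
#' `phantom`, `funnel` and `detector` maps are passed to their constructors.
#'
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("phantom", "funnel", "detector"))]
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$funnel)) args$funnel <- do.call(funnel_params, y$funnel)
  if (!is.null(y$detector)) args$detector <- do.call(detector_model, y$detector)
  do.call(pipeline_config, args)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

metrics_as_list <- function(cm) {
  lapply(unclass(cm), function(v) if (is.logical(v)) v else as.numeric(v))
}

#' Run the full preparation/evaluation pipeline
#'
#' Chains the stages end to end: phantom generation (or cohort ingest), the
#' fat-suppression filter, patient-wise splitting or k-fold planning,
#' funneling slice selection for training patients, dataset assembly with
#' manifests, synthetic or external detections, and patient-wise evaluation
#' (per fold plus a mean/sd aggregate in kfold mode). Every artifact lands
#' in `out_dir` and is a deterministic function of the configuration and its
#' seed. A stage failure aborts with the stage name; artifacts written so
#' far are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return list with `metrics` (a [cohort_metrics()], or per-fold list plus
#'   `aggregate` in kfold mode) and `manifest`(s), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "log.txt"), "w")
  on.exit(close(logf))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(logf, "stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort_dir <- config$cohort_dir
  if (is.null(cohort_dir)) {
    cohort_dir <- file.path(out_dir, "phantom")
    stage("phantom", {
      generate_cohort(config$phantom, cohort_dir, seed = config$seed,
                      write_images = config$export_images)
      log_line(logf, "phantom: generated %d patients under %s",
               config$phantom$n_patients, cohort_dir)
    })
  }

  cohort <- stage("ingest", {
    ch <- load_cohort(file.path(cohort_dir, "annotations.csv"), cohort_dir)
    log_line(logf, "ingest: %d patients loaded, %d errors",
             length(ch$cases), nrow(ch$errors))
    if (nrow(ch$errors))
      utils::write.csv(ch$errors, file.path(out_dir, "load_errors.csv"),
                       row.names = FALSE)
    ch
  })

  cohort <- stage("filter", {
    ch <- cohort
    ch$cases <- lapply(ch$cases, filter_fat_suppressed)
    n_bad <- sum(!vapply(ch$cases, function(cs) cs$usable, logical(1)))
    log_line(logf, "filter: fat-suppression filter left %d/%d usable patients",
             length(ch$cases) - n_bad, length(ch$cases))
    ch
  })
  usable <- names(cohort$cases)[vapply(cohort$cases, function(cs) cs$usable,
                                       logical(1))]

  selections_for <- function(ids) {
    sel <- lapply(ids, function(pid)
      select_training_slices(cohort$cases[[pid]]$annotation, config$funnel))
    names(sel) <- ids
    sel
  }
  selection_csv <- function(sel, path) {
    df <- do.call(rbind, lapply(names(sel), function(pid) {
      s <- sel[[pid]]
      data.frame(patient_id = pid, n_total = s$n_total, n_keep = s$n_keep,
                 remove_start = s$remove_start, remove_end = s$remove_end,
                 kept_first = s$kept_range[1], kept_last = s$kept_range[2])
    }))
    utils::write.csv(df, path, row.names = FALSE)
    df
  }
  detections_for <- function(path) {
    if (!is.null(config$detector)) {
      # ground truth for the synthetic detector comes from the loaded
      # annotations, so external cohorts work identically to phantoms
      gt <- do.call(rbind, lapply(usable, function(pid) {
        cs <- cohort$cases[[pid]]
        a <- cs$annotation
        data.frame(patient_id = pid, image_size = cs$image_size,
                   n_tumor = n_tumor_slices(a),
                   slice_start = a$slice_start, slice_end = a$slice_end,
                   row_min = unname(a$box["row_min"]),
                   col_min = unname(a$box["col_min"]),
                   row_max = unname(a$box["row_max"]),
                   col_max = unname(a$box["col_max"]),
                   stringsAsFactors = FALSE)
      }))
      generate_detections(gt, config$detector, seed = config$seed + 1L, path = path)
    } else {
      utils::read.csv(config$detections_csv, stringsAsFactors = FALSE)
    }
  }

  if (config$mode == "split") {
    split <- stage("split", {
      sp <- split_patients(usable, config$test_fraction, seed = config$seed)
      log_line(logf, "split: %d train / %d test patients",
               length(sp$train), length(sp$test))
      sp
    })
    sel <- stage("select", {
      s <- selections_for(split$train)
      df <- selection_csv(s, file.path(out_dir, "selection.csv"))
      log_line(logf, "select: kept %d of %d tumor slices across training patients",
               sum(df$n_keep), sum(df$n_total))
      s
    })
    manifest <- stage("build", {
      m <- assemble_dataset(cohort, split, sel, file.path(out_dir, "dataset"),
                            target_size = config$target_size,
                            copy = config$export_images)
      log_line(logf, "build: %d train images, %d test images",
               sum(m$subset == "train"), sum(m$subset == "test"))
      m
    })
    dets <- stage("detect", detections_for(file.path(out_dir, "detections.csv")))
    res <- stage("evaluate", {
      ev <- evaluate_cohort(cohort, dets, patient_ids = split$test,
                            tp_threshold = config$tp_threshold)
      log_line(logf, "evaluate: accuracy %.2f%% (%d TP / %d FN)",
               ev$metrics$accuracy_pct, ev$metrics$tp_count, ev$metrics$fn_count)
      ev
    })
    jsonlite::write_json(metrics_as_list(res$metrics),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(metrics = res$metrics, manifest = manifest))
  } else {
    plan <- stage("folds", {
      pl <- make_fold_plan(usable, k = config$k, seed = config$seed)
      write_fold_plan(pl, file.path(out_dir, "folds.csv"))
      log_line(logf, "folds: k = %d, fold size %d, %d remainder",
               pl$k, pl$fold_size, sum(is.na(pl$assignments)))
      pl
    })
    dets <- stage("detect", detections_for(file.path(out_dir, "detections.csv")))
    per_fold <- vector("list", plan$k)
    manifests <- vector("list", plan$k)
    for (f in seq_len(plan$k)) {
      split <- fold_split(plan, f)
      sel <- selections_for(split$train)
      fold_dir <- file.path(out_dir, sprintf("fold%02d", f))
      dir.create(fold_dir, showWarnings = FALSE)
      selection_csv(sel, file.path(fold_dir, "selection.csv"))
      manifests[[f]] <- stage(sprintf("build fold %d", f),
        assemble_dataset(cohort, split, sel, fold_dir,
                         target_size = config$target_size,
                         copy = config$export_images))
      per_fold[[f]] <- stage(sprintf("evaluate fold %d", f), {
        ev <- evaluate_cohort(cohort, dets, patient_ids = split$test,
                              tp_threshold = config$tp_threshold)
        jsonlite::write_json(metrics_as_list(ev$metrics),
                             file.path(fold_dir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        log_line(logf, "fold %d: accuracy %.2f%% (%d TP / %d FN)",
                 f, ev$metrics$accuracy_pct, ev$metrics$tp_count,
                 ev$metrics$fn_count)
        ev$metrics
      })
    }
    agg <- aggregate_folds(per_fold)
    utils::write.csv(agg, file.path(out_dir, "aggregate.csv"), row.names = FALSE)
    log_line(logf, "aggregate: mean accuracy %.2f%% +- %.2f%%",
             agg$mean[agg$metric == "accuracy_pct"],
             agg$sd[agg$metric == "accuracy_pct"])
    invisible(list(metrics = per_fold, aggregate = agg, manifests = manifests))
  }
}
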