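#' Intersection over union of two boxes
#'
#' `area(a intersect b) / area(a union b)` for half-open boxes; symmetric,
#' in `[0, 1]`, 0 for disjoint boxes.
#'
#' @param a,b [box2d()] objects.
#' @return numeric scalar in `[0, 1]`.
#' @examples
#' iou(box2d(0, 0, 10, 10), box2d(0, 0, 10, 10)) # 1
#' iou(box2d(0, 0, 1, 1), box2d(0, 0.5, 1, 1.5)) # 1/3
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "box2d"), inherits(b, "box2d"))
  ih <- min(a["row_max"], b["row_max"]) - max(a["row_min"], b["row_min"])
  iw <- min(a["col_max"], b["col_max"]) - max(a["col_min"], b["col_min"])
  if (ih <= 0 || iw <= 0) return(0)
  inter <- ih * iw
  unname(inter / (box_area(a) + box_area(b) - inter))
}

#' Evaluate one patient's detections against its annotation
#'
#' For every annotated slice, the matched detection is the one with maximal
#' IoU against the ground-truth box (ties broken by higher score, then input
#' order). Slices with no detection, or whose best match has zero overlap,
#' contribute IoU 0 and count as false-negative slices. The patient is a
#' true positive if any annotated slice overlaps a detection with
#' `IoU > tp_threshold` (default 0, i.e. any overlap at all).
#'
#' Detections on slices outside the annotated range cannot be validated
#' (there is no ground truth there); they are ignored by the metrics but
#' tallied in `fp_slice_count` for information.
#'
#' @param annotation an [annotation3d()] at evaluation resolution.
#' @param detections data.frame with columns `slice_index` (0-based),
#'   `row_min`, `col_min`, `row_max`, `col_max` (internal 0-based half-open)
#'   and `score` in `[0, 1]`. May have zero rows.
#' @param tp_threshold IoU above which a patient counts as detected.
#' @return An object of class `patient_eval`: list with `per_slice_iou`
#'   (one value per annotated slice, zeros included), `per_slice_score`
#'   (matched-detection scores, `NA` where no overlapping match), `max_iou`,
#'   `score_at_max_iou`, `is_tp`, `fn_slice_count`, `fp_slice_count`.
#' @export
evaluate_patient <- function(annotation, detections, tp_threshold = 0) {
  stopifnot(inherits(annotation, "annotation3d"))
  if (is.null(detections) || nrow(detections) == 0L) {
    detections <- data.frame(slice_index = integer(), row_min = numeric(),
                             col_min = numeric(), row_max = numeric(),
                             col_max = numeric(), score = numeric())
  }
  req <- c("slice_index", "row_min", "col_min", "row_max", "col_max", "score")
  if (!all(req %in% names(detections)))
    stop("detections need columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (any(detections$score < 0 | detections$score > 1))
    stop("detection scores must lie in [0, 1]", call. = FALSE)

  slices <- annotation$slice_start:annotation$slice_end
  gt <- annotation$box
  per_iou <- numeric(length(slices))
  per_score <- rep(NA_real_, length(slices))

  for (i in seq_along(slices)) {
    d <- detections[detections$slice_index == slices[i], , drop = FALSE]
    if (nrow(d) == 0L) next
    ious <- vapply(seq_len(nrow(d)), function(j) {
      iou(gt, box2d(d$row_min[j], d$col_min[j], d$row_max[j], d$col_max[j]))
    }, numeric(1))
    # matched detection: max IoU, ties -> higher score, then first
    best <- order(-ious, -d$score)[1L]
    per_iou[i] <- ious[best]
    if (ious[best] > 0) per_score[i] <- d$score[best]
  }

  max_i <- which.max(per_iou)
  max_iou <- per_iou[max_i]
  structure(list(
    per_slice_iou = stats::setNames(per_iou, slices),
    per_slice_score = stats::setNames(per_score, slices),
    max_iou = max_iou,
    score_at_max_iou = if (max_iou > 0) per_score[max_i] else 0,
    is_tp = max_iou > tp_threshold,
    fn_slice_count = sum(per_iou == 0),
    fp_slice_count = sum(!detections$slice_index %in% slices)
  ), class = "patient_eval")
}

#' @export
print.patient_eval <- function(x, ...) {
  cat(sprintf("<patient_eval> %s: max IoU %.3f, %d/%d FN slices\n",
              if (x$is_tp) "TP" else "FN", x$max_iou,
              x$fn_slice_count, length(x$per_slice_iou)))
  invisible(x)
}

# per-patient summaries feeding the cohort averages
patient_summary <- function(ev) {
  iou <- ev$per_slice_iou
  sc <- ev$per_slice_score
  pos <- iou > 0
  c(iou_all = mean(iou),
    iou_pos = if (any(pos)) mean(iou[pos]) else NA_real_,
    score_all = mean(ifelse(is.na(sc), 0, sc)),
    score_pos = if (any(pos)) mean(sc[pos]) else NA_real_,
    max_iou = ev$max_iou,
    score_at_max_iou = ev$score_at_max_iou)
}

#' Cohort-level detection metrics
#'
#' Aggregates per-patient evaluations into the patient-wise metric set:
#' TP/FN counts and accuracy, plus the IoU and score averages in two
#' variants. The `all` variant averages over every patient, with
#' false-negative patients contributing zeros; the `pos` (`IoU > 0`) variant
#' restricts to true-positive patients (and, within a patient, to slices
#' with positive overlap for the per-slice metrics), so `pos >= all` always.
#' IoU and score metrics are fractions in `[0, 1]`; accuracy is a percentage.
#'
#' @param evals non-empty list of [evaluate_patient()] results.
#' @return An object of class `cohort_metrics`: list with `n_patients`,
#'   `tp_count`, `fn_count`, `accuracy_pct`, `avg_iou_all`, `avg_iou_pos`,
#'   `avg_score_all`, `avg_score_pos`, `avg_max_iou_all`, `avg_max_iou_pos`,
#'   `avg_score_at_max_iou_all`, `avg_score_at_max_iou_pos`,
#'   `fn_slices_total`, `fp_slices_total` and `no_tp` (degenerate-cohort
#'   flag; when set, the `pos` variants are reported as 0).
#' @export
cohort_metrics <- function(evals) {
  if (length(evals) == 0L) stop("need at least one patient evaluation", call. = FALSE)
  stopifnot(all(vapply(evals, inherits, logical(1), "patient_eval")))
  smry <- t(vapply(evals, patient_summary, numeric(6)))
  tp <- vapply(evals, function(e) e$is_tp, logical(1))
  no_tp <- !any(tp)
  pos_mean <- function(x) if (no_tp) 0 else mean(x[tp], na.rm = TRUE)
  structure(list(
    n_patients = length(evals),
    tp_count = sum(tp),
    fn_count = sum(!tp),
    accuracy_pct = 100 * sum(tp) / length(tp),
    avg_iou_all = mean(smry[, "iou_all"]),
    avg_iou_pos = pos_mean(smry[, "iou_pos"]),
    avg_score_all = mean(smry[, "score_all"]),
    avg_score_pos = pos_mean(smry[, "score_pos"]),
    avg_max_iou_all = mean(smry[, "max_iou"]),
    avg_max_iou_pos = pos_mean(smry[, "max_iou"]),
    avg_score_at_max_iou_all = mean(smry[, "score_at_max_iou"]),
    avg_score_at_max_iou_pos = pos_mean(smry[, "score_at_max_iou"]),
    fn_slices_total = sum(vapply(evals, function(e) e$fn_slice_count, numeric(1))),
    fp_slices_total = sum(vapply(evals, function(e) e$fp_slice_count, numeric(1))),
    no_tp = no_tp
  ), class = "cohort_metrics")
}

#' @export
print.cohort_metrics <- function(x, ...) {
  cat(sprintf("<cohort_metrics> %d patients: TP %d, FN %d, accuracy %.2f%%\n",
              x$n_patients, x$tp_count, x$fn_count, x$accuracy_pct))
  cat(sprintf("  avg IoU %.2f%% (all) / %.2f%% (IoU>0); avg max IoU %.2f%% / %.2f%%\n",
              100 * x$avg_iou_all, 100 * x$avg_iou_pos,
              100 * x$avg_max_iou_all, 100 * x$avg_max_iou_pos))
  cat(sprintf("  avg score %.2f%% / %.2f%%; score @ max IoU %.2f%% / %.2f%%; FN slices %d\n",
              100 * x$avg_score_all, 100 * x$avg_score_pos,
              100 * x$avg_score_at_max_iou_all, 100 * x$avg_score_at_max_iou_pos,
              x$fn_slices_total))
  invisible(x)
}

#' Mean and standard deviation of metrics across folds
#'
#' Cross-validation summary: the arithmetic mean and the sample standard
#' deviation (denominator `n - 1`) of every numeric metric across folds.
#'
#' @param per_fold list (length >= 2) of [cohort_metrics()] results.
#' @return data.frame with columns `metric`, `mean`, `sd`.
#' @export
aggregate_folds <- function(per_fold) {
  if (length(per_fold) < 2L)
    stop("need at least 2 folds for a standard deviation", call. = FALSE)
  stopifnot(all(vapply(per_fold, inherits, logical(1), "cohort_metrics")))
  fields <- c("tp_count", "fn_count", "accuracy_pct",
              "avg_iou_all", "avg_iou_pos", "avg_score_all", "avg_score_pos",
              "avg_max_iou_all", "avg_max_iou_pos",
              "avg_score_at_max_iou_all", "avg_score_at_max_iou_pos",
              "fn_slices_total")
  m <- vapply(per_fold, function(cm) unlist(cm[fields]), numeric(length(fields)))
  data.frame(metric = fields,
             mean = apply(m, 1, mean),
             sd = apply(m, 1, stats::sd),
             row.names = NULL)
}

#' Read a detections CSV
#'
#' Expects Pascal VOC 1-based inclusive pixel coordinates (`xmin`, `ymin`,
#' `xmax`, `ymax`; x = column, y = row) with a 0-based `slice_index`, as the
#' synthetic detector writes them, and converts to the internal 0-based
#' half-open row/col convention.
#'
#' @param path CSV with columns `patient_id`, `slice_index`, `xmin`, `ymin`,
#'   `xmax`, `ymax`, `score`.
#' @return data.frame with columns `patient_id`, `slice_index`, `row_min`,
#'   `col_min`, `row_max`, `col_max`, `score`.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "slice_index", "xmin", "ymin", "xmax", "ymax", "score")
  if (!all(req %in% names(df)))
    stop("detections CSV needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  data.frame(patient_id = as.character(df$patient_id),
             slice_index = as.integer(df$slice_index),
             row_min = df$ymin - 1, col_min = df$xmin - 1,
             row_max = as.numeric(df$ymax), col_max = as.numeric(df$xmax),
             score = df$score)
}

#' Convert VOC-convention detections to the internal convention
#'
#' @param df data.frame with `xmin`, `ymin`, `xmax`, `ymax` (1-based
#'   inclusive, x = column) plus any other columns, which are kept.
#' @return the same data.frame with `row_min`, `col_min`, `row_max`,
#'   `col_max` (0-based half-open) in place of the VOC columns.
#' @export
voc_to_internal <- function(df) {
  out <- df[setdiff(names(df), c("xmin", "ymin", "xmax", "ymax"))]
  out$row_min <- df$ymin - 1
  out$col_min <- df$xmin - 1
  out$row_max <- as.numeric(df$ymax)
  out$col_max <- as.numeric(df$xmax)
  out
}

#' Evaluate a whole cohort against a detections table
#'
#' Groups detections by patient, evaluates each annotated patient and
#' aggregates. Patients with no detection rows are evaluated against an
#' empty table (false negatives).
#'
#' @param cohort a [load_cohort()] result; unusable cases are skipped.
#' @param detections detections data.frame; `convention = "voc"` (default,
#'   the CSV schema of [generate_detections()]) or `"internal"`.
#' @param patient_ids optional subset of patients to evaluate (e.g. a test
#'   fold); defaults to every usable case.
#' @param tp_threshold passed to [evaluate_patient()].
#' @param convention coordinate convention of `detections`.
#' @return list with `metrics` ([cohort_metrics()]) and `evals` (named list
#'   of [evaluate_patient()] results).
#' @export
evaluate_cohort <- function(cohort, detections, patient_ids = NULL,
                            tp_threshold = 0,
                            convention = c("voc", "internal")) {
  stopifnot(inherits(cohort, "cohort"))
  convention <- match.arg(convention)
  if (convention == "voc") detections <- voc_to_internal(detections)
  usable <- names(cohort$cases)[vapply(cohort$cases, function(cs) isTRUE(cs$usable),
                                       logical(1))]
  ids <- patient_ids %||% usable
  bad <- setdiff(ids, usable)
  if (length(bad))
    stop("not usable/loaded patients: ", paste(bad, collapse = ", "), call. = FALSE)
  evals <- lapply(ids, function(pid) {
    d <- detections[detections$patient_id == pid, , drop = FALSE]
    evaluate_patient(cohort$cases[[pid]]$annotation, d, tp_threshold)
  })
  names(evals) <- ids
  list(metrics = cohort_metrics(evals), evals = evals)
}
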