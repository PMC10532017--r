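#' Read a clinical-style annotation table
#'
#' The table is a flat CSV with one lesion annotation per patient:
#' `patient_id, series_id, start_slice, end_slice, start_row, end_row,
#' start_col, end_col`, with coordinates 1-based and inclusive as clinical
#' annotation exports typically are (`coordinate_base = "one"`). On load they
#' are converted once, centrally, to the internal 0-based half-open
#' convention.
#'
#' @param path CSV path.
#' @param coordinate_base `"one"` (1-based inclusive input, the default) or
#'   `"zero"` (already 0-based half-open).
#' @return data.frame with columns `patient_id`, `series_id`, `slice_start`,
#'   `slice_end`, `row_min`, `col_min`, `row_max`, `col_max` in internal
#'   convention.
#' @export
read_annotation_table <- function(path, coordinate_base = c("one", "zero")) {
  coordinate_base <- match.arg(coordinate_base)
  if (!file.exists(path)) stop("annotation table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "series_id", "start_slice", "end_slice",
           "start_row", "end_row", "start_col", "end_col")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("annotation table must have one row per patient", call. = FALSE)
  num <- c("start_slice", "end_slice", "start_row", "end_row", "start_col", "end_col")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v) | v != floor(v))
    if (length(bad))
      stop(sprintf("annotation row %d (patient %s): column '%s' is not an integer",
                   bad[1], df$patient_id[bad[1]], cn), call. = FALSE)
    df[[cn]] <- as.integer(v)
  }
  off <- if (coordinate_base == "one") 1L else 0L
  out <- data.frame(patient_id = as.character(df$patient_id),
                    series_id = as.character(df$series_id),
                    slice_start = df$start_slice - off,
                    slice_end = df$end_slice - off,
                    row_min = df$start_row - off,
                    col_min = df$start_col - off,
                    # 1-based inclusive max equals 0-based half-open max
                    row_max = df$end_row - off + if (coordinate_base == "one") 1L else 0L,
                    col_max = df$end_col - off + if (coordinate_base == "one") 1L else 0L,
                    stringsAsFactors = FALSE)
  bad <- which(out$slice_end < out$slice_start)
  if (length(bad))
    stop(sprintf("annotation row %d (patient %s): end slice precedes start slice",
                 bad[1], out$patient_id[bad[1]]), call. = FALSE)
  bad <- which(out$row_min >= out$row_max | out$col_min >= out$col_max |
                 out$row_min < 0 | out$col_min < 0 | out$slice_start < 0)
  if (length(bad))
    stop(sprintf("annotation row %d (patient %s): degenerate or negative box",
                 bad[1], out$patient_id[bad[1]]), call. = FALSE)
  out
}

# order a series directory's slice files by instance number (ties: filename)
order_slice_files <- function(files) {
  inst <- as.integer(sub("^.*I(\\d+)\\.png$", "\\1", basename(files)))
  if (any(is.na(inst)))
    stop("slice filenames must look like I<instance>.png", call. = FALSE)
  files[order(inst, basename(files))]
}

#' Load a patient cohort from disk
#'
#' Reads the annotation table plus a series-metadata sidecar CSV
#' (`series.csv` in `image_root`: `patient_id, series_id, scan_options,
#' n_slices, image_size`) and the per-series PNG slice stacks under
#' `image_root/images/<patient>/<series>/I<instance>.png`. Slices are ordered
#' by ascending instance number (ties broken by filename), so a shuffled
#' directory listing yields the same stack. A series is flagged
#' fat-suppressed when its scan-options text matches `fat_regex`
#' (case-insensitive), since only fat-suppressed acquisitions carry valid
#' lesion annotations in this dataset.
#'
#' Patients whose image directory is missing are recorded in the cohort's
#' `errors` and skipped; a malformed annotation row aborts the load.
#'
#' @param annotation_csv annotation table path (see
#'   [read_annotation_table()]).
#' @param image_root cohort root containing `series.csv` and `images/`.
#' @param fat_regex regular expression identifying fat-suppressed
#'   scan-options text (default: contains the token `FS`).
#' @param coordinate_base passed to [read_annotation_table()].
#' @return An object of class `cohort`: list with `cases` (named list of
#'   `patient_case`) and `errors` (data.frame `patient_id`, `message`).
#'   Each `patient_case` holds `patient_id`, `image_size`, `series` (named
#'   list: `series_id`, `scan_options`, `fat_suppressed`, `n_slices`,
#'   `slice_order`, `slice_files`), `annotation` ([annotation3d()]),
#'   `annotated_series` and `usable`.
#' @export
load_cohort <- function(annotation_csv, image_root,
                        fat_regex = "(^|[^A-Z])FS([^A-Z]|$)",
                        coordinate_base = "one") {
  ann <- read_annotation_table(annotation_csv, coordinate_base)
  series_csv <- file.path(image_root, "series.csv")
  if (!file.exists(series_csv))
    stop("series metadata not found: ", series_csv, call. = FALSE)
  smeta <- utils::read.csv(series_csv, stringsAsFactors = FALSE)
  smeta$patient_id <- as.character(smeta$patient_id)
  smeta$series_id <- as.character(smeta$series_id)

  cases <- list()
  errors <- data.frame(patient_id = character(), message = character(),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ann))) {
    pid <- ann$patient_id[i]
    res <- tryCatch(
      load_patient_case(ann[i, ], smeta[smeta$patient_id == pid, , drop = FALSE],
                        image_root, fat_regex),
      patient_load_error = function(e) e)
    if (inherits(res, "patient_load_error")) {
      errors <- rbind(errors, data.frame(patient_id = pid,
                                         message = conditionMessage(res),
                                         stringsAsFactors = FALSE))
    } else {
      cases[[pid]] <- res
    }
  }
  structure(list(cases = cases, errors = errors), class = "cohort")
}

patient_error <- function(fmt, ...) {
  stop(structure(class = c("patient_load_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

load_patient_case <- function(ann_row, smeta, image_root, fat_regex) {
  pid <- ann_row$patient_id
  if (nrow(smeta) == 0L)
    patient_error("patient %s: no series metadata", pid)
  pdir <- file.path(image_root, "images", pid)
  if (!dir.exists(pdir))
    patient_error("patient %s: image directory missing", pid)
  image_size <- unique(smeta$image_size)
  if (length(image_size) != 1L)
    patient_error("patient %s: image size differs across series", pid)

  series <- list()
  for (j in seq_len(nrow(smeta))) {
    sid <- smeta$series_id[j]
    sdir <- file.path(pdir, sid)
    if (dir.exists(sdir)) {
      files <- order_slice_files(list.files(sdir, pattern = "^I\\d+\\.png$",
                                            full.names = TRUE))
      slice_order <- as.integer(sub("^I(\\d+)\\.png$", "\\1", basename(files)))
      if (anyDuplicated(slice_order))
        patient_error("patient %s series %s: duplicate instance numbers", pid, sid)
      if (length(files) != smeta$n_slices[j])
        patient_error("patient %s series %s: %d files but metadata says %d slices",
                      pid, sid, length(files), smeta$n_slices[j])
    } else {
      # metadata-only series (pixel data not materialized)
      slice_order <- seq_len(smeta$n_slices[j])
      files <- rep(NA_character_, smeta$n_slices[j])
    }
    series[[sid]] <- list(
      series_id = sid,
      scan_options = smeta$scan_options[j],
      fat_suppressed = grepl(fat_regex, smeta$scan_options[j], ignore.case = TRUE),
      n_slices = as.integer(smeta$n_slices[j]),
      slice_order = slice_order,
      slice_files = files)
  }

  tgt <- ann_row$series_id
  if (is.null(series[[tgt]]))
    patient_error("patient %s: annotated series %s not in metadata", pid, tgt)
  if (ann_row$slice_end >= series[[tgt]]$n_slices)
    patient_error("patient %s: annotation slice range exceeds series length", pid)
  if (ann_row$row_max > image_size || ann_row$col_max > image_size)
    patient_error("patient %s: annotation box exceeds image size", pid)

  structure(list(
    patient_id = pid,
    image_size = as.integer(image_size),
    series = series,
    annotated_series = tgt,
    annotation = annotation3d(
      box2d(ann_row$row_min, ann_row$col_min, ann_row$row_max, ann_row$col_max),
      ann_row$slice_start, ann_row$slice_end),
    usable = TRUE
  ), class = "patient_case")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients loaded, %d load errors\n",
              length(x$cases), nrow(x$errors)))
  invisible(x)
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: %dpx, %d series (annotated: %s), ",
              x$patient_id, x$image_size, length(x$series), x$annotated_series))
  print(x$annotation)
  invisible(x)
}

#' Drop non-fat-suppressed series from a patient case
#'
#' Keeps only the series whose scan options flagged them fat-suppressed; the
#' annotation is untouched. A case left with zero series is flagged unusable
#' (with a warning) so downstream stages can exclude it; the patient itself
#' is never dropped here.
#'
#' @param case a `patient_case`.
#' @return The filtered `patient_case`.
#' @export
filter_fat_suppressed <- function(case) {
  stopifnot(inherits(case, "patient_case"))
  keep <- vapply(case$series, function(s) s$fat_suppressed, logical(1))
  case$series <- case$series[keep]
  if (length(case$series) == 0L) {
    warning(sprintf("patient %s: no fat-suppressed series remain; flagged unusable",
                    case$patient_id), call. = FALSE)
    case$usable <- FALSE
  }
  case
}

#' Per-slice records of one series
#'
#' Flattens a series stack into one row per slice for export and bookkeeping.
#'
#' @param case a `patient_case`.
#' @param series_id which series; defaults to the annotated one.
#' @return data.frame with columns `patient_id`, `series_id`, `slice_index`
#'   (0-based position in the instance-ordered stack), `instance`, `file`,
#'   `image_size`.
#' @export
slice_records <- function(case, series_id = case$annotated_series) {
  stopifnot(inherits(case, "patient_case"))
  s <- case$series[[series_id]]
  if (is.null(s)) stop("no such series: ", series_id, call. = FALSE)
  data.frame(patient_id = case$patient_id,
             series_id = series_id,
             slice_index = seq_along(s$slice_order) - 1L,
             instance = s$slice_order,
             file = s$slice_files,
             image_size = case$image_size,
             stringsAsFactors = FALSE)
}
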