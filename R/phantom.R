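#' Phantom cohort specification
#'
#' Parameters of the synthetic cohort generator, whose defaults mirror the
#' source cohort's structure: square slices of 320/448/512 px with weights
#' proportional to the observed 33/261/628 case counts, one lesion per
#' patient with a tumor slice count drawn from the cohort's empirical
#' distribution (support 2-131), 5-6 series per patient of which one - always
#' fat-suppressed - carries the annotation, and lesions whose cross-section
#' shrinks toward the slice-range extremities so that the single 3D box
#' (tight around the central cross-section) is loose on the edge slices.
#'
#' Lesions are superellipsoids: in-plane cross-sections are superellipses
#' with exponent `shape_exponent` (default 4, filling ~93% of the tight
#' box), scaled along the stack by an elliptical profile.
#'
#' @param n_patients cohort size.
#' @param image_sizes,image_size_weights candidate slice sizes and their
#'   sampling weights.
#' @param slice_count_table data.frame `n_slices`/`count`: the tumor
#'   slice-count sampling distribution.
#' @param semi_axis_range in-plane lesion semi-axis range, px.
#' @param series_range min/max series per patient.
#' @param fat_fraction probability that a non-annotated series is
#'   fat-suppressed.
#' @param margin_range min/max non-tumor slices padded on each side of the
#'   tumor range in the annotated series.
#' @param bg_level,lesion_level,noise_sd image model: background and lesion
#'   intensities plus Gaussian noise, on `[0, 1]`.
#' @param shape_exponent superellipse exponent of the in-plane cross-section.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 20L,
                         image_sizes = c(320L, 448L, 512L),
                         image_size_weights = c(33, 261, 628),
                         slice_count_table = duke_slice_count_table(),
                         semi_axis_range = c(8, 40),
                         series_range = c(5L, 6L),
                         fat_fraction = 0.5,
                         margin_range = c(2L, 6L),
                         bg_level = 0.2, lesion_level = 0.9, noise_sd = 0.05,
                         shape_exponent = 4) {
  stop_if_not_count(n_patients, "n_patients")
  stopifnot(length(image_sizes) == length(image_size_weights),
            all(image_size_weights > 0),
            all(c("n_slices", "count") %in% names(slice_count_table)),
            all(slice_count_table$count > 0),
            all(slice_count_table$n_slices >= 1),
            semi_axis_range[1] > 0, semi_axis_range[1] <= semi_axis_range[2],
            series_range[1] >= 1, series_range[1] <= series_range[2],
            margin_range[1] >= 0, margin_range[1] <= margin_range[2],
            shape_exponent >= 2)
  structure(list(n_patients = as.integer(n_patients),
                 image_sizes = as.integer(image_sizes),
                 image_size_weights = image_size_weights,
                 slice_count_table = slice_count_table,
                 semi_axis_range = semi_axis_range,
                 series_range = as.integer(series_range),
                 fat_fraction = fat_fraction,
                 margin_range = as.integer(margin_range),
                 bg_level = bg_level, lesion_level = lesion_level,
                 noise_sd = noise_sd,
                 shape_exponent = shape_exponent),
            class = "phantom_spec")
}

# tight 0-based half-open bound of the superellipse cross-section with
# semi-axes (ar, ac) centered at (cr, cc), on the integer pixel grid
tight_box_bounds <- function(cr, cc, ar, ac) {
  c(row_min = ceiling(cr - ar), col_min = ceiling(cc - ac),
    row_max = floor(cr + ar) + 1, col_max = floor(cc + ac) + 1)
}

# in-plane scale of the cross-section at `d` slices from the lesion center,
# for a lesion of slice half-extent h (axial semi-axis h + 0.5)
axial_scale <- function(d, h) {
  a_s <- h + 0.5
  sqrt(pmax(0, 1 - (d / a_s)^2))
}

#' Lesion cross-section mask for one slice
#'
#' Boolean pixel mask of the phantom lesion on a given slice; exported for
#' geometry checks (fill fractions, centroids) in analyses and tests.
#'
#' @param geom one row of the ground-truth table produced by
#'   [sample_phantom_cohort()] (list or data.frame row).
#' @param slice_index 0-based slice index within the annotated series.
#' @param image_size frame side length.
#' @param shape_exponent superellipse exponent.
#' @return logical matrix `image_size x image_size`.
#' @export
lesion_mask <- function(geom, slice_index, image_size, shape_exponent = 4) {
  h <- (geom$n_tumor - 1) / 2
  center_slice <- geom$slice_start + h
  s <- axial_scale(slice_index - center_slice, h)
  if (s <= 0) return(matrix(FALSE, image_size, image_size))
  r <- abs(seq_len(image_size) - 1 - geom$center_row) / (s * geom$semi_row)
  cc <- abs(seq_len(image_size) - 1 - geom$center_col) / (s * geom$semi_col)
  outer(r^shape_exponent, cc^shape_exponent, `+`) <= 1
}

#' Sample the ground-truth geometry of a phantom cohort
#'
#' Draws every random quantity of the cohort - image sizes, series layouts,
#' tumor slice counts, lesion centers and semi-axes - without writing any
#' pixel data. [generate_cohort()] materializes images from this table.
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed; the whole cohort is a deterministic function of it.
#' @return list with `patients` (one row per patient: ids, image size,
#'   lesion geometry, annotation bounds) and `series` (one row per series:
#'   `patient_id`, `series_id`, `scan_options`, `n_slices`, `image_size`,
#'   `annotated`).
#' @export
sample_phantom_cohort <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    n <- spec$n_patients
    pid <- sprintf("P%04d", seq_len(n))
    image_size <- spec$image_sizes[sample.int(length(spec$image_sizes), n,
                                              replace = TRUE,
                                              prob = spec$image_size_weights)]
    tab <- spec$slice_count_table
    n_tumor <- tab$n_slices[sample.int(nrow(tab), n, replace = TRUE,
                                       prob = tab$count)]
    margin_lo <- sample(spec$margin_range[1]:spec$margin_range[2], n, replace = TRUE)
    margin_hi <- sample(spec$margin_range[1]:spec$margin_range[2], n, replace = TRUE)
    semi_row <- stats::runif(n, spec$semi_axis_range[1],
                             pmin(spec$semi_axis_range[2], image_size / 4))
    semi_col <- stats::runif(n, spec$semi_axis_range[1],
                             pmin(spec$semi_axis_range[2], image_size / 4))
    # keep the full box inside the frame with a small margin
    center_row <- stats::runif(n, semi_row + 2, image_size - semi_row - 3)
    center_col <- stats::runif(n, semi_col + 2, image_size - semi_col - 3)

    patients <- data.frame(patient_id = pid, image_size = image_size,
                           n_tumor = n_tumor,
                           slice_start = margin_lo,
                           slice_end = margin_lo + n_tumor - 1L,
                           n_slices = margin_lo + n_tumor + margin_hi,
                           center_row = center_row, center_col = center_col,
                           semi_row = semi_row, semi_col = semi_col,
                           stringsAsFactors = FALSE)
    bounds <- t(mapply(tight_box_bounds, center_row, center_col, semi_row, semi_col))
    patients$row_min <- as.integer(bounds[, "row_min"])
    patients$col_min <- as.integer(bounds[, "col_min"])
    patients$row_max <- as.integer(bounds[, "row_max"])
    patients$col_max <- as.integer(bounds[, "col_max"])
    patients$annotated_series <- "S1"

    series <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- sample(spec$series_range[1]:spec$series_range[2], 1L)
      sid <- sprintf("S%d", seq_len(k))
      fs <- c(TRUE, stats::runif(k - 1) < spec$fat_fraction)
      nsl <- c(patients$n_slices[i],
               sample(20:60, k - 1, replace = TRUE))
      data.frame(patient_id = pid[i], series_id = sid,
                 scan_options = ifelse(fs, "FS SAT", "NONE"),
                 n_slices = nsl, image_size = image_size[i],
                 annotated = sid == "S1", stringsAsFactors = FALSE)
    }))
    list(patients = patients, series = series)
  })
}

# render one slice of a phantom patient as a [0,1] grayscale matrix
render_phantom_slice <- function(geom, slice_index, spec) {
  sz <- geom$image_size
  img <- matrix(stats::rnorm(sz * sz, spec$bg_level, spec$noise_sd), sz, sz)
  if (slice_index >= geom$slice_start && slice_index <= geom$slice_end) {
    m <- lesion_mask(geom, slice_index, sz, spec$shape_exponent)
    img[m] <- stats::rnorm(sum(m), spec$lesion_level, spec$noise_sd)
  }
  clamp(img, 0, 1)
}

#' Generate a phantom cohort on disk
#'
#' Writes, under `out_dir`, the ingest-dialect cohort: `annotations.csv`
#' (1-based inclusive clinical convention), `series.csv`, and - for the
#' annotated series of every patient - a PNG slice stack
#' `images/<patient>/<series>/I<instance>.png`. Non-annotated series appear
#' as metadata only (their pixel payloads are irrelevant to every downstream
#' stage). Byte-identical output under a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created).
#' @param seed RNG seed.
#' @param write_images if `FALSE`, write only the CSVs (sufficient for
#'   selection/partition/evaluation workflows that never touch pixels).
#' @return the [sample_phantom_cohort()] ground truth, invisibly.
#' @export
generate_cohort <- function(spec = phantom_spec(), out_dir, seed = 1L,
                            write_images = TRUE) {
  gt <- sample_phantom_cohort(spec, seed)
  p <- gt$patients
  if (any(p$row_min < 0 | p$col_min < 0 |
            p$row_max > p$image_size | p$col_max > p$image_size))
    stop("infeasible phantom spec: lesion exceeds the frame", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ann <- data.frame(patient_id = p$patient_id,
                    series_id = p$annotated_series,
                    start_slice = p$slice_start + 1L,
                    end_slice = p$slice_end + 1L,
                    start_row = p$row_min + 1L,
                    end_row = p$row_max,     # 1-based inclusive == half-open max
                    start_col = p$col_min + 1L,
                    end_col = p$col_max)
  utils::write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE)
  utils::write.csv(gt$series[, c("patient_id", "series_id", "scan_options",
                                 "n_slices", "image_size")],
                   file.path(out_dir, "series.csv"), row.names = FALSE)

  if (write_images) {
    with_seed(seed + 1L, {
      for (i in seq_len(nrow(p))) {
        geom <- as.list(p[i, ])
        sdir <- file.path(out_dir, "images", geom$patient_id, geom$annotated_series)
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        for (s in seq_len(geom$n_slices) - 1L) {
          png::writePNG(render_phantom_slice(geom, s, spec),
                        file.path(sdir, sprintf("I%d.png", s + 1L)))
        }
      }
    })
  } else {
    # image directories must exist for the loader's metadata-only mode
    for (i in seq_len(nrow(p)))
      dir.create(file.path(out_dir, "images", p$patient_id[i]),
                 recursive = TRUE, showWarnings = FALSE)
  }
  invisible(gt)
}

#' Synthetic detector model
#'
#' A stochastic stand-in for a trained lesion detector, used to exercise the
#' evaluation stack with known operating characteristics. Per patient, the
#' whole case is missed with probability `miss_rate` (no detections at all);
#' otherwise each tumor slice independently yields a detection with
#' probability `p_detect` (optionally scaled by the slice's lesion
#' cross-section fill fraction), whose box is the ground-truth box with
#' i.i.d. Gaussian corner jitter and whose score is a clipped Gaussian.
#'
#' @param p_detect per-slice detection probability.
#' @param miss_rate per-patient probability of a complete miss (the expected
#'   patient-wise FN fraction when `p_detect = 1`).
#' @param jitter_sd corner jitter standard deviation, px.
#' @param score_mean,score_sd score distribution (clipped to `[0, 1]`).
#' @param area_scaling if `TRUE`, multiply `p_detect` by the slice's
#'   cross-section area relative to the central slice.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(p_detect = 1, miss_rate = 0, jitter_sd = 0,
                           score_mean = 0.9, score_sd = 0.05,
                           area_scaling = FALSE) {
  stopifnot(p_detect >= 0, p_detect <= 1, miss_rate >= 0, miss_rate <= 1,
            jitter_sd >= 0, score_sd >= 0)
  structure(list(p_detect = p_detect, miss_rate = miss_rate,
                 jitter_sd = jitter_sd, score_mean = score_mean,
                 score_sd = score_sd, area_scaling = area_scaling),
            class = "detector_model")
}

#' Generate synthetic detections for a phantom cohort
#'
#' @param ground_truth the `patients` table from [sample_phantom_cohort()]
#'   (or the invisible return of [generate_cohort()], whose `patients`
#'   element is used).
#' @param model a [detector_model()].
#' @param seed RNG seed.
#' @param path optional CSV output path (VOC 1-based box columns `xmin`,
#'   `ymin`, `xmax`, `ymax` plus `patient_id`, `slice_index`, `score`).
#' @return data.frame of detections in the CSV schema (also written to
#'   `path` when given).
#' @export
generate_detections <- function(ground_truth, model = detector_model(),
                                seed = 1L, path = NULL) {
  if (is.list(ground_truth) && !is.data.frame(ground_truth) &&
        !is.null(ground_truth$patients))
    ground_truth <- ground_truth$patients
  stopifnot(is.data.frame(ground_truth), inherits(model, "detector_model"))
  p <- ground_truth
  out <- with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(p))) {
      if (stats::runif(1) < model$miss_rate) next
      h <- (p$n_tumor[i] - 1) / 2
      center <- p$slice_start[i] + h
      for (s in p$slice_start[i]:p$slice_end[i]) {
        pr <- model$p_detect
        if (model$area_scaling) pr <- pr * axial_scale(s - center, h)^2
        if (stats::runif(1) >= pr) next
        b <- c(p$row_min[i], p$col_min[i], p$row_max[i], p$col_max[i]) +
          if (model$jitter_sd > 0) round(stats::rnorm(4, 0, model$jitter_sd)) else 0
        b[1] <- clamp(b[1], 0, p$image_size[i] - 1)
        b[2] <- clamp(b[2], 0, p$image_size[i] - 1)
        b[3] <- clamp(b[3], b[1] + 1, p$image_size[i])
        b[4] <- clamp(b[4], b[2] + 1, p$image_size[i])
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p$patient_id[i], slice_index = s,
          xmin = b[2] + 1, ymin = b[1] + 1, xmax = b[4], ymax = b[3],
          score = clamp(stats::rnorm(1, model$score_mean, model$score_sd), 0, 1))
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(patient_id = character(), slice_index = integer(),
                    xmin = numeric(), ymin = numeric(), xmax = numeric(),
                    ymax = numeric(), score = numeric())
  })
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
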