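# Shared fixture builders. All randomness is seeded by the caller.

# detections data.frame in the internal 0-based half-open convention
det_df <- function(slice_index, row_min, col_min, row_max, col_max, score) {
  data.frame(slice_index = slice_index, row_min = row_min, col_min = col_min,
             row_max = row_max, col_max = col_max, score = score)
}

# a patient_eval for a 1-slice annotation that is either a clean hit
# (IoU `hit_iou` via a shifted box) or a complete miss
toy_eval <- function(hit = TRUE, score = 0.9) {
  ann <- annotation3d(box2d(0, 0, 10, 10), 0, 0)
  d <- if (hit) det_df(0, 0, 0, 10, 10, score) else det_df(integer(), numeric(),
                                                           numeric(), numeric(),
                                                           numeric(), numeric())
  evaluate_patient(ann, d)
}

# fold-level cohort metrics for `n` patients of which `fn` are missed
toy_fold_metrics <- function(n, fn, score = 0.9) {
  cohort_metrics(c(rep(list(toy_eval(TRUE, score)), n - fn),
                   rep(list(toy_eval(FALSE)), fn)))
}

# pixel-count IoU oracle for integer-coordinate boxes (half-open)
iou_pixel_oracle <- function(a, b) {
  lim <- max(a["row_max"], b["row_max"], a["col_max"], b["col_max"])
  grid_a <- matrix(FALSE, lim, lim)
  grid_b <- grid_a
  grid_a[(a["row_min"] + 1):a["row_max"], (a["col_min"] + 1):a["col_max"]] <- TRUE
  grid_b[(b["row_min"] + 1):b["row_max"], (b["col_min"] + 1):b["col_max"]] <- TRUE
  inter <- sum(grid_a & grid_b)
  if (inter == 0) 0 else inter / sum(grid_a | grid_b)
}

# small phantom spec: full structural fidelity but light slice counts so
# image-writing tests stay fast
light_phantom_spec <- function(n_patients = 6L, max_slices = 12L) {
  phantom_spec(n_patients = n_patients,
               slice_count_table = data.frame(n_slices = 2:max_slices, count = 1),
               margin_range = c(1L, 3L))
}

random_int_box <- function(size = 30L) {
  r <- sort(sample(0:size, 2))
  cc <- sort(sample(0:size, 2))
  if (r[1] == r[2]) r[2] <- r[2] + 1L
  if (cc[1] == cc[2]) cc[2] <- cc[2] + 1L
  box2d(r[1], cc[1], r[2], cc[2])
}
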