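# IoU, per-patient matching and cohort/fold metric aggregation.

test_that("iou matches hand-computed and degenerate cases", {
  b <- box2d(0, 0, 10, 10)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(b, box2d(10, 10, 20, 20)), 0)
  # unit squares offset by half a side: intersection 0.5, union 1.5
  expect_equal(iou(box2d(0, 0, 1, 1), box2d(0, 0.5, 1, 1.5)), 1 / 3)
  expect_equal(iou(box2d(0, 0.5, 1, 1.5), box2d(0, 0, 1, 1)), 1 / 3) # symmetric
})

test_that("iou agrees with a pixel-count oracle on random integer boxes", {
  withr::with_seed(31, {
    for (i in 1:200) {
      a <- random_int_box()
      b <- random_int_box()
      expect_equal(iou(a, b), iou_pixel_oracle(a, b), tolerance = 1e-12)
    }
  })
})

test_that("per-patient evaluation: perfect, empty and mixed detections", {
  ann <- annotation3d(box2d(10, 10, 30, 30), 5, 7)

  perfect <- det_df(5:7, 10, 10, 30, 30, 0.9)
  ev <- evaluate_patient(ann, perfect)
  expect_true(ev$is_tp)
  expect_equal(ev$max_iou, 1)
  expect_equal(ev$score_at_max_iou, 0.9)
  expect_identical(ev$fn_slice_count, 0L)

  ev0 <- evaluate_patient(ann, NULL)
  expect_false(ev0$is_tp)
  expect_equal(ev0$max_iou, 0)
  expect_identical(ev0$fn_slice_count, 3L)
  expect_equal(ev0$score_at_max_iou, 0)

  # hand-computed per-slice IoUs {0, 1/3, 1}: slice 6's box is the ground
  # truth shifted 10 px right (inter 200, union 600), slice 7's is exact
  mixed <- rbind(det_df(6, 10, 20, 30, 40, 0.8),
                 det_df(7, 10, 10, 30, 30, 0.6))
  ev2 <- evaluate_patient(ann, mixed)
  expect_equal(unname(ev2$per_slice_iou), c(0, 1 / 3, 1))
  expect_equal(mean(ev2$per_slice_iou), (0 + 1 / 3 + 1) / 3)
  expect_equal(ev2$max_iou, 1)
  expect_equal(ev2$score_at_max_iou, 0.6)
  expect_identical(ev2$fn_slice_count, 1L)
})

test_that("matching picks max IoU with score tie-break, like brute force", {
  ann <- annotation3d(box2d(0, 0, 20, 20), 0, 0)
  withr::with_seed(77, {
    for (rep in 1:50) {
      k <- sample(1:3, 1)
      d <- do.call(rbind, lapply(seq_len(k), function(i) {
        b <- random_int_box(25)
        det_df(0, b["row_min"], b["col_min"], b["row_max"], b["col_max"],
               round(stats::runif(1), 2))
      }))
      ev <- evaluate_patient(ann, d)
      # exhaustive oracle
      ious <- vapply(seq_len(k), function(i)
        iou(ann$box, box2d(d$row_min[i], d$col_min[i], d$row_max[i], d$col_max[i])),
        numeric(1))
      best <- which(ious == max(ious))
      best <- best[which.max(d$score[best])]
      expect_equal(unname(ev$per_slice_iou[1]), ious[best])
      if (ious[best] > 0)
        expect_equal(unname(ev$per_slice_score[1]), d$score[best])
    }
  })
})

test_that("zero-IoU detections never change metrics; out-of-range ones only the FP tally", {
  ann <- annotation3d(box2d(10, 10, 30, 30), 5, 7)
  d <- det_df(5:7, 10, 10, 30, 30, 0.9)
  base <- evaluate_patient(ann, d)
  noisy <- rbind(d,
                 det_df(6, 100, 100, 120, 120, 0.99), # zero overlap
                 det_df(2, 10, 10, 30, 30, 0.99))     # outside annotated range
  ev <- evaluate_patient(ann, noisy)
  expect_equal(ev$per_slice_iou, base$per_slice_iou)
  expect_equal(ev$per_slice_score, base$per_slice_score)
  expect_identical(ev$is_tp, base$is_tp)
  expect_identical(ev$fp_slice_count, 1L)
})

test_that("cohort accuracy reproduces the published TP/FN ratios", {
  expect_equal(round(toy_fold_metrics(56, 3)$accuracy_pct, 2), 94.64)
  expect_equal(round(toy_fold_metrics(56, 2)$accuracy_pct, 2), 96.43)
  expect_equal(round(toy_fold_metrics(92, 2)$accuracy_pct, 2), 97.83)
  cm <- toy_fold_metrics(56, 3)
  expect_identical(cm$tp_count, 53L)
  expect_identical(cm$fn_count, 3L)
  # accuracy from booleans equals accuracy from counts
  expect_equal(cm$accuracy_pct, 100 * cm$tp_count / (cm$tp_count + cm$fn_count))
})

test_that("all-variant averages include FN zeros; pos variants restrict to TP", {
  evals <- list(toy_eval(TRUE, 0.8), toy_eval(TRUE, 0.6), toy_eval(FALSE))
  cm <- cohort_metrics(evals)
  expect_equal(cm$avg_iou_all, 2 / 3)
  expect_equal(cm$avg_iou_pos, 1)
  expect_equal(cm$avg_score_all, (0.8 + 0.6) / 3)
  expect_equal(cm$avg_score_pos, 0.7)
  expect_gte(cm$avg_iou_pos, cm$avg_iou_all)
  expect_gte(cm$avg_max_iou_pos, cm$avg_max_iou_all)
  expect_false(cm$no_tp)
})

test_that("all-FN cohort degenerates to zeros with a flag", {
  cm <- cohort_metrics(list(toy_eval(FALSE), toy_eval(FALSE)))
  expect_equal(cm$accuracy_pct, 0)
  expect_true(cm$no_tp)
  expect_equal(cm$avg_iou_pos, 0)
  expect_equal(cm$avg_score_pos, 0)
  expect_error(cohort_metrics(list()), "at least one")
})

test_that("cross-fold aggregation reproduces the published mean and n-1 sd", {
  fn_counts <- c(3, 4, 2, 6, 3, 5, 6, 8, 5, 9)
  folds <- lapply(fn_counts, function(fn) toy_fold_metrics(92, fn))
  agg <- aggregate_folds(folds)
  acc <- agg[agg$metric == "accuracy_pct", ]
  expect_equal(round(acc$mean, 2), 94.46)
  expect_equal(round(acc$sd, 2), 2.43)
  fnr <- agg[agg$metric == "fn_count", ]
  expect_equal(round(fnr$mean, 2), 5.10)
  expect_equal(round(fnr$sd, 2), 2.23)
  # the n-denominator variant would give 2.30, not the published 2.43
  accs <- vapply(folds, function(f) f$accuracy_pct, numeric(1))
  expect_equal(round(sqrt(mean((accs - mean(accs))^2)), 2), 2.30)
  expect_false(round(acc$sd, 2) == 2.30)

  same <- aggregate_folds(list(folds[[1]], folds[[1]]))
  expect_true(all(same$sd == 0))
  expect_error(aggregate_folds(folds[1]), "at least 2")
})

test_that("detections CSV round-trips through the VOC coordinate conversion", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(patient_id = "P1", slice_index = 4L,
                   xmin = 21, ymin = 11, xmax = 40, ymax = 30, score = 0.5)
  write.csv(df, path, row.names = FALSE)
  got <- read_detections(path)
  expect_equal(got$row_min, 10)
  expect_equal(got$col_min, 20)
  expect_equal(got$row_max, 30)
  expect_equal(got$col_max, 40)
})
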