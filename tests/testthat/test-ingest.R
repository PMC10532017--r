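# Cohort loading, annotation-table conversion, fat-suppression filtering.

write_min_cohort <- function(root, ann, series, stacks = list()) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  write.csv(ann, file.path(root, "annotations.csv"), row.names = FALSE)
  write.csv(series, file.path(root, "series.csv"), row.names = FALSE)
  for (pid in unique(series$patient_id))
    dir.create(file.path(root, "images", pid), recursive = TRUE, showWarnings = FALSE)
  for (s in stacks) {
    sdir <- file.path(root, "images", s$patient_id, s$series_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (inst in s$instances)
      png::writePNG(matrix(0.5, s$size, s$size),
                    file.path(sdir, sprintf("I%d.png", inst)))
  }
  root
}

ann_row <- function(pid, sid = "S1", s0 = 3, s1 = 7, r0 = 11, r1 = 40,
                    c0 = 21, c1 = 60) {
  data.frame(patient_id = pid, series_id = sid, start_slice = s0, end_slice = s1,
             start_row = r0, end_row = r1, start_col = c0, end_col = c1)
}

test_that("1-based inclusive table converts to 0-based half-open exactly once", {
  root <- withr::local_tempdir()
  write.csv(ann_row("P1"), file.path(root, "a.csv"), row.names = FALSE)
  got <- read_annotation_table(file.path(root, "a.csv"))
  expect_identical(got$slice_start, 2L)
  expect_identical(got$slice_end, 6L)
  expect_identical(got$row_min, 10L)
  expect_identical(got$row_max, 40L) # inclusive 40 == half-open 40
  expect_identical(got$col_min, 20L)
  expect_identical(got$col_max, 60L)
  # zero-based mode is a pass-through
  write.csv(ann_row("P1", s0 = 2, s1 = 6, r0 = 10, r1 = 40, c0 = 20, c1 = 60),
            file.path(root, "b.csv"), row.names = FALSE)
  raw <- read_annotation_table(file.path(root, "b.csv"), coordinate_base = "zero")
  expect_identical(raw$row_max, 40L)
  expect_identical(raw$slice_start, 2L)
})

test_that("malformed annotation rows abort the load, naming the row", {
  root <- withr::local_tempdir()
  bad <- ann_row("P2", s0 = 9, s1 = 4)
  write.csv(rbind(ann_row("P1"), bad), file.path(root, "a.csv"), row.names = FALSE)
  expect_error(read_annotation_table(file.path(root, "a.csv")),
               "row 2 .*P2.*end slice precedes")
  write.csv(ann_row("P1", r0 = 50, r1 = 10), file.path(root, "c.csv"),
            row.names = FALSE)
  expect_error(read_annotation_table(file.path(root, "c.csv")), "degenerate")
  write.csv(rbind(ann_row("P1"), ann_row("P1")), file.path(root, "d.csv"),
            row.names = FALSE)
  expect_error(read_annotation_table(file.path(root, "d.csv")), "one row per patient")
})

test_that("cohort loads one case per row; missing image dirs become error records", {
  root <- withr::local_tempdir()
  ann <- rbind(ann_row("P1"), ann_row("P2"), ann_row("P3"))
  series <- data.frame(patient_id = c("P1", "P2", "P3"),
                       series_id = "S1", scan_options = "FS SAT",
                       n_slices = 10L, image_size = 64L)
  stacks <- lapply(c("P1", "P2"), function(p)
    list(patient_id = p, series_id = "S1", instances = 1:10, size = 64))
  write_min_cohort(root, ann, series, stacks)
  unlink(file.path(root, "images", "P3"), recursive = TRUE)

  cohort <- load_cohort(file.path(root, "annotations.csv"), root)
  expect_length(cohort$cases, 2)
  expect_identical(cohort$errors$patient_id, "P3")
  expect_match(cohort$errors$message, "image directory missing")
  expect_identical(cohort$cases$P1$annotation$slice_start, 2L)
  expect_identical(n_tumor_slices(cohort$cases$P1$annotation), 5L)
})

test_that("slice order follows instance numbers regardless of file creation order", {
  root <- withr::local_tempdir()
  # instances written shuffled, including >1 digit so lexical order differs
  write_min_cohort(root, ann_row("P1", s0 = 1, s1 = 2),
                   data.frame(patient_id = "P1", series_id = "S1",
                              scan_options = "FS", n_slices = 12L,
                              image_size = 64L),
                   list(list(patient_id = "P1", series_id = "S1",
                             instances = sample(1:12), size = 64)))
  cohort <- load_cohort(file.path(root, "annotations.csv"), root)
  s <- cohort$cases$P1$series$S1
  expect_identical(s$slice_order, 1:12)
  recs <- slice_records(cohort$cases$P1)
  expect_identical(recs$slice_index, 0:11)
  expect_identical(basename(recs$file), sprintf("I%d.png", 1:12))
})

test_that("phantom cohorts round-trip their annotations exactly", {
  root <- withr::local_tempdir()
  gt <- generate_cohort(light_phantom_spec(6), root, seed = 13, write_images = FALSE)
  cohort <- load_cohort(file.path(root, "annotations.csv"), root)
  expect_length(cohort$cases, 6)
  for (i in seq_len(nrow(gt$patients))) {
    p <- gt$patients[i, ]
    ann <- cohort$cases[[p$patient_id]]$annotation
    expect_identical(ann$slice_start, p$slice_start)
    expect_identical(ann$slice_end, p$slice_end)
    expect_identical(as.integer(ann$box), c(p$row_min, p$col_min, p$row_max, p$col_max))
  }
})

test_that("fat-suppression filter keeps FS series, never drops patients", {
  root <- withr::local_tempdir()
  series <- data.frame(patient_id = "P1",
                       series_id = c("S1", "S2", "S3"),
                       scan_options = c("FS SAT", "SAT FS GATED", "NONE"),
                       n_slices = 10L, image_size = 64L)
  write_min_cohort(root, ann_row("P1"), series,
                   list(list(patient_id = "P1", series_id = "S1",
                             instances = 1:10, size = 64)))
  cohort <- load_cohort(file.path(root, "annotations.csv"), root)
  case <- filter_fat_suppressed(cohort$cases$P1)
  expect_setequal(names(case$series), c("S1", "S2"))
  expect_true(case$usable)
  expect_identical(case$annotation, cohort$cases$P1$annotation)

  # all suppressed: identity
  all_fs <- filter_fat_suppressed(local({
    cs <- cohort$cases$P1
    cs$series <- cs$series[c("S1", "S2")]
    cs
  }))
  expect_length(all_fs$series, 2)

  # none suppressed: flagged unusable, still present
  none <- local({
    cs <- cohort$cases$P1
    cs$series <- cs$series["S3"]
    cs
  })
  expect_warning(none <- filter_fat_suppressed(none), "unusable")
  expect_false(none$usable)
  expect_length(none$series, 0)
})

test_that("the FS token match is word-bounded, not a substring grab", {
  root <- withr::local_tempdir()
  series <- data.frame(patient_id = "P1", series_id = c("S1", "S2"),
                       scan_options = c("fs", "OFFSET"), # second must not match
                       n_slices = 5L, image_size = 64L)
  write_min_cohort(root, ann_row("P1", s0 = 1, s1 = 2), series,
                   list(list(patient_id = "P1", series_id = "S1",
                             instances = 1:5, size = 64)))
  cohort <- load_cohort(file.path(root, "annotations.csv"), root)
  flags <- vapply(cohort$cases$P1$series, function(s) s$fat_suppressed, logical(1))
  expect_identical(unname(flags), c(TRUE, FALSE))
})
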