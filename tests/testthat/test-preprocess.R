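# Resolution normalization, box rescaling, VOC export, dataset assembly.

test_that("box rescaling: exact scales, identity, clamping, inverse round trip", {
  expect_equal(unclass(rescale_box(box2d(0, 0, 512, 512), resize_spec(512, 448))),
               unclass(box2d(0, 0, 448, 448)))
  expect_equal(unclass(rescale_box(box2d(7, 8, 90, 91), resize_spec(448, 448))),
               unclass(box2d(7, 8, 90, 91)))
  # scale 1.4 on multiples of 10 is exact integer arithmetic
  expect_equal(unclass(rescale_box(box2d(100, 200, 200, 300), resize_spec(320, 448))),
               unclass(box2d(140, 280, 280, 420)))
  # forward then inverse recovers the original within 1 px per coordinate
  withr::with_seed(5, {
    for (i in 1:100) {
      b <- random_int_box(320)
      fwd <- rescale_box(b, resize_spec(320, 448))
      back <- rescale_box(fwd, resize_spec(448, 320))
      expect_true(all(abs(unclass(back) - unclass(b)) <= 1))
    }
  })
  # degenerate collapse widens with a warning
  expect_warning(got <- rescale_box(box2d(100, 100, 101, 200), resize_spec(512, 64)),
                 "degenerate")
  expect_true(got["row_max"] > got["row_min"])
  expect_error(rescale_box(box2d(0, 0, 400, 400), resize_spec(320, 448)), "exceeds")
})

test_that("slice resizing: identity, constants and shape geometry survive", {
  spec_id <- resize_spec(448, 448)
  img <- matrix(runif(448^2), 448, 448)
  expect_identical(resize_slice(img, spec_id), img)

  const <- matrix(0.37, 512, 512)
  out <- resize_slice(const, resize_spec(512, 448))
  expect_identical(dim(out), c(448L, 448L))
  expect_equal(max(abs(out - 0.37)), 0, tolerance = 1e-6)

  # disk of radius r maps to radius ~ r * scale with centroid error <= 1 px
  sz <- 320L
  r <- 60
  ctr <- c(140, 180)
  xs <- matrix(seq_len(sz), sz, sz)
  disk <- 1 * ((xs - ctr[1])^2 + (t(xs) - ctr[2])^2 <= r^2)
  small <- resize_slice(disk, resize_spec(320, 448)) > 0.5
  scale <- 448 / 320
  expect_equal(sum(small) / (pi * (r * scale)^2), 1, tolerance = 0.02)
  got_ctr <- c(mean(which(small, arr.ind = TRUE)[, 1]),
               mean(which(small, arr.ind = TRUE)[, 2]))
  expect_true(all(abs(got_ctr - ctr * scale) <= 1 + scale / 2))

  expect_error(resize_slice(matrix(0, 3, 4), resize_spec(3, 4)), "square")
  expect_error(resize_slice(matrix(0, 5, 5), resize_spec(3, 4)), "original_size")
})

test_that("VOC XML writes 1-based inclusive coordinates and round-trips", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_slice_annotation(path, "img.png", 448, list(box2d(10, 20, 30, 40)))
  doc <- xml2::read_xml(path)
  val <- function(x) xml2::xml_text(xml2::xml_find_first(doc, x))
  expect_identical(val(".//bndbox/xmin"), "21")
  expect_identical(val(".//bndbox/ymin"), "11")
  expect_identical(val(".//bndbox/xmax"), "40")
  expect_identical(val(".//bndbox/ymax"), "30")
  expect_identical(val(".//object/name"), "tumor")
  back <- read_slice_annotation(path)
  expect_equal(unclass(back$boxes[[1]]), unclass(box2d(10, 20, 30, 40)))
  expect_identical(back$image_size, 448L)

  # zero boxes -> no object nodes; two boxes -> two, order preserved
  write_slice_annotation(path, "img.png", 448, list())
  expect_length(read_slice_annotation(path)$boxes, 0)
  write_slice_annotation(path, "img.png", 448,
                         list(box2d(1, 2, 3, 4), box2d(5, 6, 7, 8)))
  two <- read_slice_annotation(path)$boxes
  expect_equal(unclass(two[[1]]), unclass(box2d(1, 2, 3, 4)))
  expect_equal(unclass(two[[2]]), unclass(box2d(5, 6, 7, 8)))
})

test_that("dataset assembly: train keeps selected tumor slices, test keeps all", {
  root <- withr::local_tempdir()
  cdir <- file.path(root, "cohort")
  spec <- light_phantom_spec(n_patients = 5)
  generate_cohort(spec, cdir, seed = 21)
  cohort <- load_cohort(file.path(cdir, "annotations.csv"), cdir)
  cohort$cases <- lapply(cohort$cases, filter_fat_suppressed)
  ids <- names(cohort$cases)
  split <- list(train = ids[1:3], test = ids[4:5])
  sel <- lapply(split$train, function(p)
    select_training_slices(cohort$cases[[p]]$annotation))
  names(sel) <- split$train

  out <- file.path(root, "ds")
  manifest <- assemble_dataset(cohort, split, sel, out, target_size = 448)

  # train counts equal the funnel keep counts; test counts equal full stacks
  for (p in split$train) {
    expect_identical(sum(manifest$patient_id == p),
                     as.integer(sel[[p]]$n_keep))
    expect_true(all(manifest$has_box[manifest$patient_id == p]))
  }
  for (p in split$test) {
    n_all <- cohort$cases[[p]]$series[[cohort$cases[[p]]$annotated_series]]$n_slices
    expect_identical(sum(manifest$patient_id == p), as.integer(n_all))
  }
  # no image appears in both subsets
  expect_identical(anyDuplicated(manifest$image_file), 0L)
  expect_length(intersect(manifest$image_file[manifest$subset == "train"],
                          manifest$image_file[manifest$subset == "test"]), 0)
  # emitted files exist, are 448 px, and annotated slices carry the scaled box
  one <- manifest[manifest$subset == "train", ][1, ]
  img <- png::readPNG(file.path(out, one$image_file))
  expect_identical(dim(img)[1:2], c(448L, 448L))
  ann <- read_slice_annotation(file.path(out, one$annotation_file))
  case <- cohort$cases[[one$patient_id]]
  expect_equal(unclass(ann$boxes[[1]]),
               unclass(rescale_box(case$annotation$box,
                                   resize_spec(case$image_size, 448))))
  # a non-tumor test slice has an empty annotation
  tanns <- manifest[manifest$subset == "test" & !manifest$has_box, ]
  expect_length(read_slice_annotation(file.path(out, tanns$annotation_file[1]))$boxes, 0)

  expect_error(assemble_dataset(cohort, list(train = ids[1:2], test = ids[2:3]),
                                sel, out), "both subsets")
})

test_that("manifest-only assembly supports leakage audits without payloads", {
  root <- withr::local_tempdir()
  cdir <- file.path(root, "cohort")
  generate_cohort(light_phantom_spec(4), cdir, seed = 8, write_images = FALSE)
  cohort <- load_cohort(file.path(cdir, "annotations.csv"), cdir)
  ids <- names(cohort$cases)
  sel <- lapply(ids[1:2], function(p) select_training_slices(cohort$cases[[p]]$annotation))
  names(sel) <- ids[1:2]
  m <- assemble_dataset(cohort, list(train = ids[1:2], test = ids[3:4]), sel,
                        file.path(root, "dry"), copy = FALSE)
  expect_false(dir.exists(file.path(root, "dry", "train", "images")))
  expect_true(file.exists(file.path(root, "dry", "manifest.csv")))
  expect_identical(anyDuplicated(m$image_file), 0L)
})
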