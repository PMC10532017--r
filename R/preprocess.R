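#' Resolution normalization spec
#'
#' The cohort mixes square slices of 320, 448 and 512 px; training expects a
#' single resolution (default 448). The original size is retained because
#' bounding-box coordinates must be rescaled by the same factor.
#'
#' @param original_size source slice side length in pixels.
#' @param target_size output side length (default 448).
#' @return An object of class `resize_spec` with a precomputed `scale`.
#' @export
resize_spec <- function(original_size, target_size = 448L) {
  stop_if_not_count(original_size, "original_size")
  stop_if_not_count(target_size, "target_size")
  structure(list(original_size = as.integer(original_size),
                 target_size = as.integer(target_size),
                 scale = target_size / original_size),
            class = "resize_spec")
}

#' Rescale a bounding box to the target resolution
#'
#' Each coordinate is multiplied by `scale`, rounded to the nearest integer
#' (halves away from zero) and clamped to the frame. Should rounding
#' collapse a side to zero width, the max coordinate is pushed out by one
#' pixel with a warning so the box stays valid.
#'
#' @param box a [box2d()] valid at `spec$original_size`.
#' @param spec a [resize_spec()].
#' @return the rescaled [box2d()].
#' @examples
#' rescale_box(box2d(100, 200, 200, 300), resize_spec(320, 448))
#' @export
rescale_box <- function(box, spec) {
  stopifnot(inherits(box, "box2d"), inherits(spec, "resize_spec"))
  if (box["row_max"] > spec$original_size || box["col_max"] > spec$original_size)
    stop("box exceeds the original frame", call. = FALSE)
  v <- clamp(round_half_up(unclass(box) * spec$scale), 0, spec$target_size)
  if (v["row_min"] >= v["row_max"]) {
    warning("degenerate row extent after rescaling; widening by 1 px", call. = FALSE)
    v["row_max"] <- min(v["row_min"] + 1, spec$target_size)
    v["row_min"] <- v["row_max"] - 1
  }
  if (v["col_min"] >= v["col_max"]) {
    warning("degenerate column extent after rescaling; widening by 1 px", call. = FALSE)
    v["col_max"] <- min(v["col_min"] + 1, spec$target_size)
    v["col_min"] <- v["col_max"] - 1
  }
  box2d(v["row_min"], v["col_min"], v["row_max"], v["col_max"])
}

#' Resize a square slice to the target resolution
#'
#' Bilinear interpolation (via EBImage); a same-size input is returned
#' untouched, bit for bit.
#'
#' @param pixels square numeric matrix (`spec$original_size` per side).
#' @param spec a [resize_spec()].
#' @return numeric matrix of side `spec$target_size`.
#' @export
resize_slice <- function(pixels, spec) {
  stopifnot(inherits(spec, "resize_spec"))
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop("slice must be a square matrix", call. = FALSE)
  if (nrow(pixels) != spec$original_size)
    stop("slice size does not match spec$original_size", call. = FALSE)
  if (spec$original_size == spec$target_size) return(pixels)
  out <- EBImage::resize(EBImage::Image(pixels), w = spec$target_size,
                         h = spec$target_size)
  EBImage::imageData(out)
}

#' Write a Pascal VOC annotation XML for one slice
#'
#' One `<object>` node per box, with `name` = `label` and a `<bndbox>` in
#' VOC's 1-based inclusive pixel convention where x is the column axis and
#' y the row axis: `xmin = col_min + 1`, `ymin = row_min + 1`,
#' `xmax = col_max`, `ymax = row_max` (the internal half-open max equals the
#' inclusive 1-based max).
#'
#' @param path output XML path.
#' @param filename image filename recorded in the XML.
#' @param image_size side length of the (already resized) image.
#' @param boxes list of [box2d()] at `image_size`; may be empty.
#' @param label object class name written for every box.
#' @return `path`, invisibly.
#' @export
write_slice_annotation <- function(path, filename, image_size, boxes,
                                   label = "tumor") {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(image_size))
  xml2::xml_add_child(size, "height", as.character(image_size))
  xml2::xml_add_child(size, "depth", "1")
  for (b in boxes) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", label)
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(b["col_min"] + 1))
    xml2::xml_add_child(bb, "ymin", as.character(b["row_min"] + 1))
    xml2::xml_add_child(bb, "xmax", as.character(b["col_max"]))
    xml2::xml_add_child(bb, "ymax", as.character(b["row_max"]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Parse a Pascal VOC annotation XML back into boxes
#'
#' Inverse of [write_slice_annotation()]; used for round-trip verification
#' and for consuming externally produced annotations.
#'
#' @param path XML path.
#' @return list with `filename`, `image_size`, `label` (of the first object,
#'   or `NA`) and `boxes` (list of [box2d()], internal convention).
#' @export
read_slice_annotation <- function(path) {
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- lapply(objs, function(o) {
    g <- function(tag) as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0(".//", tag))))
    box2d(g("ymin") - 1, g("xmin") - 1, g("ymax"), g("xmax"))
  })
  list(filename = xml2::xml_text(xml2::xml_find_first(doc, ".//filename")),
       image_size = as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width"))),
       label = if (length(objs)) xml2::xml_text(xml2::xml_find_first(objs[[1]], ".//name")) else NA_character_,
       boxes = boxes)
}

#' Assemble the final train/test dataset directories
#'
#' Emits the training and test image/annotation layout from a loaded cohort,
#' a patient-wise split and precomputed slice selections. Training patients
#' contribute only the kept tumor slices of their annotated series (the
#' funneling selection); test patients contribute every slice of their
#' annotated series, tumor or not, with empty annotation files on
#' non-tumor slices. All images are resized to `target_size` and boxes
#' rescaled accordingly.
#'
#' @param cohort a [load_cohort()] result (fat-suppression filtered).
#' @param split list with `train` and `test` patient-id vectors; they must
#'   be disjoint.
#' @param selections named list of [select_training_slices()] results, one
#'   per training patient.
#' @param out_dir output root; gains `train/images`, `train/annotations`,
#'   `test/images`, `test/annotations`, `manifest.csv`, `split.csv`.
#' @param target_size output resolution (default 448).
#' @param copy if `FALSE`, compute and write only the manifest and split
#'   declaration (no image/XML payloads) — used for leakage audits and
#'   k-fold planning.
#' @param label object class name for the annotation XMLs.
#' @return the manifest data.frame: one row per emitted image with
#'   `patient_id`, `subset`, `series_id`, `slice_index`, `has_box`,
#'   `image_file`, `annotation_file`.
#' @export
assemble_dataset <- function(cohort, split, selections, out_dir,
                             target_size = 448L, copy = TRUE, label = "tumor") {
  stopifnot(inherits(cohort, "cohort"))
  overlap <- intersect(split$train, split$test)
  if (length(overlap))
    stop("patients in both subsets: ", paste(overlap, collapse = ", "), call. = FALSE)
  ids <- c(split$train, split$test)
  missing_ids <- setdiff(ids, names(cohort$cases))
  if (length(missing_ids))
    stop("split names unknown patients: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(ids))
  names(rows) <- ids
  for (pid in ids) {
    case <- cohort$cases[[pid]]
    if (!isTRUE(case$usable)) next
    subset <- if (pid %in% split$train) "train" else "test"
    recs <- slice_records(case)
    ann <- case$annotation
    if (subset == "train") {
      sel <- selections[[pid]]
      if (is.null(sel))
        stop("no slice selection for training patient ", pid, call. = FALSE)
      keep <- recs$slice_index >= sel$kept_range[1] & recs$slice_index <= sel$kept_range[2]
      recs <- recs[keep, , drop = FALSE]
    }
    spec <- resize_spec(case$image_size, target_size)
    sboxes <- rescale_box(ann$box, spec)
    stem <- sprintf("%s_%s_s%04d", pid, recs$series_id, recs$slice_index)
    has_box <- recs$slice_index >= ann$slice_start & recs$slice_index <= ann$slice_end
    img_rel <- file.path(subset, "images", paste0(stem, ".png"))
    xml_rel <- file.path(subset, "annotations", paste0(stem, ".xml"))
    if (copy) {
      dir.create(file.path(out_dir, subset, "images"), recursive = TRUE, showWarnings = FALSE)
      dir.create(file.path(out_dir, subset, "annotations"), recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(nrow(recs))) {
        if (is.na(recs$file[i]))
          stop("pixel data missing for ", stem[i], call. = FALSE)
        px <- png::readPNG(recs$file[i])
        if (length(dim(px)) == 3L) px <- px[, , 1]
        png::writePNG(clamp(resize_slice(px, spec), 0, 1),
                      file.path(out_dir, img_rel[i]))
        write_slice_annotation(file.path(out_dir, xml_rel[i]),
                               basename(img_rel[i]), target_size,
                               if (has_box[i]) list(sboxes) else list(),
                               label = label)
      }
    }
    rows[[pid]] <- data.frame(patient_id = pid, subset = subset,
                              series_id = recs$series_id,
                              slice_index = recs$slice_index,
                              has_box = has_box,
                              image_file = img_rel, annotation_file = xml_rel,
                              stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = ids,
                              subset = ifelse(ids %in% split$train, "train", "test")),
                   file.path(out_dir, "split.csv"), row.names = FALSE)
  manifest
}
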