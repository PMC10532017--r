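#' Axis-aligned 2D bounding box
#'
#' Boxes use the package-internal convention throughout: 0-based, half-open
#' pixel intervals, so `row_max`/`col_max` are one past the last lesion pixel
#' and `width = col_max - col_min`. Conversion to and from the 1-based
#' inclusive conventions of clinical annotation tables and Pascal VOC XML
#' happens only at the I/O boundary (see [read_annotation_table()] and
#' [write_slice_annotation()]).
#'
#' @param row_min,col_min,row_max,col_max box bounds in pixels (0-based,
#'   half-open).
#' @return An object of class `box2d`: a named numeric vector with elements
#'   `row_min`, `col_min`, `row_max`, `col_max`.
#' @examples
#' b <- box2d(10, 20, 30, 40)
#' box_area(b) # 400
#' @export
box2d <- function(row_min, col_min, row_max, col_max) {
  b <- c(row_min = as.numeric(row_min), col_min = as.numeric(col_min),
         row_max = as.numeric(row_max), col_max = as.numeric(col_max))
  if (any(!is.finite(b))) stop("box coordinates must be finite", call. = FALSE)
  if (b["row_min"] < 0 || b["col_min"] < 0)
    stop("box coordinates must be non-negative", call. = FALSE)
  if (b["row_min"] >= b["row_max"] || b["col_min"] >= b["col_max"])
    stop("box must satisfy row_min < row_max and col_min < col_max", call. = FALSE)
  structure(b, class = "box2d")
}

#' @rdname box2d
#' @param box a `box2d`.
#' @export
box_area <- function(box) {
  unname((box["row_max"] - box["row_min"]) * (box["col_max"] - box["col_min"]))
}

#' @export
print.box2d <- function(x, ...) {
  cat(sprintf("<box2d> rows [%g, %g), cols [%g, %g)\n",
              x["row_min"], x["row_max"], x["col_min"], x["col_max"]))
  invisible(x)
}

#' 3D lesion annotation: one 2D box plus an inclusive slice range
#'
#' The annotation scheme used by the source dataset: a single rectangle
#' (drawn around the lesion's largest cross-section) paired with the
#' inclusive range of slices on which the lesion is visible. The same
#' rectangle applies to every slice in the range, which is why cross-sections
#' near the range extremities sit loosely inside it.
#'
#' @param box a [box2d()].
#' @param slice_start,slice_end first and last tumor slice (0-based,
#'   inclusive), `slice_start <= slice_end`.
#' @return An object of class `annotation3d`.
#' @export
annotation3d <- function(box, slice_start, slice_end) {
  if (!inherits(box, "box2d")) stop("`box` must be a box2d", call. = FALSE)
  stop_if_not_count(slice_start, "slice_start", min = 0)
  stop_if_not_count(slice_end, "slice_end", min = 0)
  if (slice_end < slice_start)
    stop("slice_end must be >= slice_start", call. = FALSE)
  structure(list(box = box,
                 slice_start = as.integer(slice_start),
                 slice_end = as.integer(slice_end)),
            class = "annotation3d")
}

#' @rdname annotation3d
#' @param annotation an `annotation3d`.
#' @return `n_tumor_slices()`: the inclusive slice count of the annotation.
#' @export
n_tumor_slices <- function(annotation) {
  annotation$slice_end - annotation$slice_start + 1L
}

#' @export
print.annotation3d <- function(x, ...) {
  cat(sprintf("<annotation3d> slices %d..%d (%d slices), ",
              x$slice_start, x$slice_end, n_tumor_slices(x)))
  print(x$box)
  invisible(x)
}
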