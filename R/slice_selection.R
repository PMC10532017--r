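#' Funneling parameters
#'
#' The funneling rule keeps `ceil(n * a * ln(b))` of a tumor's `n` annotated
#' slices. With the defaults (`a = 0.75`, `b = 1.9625`) the asymptotic keep
#' fraction is `a * ln(b) ~ 0.5057`: large tumors lose roughly half of their
#' slices while small tumors (2-10 slices) are barely touched, because the
#' ceiling dominates at small `n`. Both constants are heuristic and tunable.
#'
#' @param a positive coefficient controlling the keep fraction.
#' @param b log argument, must exceed 1 so that `ln(b) > 0`.
#' @return An object of class `funnel_params`.
#' @export
funnel_params <- function(a = 0.75, b = 1.9625) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 1)
    stop("`b` must be a single number > 1", call. = FALSE)
  if (a * log(b) > 1)
    stop("a * ln(b) must be <= 1: the keep fraction cannot exceed 1", call. = FALSE)
  structure(list(a = a, b = b), class = "funnel_params")
}

#' Number of slices the funneling rule keeps
#'
#' Computes `ceil(n_total * a * ln(b))`, the count of central slices retained
#' from a tumor spanning `n_total` slices. Vectorized over `n_total`.
#'
#' @param n_total tumor slice count(s), integer-valued, `>= 1`.
#' @param params a [funnel_params()].
#' @return Integer vector of kept-slice counts, same length as `n_total`.
#' @examples
#' funnel_keep_count(9)   # 5
#' funnel_keep_count(108) # 55
#' funnel_keep_count(2)   # 2: small tumors are spared
#' @export
funnel_keep_count <- function(n_total, params = funnel_params()) {
  stopifnot(inherits(params, "funnel_params"))
  stop_if_not_count(n_total, "n_total", min = 1)
  as.integer(ceiling(n_total * params$a * log(params$b)))
}

#' Slices to remove from each end of the tumor range
#'
#' The removal total `R = n_total - funnel_keep_count(n_total)` is split
#' across the two ends of the slice range; an odd `R` removes the extra slice
#' from the end (`floor(R/2)` from the start, `ceil(R/2)` from the end).
#' Vectorized over `n_total`.
#'
#' @inheritParams funnel_keep_count
#' @return A data.frame with integer columns `remove_start` and `remove_end`.
#' @examples
#' removal_counts(108) # 26, 27
#' @export
removal_counts <- function(n_total, params = funnel_params()) {
  keep <- funnel_keep_count(n_total, params)
  r <- n_total - keep
  data.frame(remove_start = as.integer(floor(r / 2)),
             remove_end   = as.integer(ceiling(r / 2)))
}

#' Select the central training slices of an annotated tumor
#'
#' Applies the funneling rule to one annotation, trimming the loose-box edge
#' slices symmetrically and returning the contiguous central interval that
#' remains. This selection is meant for training patients only; test patients
#' keep every slice (the pipeline enforces that, not this function).
#'
#' @param annotation an [annotation3d()].
#' @inheritParams funnel_keep_count
#' @return An object of class `selection_result`: list with `n_total`,
#'   `n_keep`, `remove_start`, `remove_end` and `kept_range` (inclusive
#'   0-based slice interval, `c(first, last)`).
#' @examples
#' ann <- annotation3d(box2d(0, 0, 10, 10), slice_start = 10, slice_end = 18)
#' select_training_slices(ann)$kept_range # 12 16
#' @export
select_training_slices <- function(annotation, params = funnel_params()) {
  stopifnot(inherits(annotation, "annotation3d"))
  n <- n_tumor_slices(annotation)
  keep <- funnel_keep_count(n, params)
  rem <- removal_counts(n, params)
  kept <- c(annotation$slice_start + rem$remove_start,
            annotation$slice_end - rem$remove_end)
  structure(list(n_total = n,
                 n_keep = keep,
                 remove_start = rem$remove_start,
                 remove_end = rem$remove_end,
                 kept_range = as.integer(kept)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d tumor slices: keep %d (slices %d..%d), remove %d + %d\n",
              x$n_total, x$n_keep, x$kept_range[1], x$kept_range[2],
              x$remove_start, x$remove_end))
  invisible(x)
}

#' Funneling audit table
#'
#' Tabulates, for each tumor slice count, the removal totals, the per-end
#' removal counts and the kept-slice count.
#'
#' @param n_values tumor slice counts to tabulate.
#' @inheritParams funnel_keep_count
#' @return A data.frame with columns `n_total`, `n_remove`, `remove_start`,
#'   `remove_end`, `n_keep`.
#' @export
funnel_table <- function(n_values = 2:131, params = funnel_params()) {
  keep <- funnel_keep_count(n_values, params)
  rem <- removal_counts(n_values, params)
  data.frame(n_total = as.integer(n_values),
             n_remove = as.integer(n_values - keep),
             remove_start = rem$remove_start,
             remove_end = rem$remove_end,
             n_keep = keep)
}
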