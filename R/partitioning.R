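#' Patient-wise train/test split
#'
#' Splits patients (never individual slices) into disjoint train and test
#' sets so that no image of any patient can leak across the boundary. The
#' test size is `round(n * test_fraction)`; the assignment is a uniform
#' shuffle, deterministic under `seed`.
#'
#' @param patient_ids character or integer vector of unique patient ids.
#' @param test_fraction fraction of patients in the test set, in (0, 1).
#' @param seed RNG seed for the shuffle.
#' @return list with character vectors `train` and `test`.
#' @export
split_patients <- function(patient_ids, test_fraction, seed = 1L) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (n < 2L) stop("need at least 2 patients to split", call. = FALSE)
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique", call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie strictly between 0 and 1", call. = FALSE)
  n_test <- as.integer(round(n * test_fraction))
  if (n_test < 1L || n_test >= n)
    stop("test_fraction leaves an empty subset at this cohort size", call. = FALSE)
  shuffled <- with_seed(seed, sample(patient_ids))
  list(train = sort(shuffled[-seq_len(n_test)]),
       test  = sort(shuffled[seq_len(n_test)]))
}

#' Patient-wise k-fold plan with remainder-to-train rule
#'
#' Shuffles the patients and deals the first `k * floor(n/k)` of them into
#' `k` folds of equal size `floor(n/k)`. The `n mod k` leftover patients are
#' marked `REMAINDER`: they join every training set and are never tested.
#' For a 922-patient cohort and `k = 10` this yields ten test folds of 92 and
#' training sets of 830, with 2 remainder patients in every training set.
#'
#' @inheritParams split_patients
#' @param k number of folds (default 10).
#' @return An object of class `fold_plan`: list with `k`, `seed`, `fold_size`
#'   and `assignments`, a named integer vector mapping patient id to fold
#'   index `1..k` or `NA` for remainder patients.
#' @export
make_fold_plan <- function(patient_ids, k = 10L, seed = 1L) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k != floor(k) || k < 2L)
    stop("`k` must be an integer >= 2", call. = FALSE)
  k <- as.integer(k)
  if (n < k) stop("need at least k patients", call. = FALSE)
  m <- n %/% k
  shuffled <- with_seed(seed, sample(patient_ids))
  fold <- rep(NA_integer_, n)
  fold[seq_len(k * m)] <- rep(seq_len(k), each = m)
  assignments <- stats::setNames(fold, shuffled)
  structure(list(k = k, seed = as.integer(seed), fold_size = m,
                 assignments = assignments),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  n_rem <- sum(is.na(x$assignments))
  cat(sprintf("<fold_plan> %d patients, k = %d: folds of %d, %d remainder (always train), seed %d\n",
              length(x$assignments), x$k, x$fold_size, n_rem, x$seed))
  invisible(x)
}

#' Train/test sets for one fold of a plan
#'
#' The test set is the fold's members; the training set is every other
#' patient, remainder patients included.
#'
#' @param plan a [make_fold_plan()] result.
#' @param fold_index fold to test on, in `1..k`.
#' @return list with character vectors `train` and `test`.
#' @export
fold_split <- function(plan, fold_index) {
  stopifnot(inherits(plan, "fold_plan"))
  if (!is.numeric(fold_index) || length(fold_index) != 1L ||
      fold_index != floor(fold_index) || fold_index < 1L || fold_index > plan$k)
    stop(sprintf("`fold_index` must be in 1..%d", plan$k), call. = FALSE)
  ids <- names(plan$assignments)
  in_test <- !is.na(plan$assignments) & plan$assignments == fold_index
  list(train = sort(ids[!in_test]), test = sort(ids[in_test]))
}

#' Write / read a fold plan as CSV
#'
#' The CSV has columns `patient_id` and `fold` (an integer or the literal
#' `REMAINDER`); the shuffle seed is recorded in a `# seed:` header comment.
#'
#' @param plan a `fold_plan`.
#' @param path file path.
#' @return `write_fold_plan()` returns `path` invisibly; `read_fold_plan()`
#'   returns a `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  fold <- ifelse(is.na(plan$assignments), "REMAINDER", plan$assignments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", plan$seed), con)
  utils::write.csv(data.frame(patient_id = names(plan$assignments), fold = fold),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  header <- readLines(path, n = 1L)
  seed <- as.integer(sub("^# seed:\\s*", "", header))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  fold <- suppressWarnings(as.integer(df$fold)) # REMAINDER -> NA
  k <- max(fold, na.rm = TRUE)
  structure(list(k = k, seed = seed, fold_size = sum(!is.na(fold)) %/% k,
                 assignments = stats::setNames(fold, df$patient_id)),
            class = "fold_plan")
}
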