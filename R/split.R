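#' Constrained random training/test split
#'
#' Draws a random split of the compound set, requiring that the test-set
#' activity range be nested inside the training range (max(test) <=
#' max(training) and min(test) >= min(training)), so no test prediction is
#' an extrapolation in activity space. If a draw violates the range
#' condition the split is re-drawn with an incremented sub-seed, up to
#' `max_attempts` times. An explicit test-id list bypasses the random draw
#' (making the split independent of `seed`) but is still checked against
#' the range condition.
#'
#' @param records activity data.frame with `id` and `pic50` columns
#'   (see [read_activities()]).
#' @param training_fraction fraction of compounds assigned to training
#'   (rounded to the nearest integer count); default 0.75.
#' @param seed integer seed for the random draw.
#' @param explicit_test_ids optional character vector of test-set ids.
#' @param max_attempts re-draw budget for the range condition.
#' @return list with `training_ids` and `test_ids` (character vectors).
#' @export
split_train_test <- function(records, training_fraction = 0.75, seed = 1L,
                             explicit_test_ids = NULL, max_attempts = 100L) {
  if (nrow(records) < 5L) stop("need at least 5 records to split")
  if (any(is.na(records$pic50))) stop("pIC50 required for every record")
  ids <- as.character(records$id)
  y <- records$pic50
  range_ok <- function(test_idx) {
    train_idx <- setdiff(seq_along(ids), test_idx)
    max(y[test_idx]) <= max(y[train_idx]) &&
      min(y[test_idx]) >= min(y[train_idx])
  }
  if (!is.null(explicit_test_ids)) {
    explicit_test_ids <- as.character(explicit_test_ids)
    missing <- setdiff(explicit_test_ids, ids)
    if (length(missing)) {
      stop("explicit test ids not in dataset: ", paste(missing, collapse = ", "))
    }
    test_idx <- match(explicit_test_ids, ids)
    if (length(test_idx) == 0L || length(test_idx) == length(ids)) {
      stop("explicit test set must be a proper non-empty subset")
    }
    if (!range_ok(test_idx)) {
      stop("explicit test set violates the nested activity-range condition")
    }
    return(list(training_ids = ids[-test_idx], test_ids = ids[test_idx]))
  }
  if (training_fraction <= 0 || training_fraction >= 1) {
    stop("training_fraction must be in (0, 1)")
  }
  n <- length(ids)
  n_train <- round(training_fraction * n)
  if (n_train < 2L || n_train > n - 1L) stop("degenerate split size")
  for (attempt in seq_len(max_attempts)) {
    test_idx <- with_seed(seed + attempt - 1L,
                          sample.int(n, n - n_train))
    if (range_ok(test_idx)) {
      return(list(training_ids = ids[-test_idx], test_ids = ids[test_idx]))
    }
  }
  stop("no split satisfying the activity-range condition in ",
       max_attempts, " attempts")
}
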