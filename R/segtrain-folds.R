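#' Subject-grouped five-fold cross-validation plan
#'
#' Partitions images into folds such that all images of a subject (for
#' example both eyes) land in the same validation fold, preventing
#' subject-level leakage between training and validation. Subjects are
#' shuffled under `seed` and dealt round-robin into the folds.
#'
#' @param metadata data.frame with one row per image and a `subject_id`
#'   column (e.g. stacked [eye_metadata()] rows).
#' @param n_folds number of folds (default 5, i.e. 80%/20% splits).
#' @param seed shuffle seed.
#' @return A `fold_plan`: `list(n_folds, folds = list of subject-id
#'   vectors, fold_of = integer fold per image row)`.
#' @export
make_folds <- function(metadata, n_folds = 5, seed = 1) {
  subjects <- unique(metadata$subject_id)
  if (length(subjects) < n_folds)
    stop(sprintf("need at least %d subjects for %d folds", n_folds, n_folds),
         call. = FALSE)
  shuffled <- with_seed(seed, sample(subjects))
  fold_of_subject <- setNames(rep_len(seq_len(n_folds), length(shuffled)),
                              shuffled)
  fold_of <- unname(fold_of_subject[metadata$subject_id])
  folds <- lapply(seq_len(n_folds),
                  function(k) names(fold_of_subject)[fold_of_subject == k])
  structure(list(n_folds = as.integer(n_folds), folds = folds,
                 fold_of = as.integer(fold_of)),
            class = "fold_plan")
}

#' Train/validation image indices for one fold
#'
#' @param plan a `fold_plan` from [make_folds()].
#' @param k fold number in `1:n_folds`.
#' @return `list(train = indices, val = indices)` into the metadata rows.
#' @export
fold_split <- function(plan, k) {
  stopifnot(inherits(plan, "fold_plan"), k >= 1, k <= plan$n_folds)
  list(train = which(plan$fold_of != k), val = which(plan$fold_of == k))
}
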