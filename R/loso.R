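#' Leave-one-subject-out splits
#'
#' Builds the full set of LOSO cross-validation folds for a batch: one split
#' per subject, whose test set is exactly that subject's trials and whose
#' train set is everything else. The splits partition the trial indices.
#'
#' @param batch A [trial_batch()] with at least two distinct subjects.
#' @return A list of `loso_split` objects with fields `held_out_subject`,
#'   `train_index` and `test_index`.
#' @export
loso_splits <- function(batch) {
  stopifnot(inherits(batch, "trial_batch"))
  subjects <- sort(unique(batch$subject_ids))
  if (length(subjects) < 2L)
    stop("LOSO is undefined for a single-subject batch", call. = FALSE)
  all_idx <- seq_len(n_trials(batch))
  lapply(subjects, function(s) {
    test <- all_idx[batch$subject_ids == s]
    structure(list(held_out_subject = s,
                   train_index = setdiff(all_idx, test),
                   test_index = test),
              class = "loso_split")
  })
}

#' @export
print.loso_split <- function(x, ...) {
  cat(sprintf("<loso_split: subject %d held out; %d train / %d test trials>\n",
              x$held_out_subject, length(x$train_index), length(x$test_index)))
  invisible(x)
}
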