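#' Describe one physiological modality
#'
#' A modality spec records the name, channel count and window length of one
#' signal family (e.g. 32-channel EEG sampled into 128-sample windows).
#'
#' @param name Modality identifier, e.g. `"EEG"`.
#' @param n_channels Number of channels (columns) per trial window.
#' @param seq_len Number of time samples per trial window.
#' @return An object of class `modality_spec`.
#' @examples
#' modality_spec("EEG", n_channels = 32, seq_len = 128)
#' @export
modality_spec <- function(name, n_channels, seq_len) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_channels <- as.integer(n_channels)
  seq_len <- as.integer(seq_len)
  if (is.na(n_channels) || n_channels < 1L)
    stop("`n_channels` must be a positive integer", call. = FALSE)
  if (is.na(seq_len) || seq_len < 1L)
    stop("`seq_len` must be a positive integer", call. = FALSE)
  structure(list(name = name, n_channels = n_channels, seq_len = seq_len),
            class = "modality_spec")
}

#' @export
print.modality_spec <- function(x, ...) {
  cat(sprintf("<modality %s: %d channels x %d samples>\n",
              x$name, x$n_channels, x$seq_len))
  invisible(x)
}

#' Construct a batch of multimodal trials
#'
#' `trial_batch` is the universal data container of the package: a set of
#' trials, each observed through several modalities, with an emotion label and
#' a subject identifier per trial. Signals are stored per modality as a
#' 3-dimensional array `[n_trials, seq_len, n_channels]`.
#'
#' @param signals Named list of numeric arrays, one per modality, each of
#'   dimension `[n_trials, seq_len_i, n_channels_i]`. All modalities must have
#'   the same number of trials; names must be unique.
#' @param emotion_labels Integer vector of emotion classes in `1..n_emotions`.
#' @param subject_ids Integer vector of subject identities in `1..n_subjects`.
#' @param n_emotions,n_subjects Class/subject counts; default to the maxima of
#'   the supplied labels.
#' @return An object of class `trial_batch`.
#' @seealso [generate_synthetic()], [loso_splits()], [remove_modality()]
#' @export
trial_batch <- function(signals, emotion_labels, subject_ids,
                        n_emotions = max(emotion_labels),
                        n_subjects = max(subject_ids)) {
  if (!is.list(signals) || length(signals) == 0L)
    stop("`signals` must be a non-empty named list of arrays", call. = FALSE)
  nms <- names(signals)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("modality names must be present and unique", call. = FALSE)
  emotion_labels <- as.integer(emotion_labels)
  subject_ids <- as.integer(subject_ids)
  batch <- structure(
    list(signals = signals,
         emotion_labels = emotion_labels,
         subject_ids = subject_ids,
         n_emotions = as.integer(n_emotions),
         n_subjects = as.integer(n_subjects)),
    class = "trial_batch")
  validate_trial_batch(batch)
  batch
}

#' Validate a trial batch
#'
#' Checks the structural invariants of a [trial_batch()]: consistent trial
#' counts across modalities, labels and subject ids in range, and finite
#' signal values. Called by the constructor; exported so corrupted or
#' externally built objects can be re-checked.
#'
#' @param batch A `trial_batch`.
#' @return `batch`, invisibly, if valid; otherwise an error.
#' @export
validate_trial_batch <- function(batch) {
  stopifnot(inherits(batch, "trial_batch"))
  n <- vapply(batch$signals, function(a) dim(a)[1L], integer(1))
  if (length(unique(n)) != 1L)
    stop("all modalities must share the same number of trials", call. = FALSE)
  n <- n[[1L]]
  for (nm in names(batch$signals)) {
    a <- batch$signals[[nm]]
    if (!is.array(a) || length(dim(a)) != 3L)
      stop(sprintf("signals[[%s]] must be a [n_trials, seq_len, n_channels] array", nm),
           call. = FALSE)
    if (!all(is.finite(a)))
      stop(sprintf("signals[[%s]] contains non-finite values", nm), call. = FALSE)
  }
  if (length(batch$emotion_labels) != n || length(batch$subject_ids) != n)
    stop("label vectors must have one entry per trial", call. = FALSE)
  if (any(batch$emotion_labels < 1L) || any(batch$emotion_labels > batch$n_emotions))
    stop("emotion labels must lie in 1..n_emotions", call. = FALSE)
  if (any(batch$subject_ids < 1L) || any(batch$subject_ids > batch$n_subjects))
    stop("subject ids must lie in 1..n_subjects", call. = FALSE)
  invisible(batch)
}

#' @export
print.trial_batch <- function(x, ...) {
  dims <- vapply(names(x$signals), function(nm) {
    d <- dim(x$signals[[nm]])
    sprintf("%s[%dx%d]", nm, d[2L], d[3L])
  }, character(1))
  cat(sprintf("<trial_batch: %d trials, %d subjects, %d emotions; %s>\n",
              n_trials(x), x$n_subjects, x$n_emotions,
              paste(dims, collapse = " ")))
  invisible(x)
}

#' Number of trials in a batch
#' @param batch A `trial_batch`.
#' @return Integer trial count.
#' @export
n_trials <- function(batch) {
  stopifnot(inherits(batch, "trial_batch"))
  dim(batch$signals[[1L]])[1L]
}

#' Modality names of a batch
#' @param batch A `trial_batch`.
#' @return Character vector of modality names, in storage order.
#' @export
modality_names <- function(batch) {
  stopifnot(inherits(batch, "trial_batch"))
  names(batch$signals)
}

#' Modality specs of a batch
#' @param batch A `trial_batch`.
#' @return List of [modality_spec()] objects describing the batch.
#' @export
modality_specs_of <- function(batch) {
  stopifnot(inherits(batch, "trial_batch"))
  lapply(names(batch$signals), function(nm) {
    d <- dim(batch$signals[[nm]])
    modality_spec(nm, n_channels = d[3L], seq_len = d[2L])
  })
}

#' Subset the trials of a batch
#'
#' @param batch A `trial_batch`.
#' @param idx Integer vector of trial indices to keep (in order).
#' @return A `trial_batch` holding only the selected trials.
#' @export
subset_trials <- function(batch, idx) {
  stopifnot(inherits(batch, "trial_batch"))
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("cannot build an empty trial batch", call. = FALSE)
  if (any(idx < 1L) || any(idx > n_trials(batch)))
    stop("trial indices out of range", call. = FALSE)
  sig <- lapply(batch$signals, function(a) a[idx, , , drop = FALSE])
  trial_batch(sig, batch$emotion_labels[idx], batch$subject_ids[idx],
              n_emotions = batch$n_emotions, n_subjects = batch$n_subjects)
}

#' Drop one modality from a batch
#'
#' Used by the modality-loss robustness experiments: returns the same trials
#' observed through all modalities except `name`. Labels and subject ids are
#' untouched.
#'
#' @param batch A `trial_batch`.
#' @param name Modality to remove.
#' @return A `trial_batch` without that modality.
#' @export
remove_modality <- function(batch, name) {
  stopifnot(inherits(batch, "trial_batch"))
  if (!name %in% names(batch$signals))
    stop(sprintf("unknown modality '%s'; available: %s", name,
                 paste(names(batch$signals), collapse = ", ")), call. = FALSE)
  if (length(batch$signals) == 1L)
    stop("cannot remove the only remaining modality", call. = FALSE)
  sig <- batch$signals[setdiff(names(batch$signals), name)]
  trial_batch(sig, batch$emotion_labels, batch$subject_ids,
              n_emotions = batch$n_emotions, n_subjects = batch$n_subjects)
}

#' Corrupt a batch with additive Gaussian sensor noise
#'
#' Adds i.i.d. `N(0, sd^2)` noise to every signal value in every modality;
#' labels and subject ids are bit-identical before and after. With `sd = 0`
#' the input batch is returned unchanged.
#'
#' @param batch A `trial_batch`.
#' @param sd Noise standard deviation (`>= 0`).
#' @param seed Integer seed; the corruption is deterministic given the seed.
#' @return The corrupted `trial_batch`.
#' @export
add_gaussian_noise <- function(batch, sd, seed = 1L) {
  stopifnot(inherits(batch, "trial_batch"))
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("`sd` must be a single nonnegative number", call. = FALSE)
  if (sd == 0) return(batch)
  sig <- with_seed(seed, {
    lapply(batch$signals, function(a) {
      a + array(stats::rnorm(length(a), sd = sd), dim = dim(a))
    })
  })
  trial_batch(sig, batch$emotion_labels, batch$subject_ids,
              n_emotions = batch$n_emotions, n_subjects = batch$n_subjects)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All randomness in the package flows through
# explicit seeds via this helper; no global RNG state leaks.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
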