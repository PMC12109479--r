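#' Write a trial batch to its native on-disk container
#'
#' The native serialization is a plain-text directory: one `<modality>.csv`
#' per modality holding the trial-major flattening of the signal array (one
#' row per trial, `seq_len * n_channels` columns, time-major), a `labels.csv`
#' with the emotion label and subject id per trial, and a `meta.json` with
#' the modality specs and class counts.
#'
#' @param batch A [trial_batch()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trial_batch <- function(batch, path) {
  stopifnot(inherits(batch, "trial_batch"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    n_emotions = batch$n_emotions,
    n_subjects = batch$n_subjects,
    modalities = lapply(modality_specs_of(batch), function(sp)
      list(name = sp$name, n_channels = sp$n_channels, seq_len = sp$seq_len)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(
    data.table::data.table(emotion = batch$emotion_labels,
                           subject = batch$subject_ids),
    file.path(path, "labels.csv"))
  for (nm in names(batch$signals)) {
    a <- batch$signals[[nm]]
    m <- matrix(a, nrow = dim(a)[1L])  # trial-major flattening
    data.table::fwrite(data.table::as.data.table(m),
                       file.path(path, paste0(nm, ".csv")))
  }
  invisible(path)
}

#' Read a trial batch from its native container
#'
#' @param path Directory written by [write_trial_batch()].
#' @return A [trial_batch()].
#' @export
read_trial_batch <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file))
    stop(sprintf("no trial-batch container at '%s' (missing meta.json)", path),
         call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  labels <- data.table::fread(file.path(path, "labels.csv"))
  n <- nrow(labels)
  sig <- list()
  mods <- meta$modalities
  for (i in seq_len(nrow(mods))) {
    nm <- mods$name[i]
    m <- as.matrix(data.table::fread(file.path(path, paste0(nm, ".csv"))))
    sig[[nm]] <- array(m, dim = c(n, mods$seq_len[i], mods$n_channels[i]))
  }
  trial_batch(sig, labels$emotion, labels$subject,
              n_emotions = meta$n_emotions, n_subjects = meta$n_subjects)
}
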