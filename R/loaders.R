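#' Load the DEAP multimodal emotion dataset
#'
#' DEAP is a license-gated archive (registration required) of 32 subjects
#' watching 40 one-minute music videos while 32-channel EEG and peripheral
#' physiology were recorded, with 1-9 self-ratings of valence and arousal per
#' trial. This loader never downloads anything: it reads a local per-subject
#' CSV export of the preprocessed archive.
#'
#' Because the distributed archive is a binary bundle (MATLAB/pickle), the
#' loader expects each subject exported to text first:
#' `sXX_data.csv` (40 rows, one per trial; `n_channels * seq_len` columns,
#' channel-major) and `sXX_labels.csv` (40 rows with `valence`, `arousal`
#' columns on the 1-9 scale), e.g. via a short Python snippet using the
#' archive's own reader. Channel-to-modality assignment follows the archive's
#' channel order and is configurable: by default the first 32 channels are
#' EEG and the named peripheral channels supply EOG (2), EMG (2) and GSR (1).
#'
#' @param path Directory containing the per-subject CSV exports.
#' @param task One of `"valence"`, `"arousal"` (binary at the conventional
#'   5.0 threshold on the 1-9 scale) or `"quaternary"` (the 2x2 product of
#'   binarized valence x arousal: 1 = low/low, 2 = low/high, 3 = high/low,
#'   4 = high/high).
#' @param threshold Binarization threshold on the rating scale.
#' @param seq_len,overlap Window length (samples) and overlap used to cut
#'   each trial into windows; the archive's own segmentation is not assumed.
#'   `seq_len = NULL` keeps one window per trial, truncated to the shortest
#'   trial length.
#' @param channel_map Named list giving, per modality, the (1-based) channel
#'   columns of the export assigned to it.
#' @return A [trial_batch()].
#' @export
load_deap <- function(path, task = c("valence", "arousal", "quaternary"),
                      threshold = 5.0, seq_len = NULL, overlap = 0,
                      channel_map = list(EEG = 1:32, EOG = 33:34,
                                         EMG = 35:36, GSR = 37L)) {
  task <- match.arg(task)
  files <- sort(list.files(path, pattern = "^s[0-9]+_data\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    stop(sprintf(paste0(
      "no DEAP export found under '%s'; expected per-subject files ",
      "sXX_data.csv (40 trials x channel-major samples) and sXX_labels.csv ",
      "(40 rows: valence, arousal)"), path), call. = FALSE)
  read_subject <- function(f) {
    lf <- sub("_data\\.csv$", "_labels.csv", f)
    if (!file.exists(lf))
      stop(sprintf("missing labels file '%s'", lf), call. = FALSE)
    list(data = as.matrix(data.table::fread(f)),
         ratings = data.table::fread(lf))
  }
  subs <- lapply(files, read_subject)
  n_ch <- max(unlist(channel_map))
  assemble_external(subs, channel_map, n_ch, seq_len, overlap,
                    label_fun = function(r) {
                      v <- as.integer(r$valence > threshold)
                      a <- as.integer(r$arousal > threshold)
                      switch(task,
                             valence = v + 1L,
                             arousal = a + 1L,
                             quaternary = 2L * v + a + 1L)
                    },
                    n_emotions = if (task == "quaternary") 4L else 2L)
}

#' Load the WESAD wearable stress/affect dataset
#'
#' WESAD (15 subjects, chest- and wrist-worn sensors) is license-gated; the
#' loader reads a local per-subject CSV export: `SXX_data.csv` (one row per
#' trial window, channel-major samples) and `SXX_labels.csv` with a `label`
#' column. Only the three affective conditions used for classification are
#' kept: 1 = neutral, 2 = stress, 3 = amusement; other protocol labels are
#' dropped. Which device channels feed each modality is export-side
#' configuration mirrored in `channel_map` (default: chest EMG/EDA plus two
#' auxiliary channels standing for the ocular surrogate).
#'
#' @param path Directory containing the per-subject CSV exports.
#' @param seq_len,overlap Windowing options, as in [load_deap()].
#' @param channel_map Named list of channel columns per modality.
#' @return A three-class [trial_batch()].
#' @export
load_wesad <- function(path, seq_len = NULL, overlap = 0,
                       channel_map = list(EEG = 1:4, EOG = 5:6,
                                          EMG = 7:8, GSR = 9L)) {
  files <- sort(list.files(path, pattern = "^S[0-9]+_data\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    stop(sprintf(paste0(
      "no WESAD export found under '%s'; expected per-subject files ",
      "SXX_data.csv and SXX_labels.csv (column `label`, 1=neutral, ",
      "2=stress, 3=amusement)"), path), call. = FALSE)
  subs <- lapply(files, function(f) {
    lf <- sub("_data\\.csv$", "_labels.csv", f)
    if (!file.exists(lf))
      stop(sprintf("missing labels file '%s'", lf), call. = FALSE)
    d <- as.matrix(data.table::fread(f))
    r <- data.table::fread(lf)
    keep <- r$label %in% 1:3
    list(data = d[keep, , drop = FALSE], ratings = r[keep])
  })
  assemble_external(subs, channel_map, max(unlist(channel_map)),
                    seq_len, overlap,
                    label_fun = function(r) as.integer(r$label),
                    n_emotions = 3L)
}

# Shared assembly for the external-dataset loaders: window each trial row,
# split channels into modalities, stack subjects.
assemble_external <- function(subs, channel_map, n_ch, seq_len, overlap,
                              label_fun, n_emotions) {
  sig_rows <- list(); emo <- integer(); subj <- integer()
  for (s in seq_along(subs)) {
    d <- subs[[s]]$data
    if (ncol(d) %% n_ch != 0L)
      stop(sprintf(paste0("subject %d: %d columns is not a multiple of the ",
                          "%d mapped channels (channel-major layout expected)"),
                   s, ncol(d), n_ch), call. = FALSE)
    total_len <- ncol(d) %/% n_ch
    win <- if (is.null(seq_len)) total_len else as.integer(seq_len)
    if (win > total_len)
      stop("`seq_len` exceeds the exported trial length", call. = FALSE)
    step <- max(1L, win - as.integer(overlap))
    starts <- seq(1L, total_len - win + 1L, by = step)
    labels <- label_fun(subs[[s]]$ratings)
    for (tr in seq_len(nrow(d))) {
      x <- matrix(d[tr, ], nrow = total_len)  # [time, channel], channel-major cols
      for (st in starts) {
        w <- x[st:(st + win - 1L), , drop = FALSE]
        sig_rows[[length(sig_rows) + 1L]] <-
          lapply(channel_map, function(cols) w[, cols, drop = FALSE])
        emo <- c(emo, labels[tr]); subj <- c(subj, s)
      }
    }
  }
  n <- length(sig_rows)
  sig <- lapply(names(channel_map), function(nm) {
    d1 <- dim(sig_rows[[1L]][[nm]])
    a <- array(0, dim = c(n, d1[1L], d1[2L]))
    for (r in seq_len(n)) a[r, , ] <- sig_rows[[r]][[nm]]
    a
  })
  names(sig) <- names(channel_map)
  trial_batch(sig, emo, subj, n_emotions = n_emotions,
              n_subjects = length(subs))
}
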