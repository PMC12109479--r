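test_that("synthetic generation is deterministic and correctly sized", {
  cfg <- synthetic_config(n_subjects = 3, n_emotions = 2,
                          trials_per_subject_per_emotion = 4,
                          modality_specs = tiny_specs(), seed = 7)
  b1 <- generate_synthetic(cfg)
  b2 <- generate_synthetic(cfg)
  expect_identical(b1, b2)
  expect_equal(n_trials(b1), 3 * 2 * 4)
  expect_setequal(modality_names(b1), c("EEG", "EOG", "GSR"))
  expect_equal(dim(b1$signals$EEG), c(24, 16, 4))
  # fully crossed, balanced design
  expect_true(all(table(b1$subject_ids, b1$emotion_labels) == 4))
  # different seed changes the data
  b3 <- generate_synthetic(synthetic_config(
    n_subjects = 3, n_emotions = 2, trials_per_subject_per_emotion = 4,
    modality_specs = tiny_specs(), seed = 8))
  expect_false(identical(b1$signals$EEG, b3$signals$EEG))
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(n_subjects = 0), "positive")
  expect_error(synthetic_config(trials_per_subject_per_emotion = -1), "positive")
  expect_error(synthetic_config(noise_sd = -0.1), "nonnegative")
  expect_error(
    synthetic_config(modality_specs = list(modality_spec("A", 2, 8),
                                           modality_spec("A", 1, 8))),
    "unique")
})

test_that("with all stochastic terms disabled, same-emotion trials are a shared template", {
  cfg <- synthetic_config(n_subjects = 3, n_emotions = 2,
                          trials_per_subject_per_emotion = 2,
                          modality_specs = tiny_specs(),
                          subject_bias_scale = 0, noise_sd = 0,
                          trial_amplitude_sd = 0, seed = 3)
  b <- generate_synthetic(cfg)
  k1 <- which(b$emotion_labels == 1)
  for (nm in modality_names(b))
    for (r in k1[-1])
      expect_equal(b$signals[[nm]][r, , ], b$signals[[nm]][k1[1], , ])
})

test_that("generated trials decompose into template + subject nuisance + noise", {
  cfg <- synthetic_config(n_subjects = 2, n_emotions = 2,
                          trials_per_subject_per_emotion = 10,
                          modality_specs = tiny_specs(32L),
                          subject_bias_scale = 1, noise_sd = 0.4,
                          trial_amplitude_sd = 0, seed = 11)
  b <- generate_synthetic(cfg)
  comp <- ctelcan:::synthetic_components(cfg)
  lat <- ctelcan:::synthetic_trial_latents(cfg, n_trials(b))
  resid <- c()
  for (r in seq_len(n_trials(b))) {
    s <- b$subject_ids[r]; k <- b$emotion_labels[r]
    for (nm in modality_names(b)) {
      w <- cfg$modality_effect_weights[[nm]]
      wave <- ctelcan:::burst_waveform(32L, comp$carrier_freq[k],
                                       lat$center[r], lat$phase[r])
      template <- cfg$emotion_effect_scale * w * lat$amp[r] *
        outer(wave, comp$patterns[[k]][[nm]])
      expect_r <- comp$gains[[s]][[nm]] * template +
        comp$offsets[[s]][[nm]]
      resid <- c(resid, as.vector(b$signals[[nm]][r, , ] - expect_r))
    }
  }
  expect_lt(abs(mean(resid)), 0.01)
  expect_equal(sd(resid), 0.4, tolerance = 0.05)
})

test_that("LOSO splits partition the trials with one subject held out each", {
  b <- tiny_batch(n_subjects = 8, trials = 5)
  splits <- loso_splits(b)
  expect_length(splits, 8)
  all_test <- integer()
  for (sp in splits) {
    expect_setequal(unique(b$subject_ids[sp$test_index]), sp$held_out_subject)
    expect_false(sp$held_out_subject %in% b$subject_ids[sp$train_index])
    expect_length(intersect(sp$train_index, sp$test_index), 0)
    expect_setequal(union(sp$train_index, sp$test_index), seq_len(n_trials(b)))
    all_test <- c(all_test, sp$test_index)
  }
  expect_equal(sort(all_test), seq_len(n_trials(b)))  # exhaustive, no dups
  expect_equal(lengths(lapply(splits, `[[`, "test_index")),
               rep(n_trials(b) / 8, 8))
})

test_that("LOSO handles one-trial-per-subject batches and rejects one subject", {
  b <- tiny_batch(n_subjects = 4, n_emotions = 1, trials = 1)
  splits <- loso_splits(b)
  expect_length(splits, 4)
  expect_true(all(lengths(lapply(splits, `[[`, "test_index")) == 1))
  one <- subset_trials(b, which(b$subject_ids == 1))
  expect_error(loso_splits(one), "single-subject")
})

test_that("remove_modality drops exactly one modality and keeps labels", {
  b <- tiny_batch()
  reduced <- remove_modality(b, "EOG")
  expect_setequal(modality_names(reduced), c("EEG", "GSR"))
  expect_identical(reduced$emotion_labels, b$emotion_labels)
  expect_identical(reduced$subject_ids, b$subject_ids)
  expect_equal(n_trials(reduced), n_trials(b))
  expect_error(remove_modality(reduced, "EOG"), "available: EEG, GSR")
  # removing each modality in turn yields distinct reduced batches
  alts <- lapply(modality_names(b), function(m) remove_modality(b, m))
  sigs <- lapply(alts, function(x) sort(modality_names(x)))
  expect_equal(length(unique(sigs)), length(alts))
})

test_that("gaussian corruption perturbs signals but never labels", {
  b <- tiny_batch(trials = 8, L = 32)
  expect_identical(add_gaussian_noise(b, 0), b)
  n1 <- add_gaussian_noise(b, 1, seed = 4)
  n2 <- add_gaussian_noise(b, 1, seed = 4)
  expect_identical(n1, n2)
  expect_identical(n1$emotion_labels, b$emotion_labels)
  expect_identical(n1$subject_ids, b$subject_ids)
  # law of large numbers: per-batch variance of the added noise ~ 1
  diff <- unlist(Map(function(a, c) as.vector(a - c), n1$signals, b$signals))
  expect_equal(var(diff), 1, tolerance = 0.05)
  expect_error(add_gaussian_noise(b, -1), "nonnegative")
})

test_that("trial batches round-trip through the text container", {
  b <- tiny_batch(trials = 2)
  dir <- file.path(tempdir(), "tb-roundtrip")
  write_trial_batch(b, dir)
  b2 <- read_trial_batch(dir)
  expect_equal(b2$signals, b$signals, tolerance = 1e-12)
  expect_identical(b2$emotion_labels, b$emotion_labels)
  expect_identical(b2$subject_ids, b$subject_ids)
  expect_identical(b2$n_emotions, b$n_emotions)
  unlink(dir, recursive = TRUE)
  expect_error(read_trial_batch(file.path(tempdir(), "nope")), "meta.json")
})

test_that("trial batch invariants are enforced", {
  b <- tiny_batch()
  expect_error(trial_batch(list(A = array(0, c(2, 4, 1)),
                                B = array(0, c(3, 4, 1))),
                           c(1, 1), c(1, 1)),
               "same number of trials")
  bad <- b; bad$signals$EEG[1] <- NA
  expect_error(validate_trial_batch(bad), "non-finite")
  expect_error(trial_batch(b$signals, rep(99, n_trials(b)), b$subject_ids,
                           n_emotions = 2), "1..n_emotions")
})
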