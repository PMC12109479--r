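test_that("training runs end to end and evaluation counts correctly", {
  b <- tiny_batch()
  cfg <- tiny_exp_config()
  m <- train_fold(b, cfg)
  expect_s3_class(m, "ctelcan_model")
  expect_length(m$loss_traces, cfg$epochs)
  expect_s3_class(m$loss_traces[[1]], "loss_report")
  pred <- predict_emotion(m, b)
  expect_length(pred$class, n_trials(b))
  expect_true(all(abs(rowSums(pred$probs) - 1) < 1e-8))
  acc <- evaluate(m, b)
  expect_equal(acc, 100 * mean(pred$class == b$emotion_labels))
  expect_gte(acc, 0); expect_lte(acc, 100)
})

test_that("training is deterministic given the seed", {
  b <- tiny_batch()
  cfg <- tiny_exp_config(seed = 9)
  m1 <- train_fold(b, cfg)
  m2 <- train_fold(b, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_traces, m2$loss_traces)
  m3 <- train_fold(b, tiny_exp_config(seed = 10))
  expect_false(identical(m1$params, m3$params))
})

test_that("training reaches full accuracy on cleanly separable data", {
  b <- generate_synthetic(synthetic_config(
    n_subjects = 3, n_emotions = 2, trials_per_subject_per_emotion = 4,
    modality_specs = tiny_specs(), subject_bias_scale = 0, noise_sd = 0,
    emotion_effect_scale = 2, seed = 13))
  m <- train_fold(b, tiny_exp_config(epochs = 15L, lr = 5e-3, dropout = 0))
  expect_equal(evaluate(m, b), 100)
})

test_that("the adversary requires at least two training subjects", {
  b <- tiny_batch()
  one <- subset_trials(b, which(b$subject_ids == 1))
  expect_error(train_fold(one, tiny_exp_config()), "2 training subjects")
  # but plain supervised training on one subject is allowed
  m <- train_fold(one, tiny_exp_config(adversary = "off", epochs = 1L))
  expect_s3_class(m, "ctelcan_model")
})

test_that("joint GAN training augments batches and reports its loss", {
  b <- tiny_batch(trials = 2)
  cfg <- tiny_exp_config(epochs = 2L, augmentation = "csagan")
  m <- train_fold(b, cfg)
  expect_s3_class(m$gan, "csagan")
  expect_true(all(vapply(m$loss_traces, function(tr) tr$l_gan != 0, logical(1))))
  m0 <- train_fold(b, tiny_exp_config(epochs = 2L))
  expect_null(m0$gan)
  expect_true(all(vapply(m0$loss_traces, function(tr) tr$l_gan == 0, logical(1))))
})

test_that("LOSO evaluation aggregates per-subject accuracies", {
  b <- tiny_batch(n_subjects = 3)
  r <- run_loso(b, tiny_exp_config())
  expect_length(r$per_subject_accuracy, 3)
  expect_equal(r$mean, mean(r$per_subject_accuracy))
  expect_equal(r$sd, sqrt(mean((r$per_subject_accuracy - r$mean)^2)))
  # population-sd formula on a hand example
  expect_equal(ctelcan:::sd_pop(c(60, 70, 80)), sqrt(200 / 3))
})

test_that("evaluation on missing modalities is opt-in", {
  b <- tiny_batch()
  m <- train_fold(b, tiny_exp_config(epochs = 1L))
  reduced <- remove_modality(b, "EOG")
  expect_error(evaluate(m, reduced), "lacks modalities")
  acc <- evaluate(m, reduced, allow_missing = TRUE)
  expect_gte(acc, 0); expect_lte(acc, 100)
})

test_that("the ablation grid runs one controlled cell per setting", {
  b <- tiny_batch(n_subjects = 3, trials = 2)
  cfg <- tiny_exp_config(epochs = 1L)
  tab <- run_ablation(b, cfg, list(ct_layers = 0:1, adversary = c("on", "off")))
  expect_equal(nrow(tab), 4)
  expect_true(all(c("ct_layers", "adversary", "mean", "sd") %in% names(tab)))
  expect_length(attr(tab, "results"), 4)
  expect_error(run_ablation(b, cfg, list(bogus = 1)), "subset")
})

test_that("robustness runners corrupt only the test side", {
  b <- tiny_batch(n_subjects = 3, trials = 2)
  cfg <- tiny_exp_config(epochs = 1L)
  clean <- run_loso(b, cfg)
  r0 <- run_robustness(b, cfg, "gaussian-noise", level = 0)
  expect_identical(r0$per_subject_accuracy, clean$per_subject_accuracy)
  r1 <- run_robustness(b, cfg, "gaussian-noise", level = 2)
  expect_length(r1$per_subject_accuracy, 3)
  rd <- run_robustness(b, cfg, "drop-modality", level = "GSR")
  expect_equal(attr(rd, "mode"), "drop-modality")
  expect_error(run_robustness(b, cfg, "drop-modality", level = "ECG"),
               "unknown modality")
  one <- b
  for (m in c("EOG", "GSR")) one <- remove_modality(one, m)
  expect_error(run_robustness(one, cfg, "drop-modality", level = "EEG"),
               "only modality")
})

test_that("the lambda warm-up schedule ramps from 0 toward 1", {
  expect_equal(lambda_schedule(0), 0)
  expect_equal(lambda_schedule(1), 2 / (1 + exp(-10)) - 1, tolerance = 1e-12)
  p <- seq(0, 1, 0.1)
  expect_true(all(diff(lambda_schedule(p)) >= 0))
  expect_true(all(lambda_schedule(p) <= 1))
})
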