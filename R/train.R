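#' Experiment configuration
#'
#' Bundles the optimizer, feature-extractor, augmenter and adversarial-head
#' settings of one training run. The shipped defaults are the reference
#' protocol (Adam at learning rate 1e-4, batch size 128, 50 epochs, gradient
#' clipping at norm 10, dropout 0.1, a 4-layer / 4-head transformer with
#' hidden size 128, c-SAGAN learning rate 1e-4); desk-scale studies override
#' them explicitly.
#'
#' @param lr Adam learning rate for the main network.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (fixed horizon; no early stopping).
#' @param clip_norm Global gradient-norm clip of the main update.
#' @param ct A [ct_config()].
#' @param lcan A [lcan_config()].
#' @param csagan A [sagan_config()].
#' @param augmentation `"csagan"` trains the conditional GAN alongside the
#'   main network and mixes generated feature-space samples into each batch;
#'   `"none"` disables augmentation.
#' @param adversary `"on"` wires the modality/subject classifiers through
#'   the gradient reversal layer; `"off"` forces the reversal strength to 0
#'   (plain multitask training, no invariance pressure).
#' @param seed Integer seed governing initialization, shuffling, dropout and
#'   GAN noise.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(lr = 1e-4, batch_size = 128L, epochs = 50L,
                              clip_norm = 10,
                              ct = ct_config(), lcan = lcan_config(),
                              csagan = sagan_config(),
                              augmentation = c("csagan", "none"),
                              adversary = c("on", "off"),
                              seed = 1L) {
  augmentation <- match.arg(augmentation)
  adversary <- match.arg(adversary)
  if (epochs < 1L || batch_size < 1L)
    stop("`epochs` and `batch_size` must be >= 1", call. = FALSE)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), clip_norm = clip_norm,
                 ct = ct, lcan = lcan, csagan = csagan,
                 augmentation = augmentation, adversary = adversary,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# current reversal strength for a training-progress fraction p in [0, 1]
current_lambda <- function(cfg, p) {
  if (cfg$adversary == "off") return(0)
  if (cfg$lcan$lambda_mode == "constant") return(cfg$lcan$lambda)
  min(cfg$lcan$lambda, lambda_schedule(p))
}

#' Train one model on one training batch
#'
#' Runs the end-to-end loop: per minibatch, (i) if augmentation is enabled,
#' one discriminator/generator update of the conditional GAN on the current
#' feature-extractor outputs followed by synthesis of `ratio * n` conditioned
#' samples, then (ii) one joint update of the feature extractor, conv-block
#' feature learner and all heads on the real-plus-generated batch, with the
#' modality/subject gradients reversed by the current lambda and the global
#' gradient norm clipped. Generated samples contribute to the emotion and
#' modality losses but never to the subject loss (they carry no identity).
#' Fully deterministic given `cfg$seed`.
#'
#' @param batch Training [trial_batch()] (at least 2 subjects when the
#'   adversary is on).
#' @param cfg An [experiment_config()].
#' @return A `ctelcan_model`: parameters, configs, the subject-label mapping,
#'   the trained GAN bundle (if any) and per-epoch `loss_traces`
#'   ([total_loss()] reports averaged over the epoch's steps).
#' @export
train_fold <- function(batch, cfg) {
  stopifnot(inherits(batch, "trial_batch"), inherits(cfg, "experiment_config"))
  mods <- sort(modality_names(batch))
  specs <- modality_specs_of(batch)
  specs <- specs[order(vapply(specs, `[[`, character(1), "name"))]
  for (sp in specs) if (sp$seq_len < 4L)
    stop("sequence length must be >= 4 (conv-block receptive field)", call. = FALSE)
  train_subjects <- sort(unique(batch$subject_ids))
  if (cfg$adversary == "on" && length(train_subjects) < 2L)
    stop("adversarial training requires at least 2 training subjects", call. = FALSE)
  sub_idx0 <- match(batch$subject_ids, train_subjects) - 1L
  n <- n_trials(batch)
  ecfg <- engine_config(cfg$ct, cfg$lcan)

  params <- init_model_params(specs, cfg$ct, cfg$lcan, batch$n_emotions,
                              length(train_subjects), seed = cfg$seed)
  opt <- adam_init(params)
  gan <- NULL
  if (cfg$augmentation == "csagan") {
    fspecs <- lapply(specs, function(sp)
      list(L = sp$seq_len, D = cfg$ct$model_dim))
    names(fspecs) <- mods
    gan <- csagan_init(fspecs, batch$n_emotions, cfg$csagan,
                       seed = cfg$seed + 7L)
  }

  sig <- batch_to_cubes(batch, mods)
  emo0 <- batch$emotion_labels - 1L
  w <- cfg$lcan$weights
  n_steps_total <- cfg$epochs * max(1L, ceiling(n / cfg$batch_size))
  step <- 0L
  traces <- vector("list", cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed + 1009L * ep, sample.int(n))
    starts <- seq(1L, n, by = cfg$batch_size)
    comp_sums <- c(l_mod = 0, l_sub = 0, l_emo = 0, l_gan = 0)
    for (st in starts) {
      step <- step + 1L
      idx <- ord[st:min(st + cfg$batch_size - 1L, n)]
      bsig <- lapply(sig, function(a) a[, , idx, drop = FALSE])
      lambda <- current_lambda(cfg, step / n_steps_total)
      gen_feats <- list(); gen_emo <- integer(); l_gan <- 0
      if (!is.null(gan) && cfg$csagan$ratio > 0) {
        feats <- cpp_ct_forward(bsig, params, ecfg, -1L)
        real_f <- lapply(feats$Y, cubes_to_array)
        names(real_f) <- mods
        gs <- gan_train_step(gan, real_f, batch$emotion_labels[idx],
                             seed = cfg$seed + 13L * step)
        gan <- gs$gan
        l_gan <- gs$l_d + gs$l_g
        aug <- augment_batch(real_f, batch$emotion_labels[idx], gan,
                             ratio = cfg$csagan$ratio,
                             seed = cfg$seed + 17L * step)
        keep <- aug$is_synthetic
        gen_feats <- lapply(aug$features, function(a)
          aperm(a[keep, , , drop = FALSE], c(2L, 3L, 1L)))
        gen_emo <- aug$labels[keep] - 1L
      }
      out <- cpp_model_loss_grad(bsig, emo0[idx], sub_idx0[idx],
                                 gen_feats, gen_emo, params, ecfg,
                                 lambda, unname(w[c("alpha", "beta", "gamma_w")]),
                                 length(train_subjects), batch$n_emotions,
                                 as.integer((cfg$seed + step) %% .Machine$integer.max))
      for (nm in c("l_mod", "l_sub", "l_emo"))
        if (!is.finite(out[[nm]]))
          stop(sprintf("training diverged: loss component `%s` is not finite (step %d)",
                       nm, step), call. = FALSE)
      up <- adam_step(params, out$grads, opt, cfg$lr, cfg$clip_norm)
      params <- up$params; opt <- up$state
      comp_sums <- comp_sums +
        c(out$l_mod, out$l_sub, out$l_emo, l_gan)
    }
    k <- length(starts)
    traces[[ep]] <- total_loss(comp_sums[[1L]] / k, comp_sums[[2L]] / k,
                               comp_sums[[3L]] / k, comp_sums[[4L]] / k,
                               weights = w)
  }

  structure(list(params = params, ct = cfg$ct, lcan = cfg$lcan,
                 modalities = mods, specs = specs,
                 n_emotions = batch$n_emotions,
                 train_subjects = train_subjects,
                 gan = gan, loss_traces = traces, config = cfg),
            class = "ctelcan_model")
}

#' @export
print.ctelcan_model <- function(x, ...) {
  cat(sprintf(
    "<ctelcan_model: %s; D=%d, %d layers, %d heads; %d emotions, %d train subjects>\n",
    paste(x$modalities, collapse = "+"), x$ct$model_dim, x$ct$n_layers,
    x$ct$n_heads, x$n_emotions, length(x$train_subjects)))
  invisible(x)
}

# re-index the flat parameter list for a subset of the model's modalities
# (positional names proj.i.* / conv.i.* refer to the kept, re-sorted set)
subset_params <- function(model, keep) {
  pos <- match(keep, model$modalities)
  p <- model$params
  out <- list()
  for (nm in names(p)) {
    m <- regmatches(nm, regexec("^(proj|conv)\\.([0-9]+)\\.(.+)$", nm))[[1L]]
    if (length(m)) {
      old <- as.integer(m[3L])
      new <- match(old, pos)
      if (is.na(new)) next
      out[[paste0(m[2L], ".", new, ".", m[4L])]] <- p[[nm]]
    } else {
      out[[nm]] <- p[[nm]]
    }
  }
  out
}

#' Predict emotion classes for a batch
#'
#' Evaluation-mode forward pass: only the emotion head is active (the
#' modality and subject heads are training-time devices, and the held-out
#' subject has no meaningful subject label). Argmax ties break to the lowest
#' class index. The batch may miss modalities the model was trained on only
#' when `allow_missing = TRUE` (modality-loss evaluation); at least one
#' trained modality must remain.
#'
#' @param model A trained `ctelcan_model`.
#' @param batch A [trial_batch()].
#' @param allow_missing Permit evaluating on a subset of the trained
#'   modalities.
#' @return List with `class` (predicted labels), `probs` (`n x K`) and
#'   `fused` (pooled fused features, one row per trial).
#' @export
predict_emotion <- function(model, batch, allow_missing = FALSE) {
  stopifnot(inherits(model, "ctelcan_model"), inherits(batch, "trial_batch"))
  present <- intersect(model$modalities, modality_names(batch))
  if (length(present) < length(model$modalities) && !allow_missing)
    stop(sprintf("batch lacks modalities the model expects: %s",
                 paste(setdiff(model$modalities, modality_names(batch)),
                       collapse = ", ")), call. = FALSE)
  if (!length(present))
    stop("no trained modality present in the batch", call. = FALSE)
  params <- if (length(present) == length(model$modalities)) model$params
            else subset_params(model, present)
  sig <- batch_to_cubes(batch, present)
  out <- cpp_model_predict(sig, params, engine_config(model$ct, model$lcan))
  pr <- out$probs
  cls <- max.col(pr, ties.method = "first")
  list(class = cls, probs = pr, fused = out$fused)
}

#' Accuracy of a model on a test batch
#'
#' @param model A trained `ctelcan_model`.
#' @param batch Non-empty test [trial_batch()].
#' @param allow_missing See [predict_emotion()].
#' @return Accuracy in percent (0-100).
#' @export
evaluate <- function(model, batch, allow_missing = FALSE) {
  if (n_trials(batch) == 0L) stop("test batch is empty", call. = FALSE)
  pred <- predict_emotion(model, batch, allow_missing = allow_missing)
  100 * mean(pred$class == batch$emotion_labels)
}

# population standard deviation, the spread reported next to LOSO means
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Leave-one-subject-out evaluation
#'
#' Trains one model per LOSO fold (all folds share the same configuration
#' and seed, offset per fold) and reports the per-subject unseen-subject
#' accuracies, their arithmetic mean and population standard deviation.
#'
#' @param batch A [trial_batch()] with `>= 2` subjects.
#' @param cfg An [experiment_config()].
#' @param test_transform Optional function applied to each fold's test batch
#'   before evaluation (robustness corruption hook).
#' @param eval_modalities Optional character vector: evaluate using only
#'   these modalities (modality-loss evaluation of a fully trained model).
#' @param keep_models Retain the trained per-fold models in the result.
#' @return A `loso_result`: `per_subject_accuracy`, `mean`, `sd`,
#'   `loss_traces` (per fold) and optionally `models`.
#' @export
run_loso <- function(batch, cfg, test_transform = NULL,
                     eval_modalities = NULL, keep_models = FALSE) {
  splits <- loso_splits(batch)
  accs <- numeric(length(splits))
  names(accs) <- vapply(splits, `[[`, integer(1), "held_out_subject")
  traces <- vector("list", length(splits))
  models <- if (keep_models) vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + 131L * i
    model <- train_fold(subset_trials(batch, sp$train_index), fold_cfg)
    test <- subset_trials(batch, sp$test_index)
    if (!is.null(test_transform)) test <- test_transform(test)
    if (!is.null(eval_modalities)) {
      keep <- intersect(modality_names(test), eval_modalities)
      for (drop in setdiff(modality_names(test), keep))
        test <- remove_modality(test, drop)
      accs[i] <- evaluate(model, test, allow_missing = TRUE)
    } else {
      accs[i] <- evaluate(model, test)
    }
    traces[[i]] <- model$loss_traces
    if (keep_models) models[[i]] <- model
  }
  structure(list(per_subject_accuracy = accs, mean = mean(accs),
                 sd = sd_pop(accs), loss_traces = traces,
                 models = models),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result: mean %.2f%% / sd %.2f over %d subjects>\n",
              x$mean, x$sd, length(x$per_subject_accuracy)))
  invisible(x)
}

#' Ablation grid over augmentation, adversary and transformer depth
#'
#' Runs one LOSO evaluation per grid cell with identical seeds across cells,
#' so differences are attributable to the switches alone.
#'
#' @param batch A [trial_batch()].
#' @param cfg Base [experiment_config()].
#' @param grid Named list with any of `augmentation` (`"none"`/`"csagan"`),
#'   `adversary` (`"on"`/`"off"`), `ct_layers` (integers `>= 0`; `0` also
#'   bypasses the cross-modal attention block).
#' @return A data.frame with one row per cell (settings, mean, sd) and the
#'   full `loso_result`s as attribute `"results"`.
#' @export
run_ablation <- function(batch, cfg, grid) {
  allowed <- c("augmentation", "adversary", "ct_layers")
  if (!length(grid) || !all(names(grid) %in% allowed))
    stop("`grid` must name a subset of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell_cfg <- cfg
    if (!is.null(cells$augmentation)) cell_cfg$augmentation <- cells$augmentation[i]
    if (!is.null(cells$adversary)) cell_cfg$adversary <- cells$adversary[i]
    if (!is.null(cells$ct_layers)) {
      u <- as.integer(cells$ct_layers[i])
      cell_cfg$ct$n_layers <- u
      cell_cfg$ct$cross_attention <- u > 0L
    }
    results[[i]] <- run_loso(batch, cell_cfg)
  }
  out <- cbind(cells,
               mean = vapply(results, `[[`, numeric(1), "mean"),
               sd = vapply(results, `[[`, numeric(1), "sd"))
  attr(out, "results") <- results
  out
}

#' Robustness experiments: modality loss and Gaussian noise
#'
#' `mode = "drop-modality"` either evaluates a model trained on all
#' modalities with `level` removed from the test folds (`retrain = FALSE`)
#' or retrains without the modality altogether (`retrain = TRUE`); both
#' sub-modes are reported as what they are. `mode = "gaussian-noise"` trains
#' on clean data and corrupts the test folds with [add_gaussian_noise()] at
#' `sd = level` (so `level = 0` reproduces the clean run bit-for-bit).
#'
#' @param batch A [trial_batch()].
#' @param cfg An [experiment_config()].
#' @param mode `"drop-modality"` or `"gaussian-noise"`.
#' @param level Modality name, or noise standard deviation.
#' @param retrain Drop-modality sub-mode (see above).
#' @return A `loso_result` with attributes `mode`, `level`, `retrain`.
#' @export
run_robustness <- function(batch, cfg, mode = c("drop-modality", "gaussian-noise"),
                           level, retrain = FALSE) {
  mode <- match.arg(mode)
  res <- switch(mode,
    "drop-modality" = {
      if (!level %in% modality_names(batch))
        stop(sprintf("unknown modality '%s'; available: %s", level,
                     paste(modality_names(batch), collapse = ", ")),
             call. = FALSE)
      if (length(modality_names(batch)) == 1L)
        stop("cannot drop the only modality", call. = FALSE)
      if (retrain) run_loso(remove_modality(batch, level), cfg)
      else run_loso(batch, cfg,
                    eval_modalities = setdiff(modality_names(batch), level))
    },
    "gaussian-noise" = {
      sdl <- as.numeric(level)
      if (is.na(sdl) || sdl < 0) stop("noise sd must be >= 0", call. = FALSE)
      run_loso(batch, cfg, test_transform = function(tb)
        add_gaussian_noise(tb, sdl, seed = cfg$seed + 997L))
    })
  attr(res, "mode") <- mode
  attr(res, "level") <- level
  attr(res, "retrain") <- retrain
  res
}
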