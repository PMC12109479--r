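# Small fixtures shared across the test files. Everything is generated in
# code; sizes are kept tiny so the full unit suite runs in seconds.

tiny_specs <- function(L = 16L) {
  list(modality_spec("EEG", 4L, L), modality_spec("EOG", 2L, L),
       modality_spec("GSR", 1L, L))
}

tiny_batch <- function(n_subjects = 3L, n_emotions = 2L, trials = 3L,
                       L = 16L, seed = 5L, ...) {
  generate_synthetic(synthetic_config(
    n_subjects = n_subjects, n_emotions = n_emotions,
    trials_per_subject_per_emotion = trials,
    modality_specs = tiny_specs(L), seed = seed, ...))
}

tiny_exp_config <- function(seed = 1L, epochs = 2L, n_layers = 1L,
                            adversary = "on", augmentation = "none",
                            dropout = 0.1, lr = 2e-3, batch_size = 8L,
                            n_heads = 2L, model_dim = 16L) {
  experiment_config(
    lr = lr, batch_size = batch_size, epochs = epochs,
    ct = ct_config(model_dim = model_dim, n_heads = n_heads,
                   n_layers = n_layers, dropout = dropout,
                   cross_attention = n_layers > 0L),
    lcan = lcan_config(conv_channels = 8L, emo_hidden = 16L, head_hidden = 8L),
    csagan = sagan_config(noise_dim = 8L, emb_dim = 4L, hidden = 16L,
                          d_channels = 8L, lr = 1e-3, ratio = 0.5),
    augmentation = augmentation, adversary = adversary, seed = seed)
}

# engine loss + gradients for a batch under explicit lambda/weights
engine_loss_grad <- function(batch, params, ct, lcan, lambda, weights,
                             dropout_seed = -1L, n_sub = NULL) {
  mods <- sort(modality_names(batch))
  sig <- ctelcan:::batch_to_cubes(batch, mods)
  if (is.null(n_sub)) n_sub <- length(unique(batch$subject_ids))
  ctelcan:::cpp_model_loss_grad(
    sig, batch$emotion_labels - 1L, batch$subject_ids - 1L,
    list(), integer(), params, ctelcan:::engine_config(ct, lcan),
    lambda, weights, n_sub, batch$n_emotions, dropout_seed)
}

tiny_model_params <- function(batch, ct, lcan, seed = 2L) {
  specs <- modality_specs_of(batch)
  specs <- specs[order(vapply(specs, `[[`, character(1), "name"))]
  init_model_params(specs, ct, lcan, batch$n_emotions,
                    length(unique(batch$subject_ids)), seed = seed)
}

# triple-loop scaled dot-product attention oracle (independent of the
# package's vectorized implementation)
attention_oracle <- function(query, context, W_q, W_k, W_v) {
  Q <- query %*% W_q; K <- context %*% W_k; V <- context %*% W_v
  L <- nrow(Q); Lt <- nrow(K); Da <- ncol(W_q)
  out <- matrix(0, L, ncol(W_v))
  probs <- matrix(0, L, Lt)
  for (i in seq_len(L)) {
    s <- numeric(Lt)
    for (j in seq_len(Lt)) {
      acc <- 0
      for (d in seq_len(Da)) acc <- acc + Q[i, d] * K[j, d]
      s[j] <- acc / sqrt(Da)
    }
    e <- exp(s - max(s))
    p <- e / sum(e)
    probs[i, ] <- p
    for (j in seq_len(Lt)) out[i, ] <- out[i, ] + p[j] * V[j, ]
  }
  list(output = out, probs = probs)
}

# double-loop SAGAN self-attention oracle over a channels x positions map
self_attention_oracle <- function(x, layer) {
  Cn <- ncol(x)
  f <- layer$Wf %*% x; g <- layer$Wg %*% x; h <- layer$Wh %*% x
  o <- matrix(0, nrow(x), Cn)
  for (j in seq_len(Cn)) {
    s <- numeric(Cn)
    for (i in seq_len(Cn)) s[i] <- sum(f[, i] * g[, j])
    beta <- exp(s - max(s)); beta <- beta / sum(beta)
    agg <- 0
    for (i in seq_len(Cn)) agg <- agg + beta[i] * h[, i]
    o[, j] <- layer$Wv %*% agg
  }
  layer$gamma * o + x
}

with_seed <- ctelcan:::with_seed
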