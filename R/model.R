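#' Adversarial learning-classifying network configuration
#'
#' Hyperparameters of the feature learner and the three classifier heads.
#' The modality and subject classifiers are attached through a gradient
#' reversal layer; `lambda_mode = "schedule"` ramps the reversal strength
#' with training progress via [lambda_schedule()], `"constant"` holds it at
#' `lambda`.
#'
#' @param conv_channels Output channels of both conv-block stages.
#' @param emo_hidden Hidden width of the two-layer emotion classifier.
#' @param head_hidden Hidden width of the modality/subject classifiers.
#' @param lambda_mode `"schedule"` or `"constant"`.
#' @param lambda Reversal strength used in constant mode (and the cap of the
#'   schedule).
#' @param weights Named loss weights `alpha` (modality), `beta` (subject),
#'   `gamma_w` (emotion), `phi` (GAN) of the joint objective.
#' @return An object of class `lcan_config`.
#' @export
lcan_config <- function(conv_channels = 32L, emo_hidden = 128L,
                        head_hidden = 64L,
                        lambda_mode = c("schedule", "constant"), lambda = 1,
                        weights = c(alpha = 1, beta = 1, gamma_w = 1, phi = 1)) {
  lambda_mode <- match.arg(lambda_mode)
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  w <- weights[c("alpha", "beta", "gamma_w", "phi")]
  if (anyNA(w)) stop("`weights` must name alpha, beta, gamma_w, phi", call. = FALSE)
  structure(list(conv_channels = as.integer(conv_channels),
                 emo_hidden = as.integer(emo_hidden),
                 head_hidden = as.integer(head_hidden),
                 lambda_mode = lambda_mode, lambda = lambda, weights = w),
            class = "lcan_config")
}

# Flat config list consumed by the C++ engine.
engine_config <- function(ct, lcan = lcan_config()) {
  list(model_dim = ct$model_dim, n_heads = ct$n_heads, n_layers = ct$n_layers,
       ffn_mult = ct$ffn_mult, cross_attention = ct$cross_attention,
       dropout = ct$dropout, conv_channels = lcan$conv_channels,
       emo_hidden = lcan$emo_hidden, head_hidden = lcan$head_hidden)
}

xavier <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

# One conv-block parameter set (used per modality by the feature learner).
init_conv_block <- function(d_in, channels) {
  list(K1 = matrix(stats::rnorm(3 * d_in * channels, sd = sqrt(2 / (3 * d_in))),
                   3 * d_in, channels),
       # the LN shift starts slightly positive so freshly normalized
       # (including zero-variance) rows sit on the smooth side of the ReLU
       b1 = numeric(channels), g1 = rep(1, channels), be1 = rep(0.1, channels),
       K2 = matrix(stats::rnorm(3 * channels^2, sd = sqrt(2 / (3 * channels))),
                   3 * channels, channels),
       b2 = numeric(channels), g2 = rep(1, channels), be2 = rep(0.1, channels))
}

#' Initialize the full model parameter set
#'
#' Builds the flat named parameter list of the feature extractor, conv-block
#' feature learner and classifier heads, Xavier/He initialized under the
#' given seed. Modalities are always handled in sorted-name order.
#'
#' @param specs List of [modality_spec()] for the modalities the model sees.
#' @param ct A [ct_config()].
#' @param lcan A [lcan_config()].
#' @param n_emotions Emotion-class count of the emotion head.
#' @param n_train_subjects Output size of the subject head (the training
#'   subjects only; the held-out subject has no meaningful label). `0`
#'   omits the subject head.
#' @param seed Integer seed.
#' @return Named list of parameter matrices/vectors.
#' @export
init_model_params <- function(specs, ct, lcan, n_emotions, n_train_subjects,
                              seed = 1L) {
  nms <- vapply(specs, `[[`, character(1), "name")
  specs <- specs[order(nms)]
  D <- ct$model_dim
  with_seed(seed, {
    p <- list()
    for (i in seq_along(specs)) {
      b <- paste0("proj.", i, ".")
      p[[paste0(b, "W")]] <- xavier(specs[[i]]$n_channels, D)
      p[[paste0(b, "b")]] <- numeric(D)
    }
    if (ct$cross_attention) {
      p[["cross.Wq"]] <- xavier(D, D); p[["cross.Wk"]] <- xavier(D, D)
      p[["cross.Wv"]] <- xavier(D, D); p[["cross.Wo"]] <- xavier(D, D)
      p[["cross.lnq_g"]] <- rep(1, D); p[["cross.lnq_b"]] <- numeric(D)
      p[["cross.lnc_g"]] <- rep(1, D); p[["cross.lnc_b"]] <- numeric(D)
    }
    Dff <- ct$ffn_mult * D
    for (l in seq_len(ct$n_layers)) {
      b <- paste0("enc.", l, ".")
      p[[paste0(b, "ln1_g")]] <- rep(1, D); p[[paste0(b, "ln1_b")]] <- numeric(D)
      p[[paste0(b, "ln2_g")]] <- rep(1, D); p[[paste0(b, "ln2_b")]] <- numeric(D)
      p[[paste0(b, "Wq")]] <- xavier(D, D); p[[paste0(b, "Wk")]] <- xavier(D, D)
      p[[paste0(b, "Wv")]] <- xavier(D, D); p[[paste0(b, "Wo")]] <- xavier(D, D)
      p[[paste0(b, "W1")]] <- xavier(D, Dff); p[[paste0(b, "b1")]] <- numeric(Dff)
      p[[paste0(b, "W2")]] <- xavier(Dff, D); p[[paste0(b, "b2")]] <- numeric(D)
    }
    C <- lcan$conv_channels
    for (i in seq_along(specs)) {
      blk <- init_conv_block(D, C)
      for (nm in names(blk)) p[[paste0("conv.", i, ".", nm)]] <- blk[[nm]]
    }
    M <- length(specs)
    p[["mod_head.W1"]] <- xavier(C, lcan$head_hidden)
    p[["mod_head.b1"]] <- numeric(lcan$head_hidden)
    p[["mod_head.W2"]] <- xavier(lcan$head_hidden, M)
    p[["mod_head.b2"]] <- numeric(M)
    if (n_train_subjects > 0L) {
      p[["sub_head.W1"]] <- xavier(C, lcan$head_hidden)
      p[["sub_head.b1"]] <- numeric(lcan$head_hidden)
      p[["sub_head.W2"]] <- xavier(lcan$head_hidden, n_train_subjects)
      p[["sub_head.b2"]] <- numeric(n_train_subjects)
    }
    p[["emo_head.W1"]] <- xavier(C, lcan$emo_hidden)
    p[["emo_head.b1"]] <- numeric(lcan$emo_hidden)
    p[["emo_head.W2"]] <- xavier(lcan$emo_hidden, n_emotions)
    p[["emo_head.b2"]] <- numeric(n_emotions)
    p
  })
}

#' Convolutional feature-learner block
#'
#' Applies one modality's feature-learner: two stages of width-3 (same-pad)
#' convolution, per-position layer normalization over channels, ReLU and
#' max-pooling with window and stride 2, so an `L x D` feature map becomes
#' `floor(L / 4) x conv_channels` regardless of which modality it came from.
#'
#' @param y `L x D` feature map (`L >= 4`).
#' @param block Conv-block parameter list (`K1`, `b1`, `g1`, `be1`, `K2`,
#'   `b2`, `g2`, `be2`), e.g. the `conv.i.*` entries of a model.
#' @return `floor(L / 4) x conv_channels` matrix.
#' @export
conv_block <- function(y, block) {
  y <- as.matrix(y)
  if (nrow(y) < 4L)
    stop("input length is shorter than the block's receptive field (needs L >= 4)",
         call. = FALSE)
  cpp_conv_block(y, block)
}

#' Fuse per-modality features by temporal concatenation
#'
#' Concatenates the per-modality feature maps along the time axis in sorted
#' modality-name order (so repeated calls are bit-identical regardless of
#' input order). With a single modality, fusion is the identity.
#'
#' @param features Named list of `L'_i x D'` matrices.
#' @return `sum(L'_i) x D'` matrix.
#' @export
fuse <- function(features) {
  if (!length(features)) stop("cannot fuse an empty feature map", call. = FALSE)
  if (is.null(names(features)) || any(!nzchar(names(features))))
    stop("features must be named by modality", call. = FALSE)
  do.call(rbind, features[sort(names(features))])
}

# ------------------------------------------------------------------- Adam ---

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

# One Adam step over the flat parameter list, with global-norm gradient
# clipping (training aborts elsewhere if losses go non-finite).
adam_step <- function(params, grads, state, lr, clip_norm = 10,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip_norm) clip_norm / gnorm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
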