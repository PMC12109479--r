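#' Cross-modal Transformer configuration
#'
#' Hyperparameters of the feature extractor. `n_layers = 0` together with
#' `cross_attention = FALSE` is the depth-0 ablation, in which the extractor
#' reduces exactly to the projected, position-encoded inputs.
#'
#' @param model_dim Shared feature dimension D after projection.
#' @param n_heads Attention heads; must divide `model_dim`. Each head attends
#'   in a subspace of `model_dim / n_heads` dimensions.
#' @param n_layers Number of stacked encoder layers U (`>= 0`).
#' @param dropout Dropout probability in `[0, 1)`, applied to attention and
#'   feed-forward outputs during training.
#' @param cross_attention Apply the cross-modal attention block (each
#'   modality's sequence attending over the concatenated all-modality
#'   context) once before the encoder stack.
#' @param ffn_mult Feed-forward inner width as a multiple of `model_dim`.
#' @return An object of class `ct_config`.
#' @export
ct_config <- function(model_dim = 128L, n_heads = 4L, n_layers = 4L,
                      dropout = 0.1, cross_attention = n_layers > 0L,
                      ffn_mult = 4L) {
  model_dim <- as.integer(model_dim); n_heads <- as.integer(n_heads)
  n_layers <- as.integer(n_layers)
  if (model_dim < 1L || n_heads < 1L || model_dim %% n_heads != 0L)
    stop("`model_dim` must be a positive multiple of `n_heads`", call. = FALSE)
  if (n_layers < 0L) stop("`n_layers` must be >= 0", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  structure(list(model_dim = model_dim, n_heads = n_heads, n_layers = n_layers,
                 dropout = dropout, cross_attention = isTRUE(cross_attention),
                 ffn_mult = as.integer(ffn_mult)),
            class = "ct_config")
}

#' Sinusoidal positional encoding
#'
#' Interleaved sine/cosine encodings: `PE[pos, 2k] = sin(pos / 10000^(2k/D))`
#' and `PE[pos, 2k+1] = cos(pos / 10000^(2k/D))`, with positions indexed from
#' zero so the first row is exactly `(0, 1, 0, 1, ...)`. All entries lie in
#' `[-1, 1]`.
#'
#' @param L Sequence length (rows).
#' @param D Feature dimension (columns).
#' @return An `L x D` matrix.
#' @examples
#' positional_encoding(4, 4)[1, ]  # 0 1 0 1
#' @export
positional_encoding <- function(L, D) {
  L <- as.integer(L); D <- as.integer(D)
  if (L < 1L || D < 1L) stop("`L` and `D` must be >= 1", call. = FALSE)
  pos <- 0:(L - 1L)
  pe <- matrix(0, L, D)
  for (j in seq_len(D)) {
    k <- (j - 1L) %/% 2L
    angle <- pos / 10000^(2 * k / D)
    pe[, j] <- if (j %% 2L == 1L) sin(angle) else cos(angle)
  }
  pe
}

#' Pointwise (width-1) modality projection
#'
#' Projects one modality's window from its native channel count into the
#' shared feature space: a 1-D convolution with kernel width exactly 1, i.e.
#' each time step is mapped independently by `output[t, ] = x[t, ] W + bias`.
#'
#' @param x `L x D_i` input window.
#' @param weights `D_i x D` projection matrix.
#' @param bias Length-`D` bias (default zeros).
#' @return `L x D` projected window.
#' @export
project_modality <- function(x, weights, bias = NULL) {
  x <- as.matrix(x); weights <- as.matrix(weights)
  if (ncol(x) != nrow(weights))
    stop(sprintf("channel mismatch: input has %d channels, weights expect %d",
                 ncol(x), nrow(weights)), call. = FALSE)
  if (is.null(bias)) bias <- numeric(ncol(weights))
  if (length(bias) != ncol(weights))
    stop("bias length must equal the output dimension", call. = FALSE)
  sweep(x %*% weights, 2L, bias, "+")
}

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Scaled dot-product cross-modal attention
#'
#' Single-head reference form of the attention used between one modality's
#' sequence (queries) and the concatenated multimodal context (keys and
#' values): `softmax(Q K^T / sqrt(D_attn)) V` with `Q = query %*% W_q`,
#' `K = context %*% W_k`, `V = context %*% W_v`. Every softmax row is a
#' probability distribution over context positions.
#'
#' @param query `L x D` unimodal sequence.
#' @param context `L_T x D` concatenated multimodal context.
#' @param W_q,W_k,W_v `D x D_attn` projection matrices.
#' @return `L x D_attn` attended output, with the `L x L_T` attention
#'   probabilities attached as attribute `"attention"`.
#' @export
cross_modal_attention <- function(query, context, W_q, W_k, W_v) {
  query <- as.matrix(query); context <- as.matrix(context)
  if (ncol(query) != nrow(W_q) || ncol(context) != nrow(W_k) ||
      ncol(context) != nrow(W_v))
    stop("projection weight shapes do not match the inputs", call. = FALSE)
  if (ncol(W_q) != ncol(W_k))
    stop("query and key projections must share their output dimension",
         call. = FALSE)
  q <- query %*% W_q; k <- context %*% W_k; v <- context %*% W_v
  p <- softmax_rows(q %*% t(k) / sqrt(ncol(W_q)))
  structure(p %*% v, attention = p)
}

#' Encode a trial batch with the cross-modal Transformer
#'
#' Runs the full feature extractor of a trained (or freshly initialized)
#' model in evaluation mode: per-modality pointwise projection, positional
#' encoding, one cross-modal attention block over the concatenated context,
#' and the stacked pre-norm encoder layers. With `n_layers = 0` and
#' `cross_attention = FALSE` the output equals the projected, position-encoded
#' input (the depth-0 ablation identity).
#'
#' @param batch A [trial_batch()] whose modalities match the model.
#' @param model A model as returned by [train_fold()] (or
#'   [init_model_params()] for an untrained one).
#' @return A list with `per_modality` (named list of `[n, L_i, D]` arrays,
#'   the context-enriched sequences) and `global_context`
#'   (`[n, L_T, D]`, the concatenated projected inputs), of class
#'   `encoded_features`.
#' @export
encode <- function(batch, model) {
  stopifnot(inherits(batch, "trial_batch"))
  mods <- model$modalities
  if (!all(mods %in% modality_names(batch)))
    stop("batch lacks modalities the model was trained on", call. = FALSE)
  sig <- batch_to_cubes(batch, mods)
  out <- cpp_ct_forward(sig, model$params, engine_config(model$ct), -1L)
  per <- lapply(out$Y, cubes_to_array)
  names(per) <- mods
  ctx <- cubes_to_array(out$context)
  structure(list(per_modality = per, global_context = ctx),
            class = "encoded_features")
}

# [n, L, D] array -> [L, D, n] cube expected by the engine
batch_to_cubes <- function(batch, mods) {
  lapply(batch$signals[mods], function(a) aperm(a, c(2L, 3L, 1L)))
}
cubes_to_array <- function(cube) aperm(cube, c(3L, 1L, 2L))
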