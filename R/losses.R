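#' Batch-averaged cross-entropy
#'
#' `-mean(log p[true])` over the rows of a probability matrix; the loss of
#' every softmax classification head (modality, subject, emotion).
#'
#' @param probabilities `n x K` matrix of class probabilities (rows on the
#'   simplex), or a single probability vector.
#' @param true_label Integer labels in `1..K`, recycled if scalar.
#' @return Nonnegative scalar loss.
#' @examples
#' cross_entropy(rep(1 / 4, 4), 1)        # log(4)
#' cross_entropy(c(0.7, 0.2, 0.1), 1)     # -log(0.7)
#' @export
cross_entropy <- function(probabilities, true_label) {
  p <- if (is.matrix(probabilities)) probabilities else
    matrix(probabilities, nrow = 1L)
  true_label <- as.integer(true_label)
  if (length(true_label) == 1L) true_label <- rep(true_label, nrow(p))
  if (length(true_label) != nrow(p))
    stop("one label per probability row is required", call. = FALSE)
  if (any(true_label < 1L) || any(true_label > ncol(p)))
    stop(sprintf("labels must lie in 1..%d", ncol(p)), call. = FALSE)
  -mean(log(p[cbind(seq_len(nrow(p)), true_label)]))
}

#' Hinge discriminator loss
#'
#' The conditional GAN discriminator objective in its nonnegative hinge form:
#' `E[max(0, 1 - D(x, y))] + E[max(0, 1 + D(G(z), y))]`. It is zero exactly
#' when every real score is at least +1 and every fake score at most -1.
#'
#' @param real_scores,fake_scores Numeric vectors of per-sample discriminator
#'   scores on real and generated (sample, label) pairs.
#' @return Nonnegative scalar loss.
#' @examples
#' discriminator_loss(c(1.5, 2), c(-1, -3))  # 0
#' discriminator_loss(0, 0)                  # 2
#' @export
discriminator_loss <- function(real_scores, fake_scores) {
  if (!length(real_scores) || !length(fake_scores))
    stop("real and fake score batches must be non-empty", call. = FALSE)
  mean(pmax(0, 1 - real_scores)) + mean(pmax(0, 1 + fake_scores))
}

#' Hinge generator loss
#'
#' `-E[D(G(z), y)]`: the generator maximizes the discriminator's score on its
#' conditioned samples.
#'
#' @param fake_scores Numeric vector of discriminator scores on generated
#'   samples.
#' @return Scalar loss.
#' @export
generator_loss <- function(fake_scores) {
  if (!length(fake_scores))
    stop("fake score batch must be non-empty", call. = FALSE)
  -mean(fake_scores)
}

#' Combine the four training loss components
#'
#' The joint objective is the weighted sum
#' `total = alpha * l_mod + beta * l_sub + gamma_w * l_emo + phi * l_gan`,
#' where `l_mod`/`l_sub` are the adversarial modality and subject
#' cross-entropies, `l_emo` the emotion cross-entropy and `l_gan` the
#' combined GAN hinge loss. The weight on the emotion term is named
#' `gamma_w` to avoid collision with the GAN self-attention residual scale
#' `gamma`. The identity `total == sum(weights * components)` holds exactly.
#'
#' @param l_mod,l_sub,l_emo,l_gan Finite loss components.
#' @param weights Numeric vector with entries `alpha`, `beta`, `gamma_w`,
#'   `phi` (defaults all 1).
#' @return A `loss_report`: the components, weights and scalar `total`.
#' @examples
#' total_loss(0.5, 0.25, 1.0, 0.25)$total  # 2
#' @export
total_loss <- function(l_mod, l_sub, l_emo, l_gan,
                       weights = c(alpha = 1, beta = 1, gamma_w = 1, phi = 1)) {
  comp <- c(l_mod = l_mod, l_sub = l_sub, l_emo = l_emo, l_gan = l_gan)
  for (nm in names(comp)) if (!is.finite(comp[[nm]]))
    stop(sprintf("loss component `%s` is not finite", nm), call. = FALSE)
  w <- weights[c("alpha", "beta", "gamma_w", "phi")]
  if (anyNA(w)) stop("`weights` must name alpha, beta, gamma_w, phi", call. = FALSE)
  structure(list(l_mod = l_mod, l_sub = l_sub, l_emo = l_emo, l_gan = l_gan,
                 weights = w,
                 total = sum(w * comp)),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(
    "<loss_report: total %.4f = %.2f*mod(%.4f) + %.2f*sub(%.4f) + %.2f*emo(%.4f) + %.2f*gan(%.4f)>\n",
    x$total, x$weights[["alpha"]], x$l_mod, x$weights[["beta"]], x$l_sub,
    x$weights[["gamma_w"]], x$l_emo, x$weights[["phi"]], x$l_gan))
  invisible(x)
}

#' Gradient reversal layer (forward pass)
#'
#' The GRL is the identity in the forward pass; during backpropagation it
#' multiplies upstream gradients by `-lambda`, turning the attached
#' classifier's descent into ascent for everything upstream. The forward
#' identity is exposed here; [grl_grad()] is the corresponding backward rule
#' used by the training engine's hand-written backpropagation.
#'
#' @param x Any numeric array.
#' @param lambda Nonnegative reversal strength (unused in the forward pass).
#' @return `x`, unchanged.
#' @export
grl <- function(x, lambda = 1) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  x
}

#' Gradient reversal layer (backward rule)
#'
#' @param upstream_grad Gradient arriving from the attached classifier.
#' @param lambda Nonnegative reversal strength; `0` severs the gradient path
#'   entirely (plain multitask training, no invariance pressure).
#' @return `-lambda * upstream_grad`.
#' @export
grl_grad <- function(upstream_grad, lambda = 1) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  -lambda * upstream_grad
}

#' Adversarial lambda warm-up schedule
#'
#' The standard domain-adversarial ramp `2 / (1 + exp(-10 p)) - 1` over
#' training progress `p` in `[0, 1]`, capped at 1: the reversal strength
#' starts near zero while the classifiers are still uninformative and
#' saturates as training proceeds.
#'
#' @param p Training progress in `[0, 1]`.
#' @return Lambda in `[0, 1]`.
#' @export
lambda_schedule <- function(p) {
  pmin(1, 2 / (1 + exp(-10 * pmax(0, pmin(1, p)))) - 1)
}
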