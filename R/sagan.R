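#' Conditional self-attention GAN configuration
#'
#' Settings of the feature-space augmenter: a per-modality generator /
#' discriminator pair trained with the hinge objective, conditioned on the
#' emotion label through a shared label embedding at the generator input and
#' a projection term in the discriminator.
#'
#' @param noise_dim Dimension of the Gaussian noise prior `z`.
#' @param emb_dim Dimension of the (shared) generator label embedding.
#' @param hidden Generator hidden width.
#' @param d_channels Discriminator channel width.
#' @param lr Adam learning rate for both networks.
#' @param ratio Generated-to-real sample ratio used by [augment_batch()];
#'   `0` disables augmentation.
#' @param spectral_norm Normalize the discriminator's dense weights to unit
#'   spectral norm (one power iteration per step) for training stability.
#' @return An object of class `sagan_config`.
#' @export
sagan_config <- function(noise_dim = 64L, emb_dim = 16L, hidden = 128L,
                         d_channels = 32L, lr = 1e-4, ratio = 1,
                         spectral_norm = TRUE) {
  if (ratio < 0) stop("`ratio` must be nonnegative", call. = FALSE)
  structure(list(noise_dim = as.integer(noise_dim),
                 emb_dim = as.integer(emb_dim), hidden = as.integer(hidden),
                 d_channels = as.integer(d_channels), lr = lr, ratio = ratio,
                 spectral_norm = isTRUE(spectral_norm)),
            class = "sagan_config")
}

#' Create a self-attention layer
#'
#' The layer operates on a channels-by-positions map `x` (`C x N`): scores
#' `s_ij = f(x_i)' g(x_j)` with `f = W_f x`, `g = W_g x`; attention weights
#' `beta_{j,i}` are the softmax of `s_ij` over `i`; the output is
#' `y_i = gamma * o_i + x_i` with `o_j = W_v (sum_i beta_{j,i} W_h x_i)`.
#' `gamma` is a learnable scalar initialized to zero, so a fresh layer is
#' exactly the identity regardless of its projection weights.
#'
#' @param C Channel count of the maps the layer will see.
#' @param c_bar Reduced channel dimension of the projections (default
#'   `max(1, C / 8)`, the usual reduction).
#' @param seed Integer seed for the projection initialization.
#' @return An object of class `self_attention_layer` with fields
#'   `Wf`, `Wg`, `Wh` (`c_bar x C`), `Wv` (`C x c_bar`) and `gamma = 0`.
#' @export
self_attention_layer <- function(C, c_bar = max(1L, C %/% 8L), seed = 1L) {
  C <- as.integer(C); c_bar <- as.integer(c_bar)
  if (C < 1L || c_bar < 1L) stop("channel counts must be >= 1", call. = FALSE)
  with_seed(seed, {
    structure(list(Wf = xavier(c_bar, C), Wg = xavier(c_bar, C),
                   Wh = xavier(c_bar, C), Wv = xavier(C, c_bar),
                   gamma = 0),
              class = "self_attention_layer")
  })
}

# forward with cache (internal); layer is a plain list with Wf/Wg/Wh/Wv/gamma
sa_fwd <- function(x, layer) {
  f <- layer$Wf %*% x; g <- layer$Wg %*% x; hh <- layer$Wh %*% x
  s <- crossprod(f, g)                       # s[i, j] = f_i . g_j
  sm <- sweep(s, 2L, apply(s, 2L, max))
  e <- exp(sm)
  beta <- sweep(e, 2L, colSums(e), "/")      # beta[i, j]: j attends to i
  agg <- hh %*% beta
  o <- layer$Wv %*% agg
  list(y = layer$gamma * o + x,
       cache = list(x = x, f = f, g = g, hh = hh, beta = beta,
                    agg = agg, o = o))
}

sa_bwd <- function(dy, layer, cache) {
  dgamma <- sum(dy * cache$o)
  do <- layer$gamma * dy
  dWv <- do %*% t(cache$agg)
  dagg <- crossprod(layer$Wv, do)
  dhh <- dagg %*% t(cache$beta)
  dbeta <- crossprod(cache$hh, dagg)
  ds <- cache$beta * sweep(dbeta, 2L, colSums(cache$beta * dbeta))
  df <- cache$g %*% t(ds)
  dg <- cache$f %*% ds
  dx <- dy + crossprod(layer$Wf, df) + crossprod(layer$Wg, dg) +
    crossprod(layer$Wh, dhh)
  list(dx = dx, dWf = df %*% t(cache$x), dWg = dg %*% t(cache$x),
       dWh = dhh %*% t(cache$x), dWv = dWv, dgamma = dgamma)
}

#' Apply a self-attention layer to one feature map
#'
#' @param x `C x N` map (channels by positions, `N >= 1`).
#' @param layer A [self_attention_layer()] (or any list with fields `Wf`,
#'   `Wg`, `Wh`, `Wv`, `gamma`).
#' @return The `C x N` attended map `gamma * o + x`.
#' @export
self_attention_map <- function(x, layer) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop("the map must contain at least one position", call. = FALSE)
  if (nrow(layer$Wf) < 1L) stop("invalid layer", call. = FALSE)
  sa_fwd(x, layer)$y
}

# flat-list helpers: extract the attention sub-layer of a flat param list
attn_of <- function(p) list(Wf = p$attn.Wf, Wg = p$attn.Wg, Wh = p$attn.Wh,
                            Wv = p$attn.Wv, gamma = as.numeric(p$attn.gamma))

#' Create one generator/discriminator pair
#'
#' The generator maps `[z; embedding(label)]` through a dense hidden layer to
#' an initial `D x L` map, refines it with a self-attention layer and a
#' channel-mixing output layer, and emits an `L x D` feature-space sample.
#' The discriminator projects the map into `d_channels` channels, applies
#' self-attention, pools over positions and scores the (sample, label) pair
#' with a projection-conditioning term.
#'
#' @param L,D Time length and feature dimension of the maps this pair
#'   generates (the feature space of one modality).
#' @param n_emotions Number of emotion classes the generator conditions on.
#' @param cfg A [sagan_config()].
#' @param seed Integer seed.
#' @return An object of class `gan_pair`.
#' @export
gan_pair <- function(L, D, n_emotions, cfg = sagan_config(), seed = 1L) {
  L <- as.integer(L); D <- as.integer(D)
  with_seed(seed, {
    din <- cfg$noise_dim + cfg$emb_dim
    al_g <- self_attention_layer(D, seed = stats::runif(1, 1, 1e6))
    al_d <- self_attention_layer(cfg$d_channels, seed = stats::runif(1, 1, 1e6))
    G <- list(W1 = xavier(din, cfg$hidden), b1 = numeric(cfg$hidden),
              W2 = xavier(cfg$hidden, L * D), b2 = numeric(L * D),
              attn.Wf = al_g$Wf, attn.Wg = al_g$Wg, attn.Wh = al_g$Wh,
              attn.Wv = al_g$Wv, attn.gamma = 0,
              Wout = xavier(D, D), bout = numeric(D),
              emb = xavier(n_emotions, cfg$emb_dim))
    Dd <- list(W1 = xavier(cfg$d_channels, D), b1 = numeric(cfg$d_channels),
               attn.Wf = al_d$Wf, attn.Wg = al_d$Wg, attn.Wh = al_d$Wh,
               attn.Wv = al_d$Wv, attn.gamma = 0,
               w = stats::rnorm(cfg$d_channels, sd = sqrt(1 / cfg$d_channels)),
               b = 0,
               embD = matrix(0, n_emotions, cfg$d_channels))
    structure(list(G = G, D = Dd, L = L, D_feat = D,
                   n_emotions = as.integer(n_emotions), cfg = cfg,
                   sn_u = stats::rnorm(cfg$d_channels)),
              class = "gan_pair")
  })
}

#' Generate conditioned feature-space samples
#'
#' Deterministic given `(z, labels, pair)`: the only randomness is the noise
#' the caller supplies.
#'
#' @param z `n x noise_dim` matrix of prior noise.
#' @param labels Integer emotion labels in `1..n_emotions`, one per row of `z`.
#' @param pair A [gan_pair()].
#' @return `[n, L, D]` array of generated feature maps.
#' @export
generate <- function(z, labels, pair) {
  stopifnot(inherits(pair, "gan_pair"))
  z <- as.matrix(z)
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > pair$n_emotions))
    stop(sprintf("labels must lie in 1..%d", pair$n_emotions), call. = FALSE)
  if (length(labels) != nrow(z))
    stop("one label per noise row is required", call. = FALSE)
  g_forward(z, labels, pair$G, pair$L, pair$D_feat)$out
}

g_forward <- function(z, labels, G, L, D) {
  n <- nrow(z)
  U <- cbind(z, G$emb[labels, , drop = FALSE])
  H1p <- sweep(U %*% G$W1, 2L, G$b1, "+")
  H1 <- pmax(H1p, 0)
  X0 <- sweep(H1 %*% G$W2, 2L, G$b2, "+")
  out <- array(0, dim = c(n, L, D))
  caches <- vector("list", n)
  al <- attn_of(G)
  for (s in seq_len(n)) {
    x0 <- matrix(X0[s, ], nrow = D, ncol = L)
    sa <- sa_fwd(x0, al)
    ym <- sweep(G$Wout %*% sa$y, 1L, G$bout, "+")
    out[s, , ] <- t(ym)
    caches[[s]] <- list(sa = sa)
  }
  list(out = out, U = U, H1p = H1p, H1 = H1, X0 = X0, caches = caches)
}

g_backward <- function(dout, fw, G, L, D, labels) {
  n <- dim(dout)[1L]
  gr <- lapply(G, function(x) x * 0)
  al <- attn_of(G)
  dX0 <- matrix(0, n, L * D)
  for (s in seq_len(n)) {
    dym <- t(matrix(dout[s, , ], nrow = L))          # [D, L]
    gr$Wout <- gr$Wout + dym %*% t(fw$caches[[s]]$sa$y)
    gr$bout <- gr$bout + rowSums(dym)
    dy <- crossprod(G$Wout, dym)
    sb <- sa_bwd(dy, al, fw$caches[[s]]$sa$cache)
    gr$attn.Wf <- gr$attn.Wf + sb$dWf; gr$attn.Wg <- gr$attn.Wg + sb$dWg
    gr$attn.Wh <- gr$attn.Wh + sb$dWh; gr$attn.Wv <- gr$attn.Wv + sb$dWv
    gr$attn.gamma <- gr$attn.gamma + sb$dgamma
    dX0[s, ] <- as.vector(sb$dx)
  }
  gr$W2 <- gr$W2 + crossprod(fw$H1, dX0)
  gr$b2 <- gr$b2 + colSums(dX0)
  dH1 <- (dX0 %*% t(G$W2)) * (fw$H1p > 0)
  gr$W1 <- gr$W1 + crossprod(fw$U, dH1)
  gr$b1 <- gr$b1 + colSums(dH1)
  dU <- dH1 %*% t(G$W1)
  demb <- dU[, -seq_len(ncol(dU) - ncol(G$emb)), drop = FALSE]
  for (s in seq_len(n))
    gr$emb[labels[s], ] <- gr$emb[labels[s], ] + demb[s, ]
  gr
}

# spectral normalization of the discriminator weights (one power iteration,
# persistent u); returns normalized weights + quantities for the backward pass
d_normalize <- function(pair) {
  Dd <- pair$D
  if (!pair$cfg$spectral_norm)
    return(list(W1 = Dd$W1, w = Dd$w, u = pair$sn_u,
                v = NULL, sigma = 1, wnorm = 1))
  u <- pair$sn_u
  v <- as.vector(crossprod(Dd$W1, u)); v <- v / sqrt(sum(v^2) + 1e-12)
  u <- as.vector(Dd$W1 %*% v); u <- u / sqrt(sum(u^2) + 1e-12)
  sigma <- as.numeric(crossprod(u, Dd$W1 %*% v))
  wnorm <- sqrt(sum(Dd$w^2) + 1e-12)
  list(W1 = Dd$W1 / sigma, w = Dd$w / wnorm, u = u, v = v,
       sigma = sigma, wnorm = wnorm)
}

d_forward <- function(maps, labels, Dd, sn) {
  # maps: [n, L, D] array
  n <- dim(maps)[1L]
  scores <- numeric(n)
  caches <- vector("list", n)
  al <- attn_of(Dd)
  for (s in seq_len(n)) {
    x <- t(matrix(maps[s, , ], nrow = dim(maps)[2L]))   # [D_feat, L] -> channels x positions
    pre <- sweep(sn$W1 %*% x, 1L, Dd$b1, "+")
    h0 <- pmax(pre, 0)
    sa <- sa_fwd(h0, al)
    h <- rowMeans(sa$y)
    scores[s] <- sum(sn$w * h) + Dd$b + sum(Dd$embD[labels[s], ] * h)
    caches[[s]] <- list(x = x, pre = pre, h0 = h0, sa = sa, h = h)
  }
  list(scores = scores, caches = caches)
}

d_backward <- function(dscores, fw, labels, Dd, sn, want_dx = FALSE) {
  n <- length(dscores)
  gr <- lapply(Dd, function(x) x * 0)
  al <- attn_of(Dd)
  dmaps <- if (want_dx) vector("list", n)
  gW1hat <- Dd$W1 * 0
  gwhat <- Dd$w * 0
  for (s in seq_len(n)) {
    cc <- fw$caches[[s]]
    ds <- dscores[s]
    if (ds == 0 && !want_dx) next
    gwhat <- gwhat + ds * cc$h
    gr$b <- gr$b + ds
    gr$embD[labels[s], ] <- gr$embD[labels[s], ] + ds * cc$h
    dh <- ds * (sn$w + Dd$embD[labels[s], ])
    L <- ncol(cc$h0)
    dy <- matrix(dh / L, nrow = length(dh), ncol = L)
    sb <- sa_bwd(dy, al, cc$sa$cache)
    gr$attn.Wf <- gr$attn.Wf + sb$dWf; gr$attn.Wg <- gr$attn.Wg + sb$dWg
    gr$attn.Wh <- gr$attn.Wh + sb$dWh; gr$attn.Wv <- gr$attn.Wv + sb$dWv
    gr$attn.gamma <- gr$attn.gamma + sb$dgamma
    dpre <- sb$dx * (cc$pre > 0)
    gW1hat <- gW1hat + dpre %*% t(cc$x)
    gr$b1 <- gr$b1 + rowSums(dpre)
    if (want_dx) dmaps[[s]] <- t(crossprod(sn$W1, dpre))
  }
  # spectral-norm backward: d(W / sigma) with sigma = u' W v
  if (!is.null(sn$v)) {
    gr$W1 <- (gW1hat - sum(gW1hat * sn$W1) * (sn$u %*% t(sn$v))) / sn$sigma
    what <- sn$w
    gr$w <- (gwhat - sum(gwhat * what) * what) / sn$wnorm
  } else {
    gr$W1 <- gW1hat
    gr$w <- gwhat
  }
  list(grads = gr, dmaps = dmaps)
}

#' Initialize the multi-modality conditional GAN bundle
#'
#' One generator/discriminator pair per modality, all sharing the generator
#' label embedding (the bundle keeps the embeddings synchronized during
#' training).
#'
#' @param feature_specs Named list, one entry per modality, each
#'   `list(L = , D = )` giving that modality's feature-map shape.
#' @param n_emotions Emotion-class count.
#' @param cfg A [sagan_config()].
#' @param seed Integer seed.
#' @return An object of class `csagan` holding the pairs and optimizer state.
#' @export
csagan_init <- function(feature_specs, n_emotions, cfg = sagan_config(),
                        seed = 1L) {
  pairs <- list()
  for (i in seq_along(feature_specs)) {
    nm <- names(feature_specs)[i]
    pairs[[nm]] <- gan_pair(feature_specs[[i]]$L, feature_specs[[i]]$D,
                            n_emotions, cfg, seed = seed + 37L * i)
  }
  emb <- pairs[[1L]]$G$emb
  for (nm in names(pairs)) pairs[[nm]]$G$emb <- emb
  st <- list()
  for (nm in names(pairs)) {
    st[[nm]] <- list(G = adam_init(pairs[[nm]]$G), D = adam_init(pairs[[nm]]$D))
  }
  structure(list(pairs = pairs, cfg = cfg, n_emotions = as.integer(n_emotions),
                 state = st, step = 0L),
            class = "csagan")
}

#' One adversarial training step of the GAN bundle
#'
#' Per modality: one discriminator hinge update on (real, generated) pairs,
#' then one generator update; generator label embeddings are averaged across
#' modalities afterwards to keep them shared.
#'
#' @param gan A [csagan_init()] bundle.
#' @param features Named list of real feature-map arrays `[n, L, D]`, one per
#'   modality (the feature-extractor outputs for one minibatch).
#' @param labels Emotion labels of the real samples.
#' @param seed Integer seed for the noise draws.
#' @return List with the updated `gan` and the step's `l_d`, `l_g`.
#' @export
gan_train_step <- function(gan, features, labels, seed = 1L) {
  stopifnot(inherits(gan, "csagan"))
  labels <- as.integer(labels)
  ld_all <- lg_all <- 0
  emb_new <- NULL
  for (nm in names(gan$pairs)) {
    pair <- gan$pairs[[nm]]
    real <- features[[nm]]
    n <- dim(real)[1L]
    zs <- with_seed(seed + 101L * match(nm, names(gan$pairs)), {
      list(z1 = matrix(stats::rnorm(n * gan$cfg$noise_dim), n),
           z2 = matrix(stats::rnorm(n * gan$cfg$noise_dim), n))
    })
    sn <- d_normalize(pair)
    pair$sn_u <- sn$u
    # --- discriminator step
    fake <- g_forward(zs$z1, labels, pair$G, pair$L, pair$D_feat)$out
    fr <- d_forward(real, labels, pair$D, sn)
    ff <- d_forward(fake, labels, pair$D, sn)
    l_d <- discriminator_loss(fr$scores, ff$scores)
    ds_real <- -as.numeric(1 - fr$scores > 0) / n
    ds_fake <- as.numeric(1 + ff$scores > 0) / n
    gr_r <- d_backward(ds_real, fr, labels, pair$D, sn)$grads
    gr_f <- d_backward(ds_fake, ff, labels, pair$D, sn)$grads
    gd <- Map(`+`, gr_r, gr_f)
    up <- adam_step(pair$D, gd, gan$state[[nm]]$D, gan$cfg$lr)
    pair$D <- up$params; gan$state[[nm]]$D <- up$state
    # --- generator step (against the refreshed discriminator)
    sn2 <- d_normalize(pair)
    pair$sn_u <- sn2$u
    gfw <- g_forward(zs$z2, labels, pair$G, pair$L, pair$D_feat)
    dfw <- d_forward(gfw$out, labels, pair$D, sn2)
    l_g <- generator_loss(dfw$scores)
    dsc <- rep(-1 / n, n)
    db <- d_backward(dsc, dfw, labels, pair$D, sn2, want_dx = TRUE)
    dout <- array(0, dim = dim(gfw$out))
    for (s in seq_len(n)) dout[s, , ] <- db$dmaps[[s]]
    gg <- g_backward(dout, gfw, pair$G, pair$L, pair$D_feat, labels)
    up <- adam_step(pair$G, gg, gan$state[[nm]]$G, gan$cfg$lr)
    pair$G <- up$params; gan$state[[nm]]$G <- up$state
    gan$pairs[[nm]] <- pair
    ld_all <- ld_all + l_d; lg_all <- lg_all + l_g
    emb_new <- if (is.null(emb_new)) pair$G$emb else emb_new + pair$G$emb
  }
  # keep the label embedding shared: average the per-modality updates
  emb_new <- emb_new / length(gan$pairs)
  for (nm in names(gan$pairs)) gan$pairs[[nm]]$G$emb <- emb_new
  gan$step <- gan$step + 1L
  list(gan = gan,
       l_d = ld_all / length(gan$pairs),
       l_g = lg_all / length(gan$pairs))
}

#' Augment a feature batch with conditioned synthetic samples
#'
#' Appends `ceiling(ratio * n)` generated samples to the real feature maps.
#' Conditioning labels are the real labels recycled, so the synthetic label
#' histogram matches the conditioning histogram by construction; real samples
#' are untouched. `ratio = 0` returns the input unchanged.
#'
#' @param real_features Named list of `[n, L, D]` arrays, one per modality.
#' @param labels Emotion labels of the real samples.
#' @param gan A [csagan_init()] bundle covering the same modalities.
#' @param ratio Generated-to-real ratio (`>= 0`).
#' @param seed Integer seed for the noise draws.
#' @return List with `features` (arrays of `n + k` samples), `labels`
#'   (length `n + k`) and `is_synthetic` (logical flags).
#' @export
augment_batch <- function(real_features, labels, gan, ratio = gan$cfg$ratio,
                          seed = 1L) {
  stopifnot(inherits(gan, "csagan"))
  if (ratio < 0) stop("`ratio` must be nonnegative", call. = FALSE)
  labels <- as.integer(labels)
  n <- dim(real_features[[1L]])[1L]
  k <- ceiling(ratio * n)
  if (k == 0L)
    return(list(features = real_features, labels = labels,
                is_synthetic = rep(FALSE, n)))
  glab <- labels[((seq_len(k) - 1L) %% n) + 1L]
  z <- with_seed(seed, matrix(stats::rnorm(k * gan$cfg$noise_dim), k))
  feats <- real_features
  for (nm in names(gan$pairs)) {
    gen <- generate(z, glab, gan$pairs[[nm]])
    a <- real_features[[nm]]
    out <- array(0, dim = c(n + k, dim(a)[2L], dim(a)[3L]))
    out[seq_len(n), , ] <- a
    out[n + seq_len(k), , ] <- gen
    feats[[nm]] <- out
  }
  list(features = feats, labels = c(labels, glab),
       is_synthetic = c(rep(FALSE, n), rep(TRUE, k)))
}
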