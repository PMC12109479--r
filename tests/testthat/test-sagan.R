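test_that("hinge losses reproduce their closed-form cases", {
  expect_equal(discriminator_loss(c(1, 1.5, 2), c(-1, -2, -5)), 0)
  expect_equal(discriminator_loss(0, 0), 2)
  expect_equal(discriminator_loss(0.5, -0.5), 1.0)
  expect_equal(generator_loss(c(0, 0)), 0)
  expect_equal(generator_loss(1), -1)
  expect_equal(generator_loss(c(2, -1, -1)), 0)
  expect_true(discriminator_loss(rnorm(5), rnorm(5)) >= 0)
  expect_error(discriminator_loss(numeric(), 1), "non-empty")
  expect_error(generator_loss(numeric()), "non-empty")
})

test_that("a fresh self-attention layer is the identity (gamma = 0)", {
  layer <- self_attention_layer(C = 5, seed = 2)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(self_attention_map(x, layer), x)
  # and stays the identity whatever the projection weights are
  layer$Wf <- layer$Wf * 100; layer$Wv <- -layer$Wv
  expect_equal(self_attention_map(x, layer), x)
})

test_that("single-position maps reduce to the gamma-scaled channel path", {
  layer <- self_attention_layer(C = 3, c_bar = 2, seed = 4)
  layer$gamma <- 0.7
  x <- matrix(rnorm(3), 3, 1)
  want <- 0.7 * (layer$Wv %*% (layer$Wh %*% x)) + x  # beta = 1 when N = 1
  expect_equal(self_attention_map(x, layer), want)
  expect_error(self_attention_map(x[, 0, drop = FALSE], layer), "position")
})

test_that("self-attention matches the double-loop oracle for all small sizes", {
  set.seed(9)
  for (C in 1:6) for (N in 1:6) {
    layer <- self_attention_layer(C, c_bar = max(1, C %/% 2),
                                  seed = C * 10 + N)
    layer$gamma <- rnorm(1)
    x <- matrix(rnorm(C * N), C, N)
    expect_equal(self_attention_map(x, layer),
                 self_attention_oracle(x, layer), tolerance = 1e-5)
  }
})

test_that("generation is deterministic, shaped and label-checked", {
  pair <- gan_pair(L = 6, D = 3, n_emotions = 2,
                   cfg = sagan_config(noise_dim = 4, emb_dim = 3, hidden = 8,
                                      d_channels = 4), seed = 3)
  z <- matrix(rnorm(5 * 4), 5)
  lab <- c(1L, 2L, 1L, 1L, 2L)
  g1 <- generate(z, lab, pair)
  expect_equal(dim(g1), c(5, 6, 3))
  expect_identical(g1, generate(z, lab, pair))
  expect_error(generate(z, c(1, 2, 3, 1, 1), pair), "1..2")
  expect_error(generate(z, c(1, 2), pair), "one label per noise row")
  # with all gammas zero, the attention branch is inert: output is invariant
  # to its projection weights
  pair2 <- pair
  pair2$G$attn.Wf <- pair2$G$attn.Wf * 10
  pair2$G$attn.Wh <- -pair2$G$attn.Wh
  expect_identical(generate(z, lab, pair), generate(z, lab, pair2))
})

test_that("generator and discriminator backprop match finite differences", {
  cfg <- sagan_config(noise_dim = 4, emb_dim = 3, hidden = 8, d_channels = 5,
                      spectral_norm = FALSE)
  pair <- gan_pair(L = 4, D = 3, n_emotions = 2, cfg = cfg, seed = 3)
  pair$G$attn.gamma <- 0.3
  pair$D$attn.gamma <- -0.2
  set.seed(1)
  z <- matrix(rnorm(4 * 4), 4)
  lab <- c(1L, 2L, 1L, 2L)
  real <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  sn <- ctelcan:::d_normalize(pair)
  # generator loss gradient through the discriminator
  gloss <- function(G) {
    fw <- ctelcan:::g_forward(z, lab, G, pair$L, pair$D_feat)
    generator_loss(ctelcan:::d_forward(fw$out, lab, pair$D, sn)$scores)
  }
  fw <- ctelcan:::g_forward(z, lab, pair$G, pair$L, pair$D_feat)
  dfw <- ctelcan:::d_forward(fw$out, lab, pair$D, sn)
  db <- ctelcan:::d_backward(rep(-1 / 4, 4), dfw, lab, pair$D, sn,
                             want_dx = TRUE)
  dout <- array(0, dim = dim(fw$out))
  for (s in 1:4) dout[s, , ] <- db$dmaps[[s]]
  gg <- ctelcan:::g_backward(dout, fw, pair$G, pair$L, pair$D_feat, lab)
  for (p in c("W1", "W2", "attn.Wf", "attn.Wv", "attn.gamma", "Wout", "emb")) {
    i <- min(3, length(pair$G[[p]]))
    eps <- 1e-6
    Gp <- pair$G; Gp[[p]][i] <- Gp[[p]][i] + eps; up <- gloss(Gp)
    Gp[[p]][i] <- Gp[[p]][i] - 2 * eps; dn <- gloss(Gp)
    expect_equal(gg[[p]][i], (up - dn) / (2 * eps), tolerance = 1e-4,
                 label = paste("G grad", p))
  }
  # discriminator hinge gradient
  dloss <- function(Dp) {
    snl <- ctelcan:::d_normalize(modifyList(pair, list(D = Dp)))
    discriminator_loss(ctelcan:::d_forward(real, lab, Dp, snl)$scores,
                       ctelcan:::d_forward(fw$out, lab, Dp, snl)$scores)
  }
  fr <- ctelcan:::d_forward(real, lab, pair$D, sn)
  ff <- ctelcan:::d_forward(fw$out, lab, pair$D, sn)
  dsr <- -as.numeric(1 - fr$scores > 0) / 4
  dsf <- as.numeric(1 + ff$scores > 0) / 4
  gr <- Map(`+`, ctelcan:::d_backward(dsr, fr, lab, pair$D, sn)$grads,
                 ctelcan:::d_backward(dsf, ff, lab, pair$D, sn)$grads)
  for (p in c("W1", "b1", "attn.Wg", "attn.gamma", "w", "b", "embD")) {
    i <- min(4, length(pair$D[[p]]))
    eps <- 1e-6
    Dp <- pair$D; Dp[[p]][i] <- Dp[[p]][i] + eps; up <- dloss(Dp)
    Dp[[p]][i] <- Dp[[p]][i] - 2 * eps; dn <- dloss(Dp)
    expect_equal(gr[[p]][i], (up - dn) / (2 * eps), tolerance = 1e-4,
                 label = paste("D grad", p))
  }
})

test_that("augmentation appends label-consistent synthetic samples", {
  gan <- csagan_init(list(EEG = list(L = 4, D = 3), EOG = list(L = 4, D = 2)),
                     n_emotions = 3,
                     cfg = sagan_config(noise_dim = 4, emb_dim = 3, hidden = 8,
                                        d_channels = 4), seed = 2)
  feats <- list(EEG = array(rnorm(8 * 4 * 3), c(8, 4, 3)),
                EOG = array(rnorm(8 * 4 * 2), c(8, 4, 2)))
  labels <- rep(1:2, 4)
  none <- augment_batch(feats, labels, gan, ratio = 0)
  expect_identical(none$features, feats)
  expect_identical(none$labels, as.integer(labels))
  aug <- augment_batch(feats, labels, gan, ratio = 1, seed = 6)
  expect_equal(dim(aug$features$EEG)[1], 16)
  expect_equal(sum(aug$is_synthetic), 8)
  # synthetic label histogram equals the conditioning histogram
  syn_tab <- table(aug$labels[aug$is_synthetic])
  lab_tab <- table(labels)
  expect_equal(as.vector(syn_tab), as.vector(lab_tab))
  expect_equal(names(syn_tab), names(lab_tab))
  # real samples untouched
  expect_equal(aug$features$EEG[1:8, , ], feats$EEG)
  expect_error(augment_batch(feats, labels, gan, ratio = -1), "nonnegative")
})

test_that("adversarial training pulls generated class means toward the real ones", {
  # 1-d toy: two emotion classes with well-separated feature means
  improvements <- c()
  for (seed in 1:3) {
    cfg <- sagan_config(noise_dim = 4, emb_dim = 2, hidden = 16,
                        d_channels = 4, lr = 2e-3)
    gan <- csagan_init(list(F1 = list(L = 1, D = 1)), n_emotions = 2,
                       cfg = cfg, seed = seed)
    mu <- c(-2, 2)
    gap <- function(g) {
      z <- with_seed(seed + 50, matrix(rnorm(200 * 4), 200))
      lab <- rep(1:2, 100)
      gen <- generate(z, lab, g$pairs$F1)
      mean(abs(tapply(gen[, 1, 1], lab, mean) - mu))
    }
    g0 <- gap(gan)
    for (step in 1:120) {
      real <- with_seed(seed * 1000 + step, {
        lab <- rep(1:2, 16)
        list(x = array(rnorm(32, mean = mu[lab], sd = 0.5), c(32, 1, 1)),
             lab = lab)
      })
      gan <- gan_train_step(gan, list(F1 = real$x), real$lab,
                            seed = seed * 1000 + step)$gan
    }
    improvements <- c(improvements, g0 - gap(gan))
  }
  expect_gt(mean(improvements), 0)
})
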