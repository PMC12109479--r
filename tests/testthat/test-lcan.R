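test_that("cross-entropy matches its closed forms", {
  for (K in c(2, 3, 4, 8))
    expect_equal(cross_entropy(rep(1 / K, K), 1), log(K), tolerance = 1e-9)
  expect_equal(cross_entropy(c(0, 1, 0), 2), 0)
  expect_equal(cross_entropy(c(0.7, 0.2, 0.1), 1), -log(0.7), tolerance = 1e-12)
  # batch averaging
  p <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(cross_entropy(p, c(1, 1)), mean(-log(c(0.5, 0.9))))
  expect_error(cross_entropy(c(0.5, 0.5), 3), "labels must lie")
})

test_that("the loss report is an exact weighted sum of its components", {
  expect_equal(total_loss(0.5, 0.25, 1.0, 0.25)$total, 2.0)
  set.seed(8)
  for (i in 1:10) {
    comp <- runif(4); w <- runif(4, -1, 2)
    names(w) <- c("alpha", "beta", "gamma_w", "phi")
    rep <- total_loss(comp[1], comp[2], comp[3], comp[4], weights = w)
    expect_identical(rep$total, sum(w * comp))
  }
  # phi = 0 makes the total independent of the GAN term
  expect_equal(total_loss(1, 1, 1, 99, c(alpha = 1, beta = 1, gamma_w = 1, phi = 0))$total,
               total_loss(1, 1, 1, 0, c(alpha = 1, beta = 1, gamma_w = 1, phi = 0))$total)
  expect_equal(total_loss(3, 4, 5, 6, c(alpha = 0, beta = 0, gamma_w = 0, phi = 0))$total, 0)
  expect_error(total_loss(NaN, 0, 0, 0), "l_mod")
  expect_error(total_loss(0, 0, Inf, 0), "l_emo")
})

test_that("gradient reversal is identity forward, -lambda backward", {
  x <- matrix(rnorm(6), 2, 3)
  expect_identical(grl(x, 0.5), x)
  g <- matrix(rnorm(6), 2, 3)
  expect_equal(grl_grad(g, 0.5), -0.5 * g)
  expect_equal(grl_grad(g, 0), 0 * g)
  expect_error(grl(x, -1), "nonnegative")
})

test_that("analytic gradients through the reversal layer equal -lambda times finite differences", {
  # random small double-precision networks: scalar objective
  # f(x) = sum(v * tanh(W %*% grl(x, lambda) + b)); the gradient propagated
  # below the GRL must equal -lambda times the plain gradient of f
  set.seed(21)
  for (rep in 1:5) {
    d <- sample(2:5, 1); h <- sample(2:6, 1)
    W <- matrix(rnorm(h * d), h); b <- rnorm(h); v <- rnorm(h)
    x <- rnorm(d)
    f <- function(x) sum(v * tanh(W %*% x + b))
    plain_grad <- as.vector(t(W) %*% (v * (1 - tanh(W %*% x + b)^2)))
    for (lambda in c(0, 0.5, 1)) {
      # analytic gradient seen upstream of the GRL
      analytic <- grl_grad(plain_grad, lambda)
      fd <- vapply(seq_len(d), function(i) {
        e <- rep(0, d); e[i] <- 1e-5
        (f(x + e) - f(x - e)) / 2e-5
      }, numeric(1))
      expect_equal(analytic, -lambda * fd, tolerance = 1e-4)
    }
  }
})

test_that("conv feature blocks quarter the length and share the output shape", {
  set.seed(3)
  blk <- with_seed(4, ctelcan:::init_conv_block(6, 8))
  y <- matrix(rnorm(16 * 6), 16, 6)
  z <- conv_block(y, blk)
  expect_equal(dim(z), c(4, 8))
  expect_identical(z, conv_block(y, blk))  # deterministic
  y2 <- matrix(rnorm(12 * 6), 12, 6)
  expect_equal(dim(conv_block(y2, blk)), c(3, 8))
  expect_error(conv_block(y[1:3, ], blk), "receptive field")
})

test_that("fusion concatenates along time in fixed sorted order", {
  feats <- list(EOG = matrix(1, 8, 4), EEG = matrix(2, 8, 4),
                GSR = matrix(3, 8, 4))
  fused <- fuse(feats)
  expect_equal(dim(fused), c(24, 4))
  expect_equal(fused[1, 1], 2)   # EEG first under sorted names
  expect_identical(fuse(feats), fuse(rev(feats)))
  single <- list(EEG = matrix(rnorm(8), 2, 4))
  expect_equal(fuse(single), single$EEG, ignore_attr = TRUE)
  expect_error(fuse(list()), "empty")
})

test_that("engine adversarial wiring scales feature gradients by -lambda", {
  b <- tiny_batch()
  ct <- ct_config(model_dim = 8, n_heads = 2, n_layers = 1, dropout = 0)
  lc <- lcan_config(conv_channels = 8, emo_hidden = 16, head_hidden = 8)
  params <- tiny_model_params(b, ct, lc)
  g0 <- engine_loss_grad(b, params, ct, lc, 0, c(1, 1, 1))$grads
  g1 <- engine_loss_grad(b, params, ct, lc, 1, c(1, 1, 1))$grads
  gh <- engine_loss_grad(b, params, ct, lc, 0.5, c(1, 1, 1))$grads
  for (p in c("proj.1.W", "cross.Wq", "enc.1.W1", "conv.2.K1")) {
    # the reversal enters linearly in lambda
    expect_equal(gh[[p]], 0.5 * (g0[[p]] + g1[[p]]), tolerance = 1e-5)
    # lambda = 0 severs the adversarial path: only the emotion loss remains
    gemo <- engine_loss_grad(b, params, ct, lc, 0, c(0, 0, 1))$grads
    expect_equal(g0[[p]], gemo[[p]], tolerance = 1e-6)
  }
  # classifier-head gradients are unaffected by lambda (GRL sits upstream)
  for (p in c("mod_head.W1", "sub_head.W2", "emo_head.W1"))
    expect_equal(g0[[p]], g1[[p]], tolerance = 0)
})

test_that("subject-adversary gradients mirror an identically parameterized emotion path", {
  # with a single modality and a 4-sample window the fused sequence is one
  # row per trial, so the pooled emotion input and the per-position subject
  # input coincide; aliasing the subject head with the emotion head and
  # feeding it the emotion labels must then give exactly the negated
  # emotion gradient for every feature-learner parameter
  b <- generate_synthetic(synthetic_config(
    n_subjects = 2, n_emotions = 2, trials_per_subject_per_emotion = 3,
    modality_specs = list(modality_spec("EEG", 4L, 4L)), seed = 5))
  ct <- ct_config(model_dim = 8, n_heads = 2, n_layers = 1, dropout = 0)
  lc <- lcan_config(conv_channels = 8, emo_hidden = 16, head_hidden = 16)
  params <- tiny_model_params(b, ct, lc)
  for (nm in c("W1", "b1", "W2", "b2"))
    params[[paste0("sub_head.", nm)]] <- params[[paste0("emo_head.", nm)]]
  alias <- b
  alias$subject_ids <- alias$emotion_labels
  alias$n_subjects <- alias$n_emotions
  o_sub <- engine_loss_grad(alias, params, ct, lc, 1, c(0, 1, 0),
                            n_sub = alias$n_emotions)
  o_emo <- engine_loss_grad(alias, params, ct, lc, 1, c(0, 0, 1),
                            n_sub = alias$n_emotions)
  expect_equal(o_sub$l_sub, o_emo$l_emo, tolerance = 1e-10)
  for (p in c("proj.1.W", "cross.Wv", "enc.1.Wo", "conv.1.K1"))
    expect_equal(o_sub$grads[[p]], -o_emo$grads[[p]], tolerance = 1e-6)
})

test_that("engine gradients match directional finite differences of each loss", {
  b <- tiny_batch()
  ct <- ct_config(model_dim = 8, n_heads = 2, n_layers = 1, dropout = 0)
  lc <- lcan_config(conv_channels = 8, emo_hidden = 16, head_hidden = 8)
  params <- tiny_model_params(b, ct, lc)
  set.seed(12)
  dir <- lapply(params, function(x) {
    d <- if (is.null(dim(x))) length(x) else dim(x)
    array(rnorm(length(x)), dim = d)
  })
  shift <- function(eps) Map(function(p, d) p + eps * d, params, dir)
  # lambda = -1 turns the reversal into a plain +1 pass-through, so the
  # returned gradients are the true gradient of each weighted loss
  cases <- list(list(w = c(0, 0, 1), comp = "l_emo", lam = 0),
                list(w = c(1, 0, 0), comp = "l_mod", lam = -1),
                list(w = c(0, 1, 0), comp = "l_sub", lam = -1))
  for (cs in cases) {
    g <- engine_loss_grad(b, params, ct, lc, cs$lam, cs$w)$grads
    analytic <- sum(unlist(Map(function(gg, d) sum(as.vector(gg) * as.vector(d)),
                               g[names(dir)], dir)))
    eps <- 5e-4
    up <- engine_loss_grad(b, shift(eps), ct, lc, cs$lam, cs$w)[[cs$comp]]
    dn <- engine_loss_grad(b, shift(-eps), ct, lc, cs$lam, cs$w)[[cs$comp]]
    expect_equal(analytic, (up - dn) / (2 * eps), tolerance = 0.1,
                 label = paste("directional gradient of", cs$comp))
  }
})
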