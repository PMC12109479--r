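test_that("positional encoding matches its closed form and bounds", {
  pe <- positional_encoding(8, 4)
  expect_equal(pe[1, ], c(0, 1, 0, 1))            # position 0
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)  # 0.84147...
  expect_equal(pe[2, 2], cos(1), tolerance = 1e-12)
  expect_equal(pe[2, 3], sin(1 / 10000^(2 / 4)), tolerance = 1e-12)
  big <- positional_encoding(200, 10)
  expect_true(all(abs(big) <= 1))
  # the engine-internal encoding is the same function
  expect_equal(ctelcan:::cpp_positional_encoding(12, 6),
               positional_encoding(12, 6), tolerance = 1e-12)
})

test_that("pointwise projection maps each time step independently", {
  W <- diag(3)
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(project_modality(x, W), x)               # identity map
  b <- c(1, -2, 0.5, 3)
  z <- matrix(0, 5, 2)
  expect_equal(project_modality(z, matrix(0, 2, 4), b),
               matrix(b, 5, 4, byrow = TRUE))           # bias only
  set.seed(1)
  x <- matrix(rnorm(6), 3, 2); W <- matrix(rnorm(8), 2, 4); bb <- rnorm(4)
  loop <- t(apply(x, 1, function(row) as.vector(row %*% W) + bb))
  expect_equal(project_modality(x, W, bb), loop, tolerance = 1e-12)
  expect_error(project_modality(x, matrix(0, 3, 4)), "channel mismatch")
})

test_that("cross-modal attention has the scaled softmax form", {
  set.seed(2)
  ctx <- matrix(rnorm(15), 5, 3)
  q <- matrix(rnorm(6), 2, 3)
  # zero query projection -> uniform attention -> column means of V
  out <- cross_modal_attention(q, ctx, matrix(0, 3, 2),
                               matrix(rnorm(6), 3, 2), diag(3)[, 1:2])
  v <- ctx %*% diag(3)[, 1:2]
  expect_equal(out[1, ], colMeans(v), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a single context position receives all attention mass
  out1 <- cross_modal_attention(q, ctx[1, , drop = FALSE],
                                matrix(rnorm(6), 3, 2),
                                matrix(rnorm(6), 3, 2),
                                matrix(rnorm(6), 3, 2))
  expect_equal(out1[1, ], out1[2, ])
  expect_equal(attr(out1, "attention"), matrix(1, 2, 1))
})

test_that("attention agrees with the loop oracle on random instances", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(1:8, 1); Lt <- sample(1:8, 1)
    D <- sample(1:8, 1); Da <- sample(1:8, 1)
    q <- matrix(rnorm(L * D), L)
    ctx <- matrix(rnorm(Lt * D), Lt)
    Wq <- matrix(rnorm(D * Da), D); Wk <- matrix(rnorm(D * Da), D)
    Wv <- matrix(rnorm(D * Da), D)
    got <- cross_modal_attention(q, ctx, Wq, Wk, Wv)
    want <- attention_oracle(q, ctx, Wq, Wk, Wv)
    expect_equal(unclass(got), want$output, tolerance = 1e-5,
                 ignore_attr = TRUE)
    p <- attr(got, "attention")
    expect_equal(p, want$probs, tolerance = 1e-5)
    expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  }
})

test_that("multi-head attention decomposes into per-head single-head calls", {
  set.seed(3)
  D <- 8; H <- 2; dh <- D / H
  q <- matrix(rnorm(5 * D), 5)
  ctx <- matrix(rnorm(7 * D), 7)
  Wq <- matrix(rnorm(D * D), D); Wk <- matrix(rnorm(D * D), D)
  Wv <- matrix(rnorm(D * D), D)
  mh <- ctelcan:::cpp_multihead_attention(q, ctx, Wq, Wk, Wv, H)
  for (h in seq_len(H)) {
    cs <- ((h - 1) * dh + 1):(h * dh)
    single <- cross_modal_attention(q, ctx, Wq[, cs], Wk[, cs], Wv[, cs])
    expect_equal(mh$output[, cs], unclass(single), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(mh$probs[[h]], attr(single, "attention"), tolerance = 1e-10)
    expect_true(all(abs(rowSums(mh$probs[[h]]) - 1) < 1e-6))
  }
})

test_that("the depth-0 extractor is exactly projection plus positional encoding", {
  b <- tiny_batch()
  ct0 <- ct_config(model_dim = 8, n_heads = 2, n_layers = 0, dropout = 0,
                   cross_attention = FALSE)
  lc <- lcan_config(conv_channels = 8, emo_hidden = 8, head_hidden = 8)
  params <- tiny_model_params(b, ct0, lc)
  model <- structure(list(params = params, ct = ct0, lcan = lc,
                          modalities = sort(modality_names(b))),
                     class = "ctelcan_model")
  enc <- encode(b, model)
  pe <- positional_encoding(16, 8)
  for (nm in model$modalities) {
    i <- match(nm, model$modalities)
    W <- params[[paste0("proj.", i, ".W")]]
    bb <- params[[paste0("proj.", i, ".b")]]
    for (r in c(1, 3)) {
      want <- project_modality(b$signals[[nm]][r, , ], W, bb) + pe
      expect_equal(enc$per_modality[[nm]][r, , ], want, tolerance = 1e-5)
    }
  }
  # global context is the concatenation of the projected inputs
  expect_equal(dim(enc$global_context), c(n_trials(b), 3 * 16, 8))
})

test_that("encoded feature shapes and trial covariance hold for deep configs", {
  b <- tiny_batch(n_subjects = 2, trials = 2)
  ct <- ct_config(model_dim = 8, n_heads = 2, n_layers = 2, dropout = 0.1)
  lc <- lcan_config(conv_channels = 8, emo_hidden = 8, head_hidden = 8)
  model <- structure(list(params = tiny_model_params(b, ct, lc), ct = ct,
                          lcan = lc, modalities = sort(modality_names(b))),
                     class = "ctelcan_model")
  enc <- encode(b, model)
  for (nm in model$modalities)
    expect_equal(dim(enc$per_modality[[nm]]), c(n_trials(b), 16, 8))
  # permuting trials permutes the (evaluation-mode) outputs identically
  perm <- rev(seq_len(n_trials(b)))
  encp <- encode(subset_trials(b, perm), model)
  for (nm in model$modalities)
    expect_equal(encp$per_modality[[nm]], enc$per_modality[[nm]][perm, , ],
                 tolerance = 1e-6)
})
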