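test_that("InfoNCE losses reproduce closed-form cases", {
  # all embeddings identical, N = 2: uniform softmax over 2
  z <- matrix(rep(c(1, 0), 2), nrow = 2)
  expect_equal(infonce_wave_clinical(z, z, tau = 1), log(2),
               tolerance = 1e-9)
  # diagonal cosine 1, off-diagonal 0, tau = 1, N = 2
  zw <- diag(2)
  expect_equal(infonce_wave_clinical(zw, zw, tau = 1), log(1 + exp(-1)),
               tolerance = 1e-9)
  # wave embeddings equal to their own state anchors, states orthogonal
  zs <- diag(4)
  zw4 <- zs[, c(1, 2, 3, 4)]
  expect_equal(infonce_wave_state(zw4, 1:4, zs, tau = 1),
               -log(exp(1) / (exp(1) + 3)), tolerance = 1e-9)
  # exchangeable similarities: log K
  zsame <- matrix(rep(c(1, 0, 0, 0), 4), nrow = 4)
  expect_equal(infonce_wave_state(zsame, c(1, 2, 3, 1), zsame, tau = 0.5),
               log(4), tolerance = 1e-9)
  expect_error(infonce_wave_clinical(zw[, 1, drop = FALSE],
                                     zw[, 1, drop = FALSE], 1), "N >= 2")
  expect_error(infonce_wave_state(zw4, c(1, 2, 9, 4), zs, 1), "label")
})

test_that("InfoNCE matches a literal double-loop transcription", {
  set.seed(5)
  for (N in c(3, 5)) {
    zw <- random_unit_cols(16, N)
    zc <- random_unit_cols(16, N)
    expect_equal(infonce_wave_clinical(zw, zc, 0.07),
                 oracle_infonce_wc(zw, zc, 0.07), tolerance = 1e-10)
    zs <- random_unit_cols(16, 4)
    labs <- sample(1:4, N, replace = TRUE)
    expect_equal(infonce_wave_state(zw, labs, zs, 0.07),
                 oracle_infonce_ws(zw, labs, zs, 0.07), tolerance = 1e-10)
  }
})

test_that("sharper temperatures reduce a correctly-aligned loss", {
  set.seed(8)
  zw <- random_unit_cols(32, 6)
  # matched pairs strictly closer than mismatches
  zc <- l2_normalize(zw + 0.15 * random_unit_cols(32, 6))
  losses <- vapply(c(1, 0.5, 0.1), function(tau) {
    infonce_wave_clinical(zw, zc, tau)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("combined objective is the stated weighted sum", {
  expect_equal(total_contrastive_loss(0.5, 0.25, 1, 1), 0.75)
  expect_equal(total_contrastive_loss(0.5, 0.25, 1, 0), 0.5)
  expect_equal(total_contrastive_loss(0.5, 0.25, 0, 1), 0.25)
})

test_that("the offline text backend is deterministic and projects to 128", {
  proj <- with_seed(1, nn_linear(768, 128))
  zs1 <- encode_state(state_texts(), proj)
  zs2 <- encode_state(state_texts(), proj)
  expect_identical(zs1, zs2)
  expect_equal(dim(zs1), c(128L, 4L))
  expect_true(all(is.finite(zs1)))
  expect_error(encode_state(state_texts(), proj, backend = "biobert"),
               "biobert")
})

test_that("wave and clinical encoders produce stable 128-d embeddings", {
  ck <- test_clip_checkpoint()
  enc <- clip_encoders(ck)
  segs <- test_prep()$segments[1:3]
  X <- vapply(segs, `[[`, numeric(286), "x_norm")
  z <- encode_wave(enc, X)
  expect_equal(dim(z), c(128L, 3L))
  expect_true(all(is.finite(z)))
  expect_lt(max(abs(colSums(z^2) - 1)), 1e-6)
  # order-preserving and deterministic in eval mode
  expect_equal(encode_wave(enc, X[, c(2, 1)]), z[, c(2, 1)],
               tolerance = 1e-12)
  expect_error(encode_wave(enc, matrix(0, 100, 2)), "286")

  v <- test_clinical_mat()[1:2, ]
  zc <- encode_clinical(enc, v)
  expect_equal(dim(zc), c(128L, 2L))
  expect_error(encode_clinical(enc, matrix(0, 7, 2)), "13")
})

test_that("contrastive pretraining reduces its loss and reloads exactly", {
  ck <- test_clip_checkpoint()
  expect_lt(ck$loss_trace[length(ck$loss_trace)], ck$loss_trace[1])
  # checkpoint round trip through disk reproduces embeddings
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  enc1 <- clip_encoders(ck)
  enc2 <- clip_encoders(ck2)
  X <- vapply(test_prep()$segments[1:4], `[[`, numeric(286), "x_norm")
  expect_equal(encode_wave(enc2, X), encode_wave(enc1, X),
               tolerance = 1e-12)
})

test_that("pretraining is reproducible under a fixed seed", {
  segs <- test_prep()$segments[1:40]
  cfg <- contrastive_config(epochs = 1L, batch_size = 16L, seed = 123L,
                            stem_channels = 8L,
                            encoder_widths = c(8L, 16L, 32L))
  t1 <- train_clip(segs, test_clinical_mat(), cfg)$loss_trace
  t2 <- train_clip(segs, test_clinical_mat(), cfg)$loss_trace
  expect_identical(t1, t2)
})
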