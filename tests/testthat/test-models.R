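test_that("focal loss reduces to cross-entropy at gamma 0 and vanishes at p 1", {
  set.seed(3)
  logits <- matrix(stats::rnorm(4 * 6), 4)
  y <- sample(1:4, 6, replace = TRUE)
  ce <- mean(-log(apply(rbind(logits, y), 2, function(col) {
    p <- exp(col[1:4] - max(col[1:4]))
    (p / sum(p))[col[5]]
  })))
  expect_equal(focal_loss(logits, y, gamma = 0), ce, tolerance = 1e-6)
  # confident correct prediction drives the loss to zero
  sure <- matrix(c(50, 0, 0, 0), 4)
  expect_lt(focal_loss(sure, 1, gamma = 2), 1e-10)
})

test_that("focal loss matches a literal transcription on hand-set batches", {
  set.seed(11)
  logits <- matrix(stats::rnorm(4 * 4, sd = 2), 4)
  y <- c(2, 4, 1, 3)
  w <- c(0.5, 1, 2, 1.5)
  pen <- matrix(stats::runif(16, 0.5, 2), 4)
  # brute-force transcription
  tot <- 0
  for (i in 1:4) {
    p <- exp(logits[, i]) / sum(exp(logits[, i]))
    tot <- tot + w[y[i]] * pen[y[i], which.max(logits[, i])] *
      (1 - p[y[i]])^2 * (-log(p[y[i]]))
  }
  expect_equal(focal_loss(logits, y, gamma = 2, class_weights = w,
                          penalty = pen),
               tot / 4, tolerance = 1e-10)
})

test_that("Dice and BCE behave at their analytic anchors", {
  # perfect prediction limit
  m <- c(rep(1, 100), rep(0, 186))
  z <- ifelse(m == 1, 40, -40)
  expect_lt(dice_loss(matrix(z), matrix(m)), 1e-5)
  expect_lt(bce_loss(matrix(z), matrix(m)), 1e-10)
  # p = 0.5 everywhere against a half-ones mask
  m2 <- c(rep(1, 143), rep(0, 143))
  expect_equal(dice_loss(matrix(0, 286, 1), matrix(m2)), 0.5,
               tolerance = 1e-4)
  # equal-halves combination and multitask weighting
  expect_equal(0.5 * 0.2 + 0.5 * 0.4, 0.3)
  expect_equal(total_loss(1, 1, alpha = 1.8, beta = 0.9), 2.7)
  expect_equal(total_loss(1, 1, alpha = 1, beta = 1), 2)
  expect_equal(total_loss(1, 1, alpha = 1.8, beta = 0), 1.8)
})

test_that("loss gradients match finite differences", {
  set.seed(21)
  logits <- matrix(stats::rnorm(4 * 5), 4)
  y <- sample(1:4, 5, replace = TRUE)
  fg <- ppgrhythm:::focal_grad(logits, y, 2, rep(1, 4), matrix(1, 4, 4))
  eps <- 1e-6
  for (t in 1:10) {
    i <- sample(length(logits), 1)
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    fd <- (focal_loss(lp, y, 2) - focal_loss(lm, y, 2)) / (2 * eps)
    expect_equal(fg$grad[i], fd, tolerance = 1e-4)
  }
  z <- matrix(stats::rnorm(40), 20, 2)
  m <- matrix(rbinom(40, 1, 0.4), 20, 2)
  dg <- ppgrhythm:::dice_grad(z, m)
  bg <- ppgrhythm:::bce_grad(z, m)
  for (t in 1:10) {
    i <- sample(length(z), 1)
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    expect_equal(dg$grad[i], (dice_loss(zp, m) - dice_loss(zm, m)) / (2 * eps),
                 tolerance = 1e-4)
    expect_equal(bg$grad[i], (bce_loss(zp, m) - bce_loss(zm, m)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("baseline U-Net honours its shape contracts at full width", {
  set.seed(5)
  net <- baseline_unet()   # 64..1024 channels
  B <- 4L
  x <- array(stats::rnorm(286 * B), c(1, 286, B))
  hrv <- matrix(stats::rnorm(4 * B), 4)
  out <- net$forward(x, hrv, train = FALSE)
  expect_equal(dim(out$class_logits), c(4L, B))
  expect_equal(dim(out$seg_logits), c(286L, B))
  # SE gate is a sigmoid output
  bott <- array(stats::rnorm(1024 * 17 * 2), c(1024, 17, 2))
  g <- net$se$gate(bott)
  expect_true(all(g > 0 & g < 1))
  expect_error(baseline_unet(widths = c(64, 32, 128, 256, 512)),
               "increasing")
})

test_that("per-sample outputs are independent in eval mode", {
  set.seed(6)
  net <- baseline_unet(widths = c(8L, 16L, 32L, 64L, 128L))
  x1 <- array(stats::rnorm(286), c(1, 286, 1))
  xb <- array(0, c(1, 286, 3))
  xb[, , 1] <- x1; xb[, , 2] <- stats::rnorm(286); xb[, , 3] <- x1
  hrv <- matrix(stats::rnorm(4), 4, 3)
  hrv[, 3] <- hrv[, 1]
  out <- net$forward(xb, hrv, train = FALSE)
  expect_equal(out$class_logits[, 3], out$class_logits[, 1],
               tolerance = 1e-10)
  expect_equal(out$seg_logits[, 3], out$seg_logits[, 1], tolerance = 1e-10)
})

test_that("the CLIP U-Net transfers the pretrained encoder faithfully", {
  ck <- test_clip_checkpoint()
  set.seed(8)
  net <- clip_unet(ck)
  B <- 3L
  x <- array(stats::rnorm(286 * B), c(1, 286, B))
  hrv <- matrix(stats::rnorm(4 * B), 4)
  clin <- matrix(stats::rnorm(13 * B), 13)
  out <- net$forward(x, hrv, clin, train = FALSE)
  expect_equal(dim(out$class_logits), c(4L, B))
  expect_equal(dim(out$seg_logits), c(286L, B))
  # classification head consumes the 145-d multimodal feature
  head_in <- ck$arch$proj_dim + 4L + 13L
  expect_equal(head_in, 145L)
  first_linear <- net$head$children[[2]]
  expect_equal(ncol(first_linear$W), 145L)
  # encoder weights equal the checkpoint's
  enc <- clip_encoders(ck)
  z_ck <- encode_wave(enc, matrix(x[1, , ], ncol = B), normalize = FALSE)
  f <- net$encoder$fw_full(x, train = FALSE)
  expect_equal(f$z, z_ck, tolerance = 1e-12)
  expect_error(clip_unet(list()), "checkpoint")
})

test_that("frozen encoders are bit-identical after a training step", {
  ck <- test_clip_checkpoint()
  segs <- test_prep()$segments[1:24]
  cmat <- test_clinical_mat()
  m <- train_multitask(segs, cmat,
                       multitask_config("clip", epochs = 2L,
                                        batch_size = 8L, freeze_epochs = 2L,
                                        seed = 31L),
                       clip_checkpoint = ck)
  h <- m$train_log$encoder_hash
  expect_equal(h[2], h[1], tolerance = 1e-12)
  m2 <- train_multitask(segs, cmat,
                        multitask_config("clip", epochs = 2L,
                                         batch_size = 8L, freeze_epochs = 1L,
                                         seed = 31L),
                        clip_checkpoint = ck)
  h2 <- m2$train_log$encoder_hash
  expect_false(isTRUE(all.equal(h2[2], h2[1])))
})

test_that("multitask training reduces the loss deterministically", {
  segs <- test_prep()$segments[1:60]
  cfg <- multitask_config("baseline", epochs = 3L, batch_size = 16L,
                          widths = c(8L, 16L, 32L, 64L, 128L), seed = 77L)
  m <- train_multitask(segs, config = cfg)
  expect_lt(m$train_log$train_loss[3], m$train_log$train_loss[1])
  m2 <- train_multitask(segs, config = cfg)
  expect_identical(m$train_log$train_loss, m2$train_log$train_loss)
})

test_that("gradient flows into every parameter group when unfrozen", {
  ck <- test_clip_checkpoint()
  set.seed(9)
  net <- clip_unet(ck)
  B <- 4L
  x <- array(stats::rnorm(286 * B), c(1, 286, B))
  out <- net$forward(x, matrix(stats::rnorm(4 * B), 4),
                     matrix(stats::rnorm(13 * B), 13), train = TRUE)
  zero_grads(list(net))
  net$backward(matrix(stats::rnorm(4 * B), 4),
               matrix(stats::rnorm(286 * B), 286))
  for (l in collect_all_layers(list(net))) {
    for (p in l$param_names) {
      expect_gt(sum(abs(l[[paste0("g_", p)]])), 0)
    }
  }
})

test_that("prediction applies the argmax and 0.5-threshold conventions", {
  # ties resolve toward the lower class index
  probs <- ppgrhythm:::softmax_cols(matrix(c(3, 1, 0, 0), 4))
  expect_equal(which.max(probs[, 1]), 1L)
  tie <- matrix(c(2, 2, 0, 0), 4)
  expect_equal(which.max(tie[, 1]), 1L)
  # a segmentation logit of exactly 0 maps to mask 1 (0.5 >= 0.5)
  expect_true(1 / (1 + exp(-0)) >= 0.5)
  ck <- test_clip_checkpoint()
  segs <- test_prep()$segments[1:10]
  m <- train_multitask(segs, test_clinical_mat(),
                       multitask_config("clip", epochs = 1L, batch_size = 8L,
                                        freeze_epochs = 1L, seed = 41L),
                       clip_checkpoint = ck)
  pr <- predict_segments(m, segs, test_clinical_mat())
  expect_length(pr$labels, 10L)
  expect_true(all(pr$labels %in% rhythm_classes()))
  expect_equal(dim(pr$masks), c(286L, 10L))
  expect_true(all(pr$masks %in% c(0, 1)))
  expect_equal(unname(pr$confidence), apply(pr$probs, 2, max))
  # batch order preserved: scoring a permutation permutes the outputs
  pr2 <- predict_segments(m, segs[c(3, 1, 2)], test_clinical_mat())
  expect_equal(pr2$labels, pr$labels[c(3, 1, 2)])
})
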