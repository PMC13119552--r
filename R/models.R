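# Multitask models: the baseline 1D U-Net (waveform + HRV) and the proposed
# CLIP-initialized U-Net (waveform + HRV + clinical), with focal / BCE /
# Dice losses and the freeze-then-finetune training loop.
#
# Logit conventions: class logits are (4, B) matrices, segmentation logits
# (286, B) matrices; per-sample masks are columns.

# -- losses ------------------------------------------------------------------

softmax_cols <- function(z) {
  m <- apply(z, 2, max)
  ez <- exp(sweep(z, 2, m))
  sweep(ez, 2, colSums(ez), `/`)
}

#' Class-weighted focal loss with optional misclassification penalty
#'
#' Mean over the batch of
#' `w[y] * penalty[y, argmax] * (1 - p_y)^gamma * (-log p_y)` with
#' `p = softmax(logits)`. With `gamma = 0`, unit weights and a unit penalty
#' matrix this reduces to cross-entropy. The penalty factor (default
#' all-ones) re-weights clinically asymmetric confusions; it scales the
#' loss as a constant factor (the argmax is not differentiated through).
#'
#' @param logits Matrix `4 x N` of class logits.
#' @param labels Class labels (names or 1-based indices).
#' @param gamma Focusing parameter (>= 0).
#' @param class_weights Length-4 per-class weights.
#' @param penalty `4 x 4` penalty matrix, rows = true class, cols = predicted.
#' @return Loss value.
#' @export
focal_loss <- function(logits, labels, gamma = 2,
                       class_weights = rep(1, 4),
                       penalty = matrix(1, 4, 4)) {
  focal_grad(logits, labels, gamma, class_weights, penalty)$loss
}

focal_grad <- function(logits, labels, gamma, class_weights, penalty) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- class_index(as.character(labels))
  }
  K <- nrow(logits); N <- ncol(logits)
  if (any(labels < 1L | labels > K)) stop("invalid label", call. = FALSE)
  p <- softmax_cols(logits)
  iy <- cbind(labels, seq_len(N))
  py <- pmax(p[iy], 1e-12)
  pred <- apply(logits, 2, which.max)
  w <- class_weights[labels] * penalty[cbind(labels, pred)]
  one_m <- pmax(1 - py, 0)
  loss <- mean(w * one_m^gamma * (-log(py)))
  # d/dp_y of (1 - p_y)^g * (-log p_y); g = 0 branch avoids 0 * Inf at p_y = 1
  fprime <- if (gamma > 0) {
    gamma * one_m^(gamma - 1) * log(py) - one_m^gamma / py
  } else {
    -1 / py
  }
  coef <- w * fprime / N
  onehot <- matrix(0, K, N); onehot[iy] <- 1
  # dL/dz_k = coef * p_y * (delta_ky - p_k)
  grad <- sweep(onehot - p, 2, coef * py, `*`)
  list(loss = loss, grad = grad)
}

#' Sigmoid binary cross-entropy on segmentation logits
#'
#' @param seg_logits Matrix `L x N` of per-sample logits.
#' @param mask Binary matrix of the same shape.
#' @return Mean BCE over all samples and positions.
#' @export
bce_loss <- function(seg_logits, mask) {
  bce_grad(seg_logits, mask)$loss
}

bce_grad <- function(seg_logits, mask) {
  z <- as.matrix(seg_logits); m <- as.matrix(mask)
  if (!all(dim(z) == dim(m))) {
    stop("shape mismatch between logits and mask", call. = FALSE)
  }
  loss <- mean(pmax(z, 0) - z * m + log1p(exp(-abs(z))))
  p <- 1 / (1 + exp(-z))
  list(loss = loss, grad = (p - m) / length(z))
}

#' Soft Dice loss on segmentation logits
#'
#' `1 - mean_b (2 sum(p m) + eps) / (sum(p) + sum(m) + eps)` with
#' `p = sigmoid(logits)`, averaged per segment.
#'
#' @inheritParams bce_loss
#' @param eps Smoothing constant.
#' @return Loss value in `[0, 1]`.
#' @export
dice_loss <- function(seg_logits, mask, eps = 1e-6) {
  dice_grad(seg_logits, mask, eps)$loss
}

dice_grad <- function(seg_logits, mask, eps = 1e-6) {
  z <- as.matrix(seg_logits); m <- as.matrix(mask)
  if (!all(dim(z) == dim(m))) {
    stop("shape mismatch between logits and mask", call. = FALSE)
  }
  B <- ncol(z)
  p <- 1 / (1 + exp(-z))
  num <- 2 * colSums(p * m) + eps
  den <- colSums(p) + colSums(m) + eps
  loss <- 1 - mean(num / den)
  ddice <- sweep(2 * m, 2, den, `*`) - rep(num, each = nrow(z))
  ddice <- sweep(ddice, 2, den^2, `/`)
  grad <- -(ddice / B) * p * (1 - p)
  list(loss = loss, grad = grad)
}

#' Combined segmentation loss (equal halves of BCE and Dice)
#'
#' @inheritParams bce_loss
#' @return `0.5 * bce + 0.5 * dice`.
#' @export
combined_seg_loss <- function(seg_logits, mask) {
  0.5 * bce_loss(seg_logits, mask) + 0.5 * dice_loss(seg_logits, mask)
}

#' Multitask objective
#'
#' `alpha * clf_loss + beta * seg_loss`. The baseline model uses
#' `alpha = 1.8, beta = 0.9`; the proposed model uses `alpha = beta = 1`.
#'
#' @param clf_loss,seg_loss Component losses.
#' @param alpha,beta Task weights.
#' @return Weighted total.
#' @export
total_loss <- function(clf_loss, seg_loss, alpha = 1, beta = 1) {
  alpha * clf_loss + beta * seg_loss
}

# -- shared helpers ----------------------------------------------------------

# concatenate / split (C, L, B) tensors along the channel dimension
cat_channels <- function(a, b) cat_channels_cpp(a, b)

split_channels <- function(d, n_first) split_channels_cpp(d, n_first)

make_mlp_head <- function(in_dim, hidden, n_classes = 4L, dropout = 0.3) {
  # dropout applies to the fused input feature as well as the hidden
  # layers: with few training patients, the patient-constant covariates in
  # the input are the dominant overfitting channel
  layers <- list(nn_dropout(dropout))
  d <- in_dim
  for (h in hidden) {
    layers <- c(layers, list(nn_linear(d, h), nn_layernorm(h), nn_relu(),
                             nn_dropout(dropout)))
    d <- h
  }
  do.call(nn_sequential, c(layers, list(nn_linear(d, n_classes))))
}

# -- baseline multitask U-Net ------------------------------------------------

#' Baseline multitask 1D U-Net
#'
#' Encoder: DoubleConv (1 -> widths[1]) followed by four max-pool +
#' DoubleConv down blocks; a squeeze-and-excitation block refines the
#' bottleneck. The decoder mirrors the encoder with linear-interpolation
#' upsampling and skip concatenation; a three-layer convolutional head
#' (kernels 3, 3, 1) emits per-sample segmentation logits at the input
#' length. Classification pools the SE-refined bottleneck, concatenates the
#' 4-d HRV vector and applies an MLP with LayerNorm, ReLU and dropout.
#'
#' @param widths Five strictly increasing channel widths.
#' @param hrv_dim HRV feature dimension.
#' @param n_classes Number of rhythm classes.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param dropout Dropout rate in the classification head.
#' @param gn_groups GroupNorm group count.
#' @return Object of class `nn_layer`/`baseline_unet` with
#'   `$forward(x, hrv, train)` returning `list(class_logits, seg_logits)`
#'   and `$backward(d_class, d_seg)`.
#' @export
baseline_unet <- function(widths = c(64L, 128L, 256L, 512L, 1024L),
                          hrv_dim = 4L, n_classes = 4L, se_reduction = 16L,
                          dropout = 0.3, gn_groups = 8L) {
  if (length(widths) != 5L || is.unsorted(widths, strictly = TRUE)) {
    stop("widths must be five strictly increasing channel counts",
         call. = FALSE)
  }
  e <- new_layer("baseline_unet")
  w <- as.integer(widths)
  e$widths <- w; e$hrv_dim <- as.integer(hrv_dim)
  e$inc <- nn_double_conv(1L, w[1], gn_groups)
  e$pools <- lapply(1:4, function(i) nn_maxpool(2L))
  e$downs <- lapply(1:4, function(i) nn_double_conv(w[i], w[i + 1], gn_groups))
  e$se <- nn_se_block(w[5], se_reduction)
  e$ups_interp <- lapply(1:4, function(i) nn_interp())
  # up block i fuses the deeper map (w[6-i] channels) with skip s_{5-i}
  e$ups_conv <- lapply(1:4, function(i) {
    nn_double_conv(w[6 - i] + w[5 - i], w[5 - i], gn_groups)
  })
  e$seg_head <- nn_sequential(
    nn_conv1d(w[1], 32L, 3L), nn_groupnorm(32L, gn_groups), nn_relu(),
    nn_conv1d(32L, 16L, 3L), nn_groupnorm(16L, gn_groups), nn_relu(),
    nn_conv1d(16L, 1L, 1L, pad = 0L)
  )
  e$gap <- nn_gap()
  # head capacity matched to the proposed model's (128, 64) for a
  # controlled baseline-versus-proposed comparison
  e$head <- make_mlp_head(w[5] + hrv_dim, c(128L, 64L), n_classes, dropout)
  e$children <- c(list(e$inc), e$pools, e$downs, list(e$se),
                  e$ups_interp, e$ups_conv,
                  list(e$seg_head, e$gap, e$head))

  e$forward <- function(x, hrv, train = TRUE) {
    skips <- vector("list", 4L)
    h <- e$inc$fw(x, train); skips[[1]] <- h
    for (i in 1:3) {
      h <- e$downs[[i]]$fw(e$pools[[i]]$fw(h, train), train)
      skips[[i + 1]] <- h
    }
    s5 <- e$downs[[4]]$fw(e$pools[[4]]$fw(h, train), train)
    bott <- e$se$fw(s5, train)
    d <- bott
    for (i in 1:4) {
      sk <- skips[[5 - i]]
      up <- e$ups_interp[[i]]$fw(d, dim(sk)[2], train)
      d <- e$ups_conv[[i]]$fw(cat_channels(up, sk), train)
    }
    seg <- e$seg_head$fw(d, train)
    z <- e$gap$fw(bott, train)
    list(class_logits = e$head$fw(rbind(z, hrv), train),
         seg_logits = matrix(seg, nrow = dim(seg)[2]))
  }

  e$backward <- function(d_class, d_seg) {
    w <- e$widths
    dfeat <- e$head$bw(d_class)
    dbott_cls <- e$gap$bw(dfeat[seq_len(w[5]), , drop = FALSE])
    dd <- e$seg_head$bw(array(d_seg, c(1L, nrow(d_seg), ncol(d_seg))))
    dskips <- vector("list", 4L)
    for (i in 4:1) {
      parts <- split_channels(e$ups_conv[[i]]$bw(dd), w[6 - i])
      dskips[[5 - i]] <- parts$second
      dd <- e$ups_interp[[i]]$bw(parts$first)
    }
    dh <- e$se$bw(dd + dbott_cls)
    for (i in 4:1) {
      dh <- e$pools[[i]]$bw(e$downs[[i]]$bw(dh))
      if (i > 1) dh <- dh + dskips[[i]]
    }
    e$inc$bw(dh + dskips[[1]])
  }
  e
}

# -- CLIP-initialized multitask U-Net ----------------------------------------

#' CLIP-initialized multitask U-Net
#'
#' Reuses the pretrained contrastive wave encoder (1x15 stem to L/4, three
#' stride-2 residual blocks) as the U-Net encoder, exporting skip maps at
#' {L/4, L/8, L/16, L/32}. The decoder fuses them with three upsampling
#' DoubleConv blocks (channel fusions deep-to-shallow:
#' `w3 + w2 -> w2`, `w2 + w1 -> w1`, `w1 + stem -> stem`), then a final x4
#' upsampling, a 1x1 convolution to 16 channels and a 1x1 segmentation head,
#' interpolated to exactly the input length. Classification projects the
#' pooled bottleneck through the pretrained projection to the shared
#' embedding, concatenates the 4-d HRV vector and the standardized 13-d
#' clinical vector (145-d multimodal feature by default) and applies an MLP
#' (145 -> 128 -> 64 -> 4) with LayerNorm, ReLU and dropout.
#'
#' @param checkpoint A `clip_checkpoint` from [train_clip()].
#' @param hrv_dim,clinical_dim Auxiliary feature dimensions.
#' @param n_classes Number of rhythm classes.
#' @param dropout Dropout rate in the classification head.
#' @param gn_groups GroupNorm group count (decoder).
#' @param enc_lr_factor Learning-rate multiplier applied to the pretrained
#'   encoder's parameters once unfrozen.
#' @return Object of class `nn_layer`/`clip_unet` with
#'   `$forward(x, hrv, clin, train)` and `$backward(d_class, d_seg)`, plus
#'   `$freeze_encoder()` / `$unfreeze_encoder()`.
#' @export
clip_unet <- function(checkpoint, hrv_dim = 4L, clinical_dim = 13L,
                      n_classes = 4L, dropout = 0.3, gn_groups = 8L,
                      enc_lr_factor = 1.0) {
  if (!inherits(checkpoint, "clip_checkpoint")) {
    stop("incompatible checkpoint: expected a clip_checkpoint",
         call. = FALSE)
  }
  arch <- checkpoint$arch
  e <- new_layer("clip_unet")
  e$arch <- arch
  e$encoder <- make_wave_encoder(arch$stem, arch$widths, arch$proj_dim)
  enc_state <- checkpoint$state[seq_along(collect_layers(e$encoder))]
  load_layer_state(list(e$encoder), enc_state)
  for (l in collect_layers(e$encoder)) l$lr_scale <- enc_lr_factor
  w <- arch$widths; stem <- arch$stem
  e$ups_interp <- lapply(1:3, function(i) nn_interp())
  e$ups_conv <- list(
    nn_double_conv(w[3] + w[2], w[2], gn_groups),
    nn_double_conv(w[2] + w[1], w[1], gn_groups),
    nn_double_conv(w[1] + stem, stem, gn_groups)
  )
  e$final_interp <- nn_interp()
  e$final_conv <- nn_sequential(
    nn_conv1d(stem, 16L, 1L, pad = 0L), nn_groupnorm(16L, gn_groups),
    nn_relu(), nn_conv1d(16L, 1L, 1L, pad = 0L)
  )
  e$out_interp <- nn_interp()
  e$head <- make_mlp_head(arch$proj_dim + hrv_dim + clinical_dim,
                          c(128L, 64L), n_classes, dropout)
  e$children <- c(list(e$encoder), e$ups_interp, e$ups_conv,
                  list(e$final_interp, e$final_conv, e$out_interp, e$head))

  e$forward <- function(x, hrv, clin, train = TRUE) {
    L <- dim(x)[2]
    f <- e$encoder$fw_full(x, train)
    skips <- list(f$s3, f$s2, f$s1)
    d <- f$s4
    for (i in 1:3) {
      sk <- skips[[i]]
      up <- e$ups_interp[[i]]$fw(d, dim(sk)[2], train)
      d <- e$ups_conv[[i]]$fw(cat_channels(up, sk), train)
    }
    d <- e$final_interp$fw(d, 4L * dim(d)[2], train)
    seg <- e$final_conv$fw(d, train)
    seg <- e$out_interp$fw(seg, L, train)
    # the head consumes the embedding in the geometry the contrastive
    # phase trained: L2-normalized
    zn <- l2_normalize(f$z)
    e$z_cache <- list(z = f$z, zn = zn)
    list(class_logits = e$head$fw(rbind(zn, hrv, clin), train),
         seg_logits = matrix(seg, nrow = dim(seg)[2]))
  }

  e$backward <- function(d_class, d_seg) {
    w <- e$arch$widths
    dfeat <- e$head$bw(d_class)
    dzn <- dfeat[seq_len(e$arch$proj_dim), , drop = FALSE]
    dz <- l2_normalize_bw(e$z_cache$z, e$z_cache$zn, dzn)
    dd <- e$final_interp$bw(e$final_conv$bw(
      e$out_interp$bw(array(d_seg, c(1L, nrow(d_seg), ncol(d_seg))))))
    nch <- c(w[3], w[2], w[1])
    dskips <- vector("list", 3L)
    for (i in 3:1) {
      parts <- split_channels(e$ups_conv[[i]]$bw(dd), nch[i])
      dskips[[i]] <- parts$second
      dd <- e$ups_interp[[i]]$bw(parts$first)
    }
    e$encoder$bw_full(dz = dz, ds4 = dd, ds3 = dskips[[1]],
                      ds2 = dskips[[2]], ds1 = dskips[[3]])
  }

  e$freeze_encoder <- function() set_frozen(list(e$encoder), TRUE)
  e$unfreeze_encoder <- function() set_frozen(list(e$encoder), FALSE)
  e
}

# -- training ----------------------------------------------------------------

#' Multitask training configuration
#'
#' @param kind `"baseline"` or `"clip"`.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param gamma Focal loss focusing parameter.
#' @param alpha,beta Task weights; defaults are 1.8 / 0.9 for the baseline
#'   and 1 / 1 for the proposed model.
#' @param freeze_epochs Epochs to keep the pretrained encoder + projection
#'   frozen (clip kind only).
#' @param enc_lr_factor Learning-rate multiplier for the pretrained encoder
#'   once unfrozen (discriminative fine-tuning).
#' @param clinical_dropout Probability of withholding the entire clinical
#'   vector per sample during training (clip kind); regularizes against
#'   patient-profile memorization in small cohorts.
#' @param widths Baseline U-Net channel widths.
#' @param dropout Classification-head dropout (input and hidden layers).
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return Object of class `multitask_config`.
#' @export
multitask_config <- function(kind = c("baseline", "clip"), epochs = 15L,
                             batch_size = 32L, lr = 1e-3, gamma = 2,
                             alpha = NULL, beta = NULL, freeze_epochs = 5L,
                             enc_lr_factor = 0.1, clinical_dropout = 0.8,
                             widths = c(64L, 128L, 256L, 512L, 1024L),
                             dropout = 0.3, seed = 1L) {
  kind <- match.arg(kind)
  alpha <- alpha %||% if (kind == "baseline") 1.8 else 1.0
  beta <- beta %||% if (kind == "baseline") 0.9 else 1.0
  structure(list(kind = kind, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, gamma = gamma,
                 alpha = alpha, beta = beta,
                 freeze_epochs = as.integer(freeze_epochs),
                 enc_lr_factor = enc_lr_factor,
                 clinical_dropout = clinical_dropout,
                 widths = as.integer(widths), dropout = dropout,
                 seed = as.integer(seed)),
            class = "multitask_config")
}

segments_to_batch <- function(segments, idx, clinical_mat = NULL) {
  B <- length(idx)
  L <- length(segments[[idx[1]]]$x_norm)
  x <- array(0, c(1L, L, B))
  m <- matrix(0, L, B)
  h <- matrix(0, 4L, B)
  y <- integer(B)
  for (j in seq_len(B)) {
    s <- segments[[idx[j]]]
    x[1, , j] <- s$x_norm
    m[, j] <- s$mask
    h[, j] <- s$hrv
    y[j] <- class_index(s$label)
  }
  cl <- NULL
  if (!is.null(clinical_mat)) {
    pids <- vapply(segments[idx], `[[`, "", "patient_id")
    cl <- t(clinical_mat[pids, , drop = FALSE])
  }
  list(x = x, mask = m, hrv = h, y = y, clin = cl)
}

model_forward <- function(net, kind, batch, train, hrv_scaler = NULL,
                          clinical_dropout = 0) {
  h <- batch$hrv
  if (!is.null(hrv_scaler)) h <- (h - hrv_scaler$mu) / hrv_scaler$sd
  if (kind == "baseline") {
    return(net$forward(batch$x, h, train = train))
  }
  cl <- batch$clin
  if (train && clinical_dropout > 0) {
    # modality dropout: the whole clinical vector is withheld per sample,
    # so the network cannot rely on memorizing patient profiles
    keep <- (stats::runif(ncol(cl)) >= clinical_dropout) /
      (1 - clinical_dropout)
    cl <- sweep(cl, 2, keep, `*`)
  }
  net$forward(batch$x, h, cl, train = train)
}

# training-set standardization of the 4 HRV features (the heads consume
# them z-scored, like the clinical variables)
fit_hrv_scaler <- function(segments) {
  H <- vapply(segments, function(s) s$hrv, numeric(4))
  sd_ <- apply(H, 1, stats::sd)
  sd_[sd_ < 1e-8] <- 1
  list(mu = rowMeans(H), sd = sd_)
}

eval_total_loss <- function(net, kind, segments, clinical_mat, cw, cfg,
                            hrv_scaler = NULL, chunk = 64L) {
  n <- length(segments)
  tot <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    b <- segments_to_batch(segments, idx, clinical_mat)
    out <- model_forward(net, kind, b, train = FALSE, hrv_scaler)
    lc <- focal_loss(out$class_logits, b$y, cfg$gamma, cw)
    ls <- combined_seg_loss(out$seg_logits, b$mask)
    tot <- tot + total_loss(lc, ls, cfg$alpha, cfg$beta) * length(idx)
  }
  tot / n
}

# hash of trainable encoder parameter values (freeze-contract checks)
encoder_param_hash <- function(net) {
  if (is.null(net$encoder)) return(NA_real_)
  vals <- unlist(lapply(collect_layers(net$encoder), function(l) {
    unlist(lapply(l$param_names, function(p) as.numeric(l[[p]])))
  }))
  sum(vals * seq_along(vals) %% 97)
}

#' Train a multitask rhythm model
#'
#' Mini-batch Adam on the weighted focal + (BCE + Dice)/2 objective. For the
#' proposed (`clip`) kind, the pretrained encoder and projection are kept
#' frozen for `freeze_epochs` epochs and then fine-tuned. When validation
#' segments are supplied, the parameters with the best validation total loss
#' are restored at the end. Deterministic given `config$seed`.
#'
#' @param segments Training segments (patient-level split upstream).
#' @param clinical_mat Standardized clinical matrix (rownames = patient ids;
#'   required for the clip kind).
#' @param config A [multitask_config()].
#' @param clip_checkpoint A `clip_checkpoint` (clip kind only).
#' @param val_segments Optional validation segments for model selection.
#' @return Object of class `ppg_model`: the network, config, class weights
#'   and a per-epoch training log (train loss, validation loss, encoder
#'   parameter hash).
#' @export
train_multitask <- function(segments, clinical_mat = NULL,
                            config = multitask_config(),
                            clip_checkpoint = NULL, val_segments = NULL) {
  if (length(segments) == 0L) stop("empty training split", call. = FALSE)
  stopifnot(inherits(config, "multitask_config"))
  if (config$kind == "clip" && is.null(clip_checkpoint)) {
    stop("clip kind requires a clip_checkpoint", call. = FALSE)
  }
  labels <- vapply(segments, `[[`, "", "label")
  freq <- table(factor(labels, levels = RHYTHM_CLASSES))
  cw <- 1 / pmax(as.numeric(freq), 1)
  cw <- cw * 4 / sum(cw)   # inverse-frequency weights normalized to mean 1
  hrv_scaler <- fit_hrv_scaler(segments)
  with_seed(config$seed, {
    net <- if (config$kind == "baseline") {
      baseline_unet(widths = config$widths, dropout = config$dropout)
    } else {
      clip_unet(clip_checkpoint, dropout = config$dropout,
                enc_lr_factor = config$enc_lr_factor)
    }
    if (config$kind == "clip" && config$freeze_epochs > 0L) {
      net$freeze_encoder()
    }
    n <- length(segments)
    bs <- min(config$batch_size, n)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0), encoder_hash = numeric(0))
    best <- list(loss = Inf, state = NULL)
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      if (config$kind == "clip" && ep == config$freeze_epochs + 1L) {
        net$unfreeze_encoder()
      }
      ord <- sample.int(n)
      ep_loss <- c()
      for (start in seq(1L, n - bs + 1L, by = bs)) {
        idx <- ord[start:(start + bs - 1L)]
        b <- segments_to_batch(segments, idx, clinical_mat)
        zero_grads(list(net))
        out <- model_forward(net, config$kind, b, train = TRUE, hrv_scaler,
                             config$clinical_dropout)
        fg <- focal_grad(out$class_logits, b$y, config$gamma, cw,
                         matrix(1, 4, 4))
        bg <- bce_grad(out$seg_logits, b$mask)
        dg <- dice_grad(out$seg_logits, b$mask)
        loss <- total_loss(fg$loss, 0.5 * bg$loss + 0.5 * dg$loss,
                           config$alpha, config$beta)
        net$backward(config$alpha * fg$grad,
                     config$beta * (0.5 * bg$grad + 0.5 * dg$grad))
        t_step <- t_step + 1L
        adam_step(list(net), lr = config$lr, t = t_step)
        ep_loss <- c(ep_loss, loss)
      }
      vl <- NA_real_
      if (!is.null(val_segments) && length(val_segments)) {
        vl <- eval_total_loss(net, config$kind, val_segments, clinical_mat,
                              cw, config, hrv_scaler)
        # model selection starts once the whole network is trainable
        selectable <- config$kind != "clip" || ep > config$freeze_epochs
        if (selectable && vl < best$loss) {
          best <- list(loss = vl, state = snapshot_params(list(net)))
        }
      }
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(ep_loss),
                                   val_loss = vl,
                                   encoder_hash = encoder_param_hash(net)))
    }
    if (!is.null(best$state)) load_layer_state(list(net), best$state)
    structure(list(net = net, kind = config$kind, config = config,
                   class_weights = cw, hrv_scaler = hrv_scaler,
                   train_log = log),
              class = "ppg_model")
  })
}

#' Predict rhythm labels and abnormal-interval masks
#'
#' Label is the argmax class (ties resolved toward the lower class index);
#' the binary mask applies the `sigmoid(logit) >= 0.5` rule, i.e. a logit of
#' exactly 0 maps to 1.
#'
#' @param model A trained `ppg_model`.
#' @param segments Segments to score.
#' @param clinical_mat Standardized clinical matrix (clip kind).
#' @param chunk Scoring batch size.
#' @return List with `labels` (character), `masks` (`286 x n` binary
#'   matrix), `probs` (`4 x n` softmax matrix) and `confidence`
#'   (per-segment max probability).
#' @export
predict_segments <- function(model, segments, clinical_mat = NULL,
                             chunk = 64L) {
  stopifnot(inherits(model, "ppg_model"))
  n <- length(segments)
  L <- length(segments[[1]]$x_norm)
  probs <- matrix(0, 4L, n)
  masks <- matrix(0, L, n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    b <- segments_to_batch(segments, idx, clinical_mat)
    out <- model_forward(model$net, model$kind, b, train = FALSE,
                         model$hrv_scaler)
    probs[, idx] <- softmax_cols(out$class_logits)
    masks[, idx] <- (1 / (1 + exp(-out$seg_logits)) >= 0.5) * 1
  }
  pred_idx <- apply(probs, 2, which.max)
  list(labels = RHYTHM_CLASSES[pred_idx], masks = masks, probs = probs,
       confidence = apply(probs, 2, max))
}
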