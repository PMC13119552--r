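# CLIP-style contrastive pretraining: waveform, clinical and rhythm-text
# encoders projected into a shared 128-d space and aligned with dual
# InfoNCE objectives (wave<->clinical over in-batch negatives, wave<->state
# over the four rhythm-class anchors).

#' Rhythm-state description texts
#'
#' The four fixed clinical rhythm definitions used as semantic anchors by
#' the state encoder.
#'
#' @return Named list mapping each rhythm class to its description strings.
#' @export
state_texts <- function() {
  list(
    Normal = c(
      "Normal Sinus Rhythm (NSR). Heart rate is within normal range (60-100 bpm).",
      "Regular and consistent beats with stable P-P intervals."),
    AF = c(
      "Atrial Fibrillation. The hallmark is an 'irregularly irregular' rhythm.",
      "P waves are completely absent and replaced by chaotic fibrillatory waves.",
      "P-P intervals vary unpredictably."),
    Bradycardia = c(
      "Sinus Bradycardia. Heart rate is strictly less than 60 bpm.",
      "Rhythm is regular but significantly slow.",
      "Long P-P intervals."),
    Tachycardia = c(
      "Sinus Tachycardia. Heart rate exceeds 100 bpm but the rhythm remains regular.",
      "Fast, steady beating with consistent but shortened P-P intervals.",
      "Distinct from chaotic rhythms.")
  )
}

#' Contrastive pretraining configuration
#'
#' @param temperature Softmax temperature tau (> 0).
#' @param weight_clinical Weight of the wave-clinical loss term.
#' @param weight_state Weight of the wave-state loss term.
#' @param batch_size Mini-batch size N (>= 2).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param stem_channels,encoder_widths,proj_dim Wave-encoder architecture
#'   (1x15 stem, three stride-2 residual blocks, linear projection).
#' @param text_backend `"deterministic-offline"` (seeded hash bag-of-token
#'   768-d pseudo-embeddings) or `"biobert"` (requires external weights;
#'   errors when unavailable rather than silently falling back).
#' @param seed Integer seed.
#' @return Object of class `contrastive_config`.
#' @export
contrastive_config <- function(temperature = 0.07, weight_clinical = 1.0,
                               weight_state = 1.0, batch_size = 32L,
                               epochs = 10L, lr = 1e-3,
                               stem_channels = 32L,
                               encoder_widths = c(64L, 128L, 256L),
                               proj_dim = 128L,
                               text_backend = "deterministic-offline",
                               seed = 1L) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (batch_size < 2L) stop("batch_size must be >= 2", call. = FALSE)
  structure(list(temperature = temperature,
                 weight_clinical = weight_clinical,
                 weight_state = weight_state,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 stem_channels = as.integer(stem_channels),
                 encoder_widths = as.integer(encoder_widths),
                 proj_dim = as.integer(proj_dim),
                 text_backend = match.arg(text_backend,
                                          c("deterministic-offline",
                                            "biobert")),
                 seed = as.integer(seed)),
            class = "contrastive_config")
}

# -- encoders ----------------------------------------------------------------

# ResNet1D wave encoder shared between contrastive pretraining and the
# CLIP-initialized U-Net: 1x15 conv stem (1 -> stem channels) + max pool to
# L/4, then three stride-2 residual blocks, exporting skip feature maps at
# {L/4, L/8, L/16, L/32}; bottleneck is globally average pooled and linearly
# projected to the shared embedding dimension.
make_wave_encoder <- function(stem = 32L, widths = c(64L, 128L, 256L),
                              proj_dim = 128L) {
  e <- new_layer("wave_encoder")
  e$stem_conv <- nn_conv1d(1L, stem, 15L)
  e$stem_bn <- nn_batchnorm_conv(stem)
  e$stem_relu <- nn_relu()
  e$stem_pool <- nn_maxpool(4L)
  e$block1 <- nn_res_block(stem, widths[1], stride = 2L)
  e$block2 <- nn_res_block(widths[1], widths[2], stride = 2L)
  e$block3 <- nn_res_block(widths[2], widths[3], stride = 2L)
  e$gap <- nn_gap()
  e$proj <- nn_linear(widths[3], proj_dim)
  e$children <- list(e$stem_conv, e$stem_bn, e$stem_relu, e$stem_pool,
                     e$block1, e$block2, e$block3, e$gap, e$proj)
  e$arch <- list(stem = stem, widths = widths, proj_dim = proj_dim)
  # full forward exposing the skip pyramid and the projected embedding
  e$fw_full <- function(x, train = TRUE) {
    s1 <- e$stem_pool$fw(
      e$stem_relu$fw(e$stem_bn$fw(e$stem_conv$fw(x, train), train), train),
      train)
    s2 <- e$block1$fw(s1, train)
    s3 <- e$block2$fw(s2, train)
    s4 <- e$block3$fw(s3, train)
    z <- e$proj$fw(e$gap$fw(s4, train), train)
    list(s1 = s1, s2 = s2, s3 = s3, s4 = s4, z = z)
  }
  # backward accepting gradients for the embedding and (optionally) each
  # skip map, as the U-Net decoder feeds them
  e$bw_full <- function(dz = NULL, ds4 = NULL, ds3 = NULL, ds2 = NULL,
                        ds1 = NULL) {
    acc <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b
    d4 <- ds4
    if (!is.null(dz)) d4 <- acc(d4, e$gap$bw(e$proj$bw(dz)))
    d3 <- acc(ds3, e$block3$bw(d4))
    d2 <- acc(ds2, e$block2$bw(d3))
    d1 <- acc(ds1, e$block1$bw(d2))
    e$stem_conv$bw(e$stem_bn$bw(e$stem_relu$bw(e$stem_pool$bw(d1))))
  }
  e$fw <- function(x, train = TRUE) e$fw_full(x, train)$z
  e
}

make_clinical_encoder <- function(in_dim = 13L, hidden = 64L,
                                  out_dim = 128L) {
  nn_sequential(
    nn_linear(in_dim, hidden), nn_batchnorm_dense(hidden), nn_relu(),
    nn_linear(hidden, out_dim)
  )
}

# -- deterministic offline text backend --------------------------------------

text_token_hash <- function(token) {
  h <- 7
  for (cp in utf8ToInt(token)) h <- (h * 131 + cp) %% 2147483563
  as.integer(h)
}

# Seeded hash bag-of-token pseudo-embedding: each token maps to a fixed
# 768-d Gaussian vector keyed by its hash; a text's embedding is the
# normalized mean. Deterministic, training-free stand-in exercising the
# same 768 -> 128 projection interface a transformer [CLS] vector would.
text_embedding_768 <- function(strings, dim = 768L) {
  tokens <- unlist(strsplit(tolower(paste(strings, collapse = " ")),
                            "[^a-z0-9']+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("no tokens in text", call. = FALSE)
  v <- rowMeans(vapply(tokens, function(tok) {
    with_seed(text_token_hash(tok), stats::rnorm(dim))
  }, numeric(dim)))
  v / sqrt(sum(v^2))
}

#' Encode rhythm-state texts into the shared embedding space
#'
#' Maps each class's description strings to a 768-d text representation
#' (offline backend: seeded hash bag-of-token pseudo-embedding) and applies
#' the trainable linear projection to the shared space.
#'
#' @param texts Named list of description strings per class (see
#'   [state_texts()]).
#' @param proj An `nn_linear(768, proj_dim)` layer.
#' @param backend `"deterministic-offline"` or `"biobert"`.
#' @return Matrix `proj_dim x 4`, one column per class in
#'   [rhythm_classes()] order.
#' @export
encode_state <- function(texts = state_texts(), proj,
                         backend = "deterministic-offline") {
  if (backend == "biobert") {
    stop("biobert text backend requires external transformer weights, ",
         "which are not available; use the deterministic-offline backend",
         call. = FALSE)
  }
  H <- vapply(RHYTHM_CLASSES, function(cl) text_embedding_768(texts[[cl]]),
              numeric(768))
  proj$fw(H, train = FALSE)
}

# -- embedding normalization -------------------------------------------------

#' L2-normalize embedding columns
#'
#' @param z Matrix with one embedding per column.
#' @return Matrix with unit-norm columns.
#' @export
l2_normalize <- function(z) {
  nrm <- sqrt(colSums(z^2))
  nrm[nrm < 1e-12] <- 1
  sweep(z, 2, nrm, `/`)
}

# backward through column-wise L2 normalization
l2_normalize_bw <- function(z, zn, dzn) {
  nrm <- sqrt(colSums(z^2))
  nrm[nrm < 1e-12] <- 1
  sweep(dzn - sweep(zn, 2, colSums(dzn * zn), `*`), 2, nrm, `/`)
}

# -- InfoNCE -----------------------------------------------------------------

logsumexp_rows <- function(S) {
  m <- apply(S, 1, max)
  m + log(rowSums(exp(S - m)))
}

#' Wave-clinical InfoNCE loss
#'
#' Mean over the batch of the negative log-softmax (over in-batch clinical
#' negatives) of the matched pair's temperature-scaled cosine similarity.
#' Embeddings must be L2-normalized so the dot product equals the cosine.
#'
#' @param zw,zc Matrices `d x N` of L2-normalized wave / clinical
#'   embeddings, column i of each being the matched pair.
#' @param tau Temperature (> 0).
#' @return Loss in nats.
#' @export
infonce_wave_clinical <- function(zw, zc, tau = 0.07) {
  infonce_wc_grad(zw, zc, tau)$loss
}

infonce_wc_grad <- function(zw, zc, tau) {
  N <- ncol(zw)
  if (N < 2L || ncol(zc) != N) {
    stop("need equal batch sizes N >= 2", call. = FALSE)
  }
  S <- crossprod(zw, zc) / tau
  lse <- logsumexp_rows(S)
  loss <- mean(lse - diag(S))
  P <- exp(S - lse)
  dS <- P / N
  diag(dS) <- diag(dS) - 1 / N
  list(loss = loss,
       dzw = zc %*% t(dS) / tau,
       dzc = zw %*% dS / tau)
}

#' Wave-state InfoNCE loss
#'
#' Mean over the batch of the negative log-softmax over the K = 4 rhythm
#' state anchors, with the true class in the numerator.
#'
#' @param zw Matrix `d x N` of L2-normalized wave embeddings.
#' @param labels Class labels (names or 1-based indices into
#'   [rhythm_classes()]).
#' @param zs Matrix `d x K` of L2-normalized state embeddings.
#' @param tau Temperature.
#' @return Loss in nats.
#' @export
infonce_wave_state <- function(zw, labels, zs, tau = 0.07) {
  infonce_ws_grad(zw, labels, zs, tau)$loss
}

infonce_ws_grad <- function(zw, labels, zs, tau) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- class_index(as.character(labels))
  }
  K <- ncol(zs)
  if (any(labels < 1L | labels > K)) stop("unknown label", call. = FALSE)
  N <- ncol(zw)
  S <- crossprod(zw, zs) / tau
  lse <- logsumexp_rows(S)
  loss <- mean(lse - S[cbind(seq_len(N), labels)])
  P <- exp(S - lse)
  dS <- P / N
  dS[cbind(seq_len(N), labels)] <- dS[cbind(seq_len(N), labels)] - 1 / N
  list(loss = loss,
       dzw = zs %*% t(dS) / tau,
       dzs = zw %*% dS / tau)
}

#' Combined contrastive objective
#'
#' @param l_wc Wave-clinical loss value.
#' @param l_ws Wave-state loss value.
#' @param alpha,lambda Weights of the two terms.
#' @return `alpha * l_wc + lambda * l_ws`.
#' @export
total_contrastive_loss <- function(l_wc, l_ws, alpha = 1.0, lambda = 1.0) {
  alpha * l_wc + lambda * l_ws
}

# -- training ----------------------------------------------------------------

segments_to_wave_batch <- function(segments, idx) {
  B <- length(idx)
  L <- length(segments[[idx[1]]]$x_norm)
  x <- array(0, c(1L, L, B))
  for (j in seq_len(B)) x[1, , j] <- segments[[idx[j]]]$x_norm
  x
}

#' CLIP-style contrastive pretraining
#'
#' Jointly trains the wave encoder, clinical encoder and 768-to-128 state
#' projection by minimizing the weighted sum of the wave-clinical and
#' wave-state InfoNCE losses with Adam. Embeddings are L2-normalized before
#' the cosine similarities. Fully deterministic given `config$seed`.
#'
#' @param segments List of preprocessed segments (training patients only).
#' @param clinical_mat Standardized clinical matrix with one named row per
#'   patient (rownames = patient ids).
#' @param config A [contrastive_config()].
#' @param texts State description texts.
#' @return Object of class `clip_checkpoint`: architecture, all weights,
#'   fixed 768-d state text vectors, per-epoch loss trace and the config.
#' @export
train_clip <- function(segments, clinical_mat, config = contrastive_config(),
                       texts = state_texts()) {
  if (length(segments) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(inherits(config, "contrastive_config"))
  with_seed(config$seed, {
    wave <- make_wave_encoder(config$stem_channels, config$encoder_widths,
                              config$proj_dim)
    clin_enc <- make_clinical_encoder(13L, 64L, config$proj_dim)
    state_proj <- nn_linear(768L, config$proj_dim)
    H_state <- vapply(RHYTHM_CLASSES,
                      function(cl) text_embedding_768(texts[[cl]]),
                      numeric(768))
    layers <- list(wave, clin_enc, state_proj)
    labels_all <- vapply(segments, `[[`, "", "label")
    pids <- vapply(segments, `[[`, "", "patient_id")
    n <- length(segments)
    bs <- min(config$batch_size, n)
    trace <- numeric(config$epochs)
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (start in seq(1L, n - bs + 1L, by = bs)) {
        idx <- ord[start:(start + bs - 1L)]
        x <- segments_to_wave_batch(segments, idx)
        cvec <- t(clinical_mat[pids[idx], , drop = FALSE])
        y <- class_index(labels_all[idx])

        zero_grads(layers)
        zw_raw <- wave$fw(x, train = TRUE)
        zc_raw <- clin_enc$fw(cvec, train = TRUE)
        zs_raw <- state_proj$fw(H_state, train = TRUE)
        zw <- l2_normalize(zw_raw)
        zc <- l2_normalize(zc_raw)
        zs <- l2_normalize(zs_raw)
        wc <- infonce_wc_grad(zw, zc, config$temperature)
        ws <- infonce_ws_grad(zw, y, zs, config$temperature)
        loss <- total_contrastive_loss(wc$loss, ws$loss,
                                       config$weight_clinical,
                                       config$weight_state)
        dzw <- config$weight_clinical * wc$dzw + config$weight_state * ws$dzw
        dzc <- config$weight_clinical * wc$dzc
        dzs <- config$weight_state * ws$dzs
        wave$bw_full(dz = l2_normalize_bw(zw_raw, zw, dzw))
        clin_enc$bw(l2_normalize_bw(zc_raw, zc, dzc))
        state_proj$bw(l2_normalize_bw(zs_raw, zs, dzs))
        t_step <- t_step + 1L
        adam_step(layers, lr = config$lr, t = t_step)
        ep_losses <- c(ep_losses, loss)
      }
      trace[ep] <- mean(ep_losses)
    }
    structure(
      list(arch = wave$arch,
           state = layer_state(layers),
           state_embed_768 = H_state,
           loss_trace = trace,
           config = config,
           classes = RHYTHM_CLASSES),
      class = "clip_checkpoint")
  })
}

#' Instantiate encoders from a CLIP checkpoint
#'
#' @param ckpt A `clip_checkpoint`.
#' @return List with `wave`, `clinical`, `state_proj` layer objects carrying
#'   the checkpoint weights, plus the checkpoint's architecture.
#' @export
clip_encoders <- function(ckpt) {
  stopifnot(inherits(ckpt, "clip_checkpoint"))
  wave <- make_wave_encoder(ckpt$arch$stem, ckpt$arch$widths,
                            ckpt$arch$proj_dim)
  clin_enc <- make_clinical_encoder(13L, 64L, ckpt$arch$proj_dim)
  state_proj <- nn_linear(768L, ckpt$arch$proj_dim)
  load_layer_state(list(wave, clin_enc, state_proj), ckpt$state)
  list(wave = wave, clinical = clin_enc, state_proj = state_proj,
       arch = ckpt$arch)
}

#' Encode waveform segments into the shared embedding space
#'
#' @param enc Encoder set from [clip_encoders()].
#' @param x Numeric vector of length 286, or a matrix with one segment per
#'   column.
#' @param normalize L2-normalize the embeddings (default TRUE).
#' @return Matrix `proj_dim x n_segments`.
#' @export
encode_wave <- function(enc, x, normalize = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != 286L) stop("segments must have length 286", call. = FALSE)
  xb <- array(0, c(1L, nrow(x), ncol(x)))
  for (j in seq_len(ncol(x))) xb[1, , j] <- x[, j]
  z <- enc$wave$fw(xb, train = FALSE)
  if (normalize) l2_normalize(z) else z
}

#' Encode standardized clinical vectors into the shared embedding space
#'
#' @param enc Encoder set from [clip_encoders()].
#' @param v Numeric 13-vector or matrix with one profile per column (or one
#'   per row with 13 named columns, as produced by [clinical_transform()]).
#' @param normalize L2-normalize the embeddings (default TRUE).
#' @return Matrix `proj_dim x n_profiles`.
#' @export
encode_clinical <- function(enc, v, normalize = TRUE) {
  if (is.vector(v)) v <- matrix(v, ncol = 1)
  if (nrow(v) != 13L && ncol(v) == 13L) v <- t(v)
  if (nrow(v) != 13L) stop("clinical input must have 13 features",
                           call. = FALSE)
  z <- enc$clinical$fw(v, train = FALSE)
  if (normalize) l2_normalize(z) else z
}

#' Save / load a CLIP checkpoint
#'
#' @param ckpt A `clip_checkpoint`.
#' @param path File path.
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
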