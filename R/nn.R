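# Minimal 1D neural-network layer framework with manual backpropagation.
#
# Conventions:
#   - Convolutional feature tensors are arrays dim c(C, L, B)
#     (channels, length, batch); dense features are matrices (F, B).
#   - A layer is an environment with fields:
#       kind         layer type string
#       param_names  character vector of trainable parameter fields
#       children     list of sublayers (for composite layers)
#       frozen       logical, excluded from optimizer updates when TRUE
#       fw(x, train) forward pass (caches what backward needs)
#       bw(dy)       backward pass, accumulates g_<name> grads, returns dx
#   - Convolutions are im2col + BLAS matrix multiply; gradients are exact
#     analytic transposes (verified against finite differences in tests).
# All weight initialization draws from the current RNG stream, so model
# construction under a fixed seed is fully deterministic.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$param_names <- character(0)
  e$children <- list()
  e$frozen <- FALSE
  class(e) <- "nn_layer"
  e
}

# -- conv1d ------------------------------------------------------------------

nn_conv1d <- function(cin, cout, k, stride = 1L, pad = k %/% 2L) {
  e <- new_layer("conv1d")
  e$cin <- cin; e$cout <- cout; e$k <- as.integer(k)
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$W <- matrix(stats::rnorm(cout * cin * k, 0, sqrt(2 / (cin * k))),
                nrow = cout)
  e$b <- numeric(cout)
  e$g_W <- e$W * 0; e$g_b <- e$b * 0
  e$param_names <- c("W", "b")
  e$fw <- function(x, train = TRUE) {
    d <- dim(x)
    res <- conv1d_fw_cpp(x, e$W, e$b, e$k, e$stride, e$pad)
    e$cache <- list(Xcol = res$xcol, L = d[2], B = d[3])
    res$y
  }
  e$bw <- function(dy) {
    cc <- e$cache
    res <- conv1d_bw_cpp(dy, e$W, cc$Xcol, e$cin, cc$L, e$k, e$stride,
                         e$pad)
    e$g_W <- e$g_W + res$dW
    e$g_b <- e$g_b + as.numeric(res$db)
    res$dx
  }
  e
}

# -- pooling -----------------------------------------------------------------

nn_maxpool <- function(k) {
  e <- new_layer("maxpool")
  e$k <- as.integer(k)
  e$fw <- function(x, train = TRUE) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    k <- e$k
    Lout <- L %/% k
    y <- x[, seq(1L, by = k, length.out = Lout), , drop = FALSE]
    arg <- array(1L, dim(y))
    if (k > 1L) {
      for (j in 2:k) {
        sj <- x[, seq(j, by = k, length.out = Lout), , drop = FALSE]
        better <- sj > y
        y[better] <- sj[better]
        arg[better] <- j
      }
    }
    e$cache <- list(L = L, Lout = Lout, arg = arg, C = C, B = B)
    y
  }
  e$bw <- function(dy) {
    cc <- e$cache
    dx <- array(0, c(cc$C, cc$L, cc$B))
    for (j in seq_len(e$k)) {
      contrib <- dy * (cc$arg == j)
      pos <- seq(j, by = e$k, length.out = cc$Lout)
      dx[, pos, ] <- dx[, pos, , drop = FALSE] + contrib
    }
    dx
  }
  e
}

nn_gap <- function() {
  # global average pooling over the temporal dimension: (C, L, B) -> (C, B)
  e <- new_layer("gap")
  e$fw <- function(x, train = TRUE) {
    d <- dim(x)
    e$cache <- d
    matrix(rowMeans(matrix(aperm(x, c(1, 3, 2)), nrow = d[1] * d[3])),
           nrow = d[1])
  }
  e$bw <- function(dy) {
    d <- e$cache
    aperm(array(rep(dy / d[2], d[2]), c(d[1], d[3], d[2])), c(1, 3, 2))
  }
  e
}

# -- activations -------------------------------------------------------------

nn_relu <- function() {
  e <- new_layer("relu")
  e$fw <- function(x, train = TRUE) {
    e$cache <- x > 0
    x * e$cache
  }
  e$bw <- function(dy) dy * e$cache
  e
}

nn_dropout <- function(p = 0.2) {
  e <- new_layer("dropout")
  e$p <- p
  e$fw <- function(x, train = TRUE) {
    if (!train || e$p <= 0) {
      e$cache <- NULL
      return(x)
    }
    m <- (stats::runif(length(x)) >= e$p) / (1 - e$p)
    dim(m) <- dim(x)
    e$cache <- m
    x * m
  }
  e$bw <- function(dy) if (is.null(e$cache)) dy else dy * e$cache
  e
}

# -- dense layers ------------------------------------------------------------

nn_linear <- function(fin, fout) {
  e <- new_layer("linear")
  e$W <- matrix(stats::rnorm(fout * fin, 0, sqrt(2 / fin)), nrow = fout)
  e$b <- numeric(fout)
  e$g_W <- e$W * 0; e$g_b <- e$b * 0
  e$param_names <- c("W", "b")
  e$fw <- function(x, train = TRUE) {
    e$cache <- x
    e$W %*% x + e$b
  }
  e$bw <- function(dy) {
    e$g_W <- e$g_W + dy %*% t(e$cache)
    e$g_b <- e$g_b + rowSums(dy)
    crossprod(e$W, dy)
  }
  e
}

nn_layernorm <- function(f, eps = 1e-5) {
  # per-sample normalization over features; input (F, B)
  e <- new_layer("layernorm")
  e$gamma <- rep(1, f); e$beta <- numeric(f)
  e$g_gamma <- numeric(f); e$g_beta <- numeric(f)
  e$param_names <- c("gamma", "beta")
  e$eps <- eps
  e$fw <- function(x, train = TRUE) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + e$eps)
    xhat <- sweep(xc, 2, inv, `*`)
    e$cache <- list(xhat = xhat, inv = inv)
    e$gamma * xhat + e$beta
  }
  e$bw <- function(dy) {
    cc <- e$cache
    e$g_gamma <- e$g_gamma + rowSums(dy * cc$xhat)
    e$g_beta <- e$g_beta + rowSums(dy)
    dxhat <- dy * e$gamma
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cc$xhat)
    sweep(dxhat - rep(1, nrow(dy)) %o% m1 -
            sweep(cc$xhat, 2, m2, `*`), 2, cc$inv, `*`)
  }
  e
}

# -- normalization for conv features ----------------------------------------

nn_groupnorm <- function(C, groups = 8L, eps = 1e-5) {
  if (C %% groups != 0L) groups <- max(1L, gcd_groups(C, groups))
  e <- new_layer("groupnorm")
  e$C <- C; e$groups <- as.integer(groups); e$eps <- eps
  e$gamma <- rep(1, C); e$beta <- numeric(C)
  e$g_gamma <- numeric(C); e$g_beta <- numeric(C)
  e$param_names <- c("gamma", "beta")
  e$fw <- function(x, train = TRUE) {
    res <- groupnorm_fw_cpp(x, e$gamma, e$beta, e$groups, e$eps)
    e$cache <- list(xhat = res$xhat, inv = res$inv)
    res$y
  }
  e$bw <- function(dy) {
    cc <- e$cache
    res <- groupnorm_bw_cpp(dy, cc$xhat, cc$inv, e$gamma, e$groups)
    e$g_gamma <- e$g_gamma + as.numeric(res$dgamma)
    e$g_beta <- e$g_beta + as.numeric(res$dbeta)
    res$dx
  }
  e
}

gcd_groups <- function(C, g) {
  while (C %% g != 0L) g <- g - 1L
  g
}

nn_batchnorm_conv <- function(C, eps = 1e-5, momentum = 0.1) {
  # per-channel normalization over (length, batch); tracks running stats
  e <- new_layer("batchnorm_conv")
  e$C <- C; e$eps <- eps; e$momentum <- momentum
  e$gamma <- rep(1, C); e$beta <- numeric(C)
  e$g_gamma <- numeric(C); e$g_beta <- numeric(C)
  e$run_mean <- numeric(C); e$run_var <- rep(1, C)
  e$param_names <- c("gamma", "beta")
  e$fw <- function(x, train = TRUE) {
    d <- dim(x); L <- d[2]; B <- d[3]
    n <- L * B
    if (train) {
      mu <- .rowMeans(x, e$C, n)
      xc <- x - mu                      # per-channel recycling
      v <- .rowMeans(xc * xc, e$C, n)
      e$run_mean <- (1 - e$momentum) * e$run_mean + e$momentum * mu
      e$run_var <- (1 - e$momentum) * e$run_var + e$momentum * v
    } else {
      mu <- e$run_mean
      v <- e$run_var
      xc <- x - mu
    }
    inv <- 1 / sqrt(v + e$eps)
    xhat <- xc * inv
    e$cache <- list(xhat = xhat, inv = inv, train = train, L = L, B = B)
    e$gamma * xhat + e$beta
  }
  e$bw <- function(dy) {
    cc <- e$cache
    n <- cc$L * cc$B
    e$g_gamma <- e$g_gamma + .rowSums(dy * cc$xhat, e$C, n)
    e$g_beta <- e$g_beta + .rowSums(dy, e$C, n)
    dxhat <- dy * e$gamma
    if (cc$train) {
      m1 <- .rowMeans(dxhat, e$C, n)
      m2 <- .rowMeans(dxhat * cc$xhat, e$C, n)
      (dxhat - m1 - cc$xhat * m2) * cc$inv
    } else {
      dxhat * cc$inv
    }
  }
  e
}

nn_batchnorm_dense <- function(f, eps = 1e-5, momentum = 0.1) {
  # per-feature normalization over the batch; input (F, B)
  e <- new_layer("batchnorm_dense")
  e$f <- f; e$eps <- eps; e$momentum <- momentum
  e$gamma <- rep(1, f); e$beta <- numeric(f)
  e$g_gamma <- numeric(f); e$g_beta <- numeric(f)
  e$run_mean <- numeric(f); e$run_var <- rep(1, f)
  e$param_names <- c("gamma", "beta")
  e$fw <- function(x, train = TRUE) {
    if (train && ncol(x) > 1L) {
      mu <- rowMeans(x)
      xc <- x - mu
      v <- rowMeans(xc^2)
      e$run_mean <- (1 - e$momentum) * e$run_mean + e$momentum * mu
      e$run_var <- (1 - e$momentum) * e$run_var + e$momentum * v
      used_batch <- TRUE
    } else {
      xc <- x - e$run_mean
      v <- e$run_var
      used_batch <- FALSE
    }
    inv <- 1 / sqrt(v + e$eps)
    xhat <- xc * inv
    e$cache <- list(xhat = xhat, inv = inv, train = used_batch)
    e$gamma * xhat + e$beta
  }
  e$bw <- function(dy) {
    cc <- e$cache
    e$g_gamma <- e$g_gamma + rowSums(dy * cc$xhat)
    e$g_beta <- e$g_beta + rowSums(dy)
    dxhat <- dy * e$gamma
    if (cc$train) {
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * cc$xhat)
      (dxhat - m1 - cc$xhat * m2) * cc$inv
    } else {
      dxhat * cc$inv
    }
  }
  e
}

# -- resizing ----------------------------------------------------------------

nn_interp <- function() {
  # linear interpolation along the temporal axis to a target length given
  # at forward time; implemented as a cached dense interpolation matrix so
  # the backward pass is its exact transpose
  e <- new_layer("interp")
  e$fw <- function(x, target_len, train = TRUE) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    key <- paste(L, target_len, sep = ">")
    if (is.null(e$A_key) || e$A_key != key) {
      p <- seq(0, L - 1, length.out = target_len)
      i0 <- pmin(floor(p), L - 2)
      w <- p - i0
      A <- matrix(0, nrow = target_len, ncol = L)
      A[cbind(seq_len(target_len), i0 + 1)] <- 1 - w
      A[cbind(seq_len(target_len), i0 + 2)] <-
        A[cbind(seq_len(target_len), i0 + 2)] + w
      e$A <- A
      e$A_key <- key
    }
    xl <- matrix(aperm(x, c(2, 1, 3)), nrow = L)
    y <- e$A %*% xl
    e$cache <- list(C = C, L = L, B = B, T = target_len)
    aperm(array(y, c(target_len, C, B)), c(2, 1, 3))
  }
  e$bw <- function(dy) {
    cc <- e$cache
    dyl <- matrix(aperm(dy, c(2, 1, 3)), nrow = cc$T)
    dxl <- crossprod(e$A, dyl)
    aperm(array(dxl, c(cc$L, cc$C, cc$B)), c(2, 1, 3))
  }
  e
}

# -- squeeze-and-excitation --------------------------------------------------

nn_se_block <- function(C, reduction = 16L) {
  e <- new_layer("se")
  hidden <- max(1L, C %/% reduction)
  e$gap <- nn_gap()
  e$fc1 <- nn_linear(C, hidden)
  e$act <- nn_relu()
  e$fc2 <- nn_linear(hidden, C)
  e$children <- list(e$gap, e$fc1, e$act, e$fc2)
  e$fw <- function(x, train = TRUE) {
    z <- e$gap$fw(x, train)
    g <- 1 / (1 + exp(-e$fc2$fw(e$act$fw(e$fc1$fw(z, train), train), train)))
    d <- dim(x)
    garr <- aperm(array(rep(g, d[2]), c(d[1], d[3], d[2])), c(1, 3, 2))
    e$cache <- list(x = x, g = g, garr = garr, d = d)
    x * garr
  }
  e$bw <- function(dy) {
    cc <- e$cache
    dx1 <- dy * cc$garr
    # gradient wrt the per-channel gate, then through sigmoid and the MLP
    dg <- matrix(rowSums(matrix(aperm(dy * cc$x, c(1, 3, 2)),
                                nrow = cc$d[1] * cc$d[3])), nrow = cc$d[1])
    dpre <- dg * cc$g * (1 - cc$g)
    dz <- e$fc1$bw(e$act$bw(e$fc2$bw(dpre)))
    dx2 <- e$gap$bw(dz)
    dx1 + dx2
  }
  e$gate <- function(x) {
    # expose the gate values (inference helper, used in tests)
    z <- e$gap$fw(x, train = FALSE)
    1 / (1 + exp(-e$fc2$fw(e$act$fw(e$fc1$fw(z, FALSE), FALSE), FALSE)))
  }
  e
}

# -- composite helpers -------------------------------------------------------

nn_sequential <- function(...) {
  e <- new_layer("sequential")
  e$children <- list(...)
  e$fw <- function(x, train = TRUE) {
    for (l in e$children) x <- l$fw(x, train)
    x
  }
  e$bw <- function(dy) {
    for (l in rev(e$children)) dy <- l$bw(dy)
    dy
  }
  e
}

nn_double_conv <- function(cin, cout, gn_groups = 8L) {
  nn_sequential(
    nn_conv1d(cin, cout, 3L), nn_groupnorm(cout, gn_groups), nn_relu(),
    nn_conv1d(cout, cout, 3L), nn_groupnorm(cout, gn_groups), nn_relu()
  )
}

# residual block: two 3x1 convs with BatchNorm/ReLU and a (projected)
# identity shortcut; stride applies to the first conv and the shortcut
nn_res_block <- function(cin, cout, stride = 1L) {
  e <- new_layer("resblock")
  e$conv1 <- nn_conv1d(cin, cout, 3L, stride = stride)
  e$bn1 <- nn_batchnorm_conv(cout)
  e$relu1 <- nn_relu()
  e$conv2 <- nn_conv1d(cout, cout, 3L)
  e$bn2 <- nn_batchnorm_conv(cout)
  e$project <- (stride != 1L || cin != cout)
  if (e$project) {
    e$convs <- nn_conv1d(cin, cout, 1L, stride = stride, pad = 0L)
    e$bns <- nn_batchnorm_conv(cout)
    e$children <- list(e$conv1, e$bn1, e$relu1, e$conv2, e$bn2,
                       e$convs, e$bns)
  } else {
    e$children <- list(e$conv1, e$bn1, e$relu1, e$conv2, e$bn2)
  }
  e$fw <- function(x, train = TRUE) {
    h <- e$relu1$fw(e$bn1$fw(e$conv1$fw(x, train), train), train)
    h2 <- e$bn2$fw(e$conv2$fw(h, train), train)
    s <- if (e$project) e$bns$fw(e$convs$fw(x, train), train) else x
    out <- h2 + s
    e$mask <- out > 0
    out * e$mask
  }
  e$bw <- function(dy) {
    dsum <- dy * e$mask
    dx_main <- e$conv1$bw(e$bn1$bw(e$relu1$bw(e$conv2$bw(e$bn2$bw(dsum)))))
    dx_skip <- if (e$project) e$convs$bw(e$bns$bw(dsum)) else dsum
    dx_main + dx_skip
  }
  e
}

# -- parameter plumbing ------------------------------------------------------

collect_layers <- function(layer) {
  out <- list(layer)
  for (ch in layer$children) out <- c(out, collect_layers(ch))
  out
}

collect_all_layers <- function(layers) {
  out <- list()
  for (l in layers) out <- c(out, collect_layers(l))
  out
}

zero_grads <- function(layers) {
  for (l in collect_all_layers(layers)) {
    for (p in l$param_names) l[[paste0("g_", p)]] <- l[[paste0("g_", p)]] * 0
  }
  invisible(NULL)
}

set_frozen <- function(layers, frozen) {
  for (l in collect_all_layers(layers)) l$frozen <- frozen
  invisible(NULL)
}

n_params <- function(layers) {
  sum(vapply(collect_all_layers(layers), function(l) {
    sum(vapply(l$param_names, function(p) length(l[[p]]), 0))
  }, 0))
}

# Adam with bias correction; optimizer moments live inside the layer envs.
adam_step <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t = 1L) {
  for (l in collect_all_layers(layers)) {
    if (isTRUE(l$frozen)) next
    lr_l <- lr * (l$lr_scale %||% 1)
    for (p in l$param_names) {
      g <- l[[paste0("g_", p)]]
      mslot <- paste0("adam_m_", p)
      vslot <- paste0("adam_v_", p)
      if (is.null(l[[mslot]])) {
        l[[mslot]] <- g * 0
        l[[vslot]] <- g * 0
      }
      l[[mslot]] <- beta1 * l[[mslot]] + (1 - beta1) * g
      l[[vslot]] <- beta2 * l[[vslot]] + (1 - beta2) * g^2
      mhat <- l[[mslot]] / (1 - beta1^t)
      vhat <- l[[vslot]] / (1 - beta2^t)
      l[[p]] <- l[[p]] - lr_l * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

# Serializable snapshot of all parameters, normalization running stats
# included; restore with load_layer_state.
layer_state <- function(layers) {
  lapply(collect_all_layers(layers), function(l) {
    st <- lapply(l$param_names, function(p) l[[p]])
    names(st) <- l$param_names
    if (!is.null(l$run_mean)) {
      st$run_mean <- l$run_mean
      st$run_var <- l$run_var
    }
    st
  })
}

load_layer_state <- function(layers, state) {
  flat <- collect_all_layers(layers)
  if (length(flat) != length(state)) {
    stop("incompatible checkpoint: layer count mismatch", call. = FALSE)
  }
  for (i in seq_along(flat)) {
    l <- flat[[i]]
    for (p in l$param_names) {
      v <- state[[i]][[p]]
      if (length(v) != length(l[[p]])) {
        stop("incompatible checkpoint: parameter shape mismatch",
             call. = FALSE)
      }
      if (is.matrix(l[[p]])) v <- matrix(v, nrow = nrow(l[[p]]))
      l[[p]] <- v
    }
    if (!is.null(state[[i]]$run_mean)) {
      l$run_mean <- state[[i]]$run_mean
      l$run_var <- state[[i]]$run_var
    }
  }
  invisible(NULL)
}

# deep copy of the current parameter values (for best-model selection)
snapshot_params <- function(layers) layer_state(layers)
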