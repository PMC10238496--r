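## ---- minimal 1-D convolutional network engine ------------------------------
##
## Dense activations are stored as C x (L*B) matrices: sample b occupies the
## contiguous column block ((b-1)L+1):(bL).  Convolutions are evaluated tap
## by tap as BLAS matrix products, which keeps the whole forward/backward
## pass inside optimized linear algebra.  Batch normalization keeps running
## moments in an environment attached to the model so that inference is
## deterministic.  Only what the contrastive encoder needs is implemented.

conv_pad_geom <- function(L, K, stride) {
  Lout <- as.integer(ceiling(L / stride))
  pad <- max(0L, (Lout - 1L) * stride + K - L)
  list(Lout = Lout, pad = pad, pl = pad %/% 2L, Lp = L + pad)
}

## convolution = one GEMM against the im2col expansion (built in C++);
## the backward pass rebuilds the expansion from the cached layer input
conv_fwd <- function(X, W, stride, L, B) {
  Cout <- dim(W)[1]; Cin <- dim(W)[2]; K <- dim(W)[3]
  g <- conv_pad_geom(L, K, stride)
  Y <- .conv1d_fwd_cpp(X, matrix(W, Cout, Cin * K), Cin, K, stride,
                       L, B, g$pl, g$Lout)
  list(Y = Y, cache = list(X = X, stride = stride, g = g, L = L, B = B,
                           dimW = dim(W)))
}

conv_bwd <- function(dY, W, cache) {
  Cout <- cache$dimW[1]; Cin <- cache$dimW[2]; K <- cache$dimW[3]
  r <- .conv1d_bwd_cpp(cache$X, matrix(W, Cout, Cin * K), dY, Cin, K,
                       cache$stride, cache$L, cache$B, cache$g$pl,
                       cache$g$Lout)
  list(dX = r$dX, dW = array(r$dW, cache$dimW))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(X, prm, key, bn_env, training) {
  if (training) {
    r <- .bn_fwd_cpp(X, prm$gamma, prm$beta, BN_EPS)
    st <- bn_env[[key]]
    if (is.null(st)) st <- list(rm = numeric(nrow(X)), rv = rep(1, nrow(X)))
    st$rm <- (1 - BN_MOMENTUM) * st$rm + BN_MOMENTUM * as.numeric(r$m)
    st$rv <- (1 - BN_MOMENTUM) * st$rv + BN_MOMENTUM * as.numeric(r$v)
    bn_env[[key]] <- st
    list(Y = r$Y, cache = list(xhat = r$xhat, inv = r$inv,
                               gamma = prm$gamma))
  } else {
    st <- bn_env[[key]]
    if (is.null(st)) st <- list(rm = numeric(nrow(X)), rv = rep(1, nrow(X)))
    inv <- 1 / sqrt(st$rv + BN_EPS)
    list(Y = prm$gamma * ((X - st$rm) * inv) + prm$beta, cache = NULL)
  }
}

bn_bwd <- function(dY, cache) {
  r <- .bn_bwd_cpp(dY, cache$xhat, cache$inv, cache$gamma)
  list(dX = r$dX, dgamma = as.numeric(r$dgamma),
       dbeta = as.numeric(r$dbeta))
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, cache = mask)
}

## ---- parameter initialization ----------------------------------------------

init_conv <- function(Cout, Cin, K) {
  array(rnorm(Cout * Cin * K, sd = sqrt(2 / (Cin * K))), c(Cout, Cin, K))
}

#' @keywords internal
build_arch <- function(config) {
  L <- config$interval_length
  w <- config$width
  blocks <- list()
  cin <- w
  for (b in seq_len(config$n_blocks)) {
    cout <- w * 2L^((b - 1L) %/% config$double_every)
    stride <- if (b %% 2L == 1L && ceiling(L / 2) >= 4) 2L else 1L
    blocks[[b]] <- list(cin = cin, cout = cout, stride = stride, Lin = L)
    L <- as.integer(ceiling(L / stride))
    cin <- cout
  }
  list(blocks = blocks, c_last = cin, L_last = L)
}

init_params <- function(config, arch) {
  K <- config$kernel
  w <- config$width
  ## stem init: within each 101-long quality block the weight starts
  ## constant across positions (a quality-agnostic level extractor, since
  ## a signal's value lands at a different position every second), plus
  ## small noise so training can differentiate by quality index
  stem_W <- matrix(rnorm(w * ENC_INPUT_DIM, sd = 0.1 * sqrt(2 / N_SIGNALS)),
                   w, ENC_INPUT_DIM)
  for (s in seq_len(N_QUALITY)) {
    cols <- ((s - 1L) * QBLOCK + 1L):(s * QBLOCK)
    stem_W[, cols] <- stem_W[, cols] + rnorm(w, sd = sqrt(2 / N_SIGNALS))
  }
  raw_cols <- (N_QUALITY * QBLOCK + 1L):ENC_INPUT_DIM
  stem_W[, raw_cols] <- matrix(rnorm(w * length(raw_cols),
                                     sd = sqrt(2 / N_SIGNALS)),
                               w, length(raw_cols))
  prm <- list(
    stem = list(W = stem_W),
    bn0 = list(gamma = rep(1, w), beta = rep(0, w)),
    blocks = lapply(arch$blocks, function(bl) {
      p <- list(
        W1 = init_conv(bl$cout, bl$cin, K),
        bn1 = list(gamma = rep(1, bl$cout), beta = rep(0, bl$cout)),
        W2 = init_conv(bl$cout, bl$cout, K),
        bn2 = list(gamma = rep(1, bl$cout), beta = rep(0, bl$cout)))
      if (bl$stride != 1L || bl$cin != bl$cout) {
        p$Wp <- init_conv(bl$cout, bl$cin, 1L)
        p$bnp <- list(gamma = rep(1, bl$cout), beta = rep(0, bl$cout))
      }
      p
    }),
    head = list(
      bn = list(gamma = rep(1, arch$c_last), beta = rep(0, arch$c_last)),
      W = matrix(rnorm(config$feature_dim * arch$c_last,
                       sd = sqrt(1 / arch$c_last)),
                 config$feature_dim, arch$c_last),
      ## small nonzero bias keeps projections away from the origin, where
      ## the l2 normalization is undefined
      b = rnorm(config$feature_dim, sd = 0.01)))
  prm
}

## ---- full network forward / backward ---------------------------------------

## X: sparse or dense ENC_INPUT_DIM x (L*B) input.  Returns unit-norm
## feature columns; caches retained only when training.
nn_forward <- function(prm, arch, bn_env, X, B, training = FALSE) {
  L <- arch$blocks[[1]]$Lin
  caches <- if (training) list() else NULL
  A <- as.matrix(prm$stem$W %*% X)
  if (training) caches$X_in <- X
  bn <- bn_fwd(A, prm$bn0, "bn0", bn_env, training)
  r <- relu_fwd(bn$Y)
  if (training) { caches$bn0 <- bn$cache; caches$relu0 <- r$cache }
  A <- r$Y
  for (b in seq_along(arch$blocks)) {
    bl <- arch$blocks[[b]]
    p <- prm$blocks[[b]]
    cc <- list()
    c1 <- conv_fwd(A, p$W1, bl$stride, bl$Lin, B)
    b1 <- bn_fwd(c1$Y, p$bn1, paste0("b", b, ".bn1"), bn_env, training)
    r1 <- relu_fwd(b1$Y)
    c2 <- conv_fwd(r1$Y, p$W2, 1L, c1$cache$g$Lout, B)
    b2 <- bn_fwd(c2$Y, p$bn2, paste0("b", b, ".bn2"), bn_env, training)
    if (!is.null(p$Wp)) {
      cp <- conv_fwd(A, p$Wp, bl$stride, bl$Lin, B)
      bp <- bn_fwd(cp$Y, p$bnp, paste0("b", b, ".bnp"), bn_env, training)
      short <- bp$Y
      if (training) { cc$cp <- cp$cache; cc$bp <- bp$cache }
    } else short <- A
    ro <- relu_fwd(b2$Y + short)
    if (training) {
      cc$c1 <- c1$cache; cc$bn1 <- b1$cache; cc$r1 <- r1$cache
      cc$c2 <- c2$cache; cc$bn2 <- b2$cache; cc$ro <- ro$cache
      caches$blocks[[b]] <- cc
    }
    A <- ro$Y
  }
  ## global average pooling over the temporal axis (time-major columns:
  ## sample index cycles fastest)
  Ll <- arch$L_last
  grp <- rep(seq_len(B), Ll)
  P <- t(rowsum(t(A), grp)) / Ll
  bnh <- bn_fwd(P, prm$head$bn, "head.bn", bn_env, training)
  rh <- relu_fwd(bnh$Y)
  Z <- prm$head$W %*% rh$Y + prm$head$b
  nrm <- sqrt(colSums(Z * Z))
  nrm[nrm == 0] <- 1
  H <- Z / rep(nrm, each = nrow(Z))
  if (training) {
    caches$pool_grp <- grp; caches$Ll <- Ll
    caches$bnh <- bnh$cache; caches$rh_mask <- rh$cache; caches$rh_Y <- rh$Y
    caches$Z <- Z; caches$nrm <- nrm; caches$H <- H
  }
  list(H = H, caches = caches)
}

nn_backward <- function(prm, arch, caches, dH, B) {
  ## through l2 normalization: h = z / |z|
  H <- caches$H; nrm <- caches$nrm
  proj <- colSums(H * dH)
  dZ <- (dH - H * rep(proj, each = nrow(H))) / rep(nrm, each = nrow(H))
  g <- list(head = list(), blocks = vector("list", length(arch$blocks)))
  g$head$W <- dZ %*% t(caches$rh_Y)
  g$head$b <- rowSums(dZ)
  dRh <- t(prm$head$W) %*% dZ
  dBnh <- dRh * caches$rh_mask
  bb <- bn_bwd(dBnh, caches$bnh)
  g$head$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
  dP <- bb$dX
  ## undo pooling
  Ll <- caches$Ll
  dA <- dP[, rep(seq_len(B), Ll), drop = FALSE] / Ll
  for (b in rev(seq_along(arch$blocks))) {
    cc <- caches$blocks[[b]]
    p <- prm$blocks[[b]]
    gb <- list()
    dS <- dA * cc$ro
    b2 <- bn_bwd(dS, cc$bn2)
    gb$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
    c2 <- conv_bwd(b2$dX, p$W2, cc$c2)
    gb$W2 <- c2$dW
    dR1 <- c2$dX * cc$r1
    b1 <- bn_bwd(dR1, cc$bn1)
    gb$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
    c1 <- conv_bwd(b1$dX, p$W1, cc$c1)
    gb$W1 <- c1$dW
    dA_in <- c1$dX
    if (!is.null(p$Wp)) {
      bp <- bn_bwd(dS, cc$bp)
      gb$bnp <- list(gamma = bp$dgamma, beta = bp$dbeta)
      cp <- conv_bwd(bp$dX, p$Wp, cc$cp)
      gb$Wp <- cp$dW
      dA_in <- dA_in + cp$dX
    } else {
      dA_in <- dA_in + dS
    }
    g$blocks[[b]] <- gb
    dA <- dA_in
  }
  dA <- dA * caches$relu0
  bb0 <- bn_bwd(dA, caches$bn0)
  g$bn0 <- list(gamma = bb0$dgamma, beta = bb0$dbeta)
  g$stem <- list(W = as.matrix(bb0$dX %*% Matrix::t(caches$X_in)))
  g
}

## ---- Adam ------------------------------------------------------------------

## Names exempt from weight decay (biases and batch-norm affine terms).
.no_decay <- c("gamma", "beta", "b")

adam_init <- function(params) {
  rec <- function(p) {
    if (is.list(p)) return(lapply(p, rec))
    list(m = p * 0, v = p * 0)   # zero moments with p's exact shape
  }
  lapply(params, rec)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, wd, t,
                      eps = 1e-8) {
  rec <- function(p, g, s, nm) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (k in names(p)) {
        if (is.null(g[[k]])) next
        r <- rec(p[[k]], g[[k]], s[[k]], k)
        out_p[[k]] <- r$p; out_s[[k]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    gg <- g
    if (wd > 0 && !(nm %in% .no_decay)) gg <- gg + wd * p
    m <- beta1 * s$m + (1 - beta1) * gg
    v <- beta2 * s$v + (1 - beta2) * gg * gg
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
  }
  r <- rec(params, grads, state, "")
  list(params = r$p, state = r$s)
}
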