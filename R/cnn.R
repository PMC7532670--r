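# Compact convolutional network for patch-level MSI likelihood estimation.
#
# Architecture ("tinycnn"): conv 5x5 (3 -> 8) + ReLU + 4x4 mean-pool,
# conv 3x3 (8 -> 16) + ReLU + global mean-pool, dense 16 -> 1 logit.
# Forward/backward are im2col matrix products (BLAS); training is mini-batch
# SGD with momentum on binary cross-entropy, each patch inheriting its
# slide's label (the MIL label-inheritance scheme).

# Linear indices extracting all k x k x C receptive fields (stride 1) from an
# H x W x C array stored column-major; rows = output positions (y fastest).
im2col_idx <- function(H, W, C, k) {
  oh <- H - k + 1L; ow <- W - k + 1L
  oy <- rep(seq_len(oh), times = ow)
  ox <- rep(seq_len(ow), each = oh)
  base <- oy + (ox - 1L) * H                      # top-left pixel, channel 1
  offs <- integer(0)
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    offs <- c(offs, (dy - 1L) + (dx - 1L) * H + (c - 1L) * H * W)
  }
  list(idx = outer(base, offs, "+"), oh = oh, ow = ow)
}

tinycnn_arch <- function(input_size) {
  k1 <- 5L; c1 <- 8L; pool1 <- 4L; k2 <- 3L; c2 <- 16L
  o1 <- input_size - k1 + 1L
  if (o1 %% pool1 != 0L) stop_pathomsi("input_size must give conv1 output divisible by 4")
  p1 <- o1 %/% pool1
  o2 <- p1 - k2 + 1L
  if (o2 < 1L) stop_pathomsi("input_size too small for the tinycnn architecture")
  list(input_size = as.integer(input_size), k1 = k1, c1 = c1, pool1 = pool1,
       k2 = k2, c2 = c2, o1 = o1, p1 = p1, o2 = o2,
       im1 = im2col_idx(input_size, input_size, 3L, k1),
       im2 = im2col_idx(p1, p1, c1, k2))
}

tinycnn_init <- function(arch) {
  he <- function(nin, nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
  list(W1 = he(arch$k1^2 * 3, arch$k1^2 * 3, arch$c1), b1 = numeric(arch$c1),
       W2 = he(arch$k2^2 * arch$c1, arch$k2^2 * arch$c1, arch$c2), b2 = numeric(arch$c2),
       Wd = matrix(rnorm(arch$c2, 0, sqrt(2 / arch$c2)), arch$c2, 1), bd = 0)
}

# Forward pass for one image; returns logit and, if wanted, the caches
# needed for backprop.
tinycnn_forward <- function(x, params, arch, keep_cache = FALSE) {
  P1 <- matrix(x[arch$im1$idx], nrow = nrow(arch$im1$idx))
  A1 <- sweep(P1 %*% params$W1, 2, params$b1, "+")
  R1 <- pmax(A1, 0)
  # mean-pool each channel map from o1 x o1 to p1 x p1
  o1 <- arch$o1; p1 <- arch$p1; m <- arch$pool1
  pooled <- array(0, c(p1, p1, arch$c1))
  for (c in seq_len(arch$c1)) {
    mm <- matrix(R1[, c], o1, o1)
    mm <- matrix(colMeans(matrix(mm, nrow = m)), nrow = p1)
    pooled[, , c] <- t(matrix(colMeans(matrix(t(mm), nrow = m)), nrow = p1))
  }
  P2 <- matrix(pooled[arch$im2$idx], nrow = nrow(arch$im2$idx))
  A2 <- sweep(P2 %*% params$W2, 2, params$b2, "+")
  R2 <- pmax(A2, 0)
  feat <- colMeans(R2)
  z <- drop(crossprod(feat, params$Wd)) + params$bd
  if (!keep_cache) return(list(logit = z))
  list(logit = z, P1 = P1, A1 = A1, pooled = pooled, P2 = P2, A2 = A2, feat = feat)
}

# Backprop of dL/dlogit for one image; returns parameter gradients.
tinycnn_backward <- function(dz, cache, params, arch) {
  gWd <- matrix(cache$feat * dz, ncol = 1)
  gbd <- dz
  dfeat <- drop(params$Wd) * dz
  n2 <- arch$o2^2
  dR2 <- matrix(rep(dfeat / n2, each = n2), nrow = n2)
  dA2 <- dR2 * (cache$A2 > 0)
  gW2 <- crossprod(cache$P2, dA2)
  gb2 <- colSums(dA2)
  dP2 <- tcrossprod(dA2, params$W2)
  # scatter dP2 back to the pooled feature map
  dpooled <- array(0, c(arch$p1, arch$p1, arch$c1))
  idx2 <- arch$im2$idx
  for (j in seq_len(ncol(idx2))) {
    dpooled[idx2[, j]] <- dpooled[idx2[, j]] + dP2[, j]
  }
  # mean-pool backward: spread uniformly over each m x m block
  m <- arch$pool1; o1 <- arch$o1
  dR1 <- matrix(0, o1^2, arch$c1)
  for (c in seq_len(arch$c1)) {
    up <- dpooled[, , c][rep(seq_len(arch$p1), each = m), rep(seq_len(arch$p1), each = m)]
    dR1[, c] <- as.vector(up) / (m * m)
  }
  dA1 <- dR1 * (cache$A1 > 0)
  gW1 <- crossprod(cache$P1, dA1)
  gb1 <- colSums(dA1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, Wd = gWd, bd = gbd)
}

# Numerically stable BCE-with-logits and its gradient.
bce_with_logits <- function(z, y) {
  loss <- pmax(z, 0) - y * z + log1p(exp(-abs(z)))
  grad <- 1 / (1 + exp(-z)) - y
  list(loss = loss, grad = grad)
}

sgd_step <- function(params, velocity, grads, lr, momentum) {
  for (nm in names(params)) {
    velocity[[nm]] <- momentum * velocity[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + velocity[[nm]]
  }
  list(params = params, velocity = velocity)
}

zero_like <- function(params) lapply(params, function(p) p * 0)
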