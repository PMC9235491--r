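# Minimal convolutional encoder with manual backpropagation.
#
# The encoder contract is: backbone feature grid -> spatial average pool ->
# linear map to a D-dimensional embedding h. The desk-scale default backbone
# is a stack of 3x3 stride-2 convolution + ReLU blocks (im2col formulation,
# all plain matrix algebra). A projection head (ReLU -> linear D->D -> L2
# normalization) is used only inside the contrastive loss; downstream
# consumers always receive h, never z.
#
# Batches are stored as arrays of dim (H, W, C, B), values in [0,1].

# ---- im2col machinery -------------------------------------------------------

# Linear indices into a zero-padded (Hp, Wp, C) array for every (kernel
# element x output position); rows ordered (ky fastest, kx, c), columns
# (oy fastest, ox). Cached per layer geometry.
conv_indices <- function(H, W, C, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  oh <- (Hp - k) %/% stride + 1L
  ow <- (Wp - k) %/% stride + 1L
  ky <- rep(seq_len(k), times = k * C)
  kx <- rep(rep(seq_len(k), each = k), times = C)
  kc <- rep(seq_len(C), each = k * k)
  oy <- rep(seq_len(oh), times = ow)
  ox <- rep(seq_len(ow), each = oh)
  ry <- outer(ky, (oy - 1L) * stride, `+`)              # (kkC) x (ohow)
  rx <- outer(kx, (ox - 1L) * stride, `+`)
  idx <- ry + (rx - 1L) * Hp + (kc - 1L) * (Hp * Wp)
  list(idx = idx, oh = oh, ow = ow, Hp = Hp, Wp = Wp)
}

pad_batch <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  Xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , ] <- X
  Xp
}

# Forward convolution. W is a (k*k*Cin) x Cout matrix, b length Cout.
conv_forward <- function(X, W, b, stride = 2L, pad = 1L, geom = NULL) {
  d <- dim(X)
  if (is.null(geom)) {
    geom <- conv_indices(d[1], d[2], d[3], k = as.integer(sqrt(nrow(W) / d[3])),
                         stride = stride, pad = pad)
  }
  B <- d[4]
  Xp <- pad_batch(X, pad)
  per <- geom$Hp * geom$Wp * d[3]
  npos <- geom$oh * geom$ow
  big <- rep(as.vector(geom$idx), times = B) +
    rep((seq_len(B) - 1L) * per, each = length(geom$idx))
  col <- matrix(Xp[big], nrow = nrow(geom$idx))       # (kkC) x (npos*B)
  out <- crossprod(col, W)                            # (npos*B) x Cout
  out <- sweep(out, 2L, b, `+`)
  Y <- aperm(array(out, c(geom$oh, geom$ow, B, ncol(W))), c(1, 2, 4, 3))
  list(Y = Y, col = col, geom = geom, in_dim = d)
}

# Backward pass; dY has dim (oh, ow, Cout, B). Returns dX, dW, db.
conv_backward <- function(cache, W, dY, stride = 2L, pad = 1L) {
  geom <- cache$geom; d <- cache$in_dim
  B <- d[4]; npos <- geom$oh * geom$ow
  dmat <- matrix(aperm(dY, c(1, 2, 4, 3)), nrow = npos * B)   # (npos*B) x Cout
  dW <- cache$col %*% dmat
  db <- colSums(dmat)
  dcol <- W %*% t(dmat)                                        # (kkC) x (npos*B)
  per <- geom$Hp * geom$Wp * d[3]
  dXp <- numeric(per * B)
  boff <- rep((seq_len(B) - 1L) * per, each = npos)
  # one kernel element at a time: its target positions are unique, so the
  # scatter-add is a plain indexed addition
  for (r in seq_len(nrow(geom$idx))) {
    ind <- rep(geom$idx[r, ], times = B) + boff
    dXp[ind] <- dXp[ind] + dcol[r, ]
  }
  dXp <- array(dXp, c(geom$Hp, geom$Wp, d[3], B))
  dX <- dXp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- encoder ----------------------------------------------------------------

#' Initialize a convolutional encoder
#'
#' Builds the desk-scale backbone: `length(channels)` blocks of 3x3 stride-2
#' convolution + ReLU, a global average pool over the final feature grid, a
#' linear map to `embedding_dim`, and the projection head used by the
#' contrastive loss. Weights use He-scaled Gaussian initialization drawn from
#' the current RNG state.
#'
#' @param crop_size input image side in pixels; must be divisible by
#'   `2^length(channels)`.
#' @param channels integer vector of per-block output channel counts.
#' @param embedding_dim embedding dimension D (default 128).
#' @return an object of class `ihc_encoder`.
#' @export
init_encoder <- function(crop_size = 32L, channels = c(8L, 16L, 32L, 32L),
                         embedding_dim = 128L) {
  nb <- length(channels)
  if (crop_size %% (2^nb) != 0) {
    stopf("crop_size %d not divisible by 2^%d", crop_size, nb)
  }
  cin <- 3L
  conv <- vector("list", nb)
  bn_stats <- vector("list", nb)
  for (l in seq_len(nb)) {
    fan_in <- 9L * cin
    # each block: conv -> batch norm (gamma/beta trained, running stats kept
    # for deterministic inference) -> ReLU
    conv[[l]] <- list(
      W = matrix(rnorm(fan_in * channels[l], sd = sqrt(2 / fan_in)),
                 nrow = fan_in),
      b = numeric(channels[l]),
      gamma = rep(1, channels[l]),
      beta = numeric(channels[l])
    )
    bn_stats[[l]] <- list(mean = numeric(channels[l]),
                          var = rep(1, channels[l]))
    cin <- channels[l]
  }
  D <- as.integer(embedding_dim)
  clast <- channels[nb]
  params <- list(
    conv = conv,
    fc = list(W = matrix(rnorm(clast * D, sd = sqrt(1 / clast)), nrow = clast),
              b = numeric(D)),
    proj = list(W = matrix(rnorm(D * D, sd = sqrt(1 / D)), nrow = D),
                b = numeric(D))
  )
  structure(
    list(params = params, bn_stats = bn_stats,
         crop_size = as.integer(crop_size),
         channels = as.integer(channels), embedding_dim = D,
         grid = as.integer(crop_size / 2^nb), trained = FALSE,
         loss_history = numeric(0)),
    class = "ihc_encoder"
  )
}

# Batch normalization over (height, width, batch) per channel.
# Training mode normalizes with batch statistics and returns them; inference
# uses the encoder's running statistics, keeping embeddings deterministic.
bn_forward <- function(Y, gamma, beta, stats = NULL, eps = 1e-5) {
  d <- dim(Y)                                  # (oh, ow, C, B)
  M <- matrix(aperm(Y, c(1, 2, 4, 3)), ncol = d[3])   # (oh*ow*B) x C
  if (is.null(stats)) {
    mu <- colMeans(M)
    va <- colMeans(M^2) - mu^2
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  Xh <- (M - rep(mu, each = nrow(M))) / rep(sqrt(va + eps), each = nrow(M))
  Out <- Xh * rep(gamma, each = nrow(M)) + rep(beta, each = nrow(M))
  Yn <- aperm(array(Out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(Y = Yn, Xh = Xh, mu = mu, va = va, eps = eps, dims = d)
}

bn_backward <- function(cache, gamma, dY) {
  d <- cache$dims
  dM <- matrix(aperm(dY, c(1, 2, 4, 3)), ncol = d[3])
  m <- nrow(dM)
  dgamma <- colSums(dM * cache$Xh)
  dbeta <- colSums(dM)
  inv_sd <- 1 / sqrt(cache$va + cache$eps)
  t1 <- dM - rep(dbeta / m, each = m) -
    cache$Xh * rep(dgamma / m, each = m)
  dXm <- t1 * rep(gamma * inv_sd, each = m)
  dX <- aperm(array(dXm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Forward pass to embeddings h. X: (cs, cs, 3, B). Training mode
# (keep_cache = TRUE) normalizes with batch statistics and caches
# intermediates for the backward pass; inference mode uses the running
# statistics so embeddings are deterministic.
encoder_forward <- function(enc, X, keep_cache = FALSE) {
  p <- enc$params
  caches <- if (keep_cache) vector("list", length(p$conv)) else NULL
  A <- X
  for (l in seq_along(p$conv)) {
    cf <- conv_forward(A, p$conv[[l]]$W, p$conv[[l]]$b)
    bn <- bn_forward(cf$Y, p$conv[[l]]$gamma, p$conv[[l]]$beta,
                     stats = if (keep_cache) NULL else enc$bn_stats[[l]])
    mask <- bn$Y > 0
    A <- bn$Y * mask
    if (keep_cache) {
      cf$Y <- NULL
      bn$Y <- NULL
      caches[[l]] <- list(col = cf$col, geom = cf$geom, in_dim = cf$in_dim,
                          mask = mask, bn = bn)
    }
  }
  d <- dim(A)                        # (g, g, Clast, B)
  G <- d[1] * d[2]
  # columns of matrix(A, nrow = G) iterate over (channel, image)
  pooled <- matrix(colMeans(matrix(A, nrow = G)), nrow = d[3])  # Clast x B
  feats <- t(pooled)                                            # B x Clast
  H <- feats %*% p$fc$W + matrix(p$fc$b, nrow(feats), enc$embedding_dim,
                                 byrow = TRUE)
  list(H = H, caches = caches, feats = feats, pool_dim = d)
}

# Backward from dH (B x D) through fc + pool + conv stack.
encoder_backward <- function(enc, fwd, dH) {
  p <- enc$params
  grads <- list(conv = vector("list", length(p$conv)))
  grads$fc <- list(W = t(fwd$feats) %*% dH, b = colSums(dH))
  dfeats <- dH %*% t(p$fc$W)                                   # B x Clast
  d <- fwd$pool_dim
  G <- d[1] * d[2]
  # broadcast pooled gradient back over the grid
  dA <- array(rep(t(dfeats) / G, each = G), d)
  for (l in rev(seq_along(p$conv))) {
    cc <- fwd$caches[[l]]
    dBn <- dA * cc$mask
    bnb <- bn_backward(cc$bn, p$conv[[l]]$gamma, dBn)
    bk <- conv_backward(cc, p$conv[[l]]$W, bnb$dX)
    grads$conv[[l]] <- list(W = bk$dW, b = bk$db,
                            gamma = bnb$dgamma, beta = bnb$dbeta)
    dA <- bk$dX
  }
  grads
}

# Exponential-moving-average update of the running batch-norm statistics
# from a training-mode forward cache.
update_bn_stats <- function(enc, fwd, momentum = 0.1) {
  for (l in seq_along(fwd$caches)) {
    bn <- fwd$caches[[l]]$bn
    enc$bn_stats[[l]]$mean <- (1 - momentum) * enc$bn_stats[[l]]$mean +
      momentum * bn$mu
    enc$bn_stats[[l]]$var <- (1 - momentum) * enc$bn_stats[[l]]$var +
      momentum * bn$va
  }
  enc
}

#' Project embeddings onto the unit sphere
#'
#' The projection head of the contrastive objective: elementwise ReLU, a
#' linear D to D map, then normalization of each row to unit Euclidean length
#' (epsilon-guarded against all-zero rows).
#'
#' @param encoder an `ihc_encoder`.
#' @param H numeric matrix `B x D` of embeddings (a single vector is treated
#'   as one row).
#' @return matrix `B x D` whose rows have norm 1 (tolerance 1e-6).
#' @export
project <- function(encoder, H) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  assert_finite(H, "embeddings")
  U <- pmax(H, 0) %*% encoder$params$proj$W +
    matrix(encoder$params$proj$b, nrow(H), encoder$embedding_dim, byrow = TRUE)
  nrm <- pmax(sqrt(rowSums(U^2)), 1e-12)
  U / nrm
}

# project() with cache + backward, for training.
project_forward <- function(enc, H) {
  R <- pmax(H, 0)
  U <- R %*% enc$params$proj$W +
    matrix(enc$params$proj$b, nrow(H), enc$embedding_dim, byrow = TRUE)
  nrm <- pmax(sqrt(rowSums(U^2)), 1e-12)
  Z <- U / nrm
  list(Z = Z, U = U, nrm = nrm, R = R, relu_mask = H > 0)
}

project_backward <- function(enc, pf, dZ) {
  # z = u / ||u||  =>  du = (dz - z <dz, z>) / ||u||
  dU <- (dZ - pf$Z * rowSums(dZ * pf$Z)) / pf$nrm
  dW <- t(pf$R) %*% dU
  db <- colSums(dU)
  dR <- dU %*% t(enc$params$proj$W)
  dH <- dR * pf$relu_mask
  list(dH = dH, dW = dW, db = db)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = "ANY")
}

# params/grads/state share one nested structure of numeric leaves.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk_leaf <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (i in seq_along(p)) {
        r <- walk_leaf(p[[i]], g[[i]], s[[i]])
        out_p[[i]] <- r$p; out_s[[i]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
  }
  walk_leaf(params, grads, state)
}
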