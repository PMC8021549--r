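# Minimal CNN engine. 1D stages carry activations as (time, batch, channel)
# arrays; the fused 2D stage carries a single-channel (row, col, batch) image.
# Convolutions are lowered to one im2col matrix product per batch so the BLAS
# does the arithmetic. Every op returns a cache sufficient for its backward
# pass. Ties in max-pooling go to the earlier sample; "same" padding follows
# the floor/ceil split used by the major frameworks.

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- conv1d: X (T, N, C) -> (T, N, F), same padding ----
# im2col carries a trailing ones column so the bias add rides the gemm.
conv1d_fwd <- function(X, W, b, k) {
  r <- conv1d_fwd_cpp(X, W, b, k)
  list(out = r$out, cache = list(M = r$M, dims = dim(X), k = k))
}

conv1d_bwd <- function(dY, cache, W) {
  conv1d_bwd_cpp(dY, cache$M, W, cache$k)
}

# ---- conv2d over the fused single-channel image ----
# X (R, Wd, N); kernel kh x kw, stride (kh, 1), same padding along columns.
# Because the row stride equals the kernel height, the patch row-offset acts
# as a kh-way channel split: reshaping (R, Wd, N) to (Wd, Ho*N, kh) turns the
# 2D convolution into a 1D convolution along the columns with kh channels
# (weight rows ordered column-offset-major, matching conv1d). Output
# (Ho*Wo, N, F).
conv2d_reshape_in <- function(X, kh) {
  d <- dim(X); R <- d[1]; Wd <- d[2]; N <- d[3]
  stopifnot(R %% kh == 0L)
  Ho <- R %/% kh
  dim(X) <- c(kh, Ho, Wd, N)
  Xc <- aperm(X, c(3L, 2L, 4L, 1L))
  dim(Xc) <- c(Wd, Ho * N, kh)
  Xc
}

conv2d_fwd <- function(X, W, b, kh, kw) {
  d <- dim(X); R <- d[1]; Wd <- d[2]; N <- d[3]
  Ho <- R %/% kh
  r <- conv1d_fwd(conv2d_reshape_in(X, kh), W, b, kw)
  Y <- r$out                              # (Wd, Ho*N, F)
  dim(Y) <- c(Wd * Ho, N, ncol(W))        # (w, h) collapse is layout-free
  list(out = Y, cache = list(inner = r$cache, dims = d, kh = kh, Ho = Ho))
}

conv2d_bwd <- function(dY, cache, W) {
  d <- cache$dims; R <- d[1]; Wd <- d[2]; N <- d[3]
  kh <- cache$kh; Ho <- cache$Ho
  dim(dY) <- c(Wd, Ho * N, ncol(W))
  r <- conv1d_bwd(dY, cache$inner, W)
  dXc <- r$dX                             # (Wd, Ho*N, kh)
  dim(dXc) <- c(Wd, Ho, N, kh)
  dX <- aperm(dXc, c(4L, 2L, 1L, 3L))
  dim(dX) <- c(R, Wd, N)
  list(dX = dX, dW = r$dW, db = r$db)
}

# ---- elementwise / pooling ----
relu_fwd <- function(X) {
  Y <- relu_fwd_cpp(X)
  list(out = Y, cache = Y)
}
relu_bwd <- function(dY, Y) relu_bwd_cpp(dY, Y)

maxpool1d_fwd <- function(X) {
  stopifnot(dim(X)[1] %% 2L == 0L)
  r <- maxpool1d_fwd_cpp(X)
  list(out = r$out, cache = r$take1)
}
maxpool1d_bwd <- function(dY, take1) maxpool1d_bwd_cpp(dY, take1)

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  keep <- array(stats::runif(length(X)) >= rate, dim(X))
  list(out = X * keep / (1 - rate), cache = list(keep = keep, rate = rate))
}
dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) return(dY)
  dY * cache$keep / (1 - cache$rate)
}

# ---- batch normalization over the channel (last) axis ----
# X any (m-leading) tensor with channels last; reshaped to (m, C) internally.
bn_fwd <- function(X, gamma, beta, run_mean, run_var, train,
                   momentum = 0.99, eps = 1e-3) {
  d <- dim(X); C <- d[length(d)]
  Xm <- X; dim(Xm) <- c(length(X) / C, C)
  if (train) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2L, mu)
    va <- colMeans(xc^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var  <- momentum * run_var + (1 - momentum) * va
  } else {
    mu <- run_mean; va <- run_var
    xc <- sweep(Xm, 2L, mu)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(Y) <- d
  list(out = Y,
       cache = list(xhat = xhat, inv = inv, dims = d, train = train),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dY, cache, gamma) {
  d <- cache$dims; C <- d[length(d)]
  m <- length(dY) / C
  dYm <- dY; dim(dYm) <- c(m, C)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (cache$train) {
    dxhat <- sweep(dYm, 2L, gamma, `*`)
    dX <- sweep(
      dxhat - matrix(colMeans(dxhat), m, C, byrow = TRUE) -
        cache$xhat * matrix(colMeans(dxhat * cache$xhat), m, C, byrow = TRUE),
      2L, cache$inv, `*`)
  } else {
    dX <- sweep(sweep(dYm, 2L, gamma, `*`), 2L, cache$inv, `*`)
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- global average pooling: (T, N, C) -> (N, C) ----
gap_fwd <- function(X) {
  list(out = gap_fwd_cpp(X), cache = dim(X))
}
gap_bwd <- function(dY, d) gap_bwd_cpp(dY, d[1])

# ---- dense: (N, Cin) -> (N, F) ----
dense_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = X)
}
dense_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# ---- fusion: stack per-channel feature rows of two 1D maps into one image --
# A (2T, N, Ca), B (T, N, Cb): A is max-pooled along time to length T, then
# the Ca + Cb feature rows are stacked into a (Ca+Cb, T, N) single-channel
# image, time across columns.
fuse_stack_fwd <- function(A, B) {
  pool <- maxpool1d_fwd(A)
  Ap <- pool$out
  da <- dim(Ap); db_ <- dim(B)
  stopifnot(da[1] == db_[1], da[2] == db_[2])
  R <- da[3] + db_[3]
  img <- array(0, c(R, da[1], da[2]))
  img[seq_len(da[3]), , ] <- aperm(Ap, c(3L, 1L, 2L))
  img[da[3] + seq_len(db_[3]), , ] <- aperm(B, c(3L, 1L, 2L))
  list(out = img, cache = list(pool = pool$cache, da = da, db = db_))
}
fuse_stack_bwd <- function(dImg, cache) {
  da <- cache$da; db_ <- cache$db
  dAp <- aperm(dImg[seq_len(da[3]), , , drop = FALSE], c(2L, 3L, 1L))
  dB <- aperm(dImg[da[3] + seq_len(db_[3]), , , drop = FALSE], c(2L, 3L, 1L))
  dA <- maxpool1d_bwd(dAp, cache$pool)
  list(dA = dA, dB = dB)
}

# ---- heads and losses ----
sigmoid <- function(z) 1 / (1 + exp(-z))

softmax2 <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# y in {0,1}; w per-example weights. Returns mean weighted loss, p(true), and
# the gradient w.r.t. the head's pre-activation outputs.
head_loss <- function(Z, y, w, head) {
  n <- length(y)
  if (head == "sigmoid") {
    p <- as.vector(sigmoid(Z))
    eps <- 1e-12
    loss <- -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
    dZ <- matrix(w * (p - y) / n, ncol = 1L)
  } else {
    P <- softmax2(Z)
    p <- P[, 2L]
    eps <- 1e-12
    picked <- ifelse(y == 1L, P[, 2L], P[, 1L])
    loss <- -mean(w * log(picked + eps))
    Yoh <- cbind(1 - y, y)
    dZ <- (P - Yoh) * (w / n)
  }
  list(loss = loss, p = p, dZ = dZ)
}
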