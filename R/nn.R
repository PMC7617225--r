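# Minimal neural-network layer library used by the VAE-GAN module.
#
# Design: feature maps are stored as dense matrices of shape
# (H*W*N, C) - spatial positions column-major (y fastest) within each
# sample, samples stacked in blocks, channels as columns. Convolutions are
# im2col gathers followed by one BLAS matrix multiplication; transposed
# convolutions are the exact adjoint (scatter). All kernels are 4x4 with
# stride 2 and padding 1, halving/doubling the spatial size - the only
# geometry the VAE-GAN needs. Everything runs on base R + BLAS and is
# fully deterministic given the RNG state.

NN_K <- 4L; NN_S <- 2L; NN_P <- 1L

# Precomputed gather/scatter geometry for one (H, W, N). idx[[dk]] maps
# every output position (per sample) to a row of the zero-padded input for
# kernel offset dk; for a fixed dk the map is injective, which makes the
# scatter in the backward/transposed pass collision-free.
make_conv_geom <- function(H, W, N) {
  k <- NN_K; s <- NN_S; p <- NN_P
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  L <- Ho * Wo
  oy <- rep(seq_len(Ho), Wo); ox <- rep(seq_len(Wo), each = Ho)
  samp_off <- rep((0:(N - 1)) * Hp * Wp, each = L)
  idx <- vector("list", k * k)
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    dk <- ky + (kx - 1L) * k
    iy <- (oy - 1L) * s + ky
    ix <- (ox - 1L) * s + kx
    base <- iy + (ix - 1L) * Hp
    idx[[dk]] <- rep(base, N) + samp_off
  }
  bigidx <- unlist(idx, use.names = FALSE)
  iy <- rep(seq_len(H), W) + p
  ix <- rep(seq_len(W), each = H) + p
  interior <- rep(iy + (ix - 1L) * Hp, N) +
    rep((0:(N - 1)) * Hp * Wp, each = H * W)
  list(H = H, W = W, N = N, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, L = L,
       idx = idx, bigidx = bigidx, interior = interior,
       npad = Hp * Wp * N)
}

nn_pad <- function(X, geom) {
  Xp <- matrix(0, geom$npad, ncol(X))
  Xp[geom$interior, ] <- X
  Xp
}

# (HpWpN, C) -> (L*N, k2*C), columns ordered offset-fastest then channel.
nn_im2col <- function(Xpad, geom) {
  k2 <- NN_K * NN_K
  A <- Xpad[geom$bigidx, , drop = FALSE]
  dim(A) <- c(geom$L * geom$N, k2 * ncol(Xpad))
  A
}

# Adjoint of nn_im2col: scatter-add columns back into a padded map.
nn_col2im <- function(dcols, geom, C) {
  k2 <- NN_K * NN_K
  dXp <- matrix(0, geom$npad, C)
  ch <- (0:(C - 1)) * k2
  for (dk in seq_len(k2)) {
    rows <- geom$idx[[dk]]
    dXp[rows, ] <- dXp[rows, ] + dcols[, dk + ch, drop = FALSE]
  }
  dXp
}

# ---- layers ----------------------------------------------------------------

nn_conv_layer <- function(cin, cout) {
  k2 <- NN_K * NN_K
  sd <- sqrt(2 / (k2 * cin))
  list(kind = "conv", cin = cin, cout = cout,
       W = matrix(stats::rnorm(k2 * cin * cout, 0, sd), k2 * cin, cout),
       b = numeric(cout))
}

nn_deconv_layer <- function(cin, cout) {
  k2 <- NN_K * NN_K
  sd <- sqrt(2 / (k2 * cin))
  list(kind = "deconv", cin = cin, cout = cout,
       W = matrix(stats::rnorm(k2 * cout * cin, 0, sd), k2 * cout, cin),
       b = numeric(cout))
}

nn_dense_layer <- function(fin, fout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / fin)
  list(kind = "dense", W = matrix(stats::rnorm(fin * fout, 0, sd), fin, fout),
       b = numeric(fout))
}

nn_bn_layer <- function(c) {
  list(kind = "bn", gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

conv_f <- function(X, ly, geom) {
  cols <- nn_im2col(nn_pad(X, geom), geom)
  Y <- cols %*% ly$W
  Y <- Y + rep(ly$b, each = nrow(Y))
  list(Y = Y, cache = cols)
}

conv_b <- function(dY, ly, geom, cols) {
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dcols <- tcrossprod(dY, ly$W)
  dXp <- nn_col2im(dcols, geom, ly$cin)
  list(dX = dXp[geom$interior, , drop = FALSE], dW = dW, db = db)
}

# Transposed convolution small -> big; geom is the geometry of the BIG side.
deconv_f <- function(X, ly, geom) {
  cols <- tcrossprod(X, ly$W)        # (Ls*N, k2*cout)
  Yp <- nn_col2im(cols, geom, ly$cout)
  Y <- Yp[geom$interior, , drop = FALSE]
  Y <- Y + rep(ly$b, each = nrow(Y))
  list(Y = Y, cache = X)
}

deconv_b <- function(dY, ly, geom, Xin) {
  dcols <- nn_im2col(nn_pad(dY, geom), geom)  # (Ls*N, k2*cout)
  dX <- dcols %*% ly$W
  dW <- crossprod(dcols, Xin)
  db <- colSums(dY)
  list(dX = dX, dW = dW, db = db)
}

dense_f <- function(X, ly) {
  Y <- X %*% ly$W
  Y <- Y + rep(ly$b, each = nrow(Y))
  list(Y = Y, cache = X)
}

dense_b <- function(dY, ly, Xin) {
  list(dX = tcrossprod(dY, ly$W), dW = crossprod(Xin, dY),
       db = colSums(dY))
}

BN_EPS <- 1e-5
BN_MOM <- 0.9

bn_f <- function(X, ly, train = TRUE) {
  R <- nrow(X)
  if (train) {
    mu <- .colMeans(X, R, ncol(X))
    v <- .colMeans(X * X, R, ncol(X)) - mu^2
    invstd <- 1 / sqrt(v + BN_EPS)
    new_run <- list(mean = BN_MOM * ly$run_mean + (1 - BN_MOM) * mu,
                    var = BN_MOM * ly$run_var + (1 - BN_MOM) * v)
  } else {
    mu <- ly$run_mean
    invstd <- 1 / sqrt(ly$run_var + BN_EPS)
    new_run <- NULL
  }
  xhat <- X * rep(invstd, each = R) - rep(mu * invstd, each = R)
  Y <- xhat * rep(ly$gamma, each = R) + rep(ly$beta, each = R)
  list(Y = Y, cache = list(xhat = xhat, invstd = invstd),
       new_run = new_run)
}

bn_b <- function(dY, ly, cache) {
  R <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- dY * rep(ly$gamma, each = R)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- rep(cache$invstd / R, each = R) *
    (R * dxhat - rep(s1, each = R) - xhat * rep(s2, each = R))
  list(dX = dX, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

relu_f <- function(X) list(Y = pmax(X, 0), cache = X > 0)
relu_b <- function(dY, cache) dY * cache
lrelu_f <- function(X, a = 0.2) {
  pos <- X > 0
  list(Y = X * (a + (1 - a) * pos), cache = pos)
}
lrelu_b <- function(dY, cache, a = 0.2) dY * (a + (1 - a) * cache)

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Reshape between conv layout (L*N, C) and dense layout (N, L*C).
flatten_sp <- function(A, L, N) {
  C <- ncol(A)
  matrix(aperm(array(A, c(L, N, C)), c(2, 1, 3)), N, L * C)
}
unflatten_sp <- function(Xf, L, N) {
  C <- ncol(Xf) / L
  matrix(aperm(array(Xf, c(N, L, C)), c(2, 1, 3)), L * N, C)
}

# ---- Adam ------------------------------------------------------------------

PAR_NAMES <- c("W", "b", "gamma", "beta")

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    st <- list()
    for (p in intersect(PAR_NAMES, names(ly)))
      st[[p]] <- list(m = ly[[p]] * 0, v = ly[[p]] * 0)
    st
  })
}

# grads: list parallel to layers with entries named dW/db/dgamma/dbeta.
adam_step <- function(layers, grads, states, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(states[[i]])) {
      gp <- g[[paste0("d", p)]]
      if (is.null(gp)) next
      st <- states[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * gp
      st$v <- beta2 * st$v + (1 - beta2) * gp * gp
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      states[[i]][[p]] <- st
    }
  }
  list(layers = layers, states = states)
}
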