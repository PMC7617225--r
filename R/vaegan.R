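# VAE-GAN latent representation branch.
#
# A variational autoencoder whose reconstruction is judged both pixel-wise
# and in the feature space of an adversarial discriminator (the "learned
# similarity metric"): the encoder maps a 64x64 patch to a 16-dimensional
# diagonal Gaussian, the generator decodes a latent sample back to an
# image, and a discriminator scores real vs reconstructed patches. Feature
# maps tapped after the discriminator's fourth convolutional layer define
# the similarity term. Architecture facts fixed by design: encoder = 3
# conv layers with batch normalization + dense head emitting (mu, log
# sigma^2); generator = 3 transposed conv layers mirroring the encoder;
# discriminator = 5 conv layers with batch normalization; latent dim 16;
# Adam, learning rate 1e-4.

#' VAE-GAN architecture specification
#'
#' Layer counts, the latent dimension, and the similarity tap are fixed
#' properties of the architecture; kernel geometry (4x4, stride 2) and the
#' channel widths are implementation choices, the latter scaled by
#' \code{width_base} (encoder/generator widths \code{width_base * (1,2,4)},
#' discriminator \code{width_base * (1,2,4,8)} then 1). The default
#' \code{width_base = 16} trains in minutes on one CPU core; 32 doubles
#' every width.
#'
#' @param latent_dim Latent dimensionality (default 16).
#' @param width_base Base channel width (default 16).
#' @param dense_units Width of the two dense layers in the encoder head
#'   and generator stem (default 128).
#' @param input_size Input side length; the conv stack fixes this at 64.
#' @param similarity_tap Discriminator layer whose feature maps define the
#'   learned similarity (default 4 of 5).
#' @return A \code{VAEGANSpec} list.
#' @export
vaegan_spec <- function(latent_dim = 16L, width_base = 16L,
                        dense_units = 128L, input_size = 64L,
                        similarity_tap = 4L) {
  stopifnot(latent_dim >= 1, width_base >= 1, input_size == 64L,
            similarity_tap >= 1, similarity_tap <= 5)
  structure(list(latent_dim = as.integer(latent_dim),
                 width_base = as.integer(width_base),
                 dense_units = as.integer(dense_units),
                 input_size = 64L, enc_conv_layers = 3L,
                 gen_deconv_layers = 3L, disc_conv_layers = 5L,
                 similarity_tap = as.integer(similarity_tap)),
            class = "VAEGANSpec")
}

#' Training configuration
#'
#' The reference schedule is Adam at learning rate 1e-4 for 500 epochs
#' (see \code{\link{reference_train_config}}); the default here is a
#' 20-epoch smoke schedule for desk-scale validation. Loss weights apply
#' to (KL, pixel MSE, discriminator-feature similarity, adversarial
#' generator) terms; the unweighted sum (all 1) is the default reading.
#'
#' @param epochs Training epochs (default 20).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam learning rate for all three modules
#'   (default 1e-4).
#' @param loss_weights Named numeric: \code{kl}, \code{pix}, \code{feat},
#'   \code{gan}. Weights multiply per-sample-summed terms (KL summed over
#'   latent dimensions, pixel and feature errors summed over their
#'   elements), the scaling under which a unit-weight sum is balanced;
#'   weighting batch-mean MSEs instead collapses the posterior.
#' @param seed RNG seed; a seeded run is bit-reproducible on a fixed BLAS.
#' @param augment Apply texture-preserving augmentation (horizontal and
#'   vertical flips plus 90-degree rotations: the 8 dihedral variants).
#' @param checkpoint_every Epoch cadence for checkpoints (0 = off).
#' @param checkpoint_dir Directory for checkpoints.
#' @return A \code{TrainConfig} list.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L,
                         learning_rate = 1e-4,
                         loss_weights = c(kl = 1, pix = 1, feat = 1,
                                          gan = 1),
                         seed = 1L, augment = TRUE, checkpoint_every = 0L,
                         checkpoint_dir = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            all(loss_weights >= 0))
  w <- loss_weights[c("kl", "pix", "feat", "gan")]
  if (any(is.na(w))) stop("loss_weights needs entries kl, pix, feat, gan")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss_weights = w,
                 seed = as.integer(seed), augment = augment,
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir),
            class = "TrainConfig")
}

#' Reference (full-length) training configuration: 500 epochs, lr 1e-4
#'
#' @param ... Overrides passed to \code{\link{train_config}}.
#' @export
reference_train_config <- function(...) {
  train_config(epochs = 500L, ...)
}

get_geom <- function(model, H, N) {
  key <- paste0("g", H, "_", N)
  if (is.null(model$geoms[[key]]))
    model$geoms[[key]] <- make_conv_geom(H, H, N)
  model$geoms[[key]]
}

#' Build a VAE-GAN model with seeded initialization
#'
#' @param spec A \code{\link{vaegan_spec}}.
#' @param seed Integer seed for parameter initialization.
#' @return A model handle (list with \code{enc}, \code{gen}, \code{disc}
#'   layer sets, optimizer state, and the spec).
#' @export
build_vaegan <- function(spec = vaegan_spec(), seed = 1L) {
  stopifnot(inherits(spec, "VAEGANSpec"))
  set.seed(seed)
  w <- spec$width_base
  w1 <- w; w2 <- 2L * w; w3 <- 4L * w; w4 <- 8L * w
  du <- spec$dense_units; L <- spec$latent_dim
  enc <- list(c1 = nn_conv_layer(1L, w1), bn1 = nn_bn_layer(w1),
              c2 = nn_conv_layer(w1, w2), bn2 = nn_bn_layer(w2),
              c3 = nn_conv_layer(w2, w3), bn3 = nn_bn_layer(w3),
              d1 = nn_dense_layer(64L * w3, du),
              d2 = nn_dense_layer(du, du),
              mu = nn_dense_layer(du, L, sd = sqrt(1 / du)),
              lv = nn_dense_layer(du, L, sd = sqrt(1 / du)))
  gen <- list(d1 = nn_dense_layer(L, du), d2 = nn_dense_layer(du, 64L * w3),
              dc1 = nn_deconv_layer(w3, w2), bn1 = nn_bn_layer(w2),
              dc2 = nn_deconv_layer(w2, w1), bn2 = nn_bn_layer(w1),
              dc3 = nn_deconv_layer(w1, 1L))
  disc <- list(c1 = nn_conv_layer(1L, w1), bn1 = nn_bn_layer(w1),
               c2 = nn_conv_layer(w1, w2), bn2 = nn_bn_layer(w2),
               c3 = nn_conv_layer(w2, w3), bn3 = nn_bn_layer(w3),
               c4 = nn_conv_layer(w3, w4), bn4 = nn_bn_layer(w4),
               c5 = nn_conv_layer(w4, 1L))
  structure(list(spec = spec, enc = enc, gen = gen, disc = disc,
                 opt = list(enc = adam_init(enc), gen = adam_init(gen),
                            disc = adam_init(disc)),
                 t = 0L, geoms = new.env(parent = emptyenv())),
            class = "vaegan_model")
}

#' @export
print.vaegan_model <- function(x, ...) {
  np <- function(lys) sum(vapply(lys, function(ly)
    sum(vapply(intersect(PAR_NAMES, names(ly)), function(p)
      length(ly[[p]]), numeric(1))), numeric(1)))
  cat(sprintf(paste0("VAE-GAN: latent %d, width base %d; parameters ",
                     "enc %d / gen %d / disc %d\n"),
              x$spec$latent_dim, x$spec$width_base,
              np(x$enc), np(x$gen), np(x$disc)))
  invisible(x)
}

apply_runs <- function(layers, runs) {
  for (nm in names(runs)) {
    layers[[nm]]$run_mean <- runs[[nm]]$mean
    layers[[nm]]$run_var <- runs[[nm]]$var
  }
  layers
}

# ---- module forward/backward ----------------------------------------------

enc_forward <- function(model, X, N, train = TRUE) {
  e <- model$enc
  g64 <- get_geom(model, 64L, N); g32 <- get_geom(model, 32L, N)
  g16 <- get_geom(model, 16L, N)
  ca <- list(); runs <- list()
  o <- conv_f(X, e$c1, g64); ca$c1 <- o$cache
  b <- bn_f(o$Y, e$bn1, train); ca$bn1 <- b$cache; runs$bn1 <- b$new_run
  r <- relu_f(b$Y); ca$r1 <- r$cache
  o <- conv_f(r$Y, e$c2, g32); ca$c2 <- o$cache
  b <- bn_f(o$Y, e$bn2, train); ca$bn2 <- b$cache; runs$bn2 <- b$new_run
  r <- relu_f(b$Y); ca$r2 <- r$cache
  o <- conv_f(r$Y, e$c3, g16); ca$c3 <- o$cache
  b <- bn_f(o$Y, e$bn3, train); ca$bn3 <- b$cache; runs$bn3 <- b$new_run
  r <- relu_f(b$Y); ca$r3 <- r$cache
  f <- flatten_sp(r$Y, 64L, N)
  o <- dense_f(f, e$d1); ca$d1 <- o$cache
  r <- relu_f(o$Y); ca$rd1 <- r$cache
  o <- dense_f(r$Y, e$d2); ca$d2 <- o$cache
  r <- relu_f(o$Y); ca$rd2 <- r$cache
  mu <- dense_f(r$Y, e$mu); ca$mu <- mu$cache
  lv <- dense_f(r$Y, e$lv); ca$lv <- lv$cache
  list(mu = mu$Y, lv = lv$Y, ca = ca, runs = runs)
}

enc_backward <- function(model, dmu, dlv, ca, N) {
  e <- model$enc
  g64 <- get_geom(model, 64L, N); g32 <- get_geom(model, 32L, N)
  g16 <- get_geom(model, 16L, N)
  gr <- list()
  bmu <- dense_b(dmu, e$mu, ca$mu); gr$mu <- bmu
  blv <- dense_b(dlv, e$lv, ca$lv); gr$lv <- blv
  d <- relu_b(bmu$dX + blv$dX, ca$rd2)
  b2 <- dense_b(d, e$d2, ca$d2); gr$d2 <- b2
  d <- relu_b(b2$dX, ca$rd1)
  b1 <- dense_b(d, e$d1, ca$d1); gr$d1 <- b1
  d <- unflatten_sp(b1$dX, 64L, N)
  d <- relu_b(d, ca$r3)
  bb <- bn_b(d, e$bn3, ca$bn3); gr$bn3 <- bb
  bc <- conv_b(bb$dX, e$c3, g16, ca$c3); gr$c3 <- bc
  d <- relu_b(bc$dX, ca$r2)
  bb <- bn_b(d, e$bn2, ca$bn2); gr$bn2 <- bb
  bc <- conv_b(bb$dX, e$c2, g32, ca$c2); gr$c2 <- bc
  d <- relu_b(bc$dX, ca$r1)
  bb <- bn_b(d, e$bn1, ca$bn1); gr$bn1 <- bb
  bc <- conv_b(bb$dX, e$c1, g64, ca$c1); gr$c1 <- bc
  gr
}

gen_forward <- function(model, Z, N, train = TRUE) {
  g <- model$gen
  g64 <- get_geom(model, 64L, N); g32 <- get_geom(model, 32L, N)
  g16 <- get_geom(model, 16L, N)
  ca <- list(); runs <- list()
  o <- dense_f(Z, g$d1); ca$d1 <- o$cache
  r <- relu_f(o$Y); ca$rd1 <- r$cache
  o <- dense_f(r$Y, g$d2); ca$d2 <- o$cache
  r <- relu_f(o$Y); ca$rd2 <- r$cache
  h <- unflatten_sp(r$Y, 64L, N)
  o <- deconv_f(h, g$dc1, g16); ca$dc1 <- o$cache
  b <- bn_f(o$Y, g$bn1, train); ca$bn1 <- b$cache; runs$bn1 <- b$new_run
  r <- relu_f(b$Y); ca$r1 <- r$cache
  o <- deconv_f(r$Y, g$dc2, g32); ca$dc2 <- o$cache
  b <- bn_f(o$Y, g$bn2, train); ca$bn2 <- b$cache; runs$bn2 <- b$new_run
  r <- relu_f(b$Y); ca$r2 <- r$cache
  o <- deconv_f(r$Y, g$dc3, g64); ca$dc3 <- o$cache
  xr <- sigmoid(o$Y); ca$sig <- xr
  list(xr = xr, ca = ca, runs = runs)
}

gen_backward <- function(model, dxr, ca, N) {
  g <- model$gen
  g64 <- get_geom(model, 64L, N); g32 <- get_geom(model, 32L, N)
  g16 <- get_geom(model, 16L, N)
  gr <- list()
  d <- dxr * ca$sig * (1 - ca$sig)
  b <- deconv_b(d, g$dc3, g64, ca$dc3); gr$dc3 <- b
  d <- relu_b(b$dX, ca$r2)
  bb <- bn_b(d, g$bn2, ca$bn2); gr$bn2 <- bb
  b <- deconv_b(bb$dX, g$dc2, g32, ca$dc2); gr$dc2 <- b
  d <- relu_b(b$dX, ca$r1)
  bb <- bn_b(d, g$bn1, ca$bn1); gr$bn1 <- bb
  b <- deconv_b(bb$dX, g$dc1, g16, ca$dc1); gr$dc1 <- b
  d <- flatten_sp(b$dX, 64L, N)
  d <- relu_b(d, ca$rd2)
  b2 <- dense_b(d, g$d2, ca$d2); gr$d2 <- b2
  d <- relu_b(b2$dX, ca$rd1)
  b1 <- dense_b(d, g$d1, ca$d1); gr$d1 <- b1
  list(grads = gr, dZ = b1$dX)
}

disc_forward <- function(model, X, N, train = TRUE) {
  ds <- model$disc
  g64 <- get_geom(model, 64L, N); g32 <- get_geom(model, 32L, N)
  g16 <- get_geom(model, 16L, N); g8 <- get_geom(model, 8L, N)
  g4 <- get_geom(model, 4L, N)
  ca <- list(); runs <- list()
  o <- conv_f(X, ds$c1, g64); ca$c1 <- o$cache
  b <- bn_f(o$Y, ds$bn1, train); ca$bn1 <- b$cache; runs$bn1 <- b$new_run
  r <- lrelu_f(b$Y); ca$r1 <- r$cache
  o <- conv_f(r$Y, ds$c2, g32); ca$c2 <- o$cache
  b <- bn_f(o$Y, ds$bn2, train); ca$bn2 <- b$cache; runs$bn2 <- b$new_run
  r <- lrelu_f(b$Y); ca$r2 <- r$cache
  o <- conv_f(r$Y, ds$c3, g16); ca$c3 <- o$cache
  b <- bn_f(o$Y, ds$bn3, train); ca$bn3 <- b$cache; runs$bn3 <- b$new_run
  r <- lrelu_f(b$Y); ca$r3 <- r$cache
  o <- conv_f(r$Y, ds$c4, g8); ca$c4 <- o$cache
  b <- bn_f(o$Y, ds$bn4, train); ca$bn4 <- b$cache; runs$bn4 <- b$new_run
  r <- lrelu_f(b$Y); ca$r4 <- r$cache
  feat <- r$Y                      # tap: after 4th conv layer, (16N, w4)
  o <- conv_f(feat, ds$c5, g4); ca$c5 <- o$cache
  logit <- colMeans(matrix(o$Y, 4L, N))
  list(logit = logit, feat = feat, ca = ca, runs = runs)
}

disc_backward <- function(model, dlogit, dfeat, ca, N) {
  ds <- model$disc
  g64 <- get_geom(model, 64L, N); g32 <- get_geom(model, 32L, N)
  g16 <- get_geom(model, 16L, N); g8 <- get_geom(model, 8L, N)
  g4 <- get_geom(model, 4L, N)
  gr <- list()
  dY5 <- matrix(rep(dlogit / 4, each = 4L), ncol = 1L)
  b <- conv_b(dY5, ds$c5, g4, ca$c5); gr$c5 <- b
  d <- b$dX
  if (!is.null(dfeat)) d <- d + dfeat
  d <- lrelu_b(d, ca$r4)
  bb <- bn_b(d, ds$bn4, ca$bn4); gr$bn4 <- bb
  b <- conv_b(bb$dX, ds$c4, g8, ca$c4); gr$c4 <- b
  d <- lrelu_b(b$dX, ca$r3)
  bb <- bn_b(d, ds$bn3, ca$bn3); gr$bn3 <- bb
  b <- conv_b(bb$dX, ds$c3, g16, ca$c3); gr$c3 <- b
  d <- lrelu_b(b$dX, ca$r2)
  bb <- bn_b(d, ds$bn2, ca$bn2); gr$bn2 <- bb
  b <- conv_b(bb$dX, ds$c2, g32, ca$c2); gr$c2 <- b
  d <- lrelu_b(b$dX, ca$r1)
  bb <- bn_b(d, ds$bn1, ca$bn1); gr$bn1 <- bb
  b <- conv_b(bb$dX, ds$c1, g64, ca$c1); gr$c1 <- b
  list(grads = gr, dX = b$dX)
}

# ---- losses ----------------------------------------------------------------

#' Closed-form KL divergence of diagonal Gaussians from the unit Gaussian
#'
#' \eqn{KL(N(\mu, \sigma^2) || N(0, I)) = \frac12 \sum_d (\mu_d^2 +
#' \sigma_d^2 - \log \sigma_d^2 - 1)}, averaged over the batch (rows).
#'
#' @param mu Matrix of means (batch x latent_dim).
#' @param lv Matrix of log-variances, same shape.
#' @return Scalar mean KL.
#' @export
kl_gaussian <- function(mu, lv) {
  mean(0.5 * rowSums(mu^2 + exp(lv) - lv - 1))
}

# Stack a list of size x size patches into the (size^2 * N, 1) conv layout.
patches_to_batch <- function(patches) {
  matrix(unlist(lapply(patches, as.vector), use.names = FALSE), ncol = 1L)
}

#' Compute the five VAE-GAN loss terms on a batch of patches
#'
#' Evaluation is deterministic: batch-norm uses running statistics and the
#' latent sample defaults to the mean (\code{eps = 0}). Terms: \code{kl}
#' (closed-form divergence of the encoder posterior from the unit
#' Gaussian), \code{pixel_mse} (input vs reconstruction), \code{feature_similarity}
#' (MSE between discriminator tap-layer feature maps of input and
#' reconstruction), and the non-saturating adversarial losses
#' \code{gan_gen}, \code{gan_disc}.
#'
#' @param model A \code{\link{build_vaegan}} handle.
#' @param patches List of 64x64 matrices in \code{[0, 1]}.
#' @param eps Optional latent noise matrix (batch x latent_dim).
#' @return Named numeric vector of the five terms.
#' @export
vaegan_loss_terms <- function(model, patches, eps = NULL) {
  stopifnot(length(patches) >= 1)
  N <- length(patches)
  X <- patches_to_batch(patches)
  ef <- enc_forward(model, X, N, train = FALSE)
  if (is.null(eps)) eps <- matrix(0, N, model$spec$latent_dim)
  Z <- ef$mu + exp(0.5 * ef$lv) * eps
  gf <- gen_forward(model, Z, N, train = FALSE)
  dr <- disc_forward(model, X, N, train = FALSE)
  df <- disc_forward(model, gf$xr, N, train = FALSE)
  out <- c(kl = kl_gaussian(ef$mu, ef$lv),
           pixel_mse = mean((gf$xr - X)^2),
           feature_similarity = mean((df$feat - dr$feat)^2),
           gan_gen = mean(softplus(-df$logit)),
           gan_disc = mean(softplus(-dr$logit)) +
             mean(softplus(df$logit)))
  if (any(!is.finite(out)))
    stop("non-finite loss term(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

# The 8 dihedral variants of a square matrix (identity, rotations, flips).
dihedral_variants <- function(m) {
  r90 <- function(x) t(x[nrow(x):1, , drop = FALSE])
  m90 <- r90(m); m180 <- r90(m90); m270 <- r90(m180)
  list(m, m90, m180, m270,
       m[nrow(m):1, ], m90[nrow(m90):1, ],
       m180[nrow(m180):1, ], m270[nrow(m270):1, ])
}

# One discriminator update + one encoder/generator update on a batch.
# Returns the updated model and the batch's loss terms.
vaegan_train_step <- function(model, X, N) {
  w <- model$cfg_w; lr <- model$cfg_lr
  Ld <- model$spec$latent_dim

  # --- discriminator step (fake = reconstruction, no enc/gen updates)
  ef <- enc_forward(model, X, N, train = TRUE)
  eps <- matrix(stats::rnorm(N * Ld), N, Ld)
  Z <- ef$mu + exp(0.5 * ef$lv) * eps
  gf <- gen_forward(model, Z, N, train = TRUE)
  dr <- disc_forward(model, X, N, train = TRUE)    # real: update run stats
  model$disc <- apply_runs(model$disc, dr$runs)
  dfk <- disc_forward(model, gf$xr, N, train = TRUE)
  loss_disc <- mean(softplus(-dr$logit)) + mean(softplus(dfk$logit))
  br <- disc_backward(model, -sigmoid(-dr$logit) / N, NULL, dr$ca, N)
  bf <- disc_backward(model, sigmoid(dfk$logit) / N, NULL, dfk$ca, N)
  gd <- mapply(function(a, b) {
    if (is.null(a)) return(b)
    for (nm in names(a)) if (nm != "dX" && !is.null(b[[nm]]))
      a[[nm]] <- a[[nm]] + b[[nm]]
    a
  }, br$grads, bf$grads, SIMPLIFY = FALSE)
  model$t <- model$t + 1L
  up <- adam_step(model$disc, gd[names(model$disc)], model$opt$disc,
                  lr, model$t)
  model$disc <- up$layers; model$opt$disc <- up$states

  # --- encoder/generator step (discriminator frozen)
  ef <- enc_forward(model, X, N, train = TRUE)
  model$enc <- apply_runs(model$enc, ef$runs)
  eps <- matrix(stats::rnorm(N * Ld), N, Ld)
  sd_ <- exp(0.5 * ef$lv)
  Z <- ef$mu + sd_ * eps
  gf <- gen_forward(model, Z, N, train = TRUE)
  model$gen <- apply_runs(model$gen, gf$runs)
  drx <- disc_forward(model, X, N, train = TRUE)
  dfr <- disc_forward(model, gf$xr, N, train = TRUE)

  kl <- kl_gaussian(ef$mu, ef$lv)
  pix <- mean((gf$xr - X)^2)
  feat <- mean((dfr$feat - drx$feat)^2)
  gang <- mean(softplus(-dfr$logit))

  # reconstruction terms enter the objective as per-sample sums (matching
  # the per-sample-summed KL); reported history keeps interpretable means
  dxr_pix <- 2 * (gf$xr - X) * (w["pix"] / N)
  dfeat <- 2 * (dfr$feat - drx$feat) * (w["feat"] / N)
  dlogit <- -sigmoid(-dfr$logit) * (w["gan"] / N)
  bd <- disc_backward(model, dlogit, dfeat, dfr$ca, N)
  gb <- gen_backward(model, dxr_pix + bd$dX, gf$ca, N)
  dZ <- gb$dZ
  dmu <- dZ + w["kl"] * ef$mu / N
  dlv <- dZ * eps * 0.5 * sd_ + w["kl"] * 0.5 * (exp(ef$lv) - 1) / N
  ge <- enc_backward(model, dmu, dlv, ef$ca, N)

  up <- adam_step(model$gen, gb$grads[names(model$gen)], model$opt$gen,
                  lr, model$t)
  model$gen <- up$layers; model$opt$gen <- up$states
  up <- adam_step(model$enc, ge[names(model$enc)], model$opt$enc,
                  lr, model$t)
  model$enc <- up$layers; model$opt$enc <- up$states

  list(model = model,
       losses = c(kl = kl, pixel_mse = pix, feature_similarity = feat,
                  gan_gen = gang, gan_disc = loss_disc))
}

#' Train a VAE-GAN on a bank of 64x64 patches
#'
#' Alternates one discriminator update and one encoder/generator update
#' per minibatch. The generator-side objective is the unweighted (by
#' default) sum of KL, pixel MSE, discriminator-feature similarity and the
#' non-saturating adversarial term. Runs are reproducible given
#' \code{cfg$seed} on a fixed BLAS.
#'
#' @param model A \code{\link{build_vaegan}} handle.
#' @param patches List of 64x64 matrices in \code{[0, 1]} (a
#'   \code{PatchBank} works).
#' @param cfg A \code{\link{train_config}}.
#' @return List with the trained \code{model} and \code{history}, a data
#'   frame of per-epoch means of the five loss terms.
#' @export
train_vaegan <- function(model, patches, cfg = train_config()) {
  stopifnot(inherits(model, "vaegan_model"), inherits(cfg, "TrainConfig"))
  pts <- unname(patches)
  if (cfg$augment)
    pts <- unlist(lapply(pts, dihedral_variants), recursive = FALSE)
  n <- length(pts)
  if (n < 2L * cfg$batch_size)
    stop("need at least 2 * batch_size = ", 2L * cfg$batch_size,
         " patches after augmentation; got ", n)
  set.seed(cfg$seed)
  model$cfg_w <- cfg$loss_weights
  model$cfg_lr <- cfg$learning_rate
  N <- cfg$batch_size
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    nb <- n %/% N
    acc <- numeric(5)
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1L) * N + 1L):(bi * N)]
      X <- patches_to_batch(pts[sel])
      st <- vaegan_train_step(model, X, N)
      model <- st$model
      if (any(!is.finite(st$losses)))
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", batch ", bi, ": ",
             paste(sprintf("%s=%.3g", names(st$losses), st$losses),
                   collapse = ", "))
      acc <- acc + st$losses
    }
    hist[[ep]] <- c(epoch = ep, st$losses * 0 + acc / nb)
    if (cfg$checkpoint_every > 0 && !is.null(cfg$checkpoint_dir) &&
        ep %% cfg$checkpoint_every == 0L) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(model, file.path(cfg$checkpoint_dir,
                               sprintf("vaegan_epoch%04d.rds", ep)))
    }
  }
  history <- as.data.frame(do.call(rbind, hist))
  names(history) <- c("epoch", "kl", "pixel_mse", "feature_similarity",
                      "gan_gen", "gan_disc")
  list(model = model, history = history)
}

#' Deterministic latent codes for a bank of patches
#'
#' Uses the posterior mean (no sampling) and running batch-norm
#' statistics, so identical inputs always yield identical codes.
#'
#' @param model A trained (or freshly built) \code{vaegan_model}.
#' @param patches Named list of 64x64 matrices; names become cell IDs.
#' @return \code{LatentTable} data frame: \code{cell_id}, \code{mu_1..d},
#'   \code{logvar_1..d}.
#' @export
encode_table <- function(model, patches) {
  stopifnot(inherits(model, "vaegan_model"), length(patches) >= 1)
  sz <- model$spec$input_size
  bad <- which(!vapply(patches, function(p)
    all(dim(p) == c(sz, sz)), logical(1)))
  if (length(bad)) stop("patch size mismatch (expected ", sz, "x", sz,
                        ") at index ", bad[1])
  ids <- names(patches)
  if (is.null(ids)) ids <- as.character(seq_along(patches))
  N <- length(patches)
  X <- patches_to_batch(patches)
  ef <- enc_forward(model, X, N, train = FALSE)
  d <- model$spec$latent_dim
  out <- data.frame(cell_id = ids, ef$mu, ef$lv)
  names(out) <- c("cell_id", paste0("mu_", seq_len(d)),
                  paste0("logvar_", seq_len(d)))
  class(out) <- c("LatentTable", "data.frame")
  out
}
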