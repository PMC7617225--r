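tiny_spec <- function() vaegan_spec(width_base = 4L, dense_units = 32L)

test_that("model building is seed-deterministic and shapes are contractual", {
  m1 <- build_vaegan(tiny_spec(), seed = 3)
  m2 <- build_vaegan(tiny_spec(), seed = 3)
  m3 <- build_vaegan(tiny_spec(), seed = 4)
  expect_identical(m1$enc, m2$enc)
  expect_identical(m1$disc, m2$disc)
  expect_false(identical(m1$enc$c1$W, m3$enc$c1$W))

  set.seed(1)
  patches <- replicate(3, matrix(runif(64 * 64), 64, 64),
                       simplify = FALSE)
  lt <- encode_table(m1, patches)
  expect_identical(nrow(lt), 3L)
  expect_length(grep("^mu_", names(lt)), 16L)
  expect_length(grep("^logvar_", names(lt)), 16L)
  expect_true(all(is.finite(as.matrix(lt[, -1]))))
})

test_that("encoding is deterministic and the generator output lies in [0,1]", {
  m <- build_vaegan(tiny_spec(), seed = 7)
  set.seed(2)
  patches <- replicate(4, matrix(runif(64 * 64), 64, 64),
                       simplify = FALSE)
  l1 <- encode_table(m, patches)
  l2 <- encode_table(m, patches)
  expect_identical(l1, l2)
  expect_error(encode_table(m, list(matrix(0, 32, 32))), "mismatch")

  # decode a batch of latent vectors through the generator head
  ns <- asNamespace("h2axprofiler")
  Z <- matrix(rnorm(5 * 16), 5, 16)
  xr <- ns$gen_forward(m, Z, 5L, train = FALSE)$xr
  expect_gte(min(xr), 0); expect_lte(max(xr), 1)
})

test_that("the KL term matches a per-dimension scalar-loop oracle", {
  expect_equal(kl_gaussian(matrix(0, 3, 16), matrix(0, 3, 16)), 0)
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(1:8, 1); d <- sample(1:16, 1)
    mu <- matrix(rnorm(n * d), n, d)
    lv <- matrix(rnorm(n * d, 0, 1.5), n, d)
    acc <- 0
    for (i in 1:n) for (j in 1:d)
      acc <- acc + 0.5 * (mu[i, j]^2 + exp(lv[i, j]) - lv[i, j] - 1)
    expect_equal(kl_gaussian(mu, lv), acc / n, tolerance = 1e-6)
  }
})

test_that("loss terms are finite and reference config keeps 500 epochs", {
  m <- build_vaegan(tiny_spec(), seed = 5)
  set.seed(3)
  patches <- replicate(4, matrix(runif(64 * 64), 64, 64),
                       simplify = FALSE)
  lt <- vaegan_loss_terms(m, patches)
  expect_named(lt, c("kl", "pixel_mse", "feature_similarity", "gan_gen",
                     "gan_disc"))
  expect_true(all(is.finite(lt)))
  expect_gte(lt[["pixel_mse"]], 0)
  expect_gte(lt[["feature_similarity"]], 0)

  expect_identical(reference_train_config()$epochs, 500L)
  expect_identical(train_config()$epochs, 20L)
  expect_equal(train_config()$learning_rate, 1e-4)
})

test_that("short training runs are reproducible and log one row per epoch", {
  b <- two_class_bank(12, seed = 9)   # 24 patches
  cfg <- train_config(epochs = 2, batch_size = 8, augment = FALSE,
                      seed = 31)
  t1 <- train_vaegan(build_vaegan(tiny_spec(), seed = 31), b$patches, cfg)
  t2 <- train_vaegan(build_vaegan(tiny_spec(), seed = 31), b$patches, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(nrow(t1$history), 2L)
  expect_identical(names(t1$history),
                   c("epoch", "kl", "pixel_mse", "feature_similarity",
                     "gan_gen", "gan_disc"))
  expect_true(all(is.finite(as.matrix(t1$history))))

  cfg1 <- train_config(epochs = 1, batch_size = 8, augment = FALSE,
                       seed = 1)
  h1 <- train_vaegan(build_vaegan(tiny_spec(), seed = 1), b$patches,
                     cfg1)$history
  expect_identical(nrow(h1), 1L)

  expect_error(train_vaegan(build_vaegan(tiny_spec(), seed = 1),
                            b$patches[1:4],
                            train_config(batch_size = 8,
                                         augment = FALSE)),
               "at least 2 \\* batch_size")
})

test_that("augmentation produces the 8 dihedral variants", {
  ns <- asNamespace("h2axprofiler")
  m <- matrix(1:9, 3, 3)
  v <- ns$dihedral_variants(m)
  expect_length(unique(lapply(v, as.vector)), 8L)
  expect_true(all(vapply(v, function(x) setequal(x, 1:9), logical(1))))
})
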