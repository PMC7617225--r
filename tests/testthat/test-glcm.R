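test_that("quantization maps boundaries correctly and preserves order", {
  expect_identical(quantize_gray(matrix(0), 32), matrix(0L))
  expect_identical(quantize_gray(matrix(1), 32), matrix(31L))
  expect_identical(quantize_gray(matrix(0.5), 32), matrix(16L))
  set.seed(2)
  v <- matrix(runif(2e4), ncol = 2)
  q <- quantize_gray(v, 32)
  ord <- v[, 1] <= v[, 2]
  expect_true(all(q[ord, 1] <= q[ord, 2]))
  expect_true(all(q[!ord, 1] >= q[!ord, 2]))
  expect_error(quantize_gray(matrix(1.2), 32), "\\[0, 1\\]")
})

test_that("the 2x2 horizontal-pair example matches hand enumeration", {
  q <- matrix(c(0L, 0L, 1L, 1L), 2, 2)  # rows [[0,1],[0,1]]
  cfg <- glcm_config(n_levels = 2, angles = 0)
  p <- glcm_cooccurrence(q, cfg)
  expect_equal(p, matrix(c(0, 0.5, 0.5, 0), 2, 2), ignore_attr = TRUE)
  f <- glcm_features(p)
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["contrast"]), 1)
})

test_that("constant images give the degenerate feature vector", {
  q <- quantize_gray(matrix(0.4, 16, 16), 8)
  p <- glcm_cooccurrence(q, glcm_config(n_levels = 8))
  expect_equal(sum(p), 1)
  expect_equal(p[q[1] + 1, q[1] + 1], 1)
  f <- glcm_features(p)
  expect_equal(unname(f), c(1, 0, 0, 1))
})

test_that("background exclusion zeroes level-0 pairs before normalizing", {
  q <- matrix(c(1L, 0L, 2L, 0L), 2, 2)   # rows [[1,2],[0,0]]
  cfg <- glcm_config(n_levels = 3, angles = 0, exclude_background = TRUE)
  p <- glcm_cooccurrence(q, cfg)
  # only the (1,2) horizontal pair survives, symmetrized
  expect_equal(p[2, 3], 0.5)
  expect_equal(p[3, 2], 0.5)
  expect_equal(sum(p[1, ]) + sum(p[, 1]), 0)
  # a patch whose every pair touches background has no counts left
  q0 <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  expect_error(glcm_cooccurrence(q0, glcm_config(n_levels = 2, angles = 0,
                                                 exclude_background = TRUE)),
               "too small")
})

test_that("co-occurrence matrices are symmetric, normalized, and need room", {
  set.seed(5)
  q <- quantize_gray(matrix(runif(400), 20, 20), 16)
  p <- glcm_cooccurrence(q, glcm_config(n_levels = 16))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_identical(p, t(p))
  expect_error(glcm_cooccurrence(matrix(0L, 1, 1), glcm_config()),
               "too small")
  expect_error(glcm_features(p * 2), "normalized")
})

test_that("features agree with the double-loop oracle on random matrices", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:32, 1)
    p <- matrix(stats::rexp(n * n), n, n)
    p <- p / sum(p)
    expect_equal(glcm_features(p), brute_glcm_features(p),
                 tolerance = 1e-10)
  }
})

test_that("energy is in (0,1] and contrast vanishes exactly on diagonal matrices", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(2:16, 1)
    p <- matrix(runif(n * n), n, n); p <- p / sum(p)
    f <- glcm_features(p)
    expect_gt(f[["energy"]], 0); expect_lte(f[["energy"]], 1)
    expect_gte(f[["contrast"]], 0)
    expect_gte(f[["prominence"]], 0)
    expect_gte(f[["correlation"]], -1); expect_lte(f[["correlation"]], 1)
    d <- diag(runif(n)); d <- d / sum(d)
    expect_equal(glcm_features(d)[["contrast"]], 0)
  }
})

test_that("angle-averaged features are invariant to 90-degree rotation", {
  set.seed(12)
  patch <- matrix(runif(64 * 64), 64, 64)
  q <- quantize_gray(patch, 16)
  q90 <- t(q[nrow(q):1, ])
  cfg <- glcm_config(n_levels = 16)
  f1 <- glcm_features(glcm_cooccurrence(q, cfg))
  f2 <- glcm_features(glcm_cooccurrence(q90, cfg))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("feature tables keep ids, flag zero variance, and separate classes", {
  b <- two_class_bank(50, seed = 11)
  names(b$patches) <- paste0("cell", seq_along(b$patches))
  ft <- glcm_table(b$patches)
  expect_identical(nrow(ft), 100L)
  expect_identical(ft$cell_id, paste0("cell", 1:100))

  same <- rep(b$patches[1], 5)
  ft2 <- glcm_table(same)
  expect_equal(var(ft2$contrast), 0)

  # focal vs diffuse classes: large effect size in mean contrast
  x0 <- ft$contrast[b$labels == 0]; x1 <- ft$contrast[b$labels == 1]
  d <- abs(mean(x0) - mean(x1)) /
    sqrt((var(x0) + var(x1)) / 2)
  expect_gt(d, 0.5)
})
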