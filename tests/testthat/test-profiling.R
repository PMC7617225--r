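mk_cells <- function(z, y, x, gpos, cpos = rep(FALSE, length(z))) {
  n <- length(z)
  df <- data.frame(cell_id = seq_len(n), centroid_z = z, centroid_y = y,
                   centroid_x = x, gh2ax_pos = gpos, cd8_pos = cpos)
  attr(df, "voxel_size_um") <- c(0.32125, 0.32125, 0.32125)
  attr(df, "condition") <- "UNKNOWN"
  df
}

mk_classes <- function(cell_id, label, k) {
  out <- data.frame(cell_id = cell_id, class_label = label)
  attr(out, "k") <- as.integer(k)
  out
}

test_that("k-means pseudo-classes recover well-separated blobs exactly", {
  set.seed(40)
  X <- rbind(matrix(rnorm(50 * 3, 0, 1), 50, 3),
             matrix(rnorm(50 * 3, 10, 1), 50, 3))
  ft <- data.frame(cell_id = 1:100, f1 = X[, 1], f2 = X[, 2], f3 = X[, 3])
  cls <- cluster_representations(ft, k = 2, seed = 1)
  expect_identical(nrow(cls), 100L)
  expect_true(all(cls$class_label %in% 0:1))
  expect_equal(ari_index(cls$class_label, rep(0:1, each = 50)), 1)
  expect_true(all(c("pc1", "pc2") %in% names(cls)))
  # duplicated points always share a label
  ft2 <- rbind(ft, ft[1:10, ])
  cls2 <- cluster_representations(ft2, k = 2, seed = 1)
  expect_identical(cls2$class_label[1:10], cls2$class_label[101:110])
  expect_error(cluster_representations(ft[1:3, ], k = 5), "at least k")
})

test_that("a close pair is mutual neighbors at radius 15 but not 5", {
  cells <- mk_cells(z = c(5, 5), y = c(10, 20), x = c(10, 10),
                    gpos = c(TRUE, TRUE))
  cls <- mk_classes(1:2, c(0L, 0L), k = 2)
  p15 <- neighborhood_counts(cells, cls, 15)
  expect_equal(p15$n_class_0, c(1L, 1L))
  expect_equal(p15$n_class_1, c(0L, 0L))
  p5 <- neighborhood_counts(cells, cls, 5)
  expect_equal(p5$n_class_0, c(0L, 0L))
  expect_equal(p5$cd8_count, c(0L, 0L))
  expect_error(neighborhood_counts(cells, mk_classes(1L, 0L, 2), 15),
               "unlabeled")
})

test_that("neighborhood counts equal the O(n^2) oracle and grow with radius", {
  set.seed(77)
  n <- 100
  cells <- mk_cells(runif(n, 0, 60), runif(n, 0, 150), runif(n, 0, 150),
                    gpos = runif(n) < 0.6, cpos = runif(n) < 0.1)
  lab <- ifelse(cells$gh2ax_pos, sample(0:2, n, TRUE), NA)
  cls <- mk_classes(cells$cell_id[cells$gh2ax_pos],
                    lab[cells$gh2ax_pos], k = 3)
  vs <- attr(cells, "voxel_size_um")
  prev <- NULL
  for (r in c(20, 40, 80)) {
    got <- neighborhood_counts(cells, cls, r)
    oracle <- brute_neighbor_counts(cells, lab, r, vs)
    expect_identical(got$center_cell_id,
                     vapply(oracle, `[[`, integer(1), "cell_id"))
    om <- t(vapply(oracle, `[[`, integer(3), "counts"))
    expect_identical(unname(as.matrix(got[, paste0("n_class_", 0:2)])), om)
    expect_identical(got$cd8_count,
                     vapply(oracle, `[[`, integer(1), "cd8"))
    if (!is.null(prev))
      expect_true(all(as.matrix(got[, -(1:3)]) >= as.matrix(prev[, -(1:3)])))
    prev <- got
  }
  # symmetry: equal-class pairs within radius appear in both profiles
  got <- neighborhood_counts(cells, cls, 40)
  tot_by_class <- sapply(0:2, function(cl)
    sum(got[got$center_class == cl, paste0("n_class_", cl)]))
  expect_true(all(tot_by_class %% 2 == 0))
})

test_that("anisotropic z spacing rescales distances as declared", {
  cells <- mk_cells(z = c(0, 10), y = c(0, 0), x = c(0, 0),
                    gpos = c(TRUE, TRUE))
  cls <- mk_classes(1:2, c(0L, 0L), k = 1)
  # z step twice the lateral pitch: 10 z-voxels = 20 lateral px
  vs <- c(0.6425, 0.32125, 0.32125)
  expect_equal(neighborhood_counts(cells, cls, 15, vs)$n_class_0, c(0L, 0L))
  expect_equal(neighborhood_counts(cells, cls, 25, vs)$n_class_0, c(1L, 1L))
})

test_that("heatmaps average neighbor counts per center class", {
  # single center of class 0 with one class-3 neighbor
  cells <- mk_cells(z = c(1, 1), y = c(0, 4), x = c(0, 0),
                    gpos = c(TRUE, TRUE))
  cls <- mk_classes(1:2, c(0L, 3L), k = 5)
  pr <- neighborhood_counts(cells, cls, 10)
  hm <- cooccurrence_heatmap(pr, condition = "CONTROL")
  expect_equal(hm$H[1, 4], 1)
  expect_equal(hm$H[4, 1], 1)   # the class-3 cell sees the class-0 one
  expect_true(all(hm$H[c(2, 3, 5), ] %in% NA))
  expect_setequal(hm$absent_classes, c(1, 2, 4))

  # planted lattice: each class-0 center has exactly two class-1 neighbors
  z <- rep(1, 9); y <- rep(c(0, 3, 6), 3); x <- rep(c(0, 40, 80), each = 3)
  lab <- rep(c(0L, 1L, 1L), 3)
  cellsL <- mk_cells(z, y, x, gpos = rep(TRUE, 9))
  clsL <- mk_classes(1:9, lab, k = 2)
  prL <- neighborhood_counts(cellsL, clsL, 10)
  hmL <- cooccurrence_heatmap(prL, condition = "TREATED")
  expect_equal(hmL$H[1, 2], 2)
  # duplicating every configuration leaves the mean unchanged
  cellsD <- mk_cells(c(z, z), c(y, y), c(x, x + 500),
                     gpos = rep(TRUE, 18))
  clsD <- mk_classes(1:18, c(lab, lab), k = 2)
  hmD <- cooccurrence_heatmap(neighborhood_counts(cellsD, clsD, 10),
                              condition = "TREATED")
  expect_equal(hmD$H, hmL$H)
})

test_that("CD8 proximity reports count nested balls and convert units", {
  set.seed(55)
  n <- 80
  cells <- mk_cells(runif(n, 0, 100), runif(n, 0, 250), runif(n, 0, 250),
                    gpos = runif(n) < 0.5,
                    cpos = seq_len(n) %in% sample(n, 6))
  rep_ <- cd8_proximity_report(cells)
  expect_equal(rep_$summary$radius_um, c(10.28, 20.56, 41.12))
  pc <- rep_$per_cell
  w <- reshape(pc[, c("cd8_cell_id", "radius_px", "gh2ax_within")],
               idvar = "cd8_cell_id", timevar = "radius_px",
               direction = "wide")
  expect_true(all(w[, 4] >= w[, 3] & w[, 3] >= w[, 2]))

  none <- cd8_proximity_report(mk_cells(1, 1, 1, gpos = TRUE))
  expect_identical(nrow(none$per_cell), 0L)
  expect_equal(none$summary$total_gh2ax_near, c(0, 0, 0))
})

test_that("identical conditions give zero differences; singletons suppress p", {
  set.seed(66)
  mkhm <- function(cond) {
    cells <- simulate_region_cells(60, c(60, 150, 150), 0.5, 5,
                                   condition = cond, seed = 8)
    cls <- mk_classes(cells$cell_id[cells$gh2ax_pos],
                      rep_len(0:1, sum(cells$gh2ax_pos)), 2)
    pr <- neighborhood_counts(cells, cls, 40)
    cooccurrence_heatmap(pr, condition = cond)
  }
  hms <- list(mkhm("CONTROL"), mkhm("TREATED"), mkhm("CONTROL"),
              mkhm("TREATED"))
  cmp <- compare_conditions(heatmaps = hms, n_perm = 199, seed = 2)
  expect_true(all(abs(cmp$heatmap_diff$diff) < 1e-12))

  expect_warning(
    cmp1 <- compare_conditions(heatmaps = hms[1:2], n_perm = 99, seed = 2),
    "suppressed")
  expect_true(all(is.na(cmp1$heatmap_diff$p_value)))
})

test_that("simulated point regions honor their planted composition", {
  r <- simulate_region_cells(100, frac_gh2ax_pos = 0.3, n_cd8 = 8,
                             seed = 4)
  expect_identical(sum(r$gh2ax_pos), 30L)
  expect_identical(sum(r$cd8_pos), 8L)
  expect_false(any(r$gh2ax_pos & r$cd8_pos))
  r2 <- simulate_region_cells(100, frac_gh2ax_pos = 0.3, n_cd8 = 8,
                              gh2ax_near_cd8_boost = 0.5, seed = 4)
  expect_identical(sum(r2$gh2ax_pos), 45L)
  expect_identical(simulate_region_cells(50, seed = 9),
                   simulate_region_cells(50, seed = 9))
})
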