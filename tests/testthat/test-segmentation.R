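make_blob_channel <- function() {
  a <- array(0, c(8, 16, 16))
  a[3:5, 4:8, 4:8] <- 255 / 255
  channel_volume(a, "GH2AX")
}

test_that("fixed thresholding recovers a bright blob exactly", {
  ch <- make_blob_channel()
  m <- threshold_channel(ch, "fixed", fixed_value = 100 / 255)
  expect_identical(m$mask, ch$data > 100 / 255)
  expect_identical(sum(m$mask), 3L * 5L * 5L)
  expect_identical(m$method, "FIXED")
})

test_that("Otsu separates a bimodal channel and rejects constant input", {
  r <- generate_region(synth_spec(shape = c(32L, 96L, 96L), n_nuclei = 18L,
                                  frac_gh2ax_pos = 0.5, n_cd8 = 0L,
                                  rng_seed = 13L))
  m <- threshold_channel(r$channels$GH2AX, "otsu")
  foci <- attr(r$truth, "foci_idx")
  expect_gte(mean(m$mask[foci]), 0.99)
  flat <- channel_volume(array(0.3, c(3, 4, 4)), "GH2AX")
  expect_error(threshold_channel(flat, "otsu"), "fixed")
})

test_that("overlap fractions match hand counts and brute-force voxel loops", {
  lab <- array(0L, c(5, 10, 10))
  lab[1:4, 1:5, 1:5] <- 1L   # 100 voxels
  mask <- array(FALSE, c(5, 10, 10))
  mask[1:4, 1:5, 1:3] <- TRUE  # covers 60 of them
  lv <- label_volume(lab)
  mm <- structure(list(mask = mask, threshold_value = 0, method = "FIXED"),
                  class = "MarkerMask")
  res <- superimpose_filter(lv, mm, min_overlap_frac = 0.5,
                            dilate_labels_by = 0L)
  expect_equal(res$overlap_frac, 0.6)
  expect_true(res$positive)

  # disjoint mask
  mask2 <- array(FALSE, c(5, 10, 10)); mask2[5, 8:10, 8:10] <- TRUE
  mm2 <- structure(list(mask = mask2, threshold_value = 0,
                        method = "FIXED"), class = "MarkerMask")
  res2 <- superimpose_filter(lv, mm2, 0.5, 0L)
  expect_equal(res2$overlap_frac, 0)
  expect_false(res2$positive)

  # random multi-instance volume vs brute force, dilation 0
  set.seed(21)
  lab3 <- array(sample(0:4, 20^3, TRUE), c(20, 20, 20))
  mask3 <- array(runif(20^3) > 0.6, c(20, 20, 20))
  res3 <- superimpose_filter(label_volume(lab3),
                             structure(list(mask = mask3,
                                            threshold_value = 0,
                                            method = "FIXED"),
                                       class = "MarkerMask"), 0.5, 0L)
  expect_equal(res3$overlap_frac, unname(brute_overlap(lab3, mask3)))
  # intersections cannot exceed the mask size
  inter_total <- sum(res3$overlap_frac *
                       tabulate(lab3[lab3 > 0], 4)[res3$cell_id])
  expect_lte(inter_total, sum(mask3))
})

test_that("positivity is monotone in the overlap threshold", {
  set.seed(8)
  lab <- array(sample(0:3, 16^3, TRUE), c(16, 16, 16))
  mask <- array(runif(16^3) > 0.5, c(16, 16, 16))
  lv <- label_volume(lab)
  mm <- structure(list(mask = mask, threshold_value = 0, method = "FIXED"),
                  class = "MarkerMask")
  prev <- NULL
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    pos <- superimpose_filter(lv, mm, thr, 0L)$positive
    if (!is.null(prev)) expect_true(all(pos <= prev))
    prev <- pos
  }
})

test_that("dilation flips a membrane shell from negative to positive", {
  r <- generate_region(synth_spec(shape = c(32L, 96L, 96L), n_nuclei = 15L,
                                  frac_gh2ax_pos = 0, n_cd8 = 2L,
                                  rng_seed = 5L))
  mc <- threshold_channel(r$channels$CD8, "otsu")
  cd8_id <- r$truth$cell_id[r$truth$cd8_pos]
  s0 <- superimpose_filter(r$labels, mc, 0.15, 0L)
  s2 <- superimpose_filter(r$labels, mc, 0.15, 2L)
  expect_true(all(!s0$positive[match(cd8_id, s0$cell_id)]))
  expect_true(all(s2$positive[match(cd8_id, s2$cell_id)]))
  # dilation never merges instances: label sets are preserved
  dl <- dilate_labels(r$labels, 2L)
  expect_setequal(unique(as.vector(dl$labels)),
                  unique(as.vector(r$labels$labels)))
  expect_true(all(dl$labels[r$labels$labels > 0] ==
                    r$labels$labels[r$labels$labels > 0]))
})

test_that("cell tables carry exact centroids, bboxes and truth-matched calls", {
  # single nucleus at known voxels: z in [2,4), y in [3,6), x in [3,6)
  lab <- array(0L, c(6, 8, 8))
  lab[3:4, 4:6, 4:6] <- 9L
  ct <- suppressMessages(build_cell_table(label_volume(lab)))
  expect_equal(ct$centroid_z, 2.5)
  expect_equal(ct$centroid_y, 4)
  expect_equal(ct$centroid_x, 4)
  expect_identical(c(ct$z0, ct$y0, ct$x0), c(2L, 3L, 3L))
  expect_identical(c(ct$z1, ct$y1, ct$x1), c(4L, 6L, 6L))
  expect_identical(ct$voxel_count, 18L)

  empty <- suppressMessages(build_cell_table(label_volume(array(0L, c(3, 3, 3)))))
  expect_identical(nrow(empty), 0L)

  r <- generate_region(synth_spec(shape = c(32L, 96L, 96L), n_nuclei = 25L,
                                  frac_gh2ax_pos = 0.4, n_cd8 = 3L,
                                  rng_seed = 17L))
  ct2 <- suppressMessages(build_cell_table(
    r$labels, threshold_channel(r$channels$GH2AX, "otsu"),
    threshold_channel(r$channels$CD8, "otsu")))
  expect_identical(ct2$gh2ax_pos, r$truth$gh2ax_pos)
  expect_identical(ct2$cd8_pos, r$truth$cd8_pos)
  expect_identical(sum(ct2$gh2ax_pos), 10L)
})

test_that("patches are centered, scaled to [0,1], and one per positive cell", {
  # bright 10x10 square nucleus slice
  lab <- array(0L, c(5, 30, 30))
  lab[2:4, 11:20, 11:20] <- 1L
  ch <- array(0, c(5, 30, 30))
  ch[2:4, 11:20, 11:20] <- 0.8
  vol <- channel_volume(ch, "GH2AX")
  rec <- data.frame(cell_id = 1L, z0 = 1L, z1 = 4L, y0 = 10L, y1 = 20L,
                    x0 = 10L, x1 = 20L)
  p <- extract_patch(vol, rec, label_volume(lab))
  expect_identical(dim(p), c(64L, 64L))
  expect_equal(max(p), 1)
  on <- which(p > 0, arr.ind = TRUE)
  # centered: occupied block symmetric around the canvas center
  expect_equal(mean(range(on[, 1])), 32.5, tolerance = 1)
  expect_equal(mean(range(on[, 2])), 32.5, tolerance = 1)
  expect_identical(sum(p > 0), 100L)

  # a constant canvas (full-size constant slice) maps to all zeros
  ch2 <- array(0.5, c(5, 70, 70))
  rec2 <- data.frame(cell_id = 1L, z0 = 1L, z1 = 4L, y0 = 0L, y1 = 64L,
                     x0 = 0L, x1 = 64L)
  p2 <- extract_patch(channel_volume(ch2, "GH2AX"), rec2,
                      label_volume(array(1L, c(5, 70, 70))),
                      mask_background = FALSE)
  expect_true(all(p2 == 0))

  # degenerate bbox is skipped with a warning
  rec_bad <- data.frame(cell_id = 2L, z0 = 0L, z1 = 1L, y0 = 0L, y1 = 1L,
                        x0 = 0L, x1 = 5L)
  expect_warning(out <- extract_patch(vol, rec_bad, label_volume(lab)),
                 "degenerate")
  expect_null(out)

  # one patch per gamma-H2AX positive record
  r <- generate_region(synth_spec(shape = c(32L, 96L, 96L), n_nuclei = 15L,
                                  frac_gh2ax_pos = 0.4, n_cd8 = 0L,
                                  rng_seed = 23L))
  ct <- suppressMessages(build_cell_table(
    r$labels, threshold_channel(r$channels$GH2AX, "otsu")))
  bank <- extract_patches(r$channels$GH2AX, ct, r$labels)
  expect_length(bank, sum(ct$gh2ax_pos))

  # oversized nuclei are rescaled onto the canvas
  lab3 <- array(0L, c(5, 100, 80)); lab3[2:4, 6:95, 6:75] <- 1L
  ch3 <- array(0, c(5, 100, 80)); ch3[2:4, 6:95, 6:75] <- runif(3 * 90 * 70)
  rec3 <- data.frame(cell_id = 1L, z0 = 1L, z1 = 4L, y0 = 5L, y1 = 95L,
                     x0 = 5L, x1 = 75L)
  p3 <- extract_patch(channel_volume(ch3, "GH2AX"), rec3,
                      label_volume(lab3))
  expect_identical(dim(p3), c(64L, 64L))
})

test_that("patch banks round-trip through the CSV archive", {
  b <- two_class_bank(3, seed = 2)
  bank <- b$patches
  names(bank) <- paste0("c", seq_along(bank))
  class(bank) <- "PatchBank"
  f <- withr::local_tempfile(fileext = ".csv")
  write_patch_bank(bank, f)
  back <- read_patch_bank(f)
  expect_identical(names(back), names(bank))
  expect_equal(back[[4]], bank[[4]], tolerance = 1e-9,
               ignore_attr = TRUE)
})
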