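test_that("intensity volumes round-trip through TIFF up to 16-bit dtype", {
  v <- channel_volume(array(runif(5 * 7 * 6), c(5, 7, 6)), "GH2AX")
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f)
  v2 <- read_volume(f, "GH2AX")
  expect_identical(dim(v2$data), dim(v$data))
  expect_lt(max(abs(v2$data - v$data)), 1 / 65535)
  expect_equal(v2$voxel_size_um, c(z = 0.32125, y = 0.32125, x = 0.32125))
})

test_that("a single-slice stack is a valid volume with z-dim 1", {
  v <- channel_volume(array(runif(1 * 8 * 8), c(1, 8, 8)), "DAPI")
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f)
  v2 <- read_volume(f, "DAPI")
  expect_identical(dim(v2$data), c(1L, 8L, 8L))
})

test_that("multi-channel stacks are sliced by declared channel order", {
  set.seed(4)
  mk <- function(nm) channel_volume(array(runif(3 * 6 * 5), c(3, 6, 5)), nm)
  vols <- list(DAPI = mk("DAPI"), GH2AX = mk("GH2AX"), CD8 = mk("CD8"))
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(vols, f)
  for (nm in names(vols)) {
    got <- read_volume(f, nm, channels = names(vols))
    expect_lt(max(abs(got$data - vols[[nm]]$data)), 1 / 65535)
  }
  expect_error(read_volume(f, "PAN", channels = names(vols)),
               "not in declared order")
})

test_that("label volumes round-trip bit-exactly, including gap labels", {
  lab <- label_volume(array(sample(c(0L, 5L, 17L), 4 * 6 * 5, TRUE),
                            c(4, 6, 5)))
  f <- withr::local_tempfile(fileext = ".tif")
  write_labels(lab, f)
  back <- read_labels(f)
  expect_identical(back$labels, lab$labels)
  expect_setequal(unique(as.vector(back$labels)), c(0L, 5L, 17L))

  zero <- label_volume(array(0L, c(2, 3, 3)))
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_labels(zero, f2)
  expect_identical(read_labels(f2)$labels, zero$labels)
})

test_that("invalid volumes and files are rejected with clear errors", {
  expect_error(read_volume(tempfile(), "DAPI"), "not found")
  expect_error(channel_volume(matrix(1, 2, 2), "DAPI"), "3D")
  expect_error(channel_volume(array(-1, c(2, 2, 2)), "DAPI"),
               "non-negative")
  expect_error(label_volume(array(0.5, c(2, 2, 2))), "cast")
})

test_that("tables round-trip through CSV with metadata sidecar", {
  df <- data.frame(cell_id = 1:3, energy = c(0.123456789, 1e-7, 2 / 3),
                   gh2ax_pos = c(TRUE, FALSE, TRUE))
  attr(df, "condition") <- "CONTROL"
  attr(df, "region_id") <- "r1"
  f <- withr::local_tempfile(fileext = ".csv")
  write_table(df, f)
  back <- read_table_csv(f)
  expect_identical(back$cell_id, df$cell_id)
  expect_identical(back$gh2ax_pos, df$gh2ax_pos)
  expect_equal(back$energy, df$energy, tolerance = 1e-9)
  expect_identical(attr(back, "condition"), "CONTROL")

  empty <- df[0, ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_table(empty, f2)
  expect_identical(nrow(read_table_csv(f2)), 0L)
})

test_that("pixel radii convert to micrometers at the 0.32125 um pitch", {
  expect_equal(px_to_um(32), 10.28)
  expect_equal(px_to_um(c(32, 64, 128)), c(10.28, 20.56, 41.12))
  expect_equal(px_to_um(10, c(1, 0.5, 0.5)), 5)
  expect_error(px_to_um(1, c(1, 1, 2)), "anisotropic")
})
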