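# Marker-positive cell identification by threshold + superimposition.
#
# Nuclei come from an external instance segmenter (Cellpose or similar) as
# a LabelVolume. A marker channel (gamma-H2AX, CD8) is thresholded into a
# binary mask; each nucleus is called positive when a sufficient fraction
# of its (optionally dilated) volume falls inside the mask. Dilation exists
# for membrane-bound markers like CD8, whose signal lies just outside the
# nuclear envelope.

#' Threshold a marker channel into a binary mask
#'
#' @param channel A \code{\link{channel_volume}}.
#' @param method \code{"otsu"} (global Otsu on the intensity histogram,
#'   256 bins) or \code{"fixed"}.
#' @param fixed_value Threshold for \code{method = "fixed"}.
#' @return A \code{MarkerMask}: list with \code{mask} (logical 3D array,
#'   \code{channel > threshold}), \code{threshold_value}, \code{method}.
#' @export
threshold_channel <- function(channel, method = c("otsu", "fixed"),
                              fixed_value = NULL) {
  stopifnot(inherits(channel, "ChannelVolume"))
  method <- match.arg(method)
  x <- channel$data
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("method 'fixed' requires fixed_value")
    th <- fixed_value
  } else {
    rng <- range(x)
    if (rng[1] == rng[2])
      stop("channel is constant; Otsu is undefined - use method='fixed'")
    th <- EBImage::otsu(EBImage::Image(matrix(as.numeric(x), ncol = 1L)),
                        range = rng, levels = 256L)
  }
  structure(list(mask = x > th, threshold_value = as.numeric(th),
                 method = toupper(method)),
            class = "MarkerMask")
}

# Ball structuring-element offsets of radius r, ordered by distance from
# the center (then lexicographically) so that nearer claims win first.
.ball_offsets <- function(r) {
  s <- -r:r
  g <- expand.grid(dz = s, dy = s, dx = s)
  d2 <- g$dz^2 + g$dy^2 + g$dx^2
  keep <- d2 <= r^2 & d2 > 0
  g <- g[keep, , drop = FALSE]
  g[order(d2[keep], g$dz, g$dy, g$dx), , drop = FALSE]
}

#' Dilate an instance label volume by a ball without merging instances
#'
#' Every background voxel within \code{r} voxels of some instance is
#' assigned to the nearest original instance (ties broken deterministically
#' by offset sweep order). Original labels are never overwritten, so
#' dilation by 0 is the identity.
#'
#' @param labels A \code{LabelVolume}.
#' @param r Ball radius in voxels (integer >= 0).
#' @return A dilated \code{LabelVolume}.
#' @export
dilate_labels <- function(labels, r) {
  stopifnot(inherits(labels, "LabelVolume"), r >= 0)
  if (r == 0) return(labels)
  lab <- labels$labels
  d <- dim(lab)
  out <- lab
  claimed_d2 <- array(Inf, d)
  claimed_d2[lab > 0L] <- 0
  offs <- .ball_offsets(r)
  for (k in seq_len(nrow(offs))) {
    dz <- offs$dz[k]; dy <- offs$dy[k]; dx <- offs$dx[k]
    d2 <- dz^2 + dy^2 + dx^2
    sz <- max(1, 1 - dz):min(d[1], d[1] - dz)
    sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
    sx <- max(1, 1 - dx):min(d[3], d[3] - dx)
    src <- lab[sz, sy, sx]
    tz <- sz + dz; ty <- sy + dy; tx <- sx + dx
    tgt_d2 <- claimed_d2[tz, ty, tx]
    take <- src > 0L & tgt_d2 > d2
    if (any(take)) {
      blk <- out[tz, ty, tx]
      blk[take] <- src[take]
      out[tz, ty, tx] <- blk
      tgt_d2[take] <- d2
      claimed_d2[tz, ty, tx] <- tgt_d2
    }
  }
  label_volume(out)
}

#' Per-instance marker overlap and positivity calls
#'
#' For each nucleus instance, the overlap fraction is
#' \code{|dilated instance intersect mask| / |dilated instance|}; the
#' instance is positive when that fraction reaches
#' \code{min_overlap_frac}. Raising the threshold can only remove
#' positives.
#'
#' @param labels A \code{LabelVolume}.
#' @param mask A \code{MarkerMask} (same shape).
#' @param min_overlap_frac Positivity threshold in \code{(0, 1]}
#'   (default 0.5, i.e. majority overlap).
#' @param dilate_labels_by Ball radius (voxels) applied to the instances
#'   before superimposition; 0 for nuclear markers, > 0 for membrane-bound
#'   markers.
#' @return Data frame with \code{cell_id}, \code{overlap_frac},
#'   \code{positive}.
#' @export
superimpose_filter <- function(labels, mask, min_overlap_frac = 0.5,
                               dilate_labels_by = 0L) {
  stopifnot(inherits(labels, "LabelVolume"), inherits(mask, "MarkerMask"),
            min_overlap_frac > 0, min_overlap_frac <= 1,
            dilate_labels_by >= 0)
  if (!identical(dim(labels$labels), dim(mask$mask)))
    stop("label and mask shapes differ")
  lab <- dilate_labels(labels, dilate_labels_by)$labels
  ids <- sort(setdiff(unique(as.vector(labels$labels)), 0L))
  if (length(ids) == 0L)
    return(data.frame(cell_id = integer(0), overlap_frac = numeric(0),
                      positive = logical(0)))
  mx <- max(ids)
  tot <- tabulate(lab[lab > 0L], nbins = mx)
  inter <- tabulate(lab[lab > 0L & mask$mask], nbins = mx)
  frac <- ifelse(tot[ids] > 0, inter[ids] / tot[ids], 0)
  data.frame(cell_id = ids, overlap_frac = frac,
             positive = frac >= min_overlap_frac)
}

#' Build the per-cell table from labels and both marker masks
#'
#' One row per nucleus instance: centroid (unweighted voxel mean), 0-based
#' half-open bounding box, voxel count, gamma-H2AX and CD8 overlap
#' fractions and positivity flags. Per the marker biology, gamma-H2AX
#' positivity is computed without dilation (nuclear signal) while CD8 uses
#' a dilated superimposition (membrane signal).
#'
#' @param labels A \code{LabelVolume}.
#' @param gh2ax_mask,cd8_mask \code{MarkerMask}s for the two markers
#'   (either may be \code{NULL} to skip that call).
#' @param min_overlap_frac gamma-H2AX positivity threshold (majority
#'   overlap by default).
#' @param cd8_dilate Ball radius (voxels) for the CD8 superimposition
#'   (default 2).
#' @param cd8_min_overlap CD8 positivity threshold (default 0.15). A
#'   membrane marker can only ever cover the outer band of the dilated
#'   nucleus - roughly \code{1 - (r/(r+d))^3} of it - so majority overlap
#'   is unattainable for large nuclei and a band-sized threshold is the
#'   meaningful default.
#' @param condition Condition tag: \code{"CONTROL"}, \code{"TREATED"} or
#'   \code{"UNKNOWN"}.
#' @param region_id Region identifier string.
#' @param voxel_size_um Voxel size metadata propagated onto the table.
#' @return A \code{CellTable}: data frame with class \code{"CellTable"} and
#'   attributes \code{condition}, \code{region_id}, \code{voxel_size_um}.
#' @export
build_cell_table <- function(labels, gh2ax_mask = NULL, cd8_mask = NULL,
                             min_overlap_frac = 0.5, cd8_dilate = 2L,
                             cd8_min_overlap = 0.15,
                             condition = "UNKNOWN", region_id = "region",
                             voxel_size_um = DEFAULT_VOXEL_SIZE_UM) {
  stopifnot(inherits(labels, "LabelVolume"))
  condition <- match.arg(condition, c("CONTROL", "TREATED", "UNKNOWN"))
  lab <- labels$labels
  idx <- which(lab > 0L)
  empty <- data.frame(cell_id = integer(0), centroid_z = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      z0 = integer(0), y0 = integer(0), x0 = integer(0),
                      z1 = integer(0), y1 = integer(0), x1 = integer(0),
                      voxel_count = integer(0),
                      gh2ax_overlap_frac = numeric(0),
                      cd8_overlap_frac = numeric(0),
                      gh2ax_pos = logical(0), cd8_pos = logical(0))
  if (length(idx) == 0L)
    return(.as_cell_table(empty, condition, region_id, voxel_size_um))

  co <- arrayInd(idx, dim(lab))
  id <- lab[idx]
  ids <- sort(unique(id))
  cnt <- as.vector(rowsum(rep(1L, length(id)), id))
  sums <- rowsum(co, id)
  cent <- sums / cnt
  mins <- vapply(1:3, function(j) tapply(co[, j], id, min), numeric(length(ids)))
  maxs <- vapply(1:3, function(j) tapply(co[, j], id, max), numeric(length(ids)))
  if (length(ids) == 1L) { mins <- matrix(mins, 1); maxs <- matrix(maxs, 1) }

  tab <- data.frame(
    cell_id = ids,
    centroid_z = cent[, 1] - 1, centroid_y = cent[, 2] - 1,
    centroid_x = cent[, 3] - 1,
    z0 = as.integer(mins[, 1] - 1), y0 = as.integer(mins[, 2] - 1),
    x0 = as.integer(mins[, 3] - 1),
    z1 = as.integer(maxs[, 1]), y1 = as.integer(maxs[, 2]),
    x1 = as.integer(maxs[, 3]),
    voxel_count = cnt,
    gh2ax_overlap_frac = 0, cd8_overlap_frac = 0,
    gh2ax_pos = FALSE, cd8_pos = FALSE)

  if (!is.null(gh2ax_mask)) {
    g <- superimpose_filter(labels, gh2ax_mask, min_overlap_frac, 0L)
    tab$gh2ax_overlap_frac <- g$overlap_frac[match(tab$cell_id, g$cell_id)]
    tab$gh2ax_pos <- g$positive[match(tab$cell_id, g$cell_id)]
  }
  if (!is.null(cd8_mask)) {
    s <- superimpose_filter(labels, cd8_mask, cd8_min_overlap, cd8_dilate)
    tab$cd8_overlap_frac <- s$overlap_frac[match(tab$cell_id, s$cell_id)]
    tab$cd8_pos <- s$positive[match(tab$cell_id, s$cell_id)]
  }
  message(sprintf("region %s: %d instances, %d gamma-H2AX+, %d CD8+",
                  region_id, nrow(tab), sum(tab$gh2ax_pos),
                  sum(tab$cd8_pos)))
  .as_cell_table(tab, condition, region_id, voxel_size_um)
}

.as_cell_table <- function(df, condition, region_id, voxel_size_um) {
  class(df) <- c("CellTable", "data.frame")
  attr(df, "condition") <- condition
  attr(df, "region_id") <- region_id
  attr(df, "voxel_size_um") <- as.numeric(voxel_size_um)
  df
}

#' Extract a centered 64x64 texture patch for one nucleus
#'
#' Takes the central z-slice of the cell's bounding box from the given
#' channel, zeroes voxels outside the instance mask (so neighboring nuclei
#' cannot contaminate the texture), pads onto a \code{size x size} canvas
#' (or isotropically downscales first when larger), and min-max scales to
#' \code{[0, 1]}. A constant slice maps to all zeros.
#'
#' @param channel \code{ChannelVolume} to sample (normally GH2AX).
#' @param record One-row slice of a \code{CellTable}.
#' @param labels The matching \code{LabelVolume}.
#' @param size Canvas side (default 64).
#' @param mask_background Zero out voxels not belonging to the instance
#'   (default \code{TRUE}).
#' @return \code{size x size} numeric matrix in \code{[0, 1]}, or
#'   \code{NULL} (with a warning) for degenerate single-voxel-wide boxes.
#' @export
extract_patch <- function(channel, record, labels, size = 64L,
                          mask_background = TRUE) {
  stopifnot(inherits(channel, "ChannelVolume"),
            inherits(labels, "LabelVolume"))
  z0 <- record$z0; z1 <- record$z1
  y0 <- record$y0; y1 <- record$y1
  x0 <- record$x0; x1 <- record$x1
  if ((y1 - y0) < 2L || (x1 - x0) < 2L) {
    warning("cell ", record$cell_id,
            ": bounding box degenerate in y or x; skipped")
    return(NULL)
  }
  zc <- floor((z0 + z1) / 2)  # central slice of the half-open [z0, z1)
  sl <- channel$data[zc + 1L, (y0 + 1L):y1, (x0 + 1L):x1, drop = TRUE]
  if (mask_background) {
    m <- labels$labels[zc + 1L, (y0 + 1L):y1, (x0 + 1L):x1,
                       drop = TRUE] == record$cell_id
    sl <- sl * m
  }
  d <- dim(sl)
  if (any(d > size)) {
    sc <- size / max(d)
    nd <- pmax(1L, as.integer(round(d * sc)))
    sl <- EBImage::resize(EBImage::Image(sl), w = nd[1], h = nd[2])
    sl <- matrix(as.numeric(sl), nd[1], nd[2])
    d <- nd
  }
  canvas <- matrix(0, size, size)
  off <- floor((c(size, size) - d) / 2)
  canvas[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- sl
  rng <- range(canvas)
  if (rng[2] > rng[1]) (canvas - rng[1]) / (rng[2] - rng[1]) else canvas * 0
}

#' Extract patches for all gamma-H2AX positive cells
#'
#' @inheritParams extract_patch
#' @param cells A \code{CellTable}.
#' @return Named list of patches (names = cell_id), class
#'   \code{"PatchBank"}; skipped degenerate cells are absent.
#' @export
extract_patches <- function(channel, cells, labels, size = 64L,
                            mask_background = TRUE) {
  pos <- which(cells$gh2ax_pos)
  out <- list()
  for (i in pos) {
    p <- extract_patch(channel, cells[i, ], labels, size, mask_background)
    if (!is.null(p)) out[[as.character(cells$cell_id[i])]] <- p
  }
  class(out) <- "PatchBank"
  out
}

#' Write / read a patch bank as plain CSV
#'
#' One row per patch: \code{cell_id} followed by the \code{size^2} pixel
#' values in column-major order. Kept as text so archives are portable and
#' diffable.
#'
#' @param bank A \code{PatchBank} (named list of equal-size matrices).
#' @param path CSV path.
#' @return \code{path} invisibly / the \code{PatchBank}.
#' @export
write_patch_bank <- function(bank, path) {
  stopifnot(length(bank) > 0)
  n <- length(bank)
  sz <- dim(bank[[1]])
  m <- t(vapply(bank, as.vector, numeric(prod(sz))))
  df <- data.frame(cell_id = names(bank), m, check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("p", seq_len(prod(sz))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(size = sz, n = n), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_patch_bank
#' @export
read_patch_bank <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  sz <- meta$size
  out <- lapply(seq_len(nrow(df)), function(i)
    matrix(as.numeric(df[i, -1]), sz[1], sz[2]))
  names(out) <- df$cell_id
  class(out) <- "PatchBank"
  out
}
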