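# Pseudo texture classes and local-neighborhood profiling.
#
# Per-cell representations (GLCM features or VAE-GAN latent means) are
# standardized and clustered with k-means into k pseudo texture classes
# (class-label surrogates in the absence of expert annotation), projected
# to 2D by PCA for inspection, and then used to profile spherical
# neighborhoods around gamma-H2AX+ cells: counts of neighbors per class
# (co-occurrence heatmaps) and counts of CD8+ cells at multiple radii.

#' Cluster per-cell representations into pseudo texture classes
#'
#' Columns are standardized to zero mean / unit variance before k-means
#' (otherwise heavy-tailed features such as cluster prominence dominate
#' the metric) and before the PCA used for the 2D projection. K-means runs
#' with \code{nstart} seeded restarts.
#'
#' @param features A \code{FeatureTable} or \code{LatentTable} (data frame
#'   with \code{cell_id} plus numeric columns; for latent tables only the
#'   \code{mu_} columns are used - clustering consumes means, never
#'   samples).
#' @param k Number of pseudo classes (default 5).
#' @param seed Seed for the k-means restarts.
#' @param standardize Standardize columns first (default TRUE).
#' @param nstart Number of k-means restarts (default 10).
#' @return A \code{PseudoClassTable} data frame: \code{cell_id},
#'   \code{class_label} (0-based), \code{pc1}, \code{pc2}; cluster centers
#'   (in standardized space) and total within-cluster sum of squares in
#'   attributes \code{centers} and \code{inertia}.
#' @export
cluster_representations <- function(features, k = 5L, seed = 1L,
                                    standardize = TRUE, nstart = 10L) {
  stopifnot(is.data.frame(features), "cell_id" %in% names(features))
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  num <- setdiff(num, "cell_id")
  if (inherits(features, "LatentTable"))
    num <- grep("^mu_", num, value = TRUE)
  X <- as.matrix(features[, num, drop = FALSE])
  if (nrow(X) < k)
    stop("need at least k = ", k, " cells; got ", nrow(X))
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0   # constant columns carry nothing
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L)
  pc <- stats::prcomp(X, center = !standardize, scale. = FALSE)
  xy <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(xy) < 2L) xy <- cbind(xy, 0)
  out <- data.frame(cell_id = features$cell_id,
                    class_label = km$cluster - 1L,
                    pc1 = xy[, 1], pc2 = xy[, 2])
  class(out) <- c("PseudoClassTable", "data.frame")
  attr(out, "centers") <- km$centers
  attr(out, "inertia") <- km$tot.withinss
  attr(out, "k") <- as.integer(k)
  out
}

# Pairwise distances between cell centroids in lateral-pixel units: each
# axis difference is scaled by voxel_size / lateral_voxel_size, so "radius
# in px" means lateral pixels and anisotropic z is handled consistently.
.scaled_dist <- function(a, b, voxel_size_um) {
  v <- as.numeric(voxel_size_um)
  if (abs(v[2] - v[3]) > 1e-12)
    stop("anisotropic lateral (y vs x) voxel sizes are not supported")
  s <- v / v[2]
  dz <- outer(a[, 1], b[, 1], "-") * s[1]
  dy <- outer(a[, 2], b[, 2], "-") * s[2]
  dx <- outer(a[, 3], b[, 3], "-") * s[3]
  sqrt(dz^2 + dy^2 + dx^2)
}

.centroids <- function(cells) {
  as.matrix(cells[, c("centroid_z", "centroid_y", "centroid_x")])
}

#' Spherical-neighborhood class and CD8 counts around gamma-H2AX+ cells
#'
#' For every gamma-H2AX+ cell with a pseudo-class label, counts the other
#' gamma-H2AX+ cells of each class and the CD8+ cells whose centroids lie
#' within \code{radius_px} lateral pixels (0 < distance <= radius; a cell
#' never counts itself).
#'
#' @param cells A \code{CellTable}.
#' @param classes A \code{PseudoClassTable} labelling every gamma-H2AX+
#'   cell in \code{cells} (an error otherwise).
#' @param radius_px Neighborhood radius in lateral pixels.
#' @param voxel_size_um Voxel size used to scale the z axis.
#' @return \code{NeighborhoodProfile} data frame: \code{center_cell_id},
#'   \code{center_class}, \code{radius_px}, \code{n_class_<c>} for each
#'   class, \code{cd8_count}.
#' @export
neighborhood_counts <- function(cells, classes, radius_px,
                                voxel_size_um = attr(cells,
                                                     "voxel_size_um")) {
  stopifnot(radius_px > 0)
  if (is.null(voxel_size_um)) voxel_size_um <- DEFAULT_VOXEL_SIZE_UM
  k <- attr(classes, "k")
  if (is.null(k)) k <- max(classes$class_label) + 1L
  pos <- cells[cells$gh2ax_pos, , drop = FALSE]
  lab <- classes$class_label[match(pos$cell_id, classes$cell_id)]
  if (any(is.na(lab)))
    stop("unlabeled gamma-H2AX+ center cells; run ",
         "cluster_representations() on all positive cells first")
  ctr <- .centroids(pos)
  prof <- data.frame(center_cell_id = pos$cell_id, center_class = lab,
                     radius_px = radius_px)
  cnt <- matrix(0L, nrow(pos), k,
                dimnames = list(NULL, paste0("n_class_", 0:(k - 1))))
  if (nrow(pos) > 1) {
    D <- .scaled_dist(ctr, ctr, voxel_size_um)
    within <- D > 0 & D <= radius_px
    # self-distance is 0 so self-exclusion is automatic for distinct cells
    diag(within) <- FALSE
    for (cl in 0:(k - 1)) {
      sel <- lab == cl
      cnt[, cl + 1L] <- as.integer(rowSums(within[, sel, drop = FALSE]))
    }
  }
  cd8 <- cells[cells$cd8_pos, , drop = FALSE]
  cd8n <- integer(nrow(pos))
  if (nrow(cd8) > 0 && nrow(pos) > 0) {
    Dc <- .scaled_dist(ctr, .centroids(cd8), voxel_size_um)
    same <- outer(pos$cell_id, cd8$cell_id, "==")
    cd8n <- as.integer(rowSums(Dc > 0 & Dc <= radius_px & !same))
  }
  out <- cbind(prof, cnt, cd8_count = cd8n)
  class(out) <- c("NeighborhoodProfile", "data.frame")
  attr(out, "k") <- as.integer(k)
  out
}

#' Class-by-class co-occurrence heatmap
#'
#' \code{H[i, j]} is the mean, over center cells of class \code{i}, of the
#' number of class-\code{j} neighbors within the profile radius. Using the
#' per-center mean (rather than raw sums) makes regions of different cell
#' density comparable. Classes with no center cells yield \code{NA} rows
#' and are flagged, never imputed.
#'
#' @param profiles A \code{NeighborhoodProfile} (one radius).
#' @param k Number of classes (default from the profile attribute).
#' @param condition Condition tag stored on the result.
#' @param statistic \code{"mean"} (default) or \code{"sum"}.
#' @return \code{CooccurrenceHeatmap}: list with \code{H} (k x k matrix),
#'   \code{condition}, \code{radius_px}, \code{absent_classes}.
#' @export
cooccurrence_heatmap <- function(profiles, k = attr(profiles, "k"),
                                 condition = "UNKNOWN",
                                 statistic = c("mean", "sum")) {
  stopifnot(nrow(profiles) >= 1)
  statistic <- match.arg(statistic)
  if (is.null(k)) k <- max(profiles$center_class) + 1L
  cols <- paste0("n_class_", 0:(k - 1))
  H <- matrix(NA_real_, k, k, dimnames = list(paste0("center_", 0:(k - 1)),
                                              paste0("neigh_", 0:(k - 1))))
  for (i in 0:(k - 1)) {
    rows <- profiles$center_class == i
    if (!any(rows)) next
    m <- as.matrix(profiles[rows, cols, drop = FALSE])
    H[i + 1L, ] <- if (statistic == "mean") colMeans(m) else colSums(m)
  }
  structure(list(H = H, condition = condition,
                 radius_px = profiles$radius_px[1],
                 absent_classes = which(rowSums(!is.na(H)) == 0) - 1L),
            class = "CooccurrenceHeatmap")
}

#' gamma-H2AX+ counts in the vicinity of CD8+ cells at several radii
#'
#' For each CD8+ cell and each radius, counts the gamma-H2AX+ cells whose
#' centroids fall within the radius (in lateral pixels; also reported in
#' micrometers via the voxel size). Counts are monotone non-decreasing in
#' the radius.
#'
#' @param cells A \code{CellTable}.
#' @param radii_px Radii in lateral pixels (default \code{c(32, 64, 128)}).
#' @param voxel_size_um Voxel size for z scaling and the um conversion.
#' @return \code{ProximityReport}: list with \code{per_cell} (one row per
#'   CD8+ cell x radius) and \code{summary} (per radius: \code{radius_px},
#'   \code{radius_um}, \code{n_cd8}, \code{total_gh2ax_near},
#'   \code{mean_gh2ax_near}).
#' @export
cd8_proximity_report <- function(cells, radii_px = c(32, 64, 128),
                                 voxel_size_um = attr(cells,
                                                      "voxel_size_um")) {
  if (is.null(voxel_size_um)) voxel_size_um <- DEFAULT_VOXEL_SIZE_UM
  cd8 <- cells[cells$cd8_pos, , drop = FALSE]
  pos <- cells[cells$gh2ax_pos, , drop = FALSE]
  per <- list(); summ <- list()
  for (r in radii_px) {
    if (nrow(cd8) == 0) {
      cnt <- integer(0)
    } else if (nrow(pos) == 0) {
      cnt <- integer(nrow(cd8))
    } else {
      D <- .scaled_dist(.centroids(cd8), .centroids(pos), voxel_size_um)
      same <- outer(cd8$cell_id, pos$cell_id, "==")
      cnt <- as.integer(rowSums(D > 0 & D <= r & !same))
    }
    per[[length(per) + 1L]] <-
      data.frame(cd8_cell_id = cd8$cell_id,
                 radius_px = rep(r, nrow(cd8)),
                 radius_um = rep(px_to_um(r, voxel_size_um), nrow(cd8)),
                 gh2ax_within = cnt)
    summ[[length(summ) + 1L]] <-
      data.frame(radius_px = r, radius_um = px_to_um(r, voxel_size_um),
                 n_cd8 = nrow(cd8), total_gh2ax_near = sum(cnt),
                 mean_gh2ax_near = if (nrow(cd8)) mean(cnt) else 0)
  }
  structure(list(per_cell = do.call(rbind, per),
                 summary = do.call(rbind, summ),
                 condition = attr(cells, "condition")),
            class = "ProximityReport")
}

#' Compare neighborhood profiles between control and treated regions
#'
#' Inputs are per-region heatmaps and proximity reports. For every heatmap
#' entry (i, j) and for every radius the difference
#' \code{treated - control} of the condition means is reported together
#' with a two-sided permutation p-value obtained by reshuffling the region
#' condition labels. With a single region per condition differences are
#' still reported but p-values are suppressed with a warning.
#'
#' @param heatmaps List of \code{CooccurrenceHeatmap}s (one per region,
#'   any number of radii) with conditions set; may be \code{NULL}.
#' @param reports List of \code{ProximityReport}s, one per region; may be
#'   \code{NULL}.
#' @param n_perm Number of permutations (default 999).
#' @param seed Permutation seed.
#' @return List of data frames \code{heatmap_diff} (\code{radius_px},
#'   \code{center_class}, \code{neighbor_class}, \code{diff},
#'   \code{p_value}) and \code{proximity_diff} (\code{radius_px},
#'   \code{diff}, \code{p_value}).
#' @export
compare_conditions <- function(heatmaps = NULL, reports = NULL,
                               n_perm = 999L, seed = 1L) {
  set.seed(seed)
  perm_p <- function(vals, cond) {
    # two-sided permutation test on difference of condition means over
    # regions; NA when either condition has < 2 regions
    obs <- mean(vals[cond == "TREATED"]) - mean(vals[cond == "CONTROL"])
    if (sum(cond == "TREATED") < 2 || sum(cond == "CONTROL") < 2)
      return(c(obs, NA_real_))
    nt <- sum(cond == "TREATED")
    null <- replicate(n_perm, {
      sh <- sample(cond)
      mean(vals[sh == "TREATED"]) - mean(vals[sh == "CONTROL"])
    })
    c(obs, (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1))
  }
  hm_out <- NULL
  if (!is.null(heatmaps) && length(heatmaps)) {
    cond <- vapply(heatmaps, function(h) h$condition, character(1))
    if (!all(c("CONTROL", "TREATED") %in% cond))
      stop("both CONTROL and TREATED regions are required")
    if (sum(cond == "CONTROL") < 2 || sum(cond == "TREATED") < 2)
      warning("a condition has a single region; p-values suppressed")
    radii <- unique(vapply(heatmaps, function(h) h$radius_px, numeric(1)))
    k <- nrow(heatmaps[[1]]$H)
    rows <- list()
    for (r in radii) {
      sel <- vapply(heatmaps, function(h) h$radius_px == r, logical(1))
      hs <- heatmaps[sel]; cs <- cond[sel]
      for (i in seq_len(k)) for (j in seq_len(k)) {
        vals <- vapply(hs, function(h) h$H[i, j], numeric(1))
        keep <- !is.na(vals)
        if (!all(c("CONTROL", "TREATED") %in% cs[keep])) next
        op <- perm_p(vals[keep], cs[keep])
        rows[[length(rows) + 1L]] <-
          data.frame(radius_px = r, center_class = i - 1L,
                     neighbor_class = j - 1L, diff = op[1],
                     p_value = op[2])
      }
    }
    hm_out <- do.call(rbind, rows)
  }
  pr_out <- NULL
  if (!is.null(reports) && length(reports)) {
    cond <- vapply(reports, function(x) x$condition, character(1))
    if (!all(c("CONTROL", "TREATED") %in% cond))
      stop("both CONTROL and TREATED regions are required")
    radii <- unique(reports[[1]]$summary$radius_px)
    rows <- list()
    for (r in radii) {
      vals <- vapply(reports, function(x)
        x$summary$mean_gh2ax_near[x$summary$radius_px == r], numeric(1))
      op <- perm_p(vals, cond)
      rows[[length(rows) + 1L]] <-
        data.frame(radius_px = r, diff = op[1], p_value = op[2])
    }
    pr_out <- do.call(rbind, rows)
  }
  list(heatmap_diff = hm_out, proximity_diff = pr_out)
}

#' Simulate a region at the cell-table level (no image rendering)
#'
#' Fast point-process stand-in for a segmented region: cell centroids
#' uniform in a box, a fraction gamma-H2AX+, a few CD8+. When
#' \code{gh2ax_near_cd8_boost > 0}, an additional
#' \code{round(boost * n_gh2ax)} gamma-H2AX+ cells are planted within
#' \code{boost_radius_px} of randomly chosen CD8+ cells, emulating
#' damage-immune colocalization. Used for statistical validation of the
#' profiling stage (null calibration and power), where rendering full
#' volumes would add nothing.
#'
#' @param n_cells Total cells.
#' @param shape Region size \code{(z, y, x)} in voxels.
#' @param frac_gh2ax_pos Fraction gamma-H2AX positive.
#' @param n_cd8 Number of CD8+ cells.
#' @param gh2ax_near_cd8_boost Planted-effect size (0 = null).
#' @param boost_radius_px Radius of the planted colocalization.
#' @param condition,region_id,seed Metadata and seed.
#' @return A \code{CellTable}.
#' @export
simulate_region_cells <- function(n_cells = 100L,
                                  shape = c(130, 302, 302),
                                  frac_gh2ax_pos = 0.3, n_cd8 = 8L,
                                  gh2ax_near_cd8_boost = 0,
                                  boost_radius_px = 48,
                                  condition = "UNKNOWN",
                                  region_id = "sim", seed = 1L) {
  set.seed(seed)
  z <- stats::runif(n_cells, 0, shape[1] - 1)
  y <- stats::runif(n_cells, 0, shape[2] - 1)
  x <- stats::runif(n_cells, 0, shape[3] - 1)
  gpos <- rep(FALSE, n_cells)
  gpos[sample.int(n_cells, round(frac_gh2ax_pos * n_cells))] <- TRUE
  cpos <- rep(FALSE, n_cells)
  pool <- which(!gpos)
  if (n_cd8 > 0 && length(pool))
    cpos[pool[sample.int(length(pool), min(n_cd8, length(pool)))]] <- TRUE
  if (gh2ax_near_cd8_boost > 0 && any(cpos)) {
    n_extra <- round(gh2ax_near_cd8_boost * sum(gpos))
    anchors <- which(cpos)
    for (i in seq_len(n_extra)) {
      a <- anchors[1L + (i - 1L) %% length(anchors)]
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      rr <- boost_radius_px * stats::runif(1)^(1 / 3)
      p <- c(z[a], y[a], x[a]) + u * rr
      p <- pmin(pmax(p, 0), shape - 1)
      z <- c(z, p[1]); y <- c(y, p[2]); x <- c(x, p[3])
      gpos <- c(gpos, TRUE); cpos <- c(cpos, FALSE)
    }
  }
  n <- length(z)
  df <- data.frame(cell_id = seq_len(n), centroid_z = z, centroid_y = y,
                   centroid_x = x, z0 = 0L, y0 = 0L, x0 = 0L,
                   z1 = 1L, y1 = 1L, x1 = 1L, voxel_count = 1L,
                   gh2ax_overlap_frac = as.numeric(gpos),
                   cd8_overlap_frac = as.numeric(cpos),
                   gh2ax_pos = gpos, cd8_pos = cpos)
  .as_cell_table(df, condition, region_id, DEFAULT_VOXEL_SIZE_UM)
}
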