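# Synthetic 3D regions with known ground truth.
#
# The generator emulates the curated sub-volumes the pipeline is designed
# for: ellipsoidal nuclei (all visible in DAPI), a subset gamma-H2AX
# positive with planted damage textures (bright foci and/or diffuse
# pan-nuclear signal), and sparse CD8+ cells whose marker sits on the cell
# membrane, rendered as a thin shell just OUTSIDE the nucleus so that the
# dilation step of the CD8 superimposition rule genuinely matters.

#' Specification of one planted damage-texture class
#'
#' Texture classes are the generator's stand-in for the (unannotated)
#' damage/repair subtypes real tissue exhibits: a "focal" class has many
#' small bright foci, a "diffuse" class mostly pan-nuclear signal. At least
#' two classes should differ in \code{foci_count_range} or
#' \code{diffuse_level} for separability tests to be meaningful.
#'
#' @param class_id Integer class identifier.
#' @param foci_count_range Integer \code{c(min, max)} foci per nucleus.
#' @param foci_radius_range Numeric \code{c(min, max)} focus radius, voxels.
#' @param diffuse_level Diffuse nuclear fill level in \code{[0, 1]}
#'   (fraction of the focal peak amplitude).
#' @return A \code{TextureClassSpec} list.
#' @export
texture_class_spec <- function(class_id, foci_count_range = c(5L, 12L),
                               foci_radius_range = c(1, 2),
                               diffuse_level = 0.1) {
  stopifnot(foci_count_range[1] <= foci_count_range[2],
            foci_radius_range[1] <= foci_radius_range[2],
            diffuse_level >= 0, diffuse_level <= 1)
  structure(list(class_id = as.integer(class_id),
                 foci_count_range = as.integer(foci_count_range),
                 foci_radius_range = as.numeric(foci_radius_range),
                 diffuse_level = diffuse_level),
            class = "TextureClassSpec")
}

#' Default planted damage-texture classes
#'
#' The two canonical gamma-H2AX phenotypes: \emph{focal} (8-16 discrete
#' repair foci of radius 1.5-2.5 voxels over a 0.4 pan-nuclear floor) and
#' \emph{pan-nuclear} (focus-free 0.85 fill, as in heavily damaged or
#' apoptotic cells). Both keep an elevated floor so whole-nucleus
#' thresholding detects them; they are far apart in texture space so
#' class-recovery tests are meaningful.
#'
#' @return List of two \code{\link{texture_class_spec}}s.
#' @export
default_texture_classes <- function() {
  list(texture_class_spec(0L, c(8L, 16L), c(1.5, 2.5), 0.4),
       texture_class_spec(1L, c(0L, 0L), c(1, 2), 0.85))
}

#' Specification for one synthetic tissue region
#'
#' Defaults mirror the acquisition the pipeline targets: 302 x 302 x 130
#' voxel sub-volumes holding on the order of 500-900 nuclei (default 700).
#' Tests use much smaller shapes with proportionally fewer nuclei. A
#' minority of nuclei carry gamma-H2AX signal and a handful of cells are
#' CD8+ cytotoxic T cells.
#'
#' @param shape \code{(z, y, x)} region size in voxels.
#' @param n_nuclei Number of nuclei to place (non-overlapping ellipsoids).
#' @param frac_gh2ax_pos Fraction of nuclei that are gamma-H2AX positive.
#' @param n_cd8 Number of CD8+ cells (disjoint from the gamma-H2AX set when
#'   possible).
#' @param texture_classes List of \code{\link{texture_class_spec}}s; planted
#'   classes are assigned to positive nuclei round-robin.
#' @param rng_seed Integer seed; identical specs give voxel-identical
#'   output.
#' @param noise_sd SD of the additive Gaussian background noise.
#' @param voxel_size_um Voxel size metadata for the emitted volumes.
#' @return A \code{SynthSpec} list.
#' @export
synth_spec <- function(shape = c(130L, 302L, 302L), n_nuclei = 700L,
                       frac_gh2ax_pos = 0.1, n_cd8 = 20L,
                       texture_classes = default_texture_classes(),
                       rng_seed = 1L, noise_sd = 0.02,
                       voxel_size_um = DEFAULT_VOXEL_SIZE_UM) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_nuclei >= 1,
            frac_gh2ax_pos >= 0, frac_gh2ax_pos <= 1, n_cd8 >= 0,
            noise_sd >= 0, length(texture_classes) >= 1)
  structure(list(shape = as.integer(shape), n_nuclei = as.integer(n_nuclei),
                 frac_gh2ax_pos = frac_gh2ax_pos, n_cd8 = as.integer(n_cd8),
                 texture_classes = texture_classes,
                 rng_seed = as.integer(rng_seed), noise_sd = noise_sd,
                 voxel_size_um = voxel_size_um),
            class = "SynthSpec")
}

# Ellipsoid interior test on a (z,y,x) coordinate grid, returned as a
# logical array over the given index ranges.
.ellipsoid_mask <- function(zr, yr, xr, center, radii) {
  dz <- (zr - center[1]) / radii[1]
  dy <- (yr - center[2]) / radii[2]
  dx <- (xr - center[3]) / radii[3]
  o <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
  o <= 1
}

# Place n non-overlapping ellipsoids by rejection sampling. Radii are
# jittered per nucleus; overlap is excluded conservatively by a
# center-distance test against the sum of the largest radii.
.place_nuclei <- function(shape, n, rmin = 4, rmax = 10, max_tries = 200L) {
  centers <- matrix(0, 0, 3)
  radii <- matrix(0, 0, 3)
  rmax_eff <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      r <- stats::runif(3, rmin, rmax)
      r[1] <- r[1] * 0.7  # nuclei are flatter along z in sectioned tissue
      if (any(r + 1 > shape - r)) {
        stop("region shape ", paste(shape, collapse = "x"),
             " too small for nucleus radii ~", rmin, "-", rmax)
      }
      c0 <- stats::runif(3, r + 1, shape - r - 1 + 1)
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums(t(t(centers) - c0)^2)) > rmax_eff + max(r))) {
        centers <- rbind(centers, c0)
        radii <- rbind(radii, r)
        rmax_eff <- c(rmax_eff, max(r))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place ", n, " non-overlapping nuclei in a ",
           paste(shape, collapse = "x"), " region; achieved ",
           nrow(centers), " - reduce n_nuclei or enlarge the region")
  }
  list(centers = centers, radii = radii)
}

#' Generate a synthetic annotated 3D region
#'
#' Renders DAPI (all nuclei filled), GH2AX (positive nuclei only, textured
#' per their class spec), and CD8 (1-2 voxel membrane shell around CD8+
#' cells) channels plus the matching instance label volume and a ground
#' truth table. Additive Gaussian noise of sd \code{noise_sd} is applied to
#' every channel and intensities are clamped to \code{[0, 1]}. Output is
#' deterministic given \code{spec$rng_seed}.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @return A list with \code{channels} (named list of
#'   \code{ChannelVolume}s: DAPI, GH2AX, CD8), \code{labels}
#'   (\code{LabelVolume}), and \code{truth} - a data frame with one row per
#'   nucleus (\code{cell_id}, centroid, \code{gh2ax_pos}, \code{cd8_pos},
#'   \code{texture_class_id}) carrying the planted foci voxel indices in
#'   \code{attr(truth, "foci_idx")}.
#' @export
generate_region <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  set.seed(spec$rng_seed)
  d <- spec$shape
  dapi <- array(0, d)
  gh2ax <- array(0, d)
  cd8 <- array(0, d)
  lab <- array(0L, d)

  pl <- .place_nuclei(d, spec$n_nuclei)
  n <- spec$n_nuclei
  n_pos <- round(spec$frac_gh2ax_pos * n)
  pos_ids <- if (n_pos > 0) sample.int(n, n_pos) else integer(0)
  cd8_pool <- setdiff(seq_len(n), pos_ids)
  if (length(cd8_pool) < spec$n_cd8) cd8_pool <- seq_len(n)
  cd8_ids <- if (spec$n_cd8 > 0)
    cd8_pool[sample.int(length(cd8_pool), min(spec$n_cd8, length(cd8_pool)))]
  else integer(0)
  ncls <- length(spec$texture_classes)
  class_of <- rep(NA_integer_, n)
  if (n_pos > 0) {
    cls_idx <- rep_len(seq_len(ncls), n_pos)
    class_of[pos_ids] <- vapply(spec$texture_classes[cls_idx],
                                `[[`, integer(1), "class_id")
  }

  foci_idx <- integer(0)
  for (i in seq_len(n)) {
    c0 <- pl$centers[i, ]; r <- pl$radii[i, ]
    shell_r <- r + 2.2
    zr <- max(1, floor(c0[1] - shell_r[1])):min(d[1], ceiling(c0[1] + shell_r[1]))
    yr <- max(1, floor(c0[2] - shell_r[2])):min(d[2], ceiling(c0[2] + shell_r[2]))
    xr <- max(1, floor(c0[3] - shell_r[3])):min(d[3], ceiling(c0[3] + shell_r[3]))
    inner <- .ellipsoid_mask(zr, yr, xr, c0, r)
    dapi_lvl <- stats::runif(1, 0.55, 0.75)
    blk <- dapi[zr, yr, xr]; blk[inner] <- dapi_lvl; dapi[zr, yr, xr] <- blk
    lblk <- lab[zr, yr, xr]; lblk[inner] <- i; lab[zr, yr, xr] <- lblk

    if (i %in% pos_ids) {
      cls <- spec$texture_classes[[match(class_of[i],
        vapply(spec$texture_classes, `[[`, integer(1), "class_id"))]]
      g <- array(0, dim(inner))
      g[inner] <- cls$diffuse_level * 0.8
      nf_rng <- cls$foci_count_range
      nf <- if (nf_rng[2] > nf_rng[1])
              sample(nf_rng[1]:nf_rng[2], 1) else nf_rng[1]
      if (nf > 0) {
        for (f in seq_len(nf)) {
          # focus center inside the nucleus (rejection on the ellipsoid)
          repeat {
            u <- stats::runif(3, -0.8, 0.8)
            if (sum(u^2) <= 0.64) break
          }
          fc <- c0 + u * r
          fr <- stats::runif(1, cls$foci_radius_range[1],
                             cls$foci_radius_range[2])
          gz <- exp(-0.5 * ((zr - fc[1]) / fr)^2)
          gy <- exp(-0.5 * ((yr - fc[2]) / fr)^2)
          gx <- exp(-0.5 * ((xr - fc[3]) / fr)^2)
          bump <- outer(outer(gz, gy), gx) * 0.85
          g <- pmax(g, bump * inner)
        }
      }
      gblk <- gh2ax[zr, yr, xr]
      gh2ax[zr, yr, xr] <- pmax(gblk, g)
      # planted foci voxels: strong focal signal, for threshold validation
      loc <- which(g >= 0.4)
      if (length(loc)) {
        ai <- arrayInd(loc, dim(g))
        lin <- (zr[ai[, 1]]) + (yr[ai[, 2]] - 1) * d[1] +
               (xr[ai[, 3]] - 1) * d[1] * d[2]
        foci_idx <- c(foci_idx, lin)
      }
    }

    if (i %in% cd8_ids) {
      outer_m <- .ellipsoid_mask(zr, yr, xr, c0, r + 2)
      ring <- outer_m & !.ellipsoid_mask(zr, yr, xr, c0, r + 0.2)
      cblk <- cd8[zr, yr, xr]
      cblk[ring] <- pmax(cblk[ring], stats::runif(1, 0.6, 0.8))
      cd8[zr, yr, xr] <- cblk
    }
  }

  if (spec$noise_sd > 0) {
    nz <- length(dapi)
    dapi <- dapi + stats::rnorm(nz, 0, spec$noise_sd)
    gh2ax <- gh2ax + stats::rnorm(nz, 0, spec$noise_sd)
    cd8 <- cd8 + stats::rnorm(nz, 0, spec$noise_sd)
  }
  clamp <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

  truth <- data.frame(
    cell_id = seq_len(n),
    centroid_z = pl$centers[, 1], centroid_y = pl$centers[, 2],
    centroid_x = pl$centers[, 3],
    gh2ax_pos = seq_len(n) %in% pos_ids,
    cd8_pos = seq_len(n) %in% cd8_ids,
    texture_class_id = class_of)
  attr(truth, "foci_idx") <- unique(foci_idx)

  mk <- function(x, nm) channel_volume(clamp(x), nm, spec$voxel_size_um)
  list(channels = list(DAPI = mk(dapi, "DAPI"), GH2AX = mk(gh2ax, "GH2AX"),
                       CD8 = mk(cd8, "CD8")),
       labels = label_volume(lab),
       truth = truth)
}

# Render one 64x64 2D nucleus patch of a given texture class: elliptical
# nucleus, class-dependent foci/diffuse signal, noise, background zeroed
# (as extract_patch() would) and min-max scaled to [0,1].
.render_patch <- function(cls, size = 64L, noise_sd = 0.02) {
  r <- stats::runif(2, size * 0.22, size * 0.38)
  c0 <- size / 2 + stats::runif(2, -2, 2)
  yy <- seq_len(size); xx <- seq_len(size)
  inner <- outer(((yy - c0[1]) / r[1])^2, ((xx - c0[2]) / r[2])^2, "+") <= 1
  g <- matrix(0, size, size)
  g[inner] <- cls$diffuse_level * 0.8
  nf_rng <- cls$foci_count_range
  nf <- if (nf_rng[2] > nf_rng[1]) sample(nf_rng[1]:nf_rng[2], 1) else nf_rng[1]
  # 2D focus radius scaled up: patches are resized views of whole nuclei
  fscale <- size / 16
  if (nf > 0) for (f in seq_len(nf)) {
    repeat {
      u <- stats::runif(2, -0.8, 0.8)
      if (sum(u^2) <= 0.64) break
    }
    fc <- c0 + u * r
    fr <- stats::runif(1, cls$foci_radius_range[1],
                       cls$foci_radius_range[2]) * fscale / 2
    bump <- outer(exp(-0.5 * ((yy - fc[1]) / fr)^2),
                  exp(-0.5 * ((xx - fc[2]) / fr)^2)) * 0.85
    g <- pmax(g, bump * inner)
  }
  g <- g + stats::rnorm(size * size, 0, noise_sd)
  g[!inner] <- 0
  g[g < 0] <- 0
  rng <- range(g)
  if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else g * 0
}

#' Generate a labelled bank of 64x64 texture patches
#'
#' Training/evaluation fuel for the texture branches: balanced classes,
#' values in \code{[0, 1]}, deterministic under \code{seed}.
#'
#' @param class_specs List of \code{\link{texture_class_spec}}s.
#' @param n_per_class Patches per class.
#' @param seed Integer seed.
#' @param size Patch side length (default 64).
#' @param noise_sd Additive noise sd before rescaling.
#' @return List with \code{patches} (list of \code{size x size} matrices)
#'   and \code{labels} (integer class_id per patch).
#' @export
generate_patch_bank <- function(class_specs, n_per_class, seed = 1L,
                                size = 64L, noise_sd = 0.02) {
  stopifnot(n_per_class >= 1, length(class_specs) >= 1)
  set.seed(seed)
  patches <- list(); labels <- integer(0)
  for (cls in class_specs) {
    for (i in seq_len(n_per_class)) {
      patches[[length(patches) + 1L]] <- .render_patch(cls, size, noise_sd)
      labels <- c(labels, cls$class_id)
    }
  }
  list(patches = patches, labels = labels)
}
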