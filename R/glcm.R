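# Gray-level co-occurrence matrix (GLCM) texture features.
#
# The GLCM is a second-order statistic: after quantizing a patch to
# n_levels gray levels, it counts how often a pair of levels (i, j)
# co-occurs at a fixed pixel offset. Four Haralick-style summary features
# are used: energy, contrast, cluster prominence, and correlation. These
# react to foci-like (sparse, high-contrast) versus diffuse (smooth)
# gamma-H2AX staining in complementary ways.

#' GLCM computation settings
#'
#' @param n_levels Gray quantization levels (>= 2, default 32 - fine enough
#'   to resolve foci on 64x64 patches without starving the pair counts).
#' @param distances Integer pixel offsets (default 1).
#' @param angles Offset directions in radians; default the standard 4-angle
#'   set \code{0, pi/4, pi/2, 3pi/4}, making the averaged matrix
#'   approximately rotation-insensitive.
#' @param symmetric Add the transpose before normalizing (default TRUE).
#' @param normalized Normalize each matrix to sum 1 (default TRUE).
#' @param exclude_background Drop pairs in which either pixel is at level
#'   0 (the masked-background gray level) before normalizing. Off by
#'   default: background pixels form a legitimate gray level and their
#'   pairs carry nucleus-shape information.
#' @return A \code{GLCMConfig} list.
#' @export
glcm_config <- function(n_levels = 32L, distances = 1L,
                        angles = c(0, pi / 4, pi / 2, 3 * pi / 4),
                        symmetric = TRUE, normalized = TRUE,
                        exclude_background = FALSE) {
  stopifnot(n_levels >= 2, all(distances >= 1))
  structure(list(n_levels = as.integer(n_levels),
                 distances = as.integer(distances), angles = angles,
                 symmetric = symmetric, normalized = normalized,
                 exclude_background = exclude_background),
            class = "GLCMConfig")
}

#' Quantize a [0,1] image to integer gray levels
#'
#' \code{level = min(floor(v * n_levels), n_levels - 1)}; monotone in v,
#' 0 maps to level 0 and 1 to the top level.
#'
#' @param patch Numeric matrix with values in \code{[0, 1]}.
#' @param n_levels Number of levels.
#' @return Integer matrix with values in \code{0 .. n_levels - 1}.
#' @export
quantize_gray <- function(patch, n_levels = 32L) {
  if (any(patch < 0) || any(patch > 1))
    stop("patch values must lie in [0, 1]")
  q <- pmin(floor(patch * n_levels), n_levels - 1L)
  storage.mode(q) <- "integer"
  q
}

# Pair counting for one (dy, dx) offset on a quantized patch; returns the
# raw count matrix (i = level at s, j = level at s + offset).
.glcm_one_offset <- function(q, dy, dx, n_levels) {
  d <- dim(q)
  if (d[1] <= abs(dy) || d[2] <= abs(dx)) return(NULL)
  ys <- max(1, 1 - dy):min(d[1], d[1] - dy)
  xs <- max(1, 1 - dx):min(d[2], d[2] - dx)
  i <- q[ys, xs, drop = FALSE]
  j <- q[ys + dy, xs + dx, drop = FALSE]
  counts <- tabulate(as.vector(i) * n_levels + as.vector(j) + 1L,
                     nbins = n_levels^2)
  matrix(counts, n_levels, n_levels, byrow = TRUE)
}

#' Gray-level co-occurrence matrix of a quantized patch
#'
#' Counts level pairs at every configured (distance, angle) offset, with
#' offset \code{(dy, dx) = (round(d sin a), round(d cos a))}, optionally
#' symmetrizes (adds the transpose) and normalizes each matrix, then
#' averages over offsets.
#'
#' @param qpatch Integer matrix from \code{\link{quantize_gray}}.
#' @param cfg A \code{\link{glcm_config}}.
#' @return \code{n_levels x n_levels} matrix (rows = first level).
#' @export
glcm_cooccurrence <- function(qpatch, cfg = glcm_config()) {
  stopifnot(inherits(cfg, "GLCMConfig"))
  if (any(qpatch < 0) || any(qpatch >= cfg$n_levels))
    stop("quantized values out of range for n_levels = ", cfg$n_levels)
  mats <- list()
  for (d in cfg$distances) for (a in cfg$angles) {
    dy <- round(d * sin(a)); dx <- round(d * cos(a))
    m <- .glcm_one_offset(qpatch, dy, dx, cfg$n_levels)
    if (is.null(m)) next
    if (isTRUE(cfg$exclude_background)) {
      m[1, ] <- 0
      m[, 1] <- 0
    }
    if (sum(m) == 0) next
    if (cfg$symmetric) m <- m + t(m)
    if (cfg$normalized) m <- m / sum(m)
    mats[[length(mats) + 1L]] <- m
  }
  if (length(mats) == 0L)
    stop("no co-occurring pairs: patch too small for every configured ",
         "offset (or all pairs excluded as background)")
  Reduce(`+`, mats) / length(mats)
}

#' Haralick features of a normalized co-occurrence matrix
#'
#' With 0-based level indices i, j, marginal means \eqn{\mu_i, \mu_j} and
#' SDs \eqn{\sigma_i, \sigma_j}:
#' energy \eqn{= \sum p(i,j)^2}; contrast \eqn{= \sum (i-j)^2 p(i,j)};
#' cluster prominence \eqn{= \sum (i+j-\mu_i-\mu_j)^4 p(i,j)};
#' correlation \eqn{= \sum (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i\sigma_j)}.
#' A degenerate matrix (zero marginal variance, e.g. from a constant
#' image) has correlation defined as 1, the perfectly-correlated limit.
#'
#' @param p Normalized non-negative matrix (sum 1 within 1e-8).
#' @return Named numeric vector \code{energy}, \code{contrast},
#'   \code{prominence}, \code{correlation}.
#' @export
glcm_features <- function(p) {
  if (any(p < 0)) stop("co-occurrence matrix must be non-negative")
  if (abs(sum(p) - 1) > 1e-8)
    stop("co-occurrence matrix must be normalized to sum 1")
  n <- nrow(p)
  lev <- 0:(n - 1)
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj)
  var_i <- sum((lev - mu_i)^2 * pi_); var_j <- sum((lev - mu_j)^2 * pj)
  I <- matrix(lev, n, n); J <- matrix(lev, n, n, byrow = TRUE)
  energy <- sum(p^2)
  contrast <- sum((I - J)^2 * p)
  prominence <- sum((I + J - mu_i - mu_j)^4 * p)
  s <- sqrt(var_i * var_j)
  correlation <- if (s == 0) 1 else sum((I - mu_i) * (J - mu_j) * p) / s
  c(energy = energy, contrast = contrast, prominence = prominence,
    correlation = correlation)
}

#' GLCM feature table for a bank of patches
#'
#' Quantizes each patch, computes its averaged co-occurrence matrix and
#' the four features. Patches that fail (e.g. too small for the offsets)
#' are skipped with a message rather than aborting the batch.
#'
#' @param patches A \code{PatchBank} (named list of \code{[0,1]} matrices)
#'   or plain list; names become \code{cell_id}s.
#' @param cfg A \code{\link{glcm_config}}.
#' @return \code{FeatureTable} data frame: \code{cell_id}, \code{energy},
#'   \code{contrast}, \code{prominence}, \code{correlation}.
#' @export
glcm_table <- function(patches, cfg = glcm_config()) {
  stopifnot(length(patches) >= 1)
  ids <- names(patches)
  if (is.null(ids)) ids <- as.character(seq_along(patches))
  rows <- vector("list", length(patches))
  for (k in seq_along(patches)) {
    f <- tryCatch({
      q <- quantize_gray(patches[[k]], cfg$n_levels)
      glcm_features(glcm_cooccurrence(q, cfg))
    }, error = function(e) {
      message("patch ", ids[k], " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(f))
      rows[[k]] <- data.frame(cell_id = ids[k], energy = f["energy"],
                              contrast = f["contrast"],
                              prominence = f["prominence"],
                              correlation = f["correlation"],
                              row.names = NULL)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  class(out) <- c("FeatureTable", "data.frame")
  out
}
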