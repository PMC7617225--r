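#' @keywords internal
"_PACKAGE"

# Canonical channel names used throughout the package.
CHANNEL_NAMES <- c("DAPI", "GH2AX", "CD8", "PAN")

# Lateral pixel pitch implied by the acquisition used for all defaults:
# 32 px correspond to 10.28 um, i.e. 0.32125 um per pixel.
DEFAULT_VOXEL_SIZE_UM <- c(z = 0.32125, y = 0.32125, x = 0.32125)

#' Single-channel 3D fluorescence volume
#'
#' Container for one named fluorescence channel as a 3D intensity array.
#' The axis convention is \code{(z, y, x)} everywhere in this package:
#' \code{data[z, y, x]}, with \code{z} the optical-section (depth) axis.
#' Intensities are finite, non-negative, and by pipeline convention scaled
#' to \code{[0, 1]} before being written to disk.
#'
#' @param data 3D numeric array indexed \code{(z, y, x)}.
#' @param channel_name One of \code{"DAPI"}, \code{"GH2AX"}, \code{"CD8"},
#'   \code{"PAN"}.
#' @param voxel_size_um Numeric length-3 vector \code{(z, y, x)} of voxel
#'   edge lengths in micrometers. Defaults to isotropic 0.32125 um, the
#'   lateral pitch at which 32 px span 10.28 um. The z step of a stack is
#'   acquisition-dependent and should be overridden when known.
#' @return An object of class \code{ChannelVolume}: a list with elements
#'   \code{data}, \code{channel_name}, \code{voxel_size_um}.
#' @export
channel_volume <- function(data, channel_name,
                           voxel_size_um = DEFAULT_VOXEL_SIZE_UM) {
  channel_name <- match.arg(channel_name, CHANNEL_NAMES)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("ChannelVolume data must be a 3D array indexed (z, y, x); got ",
         paste(dim(data), collapse = "x"))
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be non-negative")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive values (z, y, x)")
  names(voxel_size_um) <- c("z", "y", "x")
  structure(list(data = data, channel_name = channel_name,
                 voxel_size_um = voxel_size_um),
            class = "ChannelVolume")
}

#' @export
print.ChannelVolume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ChannelVolume <%s> %d x %d x %d (z,y,x), voxel %s um\n",
              x$channel_name, d[1], d[2], d[3],
              paste(signif(x$voxel_size_um, 6), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Instance label volume for segmented nuclei
#'
#' 3D integer array with the same \code{(z, y, x)} convention as
#' \code{\link{channel_volume}}. 0 is background; each positive value is
#' one nucleus instance. IDs need not be contiguous. Typically produced by
#' an external instance segmenter (e.g. Cellpose on the DAPI channel) and
#' consumed here as input.
#'
#' @param labels 3D array of non-negative integers.
#' @return An object of class \code{LabelVolume}.
#' @export
label_volume <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array indexed (z, y, x)")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers (0 = background); ",
         "cast floating-point label maps explicitly first")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "LabelVolume")
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("LabelVolume %d x %d x %d (z,y,x), %d instances\n",
              d[1], d[2], d[3], length(ids)))
  invisible(x)
}

# ---- TIFF I/O --------------------------------------------------------------

# Stack a list of y-by-x slices into a (z,y,x) array.
.slices_to_array <- function(slices) {
  d <- dim(slices[[1]])
  a <- array(0, c(length(slices), d[1], d[2]))
  for (k in seq_along(slices)) a[k, , ] <- slices[[k]]
  a
}

#' Read a 3D (or multi-channel 4D) TIFF stack as a ChannelVolume
#'
#' Plain multi-page TIFFs are read as z-stacks. Multi-channel files are
#' supported when the plane interleaving is declared explicitly through
#' \code{channels}: planes are assumed ordered z-major with channels
#' fastest (z1c1, z1c2, ..., z2c1, ...), which is how
#' \code{\link{write_volume}} writes them. Channel order is never guessed
#' from TIFF metadata.
#'
#' @param path TIFF file path.
#' @param channel_name Which channel this volume represents (and, for
#'   multi-channel files, which channel to extract).
#' @param voxel_size_um Voxel size metadata attached to the result.
#' @param channels Optional character vector declaring the channel order of
#'   a multi-channel file, e.g. \code{c("DAPI", "GH2AX", "CD8")}. \code{NULL}
#'   (default) treats the file as single-channel.
#' @return A \code{\link{channel_volume}}.
#' @export
read_volume <- function(path, channel_name,
                        voxel_size_um = DEFAULT_VOXEL_SIZE_UM,
                        channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  if (any(!vapply(slices, is.matrix, logical(1))))
    stop("expected 2D grayscale planes; got a non-3D payload in ", path)
  if (!is.null(channels)) {
    nc <- length(channels)
    if (length(slices) %% nc != 0L)
      stop("plane count ", length(slices),
           " is not a multiple of declared channel count ", nc)
    ci <- match(channel_name, channels)
    if (is.na(ci))
      stop("channel ", channel_name, " not in declared order: ",
           paste(channels, collapse = ", "))
    slices <- slices[seq(ci, length(slices), by = nc)]
  }
  channel_volume(.slices_to_array(slices), channel_name, voxel_size_um)
}

#' Write one or several channels to a multi-page TIFF
#'
#' Single \code{ChannelVolume}s become plain z-stacks; a named list of
#' volumes is written z-major with channels interleaved fastest, the order
#' being the order of the list (declare the same order to
#' \code{\link{read_volume}}). Intensities must be in \code{[0, 1]} and are
#' stored as 16-bit samples.
#'
#' @param volume A \code{ChannelVolume} or a list of them (same shape).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path) {
  vols <- if (inherits(volume, "ChannelVolume")) list(volume) else volume
  if (!all(vapply(vols, inherits, logical(1), "ChannelVolume")))
    stop("volume must be a ChannelVolume or list of ChannelVolumes")
  d <- dim(vols[[1]]$data)
  slices <- vector("list", d[1] * length(vols))
  i <- 0L
  for (z in seq_len(d[1])) {
    for (v in vols) {
      if (!identical(dim(v$data), d)) stop("channel shapes differ")
      if (max(v$data) > 1) stop("intensities must be scaled to [0,1] ",
                                "before writing")
      i <- i + 1L
      slices[[i]] <- v$data[z, , ]
    }
  }
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an instance label volume from a 16-bit integer TIFF
#'
#' Values are preserved exactly (no intensity rescaling). Floating-point
#' payloads are rejected: label maps must be integer-typed.
#'
#' @param path TIFF file written by \code{\link{write_labels}} (or any
#'   unsigned-integer multi-page TIFF).
#' @return A \code{\link{label_volume}}.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  vals <- unlist(lapply(slices, as.vector), use.names = FALSE)
  if (any(vals != round(vals)))
    stop("label TIFF has a floating-point payload; cast labels to ",
         "integers explicitly before use")
  label_volume(.slices_to_array(slices))
}

#' Write an instance label volume as a 16-bit TIFF
#'
#' Bit-exact round trip for IDs up to 65535 (an error above that).
#'
#' @param labels A \code{LabelVolume}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "LabelVolume"))
  mx <- max(labels$labels)
  if (mx > 65535L) stop("label IDs above 65535 cannot be stored as 16-bit")
  d <- dim(labels$labels)
  slices <- lapply(seq_len(d[1]), function(z) labels$labels[z, , ] / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  invisible(path)
}

# ---- Tables ----------------------------------------------------------------

#' Write a per-cell table as CSV with a JSON metadata sidecar
#'
#' All tabular outputs (cell tables, feature tables, neighborhood profiles,
#' reports) are plain CSV; metadata carried as attributes (\code{condition},
#' \code{region_id}, \code{voxel_size_um}, and any others in
#' \code{attr(x, "meta")}) goes to \code{<path>.json}. Floats keep full
#' precision (>= 6 significant digits); integers and flags round-trip
#' losslessly.
#'
#' @param table A data frame.
#' @param path Output CSV path (sidecar written next to it).
#' @return \code{path}, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  meta <- list(condition = attr(table, "condition"),
               region_id = attr(table, "region_id"),
               voxel_size_um = attr(table, "voxel_size_um"))
  extra <- attr(table, "meta")
  if (!is.null(extra)) meta <- c(meta, extra)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a CSV table written by \code{\link{write_table}}
#'
#' @param path CSV path; the JSON sidecar, if present, is reattached as
#'   attributes.
#' @return A data frame.
#' @export
read_table_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in names(meta)) attr(x, nm) <- meta[[nm]]
  }
  x
}

#' Convert lateral pixel distances to micrometers
#'
#' Radii and distances in this package are quoted in lateral pixels; this
#' maps them to micrometers using the lateral (y/x) voxel size. At the
#' default pitch of 0.32125 um/px, 32 px is 10.28 um and 64 px is 20.56 um.
#'
#' @param px Numeric vector of distances in lateral pixels.
#' @param voxel_size_um \code{(z, y, x)} voxel size; the y entry is used
#'   (y and x are assumed equal; an error otherwise).
#' @return Distances in micrometers.
#' @export
px_to_um <- function(px, voxel_size_um = DEFAULT_VOXEL_SIZE_UM) {
  v <- as.numeric(voxel_size_um)
  if (length(v) != 3L) stop("voxel_size_um must have 3 entries (z, y, x)")
  if (abs(v[2] - v[3]) > 1e-12)
    stop("anisotropic lateral voxel sizes are not supported")
  px * v[2]
}
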