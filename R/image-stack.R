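#' Multi-channel 3D image stack
#'
#' Container for a multi-channel confocal volume. Voxels are stored as a 4-D
#' numeric array in `(channel, z, y, x)` order; the physical voxel size is
#' carried as a `(z, y, x)` triple in micrometres so that anisotropic
#' acquisitions (e.g. 2.5 um optical sections over 0.5 um lateral pixels)
#' keep all downstream volumes and distances in physical units.
#'
#' The coordinate convention is fixed throughout the package: the centre of
#' the voxel with (1-based) index `i` along an axis with voxel size `v` lies
#' at `(i - 0.5) * v` micrometres.
#'
#' @param voxels 4-D numeric array, dimensions `(channel, z, y, x)`.
#' @param voxel_size_um positive numeric triple `(z, y, x)`, micrometres.
#' @param channel_names character vector, one unique name per channel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size_um, channel_names) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    stop_gq("`voxels` must be a 4-D array (channel, z, y, x)")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop_gq("`voxel_size_um` must be a positive (z, y, x) triple")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(voxels)[1L])
    stop_gq("need one channel name per channel")
  if (anyDuplicated(channel_names))
    stop_gq("channel names must be unique")
  structure(
    list(voxels = voxels, voxel_size_um = voxel_size_um,
         channel_names = channel_names),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d channel(s) [%s], %d x %d x %d voxels (z,y,x)\n",
              d[1L], paste(x$channel_names, collapse = ", "),
              d[2L], d[3L], d[4L]))
  cat(sprintf("voxel size (um): %s; field extent (um): %s\n",
              paste(format(x$voxel_size_um), collapse = " x "),
              paste(format(x$voxel_size_um * d[2:4]), collapse = " x ")))
  invisible(x)
}

#' Extract one channel of a stack as a 3-D array
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return 3-D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(channel, stack$channel_names)
  if (is.na(i)) stop_gq("no channel named '", channel, "'")
  d <- dim(stack$voxels)
  array(stack$voxels[i, , , ], dim = d[2:4])
}

#' Physical volume of one voxel in cubic micrometres
#' @param x an [image_stack()] or [labeled_mask()].
#' @return scalar, um^3.
#' @export
voxel_volume_um3 <- function(x) prod(x$voxel_size_um)

# Separable Gaussian blur of a 3-D array; sigma given per axis in voxels.
# Each axis is convolved via a row-normalised dense kernel matrix (axis
# lengths here are at most a few hundred, so the matrix product is fast and
# handles edge renormalisation exactly).
blur_gaussian_3d <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    L <- dim(arr)[axis]
    if (s <= 0 || L == 1L) next
    idx <- seq_len(L)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(arr, perm)
    m <- K %*% matrix(ap, nrow = L)
    dim(m) <- dim(ap)
    arr <- aperm(m, order(perm))
  }
  arr
}

#' Global Otsu threshold of an intensity volume
#'
#' Maximises the between-class variance of the global intensity histogram
#' (256 bins over the data range). Unlike per-slice thresholding, a single
#' global threshold keeps object volumes consistent across z.
#'
#' @param x numeric array or vector of intensities.
#' @param levels number of histogram bins.
#' @return scalar threshold; voxels strictly above it are foreground. For a
#'   constant image the constant itself is returned (empty foreground).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1L]) || r[1L] == r[2L]) return(r[1L])
  breaks <- seq(r[1L], r[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  between <- (mu[levels] * w - mu)^2 / (w * (1 - w))
  between[!is.finite(between)] <- 0
  breaks[which.max(between) + 1L]
}

#' Write / read a stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered z-major, channel-minor (Z,C,Y,X). Intensities are
#' rescaled to `[0, 1]` for storage; the original range, voxel size and
#' channel names are recorded in `<path>.json` and restored on read.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  rng <- range(stack$voxels)
  span <- if (rng[2L] > rng[1L]) rng[2L] - rng[1L] else 1
  pages <- vector("list", d[1L] * d[2L])
  p <- 0L
  for (z in seq_len(d[2L])) for (ch in seq_len(d[1L])) {
    p <- p + 1L
    pages[[p]] <- (matrix(stack$voxels[ch, z, , ], d[3L], d[4L]) - rng[1L]) / span
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axes = "ZCYX", dim_zcyx = c(d[2L], d[1L], d[3L], d[4L]),
               voxel_size_um = stack$voxel_size_um,
               channel_names = stack$channel_names,
               intensity_range = rng)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dim_zcyx  # (z, c, y, x)
  vox <- array(0, dim = c(d[2L], d[1L], d[3L], d[4L]))
  p <- 0L
  for (z in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    p <- p + 1L
    vox[ch, z, , ] <- pages[[p]]
  }
  rng <- meta$intensity_range
  span <- if (rng[2L] > rng[1L]) rng[2L] - rng[1L] else 1
  vox <- vox * span + rng[1L]
  image_stack(vox, meta$voxel_size_um, meta$channel_names)
}
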