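# Small, fast simulation fixtures shared across test files. All fixtures are
# generated in code at test time with fixed seeds.

small_engulfment_params <- function(engulfed_fraction = 0.3, seed = 1L, ...) {
  engulfment_sim_params(field_shape_voxels = c(16L, 64L, 64L),
                        voxel_size_um = c(1.0, 0.5, 0.5),
                        n_glia = 2L, glia_radius_um = 6,
                        n_puncta = 40L, punctum_radius_um = 0.8,
                        engulfed_fraction = engulfed_fraction,
                        lysosomal_fraction_of_engulfed = 0.5,
                        snr = 10, psf_sigma_um = 0.3, seed = seed, ...)
}

# A stack holding a single voxelised sphere in one channel.
sphere_stack <- function(centre_um, radius_um,
                         dims = c(16L, 48L, 48L),
                         voxel = c(1.0, 0.5, 0.5),
                         channel = "glia") {
  arr <- array(0, dim = dims)
  zc <- (seq_len(dims[1]) - 0.5) * voxel[1]
  yc <- (seq_len(dims[2]) - 0.5) * voxel[2]
  xc <- (seq_len(dims[3]) - 0.5) * voxel[3]
  d2 <- outer(outer((zc - centre_um[1])^2, (yc - centre_um[2])^2, "+"),
              (xc - centre_um[3])^2, "+")
  arr[d2 <= radius_um^2] <- 1
  vox <- array(arr, dim = c(1L, dims))
  image_stack(vox, voxel, channel)
}

# Hand-built annotated puncta table for scoring unit tests.
toy_puncta <- function(volumes, channels, location, in_lysosome = NULL) {
  n <- length(volumes)
  if (is.null(in_lysosome)) in_lysosome <- rep(FALSE, n)
  df <- data.frame(id = seq_len(n), z_um = 0, y_um = 0, x_um = 0,
                   volume_um3 = volumes)
  df$channels <- channels
  df$location <- location
  df$glia_label <- ifelse(location == "inside", 1L, NA_integer_)
  df$in_lysosome <- in_lysosome
  df
}
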