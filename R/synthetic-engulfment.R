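#' Parameters for the synthetic engulfment-reporter field
#'
#' Describes one simulated confocal field of the mCherry-eGFP phagocytosis
#' reporter: glial cells (spheres, one interior lysosome blob each) and
#' synaptic puncta (smaller spheres). A planted fraction of puncta is
#' engulfed (centre inside a glial cell); a planted fraction of the engulfed
#' puncta sits inside the lysosome, where the acidic environment quenches
#' eGFP while mCherry persists, so those puncta emit mCherry but no GFP.
#' Both fractions are applied by deterministic rounding
#' (`round(n * fraction)`), not Bernoulli draws, so small fixtures have exact
#' planted counts.
#'
#' @param field_shape_voxels integer `(z, y, x)` triple.
#' @param voxel_size_um positive `(z, y, x)` triple, micrometres.
#' @param n_glia,glia_radius_um number and radius of glial spheres.
#' @param n_puncta,punctum_radius_um number and radius of synaptic puncta.
#' @param engulfed_fraction fraction of puncta planted inside glia, in
#'   `[0, 1]`.
#' @param lysosomal_fraction_of_engulfed fraction of engulfed puncta planted
#'   inside the glial lysosome (GFP quenched), in `[0, 1]`.
#' @param snr peak-signal-to-noise ratio; additive Gaussian noise with
#'   `sd = peak / snr` is applied after blurring. `Inf` disables noise.
#' @param psf_sigma_um isotropic Gaussian blur sigma emulating the point
#'   spread function; `0` disables blurring.
#' @param seed integer seed for the generator's private RNG stream.
#' @return A validated parameter list of class `engulfment_sim_params`.
#' @export
engulfment_sim_params <- function(field_shape_voxels = c(24L, 96L, 96L),
                                  voxel_size_um = c(1.0, 0.5, 0.5),
                                  n_glia = 4L,
                                  glia_radius_um = 7,
                                  n_puncta = 120L,
                                  punctum_radius_um = 0.8,
                                  engulfed_fraction = 0.3,
                                  lysosomal_fraction_of_engulfed = 0.6,
                                  snr = 10,
                                  psf_sigma_um = 0.3,
                                  seed = 1L) {
  p <- list(field_shape_voxels = as.integer(field_shape_voxels),
            voxel_size_um = as.numeric(voxel_size_um),
            n_glia = as.integer(n_glia),
            glia_radius_um = as.numeric(glia_radius_um),
            n_puncta = as.integer(n_puncta),
            punctum_radius_um = as.numeric(punctum_radius_um),
            engulfed_fraction = as.numeric(engulfed_fraction),
            lysosomal_fraction_of_engulfed =
              as.numeric(lysosomal_fraction_of_engulfed),
            snr = as.numeric(snr),
            psf_sigma_um = as.numeric(psf_sigma_um),
            seed = as.integer(seed))
  if (length(p$field_shape_voxels) != 3L || any(p$field_shape_voxels < 1L))
    stop_gq("`field_shape_voxels` must be a positive (z, y, x) triple")
  if (length(p$voxel_size_um) != 3L || any(p$voxel_size_um <= 0))
    stop_gq("`voxel_size_um` must be a positive (z, y, x) triple")
  if (p$glia_radius_um <= 0 || p$punctum_radius_um <= 0)
    stop_gq("radii must be positive")
  if (p$engulfed_fraction < 0 || p$engulfed_fraction > 1 ||
      p$lysosomal_fraction_of_engulfed < 0 ||
      p$lysosomal_fraction_of_engulfed > 1)
    stop_gq("fractions must lie in [0, 1]")
  if (p$snr <= 0) stop_gq("`snr` must be positive")
  if (p$psf_sigma_um < 0) stop_gq("`psf_sigma_um` must be nonnegative")
  if (p$n_glia < 0 || p$n_puncta < 0) stop_gq("counts must be nonnegative")
  # field must be able to hold a glial sphere away from every face
  extent <- p$field_shape_voxels * p$voxel_size_um
  pad <- max(p$voxel_size_um)
  if (p$n_glia > 0 && any(extent < 2 * (p$glia_radius_um + pad)))
    stop_gq("field too small to contain a glial cell of radius ",
            p$glia_radius_um, " um")
  class(p) <- "engulfment_sim_params"
  p
}

# Uniform point in a ball of radius r around `centre` (3-vector).
runif_ball <- function(centre, r) {
  repeat {
    u <- runif(3, -r, r)
    if (sum(u^2) <= r^2) return(centre + u)
  }
}

# Rasterise a sphere on the voxel-centre grid; returns linear indices into
# an array of dims `d` (z,y,x) with voxel sizes `v`.
sphere_voxels <- function(centre, radius, d, v) {
  lo <- pmax(1L, floor((centre - radius) / v - 0.5) + 1L)
  hi <- pmin(d, ceiling((centre + radius) / v + 0.5))
  if (any(lo > hi)) return(integer(0))
  iz <- lo[1L]:hi[1L]; iy <- lo[2L]:hi[2L]; ix <- lo[3L]:hi[3L]
  dz2 <- ((iz - 0.5) * v[1L] - centre[1L])^2
  dy2 <- ((iy - 0.5) * v[2L] - centre[2L])^2
  dx2 <- ((ix - 0.5) * v[3L] - centre[3L])^2
  g <- outer(outer(dz2, dy2, "+"), dx2, "+") <= radius^2
  if (!any(g)) return(integer(0))
  sub <- which(g, arr.ind = TRUE)
  (iz[sub[, 1L]]) + d[1L] * ((iy[sub[, 2L]] - 1L) + d[2L] * (ix[sub[, 3L]] - 1L))
}

# Rejection-sample a point satisfying `ok(point)`; bounded retries.
place_point <- function(draw, ok, max_tries = 4000L, what = "object") {
  for (i in seq_len(max_tries)) {
    pt <- draw()
    if (ok(pt)) return(pt)
  }
  stop_gq("placement error: could not place ", what, " after ",
          max_tries, " tries; the field is too crowded for the requested ",
          "geometry")
}

min_dist2 <- function(pt, pts) {
  if (nrow(pts) == 0L) return(Inf)
  min((pts[, 1L] - pt[1L])^2 + (pts[, 2L] - pt[2L])^2 +
        (pts[, 3L] - pt[3L])^2)
}

#' Generate a synthetic engulfment-reporter stack with ground truth
#'
#' Builds a 4-channel [image_stack()] (`glia`, `lysosome`, `mCherry`, `GFP`)
#' from [engulfment_sim_params()]. Before blur and noise every punctum emits
#' unit mCherry; puncta planted inside the lysosome emit zero GFP (the
#' quenching rule), all others emit unit GFP. Engulfed punctum centres lie
#' strictly inside a glial sphere, non-engulfed centres strictly outside all
#' of them. The returned ground truth records the exact planted geometry and
#' the engulfment quantities it implies, recomputed by brute force from the
#' emitted voxel masks.
#'
#' @param params an [engulfment_sim_params()] object.
#' @return list with elements `stack` ([image_stack()]) and `truth`
#'   (class `ground_truth`: `glia_labels` integer array, `lysosome_mask`
#'   logical array, `puncta_labels` integer array, `puncta` data frame with
#'   planted flags, and `planted_scores`).
#' @export
generate_engulfment_stack <- function(params) {
  stopifnot(inherits(params, "engulfment_sim_params"))
  p <- params
  d <- p$field_shape_voxels
  v <- p$voxel_size_um
  extent <- d * v
  pad <- max(v)

  with_seed(p$seed, {
    ## --- glial spheres + one interior lysosome blob each ---------------
    glia <- matrix(0, 0L, 3L)
    for (i in seq_len(p$n_glia)) {
      c_i <- place_point(
        draw = function() vapply(1:3, function(a)
          runif(1, p$glia_radius_um + pad, extent[a] - p$glia_radius_um - pad),
          0),
        ok = function(pt) min_dist2(pt, glia) > (2 * p$glia_radius_um + pad)^2,
        what = "glial cell")
      glia <- rbind(glia, c_i)
    }
    lys_radius <- 0.55 * p$glia_radius_um
    lys <- matrix(0, 0L, 3L)
    for (i in seq_len(p$n_glia)) {
      off_max <- p$glia_radius_um - lys_radius - 0.5 * max(v)
      lys <- rbind(lys, runif_ball(glia[i, ], max(off_max, 0)))
    }

    ## --- puncta: lysosomal, then other engulfed, then outside ----------
    n_eng <- round(p$n_puncta * p$engulfed_fraction)
    n_lys <- round(n_eng * p$lysosomal_fraction_of_engulfed)
    # Separation keeping blurred puncta resolvable; inside the small
    # lysosome blob only hard non-overlap is enforced.
    sep_main <- 2 * (p$punctum_radius_um + p$psf_sigma_um) + max(v)
    sep_lys <- 2 * p$punctum_radius_um + 0.2

    centres <- matrix(0, 0L, 3L)
    glia_of <- integer(0)
    if (n_eng > 0 && p$n_glia == 0L)
      stop_gq("cannot plant engulfed puncta without glia")
    host <- if (n_eng > 0) rep_len(seq_len(p$n_glia), n_eng) else integer(0)
    for (j in seq_len(n_lys)) {
      g <- host[j]
      r_in <- lys_radius - p$punctum_radius_um - 0.1
      if (r_in <= 0)
        stop_gq("placement error: lysosome too small for puncta of radius ",
                p$punctum_radius_um)
      c_j <- place_point(
        draw = function() runif_ball(lys[g, ], r_in),
        ok = function(pt) min_dist2(pt, centres) > sep_lys^2,
        what = "lysosomal punctum")
      centres <- rbind(centres, c_j); glia_of <- c(glia_of, g)
    }
    for (j in seq_len(n_eng - n_lys)) {
      g <- host[n_lys + j]
      r_in <- p$glia_radius_um - p$punctum_radius_um - 0.1
      c_j <- place_point(
        draw = function() runif_ball(glia[g, ], r_in),
        ok = function(pt) min_dist2(pt, centres) > sep_main^2,
        what = "engulfed punctum")
      centres <- rbind(centres, c_j); glia_of <- c(glia_of, g)
    }
    out_pad <- p$punctum_radius_um + pad
    clear <- p$glia_radius_um + p$punctum_radius_um + 0.25
    for (j in seq_len(p$n_puncta - n_eng)) {
      c_j <- place_point(
        draw = function() vapply(1:3, function(a)
          runif(1, out_pad, extent[a] - out_pad), 0),
        ok = function(pt) min_dist2(pt, centres) > sep_main^2 &&
          min_dist2(pt, glia) > clear^2,
        what = "extracellular punctum")
      centres <- rbind(centres, c_j); glia_of <- c(glia_of, NA_integer_)
    }

    ## --- rasterise ------------------------------------------------------
    glia_labels <- array(0L, dim = d)
    for (i in seq_len(p$n_glia))
      glia_labels[sphere_voxels(glia[i, ], p$glia_radius_um, d, v)] <- i
    lysosome_mask <- array(FALSE, dim = d)
    for (i in seq_len(p$n_glia)) {
      lv <- sphere_voxels(lys[i, ], lys_radius, d, v)
      lysosome_mask[lv[glia_labels[lv] == i]] <- TRUE  # keep inside own glia
    }
    n_p <- nrow(centres)
    is_lysosomal <- seq_len(n_p) <= n_lys
    is_engulfed <- seq_len(n_p) <= n_eng
    puncta_labels <- array(0L, dim = d)
    for (j in seq_len(n_p))
      puncta_labels[sphere_voxels(centres[j, ], p$punctum_radius_um, d, v)] <- j

    ## --- emission channels ---------------------------------------------
    mcherry <- (puncta_labels > 0) * 1
    gfp_ids <- which(!is_lysosomal)
    gfp <- array(as.numeric(puncta_labels %in% gfp_ids), dim = d)
    ch <- list(glia = (glia_labels > 0) * 1,
               lysosome = lysosome_mask * 1,
               mCherry = mcherry,
               GFP = gfp)
    if (p$psf_sigma_um > 0) {
      sig_vox <- p$psf_sigma_um / v
      ch <- lapply(ch, blur_gaussian_3d, sigma_vox = sig_vox)
    }
    if (is.finite(p$snr)) {
      sd_noise <- 1 / p$snr
      ch <- lapply(ch, function(a)
        a + array(rnorm(length(a), 0, sd_noise), dim = d))
    }
    vox <- array(0, dim = c(4L, d))
    for (k in 1:4) vox[k, , , ] <- ch[[k]]
    stack <- image_stack(vox, v, names(ch))

    puncta <- data.frame(
      id = seq_len(n_p),
      z_um = centres[, 1L], y_um = centres[, 2L], x_um = centres[, 3L],
      radius_um = p$punctum_radius_um,
      is_engulfed = is_engulfed, is_lysosomal = is_lysosomal,
      glia_label = glia_of)
    truth <- structure(
      list(glia_labels = glia_labels, lysosome_mask = lysosome_mask,
           puncta_labels = puncta_labels, puncta = puncta,
           voxel_size_um = v, params = p),
      class = "ground_truth")
    truth$planted_scores <- planted_scores(truth)
    list(stack = stack, truth = truth)
  })
}

#' Recompute the planted engulfment quantities from emitted masks
#'
#' Brute-force tally over the ground-truth voxel masks: per-punctum voxel
#' volumes, volume inside/outside glia, the quenched (lysosomal) volume that
#' the mCherry-GFP subtraction should recover, and the planted
#' volume-weighted inside percentage and lysosome fraction.
#'
#' @param truth a `ground_truth` object from [generate_engulfment_stack()].
#' @return list of planted quantities (volumes in um^3, percentages 0-100).
#' @export
planted_scores <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  vv <- prod(truth$voxel_size_um)
  pl <- truth$puncta_labels
  fg <- pl > 0L
  ids <- pl[fg]
  n_p <- nrow(truth$puncta)
  vol_vox <- tabulate(ids, nbins = n_p)
  inside_vox <- tabulate(ids[truth$glia_labels[fg] > 0L], nbins = n_p)
  lys <- truth$puncta$is_lysosomal
  eng <- truth$puncta$is_engulfed
  inside_vol <- sum(inside_vox) * vv
  total_vol <- sum(vol_vox) * vv
  glia_vox <- tabulate(truth$glia_labels[truth$glia_labels > 0L])
  phag <- unique(truth$puncta$glia_label[eng])
  phag <- phag[!is.na(phag)]
  phag_vol <- sum(glia_vox[phag]) * vv
  lys_inside_vol <- sum(vol_vox[lys]) * vv
  list(
    n_engulfed = sum(eng),
    n_lysosomal = sum(lys),
    total_puncta_volume_um3 = total_vol,
    inside_volume_um3 = inside_vol,
    outside_volume_um3 = total_vol - inside_vol,
    pct_inside = if (total_vol > 0) 100 * inside_vol / total_vol else NA_real_,
    lysosomal_volume_um3 = lys_inside_vol,
    pct_in_lysosome_of_inside =
      if (inside_vol > 0) 100 * lys_inside_vol / inside_vol else NA_real_,
    phagocytic_glia_volume_um3 = phag_vol,
    au_mcherry_alone =
      if (phag_vol > 0) lys_inside_vol / phag_vol else NA_real_)
}
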