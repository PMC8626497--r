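has_channel <- function(puncta, channel) {
  vapply(puncta$channels, function(ch) channel %in% ch, logical(1))
}

#' mCherry-alone punctum volume in a compartment
#'
#' The pH-reporter readout: total volume of reporter (mCherry-positive)
#' puncta in the compartment minus total volume of GFP-positive puncta
#' there, floored at zero. Because eGFP is quenched in lysosomes while
#' mCherry persists, this difference isolates the degraded, engulfed
#' material. The default reading takes "reporter puncta" as all
#' mCherry-positive puncta; `reading = "double_positive"` restricts the
#' minuend to strictly mCherry+GFP double-positive puncta.
#'
#' @param puncta annotated punctum data frame (see [assign_location()]).
#' @param compartment `"inside"` or `"outside"` glia.
#' @param mcherry,gfp channel names.
#' @param reading `"all_reporter"` (default) or `"double_positive"`.
#' @return volume in um^3, `>= 0`.
#' @export
mcherry_alone_volume <- function(puncta, compartment = c("inside", "outside"),
                                 mcherry = "mCherry", gfp = "GFP",
                                 reading = c("all_reporter",
                                             "double_positive")) {
  compartment <- match.arg(compartment)
  reading <- match.arg(reading)
  if (is.null(puncta$location))
    stop_gq("puncta are not annotated; run assign_location() first")
  in_comp <- puncta$location == compartment
  pos_m <- has_channel(puncta, mcherry)
  pos_g <- has_channel(puncta, gfp)
  minuend <- if (reading == "all_reporter") pos_m else (pos_m & pos_g)
  max(0, sum(puncta$volume_um3[in_comp & minuend]) -
        sum(puncta$volume_um3[in_comp & pos_g]))
}

#' Total volume of phagocytic glia
#'
#' "Phagocytic glia" are the glial labels containing at least one inside
#' punctum (`which = "phagocytic"`, the default normalisation of the
#' in-unit-glia score); `which = "all"` uses every glial label.
#'
#' @param puncta annotated punctum data frame.
#' @param glia a [labeled_mask()] of glial cells.
#' @param which `"phagocytic"` or `"all"`.
#' @return volume in um^3 (0 if no qualifying glia).
#' @export
phagocytic_glia_volume <- function(puncta, glia,
                                   which = c("phagocytic", "all")) {
  which <- match.arg(which)
  stopifnot(inherits(glia, "labeled_mask"))
  sizes <- tabulate(glia$labels[glia$labels > 0L], nbins = max(glia$labels, 1L))
  vox_vol <- prod(glia$voxel_size_um)
  if (which == "all") return(sum(sizes) * vox_vol)
  labs <- unique(puncta$glia_label[!is.na(puncta$glia_label)])
  if (length(labs) == 0L) return(0)
  sum(sizes[labs]) * vox_vol
}

#' Engulfed volume normalised to unit phagocytic glia (AU)
#'
#' The in-unit-glia score: punctum volume inside glia divided by the total
#' phagocytic glial volume. Dimensionless (arbitrary units) and invariant
#' under any voxel rescaling that preserves physical geometry.
#'
#' @param volume_inside_um3 punctum volume inside glia, um^3.
#' @param total_phagocytic_glia_volume_um3 denominator volume, um^3; an
#'   error is raised when it is zero (no phagocytic glia means the score is
#'   undefined, not zero).
#' @return the AU score.
#' @export
score_in_unit_glia <- function(volume_inside_um3,
                               total_phagocytic_glia_volume_um3) {
  if (total_phagocytic_glia_volume_um3 <= 0)
    stop_gq("undefined score: no phagocytic glia volume")
  volume_inside_um3 / total_phagocytic_glia_volume_um3
}

#' Percentages of puncta inside and outside glia
#'
#' Volume-weighted by default (the quantified readout is punctum size);
#' `weight = "count"` gives per-punctum percentages. The two percentages sum
#' to 100 over the filtered set.
#'
#' @param puncta annotated punctum data frame.
#' @param channel restrict to puncta positive for this channel (`NULL` for
#'   all).
#' @param weight `"volume"` (default) or `"count"`.
#' @return named numeric `c(pct_inside, pct_outside)`.
#' @export
inside_outside_percentages <- function(puncta, channel = "mCherry",
                                       weight = c("volume", "count")) {
  weight <- match.arg(weight)
  keep <- if (is.null(channel)) rep(TRUE, nrow(puncta))
          else has_channel(puncta, channel)
  sub <- puncta[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop_gq("no puncta pass the positivity filter")
  w <- if (weight == "volume") sub$volume_um3 else rep(1, nrow(sub))
  pct_in <- 100 * sum(w[sub$location == "inside"]) / sum(w)
  c(pct_inside = pct_in, pct_outside = 100 - pct_in)
}

#' Fraction of inside-glia punctum volume within lysosomes
#'
#' `100 * volume(inside puncta with in_lysosome) / volume(all inside
#' puncta)`.
#'
#' @param puncta annotated punctum data frame.
#' @return percentage in `[0, 100]`; error when no punctum is inside glia.
#' @export
lysosome_fraction <- function(puncta) {
  inside <- puncta[puncta$location == "inside", , drop = FALSE]
  if (nrow(inside) == 0L) stop_gq("no puncta inside glia")
  100 * sum(inside$volume_um3[inside$in_lysosome]) / sum(inside$volume_um3)
}

#' Fraction of marker-A cells also positive for marker B
#'
#' Counts the labelled cells of mask A whose label region overlaps the
#' marker-B foreground in at least `min_overlap_frac` of their voxels
#' (e.g. Iba-1+ cells that are Mac-2+).
#'
#' @param cells a [labeled_mask()] of marker-A cells.
#' @param marker_b logical 3-D array (or [labeled_mask()]) of marker-B
#'   foreground, same geometry.
#' @param min_overlap_frac minimum overlapping voxel fraction for a cell to
#'   count as double positive.
#' @return percentage in `[0, 100]`; error when mask A has no cells.
#' @export
double_positive_fraction <- function(cells, marker_b,
                                     min_overlap_frac = 0.1) {
  stopifnot(inherits(cells, "labeled_mask"))
  b <- if (inherits(marker_b, "labeled_mask")) marker_b$labels > 0L
       else marker_b > 0
  if (!identical(dim(b), dim(cells$labels)))
    stop_gq("marker masks do not share geometry")
  nl <- max(cells$labels)
  if (nl == 0L) stop_gq("no marker-A cells")
  fg <- cells$labels > 0L
  sizes <- tabulate(cells$labels[fg], nbins = nl)
  overlap <- tabulate(cells$labels[fg & b], nbins = nl)
  100 * sum(overlap / sizes >= min_overlap_frac) / nl
}

#' End-to-end engulfment quantification of one field
#'
#' Runs the full pipeline on a 4-channel reporter stack: segments glia and
#' lysosomes, detects reporter puncta per channel, merges channels, assigns
#' compartments, and computes the engulfment report.
#'
#' @param stack an [image_stack()] with glia, lysosome and reporter
#'   channels.
#' @param glia_channel,lysosome_channel,mcherry_channel,gfp_channel channel
#'   names.
#' @param method,threshold thresholding passed to segmentation/detection;
#'   the `"robust"` default (background median + 4 MAD) behaves well on both
#'   the dense glial channel and the sparse punctum channels.
#' @param min_cell_volume_um3 minimum glial component volume.
#' @param punctum_volume_um3 length-2 volume band for punctum detection.
#' @param match_radius_um cross-channel punctum matching radius.
#' @param rule compartment rule for [assign_location()].
#' @param glia_norm normalisation for the AU score ("phagocytic" or "all").
#' @return list of class `engulfment_report`: the AU scores, inside/outside
#'   percentages, lysosomal fraction, counts, plus the annotated puncta and
#'   masks.
#' @export
quantify_engulfment <- function(stack,
                                glia_channel = "glia",
                                lysosome_channel = "lysosome",
                                mcherry_channel = "mCherry",
                                gfp_channel = "GFP",
                                method = "robust", threshold = NULL,
                                min_cell_volume_um3 = 50,
                                punctum_volume_um3 = c(0.5, 50),
                                match_radius_um = 1.0,
                                rule = "centroid",
                                glia_norm = "phagocytic") {
  glia <- segment_cells(stack, glia_channel, method = method,
                        threshold = threshold,
                        min_volume_um3 = min_cell_volume_um3, kind = "glia")
  lyso <- segment_cells(stack, lysosome_channel, method = method,
                        threshold = threshold, min_volume_um3 = 0,
                        kind = "lysosome")
  dets <- lapply(c(mcherry_channel, gfp_channel), function(ch)
    detect_puncta(stack, ch, min_volume_um3 = punctum_volume_um3[1L],
                  max_volume_um3 = punctum_volume_um3[2L],
                  method = method, threshold = threshold))
  puncta <- merge_channel_puncta(dets, match_radius_um,
                                 voxel_volume_um3 = voxel_volume_um3(stack))
  puncta <- assign_location(puncta, glia, lyso, rule = rule)
  mc_alone_in <- mcherry_alone_volume(puncta, "inside",
                                      mcherry = mcherry_channel,
                                      gfp = gfp_channel)
  mc_alone_out <- mcherry_alone_volume(puncta, "outside",
                                       mcherry = mcherry_channel,
                                       gfp = gfp_channel)
  phag_vol <- phagocytic_glia_volume(puncta, glia, which = glia_norm)
  pct <- tryCatch(
    inside_outside_percentages(puncta, channel = mcherry_channel),
    error = function(e) c(pct_inside = NA_real_, pct_outside = NA_real_))
  lys_pct <- tryCatch(lysosome_fraction(puncta),
                      error = function(e) NA_real_)
  au <- if (phag_vol > 0) mc_alone_in / phag_vol else NA_real_
  structure(list(
    mcherry_alone_inside_um3 = mc_alone_in,
    mcherry_alone_outside_um3 = mc_alone_out,
    mcherry_alone_in_unit_glia_AU = au,
    pct_inside = unname(pct["pct_inside"]),
    pct_outside = unname(pct["pct_outside"]),
    pct_in_lysosome_of_inside = lys_pct,
    phagocytic_glia_volume_um3 = phag_vol,
    n_cells = n_labels(glia),
    n_puncta = nrow(puncta),
    puncta = puncta, glia = glia, lysosomes = lyso),
    class = "engulfment_report")
}

#' @export
print.engulfment_report <- function(x, ...) {
  cat("engulfment_report\n")
  cat(sprintf("  glia: %d; puncta: %d\n", x$n_cells, x$n_puncta))
  cat(sprintf("  mCherry-alone inside: %.2f um^3 (%.4f AU)\n",
              x$mcherry_alone_inside_um3, x$mcherry_alone_in_unit_glia_AU))
  cat(sprintf("  inside/outside: %.1f%% / %.1f%%; in lysosome: %.1f%%\n",
              x$pct_inside, x$pct_outside, x$pct_in_lysosome_of_inside))
  invisible(x)
}

#' Average engulfment reports over imaging fields
#'
#' Simple unweighted mean of each numeric score over the per-field reports
#' (one field = one perifocal image).
#'
#' @param reports list of `engulfment_report` objects.
#' @return named numeric vector of mean scores.
#' @export
aggregate_fields <- function(reports) {
  stopifnot(length(reports) > 0L)
  keys <- c("mcherry_alone_inside_um3", "mcherry_alone_outside_um3",
            "mcherry_alone_in_unit_glia_AU", "pct_inside", "pct_outside",
            "pct_in_lysosome_of_inside", "n_cells", "n_puncta")
  vapply(keys, function(k)
    mean(vapply(reports, function(r) as.numeric(r[[k]]), 0)), 0)
}
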