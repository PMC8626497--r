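#' The six dendritic spine classes
#'
#' Order: `filopodia`, `long_thin`, `thin`, `stubby`, `mushroom`,
#' `branched`. Mature spines are `stubby`, `mushroom` and `branched`.
#'
#' @return character vector of class names.
#' @export
spine_classes <- function() {
  c("filopodia", "long_thin", "thin", "stubby", "mushroom", "branched")
}

mature_classes <- function() c("stubby", "mushroom", "branched")

#' Classify dendritic spines by length, width and head count
#'
#' Applies the six morphological rules — filopodia: length > 2 um;
#' long-thin: length < 2 um; thin: length < 1 um; stubby: length/width < 1;
#' mushroom: width > 0.6 um; branched: two or more heads — with a fixed
#' precedence, since the raw rules overlap (a short, wide spine can satisfy
#' thin, stubby and mushroom simultaneously). Default precedence:
#' `branched, filopodia, mushroom, stubby, thin, long_thin`. All
#' inequalities are strict, exactly as stated; a single-headed spine of
#' length exactly 2 um matching no strict rule falls through to
#' `long_thin`. The map is total and deterministic: every valid geometry
#' receives exactly one class.
#'
#' @param length_um,width_um positive spine length and head width, um
#'   (vectorised).
#' @param heads number of heads, `>= 1`.
#' @param precedence permutation of [spine_classes()] giving rule order.
#' @return factor of classes with levels [spine_classes()].
#' @export
classify_spine <- function(length_um, width_um, heads,
                           precedence = c("branched", "filopodia",
                                          "mushroom", "stubby", "thin",
                                          "long_thin")) {
  n <- length(length_um)
  if (length(width_um) != n || length(heads) != n)
    stop_gq("inputs must have equal length")
  if (n == 0L) return(factor(character(0), levels = spine_classes()))
  if (any(length_um <= 0) || any(width_um <= 0) || any(heads < 1))
    stop_gq("need length > 0, width > 0, heads >= 1")
  if (!setequal(precedence, spine_classes()))
    stop_gq("`precedence` must be a permutation of spine_classes()")
  rules <- list(
    branched = heads >= 2,
    filopodia = length_um > 2,
    mushroom = width_um > 0.6,
    stubby = length_um / width_um < 1,
    thin = length_um < 1,
    long_thin = length_um < 2)
  klass <- rep(NA_character_, n)
  for (r in precedence) {
    hit <- is.na(klass) & rules[[r]]
    klass[hit] <- r
  }
  klass[is.na(klass)] <- "long_thin"  # boundary fall-through (length == 2)
  factor(klass, levels = spine_classes())
}

#' Count spines per class and compute densities
#'
#' @param spines data frame with `length_um`, `width_um`, `heads` (a `class`
#'   column is used if present, otherwise classes are computed with
#'   [classify_spine()]).
#' @param dendrite_length_um positive dendritic segment length, um.
#' @return list of class `spine_counts`: `per_class` (named counts),
#'   `total`, `mature` (stubby + mushroom + branched), `filopodia`,
#'   `pct_per_class`, `density_per_10um` (per class plus total, mature,
#'   filopodia) and `dendrite_length_um`.
#' @export
count_spines <- function(spines, dendrite_length_um) {
  if (dendrite_length_um <= 0)
    stop_gq("`dendrite_length_um` must be positive")
  klass <- if (!is.null(spines$class)) {
    factor(as.character(spines$class), levels = spine_classes())
  } else if (nrow(spines) > 0L) {
    classify_spine(spines$length_um, spines$width_um, spines$heads)
  } else factor(character(0), levels = spine_classes())
  per_class <- table(klass)
  per_class <- stats::setNames(as.integer(per_class), names(per_class))
  total <- sum(per_class)
  mature <- sum(per_class[mature_classes()])
  filo <- per_class[["filopodia"]]
  seg <- dendrite_length_um / 10
  dens <- c(per_class, total = total, mature = mature,
            filopodia_total = filo) / seg
  structure(list(per_class = per_class, total = total, mature = mature,
                 filopodia = filo,
                 pct_per_class = if (total > 0) 100 * per_class / total
                                 else per_class * NA_real_,
                 density_per_10um = dens,
                 dendrite_length_um = dendrite_length_um),
            class = "spine_counts")
}

#' @export
print.spine_counts <- function(x, ...) {
  cat(sprintf("spine_counts: %d total (%d mature, %d filopodia) on %.1f um\n",
              x$total, x$mature, x$filopodia, x$dendrite_length_um))
  print(x$per_class)
  invisible(x)
}

#' Fold change of group means
#'
#' `mean(group) / mean(reference)`, the ratio used to report e.g. a
#' 2.2-fold increase in total spine number in knockout versus control.
#'
#' @param group_counts,reference_counts numeric vectors of per-animal (or
#'   per-slice) counts.
#' @return the ratio; error when the reference mean is zero or negative.
#' @export
fold_change <- function(group_counts, reference_counts) {
  m_ref <- mean(reference_counts)
  if (!is.finite(m_ref) || m_ref <= 0)
    stop_gq("reference mean must be positive")
  mean(group_counts) / m_ref
}
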