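#' Ordered serial-section area series
#'
#' Cross-section areas of a region (or of contralateral-minus-ipsilateral
#' differences) at uniformly spaced section planes, feeding the frustum
#' volume estimator. `h` is the centre-to-centre distance between adjacent
#' sections (for 30 um sections cut every 300 um, `h = 0.3` mm), not the
#' section thickness.
#'
#' @param areas numeric vector of `>= 2` nonnegative areas (mm^2).
#' @param h positive inter-section spacing (mm).
#' @param meaning `"region"` (areas of a structure, e.g. ventricle) or
#'   `"difference"` (contralateral minus ipsilateral, e.g. atrophy).
#' @return object of class `section_area_series`.
#' @export
section_area_series <- function(areas, h,
                                meaning = c("region", "difference")) {
  meaning <- match.arg(meaning)
  areas <- as.numeric(areas)
  if (length(areas) < 2L) stop_gq("need at least 2 sections")
  if (any(!is.finite(areas)) || any(areas < 0))
    stop_gq("areas must be finite and nonnegative")
  if (!is.finite(h) || h <= 0) stop_gq("`h` must be positive")
  structure(list(areas = areas, h = h, meaning = meaning),
            class = "section_area_series")
}

#' @export
print.section_area_series <- function(x, ...) {
  cat(sprintf("section_area_series (%s): %d sections, h = %g\n",
              x$meaning, length(x$areas), x$h))
  invisible(x)
}

#' Serial-section (conic frustum) volume estimate
#'
#' `V = sum over adjacent section pairs of h/3 * (S_n + sqrt(S_n * S_{n+1})
#' + S_{n+1})`. Each pair is treated as a conic frustum, so the estimate is
#' exact (to machine precision) for any piecewise-conic area profile sampled
#' at the section planes — cylinders and cones in particular — and is
#' homogeneous of degree one in both the areas and `h`.
#'
#' @param series a [section_area_series()] (areas in mm^2, `h` in mm).
#' @return volume in mm^3.
#' @export
frustum_volume <- function(series) {
  stopifnot(inherits(series, "section_area_series"))
  a <- series$areas
  n <- length(a)
  s1 <- a[-n]
  s2 <- a[-1L]
  sum(series$h / 3 * (s1 + sqrt(s1 * s2) + s2))
}

#' Contralateral-minus-ipsilateral difference series
#'
#' Builds the area-difference series used for atrophy and infarct volumes.
#' Atrophy cannot be negative, so negative differences (contralateral
#' smaller than ipsilateral, e.g. from swelling or measurement noise) are
#' floored at zero with a warning by default; `negative = "error"` makes
#' them fatal.
#'
#' @param ipsi_areas,contra_areas equal-length numeric vectors (mm^2).
#' @param h positive inter-section spacing (mm).
#' @param negative `"floor"` (default) or `"error"`.
#' @return a [section_area_series()] with `meaning = "difference"`.
#' @export
difference_series <- function(ipsi_areas, contra_areas, h,
                              negative = c("floor", "error")) {
  negative <- match.arg(negative)
  if (length(ipsi_areas) != length(contra_areas))
    stop_gq("ipsilateral and contralateral series differ in length")
  d <- contra_areas - ipsi_areas
  if (any(d < 0)) {
    if (negative == "error")
      stop_gq("negative contra - ipsi difference at section(s) ",
              paste(which(d < 0), collapse = ", "))
    warning("flooring ", sum(d < 0),
            " negative contra - ipsi difference(s) at 0", call. = FALSE)
    d <- pmax(d, 0)
  }
  section_area_series(d, h, meaning = "difference")
}

#' Grid-walking foot-fault index
#'
#' Signed percentage `(contra_faults - ipsi_faults) / total_steps * 100`
#' from the grid-walking test. Negative values (more ipsilateral faults)
#' are preserved; the index always lies in `[-100, 100]`.
#'
#' @param contra_faults,ipsi_faults,total_steps nonnegative counts
#'   (vectorised); faults may not exceed total steps, and `total_steps`
#'   must be at least 1.
#' @return signed percentage.
#' @export
foot_fault_index <- function(contra_faults, ipsi_faults, total_steps) {
  if (any(total_steps < 1)) stop_gq("`total_steps` must be >= 1")
  if (any(contra_faults < 0) || any(ipsi_faults < 0))
    stop_gq("fault counts must be nonnegative")
  if (any(contra_faults > total_steps) || any(ipsi_faults > total_steps))
    stop_gq("fault counts cannot exceed total steps")
  (contra_faults - ipsi_faults) / total_steps * 100
}
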