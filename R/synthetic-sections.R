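#' Generate serial-section area profiles of solids with known volume
#'
#' Produces a [section_area_series()] of a named solid of revolution sampled
#' at uniformly spaced section planes, together with its closed-form volume.
#' These are the analytic fixtures for the serial-section frustum estimator:
#' the frustum formula is exact for cones and cylinders and converges
#' quadratically for the ellipsoid.
#'
#' @param profile one of `"cylinder"`, `"cone"`, `"ellipsoid"`.
#' @param h section spacing (same length unit as the solid; typically mm).
#' @param n_sections number of sections; defaults to the number needed to
#'   span the solid exactly. Must span the solid for `cone`/`ellipsoid`.
#' @param base_area cross-section area of the cylinder, or base area of the
#'   cone.
#' @param height height of the cone (for a cylinder the sampled span
#'   `(n_sections - 1) * h` is its height).
#' @param semi_axes ellipsoid semi-axes `(a, b, c)`; sections are taken
#'   perpendicular to the first axis, from `-a` to `a`.
#' @return list with `series` (a [section_area_series()]) and
#'   `analytic_volume`.
#' @export
generate_section_series <- function(profile = c("cylinder", "cone",
                                                "ellipsoid"),
                                    h,
                                    n_sections = NULL,
                                    base_area = 4,
                                    height = 2,
                                    semi_axes = c(1, 0.8, 0.6)) {
  profile <- match.arg(profile)
  if (h <= 0) stop_gq("`h` must be positive")
  span_sections <- function(span) {
    n <- round(span / h) + 1L
    if (abs((n - 1L) * h - span) > 1e-9 * max(span, 1))
      stop_gq("`h` must divide the solid's span exactly (span = ", span, ")")
    n
  }
  if (profile == "cylinder") {
    if (is.null(n_sections)) n_sections <- 2L
    if (n_sections < 2L) stop_gq("need at least 2 sections")
    areas <- rep(base_area, n_sections)
    vol <- base_area * h * (n_sections - 1L)
  } else if (profile == "cone") {
    n_need <- span_sections(height)
    if (is.null(n_sections)) n_sections <- n_need
    if (n_sections != n_need)
      stop_gq("cone sections must span base to apex: need ", n_need)
    z <- (seq_len(n_sections) - 1L) * h
    areas <- base_area * (1 - z / height)^2
    vol <- base_area * height / 3
  } else {
    a <- semi_axes[1L]; b <- semi_axes[2L]; c_ <- semi_axes[3L]
    if (any(semi_axes <= 0)) stop_gq("semi-axes must be positive")
    n_need <- span_sections(2 * a)
    if (is.null(n_sections)) n_sections <- n_need
    if (n_sections != n_need)
      stop_gq("ellipsoid sections must span -a to a: need ", n_need)
    z <- -a + (seq_len(n_sections) - 1L) * h
    areas <- pmax(0, pi * b * c_ * (1 - z^2 / a^2))
    vol <- 4 / 3 * pi * a * b * c_
  }
  if (n_sections < 2L) stop_gq("need at least 2 sections")
  list(series = section_area_series(areas, h, meaning = "region"),
       analytic_volume = vol)
}
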