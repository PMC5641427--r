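# Per-specimen morphological indicators of the head contour.

#' First-harmonic ellipse axes and aspect ratio
#'
#' The first harmonic of the normalized EFD is the ellipse
#' \eqn{(\cos t, d_1 \sin t)} scaled by the removed semi-major magnitude;
#' the absolute axes are restored from the recorded \code{scale_px}.
#'
#' @param efd Normalized \code{"efd"} object with a recorded scale.
#' @return List with \code{major_px}, \code{minor_px}, \code{aspect_ratio}.
#' @export
ellipse_axes <- function(efd) {
  stopifnot(inherits(efd, "efd"))
  if (!isTRUE(efd$normalized)) stop("ellipse_axes needs normalized coefficients")
  if (!is.finite(efd$scale_px)) stop("missing scale record (scale_px)")
  d1 <- unname(efd$coef[1L, "d"])
  list(major_px = 2 * efd$scale_px,
       minor_px = 2 * efd$scale_px * d1,
       aspect_ratio = d1)
}

#' Antero-posterior axis and its angle to the first-harmonic major axis
#'
#' The AP axis is the longest chord of the contour: the maximum point-pair
#' distance over the vertices, found on the convex hull. Theta is the acute
#' angle between that chord and the major-axis direction of the
#' first-harmonic ellipse (the rotation removed during normalization),
#' reported in degrees in [0, 90).
#'
#' @param contour Contour matrix (original, un-normalized frame).
#' @param efd The normalized \code{"efd"} of the same contour (source of
#'   the major-axis direction).
#' @return List with \code{ap_length_px} and \code{theta_deg}.
#' @export
ap_axis_theta <- function(contour, efd) {
  xy <- as_contour(contour)
  stopifnot(inherits(efd, "efd"), isTRUE(efd$normalized))
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  h <- nrow(hull)
  if (h < 2L) stop("degenerate contour: no chord")
  d2 <- as.matrix(stats::dist(hull))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
  ap <- sqrt(max(d2))
  dxy <- hull[ij[2L], ] - hull[ij[1L], ]
  alpha <- atan2(dxy[2L], dxy[1L])
  dth <- (alpha - efd$rotation_rad) %% pi
  theta <- min(dth, pi - dth) * 180 / pi
  list(ap_length_px = ap, theta_deg = as.numeric(theta))
}

#' Head area by the shoelace formula
#'
#' Absolute area of the traced boundary polygon. Self-intersecting contours
#' are rejected: their shoelace area is not a region area.
#'
#' @param contour Contour matrix (simple closed polygon).
#' @return Area in squared pixels.
#' @export
head_area <- function(contour) {
  xy <- as_contour(contour)
  if (!is_simple_polygon(xy)) stop("self-intersecting contour: area undefined")
  abs(polygon_area(xy))
}

#' Coefficient of variation, in percent
#'
#' @param values Numeric sample, n >= 2, nonzero mean.
#' @return 100 x sample SD (divisor n - 1) / sample mean.
#' @export
cv_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Measure a set of specimens
#'
#' Runs EFD estimation and normalization per contour and assembles the
#' per-specimen indicator table.
#'
#' @param records List of specimen records (or a named list of contours).
#' @param n_harmonics Harmonics for the EFD (default 20).
#' @return Data frame: \code{specimen_id}, \code{group_label} (if known),
#'   \code{aspect_ratio}, \code{major_px}, \code{minor_px},
#'   \code{ap_length_px}, \code{theta_deg}, \code{area_px2}.
#' @export
measure_heads <- function(records, n_harmonics = 20L) {
  if (!length(records)) stop("no specimens to measure")
  is_rec <- is.list(records[[1L]]) && !is.null(records[[1L]]$contour)
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    xy <- if (is_rec) rec$contour else rec
    id <- if (is_rec) rec$specimen_id else names(records)[i]
    if (is.null(id) || !nzchar(id)) id <- sprintf("specimen_%04d", i)
    e <- efd_normalize(efd_estimate(ensure_ccw(xy), n_harmonics))
    ax <- ellipse_axes(e)
    ap <- ap_axis_theta(xy, e)
    data.frame(
      specimen_id = id,
      group_label = if (is_rec && !is.null(rec$group_label)) rec$group_label else NA_character_,
      aspect_ratio = ax$aspect_ratio,
      major_px = ax$major_px,
      minor_px = ax$minor_px,
      ap_length_px = ap$ap_length_px,
      theta_deg = ap$theta_deg,
      area_px2 = head_area(xy),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
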