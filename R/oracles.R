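# Analytic and brute-force area oracles. These are deliberately
# independent of the polygon-clipping path so that the two routes can
# be checked against each other.

#' Exact overlap area of two circles
#'
#' Closed-form lens area used as the analytic oracle for
#' [intersection_area()] on discretized circles.
#'
#' @param center1,center2 numeric length-2 circle centers (pixels).
#' @param radius1,radius2 positive radii (pixels).
#' @return overlap area in square pixels: 0 when the center distance is
#'   at least `radius1 + radius2`; the full smaller disc when one
#'   circle contains the other; otherwise the standard two-circle lens
#'   formula.
#' @export
circle_circle_overlap_area <- function(center1, radius1, center2, radius2) {
  for (r in c(radius1, radius2))
    if (length(r) != 1L || !is.finite(r) || r <= 0)
      abort_hci("radii must be single positive numbers", "hci_parameter_error")
  d <- sqrt(sum((center1 - center2)^2))
  r1 <- radius1; r2 <- radius2
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - tri
}

#' Brute-force overlap area of two implicit regions
#'
#' Midpoint rasterization of the region `a` intersect `b` over a
#' bounding box. Serves as the method-independent oracle for arbitrary
#' region overlap (including the synthetic cup model, where no single
#' closed form applies).
#'
#' @param region_a,region_b vectorized predicates `f(x, y)` returning a
#'   logical vector: `TRUE` where the point lies inside the region.
#' @param bbox numeric length-4 `c(xmin, xmax, ymin, ymax)`; must
#'   contain both regions.
#' @param resolution number of grid cells per axis, at least 100.
#' @return estimated overlap area; attribute `error_bound` carries the
#'   proxy bound (cell area times the number of cells on the overlap
#'   boundary).
#' @export
grid_overlap_oracle <- function(region_a, region_b, bbox, resolution = 1000) {
  if (length(bbox) != 4L || !all(is.finite(bbox)) ||
      bbox[2L] <= bbox[1L] || bbox[4L] <= bbox[3L])
    abort_hci("bbox must be c(xmin, xmax, ymin, ymax) with positive extent",
              "hci_parameter_error")
  if (length(resolution) != 1L || !is.finite(resolution) || resolution < 100)
    abort_hci("resolution must be at least 100 cells per axis",
              "hci_parameter_error")
  n <- as.integer(resolution)
  dx <- (bbox[2L] - bbox[1L]) / n
  dy <- (bbox[4L] - bbox[3L]) / n
  xm <- bbox[1L] + (seq_len(n) - 0.5) * dx
  ym <- bbox[3L] + (seq_len(n) - 0.5) * dy
  gx <- rep(xm, times = n)
  gy <- rep(ym, each = n)
  inside <- region_a(gx, gy) & region_b(gx, gy)
  cell <- dx * dy
  area <- sum(inside) * cell
  ind <- matrix(inside, nrow = n)
  edge <- (ind[-1, , drop = FALSE] != ind[-n, , drop = FALSE])
  edge2 <- (ind[, -1, drop = FALSE] != ind[, -n, drop = FALSE])
  structure(area, error_bound = cell * (sum(edge) + sum(edge2)))
}

#' Circular-disc region predicate
#'
#' Convenience constructor of a vectorized inside-test for use with
#' [grid_overlap_oracle()].
#'
#' @param center numeric length-2 disc center.
#' @param radius positive radius.
#' @return function `f(x, y)` returning `TRUE` inside the closed disc.
#' @export
disc_region <- function(center, radius) {
  force(center); force(radius)
  function(x, y) (x - center[1L])^2 + (y - center[2L])^2 <= radius^2
}
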