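# Planar polygon kernel: validation, shoelace area, general
# simple-polygon intersection, and the shape constructors used by the
# synthetic hip generator.
#
# Coordinates follow the image convention: continuous pixel units,
# origin at the top-left corner, y increasing downward. All routines are
# algebraic, so the y-down convention only affects the sign of raw
# shoelace sums, never a reported area.

# Annotation coordinates are integer-ish pixels; snapping to a 1e-7 px
# grid cannot change an area meaningfully but makes degeneracy
# detection (exactly coincident/collinear features) reliable.
SNAP_GRID <- 1e-7

snap_coords <- function(m) {
  round(m / SNAP_GRID) * SNAP_GRID
}

#' Coerce to a polygon vertex matrix
#'
#' Accepts a two-column matrix or data frame of vertex coordinates
#' (columns x, y in pixels) and returns a validated, snapped vertex
#' matrix. The polygon is implicitly closed: the last vertex connects
#' back to the first.
#'
#' @param p two-column matrix or data frame of vertices.
#' @param arg name used in error messages.
#' @return numeric matrix with columns `x`, `y`.
#' @details Validation enforces the polygon contract: at least three
#'   vertices, finite coordinates, no two consecutive coincident
#'   vertices, and simplicity (no self-intersection). Self-intersecting
#'   input is rejected rather than repaired, because silent repair
#'   changes the measured area unpredictably.
#' @export
as_polygon <- function(p, arg = "polygon") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (!is.matrix(p) || !is.numeric(p) || ncol(p) != 2L)
    abort_hci(sprintf("%s must be a numeric matrix with two columns (x, y)", arg),
              "hci_invalid_polygon")
  if (nrow(p) < 3L)
    abort_hci(sprintf("%s has %d vertices; a polygon needs at least 3", arg, nrow(p)),
              "hci_invalid_polygon")
  if (!all(is.finite(p)))
    abort_hci(sprintf("%s contains non-finite coordinates", arg),
              "hci_invalid_polygon")
  m <- snap_coords(unname(p))
  dup <- rowSums(m == m[c(2:nrow(m), 1L), , drop = FALSE]) == 2L
  if (any(dup))
    abort_hci(sprintf("%s has coincident consecutive vertices", arg),
              "hci_invalid_polygon")
  if (!cpp_is_simple(m[, 1L], m[, 2L]))
    abort_hci(sprintf("%s is self-intersecting", arg), "hci_invalid_polygon")
  colnames(m) <- c("x", "y")
  m
}

signed_area <- function(m) cpp_signed_area(m[, 1L], m[, 2L])

ensure_ccw <- function(m) {
  if (signed_area(m) < 0) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
}

perimeter <- function(m) {
  d <- m[c(2:nrow(m), 1L), , drop = FALSE] - m
  sum(sqrt(rowSums(d^2)))
}

#' Polygon area by the shoelace formula
#'
#' @param p polygon (see [as_polygon()]).
#' @return non-negative area in square pixels; independent of vertex
#'   orientation and of which vertex comes first.
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
#' @export
polygon_area <- function(p) {
  m <- as_polygon(p)
  abs(signed_area(m))
}

#' Regular polygon inscribed in a circle
#'
#' Discretizer used for synthetic femoral heads and acetabular cups.
#' The first vertex lies at angle 0 from the +x axis; vertex angles
#' increase by `2 * pi / n_vertices`.
#'
#' @param center numeric length-2 (x, y) center in pixels.
#' @param radius circle radius in pixels, strictly positive.
#' @param n_vertices number of vertices, at least 8.
#' @return vertex matrix of the inscribed regular n-gon; its area is
#'   `n/2 * radius^2 * sin(2*pi/n)`, increasing to `pi * radius^2` from
#'   below as `n` grows.
#' @export
circle_polygon <- function(center, radius, n_vertices) {
  if (length(n_vertices) != 1L || !is.finite(n_vertices) || n_vertices < 8)
    abort_hci("n_vertices must be a single number >= 8", "hci_parameter_error")
  .regular_polygon(center, radius, n_vertices)
}

# unchecked core (tests exercise n < 8 through this)
.regular_polygon <- function(center, radius, n_vertices) {
  if (length(center) != 2L || !all(is.finite(center)))
    abort_hci("center must be a finite (x, y) pair", "hci_parameter_error")
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    abort_hci("radius must be a single positive number", "hci_parameter_error")
  n <- as.integer(n_vertices)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = center[1L] + radius * cos(th),
        y = center[2L] + radius * sin(th))
}

# ---------------------------------------------------------------------
# General simple-polygon intersection (Greiner-Hormann-style traversal).
#
# Strategy: snapped inputs are overlaid assuming generic position; the
# C++ crossing scan flags any degeneracy (vertex on edge, collinear
# overlap, crossing at a vertex). On a degeneracy the second polygon is
# translated by a deterministic sub-snap offset (1e-9 x coordinate
# scale) and the overlay is retried; the induced area error is bounded
# by perimeter x offset, orders of magnitude below the snap grid.
# Pure boundary contact (zero-width overlap) therefore resolves to an
# empty intersection, which is the intended semantics.
# ---------------------------------------------------------------------

.clip_try <- function(a, b) {
  cr <- cpp_edge_crossings(a[, 1L], a[, 2L], b[, 1L], b[, 2L])
  if (isTRUE(cr$degenerate)) return(NULL)
  m <- length(cr$i)
  if (m %% 2L == 1L) return(NULL)

  if (m == 0L) {
    if (cpp_point_in_poly(a[1L, 1L], a[1L, 2L], b[, 1L], b[, 2L]))
      return(list(rings = list(a), crossings = 0L))
    if (cpp_point_in_poly(b[1L, 1L], b[1L, 2L], a[, 1L], a[, 2L]))
      return(list(rings = list(b), crossings = 0L))
    return(list(rings = list(), crossings = 0L))
  }

  arcs_of <- function(poly, edge, tpar, cx, cy, other) {
    n <- nrow(poly)
    keye <- c(seq_len(n), edge)
    keyt <- c(rep(0, n), tpar)
    xs <- c(poly[, 1L], cx)
    ys <- c(poly[, 2L], cy)
    cid <- c(rep(0L, n), seq_along(edge))
    o <- order(keye, keyt)
    cid <- cid[o]; xs <- xs[o]; ys <- ys[o]
    ntot <- length(cid)
    cpos <- which(cid > 0L)
    k <- length(cpos)
    arcs <- vector("list", k)
    tx <- ty <- numeric(k)
    for (s in seq_len(k)) {
      p <- cpos[s]
      q <- if (s == k) cpos[1L] else cpos[s + 1L]
      idx <- if (s == k) {
        if (q == 1L && p == ntot) integer(0)
        else c(if (p < ntot) (p + 1L):ntot else integer(0),
               if (q > 1L) 1L:(q - 1L) else integer(0))
      } else if (q > p + 1L) (p + 1L):(q - 1L) else integer(0)
      if (length(idx)) {
        tx[s] <- xs[idx[1L]]; ty[s] <- ys[idx[1L]]
      } else {
        tx[s] <- (xs[p] + xs[q]) / 2; ty[s] <- (ys[p] + ys[q]) / 2
      }
      arcs[[s]] <- list(start = cid[p], end = cid[q],
                        pts = cbind(c(xs[p], xs[idx]), c(ys[p], ys[idx])))
    }
    keep <- as.logical(cpp_point_in_poly(tx, ty, other[, 1L], other[, 2L]))
    list(arcs = arcs, keep = keep)
  }

  A <- arcs_of(a, cr$i, cr$t, cr$x, cr$y, b)
  B <- arcs_of(b, cr$j, cr$u, cr$x, cr$y, a)

  kept <- c(A$arcs[A$keep], B$arcs[B$keep])
  if (length(kept) == 0L) return(list(rings = list(), crossings = m))
  starts <- vapply(kept, `[[`, integer(1), "start")
  # each crossing must launch exactly one kept arc
  if (anyDuplicated(starts) || length(starts) != m) return(NULL)
  succ <- integer(m)
  succ[starts] <- seq_along(kept)

  used <- logical(length(kept))
  rings <- list()
  for (s0 in seq_along(kept)) {
    if (used[s0]) next
    cur <- s0
    pts <- NULL
    guard <- 0L
    repeat {
      if (used[cur]) return(NULL)
      used[cur] <- TRUE
      pts <- rbind(pts, kept[[cur]]$pts)
      nxt <- succ[kept[[cur]]$end]
      if (nxt == 0L) return(NULL)
      if (nxt == s0) break
      cur <- nxt
      guard <- guard + 1L
      if (guard > m) return(NULL)
    }
    rings[[length(rings) + 1L]] <- pts
  }
  list(rings = rings, crossings = m)
}

.clip <- function(a, b) {
  a <- ensure_ccw(a)
  b <- ensure_ccw(b)
  scale <- max(abs(a), abs(b), 1)
  delta <- 1e-9 * scale
  for (k in 0:11) {
    bk <- if (k == 0L) b else {
      th <- 2.399963229728653 * k          # golden-angle direction sweep
      sweep(b, 2L, c(delta * k * cos(th), delta * k * sin(th)), "+")
    }
    res <- .clip_try(a, bk)
    if (!is.null(res)) {
      if (k > 0L) {
        # boundary-contact slivers created by the perturbation are noise
        thr <- 20 * delta * k * (perimeter(a) + perimeter(b))
        tot <- sum(vapply(res$rings, signed_area, numeric(1)))
        if (length(res$rings) && tot < thr)
          res$rings <- list()
      }
      return(res)
    }
  }
  abort_hci("polygon overlay failed to reach generic position after perturbation",
            "hci_degenerate_geometry")
}

#' Intersection of two simple polygons
#'
#' Computes the planar region `a` intersect `b` as a list of disjoint
#' simple rings, by a Greiner-Hormann-style traversal of the two
#' boundaries. Non-convex inputs are fully supported (acetabular
#' outlines are crescent-like). Boundary-only contact counts as empty.
#'
#' @param a,b polygons (see [as_polygon()]).
#' @return list of vertex matrices, one per connected piece; empty list
#'   when the interiors are disjoint. Ring order is deterministic for
#'   identical inputs. In the rare case of a multiply-connected
#'   intersection, hole boundaries appear as clockwise (negative signed
#'   area) rings.
#' @export
polygon_intersection <- function(a, b) {
  a <- as_polygon(a, "a")
  b <- as_polygon(b, "b")
  .clip(a, b)$rings
}

#' Area of overlap between two simple polygons
#'
#' @param a,b polygons (see [as_polygon()]).
#' @return overlap area in square pixels: the sum of the signed areas of
#'   the pieces returned by [polygon_intersection()]. Symmetric in its
#'   arguments and never exceeding the smaller input area (up to float
#'   tolerance).
#' @export
intersection_area <- function(a, b) {
  a <- as_polygon(a, "a")
  b <- as_polygon(b, "b")
  rings <- .clip(a, b)$rings
  if (length(rings) == 0L) return(0)
  max(0, sum(vapply(rings, signed_area, numeric(1))))
}
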