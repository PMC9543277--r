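# Planar polygon primitives used by the gridding and intersection code.
# Polygons are n x 2 matrices of vertices (open rings: first vertex not
# repeated); coordinates in km for planar grids, or in the Lambert
# cylindrical equal-area plane for sphere grids.

#' Signed area of a planar polygon ring (shoelace formula)
#'
#' Positive for counter-clockwise rings.
#'
#' @param poly numeric matrix, n x 2, open ring.
#' @return signed area in squared coordinate units.
#' @keywords internal
#' @noRd
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_area <- function(poly) abs(polygon_signed_area(poly))

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Even-odd ray-casting point-in-polygon; points on edges may go either way,
# callers needing uniqueness use nearest-centroid assignment instead.
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > pt[2]) != (yj > pt[2])) &&
        (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Sutherland-Hodgman clipping of an arbitrary subject polygon against a
# convex clip polygon (our hexagon cells are always convex). The clip ring
# must be counter-clockwise. Returns a matrix (possibly 0-row).
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # signed distance of each vertex to the directed clip edge (>= 0 inside)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1], 1L)
    keep <- vector("list", n)
    for (k in seq_len(n)) {
      p <- out[k, ]; q <- out[nxt[k], ]
      sp <- side[k]; sq <- side[nxt[k]]
      pts <- NULL
      if (sp >= 0) pts <- rbind(pts, p)
      if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
        t <- sp / (sp - sq)
        pts <- rbind(pts, p + t * (q - p))
      }
      keep[[k]] <- pts
    }
    out <- do.call(rbind, keep)
    if (is.null(out)) return(matrix(numeric(0), 0, 2))
  }
  out
}

# Area of intersection between a polygon and a convex cell.
intersection_area_convex <- function(subject, clip) {
  clipped <- clip_polygon_convex(subject, ensure_ccw(clip))
  if (nrow(clipped) < 3L) return(0)
  polygon_area(clipped)
}

# Reorient a ring counter-clockwise (required of clip polygons).
ensure_ccw <- function(poly) {
  if (polygon_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# Axis-aligned bounding box of a polygon: c(xmin, xmax, ymin, ymax).
polygon_bbox <- function(poly) {
  c(min(poly[, 1]), max(poly[, 1]), min(poly[, 2]), max(poly[, 2]))
}

bbox_overlap <- function(a, b) {
  a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
}

# Regular hexagon (pointy-top) vertices around a centre, counter-clockwise.
hex_vertices <- function(cx, cy, s) {
  ang <- (seq(30, 330, by = 60)) * pi / 180
  cbind(cx + s * cos(ang), cy + s * sin(ang))
}

# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
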