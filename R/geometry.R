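# Planar geometry primitives: polygon areas, convex clipping, point-in-polygon,
# and the 4-point pixel-to-world homography.
#
# Coordinate convention throughout: image origin at the top-left corner,
# x rightward, y downward, pixel centers at integer coordinates. Polygons are
# n x 2 matrices of vertices in order (either winding); they are treated as
# closed (last vertex joins the first).

#' Signed and absolute polygon area
#'
#' Shoelace formula. `polygon_area()` returns the absolute area; the signed
#' version is internal (sign depends on winding).
#'
#' @param poly numeric matrix with two columns (x, y), one row per vertex.
#' @return Non-negative scalar area in squared input units.
#' @export
polygon_area <- function(poly) {
  abs(polygon_area_signed(poly))
}

polygon_area_signed <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || !is.numeric(poly)) {
    stop("polygon must be a numeric matrix with columns (x, y)", call. = FALSE)
  }
  if (any(!is.finite(poly))) stop("polygon vertices must be finite", call. = FALSE)
  storage.mode(poly) <- "double"
  poly
}

#' Test whether a point lies inside a polygon
#'
#' Even-odd (ray casting) rule; points on an edge count as inside.
#'
#' @param pt length-2 numeric (x, y).
#' @param poly polygon matrix.
#' @return logical scalar.
#' @export
point_in_polygon <- function(pt, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  x <- pt[1]; y <- pt[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    d <- abs((xj - xi) * (y - yi) - (x - xi) * (yj - yi))
    if (d < 1e-12 &&
        x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
        y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
      return(TRUE)
    }
    if ((yi > y) != (yj > y)) {
      xcross <- xi + (y - yi) * (xj - xi) / (yj - yi)
      if (x < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Sutherland-Hodgman clipping of `subject` against a convex `clip` polygon.
# Exact for convex-convex pairs; `clip` must be convex.
convex_clip <- function(subject, clip) {
  subject <- as_polygon(subject)
  clip <- as_polygon(clip)
  if (polygon_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    # clip has positive signed area, so its interior is the left side of each
    # directed edge: cross(b - a, p - a) >= 0
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    for (i in seq_len(np)) {
      cur <- inp[i, ]; prv <- inp[if (i == 1) np else i - 1, ]
      sc <- side(cur); sp <- side(prv)
      if (sc >= -1e-12) {
        if (sp < -1e-12) out <- rbind(out, seg_intersect(prv, cur, a, b))
        out <- rbind(out, cur)
      } else if (sp >= -1e-12) {
        out <- rbind(out, seg_intersect(prv, cur, a, b))
      }
    }
  }
  out
}

seg_intersect <- function(p1, p2, a, b) {
  # intersection of segment p1-p2 with the infinite line a-b
  d1 <- (b[1] - a[1]) * (p1[2] - a[2]) - (b[2] - a[2]) * (p1[1] - a[1])
  d2 <- (b[1] - a[1]) * (p2[2] - a[2]) - (b[2] - a[2]) * (p2[1] - a[1])
  t <- d1 / (d1 - d2)
  p1 + t * (p2 - p1)
}

#' Intersection area of two convex polygons
#'
#' @param a,b polygon matrices (convex).
#' @return scalar area of the overlap region.
#' @export
polygon_intersection_area <- function(a, b) {
  inter <- convex_clip(a, b)
  if (nrow(inter) < 3) return(0)
  polygon_area(inter)
}

#' Intersection-over-union of two convex polygons
#'
#' @param a,b polygon matrices (convex).
#' @return IoU in \[0, 1\].
#' @export
polygon_iou <- function(a, b) {
  ia <- polygon_intersection_area(a, b)
  ua <- polygon_area(a) + polygon_area(b) - ia
  if (ua <= 0) return(0)
  ia / ua
}

collinear3 <- function(p, q, r, tol = 1e-9) {
  cr <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  scale <- max(abs(c(p, q, r)), 1)
  abs(cr) < tol * scale^2
}

any_three_collinear <- function(pts, tol = 1e-9) {
  cmb <- utils::combn(nrow(pts), 3)
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[, k]
    if (collinear3(pts[i[1], ], pts[i[2], ], pts[i[3], ], tol)) return(TRUE)
  }
  FALSE
}

#' Pixel-to-world perspective (homography) transform for a pen
#'
#' Computes the 3x3 projective matrix H mapping the four configured pen-corner
#' pixels to the corners of the world rectangle, via the 4-point direct linear
#' solution. Corner i maps to (0,0), (L,0), (L,W), (0,W) in centimetres, in
#' the configured order (clockwise in the image from the corner chosen as the
#' world origin); the pen length L runs along the world x axis.
#'
#' @param corners_px 4x2 matrix of pixel corner coordinates, ordered.
#' @param world_dims length-2 numeric `(length_cm, width_cm)`; defaults to the
#'   580 x 380 cm pen of the reference setup.
#' @return object of class `world_transform` with elements `H`, `Hinv`,
#'   `corners_px`, `world_dims`.
#' @export
compute_world_transform <- function(corners_px, world_dims = c(580, 380)) {
  corners_px <- as_polygon(corners_px)
  if (nrow(corners_px) != 4) stop("exactly 4 pixel corners required", call. = FALSE)
  if (any(world_dims <= 0)) stop("world dimensions must be positive", call. = FALSE)
  if (any_three_collinear(corners_px)) {
    stop("degenerate homography: three pen corners are collinear", call. = FALSE)
  }
  L <- world_dims[1]; W <- world_dims[2]
  dst <- rbind(c(0, 0), c(L, 0), c(L, W), c(0, W))
  H <- solve_homography(corners_px, dst)
  structure(
    list(H = H, Hinv = solve(H), corners_px = corners_px,
         world_dims = c(length_cm = L, width_cm = W)),
    class = "world_transform"
  )
}

# Direct linear solution of the 8 unknowns of H (h33 = 1) from 4 point pairs.
solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8)
  rhs <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    rhs[2 * i - 1] <- u
    rhs[2 * i]     <- v
  }
  h <- solve(A, rhs)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Apply a homography to points
#'
#' @param transform `world_transform` object.
#' @param xy n x 2 matrix (or length-2 vector) of points.
#' @param inverse if TRUE map world (cm) back to pixels.
#' @return n x 2 matrix of mapped points.
#' @export
apply_transform <- function(transform, xy, inverse = FALSE) {
  stopifnot(inherits(transform, "world_transform"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy <- as.matrix(xy)
  H <- if (inverse) transform$Hinv else transform$H
  hom <- cbind(xy, 1) %*% t(H)
  out <- hom[, 1:2, drop = FALSE] / hom[, 3]
  colnames(out) <- if (inverse) c("x_px", "y_px") else c("x_cm", "y_cm")
  out
}

#' @export
print.world_transform <- function(x, ...) {
  cat("world_transform: pen", x$world_dims[1], "x", x$world_dims[2], "cm\n")
  print(signif(x$H, 6))
  invisible(x)
}
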