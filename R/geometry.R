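# Exact 3D primitives. All coordinates are world millimetres in the LPS frame
# (+x patient-left, +y posterior, +z superior); angles are degrees.

RAD2DEG <- 180 / pi

#' Validate a 3D point
#'
#' Points are plain numeric vectors of length 3 (x, y, z) in millimetres,
#' LPS frame. All components must be finite.
#'
#' @param p numeric vector of length 3.
#' @param what label used in error messages.
#' @return the point, as a plain unnamed numeric vector.
#' @export
as_point3 <- function(p, what = "point") {
  p <- unname(as.numeric(p))
  if (length(p) != 3L || !all(is.finite(p))) {
    stop(sprintf("%s must be a finite numeric vector of length 3", what),
         call. = FALSE)
  }
  p
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a reference plane through three points
#'
#' The plane is stored in Hessian normal form: the locus of points `p` with
#' `normal %*% p == offset`, `|normal| == 1`. The normal is the normalised
#' cross product of `p2 - p1` and `p3 - p1`, with its sign fixed so the
#' z-component is non-negative ("superior" side well defined); ties are broken
#' by making the first nonzero component positive. Angle computations use the
#' absolute dot product, so the sign convention cannot change any result.
#'
#' @param p1,p2,p3 points (numeric length-3, mm).
#' @param ids optional character vector of length 3 naming the landmarks the
#'   points came from; used in error messages and kept in the result.
#' @return an object of class `reference_plane`: a list with elements
#'   `normal` (unit 3-vector), `offset` (mm), `points` (3x3 matrix, one
#'   defining point per row) and `ids`.
#' @examples
#' pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' pl$normal  # (0, 0, 1)
#' @export
plane_from_points <- function(p1, p2, p3, ids = NULL) {
  p1 <- as_point3(p1, "p1"); p2 <- as_point3(p2, "p2"); p3 <- as_point3(p3, "p3")
  n <- cross3(p2 - p1, p3 - p1)
  nn <- sqrt(sum(n^2))
  # |cross| = 2 * triangle area; degenerate below 1e-9 mm^2
  if (nn <= 2e-9) {
    lab <- if (is.null(ids)) "p1, p2, p3" else paste(ids, collapse = ", ")
    stop(sprintf("degenerate plane: points %s are collinear or coincident", lab),
         call. = FALSE)
  }
  n <- n / nn
  # sign convention: z-component >= 0, ties broken by first nonzero positive
  key <- c(n[3], n[1], n[2])
  first <- key[which(abs(key) > 0)[1]]
  if (first < 0) n <- -n
  structure(
    list(normal = n, offset = sum(n * p1),
         points = rbind(p1, p2, p3, deparse.level = 0), ids = ids),
    class = "reference_plane"
  )
}

#' @export
print.reference_plane <- function(x, ...) {
  cat(sprintf("Reference plane: normal (%.6f, %.6f, %.6f), offset %.4f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  if (!is.null(x$ids)) cat("  defined by:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Signed point-to-plane distance
#'
#' @param plane a `reference_plane`.
#' @param p a point.
#' @return signed distance in mm (positive on the side the normal points to).
#' @export
plane_distance_mm <- function(plane, p) {
  p <- as_point3(p)
  sum(plane$normal * p) - plane$offset
}

#' Angle between a line segment and a plane, in degrees
#'
#' Returns `asin(|n . d|) * 180 / pi` where `d` is the unit vector from `a`
#' to `b` and `n` the plane's unit normal. The result lies in \[0, 90\] and is
#' independent of segment direction and of the normal's sign.
#'
#' @param a,b segment endpoints (mm). Must be distinct.
#' @param plane a `reference_plane`.
#' @return angle in degrees.
#' @export
line_plane_angle_deg <- function(a, b, plane) {
  a <- as_point3(a, "a"); b <- as_point3(b, "b")
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length segment: endpoints coincide", call. = FALSE)
  s <- abs(sum(plane$normal * d)) / len
  asin(min(1, s)) * RAD2DEG
}

#' Euclidean distance between two points, mm
#'
#' @param a,b points (mm).
#' @return distance in mm.
#' @export
distance_mm <- function(a, b) {
  a <- as_point3(a, "a"); b <- as_point3(b, "b")
  sqrt(sum((b - a)^2))
}

#' Construct a rigid (proper orthogonal) transform
#'
#' @param rotation 3x3 rotation matrix: orthonormal with determinant +1
#'   (checked to 1e-9).
#' @param translation length-3 translation vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as_point3(translation, "translation")
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be a 3x3 orthonormal matrix with determinant +1",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to a point
#'
#' @param t a `rigid_transform`.
#' @param p a point (mm).
#' @return the transformed point `R p + translation`.
#' @export
apply_rigid <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  p <- as_point3(p)
  as.numeric(t$rotation %*% p) + t$translation
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis one of "x", "y", "z".
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
axis_rotation <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  th <- angle_deg / RAD2DEG
  c0 <- cos(th); s0 <- sin(th)
  switch(axis,
    x = rbind(c(1, 0, 0), c(0, c0, -s0), c(0, s0, c0)),
    y = rbind(c(c0, 0, s0), c(0, 1, 0), c(-s0, 0, c0)),
    z = rbind(c(c0, -s0, 0), c(s0, c0, 0), c(0, 0, 1)))
}
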