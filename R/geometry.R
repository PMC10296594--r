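# Vector geometry primitives on C-alpha coordinates.  All angles are in
# degrees; all distances in Angstroms.  Inputs are plain numeric 3-vectors.

RAD2DEG <- 180 / pi

vec_norm <- function(v) sqrt(sum(v^2))

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

check_vec3 <- function(v, arg) {
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v))) {
    stop(sprintf("`%s` must be a finite numeric 3-vector", arg), call. = FALSE)
  }
  as.numeric(v)
}

abort_geometry <- function(msg) {
  rlang::abort(msg, class = "catrace_invalid_geometry")
}

#' Angle between two vectors
#'
#' Arc-cosine of the normalised dot product, in degrees.
#'
#' @param u,v Numeric 3-vectors. Must be nonzero.
#' @return Angle in `[0, 180]` degrees.
#' @examples
#' vector_angle(c(1, 0, 0), c(0, 1, 0)) # 90
#' @export
vector_angle <- function(u, v) {
  u <- check_vec3(u, "u")
  v <- check_vec3(v, "v")
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu == 0 || nv == 0) abort_geometry("zero-length vector in vector_angle()")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * RAD2DEG
}

#' Interior angle at the middle point of a point triple
#'
#' The angle at `q` of the triangle `(p, q, r)`, e.g. the pseudo bond angle
#' at a C-alpha atom given its sequence neighbours.
#'
#' @param p,q,r Numeric 3-vectors; `q` is the vertex.
#' @return Angle in `[0, 180]` degrees.
#' @examples
#' interior_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
#' @export
interior_angle <- function(p, q, r) {
  p <- check_vec3(p, "p")
  q <- check_vec3(q, "q")
  r <- check_vec3(r, "r")
  a <- p - q
  b <- r - q
  if (vec_norm(a) == 0 || vec_norm(b) == 0) {
    abort_geometry("zero-length arm in interior_angle()")
  }
  vector_angle(a, b)
}

#' Signed torsion (dihedral) angle of four points
#'
#' The angle between the plane through `(p1, p2, p3)` and the plane through
#' `(p2, p3, p4)`, signed with the IUPAC convention (right-handed rotations
#' positive, cis = 0, trans = 180).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Signed dihedral in `(-180, 180]` degrees.
#' @examples
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)) # 0 (cis)
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  p1 <- check_vec3(p1, "p1")
  p2 <- check_vec3(p2, "p2")
  p3 <- check_vec3(p3, "p3")
  p4 <- check_vec3(p4, "p4")
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  if (vec_norm(n1) == 0 || vec_norm(n2) == 0) {
    abort_geometry("collinear triple in torsion_angle()")
  }
  b2u <- b2 / vec_norm(b2)
  x <- sum(n1 * n2)
  y <- sum(vec_cross(n1, n2) * b2u)
  ang <- atan2(y, x) * RAD2DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

project_on_line <- function(p, a, b) {
  d <- b - a
  a + sum((p - a) * d) / sum(d * d) * d
}

#' Distance along a virtual axis
#'
#' Distance between two points after optionally projecting either of them
#' orthogonally onto the infinite line through `axis_a` and `axis_b`.  This
#' is the primitive behind the axis-distance block of the residue
#' descriptor, where a virtual axis is drawn through two flanking C-alpha
#' atoms and distances are measured between atoms and/or their projections
#' on that axis.
#'
#' @param axis_a,axis_b Two distinct points defining the axis.
#' @param from_pt,to_pt The points measured.
#' @param project_from,project_to Whether to replace each point by its
#'   orthogonal projection onto the axis before measuring.
#' @return Distance in Angstroms.
#' @export
axis_distance <- function(axis_a, axis_b, from_pt, to_pt,
                          project_from = FALSE, project_to = FALSE) {
  axis_a <- check_vec3(axis_a, "axis_a")
  axis_b <- check_vec3(axis_b, "axis_b")
  from_pt <- check_vec3(from_pt, "from_pt")
  to_pt <- check_vec3(to_pt, "to_pt")
  if (vec_norm(axis_b - axis_a) == 0) {
    abort_geometry("degenerate axis in axis_distance()")
  }
  f <- if (project_from) project_on_line(from_pt, axis_a, axis_b) else from_pt
  t <- if (project_to) project_on_line(to_pt, axis_a, axis_b) else to_pt
  vec_norm(f - t)
}

#' Distance from a point to the line through a segment
#'
#' Returns the perpendicular distance from `p` to the infinite line through
#' `a` and `b`, together with whether the foot of the perpendicular lies
#' within the segment `[a, b]` (inclusive).  Used by the neighborhood
#' filter, which keeps residue k only when its C-alpha projects inside the
#' segment between the query residue's sequence neighbours.
#'
#' @param p Query point.
#' @param a,b Segment endpoints, `a != b`.
#' @return A list with elements `distance` (Angstroms) and `inside`
#'   (logical).
#' @export
point_segment_distance <- function(p, a, b) {
  p <- check_vec3(p, "p")
  a <- check_vec3(a, "a")
  b <- check_vec3(b, "b")
  d <- b - a
  if (vec_norm(d) == 0) abort_geometry("degenerate segment in point_segment_distance()")
  t <- sum((p - a) * d) / sum(d * d)
  foot <- a + t * d
  list(distance = vec_norm(p - foot), inside = t >= 0 && t <= 1)
}

# Uniform random proper rotation (QR of a Gaussian matrix, det forced +1).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
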