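# Small 3D geometry kernel shared by the builders and classifiers.
# All coordinates in Angstrom, all angles in degrees.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle at vertex b of the triple a-b-c, in degrees
#' @noRd
angle3 <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Torsion angle of the atom chain p1-p2-p3-p4
#'
#' Signed dihedral in (-180, 180]; invariant under reversal of the chain.
#' @noRd
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

#' Place atom d given positions a, b, c and internal coordinates
#'
#' Returns d with |d - c| = bond, angle(b, c, d) = angle and
#' dihedral(a, b, c, d) = dih (NeRF construction).
#' @noRd
place_atom <- function(a, b, c, bond, angle, dih) {
  angle <- deg2rad(angle)
  dih <- deg2rad(dih)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(dih), sin(angle) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix for a rotation by `angle` degrees about unit axis
#' @noRd
rotmat_axis <- function(axis, angle) {
  u <- unitv(axis)
  th <- deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

#' Random proper rotation (uniform via QR of a Gaussian matrix)
#' @noRd
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Least-squares plane of a point cloud
#'
#' Returns list(center, normal); normal is the unit vector of least variance.
#' @noRd
ls_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  list(center = ctr, normal = s$v[, 3])
}

#' Shoelace area of a 2D polygon (vertices in order, n x 2 matrix)
#' @noRd
polygon_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Intersection of two convex polygons by Sutherland-Hodgman clipping
#'
#' Both polygons as n x 2 matrices with vertices in counter-clockwise order.
#' Returns the clipped polygon (possibly with 0 rows).
#' @noRd
convex_clip <- function(subject, clip) {
  ensure_ccw <- function(p) {
    n <- nrow(p)
    s <- sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])
    if (s < 0) p[n:1, , drop = FALSE] else p
  }
  subject <- ensure_ccw(subject)
  clip <- ensure_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    # inside = left of directed edge a -> b
    edge <- b - a
    inside <- function(p) edge[1] * (p[2] - a[2]) - edge[2] * (p[1] - a[1]) >= -1e-12
    isect <- function(p, q) {
      # intersection of segment p-q with the infinite edge line
      r <- q - p
      denom <- edge[1] * r[2] - edge[2] * r[1]
      t <- (edge[1] * (a[2] - p[2]) - edge[2] * (a[1] - p[1])) / denom
      p + t * r
    }
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      cur <- inp[j, ]
      prv <- inp[if (j == 1) np else j - 1, ]
      ci <- inside(cur); pi_ <- inside(prv)
      if (ci) {
        if (!pi_) out <- rbind(out, isect(prv, cur))
        out <- rbind(out, cur)
      } else if (pi_) {
        out <- rbind(out, isect(prv, cur))
      }
    }
  }
  out
}

#' Area of intersection of two convex polygons
#' @noRd
convex_intersection_area <- function(p1, p2) {
  polygon_area(convex_clip(p1, p2))
}
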