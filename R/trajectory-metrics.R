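# Trajectory-level observables: base-stacking overlap areas by polygon
# projection, helical twist between base pairs and hydrogen-bond distance
# distributions.

# resolve a base-pair reference: an imclip_base_pair or
# list(res1 = list(chain, resno), res2 = list(chain, resno))
bp_residues <- function(model, bp) {
  if (inherits(bp, "imclip_base_pair"))
    return(list(r1 = bp$res1, r2 = bp$res2))
  list(r1 = list(chain = bp[[1]][[1]], resno = as.integer(bp[[1]][[2]])),
       r2 = list(chain = bp[[2]][[1]], resno = as.integer(bp[[2]][[2]])))
}

bp_atoms <- function(model, bp, exocyclic = FALSE) {
  rs <- bp_residues(model, bp)
  get1 <- function(r) {
    ty <- residue_type(model, r$chain, r$resno)
    nm <- ring_atom_names(ty)
    if (exocyclic) nm <- c(nm, exocyclic_heavy_names(ty))
    residue_xyz(model, r$chain, r$resno, nm)
  }
  rbind(get1(rs$r1), get1(rs$r2))
}

bp_normal <- function(model, bp) {
  ls_plane(bp_atoms(model, bp, exocyclic = FALSE))$normal
}

#' Base-stacking overlap area of two base pairs
#'
#' Projects the atoms of both base pairs onto the least-squares mean
#' plane of the union of their ring atoms, takes the convex hull of each
#' pair and intersects the two hulls by polygon clipping. The area is
#' computed for ring atoms only and for ring plus exocyclic heavy atoms
#' (the variant usually quoted for 3DNA-style overlaps). Steps with
#' nearly perpendicular pair planes (normals > 65 deg apart) are still
#' computed but flagged unreliable.
#'
#' @param model StructureModel
#' @param bp_i,bp_j base pairs: \code{imclip_base_pair} objects or lists
#'   of two \code{list(chain, resno)} references
#' @return object of class \code{imclip_overlap} with \code{area_ring},
#'   \code{area_with_exocyclic} (A^2) and \code{unreliable}
#' @export
stacking_overlap <- function(model, bp_i, bp_j) {
  ring_i <- bp_atoms(model, bp_i, exocyclic = FALSE)
  ring_j <- bp_atoms(model, bp_j, exocyclic = FALSE)
  n1 <- ls_plane(ring_i)$normal
  n2 <- ls_plane(ring_j)$normal
  if (sum(n1 * n2) < 0) n2 <- -n2
  tilt <- rad2deg(acos(min(1, abs(sum(n1 * n2)))))
  # project onto the mean base-pair plane of the step (the individual pair
  # planes are well conditioned; the union cloud is not)
  pl <- list(center = (colMeans(ring_i) + colMeans(ring_j)) / 2,
             normal = unitv(n1 + n2))
  basis <- plane_basis(pl$normal)
  proj <- function(xyz) {
    rel <- sweep(xyz, 2, pl$center)
    cbind(rel %*% basis$u, rel %*% basis$v)
  }
  area_pair <- function(exo) {
    p1 <- proj(bp_atoms(model, bp_i, exocyclic = exo))
    p2 <- proj(bp_atoms(model, bp_j, exocyclic = exo))
    h1 <- p1[grDevices::chull(p1), , drop = FALSE]
    h2 <- p2[grDevices::chull(p2), , drop = FALSE]
    convex_intersection_area(h1, h2)
  }
  structure(list(area_ring = area_pair(FALSE),
                 area_with_exocyclic = area_pair(TRUE),
                 tilt = tilt, unreliable = tilt > 65),
            class = "imclip_overlap")
}

#' @export
print.imclip_overlap <- function(x, ...) {
  cat(sprintf("Stacking overlap: ring %.2f A^2, ring+exocyclic %.2f A^2 (tilt %.1f deg%s)\n",
              x$area_ring, x$area_with_exocyclic, x$tilt,
              if (x$unreliable) ", unreliable: near-perpendicular planes" else ""))
  invisible(x)
}

# orthonormal in-plane basis for a plane normal
plane_basis <- function(normal) {
  n <- unitv(normal)
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitv(cross3(n, a))
  v <- cross3(n, u)
  list(u = u, v = v)
}

#' Helical twist between two base pairs
#'
#' The signed angle, in (-180, 180], between the two C1'->C1' vectors
#' (strand a to strand b of each pair) projected onto the step's mean
#' plane, with the sign taken about the mean base-pair normal.
#'
#' @param model StructureModel
#' @param bp_i,bp_j base pairs as in \code{\link{stacking_overlap}}
#' @return twist angle in degrees
#' @export
helical_twist <- function(model, bp_i, bp_j) {
  c1vec <- function(bp) {
    rs <- bp_residues(model, bp)
    a <- atom_xyz(model, rs$r1$chain, rs$r1$resno, "C1'")
    b <- atom_xyz(model, rs$r2$chain, rs$r2$resno, "C1'")
    if (vnorm(b - a) < 1e-6) stop("coincident C1' positions")
    b - a
  }
  v1 <- c1vec(bp_i)
  v2 <- c1vec(bp_j)
  n1 <- bp_normal(model, bp_i)
  n2 <- bp_normal(model, bp_j)
  if (sum(n1 * n2) < 0) n2 <- -n2
  n <- unitv(n1 + n2)
  # orient the step normal from bp_i toward bp_j so the sign is defined
  ctr <- function(bp) ls_plane(bp_atoms(model, bp, exocyclic = FALSE))$center
  if (sum(n * (ctr(bp_j) - ctr(bp_i))) < 0) n <- -n
  p1 <- unitv(v1 - sum(v1 * n) * n)
  p2 <- unitv(v2 - sum(v2 * n) * n)
  rad2deg(atan2(sum(cross3(p1, p2) * n), sum(p1 * p2)))
}

#' Hydrogen-bond distance distribution over a trajectory
#'
#' Computes the heavy-atom donor-acceptor distance in every frame and
#' histograms it with fixed-width bins. Densities integrate to one.
#'
#' @param traj \code{imclip_trajectory}
#' @param donor,acceptor atom references: \code{list(chain, resno, name)}
#' @param bin_width A (default 0.1)
#' @return object of class \code{imclip_disthist} with \code{breaks},
#'   \code{density}, \code{mids}, \code{n_frames}, \code{mode} and
#'   \code{frac_bonded} (fraction of frames < 3.5 A)
#' @export
hbond_distance_series <- function(traj, donor, acceptor, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin width must be positive")
  nf <- n_frames(traj)
  if (nf < 1) stop("empty trajectory")
  at <- traj$topology$atoms
  idx <- function(a) {
    i <- which(at$chain == a$chain & at$resno == a$resno & at$name == a$name)
    if (length(i) != 1) stop("atom not found in topology: ",
                             paste(a$chain, a$resno, a$name))
    i
  }
  i1 <- idx(donor); i2 <- idx(acceptor)
  d <- sqrt(colSums((traj$coords[i1, , ] - traj$coords[i2, , ])^2))
  if (nf == 1) d <- vnorm(traj$coords[i1, , 1] - traj$coords[i2, , 1])
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(donor = donor, acceptor = acceptor,
                 breaks = h$breaks, density = h$density, mids = h$mids,
                 counts = h$counts, distances = d, n_frames = nf,
                 mode = h$mids[which.max(h$counts)],
                 frac_bonded = mean(d < 3.5)),
            class = "imclip_disthist")
}

#' @export
print.imclip_disthist <- function(x, ...) {
  cat(sprintf("H-bond distance distribution over %d frames: mode %.2f A, %.1f%% < 3.5 A\n",
              x$n_frames, x$mode, 100 * x$frac_bonded))
  invisible(x)
}

#' @export
plot.imclip_disthist <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h",
                 xlab = "Donor-acceptor distance (A)", ylab = "Density", ...)
  graphics::abline(v = 3.5, lty = 2)
  invisible(x)
}

#' Monte-Carlo reference for a convex polygon intersection area
#'
#' Point-sampling estimate used as an independent check of the clipping
#' algorithm: samples uniformly over the bounding box of the two hulls
#' and counts points inside both.
#'
#' @param p1,p2 polygons (n x 2 matrices, convex)
#' @param n number of sample points
#' @return estimated intersection area
#' @export
mc_intersection_area <- function(p1, p2, n = 1e5) {
  lo <- pmin(apply(p1, 2, min), apply(p2, 2, min))
  hi <- pmax(apply(p1, 2, max), apply(p2, 2, max))
  pts <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]))
  inside <- in_convex(pts, p1) & in_convex(pts, p2)
  mean(inside) * prod(hi - lo)
}

# vectorized point-in-convex-polygon (vertices in CCW or CW order)
in_convex <- function(pts, poly) {
  n <- nrow(poly)
  # orient CCW
  s <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  if (s < 0) poly <- poly[n:1, , drop = FALSE]
  ok <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    ok <- ok & ((b[1] - a[1]) * (pts[, 2] - a[2]) -
                  (b[2] - a[2]) * (pts[, 1] - a[1]) >= 0)
  }
  ok
}
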