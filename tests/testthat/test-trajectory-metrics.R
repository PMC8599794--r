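# Trajectory observables: subsampling, stacking overlap, helical twist,
# distance histograms and average structures.

test_that("subsampling keeps frames at multiples of the stride, excluding t=0", {
  m <- fixture_model()
  tr <- perturb_trajectory(m, n_frames = 10000, amplitude = 0, timestep = 100)
  sub <- subsample(tr, 100)
  expect_equal(n_frames(sub), 10000) # 1 us at 100 ps
  tr1ns <- perturb_trajectory(m, n_frames = 100, amplitude = 0, timestep = 10)
  expect_equal(n_frames(subsample(tr1ns, 100)), 10) # 1 ns at 100 ps
  expect_equal(n_frames(subsample(tr1ns, 1000)), 1) # stride = full length
  expect_error(subsample(tr1ns, 5), "native")
  expect_error(subsample(tr1ns, 15), "grid")
})

test_that("stacking overlap matches simple geometric limits", {
  m <- fixture_model()
  pairs <- find_base_pairs(m)
  names(pairs) <- vapply(pairs, function(p)
    paste0(p$res1$chain, p$res1$resno), character(1))
  # a pair eclipsed with a 3.4 A translated copy of itself overlaps in
  # its own full hull area
  bp <- pairs[["A4"]]
  m2 <- m
  dup <- m$atoms$resno == 4 & m$atoms$chain %in% c("A", "B")
  shifted <- m$atoms[dup, ]
  shifted$resno <- 99L
  shifted$z <- shifted$z + 3.4
  m2$atoms <- rbind(m2$atoms, shifted)
  bp99 <- list(list(chain = "A", resno = 99), list(chain = "B", resno = 99))
  ov <- stacking_overlap(m2, bp, bp99)
  ring <- imclip:::bp_atoms(m2, bp, exocyclic = FALSE)
  hull2d <- ring[grDevices::chull(ring[, 1:2]), 1:2]
  own <- imclip:::polygon_area(hull2d)
  expect_equal(ov$area_ring, own, tolerance = 1e-6)
  expect_false(ov$unreliable)
  # a 20 A lateral displacement kills the overlap
  far <- m$atoms[dup, ]
  far$resno <- 98L
  far$x <- far$x + 20
  m3 <- m
  m3$atoms <- rbind(m3$atoms, far)
  bp98 <- list(list(chain = "A", resno = 98), list(chain = "B", resno = 98))
  expect_equal(stacking_overlap(m3, bp, bp98)$area_ring, 0)
  # invariants on real steps
  ov2 <- stacking_overlap(m, pairs[["A3"]], pairs[["A4"]])
  expect_lte(ov2$area_ring, ov2$area_with_exocyclic + 1e-9)
  expect_gte(ov2$area_ring, 0)
  # symmetry in the arguments
  ov3 <- stacking_overlap(m, pairs[["A4"]], pairs[["A3"]])
  expect_equal(ov2$area_ring, ov3$area_ring, tolerance = 1e-9)
  expect_equal(ov2$area_with_exocyclic, ov3$area_with_exocyclic, tolerance = 1e-9)
})

test_that("near-perpendicular pair planes are computed but flagged unreliable", {
  # the orthogonal-duplex junction pairs of the compact topology remain
  # plane-parallel (rotated about the stack axis), so the flag must stay off
  m <- build_model(topology_spec("AGAGCCC", "3'E", chi = c("4" = 60)))
  pairs <- find_base_pairs(m)
  names(pairs) <- vapply(pairs, function(p) {
    dup <- m$atoms$duplex[m$atoms$chain == p$res1$chain][1]
    paste0(dup, p$res1$resno)
  }, character(1))
  ov0 <- stacking_overlap(m, pairs[["I4"]], pairs[["II7"]])
  expect_false(ov0$unreliable)
  # a pair tipped by 80 deg about an in-plane axis triggers the flag
  m2 <- m
  dup <- m$atoms$resno == 4 & m$atoms$chain %in% c("A", "B")
  seg <- m$atoms[dup, ]
  ctr <- colMeans(as.matrix(seg[, c("x", "y", "z")]))
  xyz <- sweep(as.matrix(seg[, c("x", "y", "z")]), 2, ctr) %*%
    t(imclip:::rotmat_axis(c(1, 0, 0), 80))
  xyz <- sweep(xyz, 2, -ctr)
  seg$x <- xyz[, 1]; seg$y <- xyz[, 2]; seg$z <- xyz[, 3]
  seg$resno <- 99L
  m2$atoms <- rbind(m2$atoms, seg)
  ov <- stacking_overlap(m2, pairs[["I5"]],
                         list(list(chain = "A", resno = 99),
                              list(chain = "B", resno = 99)))
  expect_true(ov$unreliable)
  expect_gt(ov$tilt, 65)
})

test_that("polygon intersection agrees with the Monte-Carlo oracle", {
  # unit squares offset by half a side: area exactly 0.5
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sq2 <- sq; sq2[, 1] <- sq2[, 1] + 0.5
  expect_equal(imclip:::convex_intersection_area(sq, sq2), 0.5, tolerance = 1e-12)
  set.seed(21)
  expect_equal(mc_intersection_area(sq, sq2, n = 2e5), 0.5, tolerance = 0.01)
  # random convex polygons
  for (k in 1:10) {
    p1 <- matrix(stats::rnorm(16, sd = 2), ncol = 2)
    p2 <- sweep(matrix(stats::rnorm(16, sd = 2), ncol = 2), 2, stats::runif(2, -1, 1))
    h1 <- p1[grDevices::chull(p1), ]
    h2 <- p2[grDevices::chull(p2), ]
    a_poly <- imclip:::convex_intersection_area(h1, h2)
    a_mc <- mc_intersection_area(h1, h2, n = 2e5)
    ref <- min(imclip:::polygon_area(h1), imclip:::polygon_area(h2))
    expect_lt(abs(a_poly - a_mc), 0.015 * ref + 0.01)
    expect_lte(a_poly, ref + 1e-9)
  }
})

test_that("helical twist equals a constructed rotation angle", {
  m <- fixture_model()
  pairs <- find_base_pairs(m)
  names(pairs) <- vapply(pairs, function(p)
    paste0(p$res1$chain, p$res1$resno), character(1))
  bp <- pairs[["A4"]]
  rotated_copy <- function(angle) {
    m2 <- m
    dup <- m$atoms$resno == 4 & m$atoms$chain %in% c("A", "B")
    seg <- m$atoms[dup, ]
    xyz <- as.matrix(seg[, c("x", "y", "z")]) %*%
      t(imclip:::rotmat_axis(c(0, 0, 1), angle))
    seg$x <- xyz[, 1]; seg$y <- xyz[, 2]; seg$z <- xyz[, 3] - 3.4
    seg$resno <- 99L
    m2$atoms <- rbind(m2$atoms, seg)
    m2
  }
  bp99 <- list(list(chain = "A", resno = 99), list(chain = "B", resno = 99))
  for (ang in c(0, 30, -150)) {
    m2 <- rotated_copy(ang)
    tw <- helical_twist(m2, bp, bp99)
    # sign convention: the step normal points from bp_i to bp_j (here -z),
    # so a rotation by +ang about +z reads as -ang about the step normal
    expect_equal(tw, -ang, tolerance = 1e-6)
  }
  # in-model: consecutive same-duplex CH+.C pairs are two 15-deg slots apart
  expect_equal(abs(helical_twist(m, pairs[["A1"]], pairs[["A2"]])), 30,
               tolerance = 1e-6)
  expect_equal(helical_twist(m, bp, bp), 0)
})

test_that("distance histograms are normalized and match jitter statistics", {
  m <- fixture_model()
  don <- list(chain = "A", resno = 4, name = "N2")
  acc <- list(chain = "B", resno = 4, name = "N3")
  tr0 <- perturb_trajectory(m, n_frames = 10, amplitude = 0)
  h0 <- hbond_distance_series(tr0, don, acc)
  expect_equal(sum(h0$counts > 0), 1) # single occupied bin
  expect_equal(h0$mode, 2.9, tolerance = 0.06)
  expect_equal(h0$frac_bonded, 1.0)
  expect_equal(sum(h0$density) * 0.1, 1, tolerance = 1e-9)
  # sigma = 0.2 jitter: distance sd ~ sqrt(2) * 0.2 at this separation
  tr <- perturb_trajectory(m, n_frames = 5000, amplitude = 0.2, seed = 4)
  h <- hbond_distance_series(tr, don, acc)
  expect_equal(stats::sd(h$distances), sqrt(2) * 0.2, tolerance = 0.1 * sqrt(2) * 0.2)
  expect_equal(sum(h$density) * 0.1, 1, tolerance = 1e-9)
  expect_error(hbond_distance_series(tr, don, list(chain = "Z", resno = 1, name = "X")),
               "not found")
})

test_that("average structures superpose and converge to the reference", {
  m <- fixture_model()
  tr0 <- perturb_trajectory(m, n_frames = 3, amplitude = 0)
  avg0 <- average_structure(tr0)
  expect_equal(xyz_of(avg0), xyz_of(m), tolerance = 1e-9)
  # mirrored jitter: mean is exactly the reference
  trm <- perturb_trajectory(m, n_frames = 2, amplitude = 0)
  delta <- matrix(stats::rnorm(length(xyz_of(m)), sd = 0.2), ncol = 3)
  trm$coords[, , 1] <- xyz_of(m) + delta
  trm$coords[, , 2] <- xyz_of(m) - delta
  # no superposition bias for symmetric perturbations of a fixed frame:
  # compare the plain coordinate mean
  expect_equal((trm$coords[, , 1] + trm$coords[, , 2]) / 2, xyz_of(m),
               ignore_attr = TRUE)
  # CLT: 1000 jittered frames at sigma = 0.3 average to < 0.05 A RMSD
  tr <- perturb_trajectory(m, n_frames = 1000, amplitude = 0.3, seed = 8)
  avg <- average_structure(tr)
  rmsd <- sqrt(mean(rowSums((xyz_of(avg) - xyz_of(m))^2)))
  expect_lt(rmsd, 0.05)
  expect_error(average_structure(perturb_trajectory(m, 1, amplitude = 0)),
               "at least 2")
})
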