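# Synthetic-data generators: melting curves, NOE buildups, models and
# jittered trajectories.

test_that("equilibrium melting curve recovers the true Tm and no hysteresis", {
  p <- thermo_params(tm_true = 37, noise_sd = 0, relax_rate_at_tm = Inf)
  heat <- generate_melting_curve(p, "heating")
  cool <- generate_melting_curve(p, "cooling")
  tm_h <- melt_fit(heat)$tm
  tm_c <- melt_fit(cool)$tm
  expect_equal(tm_h, 37.0, tolerance = 0.1)
  expect_lt(abs(tm_h - tm_c), 0.1)
  # equilibrium limit: heating and cooling coincide pointwise
  expect_equal(heat$signal, rev(cool$signal), tolerance = 1e-12)
})

test_that("slow relaxation produces heating/cooling lag matching an ODE oracle", {
  p <- thermo_params(tm_true = 39, relax_rate_at_tm = 0.05, scan_rate = 0.33)
  heat <- generate_melting_curve(p, "heating")
  cool <- generate_melting_curve(p, "cooling")
  tm_h <- melt_fit(heat)$tm
  tm_c <- melt_fit(cool)$tm
  expect_gt(tm_h, tm_c) # heating Tm above cooling Tren
  # independent oracle: brute-force forward-Euler integration of
  # df/dT = k(T)/rate (f_eq - f) on a very fine grid
  oracle <- function(direction) {
    tt <- if (direction == "heating") seq(5, 85, by = 0.001) else seq(85, 5, by = -0.001)
    f <- imclip:::fraction_folded_eq(p, tt[1])
    out <- numeric(length(tt))
    out[1] <- f
    for (i in 2:length(tt)) {
      s <- imclip:::relax_rate(p, tt[i - 1]) / p$scan_rate
      f <- f + s * (imclip:::fraction_folded_eq(p, tt[i - 1]) - f) *
        abs(tt[i] - tt[i - 1])
      f <- min(1, max(0, f))
      out[i] <- f
    }
    stats::approx(tt, out, xout = heat$temperature_C)$y
  }
  expect_equal(attr(heat, "fraction_true"), oracle("heating"), tolerance = 5e-3)
  expect_equal(attr(cool, "fraction_true"), rev(oracle("cooling")), tolerance = 5e-3)
})

test_that("melting generator is deterministic in the seed and flags out-of-grid Tm", {
  p <- thermo_params(tm_true = 37, noise_sd = 0.05, seed = 42L)
  c1 <- generate_melting_curve(p, "heating")
  c2 <- generate_melting_curve(p, "heating")
  expect_identical(c1$signal, c2$signal)
  p2 <- thermo_params(tm_true = 37, noise_sd = 0.05, seed = 43L)
  expect_false(identical(generate_melting_curve(p2, "heating")$signal, c1$signal))
  p3 <- thermo_params(tm_true = 99)
  expect_warning(out <- generate_melting_curve(p3, "heating"), "outside")
  expect_true(attr(out, "tm_outside_grid"))
  expect_error(generate_melting_curve(p, "heating", t_range = numeric(0)), "empty")
})

test_that("NOE generator follows the r^-6 law and calibration is exact when noiseless", {
  m <- fixture_model()
  bu <- generate_noe_buildup(m, pairs = NULL, lambda = 0)
  # all reference peaks: identical distances -> identical initial rates
  rates <- vapply(bu, function(b) initial_rate(b)$rate, numeric(1))
  expect_equal(max(rates) / min(rates), 1, tolerance = 1e-9)
  # rate ratio of a pair at 2x the distance is 2^-6 = 1/64
  r_ref <- cytosine_reference_distance()
  v1 <- 1e4 * r_ref^-6 * c(70, 100, 150)
  v2 <- 1e4 * (2 * r_ref)^-6 * c(70, 100, 150)
  b1 <- noe_buildup("a", list(chain = "A", resno = 1, name = "x"),
                    list(chain = "A", resno = 1, name = "y"), c(70, 100, 150), v1)
  b2 <- noe_buildup("b", list(chain = "A", resno = 1, name = "x"),
                    list(chain = "A", resno = 2, name = "y"), c(70, 100, 150), v2)
  expect_equal(initial_rate(b2)$rate / initial_rate(b1)$rate, 1 / 64,
               tolerance = 1e-9)
  expect_error(generate_noe_buildup(m, data.frame(
    chain1 = "A", resno1 = 1, atom1 = "N3",
    chain2 = "A", resno2 = 1, atom2 = "N3")), "zero")
})

test_that("noisy NOE distances are recovered within 5% in the median", {
  m <- fixture_model()
  set.seed(7)
  prs <- data.frame(chain1 = "A", resno1 = 4, atom1 = "H8",
                    chain2 = "B", resno2 = 4, atom2 = "H8")
  r_ref <- cytosine_reference_distance()
  errs <- vapply(1:100, function(s) {
    bu <- generate_noe_buildup(m, prs, noise_frac = 0.1, seed = s)
    rst <- noe_restraints(bu, r_ref = r_ref)
    truth <- attr(bu, "r_true")[1]
    abs(rst$r_calibrated[rst$peak_id == "peak001"] - truth) / truth
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("trajectory jitter has the expected displacement statistics", {
  m <- fixture_model()
  tr0 <- perturb_trajectory(m, n_frames = 3, amplitude = 0, seed = 1)
  for (i in 1:3)
    expect_equal(tr0$coords[, , i], xyz_of(m), ignore_attr = TRUE)
  tr <- perturb_trajectory(m, n_frames = 1000, amplitude = 0.3, seed = 2)
  ref <- xyz_of(m)
  # per-atom RMS displacement = amplitude * sqrt(3) for isotropic jitter
  sq <- apply((tr$coords - array(ref, dim(tr$coords)))^2, c(1, 3), sum)
  rms <- sqrt(rowMeans(sq))
  expect_equal(mean(rms), 0.3 * sqrt(3), tolerance = 0.05)
  # determinism
  tr2 <- perturb_trajectory(m, n_frames = 5, amplitude = 0.3, seed = 9)
  tr3 <- perturb_trajectory(m, n_frames = 5, amplitude = 0.3, seed = 9)
  expect_identical(tr2$coords, tr3$coords)
  expect_error(perturb_trajectory(m, 5, amplitude = -1), "amplitude")
})

test_that("trajectory timestamps span n_frames * timestep", {
  m <- fixture_model()
  tr <- perturb_trajectory(m, n_frames = 100, amplitude = 0, timestep = 100)
  expect_equal(max(tr$timestamps), 1e4)
  expect_equal(n_frames(tr), 100)
})
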