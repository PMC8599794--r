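# NOE buildup fitting, distance calibration, restraint categories and
# restraint file dialects.

test_that("initial rate fits linear and curved buildups", {
  tau <- c(70, 100, 150)
  b_lin <- noe_buildup("lin", list(chain = "A", resno = 1, name = "a"),
                       list(chain = "A", resno = 2, name = "b"), tau, 6 * tau)
  expect_equal(initial_rate(b_lin)$rate, 6, tolerance = 1e-9)
  # curved buildup with known R and lambda
  R <- 0.8; lam <- 0.001
  b_cur <- noe_buildup("cur", list(chain = "A", resno = 1, name = "a"),
                       list(chain = "A", resno = 2, name = "b"),
                       tau, R * tau * (1 - lam * tau))
  fit <- initial_rate(b_cur)
  expect_equal(fit$rate, R, tolerance = 0.01 * R)
  expect_equal(fit$lambda, lam, tolerance = 1e-6)
  # linear-only fit on curved data underestimates the rate
  expect_lt(initial_rate(b_cur, spin_diffusion = FALSE)$rate, R)
  # single-point fallback
  b1 <- noe_buildup("one", list(chain = "A", resno = 1, name = "a"),
                    list(chain = "A", resno = 2, name = "b"), 100, 5)
  expect_warning(r1 <- initial_rate(b1), "single")
  expect_equal(r1$rate, 0.05)
  b0 <- noe_buildup("zero", list(chain = "A", resno = 1, name = "a"),
                    list(chain = "A", resno = 2, name = "b"), tau, c(0, 0, 0))
  expect_error(initial_rate(b0), "all-zero")
})

test_that("distance calibration follows the r^-6 law", {
  expect_equal(calibrate_distance(1, 1), 2.48)
  expect_equal(calibrate_distance(1 / 64, 1), 4.96)
  expect_equal(calibrate_distance(64, 1), 1.24)
  expect_error(calibrate_distance(-1, 1), "positive")
})

test_that("categories partition distances with the printed bounds", {
  s <- categorize(2.4)
  expect_equal(as.character(s$category), "strong")
  expect_equal(c(s$lower, s$upper), c(1.8, 3.6))
  expect_equal(as.character(categorize(3.0)$category), "strong")
  expect_equal(as.character(categorize(3.0001)$category), "medium")
  expect_equal(c(categorize(3.5)$lower, categorize(3.5)$upper), c(2.6, 5.0))
  expect_equal(as.character(categorize(4.25)$category), "medium")
  expect_equal(as.character(categorize(4.26)$category), "weak")
  expect_equal(c(categorize(5.5)$lower, categorize(5.5)$upper), c(3.5, 6.0))
  # flags dominate regardless of distance
  for (fl in c("overlapped", "exchangeable", "long_mixing_only")) {
    fr <- categorize(2.0, fl)
    expect_equal(as.character(fr$category), "flagged")
    expect_equal(c(fr$lower, fr$upper), c(2.5, 6.5))
  }
  expect_equal(categorize(NA, "overlapped")$upper, 6.5)
  expect_error(categorize(-1), "positive")
  # monotone: larger r never maps to a tighter category
  rank <- c(strong = 1, medium = 2, weak = 3)
  rs <- sort(stats::runif(50, 1.9, 6))
  cats <- rank[vapply(rs, function(r) as.character(categorize(r)$category),
                      character(1))]
  expect_true(all(diff(cats) >= 0))
})

test_that("chi restraints use the printed ranges and force constant", {
  g <- chi_restraint("DG", "syn")
  expect_equal(c(g$lo, g$hi, g$force_constant), c(25, 95, 200))
  cc <- chi_restraint("DC", "anti")
  expect_equal(c(cc$lo, cc$hi), c(170, 310))
  a <- chi_restraint("DA", "anti")
  expect_equal(c(a$lo, a$hi), c(200, 280))
  expect_equal(c(chi_restraint("5mC", "anti")$lo, chi_restraint("5mC", "anti")$hi),
               c(170, 310))
  expect_error(chi_restraint("XX", "syn"), "unknown residue")
})

test_that("restraint tables round-trip through the TSV dialect", {
  m <- fixture_model()
  prs <- data.frame(chain1 = "A", resno1 = c(4, 5), atom1 = "H8",
                    chain2 = "B", resno2 = c(4, 5), atom2 = "H8",
                    flags = c("", "overlapped"))
  bu <- generate_noe_buildup(m, prs)
  rst <- noe_restraints(bu)
  f <- tempfile(fileext = ".tsv")
  write_restraints(rst, f)
  back <- read_restraints(f)
  expect_equal(nrow(back), nrow(rst))
  for (col in c("peak_id", "category", "lower", "upper", "force_constant"))
    expect_equal(back[[col]], rst[[col]], tolerance = 1e-6)
  # flagged bounds appear verbatim in the file
  lines <- readLines(f)
  flagged_line <- grep("flagged", lines, value = TRUE)
  expect_true(all(grepl("2\\.5\t6\\.5", flagged_line)))
  # empty table still writes a valid header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_restraints(rst[0, ], f2)
  expect_equal(nrow(read_restraints(f2)), 0)
})

test_that("the amber dialect resolves atom serials and fails on bad references", {
  m <- fixture_model()
  prs <- data.frame(chain1 = "A", resno1 = 4, atom1 = "H8",
                    chain2 = "B", resno2 = 4, atom2 = "H8")
  rst <- noe_restraints(generate_noe_buildup(m, prs))
  f <- tempfile(fileext = ".rst")
  write_restraints(rst, f, dialect = "amber", model = m)
  lines <- readLines(f)
  expect_true(any(grepl("&rst iat=", lines)))
  expect_true(any(grepl("rk2=20.0", lines)))
  expect_error(write_restraints(rst, f, dialect = "amber"), "model")
  bad <- rst
  bad$atom1[1] <- "HX9"
  expect_error(write_restraints(bad, f, dialect = "amber", model = m),
               "unresolvable")
})

test_that("noiseless end-to-end restraints bracket the true model distances", {
  m <- fixture_model()
  prs <- data.frame(chain1 = "A", resno1 = c(4, 6), atom1 = c("H8", "H1"),
                    chain2 = "B", resno2 = c(4, 6), atom2 = c("H8", "H1"))
  bu <- generate_noe_buildup(m, prs)
  truth <- attr(bu, "r_true")
  rst <- noe_restraints(bu, r_ref = cytosine_reference_distance())
  keep <- truth <= 6.0 # only ranges the category system can bracket
  expect_true(all(rst$lower[keep] < rst$r_calibrated[keep] + 1e-9))
  expect_equal(rst$r_calibrated, truth, tolerance = 1e-6)
})

test_that("pair restraints carry template H-bond targets and planarity records", {
  m <- fixture_model()
  pr <- pair_restraints(m)
  expect_gt(nrow(pr$hbond), 0)
  expect_true(all(pr$hbond$lower == 2.8 & pr$hbond$upper == 3.0))
  expect_true(all(pr$hbond$force_constant == 20))
  expect_gt(nrow(pr$planarity), 0)
  expect_true(all(pr$planarity$force_constant == 100))
})
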