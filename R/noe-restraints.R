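# NOE buildup processing: initial rates by extrapolation to zero mixing
# time, distance calibration against the cytosine H5-H6 reference
# (2.48 A), restraint categorization and restraint file output.

#' NOEBuildup constructor
#'
#' @param peak_id character id
#' @param atom1,atom2 atom references: list(chain, resno, name)
#' @param tau mixing times, ms
#' @param volume cross-peak volumes (arbitrary units, >= 0)
#' @param flags character subset of \code{c("overlapped", "exchangeable",
#'   "long_mixing_only")}
#' @return object of class \code{imclip_noe_buildup}
#' @export
noe_buildup <- function(peak_id, atom1, atom2, tau, volume,
                        flags = character(0)) {
  stopifnot(length(tau) == length(volume), length(tau) >= 1)
  if (any(tau <= 0)) stop("all mixing times must be positive")
  if (any(volume < 0)) stop("volumes must be non-negative")
  bad <- setdiff(flags, c("overlapped", "exchangeable", "long_mixing_only"))
  if (length(bad)) stop("unknown flag(s): ", paste(bad, collapse = ", "))
  structure(list(peak_id = peak_id, atom1 = atom1, atom2 = atom2,
                 volumes = data.frame(tau_ms = tau, volume = volume),
                 flags = flags),
            class = "imclip_noe_buildup")
}

#' Generate synthetic NOE buildup tables from a structure
#'
#' Cross-peak volumes follow the isolated-spin-pair buildup
#' V(tau) = k r^-6 tau (1 - lambda tau) with a shared scale k, a
#' spin-diffusion coefficient lambda and multiplicative Gaussian noise.
#' One intra-cytosine H5-H6 reference peak per cytosine residue is always
#' appended (5-methylcytosines lack H5 and are skipped).
#'
#' @param model StructureModel
#' @param pairs data.frame with columns \code{chain1,resno1,atom1,
#'   chain2,resno2,atom2} (and optionally \code{flags})
#' @param mixing_times ms (default 70, 100, 150)
#' @param noise_frac fractional Gaussian noise on each volume
#' @param seed integer seed
#' @param scale volume scale factor k
#' @param lambda spin-diffusion coefficient, 1/ms (>= 0)
#' @return list of \code{\link{noe_buildup}} objects; true distances in
#'   attribute \code{"r_true"}
#' @export
generate_noe_buildup <- function(model, pairs = NULL,
                                 mixing_times = c(70, 100, 150),
                                 noise_frac = 0, seed = 1L,
                                 scale = 1e4, lambda = 0) {
  if (any(mixing_times <= 0)) stop("mixing times must be positive")
  if (lambda < 0) stop("lambda must be >= 0")
  set.seed(as.integer(seed))
  res <- model_residues(model)
  ref_rows <- res[res$resid == "DC", , drop = FALSE]
  plist <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      plist[[length(plist) + 1]] <- list(
        id = sprintf("peak%03d", i),
        a1 = list(chain = pairs$chain1[i], resno = pairs$resno1[i],
                  name = pairs$atom1[i]),
        a2 = list(chain = pairs$chain2[i], resno = pairs$resno2[i],
                  name = pairs$atom2[i]),
        flags = if ("flags" %in% names(pairs) && nzchar(pairs$flags[i]))
          strsplit(pairs$flags[i], ";")[[1]] else character(0))
    }
  }
  for (i in seq_len(nrow(ref_rows))) {
    plist[[length(plist) + 1]] <- list(
      id = sprintf("ref_C%s_%d", ref_rows$chain[i], ref_rows$resno[i]),
      a1 = list(chain = ref_rows$chain[i], resno = ref_rows$resno[i], name = "H5"),
      a2 = list(chain = ref_rows$chain[i], resno = ref_rows$resno[i], name = "H6"),
      flags = character(0))
  }
  out <- list()
  r_true <- numeric(0)
  for (p in plist) {
    x1 <- atom_xyz(model, p$a1$chain, p$a1$resno, p$a1$name)
    x2 <- atom_xyz(model, p$a2$chain, p$a2$resno, p$a2$name)
    r <- vnorm(x1 - x2)
    if (r < 1e-6) stop("zero interatomic distance for peak ", p$id)
    v <- scale * r^-6 * mixing_times * (1 - lambda * mixing_times)
    if (noise_frac > 0) v <- v + stats::rnorm(length(v), sd = noise_frac * abs(v))
    v <- pmax(v, 0)
    out[[length(out) + 1]] <- noe_buildup(p$id, p$a1, p$a2,
                                          mixing_times, v, p$flags)
    r_true <- c(r_true, r)
  }
  attr(out, "r_true") <- r_true
  out
}

#' Initial buildup rate by extrapolation to zero mixing time
#'
#' Fits V(tau) = R tau (1 - lambda tau) through the origin by least
#' squares and returns the initial rate R (a.u./ms). The quadratic
#' spin-diffusion term is included by default when three or more mixing
#' times are available. A single point falls back to R = V/tau with a
#' warning.
#'
#' @param b \code{\link{noe_buildup}}
#' @param spin_diffusion logical; NULL (default) enables the quadratic
#'   term when >= 3 mixing times are present
#' @return list with \code{rate}, \code{lambda}, \code{n}
#' @export
initial_rate <- function(b, spin_diffusion = NULL) {
  v <- b$volumes$volume
  tau <- b$volumes$tau_ms
  if (all(v == 0)) stop("all-zero volumes for peak ", b$peak_id)
  if (length(tau) == 1) {
    warning("single mixing time for peak ", b$peak_id,
            ": rate = V/tau fallback")
    return(list(rate = v / tau, lambda = 0, n = 1L))
  }
  if (is.null(spin_diffusion)) spin_diffusion <- length(tau) >= 3
  if (spin_diffusion && length(tau) >= 3) {
    fit <- stats::lm(v ~ 0 + tau + I(-tau^2))
    rate <- unname(stats::coef(fit)[1])
    lambda <- unname(stats::coef(fit)[2]) / rate
  } else {
    fit <- stats::lm(v ~ 0 + tau)
    rate <- unname(stats::coef(fit)[1])
    lambda <- 0
  }
  list(rate = rate, lambda = lambda, n = length(tau))
}

#' Calibrate an interproton distance from an initial-rate ratio
#'
#' r = r_ref (rate_ref / rate)^(1/6), with the cytosine H5-H6 distance
#' (2.48 A) as the default reference.
#'
#' @param rate initial rate of the cross peak
#' @param rate_ref initial rate of the reference peak
#' @param r_ref reference distance, A (default 2.48)
#' @return calibrated distance, A
#' @examples
#' calibrate_distance(1, 1)        # 2.48
#' calibrate_distance(1 / 64, 1)   # 4.96
#' @export
calibrate_distance <- function(rate, rate_ref, r_ref = 2.48) {
  if (any(rate <= 0) || any(rate_ref <= 0)) stop("rates must be positive")
  r_ref * (rate_ref / rate)^(1 / 6)
}

# printed category bounds
restraint_bounds <- function(category) {
  switch(category,
    strong = c(1.8, 3.6),
    medium = c(2.6, 5.0),
    weak = c(3.5, 6.0),
    flagged = c(2.5, 6.5),
    stop("unknown category: ", category))
}

#' Categorize a calibrated distance into a restraint
#'
#' Flagged peaks (overlapped, exchangeable, or present only at long
#' mixing times) get the widened 2.5--6.5 A range. Otherwise the category
#' partition is r <= 3.0 strong, 3.0 < r <= 4.25 medium, r > 4.25 weak,
#' with the printed bounds strong (1.8--3.6), medium (2.6--5.0), weak
#' (3.5--6.0) and a force constant of 20 kcal/mol/A^2.
#'
#' @param r calibrated distance, A (may be NA for flagged peaks)
#' @param flags character vector of peak flags
#' @return one-row data.frame with \code{category}, \code{lower},
#'   \code{upper}, \code{r_calibrated}, \code{force_constant}
#' @export
categorize <- function(r, flags = character(0)) {
  if (length(flags) && any(flags %in% c("overlapped", "exchangeable",
                                        "long_mixing_only"))) {
    b <- restraint_bounds("flagged")
    return(data.frame(category = "flagged", lower = b[1], upper = b[2],
                      r_calibrated = if (is.null(r) || is.na(r)) NA_real_ else r,
                      force_constant = 20))
  }
  if (is.null(r) || is.na(r) || r <= 0)
    stop("a positive calibrated distance is required for unflagged peaks")
  cat_ <- if (r <= 3.0) "strong" else if (r <= 4.25) "medium" else "weak"
  b <- restraint_bounds(cat_)
  data.frame(category = cat_, lower = b[1], upper = b[2],
             r_calibrated = r, force_constant = 20)
}

#' Chi glycosidic-torsion restraint
#'
#' syn -> 25--95 deg for any base; anti -> 170--310 deg (pyrimidines) or
#' 200--280 deg (purines); force constant 200 kcal/mol/A^2.
#'
#' @param residue_type one of DA, DG, DC, 5mC, DI, 2AP
#' @param conformer \code{"syn"} or \code{"anti"}
#' @param resno residue number (informational)
#' @return one-row data.frame with \code{angle}, \code{lo}, \code{hi},
#'   \code{force_constant}
#' @export
chi_restraint <- function(residue_type, conformer = c("syn", "anti"),
                          resno = NA_integer_) {
  conformer <- match.arg(conformer)
  if (!residue_type %in% RESIDUE_TYPES)
    stop("unknown residue class: ", residue_type)
  rng <- if (conformer == "syn") c(25, 95)
  else if (is_purine_type(residue_type)) c(200, 280)
  else c(170, 310)
  data.frame(resno = resno, residue = residue_type, angle = "chi",
             conformer = conformer, lo = rng[1], hi = rng[2],
             force_constant = 200)
}

#' Base-pair hydrogen-bond and planarity restraints for a model
#'
#' For every classified base pair, emits donor-acceptor distance
#' restraints targeting the idealized template separation (2.8--3.0 A
#' band around 2.9 A, force constant 20) and a four-atom improper-style
#' planarity record over the hydrogen-bonded edge atoms (donor
#' antecedent, donor, acceptor, acceptor antecedent; force constant 100).
#'
#' @param model StructureModel
#' @param pairs optional precomputed list from \code{\link{find_base_pairs}}
#' @return list with data.frames \code{hbond} and \code{planarity}
#' @export
pair_restraints <- function(model, pairs = NULL) {
  if (is.null(pairs)) pairs <- find_base_pairs(model)
  hrows <- list(); prows <- list()
  antecedent <- c(N1 = "C6", N2 = "C2", N3 = "C2", N4 = "C4", N6 = "C6",
                  N7 = "C5", O6 = "C6", O2 = "C2")
  for (bp in pairs) {
    hb <- bp$hbonds
    for (i in seq_len(nrow(hb))) {
      hrows[[length(hrows) + 1]] <- data.frame(
        chain1 = hb$donor_chain[i], resno1 = hb$donor_resno[i],
        atom1 = hb$donor_atom[i], chain2 = hb$acceptor_chain[i],
        resno2 = hb$acceptor_resno[i], atom2 = hb$acceptor_atom[i],
        lower = 2.8, upper = 3.0, force_constant = 20,
        geometry = bp$geometry)
      d_ant <- antecedent[[hb$donor_atom[i]]]
      a_ant <- antecedent[[hb$acceptor_atom[i]]]
      if (!is.null(d_ant) && !is.null(a_ant))
        prows[[length(prows) + 1]] <- data.frame(
          chain1 = hb$donor_chain[i], resno1 = hb$donor_resno[i],
          atom_a = d_ant, atom_b = hb$donor_atom[i],
          chain2 = hb$acceptor_chain[i], resno2 = hb$acceptor_resno[i],
          atom_c = hb$acceptor_atom[i], atom_d = a_ant,
          force_constant = 100)
    }
  }
  list(hbond = if (length(hrows)) do.call(rbind, hrows) else NULL,
       planarity = if (length(prows)) do.call(rbind, prows) else NULL)
}

#' Calibrate a set of NOE buildups into distance restraints
#'
#' Computes initial rates for all peaks, averages the rates of the
#' intra-cytosine H5-H6 reference peaks, calibrates every unflagged peak
#' against that mean reference rate and categorizes the results.
#'
#' @param buildups list of \code{\link{noe_buildup}}
#' @param r_ref reference distance, A (default 2.48)
#' @param spin_diffusion passed to \code{\link{initial_rate}}
#' @return data.frame of class \code{imclip_restraints}, one row per peak
#' @export
noe_restraints <- function(buildups, r_ref = 2.48, spin_diffusion = NULL) {
  rates <- lapply(buildups, initial_rate, spin_diffusion = spin_diffusion)
  is_ref <- vapply(buildups, function(b) {
    identical(b$atom1$chain, b$atom2$chain) &&
      identical(b$atom1$resno, b$atom2$resno) &&
      setequal(c(b$atom1$name, b$atom2$name), c("H5", "H6")) &&
      !length(b$flags)
  }, logical(1))
  if (!any(is_ref))
    stop("no intra-cytosine H5-H6 reference peak among the buildups")
  rate_ref <- mean(vapply(rates[is_ref], `[[`, numeric(1), "rate"))
  rows <- list()
  for (i in seq_along(buildups)) {
    b <- buildups[[i]]
    flagged <- length(b$flags) > 0
    r <- if (flagged) NA_real_
    else calibrate_distance(rates[[i]]$rate, rate_ref, r_ref)
    cat_ <- categorize(r, b$flags)
    rows[[length(rows) + 1]] <- data.frame(
      peak_id = b$peak_id,
      chain1 = b$atom1$chain, resno1 = b$atom1$resno, atom1 = b$atom1$name,
      chain2 = b$atom2$chain, resno2 = b$atom2$resno, atom2 = b$atom2$name,
      rate = rates[[i]]$rate, r_calibrated = cat_$r_calibrated,
      category = cat_$category, lower = cat_$lower, upper = cat_$upper,
      force_constant = cat_$force_constant,
      flags = paste(b$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("imclip_restraints", "data.frame")
  attr(out, "rate_ref") <- rate_ref
  attr(out, "r_ref") <- r_ref
  out
}

#' Write distance restraints to disk
#'
#' \code{dialect = "tsv"} writes a flat tab-separated table that
#' round-trips through \code{\link{read_restraints}}. \code{dialect =
#' "amber"} writes an Amber NMR restraint (DISANG/RST-style) text file
#' with flat-bottom wells r1 < r2 = lower, r3 = upper < r4; it needs a
#' \code{model} to resolve atom references to serial numbers.
#'
#' @param restraints \code{imclip_restraints} data.frame
#' @param path output file
#' @param dialect \code{"tsv"} or \code{"amber"}
#' @param model StructureModel (required for the amber dialect)
#' @export
write_restraints <- function(restraints, path, dialect = c("tsv", "amber"),
                             model = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    utils::write.table(as.data.frame(restraints), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (is.null(model)) stop("the amber dialect needs a model to resolve atom serials")
  at <- model$atoms
  serial <- function(chain, resno, name) {
    i <- which(at$chain == chain & at$resno == resno & at$name == name)
    if (length(i) != 1)
      stop(sprintf("unresolvable atom reference %s/%s/%s", chain, resno, name))
    i
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Amber-style NMR distance restraints", con)
  for (i in seq_len(nrow(restraints))) {
    r <- restraints[i, ]
    writeLines(sprintf(
      " &rst iat=%d,%d, r1=%.2f, r2=%.2f, r3=%.2f, r4=%.2f, rk2=%.1f, rk3=%.1f, &end",
      serial(r$chain1, r$resno1, r$atom1), serial(r$chain2, r$resno2, r$atom2),
      max(0, r$lower - 0.5), r$lower, r$upper, r$upper + 0.5,
      r$force_constant, r$force_constant), con)
  }
  invisible(path)
}

#' @rdname write_restraints
#' @return \code{read_restraints}: the restraint table
#' @export
read_restraints <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (!"flags" %in% names(out)) out$flags <- ""
  out$flags[is.na(out$flags)] <- ""
  class(out) <- c("imclip_restraints", "data.frame")
  out
}
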