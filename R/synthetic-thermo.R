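# Synthetic melting-curve generator.
#
# Two-state monomolecular folding with linear folded/unfolded baselines and
# first-order relaxation toward the van't Hoff equilibrium along the
# temperature ramp. A finite relaxation rate produces the scan-rate
# dependent lag between heating and cooling (hysteresis); in the limit
# relax_rate_at_tm -> Inf the curve is the equilibrium curve and heating
# and cooling coincide.

R_KCAL <- 0.0019872041 # gas constant, kcal / (mol K)

#' Thermodynamic/kinetic parameters for the melting-curve generator
#'
#' @param tm_true true melting temperature, deg C
#' @param dh_vh van't Hoff enthalpy of folding, kcal/mol (negative for a
#'   folding transition)
#' @param baseline_folded,baseline_unfolded numeric (intercept, slope per
#'   deg C) of the linear baselines in signal units
#' @param noise_sd Gaussian noise standard deviation, signal units
#' @param scan_rate temperature scan rate, deg C per minute (0.33 matches
#'   a 2 deg C step with ~6 min per point)
#' @param relax_rate_at_tm first-order relaxation rate toward equilibrium
#'   at Tm, 1/min; Inf gives the equilibrium curve
#' @param seed integer seed; identical seeds give identical curves
#' @return object of class \code{imclip_thermo_params}
#' @export
thermo_params <- function(tm_true = 37, dh_vh = -60,
                          baseline_folded = c(1, 0),
                          baseline_unfolded = c(0, 0),
                          noise_sd = 0, scan_rate = 0.33,
                          relax_rate_at_tm = Inf, seed = 1L) {
  stopifnot(noise_sd >= 0, scan_rate > 0, relax_rate_at_tm > 0,
            length(baseline_folded) == 2, length(baseline_unfolded) == 2)
  structure(list(tm_true = tm_true, dh_vh = dh_vh,
                 baseline_folded = baseline_folded,
                 baseline_unfolded = baseline_unfolded,
                 noise_sd = noise_sd, scan_rate = scan_rate,
                 relax_rate_at_tm = relax_rate_at_tm,
                 seed = as.integer(seed)),
            class = "imclip_thermo_params")
}

# equilibrium fraction folded at temperature T (deg C)
fraction_folded_eq <- function(p, temp_c) {
  tk <- temp_c + 273.15
  tmk <- p$tm_true + 273.15
  dG <- p$dh_vh * (1 - tk / tmk) # = dH - T dS with dS = dH/Tm
  1 / (1 + exp(dG / (R_KCAL * tk)))
}

# Arrhenius-scaled relaxation rate (1/min); activation enthalpy |dH|/2
relax_rate <- function(p, temp_c) {
  tk <- temp_c + 273.15
  tmk <- p$tm_true + 273.15
  ea <- abs(p$dh_vh) / 2
  p$relax_rate_at_tm * exp(-ea / R_KCAL * (1 / tk - 1 / tmk))
}

#' MeltingCurve constructor
#'
#' @param temperatures deg C (monotone in scan direction)
#' @param signal signal values (Delta-epsilon or absorbance)
#' @param direction \code{"heating"} or \code{"cooling"}
#' @param wavelength nm (informational)
#' @return data.frame of class \code{imclip_melting_curve} with columns
#'   \code{temperature_C}, \code{signal}
#' @export
melting_curve <- function(temperatures, signal,
                          direction = c("heating", "cooling"),
                          wavelength = NA_real_) {
  direction <- match.arg(direction)
  if (length(temperatures) < 5) stop("a melting curve needs at least 5 points")
  dt <- diff(temperatures)
  if (direction == "heating" && any(dt <= 0))
    stop("heating curve temperatures must be strictly increasing")
  if (direction == "cooling" && any(dt >= 0))
    stop("cooling curve temperatures must be strictly decreasing")
  structure(data.frame(temperature_C = temperatures, signal = signal),
            direction = direction, wavelength = wavelength,
            class = c("imclip_melting_curve", "data.frame"))
}

#' Generate a synthetic melting curve
#'
#' Integrates df/dT = k(T)/rate * (f_eq(T) - f) along the requested scan
#' (4th-order Runge-Kutta on a refined grid) starting from equilibrium at
#' the first temperature, then blends the folded and unfolded baselines
#' with the kinetic fraction folded and adds Gaussian noise.
#'
#' @param p \code{\link{thermo_params}}
#' @param direction \code{"heating"} or \code{"cooling"}
#' @param t_range temperature grid in deg C, monotone in the scan
#'   direction (increasing for heating, decreasing for cooling); an
#'   increasing grid passed for cooling is reversed with a message.
#' @return \code{\link{melting_curve}}; the noiseless generator fraction
#'   folded is attached as attribute \code{"fraction_true"}, and attribute
#'   \code{"tm_outside_grid"} flags a Tm outside the simulated span.
#' @export
generate_melting_curve <- function(p, direction = c("heating", "cooling"),
                                   t_range = seq(5, 85, by = 2)) {
  direction <- match.arg(direction)
  if (!length(t_range)) stop("empty temperature grid")
  if (direction == "cooling" && all(diff(t_range) > 0)) t_range <- rev(t_range)
  warn_tm <- p$tm_true < min(t_range) || p$tm_true > max(t_range)
  if (warn_tm) warning("tm_true lies outside the simulated temperature grid")

  if (is.infinite(p$relax_rate_at_tm)) {
    f <- fraction_folded_eq(p, t_range)
  } else {
    # df/dt = k(T) (f_eq - f) with dT/dt = +/- scan_rate. Over a substep
    # with frozen midpoint coefficients the solution relaxes
    # exponentially toward f_eq, so an integrating-factor step is exact
    # per substep and remains stable for arbitrarily fast relaxation
    # (where generic stiff solvers stall).
    nsub <- 20L
    f <- numeric(length(t_range))
    f[1] <- fraction_folded_eq(p, t_range[1])
    for (i in seq_along(t_range)[-1]) {
      ts <- seq(t_range[i - 1], t_range[i], length.out = nsub + 1)
      fi <- f[i - 1]
      for (j in seq_len(nsub)) {
        tmid <- (ts[j] + ts[j + 1]) / 2
        s <- relax_rate(p, tmid) / p$scan_rate # 1/degC
        feq <- fraction_folded_eq(p, tmid)
        fi <- feq + (fi - feq) * exp(-s * abs(ts[j + 1] - ts[j]))
      }
      f[i] <- fi
    }
    f <- pmin(1, pmax(0, f))
  }
  bf <- p$baseline_folded[1] + p$baseline_folded[2] * t_range
  bu <- p$baseline_unfolded[1] + p$baseline_unfolded[2] * t_range
  sig <- f * bf + (1 - f) * bu
  if (p$noise_sd > 0) {
    set.seed(p$seed + if (direction == "cooling") 1000L else 0L)
    sig <- sig + stats::rnorm(length(sig), sd = p$noise_sd)
  }
  out <- melting_curve(t_range, sig, direction = direction)
  attr(out, "fraction_true") <- f
  attr(out, "tm_outside_grid") <- warn_tm
  out
}
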