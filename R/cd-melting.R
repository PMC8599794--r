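# CD/UV melting analysis: molar CD conversion, dual-baseline
# normalization, Tm extraction and melting/renaturation hysteresis.

#' Convert measured ellipticity to molar CD
#'
#' Delta-epsilon [1/(M cm)] = theta / (32.98 c l), with theta the measured
#' ellipticity in millidegrees, c the molar strand concentration and l the
#' optical path length in cm.
#'
#' @param theta ellipticity, mdeg (vectorized)
#' @param c strand concentration, mol/L
#' @param l path length, cm
#' @return Delta-epsilon in 1/(M cm)
#' @examples
#' ellipticity_to_delta_eps(32.98, 1, 1)       # 1
#' ellipticity_to_delta_eps(16.49, 1.5e-4, 0.05)
#' @export
ellipticity_to_delta_eps <- function(theta, c, l) {
  if (any(c <= 0)) stop("strand concentration must be positive")
  if (any(l <= 0)) stop("path length must be positive")
  theta / (32.98 * c * l)
}

#' Dual-baseline normalization of a melting curve
#'
#' Fits linear baselines in a cool (folded) and a hot (unfolded)
#' temperature window and converts the signal to the fraction folded
#' f(T) = (s(T) - u(T)) / (n(T) - u(T)), clamped to [0, 1], where n and u
#' are the folded and unfolded baselines.
#'
#' @param curve \code{\link{melting_curve}} (or data.frame with
#'   \code{temperature_C} and \code{signal})
#' @param folded_window,unfolded_window numeric length-2 temperature spans
#'   used for the baseline fits; by default the coolest and hottest 15\%
#'   of the temperature range.
#' @return object of class \code{imclip_melt_norm}: a data.frame with
#'   \code{temperature_C} and \code{fraction_folded} plus baseline
#'   coefficients in attributes.
#' @export
normalize_melting <- function(curve, folded_window = NULL,
                              unfolded_window = NULL) {
  tt <- curve$temperature_C
  ss <- curve$signal
  rng <- range(tt)
  span <- diff(rng)
  # default windows: the coolest/hottest 15% of the span, widened if
  # needed so each baseline fit sees at least 8 points (short baselines
  # dominate the Tm noise otherwise)
  wdef <- function() {
    w <- 0.15 * span
    if (length(tt) > 1) {
      step <- stats::median(diff(sort(tt)))
      w <- max(w, 7.5 * step)
    }
    w
  }
  if (is.null(folded_window)) folded_window <- c(rng[1], rng[1] + wdef())
  if (is.null(unfolded_window)) unfolded_window <- c(rng[2] - wdef(), rng[2])
  folded_window <- sort(folded_window)
  unfolded_window <- sort(unfolded_window)
  if (folded_window[2] > unfolded_window[1])
    stop("folded and unfolded baseline windows overlap")
  inw <- function(w) tt >= w[1] & tt <= w[2]
  if (sum(inw(folded_window)) < 3 || sum(inw(unfolded_window)) < 3)
    stop("each baseline window needs at least 3 points")
  fitf <- stats::lm(ss ~ tt, subset = inw(folded_window))
  fitu <- stats::lm(ss ~ tt, subset = inw(unfolded_window))
  n <- stats::predict(fitf, newdata = data.frame(tt = tt))
  u <- stats::predict(fitu, newdata = data.frame(tt = tt))
  denom <- n - u
  if (any(abs(denom) < 1e-3 * stats::sd(ss)))
    stop("degenerate baselines: folded and unfolded baselines coincide ",
         "within the temperature range")
  f <- pmin(1, pmax(0, (ss - u) / denom))
  structure(data.frame(temperature_C = tt, fraction_folded = f),
            direction = attr(curve, "direction"),
            baseline_folded = stats::coef(fitf),
            baseline_unfolded = stats::coef(fitu),
            class = c("imclip_melt_norm", "data.frame"))
}

#' Melting temperature from a normalized curve
#'
#' Tm is the temperature at which half of the molecules are folded:
#' the fraction-folded curve is linearly interpolated between the two
#' points bracketing its 0.5 crossing; when noise creates several
#' crossings, the one with the steepest local |df/dT| is used. The result
#' is reported to 0.1 deg C.
#'
#' @param norm \code{imclip_melt_norm} from \code{\link{normalize_melting}}
#'   (or a data.frame with \code{temperature_C} and \code{fraction_folded})
#' @return Tm in deg C
#' @export
extract_tm <- function(norm) {
  o <- order(norm$temperature_C)
  tt <- norm$temperature_C[o]
  f <- norm$fraction_folded[o]
  d <- f - 0.5
  cross <- which(d[-1] * d[-length(d)] < 0 | d[-length(d)] == 0)
  if (d[length(d)] == 0) cross <- c(cross, length(d) - 1)
  if (!length(cross))
    stop("fraction folded never crosses 0.5: curve is unmelted/fully melted in range")
  slope <- abs((f[cross + 1] - f[cross]) / (tt[cross + 1] - tt[cross]))
  i <- cross[which.max(slope)]
  tm <- tt[i] + (0.5 - f[i]) * (tt[i + 1] - tt[i]) / (f[i + 1] - f[i])
  round(tm, 1)
}

#' Melting/renaturation hysteresis
#'
#' H = Tm - Tren, classified on half-open intervals:
#' none [0, 1), small [1, 5), medium [5, 10), large [10, Inf) deg C.
#'
#' @param tm melting temperature (heating), deg C; may also be a
#'   \code{melt_fit} object
#' @param tren renaturation temperature (cooling), deg C
#' @return list with \code{h} and \code{class}
#' @examples
#' hysteresis(37.0, 36.8)  # none
#' hysteresis(39.0, 27.5)  # large
#' @export
hysteresis <- function(tm, tren) {
  if (inherits(tm, "imclip_melt_fit")) tm <- tm$tm
  if (inherits(tren, "imclip_melt_fit")) tren <- tren$tm
  h <- tm - tren
  if (h < -0.5)
    stop("negative hysteresis beyond noise tolerance (-0.5 deg C): ",
         "heating and cooling scans are likely swapped")
  cls <- if (h < 1) "none" else if (h < 5) "small" else if (h < 10) "medium" else "large"
  list(h = h, class = cls)
}

#' Full melting analysis of one curve
#'
#' Convenience wrapper: normalize, then extract Tm.
#'
#' @param curve \code{\link{melting_curve}}
#' @param ... passed to \code{\link{normalize_melting}}
#' @return object of class \code{imclip_melt_fit} with \code{tm},
#'   \code{norm} and the input curve
#' @export
melt_fit <- function(curve, ...) {
  norm <- normalize_melting(curve, ...)
  structure(list(tm = extract_tm(norm), norm = norm, curve = curve,
                 direction = attr(curve, "direction")),
            class = "imclip_melt_fit")
}

#' @export
print.imclip_melt_fit <- function(x, ...) {
  cat(sprintf("Melting analysis (%s scan): Tm = %.1f degC\n",
              x$direction %||% "unknown", x$tm))
  invisible(x)
}

#' @export
plot.imclip_melt_fit <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$curve$temperature_C, x$curve$signal, type = "b",
                 xlab = "Temperature (degC)", ylab = "Signal",
                 main = "Raw melting curve", ...)
  graphics::plot(x$norm$temperature_C, x$norm$fraction_folded, type = "b",
                 xlab = "Temperature (degC)", ylab = "Fraction folded",
                 main = sprintf("Normalized (Tm = %.1f)", x$tm), ...)
  graphics::abline(h = 0.5, lty = 2)
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read melting curves as CSV
#'
#' CSV columns: \code{temperature_C}, \code{signal}, \code{direction}.
#' @param curve \code{\link{melting_curve}}
#' @param path file path
#' @export
write_melting_csv <- function(curve, path) {
  df <- data.frame(temperature_C = curve$temperature_C, signal = curve$signal,
                   direction = attr(curve, "direction"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_melting_csv
#' @param path file path
#' @return \code{read_melting_csv}: a \code{\link{melting_curve}}
#' @export
read_melting_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "signal", "direction")
  if (!all(need %in% names(df)))
    stop("melting CSV must have columns: ", paste(need, collapse = ", "))
  melting_curve(df$temperature_C, df$signal, direction = df$direction[1])
}
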