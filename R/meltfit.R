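#' Molar ellipticity from measured ellipticity
#'
#' Converts a circular-dichroism signal measured in millidegrees to molar
#' ellipticity, `[theta] = theta / (10 * d * c)`, where `d` is the cuvette
#' path length in cm and `c` the RNA concentration in mol/L.
#'
#' @param theta Measured ellipticity (millidegrees); vectorised.
#' @param d Path length (cm), e.g. 0.1 for a 1-mm cuvette.
#' @param c Concentration (mol/L).
#' @return Molar ellipticity (deg cm^2 dmol^-1).
#' @examples
#' molar_ellipticity(10, d = 0.1, c = 1e-6)  # 1e7
#' @export
molar_ellipticity <- function(theta, d, c) {
  if (!is.finite(d) || d <= 0) stop("path length d must be positive")
  if (!is.finite(c) || c <= 0) stop("concentration c must be positive")
  theta / (10 * d * c)
}

#' Molecular weight of an RNA sequence
#'
#' Approximate molecular weight from monophosphate residue masses, for
#' converting a mass concentration (e.g. 15 ug/mL) to mol/L. By default the
#' 5' end carries a triphosphate, as in an in vitro T7 transcript; 2'-fluoro
#' pyrimidine modifications add 2.0 Da per pyrimidine (F replaces OH) and
#' can be included with `two_prime_f = TRUE`.
#'
#' @param sequence RNA or DNA-spelled sequence (U/T equivalent).
#' @param five_prime `"triphosphate"` (default, +159.0) or `"OH"` (+18.0).
#' @param two_prime_f Add the 2'F pyrimidine mass correction.
#' @return Molecular weight in g/mol.
#' @examples
#' rna_molecular_weight("GGAUC")
#' @export
rna_molecular_weight <- function(sequence,
                                 five_prime = c("triphosphate", "OH"),
                                 two_prime_f = FALSE) {
  five_prime <- match.arg(five_prime)
  s <- normalize_dna(sequence)
  if (grepl("[^ACGT]", s)) stop("sequence must contain only A/C/G/U/T")
  masses <- c(A = 329.21, C = 305.18, G = 345.21, T = 306.17)  # T stands for U
  chars <- strsplit(s, "")[[1]]
  mw <- sum(masses[chars]) + if (five_prime == "triphosphate") 159.0 else 18.0
  if (two_prime_f) mw <- mw + 2.0 * sum(chars %in% c("C", "T"))
  unname(mw)
}

#' Mass concentration to molar concentration
#'
#' @param ug_per_ml Mass concentration in micrograms per millilitre.
#' @param mw Molecular weight in g/mol, e.g. from [rna_molecular_weight()].
#' @return Concentration in mol/L.
#' @export
molar_concentration <- function(ug_per_ml, mw) {
  if (mw <= 0) stop("molecular weight must be positive")
  ug_per_ml * 1e-3 / mw
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares polynomial smoothing with the standard window-11,
#' order-2 defaults used for CD spectra. Polynomials up to the filter order
#' pass through unchanged.
#'
#' @param values Numeric vector (e.g. ellipticity per wavelength).
#' @param window Odd window size, default 11.
#' @param order Polynomial order, default 2; must be smaller than `window`.
#' @return Smoothed vector of the same length.
#' @examples
#' smooth_spectrum(sin(seq(0, pi, length.out = 50)) + rnorm(50, sd = 0.05))
#' @export
smooth_spectrum <- function(values, window = 11L, order = 2L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  if (length(values) < window) {
    stop("need at least ", window, " points, got ", length(values))
  }
  as.numeric(signal::sgolayfilt(values, p = order, n = window))
}

#' Descriptive spectral extrema
#'
#' Reports the wavelengths of the maximum and minimum of a (smoothed) CD
#' spectrum — a descriptive band-shape summary, with no structural
#' classification.
#'
#' @param wavelength,values Equal-length numeric vectors.
#' @return List with `max_nm`, `min_nm`, `max_value`, `min_value`.
#' @export
spectrum_extrema <- function(wavelength, values) {
  stopifnot(length(wavelength) == length(values), length(values) > 0)
  list(max_nm = wavelength[which.max(values)],
       min_nm = wavelength[which.min(values)],
       max_value = max(values), min_value = min(values))
}

#' Melt curve container
#'
#' A temperature-versus-ellipticity series recorded at a single wavelength
#' (typically 265 nm), for Boltzmann melt fitting.
#'
#' @param temperature Strictly increasing temperatures (degrees C), length
#'   >= 5.
#' @param ellipticity Ellipticity values (millidegrees or molar ellipticity;
#'   the melting temperature is invariant to linear rescaling).
#' @param wavelength Recording wavelength in nm (metadata), default 265.
#' @return Object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, ellipticity, wavelength = 265) {
  temperature <- as.numeric(temperature)
  ellipticity <- as.numeric(ellipticity)
  if (length(temperature) != length(ellipticity)) {
    stop("temperature and ellipticity must have equal length")
  }
  if (length(temperature) < 5L) stop("need at least 5 points")
  if (is.unsorted(temperature, strictly = TRUE)) {
    stop("temperatures must be strictly increasing")
  }
  if (any(!is.finite(temperature)) || any(!is.finite(ellipticity))) {
    stop("values must be finite")
  }
  structure(list(temperature = temperature, ellipticity = ellipticity,
                 wavelength = wavelength), class = "melt_curve")
}

#' Read a melt curve from CSV
#'
#' @param path CSV with columns `temperature`, `ellipticity`.
#' @param wavelength Recording wavelength metadata.
#' @return A [melt_curve()].
#' @export
read_melt_curve <- function(path, wavelength = 265) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  melt_curve(df$temperature, df$ellipticity, wavelength = wavelength)
}

#' Boltzmann sigmoid melt model
#'
#' `theta(T) = theta_min + (theta_max - theta_min) / (1 + exp((tm - T)/s))`:
#' at `T = tm` the signal is the midpoint of the two asymptotes; `s` (> 0,
#' degrees C) sets the transition width.
#'
#' @param temperature Temperatures (degrees C); vectorised.
#' @param theta_min,theta_max Low- and high-temperature asymptotes.
#' @param tm Melting temperature (degrees C).
#' @param s Slope parameter (degrees C), > 0.
#' @return Model ellipticity values.
#' @examples
#' boltzmann_model(62, 0, 1, tm = 60, s = 2)  # 1/(1 + exp(-1))
#' @export
boltzmann_model <- function(temperature, theta_min, theta_max, tm, s) {
  if (s <= 0) stop("slope s must be positive")
  theta_min + (theta_max - theta_min) / (1 + exp((tm - temperature) / s))
}

#' Fit the Boltzmann sigmoid to a melt curve
#'
#' Bounded Levenberg-Marquardt nonlinear least squares for
#' (theta_min, theta_max, tm, s). Initial values: the asymptotes from the
#' means of the first and last three points, tm at the temperature of the
#' steepest finite-difference slope, s = 2 degrees C. Bounds keep s in
#' (0, 50] and tm within the data range plus/minus 20 degrees C, which
#' prevents asymptote-swapped solutions. Non-convergence is reported in the
#' `converged` flag, not as an error.
#'
#' @param curve A [melt_curve()], or a numeric temperature vector when
#'   `ellipticity` is given.
#' @param ellipticity Optional ellipticity vector (with `curve` as
#'   temperatures).
#' @return Object of class `melt_fit`: list with `theta_min`, `theta_max`,
#'   `tm`, `s`, `residual_norm`, `converged`, `fitted`, `data`.
#' @examples
#' temp <- seq(22, 94, by = 2)
#' y <- boltzmann_model(temp, 0, 1, tm = 58.92, s = 2)
#' fit_melt(melt_curve(temp, y))$tm
#' @export
fit_melt <- function(curve, ellipticity = NULL) {
  if (!inherits(curve, "melt_curve")) {
    curve <- melt_curve(curve, ellipticity)
  }
  temp <- curve$temperature
  y <- curve$ellipticity
  if (length(y) < 5L) stop("need more points than parameters (4)")

  dy <- diff(y) / diff(temp)
  mid <- temp[-1] - diff(temp) / 2
  start <- list(
    theta_min = mean(y[seq_len(min(3L, length(y)))]),
    theta_max = mean(y[seq(length(y) - min(3L, length(y)) + 1L, length(y))]),
    tm = mid[which.max(abs(dy))],
    s = 2
  )
  # Coarse range check: warn when the signal has not clearly reached both
  # asymptote regions (identifiability suffers).
  span <- abs(start$theta_max - start$theta_min)
  if (span < 0.5 * (max(y) - min(y))) {
    warning("melt signal may not span both asymptote regions; ",
            "Tm estimate can be poorly identified")
  }
  lower <- c(theta_min = -Inf, theta_max = -Inf, tm = min(temp) - 20,
             s = 1e-6)
  upper <- c(theta_min = Inf, theta_max = Inf, tm = max(temp) + 20, s = 50)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ theta_min + (theta_max - theta_min) / (1 + exp((tm - t) / s)),
      data = data.frame(t = temp, y = y),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    out <- list(theta_min = start$theta_min, theta_max = start$theta_max,
                tm = start$tm, s = start$s,
                residual_norm = sqrt(sum((y - boltzmann_model(
                  temp, start$theta_min, start$theta_max, start$tm,
                  start$s))^2)),
                converged = FALSE,
                fitted = rep(NA_real_, length(y)), data = curve)
    class(out) <- "melt_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  out <- list(theta_min = unname(cf["theta_min"]),
              theta_max = unname(cf["theta_max"]),
              tm = unname(cf["tm"]), s = unname(cf["s"]),
              residual_norm = sqrt(sum(stats::residuals(fit)^2)),
              converged = isTRUE(fit$convInfo$isConv),
              fitted = as.numeric(stats::fitted(fit)), data = curve)
  class(out) <- "melt_fit"
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit: Tm = %.2f C, s = %.3f C%s\n", x$tm, x$s,
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  asymptotes: %.4g (low T) -> %.4g (high T), residual norm %.3g\n",
              x$theta_min, x$theta_max, x$residual_norm))
  invisible(x)
}
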