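# Frequency-domain and CW photon diffusion for a semi-infinite medium.
# Extrapolated-boundary Green's function; tissue refractive index 1.4.

C_VACUUM_MM_S <- 2.99792458e11
TISSUE_N <- 1.4
# effective internal reflection coefficient for n = 1.4 (Fresnel average)
R_EFF <- 0.493

#' Frequency-domain measurement bundle
#'
#' Multi-frequency amplitude/phase data at a set of laser wavelengths, as
#' acquired by a frequency-domain photon migration instrument.
#'
#' @param wavelengths_nm laser wavelengths (nm), e.g. c(690, 785, 835)
#' @param frequencies_mhz modulation frequencies (MHz), ascending
#' @param amplitude,phase numeric matrices, rows = wavelengths, cols =
#'   frequencies; amplitude > 0 (arbitrary units), phase in radians
#' @param separation_mm source-detector separation (mm); default 28
#' @return object of class \code{fd_measurement}
#' @export
fd_measurement <- function(wavelengths_nm, frequencies_mhz, amplitude, phase,
                           separation_mm = 28) {
  amplitude <- rbind(amplitude)
  phase <- rbind(phase)
  stopifnot(nrow(amplitude) == length(wavelengths_nm),
            ncol(amplitude) == length(frequencies_mhz),
            all(dim(amplitude) == dim(phase)))
  if (any(amplitude <= 0)) stop("amplitude must be positive", call. = FALSE)
  if (is.unsorted(frequencies_mhz, strictly = TRUE)) {
    stop("modulation frequencies must be strictly ascending", call. = FALSE)
  }
  structure(list(wavelengths_nm = wavelengths_nm,
                 frequencies_mhz = frequencies_mhz,
                 amplitude = amplitude, phase = phase,
                 separation_mm = separation_mm),
            class = "fd_measurement")
}

#' Broadband continuous-wave reflectance spectrum
#'
#' @param wavelength_nm wavelength grid (nm), 650-1000
#' @param reflectance calibrated diffuse reflectance (dimensionless), > 0
#' @param separation_mm source-detector separation (mm); default 28
#' @return object of class \code{cw_spectrum}
#' @export
cw_spectrum <- function(wavelength_nm, reflectance, separation_mm = 28) {
  check_wavelengths(wavelength_nm)
  stopifnot(length(wavelength_nm) == length(reflectance))
  if (any(reflectance <= 0)) stop("reflectance must be positive", call. = FALSE)
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 reflectance = as.numeric(reflectance),
                 separation_mm = separation_mm),
            class = "cw_spectrum")
}

# Complex photon-density-wave reflectance, vectorized over any argument.
pdw_reflectance <- function(mua, mus_prime, separation_mm, freq_mhz) {
  mu_t <- mua + mus_prime
  D <- 1 / (3 * mu_t)
  z0 <- 1 / mu_t
  A <- (1 + R_EFF) / (1 - R_EFF)
  zb <- 2 * A * D
  v <- C_VACUUM_MM_S / TISSUE_N
  omega <- 2 * pi * freq_mhz * 1e6
  k <- sqrt(complex(real = mua, imaginary = omega / v) / D)
  r1 <- sqrt(separation_mm^2 + z0^2)
  r2 <- sqrt(separation_mm^2 + (z0 + 2 * zb)^2)
  (exp(-k * r1) / r1 - exp(-k * r2) / r2) / (4 * pi * D)
}

#' Forward frequency-domain diffusion model
#'
#' Amplitude and phase of the photon-density wave measured in reflectance
#' on a semi-infinite homogeneous medium (extrapolated-boundary condition,
#' tissue refractive index 1.4). Phase is the positive lag relative to the
#' source modulation, unwrapped over frequency, and tends to 0 as the
#' modulation frequency vanishes.
#'
#' @param mua absorption coefficient, mm^-1 (> 0)
#' @param mus_prime reduced scattering coefficient, mm^-1 (> 0)
#' @param separation_mm source-detector separation, mm
#' @param frequencies_mhz modulation frequencies, MHz (> 0), ascending
#' @return data.frame with columns \code{freq_mhz}, \code{amplitude},
#'   \code{phase_rad}. If the diffusion-validity condition
#'   mus' >= 10 * mua is violated, attribute \code{diffusion_warning} is
#'   set to \code{TRUE}.
#' @export
fd_forward <- function(mua, mus_prime, separation_mm = 28, frequencies_mhz) {
  stopifnot(length(mua) == 1L, length(mus_prime) == 1L)
  if (!is.finite(mua) || mua <= 0 || !is.finite(mus_prime) || mus_prime <= 0) {
    stop("mua and mus_prime must be positive", call. = FALSE)
  }
  if (any(frequencies_mhz <= 0)) {
    stop("modulation frequencies must be positive", call. = FALSE)
  }
  ord <- order(frequencies_mhz)
  f <- frequencies_mhz[ord]
  refl <- pdw_reflectance(mua, mus_prime, separation_mm, f)
  phase <- unwrap_phase(-Arg(refl))
  out <- data.frame(freq_mhz = frequencies_mhz,
                    amplitude = Mod(refl)[order(ord)],
                    phase_rad = phase[order(ord)])
  if (mus_prime < 10 * mua) attr(out, "diffusion_warning") <- TRUE
  out
}

# unwrap a phase sequence assumed to start near 0 and vary slowly
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- c(0, cumsum(round(-d / (2 * pi))))
  p + 2 * pi * jumps
}

# CW diffuse reflectance: the same Green's function at zero modulation.
cw_forward <- function(mua, mus_prime, separation_mm = 28) {
  Re(pdw_reflectance(mua, mus_prime, separation_mm, 0))
}

#' Invert frequency-domain data for optical properties
#'
#' Levenberg-Marquardt fit of the semi-infinite diffusion model to
#' multi-frequency amplitude and phase at one wavelength. Amplitude enters
#' in self-normalized (relative) mode by default — both data and model are
#' divided by their value at the lowest modulation frequency — so absolute
#' instrument throughput cancels. Residuals are the concatenation of
#' log-amplitude and phase misfits, each scaled by its noise level.
#' Parameters are log-transformed, keeping iterates positive.
#'
#' @param meas an \code{fd_measurement}
#' @param wavelength_nm which wavelength of \code{meas} to invert
#' @param start optional c(mua, mus_prime) initial guess (mm^-1)
#' @param sigma_logamp,sigma_phase_rad noise scales for the two residual
#'   blocks; defaults 0.01 (1\% amplitude) and 0.1 degree in radians
#' @param relative_amplitude logical; self-normalized amplitude mode
#' @return list with \code{mua}, \code{mus_prime} (mm^-1),
#'   \code{residual_norm}, \code{converged}
#' @export
fd_invert <- function(meas, wavelength_nm,
                      start = c(0.01, 1.0),
                      sigma_logamp = 0.01,
                      sigma_phase_rad = 0.1 * pi / 180,
                      relative_amplitude = TRUE) {
  stopifnot(inherits(meas, "fd_measurement"))
  i <- match(wavelength_nm, meas$wavelengths_nm)
  if (is.na(i)) stop("wavelength not present in measurement", call. = FALSE)
  f <- meas$frequencies_mhz
  if (length(f) < 2L) stop("need at least 2 modulation frequencies", call. = FALSE)
  amp <- meas$amplitude[i, ]
  ph <- meas$phase[i, ]
  norm_amp <- function(a) if (relative_amplitude) a / a[1] else a
  resid_fun <- function(p) {
    fw <- fd_forward(exp(p[1]), exp(p[2]), meas$separation_mm, f)
    c((log(norm_amp(fw$amplitude)) - log(norm_amp(amp))) / sigma_logamp,
      (fw$phase_rad - ph) / sigma_phase_rad)
  }
  fit <- minpack.lm::nls.lm(
    par = log(start), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  rn <- sqrt(sum(fit$fvec^2))
  if (fit$info %in% c(0, 5) || !is.finite(rn)) {
    stop(sprintf("frequency-domain inversion did not converge (residual %.3g)",
                 rn), call. = FALSE)
  }
  list(mua = exp(fit$par[1]), mus_prime = exp(fit$par[2]),
       residual_norm = rn, converged = TRUE)
}

#' Recover broadband absorption from a CW reflectance spectrum
#'
#' Per-wavelength inversion of the CW diffusion model, with the reduced
#' scattering spectrum supplied by the fitted power law and the unknown
#' instrument throughput calibrated against frequency-domain absorption
#' anchors: the spectrum is rescaled so the model reflectance at the
#' anchor wavelengths (evaluated at the anchor mua values) matches the
#' measured spectrum in the least-squares sense, then mua is solved for
#' at every wavelength by bisection (the model is strictly decreasing in
#' mua). Wavelengths whose reflectance is unattainable by any positive
#' mua are flagged and filled by linear interpolation.
#'
#' @param cw a \code{cw_spectrum}
#' @param scatter a \code{scatter_params} giving mus'(lambda)
#' @param anchors data.frame with columns \code{wavelength_nm} and
#'   \code{mua} from \code{fd_invert}; wavelengths must lie on the CW grid
#' @return numeric vector of mua (mm^-1) on the CW grid, with attributes
#'   \code{scale} (calibration factor applied to the measured spectrum)
#'   and \code{gap} (logical vector marking interpolated wavelengths)
#' @export
broadband_mua <- function(cw, scatter, anchors) {
  stopifnot(inherits(cw, "cw_spectrum"), inherits(scatter, "scatter_params"))
  ia <- match(anchors$wavelength_nm, cw$wavelength_nm)
  if (anyNA(ia)) stop("anchor wavelengths must lie on the CW grid", call. = FALSE)
  mus <- powerlaw_mus(scatter, cw$wavelength_nm)
  model_anchor <- cw_forward(anchors$mua, mus[ia], cw$separation_mm)
  meas_anchor <- cw$reflectance[ia]
  s <- sum(model_anchor * meas_anchor) / sum(meas_anchor^2)
  target <- s * cw$reflectance
  lo <- rep(1e-6, length(target))
  hi <- rep(5, length(target))
  r_lo <- cw_forward(lo, mus, cw$separation_mm)
  r_hi <- cw_forward(hi, mus, cw$separation_mm)
  gap <- target > r_lo | target < r_hi
  for (iter in 1:60) {
    mid <- sqrt(lo * hi)
    r_mid <- cw_forward(mid, mus, cw$separation_mm)
    high_side <- r_mid > target # mua too small
    lo <- ifelse(high_side, mid, lo)
    hi <- ifelse(high_side, hi, mid)
  }
  mua <- sqrt(lo * hi)
  if (any(gap)) {
    ok <- which(!gap)
    if (length(ok) < 2L) stop("CW spectrum unattainable by the model",
                              call. = FALSE)
    mua[gap] <- stats::approx(cw$wavelength_nm[ok], mua[ok],
                              xout = cw$wavelength_nm[gap], rule = 2)$y
  }
  attr(mua, "scale") <- s
  attr(mua, "gap") <- gap
  mua
}
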