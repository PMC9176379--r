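#' Tissue chromophore composition
#'
#' Container for the per-measurement tissue composition recovered by
#' broadband diffuse optical spectroscopy: oxygenated and de-oxygenated
#' hemo+myoglobin (uM), water and fat (percent volume fraction). Total
#' heme (THbMb) and tissue oxygen saturation (StO2 = 100*HbMbO2/THbMb)
#' are derived. Either the oxy/deoxy pair or the (thbmb, sto2) pair may
#' be supplied. All fields may be vectors of common length.
#'
#' @param hbmbo2,hbmbr oxygenated / de-oxygenated hemo+myoglobin, uM
#' @param thbmb,sto2 alternative parameterization: total heme (uM) and
#'   oxygen saturation (percent)
#' @param water,fat tissue water / fat content, percent (0-100)
#' @return object of class \code{chromophore_set}: list of numeric vectors
#'   \code{hbmbo2}, \code{hbmbr}, \code{thbmb}, \code{sto2}, \code{water},
#'   \code{fat}. \code{sto2} is \code{NA} where \code{thbmb} is zero.
#' @examples
#' lean <- chromophore_set(thbmb = 125.2, sto2 = 67.1, water = 73.0, fat = 1.1)
#' compute_off(lean)
#' @export
chromophore_set <- function(hbmbo2 = NULL, hbmbr = NULL,
                            thbmb = NULL, sto2 = NULL,
                            water, fat) {
  if (is.null(hbmbo2) != is.null(hbmbr)) {
    stop("supply both hbmbo2 and hbmbr, or neither", call. = FALSE)
  }
  if (is.null(hbmbo2)) {
    if (is.null(thbmb) || is.null(sto2)) {
      stop("supply either (hbmbo2, hbmbr) or (thbmb, sto2)", call. = FALSE)
    }
    hbmbo2 <- thbmb * sto2 / 100
    hbmbr <- thbmb - hbmbo2
  }
  n <- max(length(hbmbo2), length(hbmbr), length(water), length(fat))
  hbmbo2 <- rep_len(as.numeric(hbmbo2), n)
  hbmbr <- rep_len(as.numeric(hbmbr), n)
  water <- rep_len(as.numeric(water), n)
  fat <- rep_len(as.numeric(fat), n)
  vals <- c(hbmbo2, hbmbr, water, fat)
  if (any(!is.finite(vals)) || any(vals < -1e-12)) {
    stop("chromophore concentrations must be finite and non-negative",
         call. = FALSE)
  }
  if (any(water > 100 + 1e-9) || any(fat > 100 + 1e-9)) {
    stop("water and fat are percent volume fractions and must be <= 100 ",
         "(unit guard: expected units are uM for heme, % for water/fat)",
         call. = FALSE)
  }
  th <- hbmbo2 + hbmbr
  structure(list(
    hbmbo2 = hbmbo2, hbmbr = hbmbr, thbmb = th,
    sto2 = ifelse(th > 0, 100 * hbmbo2 / th, NA_real_),
    water = water, fat = fat
  ), class = "chromophore_set")
}

#' @export
print.chromophore_set <- function(x, ...) {
  cat(sprintf("chromophore_set (n = %d)\n", length(x$thbmb)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.chromophore_set <- function(x, ...) {
  data.frame(hbmbo2 = x$hbmbo2, hbmbr = x$hbmbr, thbmb = x$thbmb,
             sto2 = x$sto2, water = x$water, fat = x$fat)
}

#' Reduced-scattering power-law parameters
#'
#' Mie-type wavelength dependence of the reduced scattering coefficient,
#' mus'(lambda) = A500 * (lambda/500 nm)^(-b). \code{b_power} is stored so
#' that positive values mean scattering decreasing with wavelength (normal
#' tissue). Published tables sometimes print the exponent with the opposite
#' sign convention; set \code{sign_convention = "table"} to negate on
#' ingest.
#'
#' @param a500 scattering amplitude at 500 nm, mm^-1 (> 0); vectorized
#' @param b_power scattering power (unitless); vectorized
#' @param sign_convention \code{"power"} (default; b as the exponent
#'   magnitude in mus' = A500*(lambda/500)^(-b)) or \code{"table"} (printed
#'   negative convention; negated on ingest)
#' @return object of class \code{scatter_params} with fields \code{a500},
#'   \code{b_power} and derived \code{mus800} (mm^-1)
#' @export
scatter_params <- function(a500, b_power, sign_convention = c("power", "table")) {
  sign_convention <- match.arg(sign_convention)
  if (any(!is.finite(a500)) || any(a500 <= 0)) {
    stop("a500 must be positive", call. = FALSE)
  }
  if (identical(sign_convention, "table")) b_power <- -b_power
  n <- max(length(a500), length(b_power))
  a500 <- rep_len(as.numeric(a500), n)
  b_power <- rep_len(as.numeric(b_power), n)
  structure(list(a500 = a500, b_power = b_power,
                 mus800 = a500 * (800 / 500)^(-b_power)),
            class = "scatter_params")
}

#' @export
print.scatter_params <- function(x, ...) {
  print(data.frame(a500 = x$a500, b_power = x$b_power, mus800 = x$mus800), ...)
  invisible(x)
}

#' Compose an absorption spectrum from chromophore concentrations
#'
#' Forward spectral mixing: mua(lambda) = eps_HbMbO2*HbMbO2 +
#' eps_HbMbR*HbMbR + eps_water*water + eps_fat*fat, linear in every
#' concentration.
#'
#' @param chromophores a \code{chromophore_set} of length 1
#' @param lib an \code{extinction_library}
#' @param grid wavelengths (nm) inside the library grid; default the
#'   library's own grid
#' @return numeric vector of absorption coefficients (mm^-1) on \code{grid}
#' @export
compose_mua <- function(chromophores, lib = nir_extinction_library(),
                        grid = lib$wavelength_nm) {
  stopifnot(inherits(chromophores, "chromophore_set"))
  if (length(chromophores$thbmb) != 1L) {
    stop("compose_mua expects a single chromophore_set record", call. = FALSE)
  }
  sub <- subset_extinction(lib, grid)
  conc <- c(chromophores$hbmbo2, chromophores$hbmbr,
            chromophores$water, chromophores$fat)
  as.numeric(sub$eps %*% conc)
}

#' Decompose an absorption spectrum into chromophore concentrations
#'
#' Non-negative least squares (Lawson-Hanson active set) over the four
#' basis spectra. Round-trips \code{compose_mua} to solver tolerance on
#' noiseless input; an all-zero spectrum yields an all-zero composition.
#'
#' @param mua absorption spectrum (mm^-1) on \code{grid}
#' @param lib an \code{extinction_library}
#' @param grid wavelengths (nm); default the library grid. Must contain at
#'   least 4 wavelengths and span the lipid (~930 nm) and water (~970 nm)
#'   absorption peaks.
#' @return a \code{chromophore_set}
#' @export
decompose_mua <- function(mua, lib = nir_extinction_library(),
                          grid = lib$wavelength_nm) {
  sub <- subset_extinction(lib, grid)
  if (length(mua) != length(grid)) {
    stop("mua and grid lengths differ", call. = FALSE)
  }
  if (length(grid) < ncol(sub$eps)) {
    stop("underdetermined: fewer wavelengths than chromophores", call. = FALSE)
  }
  if (max(grid) < 960 || !any(grid >= 910 & grid <= 950)) {
    warning("grid does not span the fat (~930 nm) and water (~970 nm) peaks; ",
            "water/fat separation may be poor")
  }
  if (all(abs(mua) < 1e-15)) {
    conc <- rep(0, 4)
  } else {
    conc <- pracma::lsqnonneg(sub$eps, as.numeric(mua))$x
  }
  chromophore_set(hbmbo2 = conc[1], hbmbr = conc[2],
                  water = conc[3], fat = conc[4])
}

#' Evaluate the reduced-scattering power law
#'
#' @param params a \code{scatter_params} of length 1
#' @param grid wavelengths (nm), > 0
#' @return mus'(lambda) = a500*(lambda/500)^(-b_power), mm^-1
#' @export
powerlaw_mus <- function(params, grid) {
  stopifnot(inherits(params, "scatter_params"))
  if (length(params$a500) != 1L) {
    stop("powerlaw_mus expects a single scatter_params record", call. = FALSE)
  }
  if (any(grid <= 0)) stop("wavelengths must be positive", call. = FALSE)
  params$a500 * (grid / 500)^(-params$b_power)
}

#' Fit the reduced-scattering power law
#'
#' Least-squares fit of log mus' against log(lambda/500): the standard
#' Mie-slope regression. Exact on noiseless power-law input; with exactly
#' two points the fit interpolates; scale-equivariant in mus'.
#'
#' @param wavelength_nm wavelengths (nm), at least 2 distinct
#' @param mus_prime reduced scattering coefficients (mm^-1), > 0
#' @return a \code{scatter_params}
#' @export
fit_powerlaw <- function(wavelength_nm, mus_prime) {
  if (length(wavelength_nm) != length(mus_prime)) {
    stop("wavelength and mus_prime lengths differ", call. = FALSE)
  }
  if (length(unique(wavelength_nm)) < 2L) {
    stop("need at least 2 distinct wavelengths", call. = FALSE)
  }
  if (any(!is.finite(mus_prime)) || any(mus_prime <= 0)) {
    stop("mus_prime must be positive", call. = FALSE)
  }
  x <- log(wavelength_nm / 500)
  fit <- stats::lm.fit(cbind(1, x), log(mus_prime))
  scatter_params(a500 = exp(fit$coefficients[[1]]),
                 b_power = -fit$coefficients[[2]])
}
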