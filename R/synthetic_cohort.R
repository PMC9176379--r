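# Seeded synthetic cohort emulating a two-layer (adipose-over-muscle)
# tissue study: per-site optical composition is a depth-weighted mixture of
# lean and fat endmembers, with ultrasound SATT, DXA records and noise.

#' Lean/fat tissue endmembers
#'
#' Reference compositions for pure lean (muscle-dominated) and pure fat
#' (adipose-dominated) optical signals. Defaults are the in-vivo
#' endmember averages observed at the thinnest and thickest adipose
#' layers: lean THbMb 125.2 uM, StO2 67.1\%, water 73.0\%, fat 1.1\%,
#' A500 0.87 mm^-1, scattering power 1.28; fat THbMb 19.4 uM, StO2
#' 63.0\%, water 11.3\%, fat 67.3\%, A500 0.85 mm^-1, power 0.42.
#'
#' @param lean,fat lists with elements \code{chromophores}
#'   (\code{chromophore_set}) and \code{scatter} (\code{scatter_params})
#' @return object of class \code{endmember_pair}
#' @export
endmember_pair <- function(
    lean = list(
      chromophores = chromophore_set(thbmb = 125.2, sto2 = 67.1,
                                     water = 73.0, fat = 1.1),
      scatter = scatter_params(a500 = 0.87, b_power = 1.28)),
    fat = list(
      chromophores = chromophore_set(thbmb = 19.4, sto2 = 63.0,
                                     water = 11.3, fat = 67.3),
      scatter = scatter_params(a500 = 0.85, b_power = 0.42))) {
  stopifnot(inherits(lean$chromophores, "chromophore_set"),
            inherits(fat$chromophores, "chromophore_set"),
            inherits(lean$scatter, "scatter_params"),
            inherits(fat$scatter, "scatter_params"))
  if (!(lean$chromophores$fat < fat$chromophores$fat)) {
    stop("lean endmember must have less fat than the fat endmember",
         call. = FALSE)
  }
  if (!(lean$chromophores$thbmb > fat$chromophores$thbmb)) {
    stop("lean endmember must have more THbMb than the fat endmember",
         call. = FALSE)
  }
  structure(list(lean = lean, fat = fat), class = "endmember_pair")
}

#' Adipose mixing weight as a function of SATT
#'
#' Fraction of the measured optical signal attributable to the adipose
#' layer: w = 1 - exp(-(satt/z0)^shape). The depth scale z0 defaults to
#' 0.93 cm, one third of the 28 mm source-detector separation (the
#' rule-of-thumb optical penetration depth). \code{shape = 1} gives the
#' plain exponential saturation; larger shapes sharpen the transition so
#' that thin layers read nearly pure muscle and thick layers nearly pure
#' adipose.
#'
#' @param satt_cm skin+adipose tissue thickness, cm (>= 0); vectorized
#' @param z0_cm penetration depth scale, cm (> 0)
#' @param shape transition sharpness exponent (> 0); default 1
#' @return mixing weight in [0, 1), monotone increasing in \code{satt_cm}
#' @export
mixing_weight <- function(satt_cm, z0_cm = 0.93, shape = 1) {
  if (any(satt_cm < 0)) stop("SATT must be non-negative", call. = FALSE)
  if (z0_cm <= 0 || shape <= 0) stop("z0_cm and shape must be positive",
                                     call. = FALSE)
  1 - exp(-(satt_cm / z0_cm)^shape)
}

#' Noise configuration for the synthetic cohort
#'
#' All coefficients of variation are multiplicative log-normal scales.
#' \code{replicate_cv} acts per replicate on every chromophore/scattering
#' field; \code{field_cv} acts per participant-site on the chromophores;
#' StO2 receives additive Gaussian noise of \code{sto2_sd} points; the
#' scattering power gets \code{b_cv}; A500 is drawn independently of SATT
#' (as observed: scattering amplitude does not track adiposity) around
#' \code{a500_mean} with \code{a500_cv}; per-site SATT varies around the
#' participant baseline with \code{satt_site_cv}; the DXA fat\% residual
#' standard deviation is \code{dxa_residual_sd} (percent points).
#'
#' @param replicate_cv,field_cv,sto2_sd,b_cv,a500_mean,a500_cv,satt_site_cv,dxa_residual_sd
#'   see description
#' @return list of class \code{cohort_noise}
#' @export
cohort_noise <- function(replicate_cv = 0.03, field_cv = 0.10,
                         sto2_sd = 3.5, b_cv = 0.7,
                         a500_mean = 0.86, a500_cv = 0.13,
                         satt_site_cv = 0.15, dxa_residual_sd = 3) {
  vals <- c(replicate_cv, field_cv, sto2_sd, b_cv, a500_mean, a500_cv,
            satt_site_cv, dxa_residual_sd)
  if (any(!is.finite(vals)) || any(vals < 0) || a500_mean <= 0) {
    stop("invalid noise configuration", call. = FALSE)
  }
  structure(list(replicate_cv = replicate_cv, field_cv = field_cv,
                 sto2_sd = sto2_sd, b_cv = b_cv, a500_mean = a500_mean,
                 a500_cv = a500_cv, satt_site_cv = satt_site_cv,
                 dxa_residual_sd = dxa_residual_sd),
            class = "cohort_noise")
}

noiseless_cohort <- function() {
  cohort_noise(replicate_cv = 0, field_cv = 0, sto2_sd = 0, b_cv = 0,
               a500_cv = 0, satt_site_cv = 0, dxa_residual_sd = 0)
}

lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# relative thickness of the skin+adipose layer at each site vs quadriceps
SITE_SATT_MULT <- c(BS = 0.80, BL = 0.80,
                    LL = 1.50, LR = 1.50, UL = 1.50, UR = 1.50,
                    VL = 0.90, RF = 1.12,
                    GM = 0.70, GL = 0.70)

#' Generate a synthetic cohort
#'
#' Draws \code{n} participants with per-site skin+adipose thickness, true
#' tissue composition as a depth-weighted lean/fat endmember mixture,
#' replicate measurement noise, ultrasound SATT records at the two
#' quadriceps sites, and DXA records in which whole-body fat\% is an
#' affine function of the four region-averaged optical fat fractions plus
#' residual noise (so the planted linear model is recoverable).
#'
#' @param n number of participants (>= 2)
#' @param seed integer seed; the output is fully reproducible from it
#' @param endmembers an \code{endmember_pair}
#' @param noise a \code{cohort_noise}
#' @param z0_cm,shape mixing-weight parameters (see
#'   \code{mixing_weight}); shape defaults to 3 here so the cohort spans
#'   nearly pure muscle to nearly pure adipose across the observed SATT
#'   range
#' @param satt_lognorm c(meanlog, sdlog) of the quadriceps SATT draw;
#'   values clamped into \code{satt_range}
#' @param satt_range admissible quadriceps SATT range, cm
#' @param satt_coupling optional c(a, b): overwrite the quadriceps SATT
#'   records with a * exp(b * OFF) evaluated at the participant's
#'   quadriceps OFF (fraction scale), planting the exponential SATT model
#'   exactly
#' @param dxa_coef named coefficients (intercept and one per region, on
#'   percent OFF) of the planted whole-body fat\% model
#' @return list of class \code{synthetic_cohort}:
#'   \code{sites} (per participant x site x replicate measurement table),
#'   \code{satt} (ultrasound records at RF and VL, plus quadriceps mean),
#'   \code{dxa} (DXA masses and fractions), \code{participants}
#'   (demographic dressing), \code{truth} (noiseless per-site composition
#'   and mixing weights), \code{seed}, \code{config}
#' @export
generate_cohort <- function(n = 99, seed = 1L,
                            endmembers = endmember_pair(),
                            noise = cohort_noise(),
                            z0_cm = 0.93, shape = 3,
                            satt_lognorm = c(meanlog = log(0.70),
                                             sdlog = 0.42),
                            satt_range = c(0.2, 1.6),
                            satt_coupling = NULL,
                            dxa_coef = c(intercept = 12, biceps = 0.10,
                                         abdomen = 0.15, quadriceps = 0.10,
                                         calf = 0.05)) {
  if (n < 2L) stop("need n >= 2 participants", call. = FALSE)
  stopifnot(inherits(endmembers, "endmember_pair"),
            inherits(noise, "cohort_noise"))
  need_coef <- c("intercept", region_names)
  if (!all(need_coef %in% names(dxa_coef))) {
    stop("dxa_coef needs: ", paste(need_coef, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    ids <- sprintf("P%03d", seq_len(n))
    base_satt <- pmin(pmax(
      stats::rlnorm(n, satt_lognorm[[1]], satt_lognorm[[2]]),
      satt_range[1]), satt_range[2])

    grid_ps <- expand.grid(participant_id = ids,
                           site = names(SITE_SATT_MULT),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    m <- nrow(grid_ps)
    grid_ps$satt_cm <- base_satt[match(grid_ps$participant_id, ids)] *
      SITE_SATT_MULT[grid_ps$site] * lnorm_factor(m, noise$satt_site_cv)
    grid_ps$w <- mixing_weight(grid_ps$satt_cm, z0_cm, shape)

    le <- endmembers$lean; fa <- endmembers$fat
    mix <- function(lean_v, fat_v, w) w * fat_v + (1 - w) * lean_v
    w <- grid_ps$w
    thbmb0 <- mix(le$chromophores$thbmb, fa$chromophores$thbmb, w)
    sto2_0 <- mix(le$chromophores$hbmbo2, fa$chromophores$hbmbo2, w) /
      thbmb0 * 100
    water0 <- mix(le$chromophores$water, fa$chromophores$water, w)
    fat0 <- mix(le$chromophores$fat, fa$chromophores$fat, w)
    b0 <- mix(le$scatter$b_power, fa$scatter$b_power, w)

    thbmb_t <- thbmb0 * lnorm_factor(m, noise$field_cv)
    water_t <- pmin(water0 * lnorm_factor(m, noise$field_cv), 100)
    fat_t <- pmin(fat0 * lnorm_factor(m, noise$field_cv), 100)
    sto2_t <- pmin(pmax(sto2_0 + stats::rnorm(m, 0, noise$sto2_sd), 1), 99)
    b_t <- b0 * lnorm_factor(m, noise$b_cv)
    a500_t <- noise$a500_mean * lnorm_factor(m, noise$a500_cv)

    truth <- cbind(grid_ps,
                   data.frame(thbmb = thbmb_t, sto2 = sto2_t,
                              water = water_t, fat = fat_t,
                              a500 = a500_t, b_power = b_t))

    reps <- truth[rep(seq_len(m), each = 3L), , drop = FALSE]
    reps$replicate <- rep(1:3, times = m)
    k <- nrow(reps)
    rcv <- noise$replicate_cv
    reps$thbmb <- reps$thbmb * lnorm_factor(k, rcv)
    reps$water <- pmin(reps$water * lnorm_factor(k, rcv), 100)
    reps$fat <- pmin(reps$fat * lnorm_factor(k, rcv), 100)
    reps$a500 <- reps$a500 * lnorm_factor(k, rcv)
    reps$b_power <- reps$b_power * lnorm_factor(k, rcv)
    reps$hbmbo2 <- reps$thbmb * reps$sto2 / 100
    reps$hbmbr <- reps$thbmb - reps$hbmbo2
    sites <- reps[c("participant_id", "site", "replicate",
                    "hbmbo2", "hbmbr", "water", "fat", "a500", "b_power")]
    rownames(sites) <- NULL

    quad <- aggregate_region(
      sites[sites$site %in% c("VL", "RF"), , drop = FALSE], "quadriceps")
    satt <- truth[truth$site %in% c("VL", "RF"),
                  c("participant_id", "site", "satt_cm")]
    if (!is.null(satt_coupling)) {
      off_frac <- quad$off[match(satt$participant_id,
                                 quad$participant_id)] / 100
      satt$satt_cm <- satt_coupling[[1]] * exp(satt_coupling[[2]] * off_frac)
    }
    quad_satt <- stats::aggregate(satt["satt_cm"],
                                  by = satt["participant_id"], FUN = mean)
    rownames(satt) <- NULL

    regions <- summarize_regions(sites)
    wide_off <- regions_wide(regions, "off")
    X <- as.matrix(wide_off[region_names])
    fat_pct <- dxa_coef[["intercept"]] + X %*% dxa_coef[region_names] +
      stats::rnorm(n, 0, noise$dxa_residual_sd)
    # physical floor; with the default coefficients it essentially never binds
    fat_pct <- pmax(as.numeric(fat_pct), 0.5)
    bone_pct <- pmin(pmax(stats::rnorm(n, 5, 0.4), 3.5), 6.5)
    lst_pct <- 100 - fat_pct - bone_pct
    age <- round(stats::runif(n, 7, 34), 1)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    total_mass <- pmax(20 + 1.6 * age + stats::rnorm(n, 0, 6), 18)
    dxa <- data.frame(participant_id = wide_off$participant_id,
                      fat_mass = fat_pct / 100 * total_mass,
                      lst_mass = lst_pct / 100 * total_mass,
                      bone_mass = bone_pct / 100 * total_mass)
    dxa <- cbind(dxa, dxa_fractions(dxa$fat_mass, dxa$lst_mass,
                                    dxa$bone_mass))
    participants <- data.frame(participant_id = ids, age = age, sex = sex,
                               quad_satt_cm = quad_satt$satt_cm[
                                 match(ids, quad_satt$participant_id)])
    structure(list(sites = sites, satt = satt, dxa = dxa,
                   participants = participants, truth = truth,
                   seed = seed,
                   config = list(z0_cm = z0_cm, shape = shape,
                                 noise = noise, dxa_coef = dxa_coef,
                                 satt_coupling = satt_coupling)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d participants, %d site rows, seed %d\n",
    nrow(x$participants), nrow(x$sites), x$seed))
  invisible(x)
}

#' Instrument configuration for synthetic measurements
#'
#' @param separation_mm source-detector separation (mm)
#' @param frequencies_mhz modulation frequencies (MHz)
#' @param wavelengths_nm frequency-domain laser wavelengths (nm)
#' @param grid broadband CW wavelength grid (nm)
#' @param amp_noise_cv multiplicative amplitude noise CV
#' @param phase_noise_rad additive phase noise SD (radians)
#' @param cw_noise_cv multiplicative CW reflectance noise CV
#' @return list of class \code{instrument_config}
#' @export
instrument_config <- function(separation_mm = 28,
                              frequencies_mhz = seq(50, 400, by = 50),
                              wavelengths_nm = c(690, 785, 835),
                              grid = 650:1000,
                              amp_noise_cv = 0, phase_noise_rad = 0,
                              cw_noise_cv = 0) {
  vals <- c(amp_noise_cv, phase_noise_rad, cw_noise_cv)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("noise levels must be non-negative", call. = FALSE)
  }
  structure(list(separation_mm = separation_mm,
                 frequencies_mhz = frequencies_mhz,
                 wavelengths_nm = wavelengths_nm, grid = grid,
                 amp_noise_cv = amp_noise_cv,
                 phase_noise_rad = phase_noise_rad,
                 cw_noise_cv = cw_noise_cv),
            class = "instrument_config")
}

#' Simulate instrument measurements for one tissue composition
#'
#' Runs the spectral and photon-diffusion forward models: composes the
#' broadband absorption spectrum from the chromophores, evaluates the
#' scattering power law, produces multi-frequency amplitude/phase at the
#' laser wavelengths and a broadband CW reflectance spectrum, and applies
#' the configured measurement noise.
#'
#' @param chromophores a \code{chromophore_set} (single record)
#' @param scatter a \code{scatter_params} (single record)
#' @param instrument an \code{instrument_config}
#' @param lib extinction library
#' @return list with \code{fd} (\code{fd_measurement}), \code{cw}
#'   (\code{cw_spectrum}) and \code{noiseless} (logical)
#' @export
generate_measurements <- function(chromophores, scatter,
                                  instrument = instrument_config(),
                                  lib = nir_extinction_library()) {
  stopifnot(inherits(instrument, "instrument_config"))
  mua_grid <- compose_mua(chromophores, lib, instrument$grid)
  mus_grid <- powerlaw_mus(scatter, instrument$grid)
  iwl <- match(instrument$wavelengths_nm, instrument$grid)
  if (anyNA(iwl)) stop("laser wavelengths must lie on the CW grid",
                       call. = FALSE)
  nf <- length(instrument$frequencies_mhz)
  amp <- ph <- matrix(NA_real_, length(iwl), nf)
  for (j in seq_along(iwl)) {
    fw <- fd_forward(mua_grid[iwl[j]], mus_grid[iwl[j]],
                     instrument$separation_mm, instrument$frequencies_mhz)
    amp[j, ] <- fw$amplitude * lnorm_factor(nf, instrument$amp_noise_cv)
    ph[j, ] <- fw$phase_rad +
      stats::rnorm(nf, 0, instrument$phase_noise_rad)
  }
  refl <- cw_forward(mua_grid, mus_grid, instrument$separation_mm) *
    lnorm_factor(length(mua_grid), instrument$cw_noise_cv)
  list(fd = fd_measurement(instrument$wavelengths_nm,
                           instrument$frequencies_mhz, amp, ph,
                           instrument$separation_mm),
       cw = cw_spectrum(instrument$grid, refl, instrument$separation_mm),
       noiseless = instrument$amp_noise_cv == 0 &&
         instrument$phase_noise_rad == 0 && instrument$cw_noise_cv == 0)
}

#' Simulate paired OFF/SATT data under the exponential model
#'
#' Draws OFF uniformly on \code{off_range} and SATT = a * exp(b * OFF)
#' with multiplicative log-normal noise, the noise model matching the
#' positivity of thickness measurements.
#'
#' @param n sample size
#' @param a,b exponential model coefficients (OFF on the fraction scale)
#' @param sigma log-normal noise SD (log scale)
#' @param seed integer seed
#' @param off_range range of the OFF draw (fraction scale)
#' @return data.frame with columns \code{off}, \code{satt_cm}
#' @export
simulate_satt_data <- function(n, a = 0.2856, b = 2.214, sigma = 0.15,
                               seed = 1L, off_range = c(0, 0.7)) {
  withr::with_seed(seed, {
    off <- stats::runif(n, off_range[1], off_range[2])
    satt <- a * exp(b * off) * exp(stats::rnorm(n, 0, sigma))
    data.frame(off = off, satt_cm = satt)
  })
}
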