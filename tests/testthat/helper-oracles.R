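# Independent oracles, coded separately from the package internals.

# Closed-form photon-density-wave reflectance for a semi-infinite medium,
# evaluated with explicit real/imaginary arithmetic (no complex numbers),
# extrapolated boundary, tissue index 1.4, R_eff = 0.493.
oracle_fd <- function(mua, mus_prime, rho_mm, f_mhz) {
  mu_t <- mua + mus_prime
  D <- 1 / (3 * mu_t)
  z0 <- 1 / mu_t
  A <- (1 + 0.493) / (1 - 0.493)
  zb <- 2 * A * D
  v <- 2.99792458e11 / 1.4
  om <- 2 * pi * f_mhz * 1e6
  M <- sqrt(mua^2 + (om / v)^2)
  kr <- sqrt((M + mua) / (2 * D))
  ki <- sqrt((M - mua) / (2 * D))
  r1 <- sqrt(rho_mm^2 + z0^2)
  r2 <- sqrt(rho_mm^2 + (z0 + 2 * zb)^2)
  re <- (exp(-kr * r1) * cos(ki * r1) / r1 -
           exp(-kr * r2) * cos(ki * r2) / r2) / (4 * pi * D)
  im <- (-exp(-kr * r1) * sin(ki * r1) / r1 +
           exp(-kr * r2) * sin(ki * r2) / r2) / (4 * pi * D)
  list(amplitude = sqrt(re^2 + im^2), phase = -atan2(im, re))
}

# ordinary least squares by the normal equations
oracle_normal_equations <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# hand-evaluated weighted sum of extinction spectra at selected wavelengths
oracle_weighted_sum <- function(lib, wl, conc) {
  i <- match(wl, lib$wavelength_nm)
  lib$eps[i, "hbmbo2"] * conc[1] + lib$eps[i, "hbmbr"] * conc[2] +
    lib$eps[i, "water"] * conc[3] + lib$eps[i, "fat"] * conc[4]
}

# random non-negative tissue-like chromophore set
random_chromophores <- function(w = runif(1, 0.1, 0.9)) {
  lean <- c(thbmb = 125.2, sto2 = 67.1, water = 73.0, fat = 1.1)
  fat <- c(thbmb = 19.4, sto2 = 63.0, water = 11.3, fat = 67.3)
  mix <- w * fat + (1 - w) * lean
  jitter <- runif(4, 0.8, 1.2)
  chromophore_set(thbmb = mix["thbmb"] * jitter[1],
                  sto2 = min(mix["sto2"] * jitter[2], 99),
                  water = min(mix["water"] * jitter[3], 100),
                  fat = min(mix["fat"] * jitter[4], 100))
}

# build a quadriceps table (region + SATT) from a generated cohort
quad_with_satt <- function(cohort) {
  regions <- summarize_regions(cohort$sites)
  quad <- regions[regions$region == "quadriceps", , drop = FALSE]
  qs <- stats::aggregate(cohort$satt["satt_cm"],
                         by = cohort$satt["participant_id"], FUN = mean)
  quad$satt_cm <- qs$satt_cm[match(quad$participant_id, qs$participant_id)]
  quad
}
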