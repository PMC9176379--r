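test_that("extinction library satisfies its physical invariants", {
  lib <- nir_extinction_library()
  expect_true(all(lib$eps >= 0))
  expect_identical(dim(lib$eps), c(351L, 4L))
  # oxy/deoxy heme spectra cross in the isosbestic region near 800 nm
  d <- lib$eps[, "hbmbo2"] - lib$eps[, "hbmbr"]
  cross <- lib$wavelength_nm[which(diff(sign(d)) != 0)]
  expect_length(cross, 1)
  expect_lt(abs(cross - 800), 15)
  # water and lipid peaks sit near 970 and 930 nm
  expect_lt(abs(lib$wavelength_nm[which.max(lib$eps[, "water"])] - 970), 10)
  expect_lt(abs(lib$wavelength_nm[which.max(lib$eps[, "fat"])] - 930), 10)
})

test_that("extinction library round-trips through its TSV format", {
  lib <- nir_extinction_library()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_extinction(lib, path)
  back <- read_extinction(path)
  expect_equal(back$wavelength_nm, lib$wavelength_nm)
  expect_equal(unname(back$eps), unname(lib$eps), tolerance = 1e-12)
})

test_that("compose_mua is linear, zero at zero, and matches a hand sum", {
  lib <- nir_extinction_library()
  zero <- chromophore_set(thbmb = 0, sto2 = 0, water = 0, fat = 0)
  expect_true(all(compose_mua(zero, lib) == 0))

  mid <- chromophore_set(thbmb = 60, sto2 = 65, water = 40, fat = 25)
  double <- chromophore_set(hbmbo2 = 2 * mid$hbmbo2, hbmbr = 2 * mid$hbmbr,
                            water = 2 * mid$water, fat = 2 * mid$fat)
  expect_equal(compose_mua(double, lib), 2 * compose_mua(mid, lib),
               tolerance = 1e-12)

  lean <- chromophore_set(thbmb = 125.2, sto2 = 67.1, water = 73.0, fat = 1.1)
  wl <- c(660, 760, 830, 930, 970)
  hand <- oracle_weighted_sum(lib, wl, c(lean$hbmbo2, lean$hbmbr,
                                         lean$water, lean$fat))
  expect_equal(compose_mua(lean, lib, wl), hand, tolerance = 1e-12)

  expect_error(compose_mua(lean, lib, c(700, 1100)), "650-1000")
  expect_error(chromophore_set(thbmb = -1, sto2 = 50, water = 10, fat = 10),
               "non-negative")
})

test_that("decompose_mua round-trips compose_mua and respects constraints", {
  lib <- nir_extinction_library()
  expect_equal(as.data.frame(decompose_mua(rep(0, 351), lib)),
               as.data.frame(chromophore_set(thbmb = 0, sto2 = 0,
                                             water = 0, fat = 0)))
  withr::with_seed(11, {
    for (i in 1:25) {
      truth <- random_chromophores()
      rec <- decompose_mua(compose_mua(truth, lib), lib)
      expect_equal(rec$hbmbo2, truth$hbmbo2, tolerance = 1e-6)
      expect_equal(rec$hbmbr, truth$hbmbr, tolerance = 1e-6)
      expect_equal(rec$water, truth$water, tolerance = 1e-6)
      expect_equal(rec$fat, truth$fat, tolerance = 1e-6)
    }
  })
  expect_error(decompose_mua(c(0.01, 0.02, 0.03), lib, c(700, 800, 900)),
               "underdetermined")
})

test_that("NNLS decomposition returns non-negative output on ghost input", {
  lib <- nir_extinction_library()
  # spectrum composed with a negative fat 'ghost' concentration
  ghost <- lib$eps %*% c(50, 30, 40, -5)
  ghost <- pmax(as.numeric(ghost), 0)
  rec <- decompose_mua(ghost, lib)
  expect_true(all(c(rec$hbmbo2, rec$hbmbr, rec$water, rec$fat) >= 0))
})

test_that("decomposition tolerates additive noise at endmember magnitudes", {
  lib <- nir_extinction_library()
  lean <- chromophore_set(thbmb = 125.2, sto2 = 67.1, water = 73.0, fat = 1.1)
  fat <- chromophore_set(thbmb = 19.4, sto2 = 63.0, water = 11.3, fat = 67.3)
  errs <- withr::with_seed(21, {
    sapply(1:200, function(i) {
      truth <- if (i %% 2) lean else fat
      mua <- compose_mua(truth, lib)
      noisy <- pmax(mua + rnorm(length(mua), 0, 0.01 * max(mua)), 0)
      rec <- decompose_mua(noisy, lib)
      max(abs(rec$water - truth$water), abs(rec$fat - truth$fat))
    })
  })
  expect_lt(median(errs), 3)
})

test_that("the scattering power law evaluates and identifies exactly", {
  flat <- scatter_params(a500 = 1.0, b_power = 0)
  expect_equal(powerlaw_mus(flat, c(650, 800, 1000)), rep(1, 3))
  lean_like <- scatter_params(a500 = 0.87, b_power = 1.28)
  expect_equal(powerlaw_mus(lean_like, 800), 0.87 * 1.6^(-1.28),
               tolerance = 1e-12)
  expect_equal(powerlaw_mus(lean_like, 500), 0.87)
  expect_equal(lean_like$mus800, 0.87 * 1.6^(-1.28))
  expect_error(scatter_params(a500 = -1, b_power = 1), "positive")
  # printed-table sign convention negates on ingest
  tb <- scatter_params(a500 = 0.87, b_power = -1.28,
                       sign_convention = "table")
  expect_equal(tb$b_power, 1.28)
})

test_that("fit_powerlaw recovers parameters and is scale-equivariant", {
  wl <- c(690, 785, 835)
  truth <- scatter_params(a500 = 0.85, b_power = 0.42)
  fit <- fit_powerlaw(wl, powerlaw_mus(truth, wl))
  expect_equal(fit$a500, 0.85, tolerance = 1e-10)
  expect_equal(fit$b_power, 0.42, tolerance = 1e-10)

  const <- fit_powerlaw(wl, rep(1.3, 3))
  expect_equal(const$b_power, 0, tolerance = 1e-12)
  expect_equal(const$a500, 1.3, tolerance = 1e-12)

  withr::with_seed(5, {
    mus <- powerlaw_mus(truth, wl) * exp(rnorm(3, 0, 0.05))
    f1 <- fit_powerlaw(wl, mus)
    f2 <- fit_powerlaw(wl, 3.7 * mus)
    expect_equal(f2$a500, 3.7 * f1$a500, tolerance = 1e-10)
    expect_equal(f2$b_power, f1$b_power, tolerance = 1e-10)
  })
  # self-consistency: evaluating the fit at 500 nm returns a500
  expect_equal(powerlaw_mus(fit, 500), fit$a500)
  expect_error(fit_powerlaw(wl, c(1, -1, 1)), "positive")
})
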