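test_that("endmember defaults satisfy their definitional invariants", {
  em <- endmember_pair()
  expect_lt(em$lean$chromophores$fat, em$fat$chromophores$fat)
  expect_gt(em$lean$chromophores$thbmb, em$fat$chromophores$thbmb)
  expect_error(endmember_pair(lean = list(
    chromophores = chromophore_set(thbmb = 10, sto2 = 60, water = 10,
                                   fat = 80),
    scatter = scatter_params(0.9, 1))), "less fat")
})

test_that("mixing_weight has the right limits and shape", {
  expect_equal(mixing_weight(0), 0)
  expect_gt(mixing_weight(100), 1 - 1e-12)
  expect_equal(mixing_weight(0.93, z0_cm = 0.93), 1 - exp(-1))
  w <- mixing_weight(seq(0, 2, 0.1))
  expect_true(all(diff(w) > 0))
  # sharper transition with larger shape
  expect_lt(mixing_weight(0.25, shape = 3), mixing_weight(0.25, shape = 1))
  expect_gt(mixing_weight(1.55, shape = 3), mixing_weight(1.55, shape = 1))
  expect_error(mixing_weight(-1), "non-negative")
})

test_that("generate_cohort is deterministic from its seed", {
  a <- generate_cohort(20, seed = 77)
  b <- generate_cohort(20, seed = 77)
  expect_identical(a, b)
  other <- generate_cohort(20, seed = 78)
  expect_false(identical(a$sites, other$sites))
})

test_that("thin SATT reads lean-dominated, and cohort OFF spans the range", {
  thin <- generate_cohort(10, seed = 3, noise = dosicomp:::noiseless_cohort(),
                          satt_lognorm = c(log(0.25), 1e-9),
                          satt_range = c(0.25, 0.25))
  quad <- summarize_regions(thin$sites)
  quad <- quad[quad$region == "quadriceps", ]
  expect_true(all(quad$off < 20))
  expect_true(all(quad$thbmb > 100))

  big <- generate_cohort(99, seed = 10)
  regions <- summarize_regions(big$sites)
  expect_lt(min(regions$off), 5)
  expect_gt(max(regions$off), 55)
})

test_that("noiseless SATT coupling plants the exponential model exactly", {
  ch <- generate_cohort(40, seed = 5, noise = dosicomp:::noiseless_cohort(),
                        satt_coupling = c(0.2856, 2.214))
  quad <- quad_with_satt(ch)
  fit <- fit_satt(quad$off / 100, quad$satt_cm)
  expect_equal(fit$a_satt, 0.2856, tolerance = 1e-4)
  expect_equal(fit$b_satt, 2.214, tolerance = 1e-4)
})

test_that("cohort tables are schema-complete and internally consistent", {
  ch <- generate_cohort(15, seed = 9)
  expect_equal(nrow(ch$sites), 15 * 10 * 3)
  expect_true(all(table(ch$sites$participant_id) == 30))
  expect_setequal(unique(ch$sites$site), names(site_regions))
  expect_equal(nrow(ch$satt), 15 * 2)
  expect_true(all(ch$satt$satt_cm > 0))
  expect_equal(ch$dxa$fat_pct + ch$dxa$lst_pct + ch$dxa$bone_pct,
               rep(100, 15), tolerance = 1e-9)
  expect_true(all(mixing_weight(ch$truth$satt_cm,
                                shape = ch$config$shape) >= 0))
  expect_error(cohort_noise(replicate_cv = -1), "invalid")
})

test_that("the planted DXA model is recoverable from noiseless data", {
  ch <- generate_cohort(30, seed = 13, noise = dosicomp:::noiseless_cohort())
  regions <- summarize_regions(ch$sites)
  m <- fit_bodycomp(regions, ch$dxa, "fat_pct")
  cf <- ch$config$dxa_coef
  expect_equal(m$intercept, cf[["intercept"]], tolerance = 1e-6)
  expect_equal(unname(m$coefficients), unname(cf[region_names]),
               tolerance = 1e-6)
})

test_that("generate_measurements flags noiseless output and adds noise", {
  lean <- chromophore_set(thbmb = 125.2, sto2 = 67.1, water = 73, fat = 1.1)
  sc <- scatter_params(0.87, 1.28)
  gm <- generate_measurements(lean, sc)
  expect_true(gm$noiseless)
  expect_s3_class(gm$fd, "fd_measurement")
  expect_s3_class(gm$cw, "cw_spectrum")
  noisy <- withr::with_seed(1, generate_measurements(
    lean, sc, instrument_config(amp_noise_cv = 0.01)))
  expect_false(noisy$noiseless)
  expect_false(identical(noisy$fd$amplitude, gm$fd$amplitude))
})

test_that("replicate noise in measurements raises recovered-fat spread", {
  lib <- nir_extinction_library()
  mid <- chromophore_set(thbmb = 70, sto2 = 65, water = 45, fat = 30)
  sc <- scatter_params(0.86, 0.8)
  spread <- sapply(c(0.002, 0.02, 0.12), function(cv) {
    inst <- instrument_config(amp_noise_cv = cv,
                              phase_noise_rad = cv,
                              cw_noise_cv = cv)
    fats <- withr::with_seed(round(cv * 1e4), {
      sapply(1:4, function(i) {
        gm <- generate_measurements(mid, sc, inst, lib)
        invert_measurement(gm$fd, gm$cw, lib)$chromophores$fat
      })
    })
    sd(fats)
  })
  expect_true(all(diff(spread) > 0))
})

test_that("simulate_satt_data is seeded and follows the exponential trend", {
  d1 <- simulate_satt_data(50, seed = 4)
  d2 <- simulate_satt_data(50, seed = 4)
  expect_identical(d1, d2)
  expect_true(all(d1$satt_cm > 0))
  # log-linear trend: slope near b, intercept near log(a)
  fit <- lm(log(satt_cm) ~ off, data = simulate_satt_data(2000, sigma = 0.15,
                                                          seed = 5))
  expect_equal(unname(coef(fit)[2]), 2.214, tolerance = 0.1)
  expect_equal(exp(unname(coef(fit)[1])), 0.2856, tolerance = 0.05)
})
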