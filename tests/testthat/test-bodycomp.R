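# build a regions table with independent random optical fractions
random_regions <- function(n, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("P%02d", 1:n)
    df <- expand.grid(participant_id = ids, region = region_names,
                      stringsAsFactors = FALSE)
    df$off <- runif(nrow(df), 2, 65)
    df$olf <- 100 - df$off
    df
  })
}

test_that("fit_bodycomp recovers a planted single-region model", {
  regions <- random_regions(30, seed = 4)
  ab <- regions$off[regions$region == "abdomen"]
  dxa <- data.frame(participant_id = unique(regions$participant_id),
                    fat_pct = 5 + 0.4 * ab, lst_pct = NA_real_)
  m <- fit_bodycomp(regions, dxa, "fat_pct")
  expect_equal(m$intercept, 5, tolerance = 1e-8)
  expect_equal(unname(m$coefficients["abdomen"]), 0.4, tolerance = 1e-8)
  expect_equal(unname(m$coefficients[c("biceps", "quadriceps", "calf")]),
               rep(0, 3), tolerance = 1e-8)

  # constant target: intercept only
  dxa$fat_pct <- 22
  mc <- fit_bodycomp(regions, dxa, "fat_pct")
  expect_equal(mc$intercept, 22, tolerance = 1e-8)
  expect_equal(unname(mc$coefficients), rep(0, 4), tolerance = 1e-8)

  # invariance to participant ordering
  perm <- withr::with_seed(9, sample(nrow(regions)))
  dxa$fat_pct <- 5 + 0.4 * ab
  m2 <- fit_bodycomp(regions[perm, ], dxa, "fat_pct")
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-10)
})

test_that("fit equals the normal-equations solution on random fixtures", {
  for (s in 1:10) {
    regions <- random_regions(25, seed = 100 + s)
    wide <- dosicomp:::regions_wide(regions, "off")
    y <- withr::with_seed(200 + s,
                          10 + rowSums(as.matrix(wide[region_names])) / 10 +
                            rnorm(25, 0, 2))
    dxa <- data.frame(participant_id = wide$participant_id, fat_pct = y)
    m <- fit_bodycomp(regions, dxa, "fat_pct")
    X <- cbind(1, as.matrix(wide[region_names]))
    beta <- oracle_normal_equations(X, y)
    expect_equal(unname(c(m$intercept, m$coefficients)), beta,
                 tolerance = 1e-8)
  }
})

test_that("prediction applies the linear model with range clamping", {
  m <- structure(list(target = "fat_pct", predictor = "off",
                      intercept = 25,
                      coefficients = stats::setNames(rep(0, 4), region_names),
                      train_ids = character(), n = 0, sigma = NA_real_),
                 class = "bodycomp_model")
  regions <- random_regions(5, seed = 6)
  p <- predict_bodycomp(m, regions)
  expect_equal(p$prediction, rep(25, 5))

  m$coefficients["abdomen"] <- 0.4
  m$intercept <- 5
  one <- regions[regions$participant_id == "P01", ]
  one$off[one$region == "abdomen"] <- 50
  expect_equal(predict_bodycomp(m, one)$prediction, 25)

  m$intercept <- -300
  pc <- predict_bodycomp(m, regions)
  expect_true(all(pc$prediction == 0) && all(pc$out_of_range))

  expect_error(predict_bodycomp(m, regions[regions$region != "calf", ]),
               "all four regions")
})

test_that("complementary OFF/OLF models give complementary predictions", {
  regions <- random_regions(40, seed = 12)
  wide_off <- dosicomp:::regions_wide(regions, "off")
  fat <- 8 + as.matrix(wide_off[region_names]) %*% c(0.1, 0.15, 0.1, 0.05)
  dxa <- data.frame(participant_id = wide_off$participant_id,
                    fat_pct = as.numeric(fat),
                    lst_pct = 100 - as.numeric(fat))
  mf <- fit_bodycomp(regions, dxa, "fat_pct")
  ml <- fit_bodycomp(regions, dxa, "lst_pct")
  pf <- predict_bodycomp(mf, regions)
  pl <- predict_bodycomp(ml, regions)
  expect_equal(pf$prediction + pl$prediction, rep(100, 40),
               tolerance = 1e-8)
})

test_that("evaluation guards leakage and handles degenerate hold-outs", {
  regions <- random_regions(20, seed = 15)
  wide <- dosicomp:::regions_wide(regions, "off")
  y <- 8 + as.matrix(wide[region_names]) %*% c(0.1, 0.15, 0.1, 0.05)
  dxa <- data.frame(participant_id = wide$participant_id,
                    fat_pct = as.numeric(y))
  split <- split_cohort(wide$participant_id, 0.8, seed = 3)
  m <- fit_bodycomp(regions, dxa, "fat_pct", train_ids = split$train)

  # noiseless planted data: evaluating held-out participants gives zero bias
  ev <- evaluate_bodycomp(m, regions, dxa, test_ids = split$test)
  expect_equal(ev$bias, 0, tolerance = 1e-8)

  expect_error(evaluate_bodycomp(m, regions, dxa,
                                 test_ids = split$train[1]), "leak")

  one <- split$test[1]
  ev1 <- evaluate_bodycomp(m, regions[regions$participant_id == one, ],
                           dxa, test_ids = one)
  expect_false(ev1$loa_defined)
})

test_that("training requires complete regions and DXA records", {
  regions <- random_regions(10, seed = 30)
  dxa <- data.frame(participant_id = unique(regions$participant_id),
                    fat_pct = runif(10, 15, 30))
  incomplete <- regions[!(regions$participant_id == "P03" &
                            regions$region == "calf"), ]
  expect_error(fit_bodycomp(incomplete, dxa, "fat_pct",
                            train_ids = unique(regions$participant_id)),
               "P03")
  expect_error(fit_bodycomp(regions, dxa[-1, ], "fat_pct",
                            train_ids = unique(regions$participant_id)),
               "DXA")
})

test_that("split_cohort is seeded and respects the train fraction", {
  ids <- sprintf("P%02d", 1:99)
  s1 <- split_cohort(ids, 0.8, seed = 42)
  s2 <- split_cohort(ids, 0.8, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1$train, 79)
  expect_length(s1$test, 20)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_error(split_cohort(ids, 1.2), "in \\(0, 1\\)")
})
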