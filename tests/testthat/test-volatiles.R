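# Calibration, peak matching, quantification and compositional
# statistics.

test_that("fit_calibration is OLS with diagnostics", {
  amounts <- c(10, 25, 50, 100, 200)
  cv <- fit_calibration(amounts, 3 * amounts)
  expect_equal(cv$slope, 3)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$n_points, 5L)
  expect_error(fit_calibration(rep(50, 5), rnorm(5)), "distinct")
  expect_error(fit_calibration(1:3, 1:2), "length")
})

test_that("calibration recovers generator parameters as noise vanishes", {
  curves <- data.frame(compound = "15ene", slope = 2.7, intercept = 12)
  for (sd in c(0, 1e-6)) {
    run <- simulate_gcms_run(c(`15ene` = 50), curves, noise_sd = sd,
                             seed = 8)
    fit <- fit_calibration_set(run$standards)[["15ene"]]
    expect_equal(fit$slope, 2.7, tolerance = 1e-3)
    expect_equal(fit$intercept, 12, tolerance = 1e-2)
  }
})

test_that("match_peak picks the nearest alias within tolerance", {
  expect_equal(match_peak(1492), "15ene")
  expect_true(is.na(match_peak(1200, tolerance = 5)))
  # 1015 sits between the two MBQ aliases 1011/1018
  expect_equal(match_peak(1015), "MBQ")
  expect_equal(match_peak(c(1098, 1109)), c("EBQ", "EBQ"))
  # equidistant between MHQ alias 1367 and a synthetic registry entry
  reg <- compound_registry()
  reg$ri2[reg$compound == "EHQ"] <- 1369
  expect_warning(res <- match_peak(1368, reg), "ties")
  expect_true(is.na(res))
  expect_error(match_peak(1000, tolerance = -1), "tolerance")
})

test_that("quantify_mass inverts the curve and clips at zero", {
  cv <- fit_calibration(c(0, 10), c(5, 25))   # slope 2, intercept 5
  expect_equal(quantify_mass(5, cv), 0)        # area == intercept
  expect_equal(quantify_mass(25, cv), 10)
  expect_equal(quantify_mass(1, cv), 0)        # below blank clips
  expect_error(quantify_mass(5, list(slope = 2)), "fitted")
})

test_that("quantification round-trips for any non-negative mass", {
  cv <- fit_calibration(c(10, 25, 50, 100, 200),
                        2.4 * c(10, 25, 50, 100, 200) + 7)
  set.seed(1)
  m <- c(0, runif(20, 0, 500))
  expect_equal(quantify_mass(2.4 * m + 7, cv), m)
})

test_that("molar totals convert summed masses with the right weights", {
  expect_equal(molar_totals(list(MBQ_sum = 0, EBQ_sum = 0, `15ene` = 0,
                                 `17diene` = 0, `17ene` = 0)),
               list(quinones_nmol = 0, alkenes_nmol = 0))
  # 122.04 ng of MBQ_sum is exactly 1 nmol
  tot <- molar_totals(list(MBQ_sum = 122.04, EBQ_sum = 136.05,
                           `15ene` = 210.24, `17diene` = 236.25,
                           `17ene` = 238.27), unit = "ng")
  expect_equal(tot$quinones_nmol, 2)
  expect_equal(tot$alkenes_nmol, 3)
  expect_error(molar_totals(list(MBQ_sum = 1)), "missing")
})

test_that("alkene fractions sum to one and guard empty pools", {
  set.seed(7)
  for (i in 1:20) {
    m <- as.list(setNames(runif(5, 0.01, 10),
                          c("MBQ_sum", "EBQ_sum", "15ene",
                            "17diene", "17ene")))
    expect_equal(sum(alkene_fractions(m)), 1)
  }
  expect_warning(
    fr <- alkene_fractions(list(MBQ_sum = 5, EBQ_sum = 5, `15ene` = 0,
                                `17diene` = 0, `17ene` = 0)),
    "undefined")
  expect_true(all(is.na(fr)))
})

test_that("compositional report produces coherent cell statistics", {
  # two beetles x two glands of one sex, fixed masses
  prof <- data.frame(
    sample_id = c("b1t", "b2t", "b1a", "b2a"),
    sex = "male", gland = rep(c("thr", "abd"), each = 2),
    MBQ_sum = c(5000, 6000, 8000, 9000),
    EBQ_sum = c(7000, 7200, 10000, 11000),
    `15ene` = c(4500, 5000, 9500, 10000),
    `17diene` = c(2300, 2500, 500, 520),
    `17ene` = c(1000, 1100, 1000, 1100), check.names = FALSE)
  rep_ <- compositional_report(prof)
  expect_equal(nrow(rep_), 2)
  expect_equal(sum(rep_$share_quinones), 1)
  expect_equal(sum(rep_$share_alkenes), 1)
  expect_equal(rep_$frac_15ene + rep_$frac_17diene + rep_$frac_17ene,
               c(1, 1))
  thr <- rep_[rep_$gland == "thr", ]
  expect_equal(thr$mbq_ebq_molar_ratio,
               (5500 / 122.04) / (7100 / 136.05))
  expect_error(compositional_report(prof[0, ]), "empty")
})

test_that("group comparison flags a planted quinone-less knock-down", {
  set.seed(21)
  n <- 15
  wt <- data.frame(MBQ_sum = rnorm(n, 5000, 800),
                   EBQ_sum = rnorm(n, 7000, 900),
                   `15ene` = rnorm(n, 4700, 600),
                   `17diene` = rnorm(n, 2400, 300),
                   `17ene` = rnorm(n, 1000, 150), check.names = FALSE)
  kd <- wt
  kd$MBQ_sum <- abs(rnorm(n, 0, 10))      # quinones wiped out
  kd$EBQ_sum <- abs(rnorm(n, 0, 10))
  p <- compare_volatile_groups(wt, kd)
  expect_lt(p[["MBQ_sum"]], 0.001)
  expect_lt(p[["EBQ_sum"]], 0.001)
  expect_gt(p[["17ene"]], 0.05)
  # sexes with identical distributions are not flagged
  ps <- compare_volatile_sexes(wt, wt)
  expect_true(all(ps == 1))
  expect_error(compare_volatile_sexes(wt[1, ], wt), "n >= 2")
})
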