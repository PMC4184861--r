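# The four onset predictors against trivial cases and the independent
# day-by-day loop oracles.

test_that("degree-day accumulation matches the loop oracle", {
  base <- met_from_vec(rep(8, 426))
  expect_equal(gdd_accumulate(base, t_th = 8)$cum_gdd, rep(0, 365))
  expect_equal(gdd_accumulate(met_from_vec(rep(18, 426)), t_th = 8)$cum_gdd,
               10 * (1:365))

  ser <- random_series(5, seed = 11)
  for (s in ser) {
    met <- met_from_vec(s$tmean)
    cum <- gdd_accumulate(met, t_th = 4, t0 = 20)$cum_gdd
    acc <- 0
    expected <- numeric(365)
    for (t in 20:365) {
      acc <- acc + max(s$tmean[61 + t] - 4, 0)
      expected[t] <- acc
    }
    expect_equal(cum, expected)
  }
})

test_that("GDD onset: inclusive threshold, missing when never reached", {
  met16 <- met_from_vec(rep(16, 426))
  expect_equal(predict_gdd(met16, 6, 50)$bgs_doy, 5L)
  cold <- met_from_vec(rep(-5, 426))
  expect_true(is.na(predict_gdd(cold, 6, 50)$bgs_doy))
  # reference evergreen-needleleaf parameters on a seasonal fixture
  sites <- generate_landscape(1, c(`evergreen needleleaf forest` = 1),
                              gradients = list(mean_annual_temp = 4), seed = 8)
  met <- generate_climate(sites, 2001)
  expect_equal(predict_gdd(met, 6, 50)$bgs_doy,
               oracle_gdd(met$tmean, 6, 50))
})

test_that("soil-temperature proxy is a trailing mean with warm-up", {
  const <- met_from_vec(rep(7, 426))
  expect_equal(soil_temperature(const)$tsoil, rep(7, 426))
  ramp <- met_from_vec(seq(0, by = 0.1, length.out = 426))
  expect_equal(soil_temperature(ramp, window = 1)$tsoil, ramp$tmean)
  s11 <- soil_temperature(ramp, window = 11)$tsoil
  # trailing 11-day mean of a linear ramp lags air temperature by 5 days
  expect_equal(s11[11:426], ramp$tmean[11:426] - 0.5)
  expect_equal(s11[1:10], cumsum(ramp$tmean[1:10]) / (1:10))
  noisy <- random_series(1, seed = 5)[[1]]
  expect_equal(soil_temperature(met_from_vec(noisy$tmean))$tsoil,
               oracle_soil(noisy$tmean, 11))
})

test_that("day length follows solar geometry with polar clamps", {
  expect_equal(day_length(80, latitude = 0), 43200, tolerance = 600)
  expect_equal(day_length(355, latitude = 80), 0)    # polar night
  expect_equal(day_length(172, latitude = 80), 86400)  # polar day
  for (doy in c(1, 81, 172, 264, 355)) {
    for (lat in c(0, 23, 45, 66, 80)) {
      expect_equal(day_length(doy, lat), oracle_day_length(lat, doy),
                   tolerance = 1e-8)
    }
  }
  expect_error(day_length(100, latitude = 95), "latitude")
})

test_that("woody onset: critical sum, day-length gate and 15-day offset", {
  sites <- generate_landscape(1, c(`deciduous broadleaf forest` = 1),
                              gradients = list(mean_annual_temp = 9), seed = 12)
  met <- generate_climate(sites, 2001)
  got <- predict_bbgc_woody(met, t_th = -5, a = 5.505, b = 0.085,
                            latitude = 45)
  expect_equal(got$bgs_doy, oracle_bbgc_woody(met$tmean, 45, -5, 5.505, 0.085))

  # a = b = 0 means a critical sum of exactly one degree-day
  warm <- met_from_vec(rep(20, 426))
  one_dd <- predict_bbgc_woody(warm, t_th = 0, a = 0, b = 0, latitude = 0)
  # crossing on day 1 (soil excess 20 >= 1), minus offset, floored at 1
  expect_equal(one_dd$bgs_doy, 1L)
})

test_that("grass onset: joint thermal and precipitation criteria", {
  s <- random_series(1, seed = 7)[[1]]
  met <- met_from_vec(s$tmean + 12, s$precip)
  expect_equal(predict_bbgc_grass(met, -5, 15, 369, 0.05)$bgs_doy,
               oracle_bbgc_grass(s$tmean + 12, s$precip, -5, 15, 369, 0.05))
  # k = 0: precipitation criterion holds from day 1, thermal rule alone
  dry <- met_from_vec(s$tmean + 12, rep(0, 426))
  expect_equal(predict_bbgc_grass(met, -5, 15, 369, 0)$bgs_doy,
               predict_bbgc_grass(dry, -5, 15, 369, 0)$bgs_doy)
  # no rain all year with k > 0: onset never triggers
  expect_true(is.na(predict_bbgc_grass(dry, -5, 15, 369, 0.05)$bgs_doy))
})

test_that("NGD onset counts days above base", {
  warm <- met_from_vec(rep(12, 426))
  expect_equal(predict_ngd(warm, 5, 6)$bgs_doy, 6L)
  cold <- met_from_vec(rep(2, 426))
  expect_true(is.na(predict_ngd(cold, 5, 6)$bgs_doy))
  sites <- generate_landscape(1, c(`deciduous broadleaf forest` = 1),
                              gradients = list(mean_annual_temp = 6), seed = 13)
  met <- generate_climate(sites, 2001)
  expect_equal(predict_ngd(met, 6, 21)$bgs_doy, oracle_ngd(met$tmean, 6, 21))
})

test_that("chilling-forcing onset follows the negative-exponential law", {
  # winter never below the chill base: critical forcing stays g + h
  mild <- met_from_vec(pmax(rep(5, 426), 5))
  expect_equal(predict_ncd_gdd(mild, 0, -5, -300, 400, -0.1)$bgs_doy,
               predict_gdd(mild, -5, 100)$bgs_doy)
  # w = 0: constant critical forcing g + h regardless of chilling
  s <- random_series(1, seed = 9)[[1]]
  met <- met_from_vec(s$tmean)
  expect_equal(predict_ncd_gdd(met, 0, -5, -100, 700, 0)$bgs_doy,
               predict_gdd(met, -5, 600)$bgs_doy)
  sites <- generate_landscape(1, c(`deciduous broadleaf forest` = 1),
                              gradients = list(mean_annual_temp = 7), seed = 14)
  met2 <- generate_climate(sites, 2001)
  expect_equal(predict_ncd_gdd(met2, 0, -5, -100, 700, -0.1)$bgs_doy,
               oracle_ncd_gdd(met2$tmean, 0, -5, -100, 700, -0.1))
  expect_error(predict_ncd_gdd(met2, 0, -5, -100, 700, 0.2), "w must")
})

test_that("every predictor agrees with its naive oracle on random series", {
  ser <- random_series(60, seed = 31)
  for (i in seq_along(ser)) {
    s <- ser[[i]]
    met <- met_from_vec(s$tmean, s$precip)
    expect_identical(predict_gdd(met, 4, 180)$bgs_doy,
                     oracle_gdd(s$tmean, 4, 180))
    expect_identical(predict_ngd(met, 4, 25)$bgs_doy,
                     oracle_ngd(s$tmean, 4, 25))
    expect_identical(predict_bbgc_woody(met, t_th = -2, a = 5, b = 0.08,
                                        latitude = 48)$bgs_doy,
                     oracle_bbgc_woody(s$tmean, 48, -2, 5, 0.08))
    expect_identical(predict_bbgc_grass(met, -2, 12, 150, 0.08)$bgs_doy,
                     oracle_bbgc_grass(s$tmean, s$precip, -2, 12, 150, 0.08))
    expect_identical(predict_ncd_gdd(met, 0, -3, -150, 500, -0.08)$bgs_doy,
                     oracle_ncd_gdd(s$tmean, 0, -3, -150, 500, -0.08))
  }
})

test_that("warming never delays one-phase onset at fixed critical values", {
  ser <- random_series(25, seed = 17)
  for (s in ser) {
    met <- met_from_vec(s$tmean, s$precip)
    warmer <- met_from_vec(s$tmean + 1.5, s$precip)
    cmp <- function(p0, p1) {
      expect_true(is.na(p0) || (!is.na(p1) && p1 <= p0))
    }
    cmp(predict_gdd(met, 4, 200)$bgs_doy, predict_gdd(warmer, 4, 200)$bgs_doy)
    cmp(predict_ngd(met, 4, 30)$bgs_doy, predict_ngd(warmer, 4, 30)$bgs_doy)
    # b = 0 and c = 0 hold the critical sums fixed under warming
    cmp(predict_bbgc_woody(met, t_th = 0, a = 6, b = 0, latitude = 45)$bgs_doy,
        predict_bbgc_woody(warmer, t_th = 0, a = 6, b = 0,
                           latitude = 45)$bgs_doy)
    cmp(predict_bbgc_grass(met, 0, 0, 400, 0.05)$bgs_doy,
        predict_bbgc_grass(warmer, 0, 0, 400, 0.05)$bgs_doy)
  }
})

test_that("onset dates always fall in [1, 365] and the offset floors at 1", {
  ser <- random_series(40, seed = 23)
  all_doys <- unlist(lapply(ser, function(s) {
    met <- met_from_vec(s$tmean, s$precip)
    c(predict_gdd(met, 0, 50)$bgs_doy,
      predict_ngd(met, 0, 10)$bgs_doy,
      predict_bbgc_woody(met, t_th = -5, a = 1, b = 0, latitude = 20)$bgs_doy,
      predict_bbgc_grass(met, -5, 0, 1, 0.001)$bgs_doy,
      predict_ncd_gdd(met, 0, -5, 0, 10, -0.1)$bgs_doy)
  }))
  ok <- all_doys[!is.na(all_doys)]
  expect_true(all(ok >= 1 & ok <= 365))
})

test_that("without chilling the two-phase model reduces to GDD", {
  ser <- random_series(20, seed = 29)
  for (s in ser) {
    met <- met_from_vec(s$tmean)
    expect_identical(predict_ncd_gdd(met, -Inf, 2, 100, 150, -0.1)$bgs_doy,
                     predict_gdd(met, 2, 250)$bgs_doy)
  }
})

test_that("dispatch routes models and schemes correctly", {
  sites <- generate_landscape(
    2, c(grassland = 0.5, `deciduous broadleaf forest` = 0.5),
    gradients = list(mean_annual_temp = 8), seed = 19)
  met <- generate_climate(sites, 2001)
  expect_equal(predict_bgs(met, "gdd", list(t_th = 5, gdd_c = 100)),
               predict_gdd(met, 5, 100))
  bb <- predict_bgs(met, "bbgc", params = NULL, sites = sites)
  gr <- sites$pixel_id[sites$biome == "grassland"]
  wd <- sites$pixel_id[sites$biome != "grassland"]
  expect_equal(bb$bgs_doy[bb$pixel_id == gr],
               predict_bbgc_grass(met[met$pixel_id == gr, ],
                                  -5, 15, 369, 0.05)$bgs_doy)
  expect_equal(bb$bgs_doy[bb$pixel_id == wd],
               predict_bbgc_woody(met[met$pixel_id == wd, ],
                                  t_th = -5, a = 5.505, b = 0.085,
                                  latitude = 45)$bgs_doy)
  expect_error(predict_bgs(met, "gdd", list(t_th = 5)), "lacks")
})
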