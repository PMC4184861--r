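# Pairing and the comparison metrics.

pairs_of <- function(obs, pred) {
  n <- length(obs)
  pair_bgs(tibble::tibble(pixel_id = sprintf("p%03d", 1:n), year = 2001L,
                          bgs_doy = as.integer(obs)),
           tibble::tibble(pixel_id = sprintf("p%03d", 1:n), year = 2001L,
                          bgs_doy = as.integer(pred)))
}

test_that("pairing inner-joins and drops missing sides", {
  p <- pairs_of(c(100, 110, 120), c(101, 111, 121))
  expect_equal(nrow(p), 3)
  expect_equal(attr(p, "n_dropped"), 0)
  p2 <- pairs_of(c(100, 110, 120), c(101, NA, 121))
  expect_equal(nrow(p2), 2)
  expect_equal(attr(p2, "n_dropped"), 1)
  expect_error(
    pair_bgs(tibble::tibble(pixel_id = "a", year = 2001L, bgs_doy = 1L),
             tibble::tibble(pixel_id = "b", year = 2001L, bgs_doy = 1L)),
    "no common")
})

test_that("rmse and mean absolute error follow their definitions", {
  perfect <- pairs_of(c(100, 120), c(100, 120))
  expect_equal(bgs_rmse(perfect), 0)
  expect_equal(bgs_mae(perfect), 0)
  pm3 <- pairs_of(c(100, 120), c(103, 117))
  expect_equal(bgs_rmse(pm3), 3)
  expect_equal(bgs_mae(pm3), 3)
  mix <- pairs_of(c(100, 120), c(100, 126))
  expect_equal(bgs_rmse(mix), sqrt(36 / 2))
  expect_equal(bgs_mae(mix), 3)
})

test_that("R-squared is the squared Pearson correlation", {
  obs <- c(100, 110, 125, 140)
  expect_equal(bgs_r_squared(pairs_of(obs, obs)), 1)
  expect_equal(bgs_r_squared(pairs_of(obs, 2 * obs + 7)), 1)
  expect_error(bgs_r_squared(pairs_of(obs, rep(100, 4))), "zero variance")
  expect_error(bgs_r_squared(pairs_of(obs[1:2], obs[1:2])), "at least 3")
  skewed <- pairs_of(obs, obs + 20)
  expect_equal(bgs_r_squared(skewed), 1)
  expect_lt(bgs_r_squared(skewed, "one_minus_sse_sst"), 1)
})

test_that("interannual correlation works on biome-mean series", {
  sites <- tibble::tibble(pixel_id = sprintf("p%03d", 1:4),
                          biome = rep(c("grassland", "savanna"), each = 2))
  years <- 2001:2010
  set.seed(42)
  obs <- tidyr::expand_grid(pixel_id = sites$pixel_id, year = years) |>
    dplyr::mutate(bgs_doy = as.integer(100 + 3 * (year - 2000) +
                                         sample(-5:5, dplyr::n(), TRUE)))
  pred <- dplyr::mutate(obs, bgs_doy = as.integer(bgs_doy +
                                                    sample(-7:7, dplyr::n(), TRUE)))
  pairs <- pair_bgs(obs, pred)
  got <- interannual_r(pairs, sites)
  # direct formula oracle: correlate the annual pixel-mean series
  for (b in unique(sites$biome)) {
    px <- sites$pixel_id[sites$biome == b]
    o <- tapply(pairs$observed[pairs$pixel_id %in% px],
                pairs$year[pairs$pixel_id %in% px], mean)
    p <- tapply(pairs$predicted[pairs$pixel_id %in% px],
                pairs$year[pairs$pixel_id %in% px], mean)
    expect_equal(got$r[got$biome == b], unname(cor(o, p)))
  }
  expect_equal(interannual_r(pair_bgs(obs, obs), sites)$r, c(1, 1))
  const_pred <- dplyr::mutate(obs, bgs_doy = 100L)
  expect_error(interannual_r(pair_bgs(obs, const_pred), sites), "constant")
  short <- pairs[pairs$year <= 2002, ]
  expect_error(interannual_r(short, sites), ">= 3 years")
})

test_that("cumulative frequencies count pixels within thresholds", {
  exact <- pairs_of(c(100, 120), c(100, 120))
  expect_true(all(cumulative_within(exact, c(0, 5, 10))$pct == 100))
  two <- pairs_of(c(100, 120), c(102, 132))
  expect_equal(cumulative_within(two, 10)$pct, 50)
  expect_equal(cumulative_within(two, 1000)$pct, 100)  # saturation
})

test_that("metric identities hold on random pairs", {
  set.seed(19)
  for (i in 1:20) {
    obs <- sample(60:200, 40, replace = TRUE)
    pred <- pmin(pmax(obs + sample(-30:30, 40, TRUE), 1), 365)
    p <- pairs_of(obs, pred)
    expect_gte(bgs_rmse(p), bgs_mae(p))
    cf <- cumulative_within(p, 0:40)
    expect_true(all(diff(cf$pct) >= 0))
    expect_equal(cf$pct[cf$threshold == max(abs(pred - obs))], 100)
    shuf <- p[sample(nrow(p)), ]
    expect_equal(bgs_rmse(shuf), bgs_rmse(p))
    expect_equal(bgs_mae(shuf), bgs_mae(p))
  }
  allsame <- pairs_of(c(100, 120, 150), c(104, 116, 154))
  expect_equal(bgs_rmse(allsame), bgs_mae(allsame))  # equal |errors|
})

test_that("rmse and mae estimate sigma and sigma*sqrt(2/pi) under Gaussian error", {
  set.seed(7)
  n <- 10000
  sigma <- 6
  obs <- round(runif(n, 80, 180))
  pred <- obs + rnorm(n, 0, sigma)
  p <- pairs_of(obs, round(pred))
  # rounding adds 1/12 variance; allow 3 standard errors
  se_rmse <- sigma / sqrt(2 * n)
  expect_lt(abs(bgs_rmse(p) - sqrt(sigma^2 + 1 / 12)), 3 * se_rmse)
  mae_expect <- sqrt(sigma^2 + 1 / 12) * sqrt(2 / pi)
  se_mae <- sigma * sqrt((1 - 2 / pi)) / sqrt(n)
  expect_lt(abs(bgs_mae(p) - mae_expect), 3 * se_mae + 0.05)
})

test_that("evaluate_model is exact on self-consistent data and tracks noise", {
  sites <- generate_landscape(60, c(grassland = 1),
                              gradients = list(mean_annual_temp = c(0, 10)),
                              seed = 10)
  met <- generate_climate(sites, 2001:2005)
  params <- list(t_th = 2, gdd_c = 200)
  obs0 <- generate_bgs_observations(met, sites, "gdd", params,
                                    obs_noise_sd = 0)
  ev0 <- evaluate_model(obs0, met, "gdd", params, sites = sites)
  expect_equal(ev0$metrics$rmse, 0)
  expect_equal(ev0$metrics$r_a, 0)
  expect_equal(ev0$metrics$r2, 1)
  expect_equal(ev0$metrics$r2_sse_sst, 1)
  expect_true(all(ev0$cumfreq$pct == 100))

  obs5 <- generate_bgs_observations(met, sites, "gdd", params,
                                    obs_noise_sd = 5, seed = 3)
  ev5 <- evaluate_model(obs5, met, "gdd", params, sites = sites)
  expect_equal(ev5$metrics$rmse, 5, tolerance = 0.1)

  # train/validation halves differ only by sampling, no leakage asymmetry
  sp <- split_half(sites, seed = 4)
  rmse_half <- vapply(sp, function(half) {
    idx <- met$pixel_id %in% half$pixel_id
    evaluate_model(obs5[obs5$pixel_id %in% half$pixel_id, ],
                   met[idx, ], "gdd", params)$metrics$rmse
  }, numeric(1))
  expect_lt(abs(rmse_half[1] - rmse_half[2]), 1)
  expect_s3_class(autoplot(ev5), "ggplot")
  expect_equal(nrow(tidy(ev5)), ncol(ev5$metrics) - 1)
  expect_equal(glance(ev5), ev5$metrics)
})

test_that("missing predictions are dropped before any metric", {
  sites <- generate_landscape(4, c(grassland = 1),
                              gradients = list(mean_annual_temp = c(6, 10)),
                              seed = 11)
  met <- generate_climate(sites, 2001)
  obs <- generate_bgs_observations(met, sites, "gdd",
                                   list(t_th = 2, gdd_c = 100),
                                   obs_noise_sd = 0)
  # an impossible critical sum for one cold pixel: prediction missing there
  cold <- met
  cold$tmean[cold$pixel_id == "px0001"] <- -20
  pred <- predict_bgs(cold, "gdd", list(t_th = 2, gdd_c = 100))
  expect_true(is.na(pred$bgs_doy[pred$pixel_id == "px0001"]))
  p <- pair_bgs(obs, pred)
  expect_equal(nrow(p), 3)
  expect_false("px0001" %in% p$pixel_id)
})
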