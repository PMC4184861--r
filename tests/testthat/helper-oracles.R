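# Independent naive day-by-day oracles for every onset model, written as
# plain scalar loops with no shared code with the package's vectorised
# implementations, plus small fixture builders.

PRE <- 61L   # Nov 1 .. Dec 31 prefix length
NDY <- 365L

# Build a met tibble for one pixel-year from full 426-day vectors.
met_from_vec <- function(tmean, precip = rep(0, PRE + NDY),
                         pixel_id = "p1", year = 2001) {
  stopifnot(length(tmean) == PRE + NDY, length(precip) == PRE + NDY)
  doy <- c(305:365, 1:365)
  cal_year <- c(rep(year - 1L, PRE), rep(year, NDY))
  jan1 <- as.Date(paste0(cal_year, "-01-01"))
  leap <- (cal_year %% 4 == 0 & cal_year %% 100 != 0) | cal_year %% 400 == 0
  tibble::tibble(pixel_id = pixel_id, year = year,
                 rel_day = seq_len(PRE + NDY), doy = doy,
                 date = jan1 + (doy - 1L) + ifelse(leap & doy >= 60, 1L, 0L),
                 tmean = tmean, precip = precip)
}

# A bundle of randomized 426-day series for property tests: sinusoid with
# random mean/amplitude/phase plus noise, random precipitation bursts.
random_series <- function(n, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    mean_t <- runif(1, -8, 18)
    amp <- runif(1, 0, 18)
    phase <- runif(1, 0, 365)
    d <- seq_len(PRE + NDY)
    tmean <- mean_t - amp * cos(2 * pi * (d - phase) / 365) +
      rnorm(PRE + NDY, 0, runif(1, 0, 3))
    precip <- rgamma(PRE + NDY, shape = 0.4, scale = runif(1, 0, 8))
    list(tmean = tmean, precip = precip)
  }))
}

oracle_gdd <- function(tmean426, t_th, gdd_c, t0 = 1) {
  acc <- 0
  for (t in t0:NDY) {
    x <- tmean426[PRE + t] - t_th
    if (x > 0) acc <- acc + x
    if (acc >= gdd_c) return(as.integer(t))
  }
  NA_integer_
}

oracle_ngd <- function(tmean426, t_th, ngd_c, t0 = 1) {
  cnt <- 0
  for (t in t0:NDY) {
    if (tmean426[PRE + t] > t_th) cnt <- cnt + 1
    if (cnt >= ngd_c) return(as.integer(t))
  }
  NA_integer_
}

oracle_soil <- function(x, window = 11) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    out[i] <- mean(x[max(1, i - window + 1):i])
  }
  out
}

oracle_day_length <- function(lat, doy) {
  decl_deg <- -23.44 * cos(2 * pi * (doy + 10) / 365)
  co <- -tan(lat * pi / 180) * tan(decl_deg * pi / 180)
  if (co <= -1) return(86400)
  if (co >= 1) return(0)
  2 * (acos(co) * 180 / pi) / 15 * 3600
}

oracle_bbgc_woody <- function(tmean426, lat, t_th, a, b,
                              gate_s = 39300, offset = 15, window = 11) {
  t_avg <- mean(tmean426[(PRE + 1):(PRE + NDY)])
  crit <- exp(a + b * t_avg)
  soil <- oracle_soil(tmean426, window)
  acc <- 0
  for (t in 1:NDY) {
    s <- soil[PRE + t]
    if (s > t_th) acc <- acc + (s - t_th)
    if (acc >= crit && oracle_day_length(lat, t) > gate_s) {
      return(as.integer(max(t - offset, 1)))
    }
  }
  NA_integer_
}

oracle_bbgc_grass <- function(tmean426, precip426, t_th, c_, d, k,
                              offset = 15, window = 11) {
  yr <- (PRE + 1):(PRE + NDY)
  t_avg <- mean(tmean426[yr])
  ann_p <- sum(precip426[yr])
  crit_t <- c_ * max(t_avg, 0) + d
  crit_p <- if (k > 0 && ann_p == 0) Inf else k * ann_p
  soil <- oracle_soil(tmean426, window)
  acc_t <- 0
  acc_p <- 0
  for (t in 1:NDY) {
    s <- soil[PRE + t]
    if (s > t_th) acc_t <- acc_t + (s - t_th)
    acc_p <- acc_p + precip426[PRE + t]
    if (acc_t >= crit_t && acc_p >= crit_p) return(as.integer(max(t - offset, 1)))
  }
  NA_integer_
}

oracle_ncd_gdd <- function(tmean426, t_th_chill, t_th_forc, g, h, w) {
  acc <- 0
  for (t in 1:NDY) {
    x <- tmean426[PRE + t] - t_th_forc
    if (x > 0) acc <- acc + x
    ncd <- sum(tmean426[1:(PRE + t)] < t_th_chill)
    if (acc >= g + h * exp(w * ncd)) return(as.integer(t))
  }
  NA_integer_
}
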