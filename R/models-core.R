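# Matrix representation of a collection of pixel-year met series, plus the
# vectorised day-scan cores of the four onset models. Each core returns an
# integer vector of onset DOY per pixel-year, NA where the model never
# triggers. The tidy user-facing wrappers live in models.R; an independent
# naive day-loop oracle (used only in tests) guards these implementations.

# Build the matrix form: 426 x n matrices of tmean and precip, one column
# per pixel-year, with per-column annual summaries taken over the Jan--Dec
# window of the target year.
met_matrix <- function(met, sites = NULL) {
  assert_met(met)
  met <- dplyr::arrange(met, .data$pixel_id, .data$year, .data$rel_day)
  keys <- dplyr::distinct(met, .data$pixel_id, .data$year)
  n <- nrow(keys)
  if (nrow(met) != n * SERIES_DAYS ||
      !all(met$rel_day == rep(seq_len(SERIES_DAYS), n))) {
    stop("each pixel-year must contain exactly the 426 consecutive days ",
         "Nov 1 (year-1) .. Dec 31 (year)", call. = FALSE)
  }
  tmean <- matrix(met$tmean, nrow = SERIES_DAYS)
  precip <- matrix(met$precip, nrow = SERIES_DAYS)
  if (any(precip < 0)) stop("precip must be >= 0", call. = FALSE)
  yr <- (PREFIX_DAYS + 1L):SERIES_DAYS
  latitude <- rep(NA_real_, n)
  if (!is.null(sites) && "latitude" %in% names(sites)) {
    latitude <- sites$latitude[match(keys$pixel_id, sites$pixel_id)]
  }
  list(keys = keys,
       n = n,
       tmean = tmean,
       precip = precip,
       latitude = latitude,
       t_avg = colMeans(tmean[yr, , drop = FALSE]),
       ann_prcp = colSums(precip[yr, , drop = FALSE]),
       cache = new.env(parent = emptyenv()))
}

mm_memo <- function(mm, key, value_fn) {
  if (is.null(mm$cache[[key]])) mm$cache[[key]] <- value_fn()
  mm$cache[[key]]
}

# Trailing running mean over the full 426-day series; the first window-1
# days average all available days.
soil_from_tmean <- function(tmean, window) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  cs <- col_cumsum(tmean)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = 1L)
  nr <- nrow(cs)
  idx <- seq_len(nr)
  lag <- rbind(matrix(0, nrow = min(window, nr), ncol = ncol(cs)),
               cs[seq_len(max(nr - window, 0L)), , drop = FALSE])
  denom <- pmin(idx, window)
  (cs - lag) / denom
}

mm_soil <- function(mm, window) {
  mm_memo(mm, paste0("soil_", window),
          function() soil_from_tmean(mm$tmean, window))
}

# 365 x n matrix of TRUE where astronomical day length exceeds gate_s.
mm_daylight_gate <- function(mm, gate_s) {
  if (anyNA(mm$latitude)) {
    stop("latitude required (supply sites) for the day-length gate",
         call. = FALSE)
  }
  mm_memo(mm, paste0("gate_", gate_s), function() {
    dl <- outer(seq_len(YEAR_DAYS), mm$latitude, day_length)
    dl > gate_s
  })
}

yr_rows <- function() (PREFIX_DAYS + 1L):SERIES_DAYS

# --- model cores -----------------------------------------------------------

core_gdd <- function(mm, t_th, gdd_c, t0 = 1L) {
  t0 <- as.integer(t0)
  stopifnot(t0 >= 1L, t0 <= YEAR_DAYS, gdd_c >= 0)
  cum <- mm_memo(mm, sprintf("gddcum_%.10g_%d", t_th, t0), function() {
    rows <- (PREFIX_DAYS + t0):SERIES_DAYS
    col_cumsum(pmax(mm$tmean[rows, , drop = FALSE] - t_th, 0))
  })
  if (is.null(dim(cum))) cum <- matrix(cum, ncol = 1L)
  t0 - 1L + first_at_least(cum, gdd_c)
}

core_ngd <- function(mm, t_th, ngd_c, t0 = 1L) {
  t0 <- as.integer(t0)
  ngd_c <- as.integer(round(ngd_c))
  stopifnot(t0 >= 1L, t0 <= YEAR_DAYS, ngd_c >= 1L)
  cnt <- mm_memo(mm, sprintf("ngdcnt_%.10g_%d", t_th, t0), function() {
    rows <- (PREFIX_DAYS + t0):SERIES_DAYS
    col_cumsum((mm$tmean[rows, , drop = FALSE] > t_th) * 1L)
  })
  if (is.null(dim(cnt))) cnt <- matrix(cnt, ncol = 1L)
  t0 - 1L + first_at_least(cnt, ngd_c)
}

# cumulative soil-temperature excess above t_th from Jan 1 (365 x n)
soil_excess_cum <- function(mm, t_th, window) {
  mm_memo(mm, sprintf("soilcum_%.10g_%d", t_th, window), function() {
    soil <- mm_soil(mm, window)[yr_rows(), , drop = FALSE]
    col_cumsum(pmax(soil - t_th, 0))
  })
}

core_bbgc_woody <- function(mm, t_th, a, b, gate_s = 39300, offset = 15L,
                            window = 11L) {
  cum <- soil_excess_cum(mm, t_th, window)
  crit <- exp(a + b * mm$t_avg)
  gate <- mm_daylight_gate(mm, gate_s)
  eligible <- (cum >= rep(crit, each = YEAR_DAYS)) & gate
  day <- first_true(eligible)
  pmax(day - as.integer(offset), 1L)
}

core_bbgc_grass <- function(mm, t_th, c, d, k, offset = 15L, window = 11L) {
  stopifnot(k >= 0, k <= 1, d >= 0)
  cum_t <- soil_excess_cum(mm, t_th, window)
  cum_p <- mm_memo(mm, "prcpcum", function() {
    col_cumsum(mm$precip[yr_rows(), , drop = FALSE])
  })
  crit_t <- c * pmax(mm$t_avg, 0) + d
  # a rainless pixel-year cannot satisfy a water requirement (k > 0):
  # 0 >= k*0 would otherwise hold vacuously
  crit_p <- ifelse(k > 0 & mm$ann_prcp == 0, Inf, k * mm$ann_prcp)
  eligible <- (cum_t >= rep(crit_t, each = YEAR_DAYS)) &
    (cum_p >= rep(crit_p, each = YEAR_DAYS))
  day <- first_true(eligible)
  pmax(day - as.integer(offset), 1L)
}

core_ncd_gdd <- function(mm, t_th_chill, t_th_forc, g, h, w) {
  stopifnot(w <= 0, h >= 0)
  ncd <- mm_memo(mm, sprintf("ncd_%.10g", t_th_chill), function() {
    col_cumsum((mm$tmean < t_th_chill) * 1L)[yr_rows(), , drop = FALSE]
  })
  gdd <- mm_memo(mm, sprintf("forccum_%.10g", t_th_forc), function() {
    col_cumsum(pmax(mm$tmean[yr_rows(), , drop = FALSE] - t_th_forc, 0))
  })
  expw <- mm_memo(mm, sprintf("expw_%.10g_%.10g", w, t_th_chill),
                  function() exp(w * ncd))
  crit <- g + h * expw
  first_true(gdd >= crit)
}
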