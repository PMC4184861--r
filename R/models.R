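# Tidy user-facing layer over the matrix cores: each predictor takes a met
# tibble (any number of pixel-years) and returns one BGS record per
# pixel-year. Thresholds are inclusive (>=) everywhere and ties resolve to
# the earliest qualifying day.

#' Astronomical day length
#'
#' Day length in seconds from solar declination and the sunrise hour angle:
#' declination `delta = -23.44 * cos(2*pi*(doy + 10)/365)` degrees,
#' `cos(omega) = -tan(latitude) * tan(delta)`, day length `2*omega/15` hours.
#' Polar day and polar night clamp to 86400 and 0 s.
#'
#' @param doy Day-of-year (1..365), vectorised.
#' @param latitude Latitude in degrees, `|latitude| <= 90`, vectorised.
#' @return Day length in seconds.
#' @export
#' @examples
#' day_length(172, 45) / 3600  # hours near the June solstice
day_length <- function(doy, latitude) {
  if (any(abs(latitude) > 90)) stop("|latitude| must be <= 90", call. = FALSE)
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  cos_omega <- -tan(latitude * pi / 180) * tan(decl)
  out <- ifelse(cos_omega <= -1, 86400,
                ifelse(cos_omega >= 1, 0,
                       2 * acos(pmin(pmax(cos_omega, -1), 1)) * 180 / pi / 15 * 3600))
  as.numeric(out)
}

#' Soil-temperature proxy: trailing running mean of air temperature
#'
#' Soil temperature is approximated by the trailing (causal) running mean of
#' daily mean air temperature over the preceding `window` days, inclusive of
#' the current day; the first `window - 1` days of a series average all days
#' available so far. Computed over the full 426-day series, so the Jan 1
#' value already has a full window from the Nov--Dec prefix.
#'
#' @param met Met tibble (see [generate_climate()]).
#' @param window Window length in days (default 11).
#' @return `met` with an added `tsoil` column.
#' @export
soil_temperature <- function(met, window = 11L) {
  assert_met(met)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  mm <- met_matrix(met)
  soil <- mm_soil(mm, window)
  out <- dplyr::arrange(met, .data$pixel_id, .data$year, .data$rel_day)
  out$tsoil <- as.vector(soil)
  out
}

#' Cumulative growing degree-days
#'
#' Accumulates `max(tmean - t_th, 0)` from day-of-year `t0` (default Jan 1)
#' through Dec 31 for every pixel-year; days before `t0` carry 0.
#'
#' @param met Met tibble.
#' @param t_th Degree-day base temperature (degC).
#' @param t0 Accumulation start day-of-year (default 1).
#' @return Tibble `pixel_id`, `year`, `doy` (1..365), `cum_gdd`
#'   (degree-days, non-decreasing from `t0`).
#' @export
#' @examples
#' sites <- generate_landscape(1, c(grassland = 1))
#' gdd_accumulate(generate_climate(sites, 2001), t_th = 5)
gdd_accumulate <- function(met, t_th, t0 = 1L) {
  assert_met(met)
  t0 <- as.integer(t0)
  stopifnot(t0 >= 1L, t0 <= YEAR_DAYS)
  mm <- met_matrix(met)
  cum <- matrix(0, nrow = YEAR_DAYS, ncol = mm$n)
  rows <- (PREFIX_DAYS + t0):SERIES_DAYS
  cum[t0:YEAR_DAYS, ] <- col_cumsum(pmax(mm$tmean[rows, , drop = FALSE] - t_th, 0))
  tibble::tibble(
    pixel_id = rep(mm$keys$pixel_id, each = YEAR_DAYS),
    year = rep(mm$keys$year, each = YEAR_DAYS),
    doy = rep(seq_len(YEAR_DAYS), mm$n),
    cum_gdd = as.vector(cum))
}

bgs_tibble <- function(mm, doy) {
  tibble::tibble(pixel_id = mm$keys$pixel_id,
                 year = mm$keys$year,
                 bgs_doy = as.integer(doy))
}

#' Growing degree-day (GDD) onset model
#'
#' Onset is the first day, counting from `t0`, on which the cumulative sum
#' of daily mean temperature excess above the base `t_th` reaches the
#' critical value `gdd_c`. Missing if the sum never reaches `gdd_c` by
#' Dec 31.
#'
#' @param met Met tibble.
#' @param t_th Degree-day base temperature (degC).
#' @param gdd_c Critical degree-day sum (degree-days, >= 0).
#' @param t0 Accumulation start day-of-year (default Jan 1).
#' @return BGS tibble: `pixel_id`, `year`, `bgs_doy` (integer DOY or `NA`).
#' @export
predict_gdd <- function(met, t_th, gdd_c, t0 = 1L) {
  assert_met(met)
  if (gdd_c < 0) stop("gdd_c must be >= 0", call. = FALSE)
  mm <- met_matrix(met)
  bgs_tibble(mm, core_gdd(mm, t_th, gdd_c, t0))
}

#' Number-of-growing-days (NGD) onset model
#'
#' Onset is the first day on which the count, from `t0`, of days with mean
#' temperature strictly above the base `t_th` reaches the critical count
#' `ngd_c`.
#'
#' @inheritParams predict_gdd
#' @param ngd_c Critical number of growing days (integer >= 1).
#' @return BGS tibble.
#' @export
predict_ngd <- function(met, t_th, ngd_c, t0 = 1L) {
  assert_met(met)
  if (ngd_c < 1) stop("ngd_c must be >= 1", call. = FALSE)
  mm <- met_matrix(met)
  bgs_tibble(mm, core_ngd(mm, t_th, ngd_c, t0))
}

#' Biome-BGC woody onset model
#'
#' From Jan 1, the excess of the soil-temperature proxy (11-day trailing
#' mean, [soil_temperature()]) above base `t_th` is accumulated on days when
#' the proxy exceeds the base. The crossing day is the first day on which
#' (i) the running sum reaches the critical value `exp(a + b * T_avg)`
#' (with `T_avg` the pixel-year's mean annual temperature) and (ii) day
#' length exceeds `gate_s` seconds. The reported onset is `offset` days
#' before the crossing day, floored at DOY 1.
#'
#' @param met Met tibble.
#' @param sites Sites tibble carrying `pixel_id` and `latitude`; or supply
#'   `latitude` directly.
#' @param t_th Base soil temperature (degC).
#' @param a,b Empirical coefficients of the critical-sum relation.
#' @param latitude Scalar latitude used for all pixels when `sites` is NULL.
#' @param gate_s Day-length gate (seconds, default 39300).
#' @param offset Onset offset before the crossing day (days, default 15).
#' @param window Soil-temperature window (days, default 11).
#' @return BGS tibble.
#' @export
predict_bbgc_woody <- function(met, sites = NULL, t_th, a, b,
                               latitude = NULL, gate_s = 39300,
                               offset = 15L, window = 11L) {
  assert_met(met)
  mm <- met_matrix(met, sites)
  if (!is.null(latitude)) mm$latitude <- rep(latitude, length.out = mm$n)
  bgs_tibble(mm, core_bbgc_woody(mm, t_th, a, b, gate_s, offset, window))
}

#' Biome-BGC grass onset model
#'
#' From Jan 1, both the soil-temperature excess above `t_th` and daily
#' precipitation are accumulated. The crossing day is the first day on which
#' the thermal sum reaches `c * max(T_avg, 0) + d` and the precipitation sum
#' reaches `k * AvgAnnPrcp` (the pixel-year's annual precipitation). Onset is
#' `offset` days before the crossing day, floored at DOY 1. A rainless
#' pixel-year never satisfies the precipitation criterion when `k > 0` (the
#' vacuous `0 >= k*0` is not treated as fulfilment).
#'
#' @inheritParams predict_bbgc_woody
#' @param c Thermal-criterion slope on mean annual temperature
#'   (degree-days per degC).
#' @param d Thermal-criterion intercept (degree-days, >= 0).
#' @param k Fraction of annual precipitation required (0..1).
#' @return BGS tibble.
#' @export
predict_bbgc_grass <- function(met, t_th, c, d, k, offset = 15L,
                               window = 11L) {
  assert_met(met)
  mm <- met_matrix(met)
  bgs_tibble(mm, core_bbgc_grass(mm, t_th, c, d, k, offset, window))
}

#' Chilling-forcing (NCD-GDD) onset model
#'
#' Two-phase model: chilling days are days since Nov 1 (of the preceding
#' year) with mean temperature below `t_th_chill`; forcing is the cumulative
#' degree-day sum above `t_th_forc` since Jan 1. Onset is the first day `t`
#' with `GDD(t) >= g + h * exp(w * NCD(t))` -- more accumulated chilling
#' lowers the forcing requirement (`w <= 0`).
#'
#' @param met Met tibble (must include the 61-day Nov--Dec prefix).
#' @param t_th_chill Chill-day base temperature (degC).
#' @param t_th_forc Degree-day base temperature (degC).
#' @param g,h,w Coefficients of the negative-exponential critical-forcing
#'   law (`h >= 0`, `w <= 0`).
#' @return BGS tibble.
#' @export
predict_ncd_gdd <- function(met, t_th_chill, t_th_forc, g, h, w) {
  assert_met(met)
  if (w > 0) stop("w must be <= 0", call. = FALSE)
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  mm <- met_matrix(met)
  bgs_tibble(mm, core_ncd_gdd(mm, t_th_chill, t_th_forc, g, h, w))
}

#' Predict onset with any model family
#'
#' Dispatch wrapper over the four predictors. With `params = NULL` the
#' per-biome defaults of [default_biome_params()] are used, dispatching on
#' each site's biome; `model = "bbgc"` selects the woody or grass variant
#' from the biome's phenology scheme ([biome_scheme()]).
#'
#' @param met Met tibble.
#' @param model `"gdd"`, `"ngd"`, `"bbgc"`, `"bbgc_woody"`, `"bbgc_grass"`
#'   or `"ncd_gdd"`.
#' @param params Named parameter list for the chosen family (see the
#'   `predict_*` functions), or `NULL` for per-biome defaults.
#' @param sites Sites tibble; required for latitude (woody day-length gate)
#'   and for per-biome dispatch.
#' @return BGS tibble with one row per pixel-year.
#' @export
#' @examples
#' sites <- generate_landscape(2, c(grassland = 1))
#' met <- generate_climate(sites, 2001:2002)
#' predict_bgs(met, "gdd", list(t_th = 5, gdd_c = 100))
predict_bgs <- function(met, model = c("gdd", "ngd", "bbgc", "bbgc_woody",
                                       "bbgc_grass", "ncd_gdd"),
                        params = NULL, sites = NULL) {
  model <- match.arg(model)
  assert_met(met)
  if (is.null(params)) {
    if (is.null(sites) || !"biome" %in% names(sites)) {
      stop("params = NULL requires sites with a biome column", call. = FALSE)
    }
    biome_of <- sites$biome[match(unique(met$pixel_id), sites$pixel_id)]
    parts <- split(unique(met$pixel_id), biome_of)
    out <- purrr::map_dfr(names(parts), function(bio) {
      fam <- if (model == "bbgc") "bbgc" else model
      p <- biome_params(bio, fam)
      sub <- met[met$pixel_id %in% parts[[bio]], , drop = FALSE]
      sub_model <- if (model == "bbgc") {
        if (biome_scheme(bio) == "grass") "bbgc_grass" else "bbgc_woody"
      } else {
        model
      }
      predict_bgs(sub, sub_model, p, sites = sites)
    })
    return(dplyr::arrange(out, .data$pixel_id, .data$year))
  }
  if (model == "bbgc") {
    if (is.null(sites) || !"biome" %in% names(sites)) {
      stop('model = "bbgc" requires sites with a biome column to choose ',
           "the woody or grass scheme (or call a variant directly)",
           call. = FALSE)
    }
    scheme_of <- biome_scheme(sites$biome[match(unique(met$pixel_id),
                                                sites$pixel_id)])
    parts <- split(unique(met$pixel_id), scheme_of)
    out <- purrr::map_dfr(names(parts), function(sch) {
      sub <- met[met$pixel_id %in% parts[[sch]], , drop = FALSE]
      predict_bgs(sub, paste0("bbgc_", sch), params, sites = sites)
    })
    return(dplyr::arrange(out, .data$pixel_id, .data$year))
  }
  needed <- switch(model,
    gdd = c("t_th", "gdd_c"),
    ngd = c("t_th", "ngd_c"),
    bbgc_woody = c("t_th", "a", "b"),
    bbgc_grass = c("t_th", "c", "d", "k"),
    ncd_gdd = c("t_th_chill", "t_th_forc", "g", "h", "w"))
  missing_p <- setdiff(needed, names(params))
  if (length(missing_p)) {
    stop("params for model '", model, "' lacks: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  switch(model,
    gdd = predict_gdd(met, params$t_th, params$gdd_c,
                      t0 = params$t0 %||% 1L),
    ngd = predict_ngd(met, params$t_th, params$ngd_c,
                      t0 = params$t0 %||% 1L),
    bbgc_woody = predict_bbgc_woody(met, sites, params$t_th, params$a,
                                    params$b,
                                    latitude = params$latitude %||% NULL,
                                    gate_s = params$gate_s %||% 39300,
                                    offset = params$offset %||% 15L,
                                    window = params$window %||% 11L),
    bbgc_grass = predict_bbgc_grass(met, params$t_th, params$c, params$d,
                                    params$k,
                                    offset = params$offset %||% 15L,
                                    window = params$window %||% 11L),
    ncd_gdd = predict_ncd_gdd(met, params$t_th_chill, params$t_th_forc,
                              params$g, params$h, params$w))
}
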