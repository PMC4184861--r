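# Synthetic landscape / daily climate / onset-observation generators.
#
# These emulate the real inputs of hemispheric onset modelling -- gridded
# reanalysis daily temperature and precipitation, and satellite-derived
# onset dates -- so that every downstream stage (classification, model
# prediction, calibration, evaluation) can be exercised without downloads.
# Daily temperature is a latitude/site-specific sinusoid plus iid Gaussian
# noise; precipitation is gamma-distributed daily amounts modulated by a
# raised-cosine seasonal weight; onset observations are produced by a chosen
# model plus integer-rounded Gaussian error (satellite onsets are reported
# in whole days).

#' Climate generator configuration
#'
#' Validated set of per-site climate parameters used by [generate_climate()].
#'
#' @param mean_annual_temp Mean annual temperature (degC).
#' @param seasonal_amplitude Half peak-to-trough seasonal amplitude (degC),
#'   non-negative.
#' @param temp_noise_sd Standard deviation of iid daily temperature noise
#'   (degC), non-negative.
#' @param peak_doy Day-of-year of the warmest day (default 200, mid-July).
#' @param annual_precip Expected annual precipitation sum (mm), non-negative.
#' @param wet_season_center_doy Day-of-year around which precipitation is
#'   concentrated.
#' @param precip_concentration Non-negative exponent of the raised-cosine
#'   seasonal weight; 0 gives a uniform season, larger values a sharper wet
#'   season.
#' @param seed Integer seed for the site's climate stream.
#' @return A named list of class `climate_config`.
#' @export
#' @examples
#' climate_config(mean_annual_temp = 5, seasonal_amplitude = 15)
climate_config <- function(mean_annual_temp,
                           seasonal_amplitude = 12,
                           temp_noise_sd = 1,
                           peak_doy = 200,
                           annual_precip = 500,
                           wet_season_center_doy = 180,
                           precip_concentration = 2,
                           seed = 1L) {
  if (!is.finite(seasonal_amplitude) || seasonal_amplitude < 0) {
    stop("invalid climate config: seasonal_amplitude must be >= 0",
         call. = FALSE)
  }
  if (!is.finite(temp_noise_sd) || temp_noise_sd < 0) {
    stop("invalid climate config: temp_noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.finite(annual_precip) || annual_precip < 0) {
    stop("invalid climate config: annual_precip must be >= 0", call. = FALSE)
  }
  if (!is.finite(precip_concentration) || precip_concentration < 0) {
    stop("invalid climate config: precip_concentration must be >= 0",
         call. = FALSE)
  }
  structure(list(mean_annual_temp = mean_annual_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 temp_noise_sd = temp_noise_sd,
                 peak_doy = peak_doy,
                 annual_precip = annual_precip,
                 wet_season_center_doy = wet_season_center_doy,
                 precip_concentration = precip_concentration,
                 seed = as.integer(seed)),
            class = "climate_config")
}

config_cols <- c("mean_annual_temp", "seasonal_amplitude", "temp_noise_sd",
                 "peak_doy", "annual_precip", "wet_season_center_doy",
                 "precip_concentration", "seed")

#' Generate a landscape of pixel sites
#'
#' Creates `n_pixels` sites whose biome labels follow `biome_mix`
#' (largest-remainder rounding, interleaved so every biome spans the climate
#' gradients) and whose climate configurations span the requested gradients.
#' The first gradient field is laid out in site order; further gradient
#' fields are evenly spaced but deterministically permuted so gradients are
#' not collinear across fields.
#'
#' @param n_pixels Number of sites (>= 1).
#' @param biome_mix Named numeric vector of biome proportions summing to 1.
#'   Names are biome classes ([biome_classes()]) or one of the four
#'   subdividable base types (`"mixed forest"`, `"closed shrub"`,
#'   `"open shrub"`, `"woody savanna"`) to be resolved later by
#'   [classify_sites()].
#' @param gradients Named list of climate-config fields to vary across sites;
#'   each element a length-2 range `c(lo, hi)` (linearly spanned) or a scalar
#'   (constant). Defaults to a mean-annual-temperature gradient of -2..10
#'   degC.
#' @param base_config A [climate_config()] supplying the non-varying fields.
#' @param latitude Site latitude(s), degrees north in \[0, 90\]: a scalar or a
#'   range `c(lo, hi)` spanned across sites.
#' @param seed Integer seed controlling the permutations and per-site climate
#'   seeds.
#' @return A sites tibble: `pixel_id`, `latitude`, `biome`, plus one column
#'   per climate-config field.
#' @export
#' @examples
#' generate_landscape(6, c(grassland = 0.5, savanna = 0.5),
#'                    gradients = list(mean_annual_temp = c(0, 10)))
generate_landscape <- function(n_pixels,
                               biome_mix = c(grassland = 1),
                               gradients = list(mean_annual_temp = c(-2, 10)),
                               base_config = climate_config(mean_annual_temp = 5),
                               latitude = 45,
                               seed = 1L) {
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 1L) stop("n_pixels must be >= 1", call. = FALSE)
  if (length(biome_mix) == 0L) stop("biome_mix must be non-empty", call. = FALSE)
  if (abs(sum(biome_mix) - 1) > 1e-8) {
    stop("biome_mix proportions must sum to 1", call. = FALSE)
  }
  if (any(latitude < 0 | latitude > 90)) {
    stop("latitude must lie in [0, 90]", call. = FALSE)
  }
  stopifnot(inherits(base_config, "climate_config"))

  # largest-remainder apportionment of pixels to biomes
  raw <- biome_mix * n_pixels
  counts <- floor(raw)
  rem <- n_pixels - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  # interleave biomes along the site order so each spans the gradients
  assign_tbl <- tibble::tibble(
    biome = rep(names(biome_mix), counts),
    pos = unlist(purrr::map(counts, function(k) {
      if (k == 0) numeric(0) else (seq_len(k) - 0.5) / k
    }), use.names = FALSE))
  biome_seq <- assign_tbl$biome[order(assign_tbl$pos, assign_tbl$biome)]

  span <- function(x, n) {
    if (length(x) == 1L) rep(x, n) else seq(x[1], x[2], length.out = n)
  }
  cfg <- tibble::as_tibble(unclass(base_config)[config_cols])
  cfg <- cfg[rep(1L, n_pixels), ]
  first <- TRUE
  for (field in names(gradients)) {
    if (!field %in% config_cols) {
      stop("unknown climate-config field in gradients: ", field, call. = FALSE)
    }
    vals <- span(gradients[[field]], n_pixels)
    if (!first && length(gradients[[field]]) > 1L) {
      vals <- with_seed(derive_seed(seed, match(field, config_cols)),
                        sample(vals))
    }
    cfg[[field]] <- vals
    first <- FALSE
  }
  cfg$seed <- vapply(seq_len(n_pixels), function(i) derive_seed(seed, i),
                     integer(1))

  tibble::tibble(
    pixel_id = sprintf("px%04d", seq_len(n_pixels)),
    latitude = span(latitude, n_pixels),
    biome = biome_seq) |>
    dplyr::bind_cols(cfg)
}

# One calendar year (365 days) of deterministic sinusoid + noise for a site
# config row; separate RNG streams for temperature and precipitation so the
# two are reproducible independently.
year_block <- function(cfg, year) {
  doy <- seq_len(YEAR_DAYS)
  det <- cfg$mean_annual_temp - cfg$seasonal_amplitude *
    cos(2 * pi * (doy - cfg$peak_doy + 182.5) / 365)
  eps <- if (cfg$temp_noise_sd > 0) {
    with_seed(derive_seed(cfg$seed, year, 1), stats::rnorm(YEAR_DAYS, 0, cfg$temp_noise_sd))
  } else {
    numeric(YEAR_DAYS)
  }
  u <- (1 + cos(2 * pi * (doy - cfg$wet_season_center_doy) / 365)) / 2
  s <- u^cfg$precip_concentration
  mu <- if (sum(s) > 0) cfg$annual_precip * s / sum(s) else rep(0, YEAR_DAYS)
  shape <- 0.8  # daily gamma shape; mean mu_d preserved via scale = mu_d/shape
  precip <- numeric(YEAR_DAYS)
  pos <- mu > 0
  if (any(pos)) {
    precip[pos] <- with_seed(derive_seed(cfg$seed, year, 2),
                             stats::rgamma(sum(pos), shape = shape,
                                           scale = mu[pos] / shape))
  }
  list(tmean = det + eps, precip = precip)
}

#' Generate daily climate series for sites
#'
#' Produces, for every site and target year, the canonical pixel-year met
#' series: 426 consecutive days from Nov 1 of the preceding year through
#' Dec 31 of the target year on the 365-day no-leap calendar. Daily mean
#' temperature is `mean_annual_temp - seasonal_amplitude *
#' cos(2*pi*(doy - peak_doy + 182.5)/365)` plus iid Normal(0, temp_noise_sd^2)
#' noise; daily precipitation is gamma-distributed with a raised-cosine
#' seasonal mean whose annual sum equals `annual_precip` in expectation.
#' Output is bitwise reproducible given the site seeds, and the Nov--Dec
#' prefix of year y+1 coincides with the Nov--Dec of year y.
#'
#' @param sites Sites tibble from [generate_landscape()] (or any tibble with
#'   `pixel_id`, `latitude` and the climate-config columns).
#' @param years Integer vector of target calendar years.
#' @return A met tibble: `pixel_id`, `year` (target year), `rel_day`
#'   (1..426), `doy` (day-of-year of the calendar day: 305..365 for the
#'   prefix, 1..365 for the target year), `date`, `tmean` (degC), `precip`
#'   (mm).
#' @export
#' @examples
#' sites <- generate_landscape(2, c(grassland = 1))
#' met <- generate_climate(sites, 2001)
generate_climate <- function(sites, years) {
  years <- as.integer(years)
  stopifnot(all(c("pixel_id", config_cols) %in% names(sites)))
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    cfg <- climate_config(
      mean_annual_temp = sites$mean_annual_temp[i],
      seasonal_amplitude = sites$seasonal_amplitude[i],
      temp_noise_sd = sites$temp_noise_sd[i],
      peak_doy = sites$peak_doy[i],
      annual_precip = sites$annual_precip[i],
      wet_season_center_doy = sites$wet_season_center_doy[i],
      precip_concentration = sites$precip_concentration[i],
      seed = sites$seed[i])
    cal_years <- sort(unique(c(years - 1L, years)))
    blocks <- purrr::map(cal_years, function(y) year_block(cfg, y))
    names(blocks) <- as.character(cal_years)
    purrr::map_dfr(years, function(y) {
      prev <- blocks[[as.character(y - 1L)]]
      cur <- blocks[[as.character(y)]]
      pre_idx <- (YEAR_DAYS - PREFIX_DAYS + 1L):YEAR_DAYS  # doy 305..365
      doy <- c(pre_idx, seq_len(YEAR_DAYS))
      cal_year <- c(rep(y - 1L, PREFIX_DAYS), rep(y, YEAR_DAYS))
      tibble::tibble(
        pixel_id = sites$pixel_id[i],
        year = y,
        rel_day = seq_len(SERIES_DAYS),
        doy = as.integer(doy),
        date = noleap_to_date(cal_year, doy),
        tmean = c(prev$tmean[pre_idx], cur$tmean),
        precip = c(prev$precip[pre_idx], cur$precip))
    })
  })
}

#' Generate onset observations from a model plus observation noise
#'
#' Runs the chosen phenology model on every pixel-year of `met` and adds
#' integer-rounded Gaussian observation error, clamped to \[1, 365\],
#' emulating satellite-derived onset dates (reported in whole days).
#' Pixel-years where the model never triggers are emitted with missing
#' `bgs_doy`.
#'
#' @param met Met tibble from [generate_climate()].
#' @param sites Sites tibble (needed for latitude / per-biome dispatch).
#' @param model One of `"gdd"`, `"ngd"`, `"bbgc"`, `"bbgc_woody"`,
#'   `"bbgc_grass"`, `"ncd_gdd"`.
#' @param params Named parameter list for the model, or `NULL` to use the
#'   per-biome defaults of [default_biome_params()].
#' @param obs_noise_sd Observation noise standard deviation in days
#'   (default 3; satellite onset validation studies report day-scale to
#'   two-week differences against ground observations).
#' @param seed Integer seed for the observation noise.
#' @return Observations tibble: `pixel_id`, `year`, `bgs_doy` (integer or
#'   `NA` for no onset).
#' @export
generate_bgs_observations <- function(met, sites, model, params = NULL,
                                      obs_noise_sd = 3, seed = 1L) {
  if (obs_noise_sd < 0) stop("obs_noise_sd must be >= 0", call. = FALSE)
  pred <- predict_bgs(met, model = model, params = params, sites = sites)
  out <- dplyr::arrange(pred, .data$pixel_id, .data$year)
  ok <- !is.na(out$bgs_doy)
  if (obs_noise_sd > 0 && any(ok)) {
    noise <- with_seed(derive_seed(seed, 7L),
                       round(stats::rnorm(sum(ok), 0, obs_noise_sd)))
    out$bgs_doy[ok] <- pmin(pmax(out$bgs_doy[ok] + as.integer(noise), 1L), 365L)
  }
  out
}
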