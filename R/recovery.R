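# Parameter-recovery simulation experiments: generate noise-free onset
# observations from a reference parameter set over a synthetic climate
# gradient, calibrate the same model family from scratch, and compare the
# recovered parameters with the generating truth. These are the package's
# primary self-validation: with zero observation noise the generating
# parameters attain SSE 0, so a sound optimiser must return a parameter set
# predicting identically to the truth.

recovery_designs <- function() {
  list(
    gdd = list(
      biome = "evergreen needleleaf forest",
      n_pixels = 200L, years = 2001:2010,
      gradients = list(mean_annual_temp = c(-2, 10)),
      base = list(seasonal_amplitude = 12, temp_noise_sd = 1),
      latitude = 45),
    ngd = list(
      biome = "deciduous broadleaf forest",
      n_pixels = 200L, years = 2001:2010,
      gradients = list(mean_annual_temp = c(-2, 10)),
      base = list(seasonal_amplitude = 12, temp_noise_sd = 1),
      latitude = 45),
    bbgc_woody = list(
      biome = "deciduous broadleaf forest",
      n_pixels = 300L, years = 2001:2010,
      gradients = list(mean_annual_temp = c(0, 18)),
      base = list(seasonal_amplitude = 12, temp_noise_sd = 0.5),
      latitude = 45),
    # winter severity spans no-chill to deep-chill sites so the
    # negative-exponential chilling response is sampled over its whole range
    ncd_gdd = list(
      biome = "deciduous broadleaf forest",
      n_pixels = 300L, years = 2001:2010,
      gradients = list(mean_annual_temp = c(0, 16)),
      base = list(seasonal_amplitude = 8, temp_noise_sd = 1),
      latitude = 45),
    # warm springs with late, variable wet seasons: the precipitation
    # criterion binds for a large share of pixel-years
    bbgc_grass = list(
      biome = "grassland",
      n_pixels = 300L, years = 2001:2010,
      gradients = list(mean_annual_temp = c(8, 16),
                       wet_season_center_doy = c(60, 300),
                       annual_precip = c(300, 700)),
      base = list(seasonal_amplitude = 10, temp_noise_sd = 1,
                  precip_concentration = 4),
      latitude = 45))
}

recovery_free <- function(model, truth) {
  switch(model,
    gdd = list(free = NULL, fixed = list()),
    ngd = list(free = NULL, fixed = list()),
    bbgc_woody = list(free = NULL, fixed = list()),
    # chill and forcing bases fixed at truth; (g, h, w) free
    ncd_gdd = list(free = NULL,
                   fixed = list(t_th_chill = truth$t_th_chill,
                                t_th_forc = truth$t_th_forc)),
    # soil-temperature base fixed at truth; (c, d, k) free
    bbgc_grass = list(free = NULL, fixed = list(t_th = truth$t_th)))
}

#' Parameter-recovery experiment for one model family
#'
#' Generates a synthetic landscape spanning the climate gradient the family
#' needs for identifiability, produces noise-free onset observations with
#' the reference ("truth") parameters of the design's biome, calibrates the
#' family on all pixel-years, and returns the fit together with the truth.
#'
#' Designs per family: GDD and NGD use 200 pixels x 10 years with site mean
#' annual temperatures spanning -2..10 degC (seasonal amplitude 12 degC,
#' daily noise sd 1 degC); the woody Biome-BGC variant uses 300 pixels over
#' 0..18 degC (noise sd 0.5) at latitude 45 so the critical-sum dependence
#' on mean temperature is identifiable; the chilling-forcing family uses 300
#' pixels over 0..16 degC at amplitude 8 so accumulated chilling spans
#' no-chill to deep-chill; the grass variant uses warm springs with
#' late-arriving wet seasons of varying onset so the precipitation criterion
#' binds for many pixel-years. For the chilling-forcing and grass families
#' the base temperatures are held at truth, matching their design.
#'
#' @param model One of `"gdd"`, `"ngd"`, `"bbgc_woody"`, `"ncd_gdd"`,
#'   `"bbgc_grass"`.
#' @param seed Integer seed for the synthetic climate.
#' @param n_pixels,years Override the design's problem size (used to scale
#'   the experiment down in examples and quick checks).
#' @param obs_noise_sd Observation noise in days (default 0: noise-free
#'   recovery).
#' @param max_sweeps Passed to [calibrate_model()].
#' @return List with `fit` (a `pheno_fit`), `truth` (named list), `model`,
#'   `n_records`, and `recovered` (named numeric vector of the free
#'   parameters).
#' @export
#' @examples
#' \donttest{
#' rec <- recovery_experiment("gdd", seed = 1, n_pixels = 20, years = 2001:2002)
#' rec$recovered
#' }
recovery_experiment <- function(model, seed = 1L, n_pixels = NULL,
                                years = NULL, obs_noise_sd = 0,
                                max_sweeps = 200L) {
  model <- match.arg(model, model_families)
  design <- recovery_designs()[[model]]
  n_pixels <- n_pixels %||% design$n_pixels
  years <- years %||% design$years
  truth <- biome_params(design$biome,
                        if (model %in% c("bbgc_woody", "bbgc_grass")) "bbgc"
                        else model)
  base_cfg <- do.call(climate_config,
                      c(list(mean_annual_temp = 5), design$base))
  sites <- generate_landscape(n_pixels, stats::setNames(1, design$biome),
                              gradients = design$gradients,
                              base_config = base_cfg,
                              latitude = design$latitude, seed = seed)
  met <- generate_climate(sites, years)
  obs <- generate_bgs_observations(met, sites, model = model, params = truth,
                                   obs_noise_sd = obs_noise_sd,
                                   seed = derive_seed(seed, 3L))
  search <- recovery_free(model, truth)
  fit <- calibrate_model(obs, met, model, free = search$free,
                         fixed = search$fixed, sites = sites,
                         max_sweeps = max_sweeps)
  recovered <- unlist(fit$params[fit$free])
  list(model = model, fit = fit, truth = truth,
       recovered = recovered, n_records = fit$n_train,
       sites = sites, met = met, obs = obs)
}
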