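# Reference parameter sets per biome class and helpers to extract the
# parameter list a given model family expects.

#' Biome classes recognised by the package
#'
#' The 14 calibrated vegetation classes: the IGBP natural classes retained
#' for Northern Hemisphere onset modelling, with the four wide-latitude types
#' (mixed forest, closed shrub, open shrub, woody savanna) split into cool
#' and warm classes by the climate criteria of [subdivide_biome()].
#'
#' @return Character vector of the 14 class names.
#' @seealso [biome_scheme()], [default_biome_params()]
#' @export
biome_classes <- function() {
  c("evergreen needleleaf forest", "deciduous needleleaf forest",
    "deciduous broadleaf forest", "cool mixed forest", "warm mixed forest",
    "cool closed shrub", "warm closed shrub", "cool open shrub",
    "warm open shrub", "cool woody savanna", "warm woody savanna",
    "savanna", "grassland", "permanent wetland")
}

#' Phenology scheme (woody vs grass) of a biome class
#'
#' Selects the Biome-BGC onset variant: grassland, savanna and the woody
#' savanna classes follow the grass scheme (temperature plus precipitation
#' criterion); forests, shrubs and permanent wetland follow the woody scheme
#' (temperature criterion with a day-length gate).
#'
#' @param biome Character vector of biome class names (see [biome_classes()]).
#' @return Character vector, `"woody"` or `"grass"` per element.
#' @export
#' @examples
#' biome_scheme(c("grassland", "deciduous broadleaf forest"))
biome_scheme <- function(biome) {
  tab <- default_biome_params()
  bad <- setdiff(unique(biome), tab$biome)
  if (length(bad)) {
    stop("unknown biome class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tab$scheme[match(biome, tab$biome)]
}

#' Reference calibrated parameter values per biome class
#'
#' Published satellite-calibrated parameter values for all four model
#' families across the 14 Northern Hemisphere biome classes. These serve as
#' package defaults for prediction and as generating truths in parameter
#' recovery experiments. Grass-scheme rows populate `c`, `d`, `k`;
#' woody-scheme rows populate `a`, `b`.
#'
#' @return A tibble with one row per biome class and columns
#'   `biome`, `scheme`, `t_th_gdd`, `gdd_c`, `t_th_bbgc`, `a`, `b`, `c`, `d`,
#'   `k`, `t_th_ngd`, `ngd_c`, `t_th_ncd`, `t_th_ncdgdd`, `g`, `h`, `w`.
#' @export
#' @examples
#' default_biome_params()
default_biome_params <- function() {
  path <- system.file("extdata", "biome_params.csv", package = "phenospring",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    biome = readr::col_character(),
                    scheme = readr::col_character(),
                    .default = readr::col_double()))
}

#' Legacy dynamic-vegetation-model GDD defaults
#'
#' The uncalibrated growing degree-day parameters used by the IBIS dynamic
#' vegetation model: base temperature 0 degC and critical sum 100 degree-days
#' for winter-deciduous forest; 5 degC and 150 degree-days for grassland and
#' shrub. Useful as the baseline in calibrated-vs-default comparisons.
#'
#' @param vegetation `"winter_deciduous_forest"` or `"grassland_shrub"`.
#' @return Named list with `t_th` (degC) and `gdd_c` (degree-days).
#' @export
#' @examples
#' ibis_default_gdd_params("grassland_shrub")
ibis_default_gdd_params <- function(vegetation = c("winter_deciduous_forest",
                                                   "grassland_shrub")) {
  vegetation <- match.arg(vegetation)
  switch(vegetation,
         winter_deciduous_forest = list(t_th = 0, gdd_c = 100),
         grassland_shrub = list(t_th = 5, gdd_c = 150))
}

#' Extract one model family's parameter list for a biome
#'
#' @param biome A single biome class name.
#' @param model One of `"gdd"`, `"ngd"`, `"bbgc"`, `"ncd_gdd"`. For `"bbgc"`
#'   the woody or grass parameter set is chosen by the biome's scheme.
#' @param params Parameter table, defaults to [default_biome_params()].
#' @return Named list of parameters as expected by the matching
#'   `predict_*()` function.
#' @export
#' @examples
#' biome_params("grassland", "bbgc")
biome_params <- function(biome, model = c("gdd", "ngd", "bbgc", "ncd_gdd"),
                         params = default_biome_params()) {
  model <- match.arg(model)
  row <- params[params$biome == biome, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown biome class: ", biome, call. = FALSE)
  }
  switch(model,
    gdd = list(t_th = row$t_th_gdd, gdd_c = row$gdd_c),
    ngd = list(t_th = row$t_th_ngd, ngd_c = as.integer(row$ngd_c)),
    bbgc = if (identical(row$scheme, "grass")) {
      list(t_th = row$t_th_bbgc, c = row$c, d = row$d, k = row$k)
    } else {
      list(t_th = row$t_th_bbgc, a = row$a, b = row$b)
    },
    ncd_gdd = list(t_th_chill = row$t_th_ncd, t_th_forc = row$t_th_ncdgdd,
                   g = row$g, h = row$h, w = row$w))
}
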