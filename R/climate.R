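# Annual climate statistics and the cool/warm subdivision of the four
# wide-latitude vegetation types.

#' Annual climate statistics per pixel
#'
#' Computes, over the Jan 1 -- Dec 31 window of each pixel-year, the annual
#' mean (`t_mean`), minimum (`t_c`) and maximum (`t_w`) of daily mean
#' temperature and the annual range `delta_t = t_w - t_c`, then averages each
#' statistic across the supplied years.
#'
#' @param met Met tibble covering at least one full pixel-year.
#' @return Tibble with one row per pixel: `pixel_id`, `t_mean`, `t_c`,
#'   `t_w`, `delta_t` (degC), `n_years`.
#' @export
#' @examples
#' sites <- generate_landscape(2, c(`mixed forest` = 1))
#' compute_climate_stats(generate_climate(sites, 2001:2002))
compute_climate_stats <- function(met) {
  assert_met(met)
  counts <- dplyr::count(met, .data$pixel_id, .data$year)
  if (any(counts$n != SERIES_DAYS)) {
    stop("incomplete year: every pixel-year needs its full 426-day series",
         call. = FALSE)
  }
  met |>
    dplyr::filter(.data$rel_day > PREFIX_DAYS) |>
    dplyr::group_by(.data$pixel_id, .data$year) |>
    dplyr::summarise(t_mean = mean(.data$tmean),
                     t_c = min(.data$tmean),
                     t_w = max(.data$tmean),
                     .groups = "drop") |>
    dplyr::group_by(.data$pixel_id) |>
    dplyr::summarise(t_mean = mean(.data$t_mean),
                     t_c = mean(.data$t_c),
                     t_w = mean(.data$t_w),
                     n_years = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(delta_t = .data$t_w - .data$t_c) |>
    dplyr::select("pixel_id", "t_mean", "t_c", "t_w", "delta_t", "n_years")
}

subdividable_types <- c("mixed forest", "closed shrub", "open shrub",
                        "woody savanna")

#' Subdivide a wide-latitude vegetation type into its cool or warm class
#'
#' Applies the climate criteria splitting the four vegetation types that
#' span a wide latitude range: mixed forest, closed shrub and woody savanna
#' are cool iff `t_c < 0` degC; open shrub is cool iff `delta_t > 20` degC
#' or `t_c < 5` degC. Boundary values resolve to the warm class (the cool
#' criteria are strict inequalities).
#'
#' @param base_type Character vector of base types (`"mixed forest"`,
#'   `"closed shrub"`, `"open shrub"`, `"woody savanna"`).
#' @param t_c Annual minimum daily temperature (degC), vectorised.
#' @param delta_t Annual temperature range `t_w - t_c` (degC), vectorised.
#' @return Character vector of resolved biome classes.
#' @export
#' @examples
#' subdivide_biome("mixed forest", t_c = -3, delta_t = 35)
#' subdivide_biome("open shrub", t_c = 7, delta_t = 18)
subdivide_biome <- function(base_type, t_c, delta_t = NULL) {
  bad <- setdiff(unique(base_type), subdividable_types)
  if (length(bad)) {
    stop("not a subdivided type: ", paste(bad, collapse = ", "),
         "; use the biome class unchanged", call. = FALSE)
  }
  if (any(base_type == "open shrub") && is.null(delta_t)) {
    stop("delta_t is required to subdivide open shrub", call. = FALSE)
  }
  n <- max(length(base_type), length(t_c), length(delta_t %||% 0))
  base_type <- rep_len(base_type, n)
  t_c <- rep_len(t_c, n)
  delta_t <- rep_len(delta_t %||% NA_real_, n)
  cool <- ifelse(base_type == "open shrub",
                 delta_t > 20 | t_c < 5,
                 t_c < 0)
  paste(ifelse(cool, "cool", "warm"), base_type)
}

#' Resolve subdividable biome labels on a sites table
#'
#' Computes climate statistics from `met` and replaces any of the four base
#' types in `sites$biome` by their cool/warm class; already-resolved classes
#' pass through unchanged. Adds the phenology scheme column.
#'
#' @param sites Sites tibble with `pixel_id` and `biome`.
#' @param met Met tibble covering the classification years.
#' @return `sites` with resolved `biome` and a `scheme` column
#'   (`"woody"`/`"grass"`).
#' @export
classify_sites <- function(sites, met) {
  stats <- compute_climate_stats(met)
  out <- dplyr::left_join(sites, stats, by = "pixel_id")
  todo <- out$biome %in% subdividable_types
  if (any(is.na(out$t_c[todo]))) {
    stop("met lacks series for some sites needing subdivision", call. = FALSE)
  }
  out$biome[todo] <- subdivide_biome(out$biome[todo], out$t_c[todo],
                                     out$delta_t[todo])
  out$scheme <- biome_scheme(out$biome)
  dplyr::select(out, -"t_mean", -"t_c", -"t_w", -"delta_t", -"n_years")
}
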