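# CSV readers/writers for the package's interchange formats. CSV is the
# canonical interchange; every writer can stamp a comment header (seed,
# config hash) which readers skip. Dates are ISO-8601 on disk and mapped to
# the 365-day no-leap calendar in memory.

write_header <- function(path, header) {
  if (length(header)) {
    writeLines(paste0("# ", header), path)
  }
}

append_csv <- function(df, path, header = character()) {
  write_header(path, header)
  readr::write_csv(df, path, append = length(header) > 0,
                   col_names = TRUE, na = "")
  invisible(path)
}

#' Write / read daily met series CSV
#'
#' On disk the series is one row per pixel and calendar day (`pixel_id`,
#' `date`, `tmean_c`, `precip_mm`): overlapping Nov--Dec windows of
#' consecutive pixel-years are stored once. `read_met_csv()` rebuilds the
#' canonical 426-day pixel-year records for every target year whose full
#' window (Nov 1 of the preceding year through Dec 31) is covered, and
#' errors on any gap in a pixel's daily series, naming the pixel and date.
#'
#' @param met Met tibble (see [generate_climate()]).
#' @param path File path.
#' @param header Optional character vector written as `#`-prefixed comment
#'   lines before the CSV header.
#' @return `write_met_csv()` the path, invisibly; `read_met_csv()` a met
#'   tibble.
#' @export
write_met_csv <- function(met, path, header = character()) {
  assert_met(met)
  cal_year <- ifelse(met$rel_day <= PREFIX_DAYS, met$year - 1L, met$year)
  df <- tibble::tibble(pixel_id = met$pixel_id,
                       date = noleap_to_date(cal_year, met$doy),
                       tmean_c = met$tmean, precip_mm = met$precip) |>
    dplyr::distinct(.data$pixel_id, .data$date, .keep_all = TRUE) |>
    dplyr::arrange(.data$pixel_id, .data$date)
  append_csv(df, path, header)
}

#' @rdname write_met_csv
#' @param years Target years to reconstruct; `NULL` means every year with a
#'   complete window.
#' @export
read_met_csv <- function(path, years = NULL) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("pixel_id", "date", "tmean_c", "precip_mm")
  if (!all(need %in% names(df))) {
    stop("met CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning("ignoring unknown met CSV column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  nl <- date_to_noleap(df$date)
  df$abs_day <- nl$year * 365 + nl$doy
  df$cal_year <- nl$year
  df$doy <- nl$doy
  df <- dplyr::arrange(df, .data$pixel_id, .data$abs_day)
  purrr::map_dfr(split(df, df$pixel_id), function(px) {
    gaps <- which(diff(px$abs_day) != 1)
    if (length(gaps)) {
      stop("gap in daily series for pixel ", px$pixel_id[1],
           " after ", px$date[gaps[1]], call. = FALSE)
    }
    cand <- intersect(unique(px$cal_year), years %||% unique(px$cal_year))
    purrr::map_dfr(sort(cand), function(y) {
      lo <- (y - 1) * 365 + 305
      hi <- y * 365 + 365
      idx <- match(lo:hi, px$abs_day)
      if (anyNA(idx)) return(NULL)  # incomplete window for this target year
      tibble::tibble(pixel_id = px$pixel_id[1], year = y,
                     rel_day = seq_len(SERIES_DAYS),
                     doy = px$doy[idx], date = px$date[idx],
                     tmean = px$tmean_c[idx], precip = px$precip_mm[idx])
    })
  })
}

#' Write / read onset-record CSV
#'
#' Columns `pixel_id`, `year`, `bgs_doy`; an empty `bgs_doy` field encodes
#' the missing (no-onset) state, bijectively. Reading rejects any day-of-year
#' outside 1..366 (366 is tolerated for sources on a leap calendar).
#'
#' @param bgs BGS tibble (`pixel_id`, `year`, `bgs_doy`).
#' @inheritParams write_met_csv
#' @return `write_bgs_csv()` the path, invisibly; `read_bgs_csv()` a BGS
#'   tibble.
#' @export
write_bgs_csv <- function(bgs, path, header = character()) {
  stopifnot(all(c("pixel_id", "year", "bgs_doy") %in% names(bgs)))
  append_csv(dplyr::select(bgs, "pixel_id", "year", "bgs_doy"), path, header)
}

#' @rdname write_bgs_csv
#' @export
read_bgs_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          pixel_id = readr::col_character(),
                          year = readr::col_integer(),
                          bgs_doy = readr::col_integer()))
  bad <- !is.na(df$bgs_doy) & (df$bgs_doy < 1L | df$bgs_doy > 366L)
  if (any(bad)) {
    stop("bgs_doy out of range [1, 366] at row ", which(bad)[1], call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write / read sites CSV
#'
#' @param sites Sites tibble.
#' @inheritParams write_met_csv
#' @return `write_sites_csv()` the path, invisibly; `read_sites_csv()` a
#'   sites tibble.
#' @export
write_sites_csv <- function(sites, path, header = character()) {
  append_csv(sites, path, header)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
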