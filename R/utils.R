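# Calendar, seeding and matrix helpers shared across modules.
#
# All date handling uses a fixed 365-day no-leap calendar: DOY is 1-based
# (Jan 1 = 1, Dec 31 = 365) and Feb 29 never occurs.  Every pixel-year met
# series carries the preceding Nov 1 -- Dec 31 (61 days) so chilling sums
# starting November 1 need no cross-record lookup.

PREFIX_DAYS <- 61L   # Nov 1 (year-1) .. Dec 31 (year-1)
YEAR_DAYS   <- 365L
SERIES_DAYS <- PREFIX_DAYS + YEAR_DAYS  # 426

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Convert (year, doy) on the no-leap calendar to a Gregorian Date, skipping
# Feb 29 in real leap years so day counts stay aligned.
noleap_to_date <- function(year, doy) {
  stopifnot(all(doy >= 1L & doy <= 365L))
  jan1 <- as.Date(paste0(year, "-01-01"))
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  # from Mar 1 onward (noleap doy >= 60) leap years need one extra real day
  jan1 + (doy - 1L) + ifelse(leap & doy >= 60L, 1L, 0L)
}

# Inverse of noleap_to_date(); Feb 29 inputs are rejected.
date_to_noleap <- function(date) {
  date <- as.Date(date)
  year <- as.integer(format(date, "%Y"))
  yd <- as.integer(format(date, "%j"))
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  if (any(leap & yd == 60L)) {
    stop("Feb 29 has no day-of-year on the 365-day no-leap calendar",
         call. = FALSE)
  }
  doy <- ifelse(leap & yd > 60L, yd - 1L, yd)
  list(year = year, doy = as.integer(doy))
}

# Deterministic combination of integer seed components into a valid seed
# below 2^31 (Lehmer-style mixing; order of components matters).
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  m <- 2147483647
  s <- 12345
  for (p in parts) {
    s <- (s * 48271 + (p %% m) + 1) %% m
  }
  as.integer(s)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Column-wise cumulative sums of a matrix.
col_cumsum <- function(m) {
  if (is.null(dim(m))) return(cumsum(m))
  apply(m, 2L, cumsum)
}

# Index of the first TRUE per column; NA_integer_ where a column has none.
first_true <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  idx <- max.col(t(unclass(m) * 1), ties.method = "first")
  idx[colSums(m) == 0L] <- NA_integer_
  as.integer(idx)
}

# First row index per column where the non-decreasing column meets/exceeds
# crit (scalar or per-column vector); NA where never reached.
first_at_least <- function(cum, crit) {
  if (is.null(dim(cum))) cum <- matrix(cum, ncol = 1L)
  if (length(crit) == 1L) {
    idx <- colSums(cum < crit) + 1L
  } else {
    stopifnot(length(crit) == ncol(cum))
    idx <- colSums(cum < rep(crit, each = nrow(cum))) + 1L
  }
  idx[idx > nrow(cum)] <- NA_integer_
  as.integer(idx)
}

assert_met <- function(met) {
  need <- c("pixel_id", "year", "rel_day", "doy", "tmean", "precip")
  missing_cols <- setdiff(need, names(met))
  if (length(missing_cols)) {
    stop("met is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(met)
}
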