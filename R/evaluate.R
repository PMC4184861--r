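# Comparison metrics between observed and predicted onset: R^2, RMSE, mean
# absolute error (R_A), Pearson correlation of interannual biome-mean
# series, and cumulative frequencies of absolute differences.

#' Pair observed and predicted onset records
#'
#' Inner join on `(pixel_id, year)`; pairs where either side is missing are
#' dropped and the number of drops is attached as the `n_dropped` attribute.
#'
#' @param observed,predicted BGS tibbles (`pixel_id`, `year`, `bgs_doy`).
#' @return Tibble `pixel_id`, `year`, `observed`, `predicted` with at least
#'   one row; errors if the join is empty.
#' @export
pair_bgs <- function(observed, predicted) {
  j <- dplyr::inner_join(observed, predicted, by = c("pixel_id", "year"),
                         suffix = c("_obs", "_pred"))
  if (nrow(j) == 0L) {
    stop("no common (pixel_id, year) keys between observations and ",
         "predictions", call. = FALSE)
  }
  keep <- !is.na(j$bgs_doy_obs) & !is.na(j$bgs_doy_pred)
  out <- tibble::tibble(pixel_id = j$pixel_id[keep], year = j$year[keep],
                        observed = j$bgs_doy_obs[keep],
                        predicted = j$bgs_doy_pred[keep])
  if (nrow(out) == 0L) {
    stop("all joined pairs have a missing side", call. = FALSE)
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Root mean square error of paired onset dates
#' @param pairs Paired tibble from [pair_bgs()].
#' @return RMSE in days.
#' @export
bgs_rmse <- function(pairs) {
  stopifnot(nrow(pairs) >= 1L)
  sqrt(mean((pairs$predicted - pairs$observed)^2))
}

#' Mean absolute error (R_A) of paired onset dates
#' @inheritParams bgs_rmse
#' @return Mean absolute error in days.
#' @export
bgs_mae <- function(pairs) {
  stopifnot(nrow(pairs) >= 1L)
  mean(abs(pairs$predicted - pairs$observed))
}

#' Coefficient of determination of paired onset dates
#'
#' Primary definition: the squared Pearson correlation between predicted and
#' observed onset. The regression-free alternative
#' `1 - SSE/SST` (sum of squared prediction errors over total observed
#' variation) is available as `method = "one_minus_sse_sst"` and is reported
#' separately by [evaluate_model()] -- the two differ whenever predictions
#' are biased.
#'
#' @inheritParams bgs_rmse
#' @param method `"pearson"` (default) or `"one_minus_sse_sst"`.
#' @return Dimensionless; in \[0, 1\] for `"pearson"`.
#' @export
bgs_r_squared <- function(pairs, method = c("pearson", "one_minus_sse_sst")) {
  method <- match.arg(method)
  if (nrow(pairs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(pairs$observed) == 0) {
    stop("undefined metric: observed values have zero variance",
         call. = FALSE)
  }
  if (method == "pearson") {
    if (stats::sd(pairs$predicted) == 0) {
      stop("undefined metric: predicted values have zero variance",
           call. = FALSE)
    }
    stats::cor(pairs$predicted, pairs$observed)^2
  } else {
    1 - sum((pairs$predicted - pairs$observed)^2) /
      sum((pairs$observed - mean(pairs$observed))^2)
  }
}

#' Pearson correlation of interannual biome-mean onset series
#'
#' Averages observed and predicted onset over all pixels of each biome per
#' year (unweighted), then correlates the two annual series across years.
#'
#' @inheritParams bgs_rmse
#' @param sites Sites tibble supplying the `biome` of each pixel.
#' @return Tibble `biome`, `r`, `n_years` (one row per biome with >= 3
#'   years); errors if any biome has fewer than 3 years or a constant
#'   annual-mean series.
#' @export
interannual_r <- function(pairs, sites) {
  ann <- pairs |>
    dplyr::left_join(dplyr::select(sites, "pixel_id", "biome"),
                     by = "pixel_id") |>
    dplyr::group_by(.data$biome, .data$year) |>
    dplyr::summarise(obs = mean(.data$observed), pred = mean(.data$predicted),
                     .groups = "drop_last") |>
    dplyr::summarise(r = {
      if (dplyr::n() < 3L) stop("need >= 3 years per biome", call. = FALSE)
      if (stats::sd(.data$obs) == 0 || stats::sd(.data$pred) == 0) {
        stop("undefined metric: constant annual-mean onset series",
             call. = FALSE)
      }
      stats::cor(.data$obs, .data$pred)
    }, n_years = dplyr::n(), .groups = "drop")
  ann
}

#' Cumulative frequency of absolute onset differences
#'
#' For each threshold tau, the percentage of pairs with
#' `|predicted - observed| <= tau`.
#'
#' @inheritParams bgs_rmse
#' @param thresholds Numeric vector of day thresholds (default 1..30).
#' @return Tibble `threshold`, `pct` (0..100, non-decreasing in threshold).
#' @export
cumulative_within <- function(pairs, thresholds = 1:30) {
  stopifnot(nrow(pairs) >= 1L)
  err <- abs(pairs$predicted - pairs$observed)
  tibble::tibble(
    threshold = as.numeric(thresholds),
    pct = vapply(thresholds, function(tau) 100 * mean(err <= tau),
                 numeric(1)))
}

#' Evaluate a phenology model against onset observations
#'
#' Predicts onset on the supplied pixel-years, pairs predictions with
#' observations and computes the full metric set.
#'
#' @param observations BGS tibble of observed onsets.
#' @param met Met tibble covering the evaluated pixel-years.
#' @param model,params,sites Passed to [predict_bgs()].
#' @param thresholds Day thresholds for [cumulative_within()].
#' @return A `pheno_eval` object: `$metrics` (one-row tibble with `r2`
#'   squared-Pearson, `r2_sse_sst`, `rmse`, `r_a`, `n`, `n_dropped`),
#'   `$cumfreq`, `$interannual` (per-biome tibble, or `NULL` when `sites`
#'   lacks biomes or spans < 3 years), `$pairs`. Methods: `print()`,
#'   `tidy()`, `glance()`, `autoplot()`.
#' @export
evaluate_model <- function(observations, met, model, params = NULL,
                           sites = NULL, thresholds = 1:30) {
  pred <- predict_bgs(met, model = model, params = params, sites = sites)
  pairs <- pair_bgs(observations, pred)
  inter <- NULL
  if (!is.null(sites) && "biome" %in% names(sites) &&
      length(unique(pairs$year)) >= 3L) {
    inter <- tryCatch(interannual_r(pairs, sites), error = function(e) NULL)
  }
  metrics <- tibble::tibble(
    model = model,
    r2 = tryCatch(bgs_r_squared(pairs), error = function(e) NA_real_),
    r2_sse_sst = tryCatch(bgs_r_squared(pairs, "one_minus_sse_sst"),
                          error = function(e) NA_real_),
    rmse = bgs_rmse(pairs),
    r_a = bgs_mae(pairs),
    n = nrow(pairs),
    n_dropped = attr(pairs, "n_dropped"))
  structure(list(metrics = metrics,
                 cumfreq = cumulative_within(pairs, thresholds),
                 interannual = inter,
                 pairs = pairs),
            class = "pheno_eval")
}

#' @export
print.pheno_eval <- function(x, ...) {
  m <- x$metrics
  cat("<pheno_eval> model:", m$model, "\n")
  cat(sprintf("  n = %d pairs (%d dropped); R2 = %.3f, RMSE = %.2f d, R_A = %.2f d\n",
              m$n, m$n_dropped, m$r2, m$rmse, m$r_a))
  if (!is.null(x$interannual)) {
    cat("  interannual r:",
        paste(sprintf("%s %.2f", x$interannual$biome, x$interannual$r),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy an onset-model evaluation
#'
#' @param x A `pheno_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return Long tibble `metric`, `value`.
#' @method tidy pheno_eval
#' @export
tidy.pheno_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"model", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of an onset-model evaluation
#' @inheritParams tidy.pheno_eval
#' @return The one-row metrics tibble.
#' @method glance pheno_eval
#' @export
glance.pheno_eval <- function(x, ...) {
  x$metrics
}
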