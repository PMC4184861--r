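# Per-biome parameter estimation: minimise the error sum of squares between
# predicted and observed onset over training pixel-years. Predicted onset is
# a piecewise-constant (step) function of every parameter, so derivative
# methods are ill-posed; the optimiser is a deterministic coarse grid scan
# followed by coordinate pattern search with step halving (integer
# neighbourhood descent for day-count parameters). The objective never
# increases across refinement and the whole procedure is reproducible.

#' Random half split of pixels
#'
#' Randomly assigns half of the pixels (all years of a pixel stay together)
#' to a calibration set and the rest to a validation set; the training half
#' has `ceiling(n/2)` pixels.
#'
#' @param sites Sites tibble with at least 2 rows.
#' @param seed Integer seed making the split reproducible.
#' @return Named list of two tibbles, `train` and `validation`, a disjoint
#'   exhaustive split of `sites`.
#' @export
#' @examples
#' split_half(generate_landscape(10, c(grassland = 1)), seed = 1)
split_half <- function(sites, seed = 1L) {
  n <- nrow(sites)
  if (n < 2L) stop("need at least 2 sites to split", call. = FALSE)
  n_train <- ceiling(n / 2)
  idx <- with_seed(derive_seed(seed, 11L), sample.int(n, n_train))
  list(train = sites[sort(idx), , drop = FALSE],
       validation = sites[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Error sum of squares between observed and predicted onset
#'
#' Sums squared day differences over records where both sides are present;
#' records with an observed onset but a missing prediction are charged
#' `penalty_days^2` each (so a model cannot improve its score by never
#' predicting onset); records with missing observations are skipped.
#'
#' @param observed,predicted BGS tibbles (`pixel_id`, `year`, `bgs_doy`)
#'   joined on `(pixel_id, year)`.
#' @param penalty_days Days charged per missing prediction (> 0, default 60).
#' @return SSE in days^2.
#' @export
bgs_sse <- function(observed, predicted, penalty_days = 60) {
  if (penalty_days <= 0) stop("penalty_days must be > 0", call. = FALSE)
  j <- dplyr::inner_join(observed, predicted, by = c("pixel_id", "year"),
                         suffix = c("_obs", "_pred"))
  sse_vec(j$bgs_doy_pred, j$bgs_doy_obs, penalty_days)
}

sse_vec <- function(pred, obs, penalty_days) {
  valid <- !is.na(obs)
  miss <- valid & is.na(pred)
  hit <- valid & !is.na(pred)
  sum((pred[hit] - obs[hit])^2) + penalty_days^2 * sum(miss)
}

model_families <- c("gdd", "ngd", "bbgc_woody", "bbgc_grass", "ncd_gdd")

# Default search space per model family: bounds bracket all reference
# parameter values with margin; n gives the coarse grid resolution.
default_free <- function(model) {
  switch(model,
    gdd = list(t_th = list(lower = -10, upper = 15, n = 26),
               gdd_c = list(lower = 0, upper = 1500, n = 61)),
    ngd = list(t_th = list(lower = -10, upper = 15, n = 26),
               ngd_c = list(lower = 1, upper = 120, n = 25, integer = TRUE)),
    bbgc_woody = list(t_th = list(lower = -10, upper = 15, n = 6),
                      a = list(lower = 3, upper = 8, n = 11),
                      b = list(lower = 0, upper = 0.2, n = 9)),
    bbgc_grass = list(c = list(lower = 0, upper = 30, n = 7),
                      d = list(lower = 0, upper = 600, n = 13),
                      k = list(lower = 0, upper = 0.3, n = 7)),
    ncd_gdd = list(g = list(lower = -500, upper = 200, n = 8),
                   h = list(lower = 0, upper = 1500, n = 7),
                   w = list(lower = -0.5, upper = 0, n = 6)))
}

default_fixed <- function(model) {
  switch(model,
    gdd = list(t0 = 1L),
    ngd = list(t0 = 1L),
    bbgc_woody = list(gate_s = 39300, offset = 15L, window = 11L),
    bbgc_grass = list(t_th = -5, offset = 15L, window = 11L),
    ncd_gdd = list(t_th_chill = 0, t_th_forc = -5))
}

# Grid ties resolve lexicographically: for GDD/NGD the day-count/critical-sum
# parameter is most significant (smallest first), then the base temperature;
# other families use the declared free-parameter order.
tie_priority <- function(model, free_names) {
  pref <- switch(model,
                 gdd = c("gdd_c", "t_th"),
                 ngd = c("ngd_c", "t_th"),
                 free_names)
  c(intersect(pref, free_names), setdiff(free_names, pref))
}

predict_core <- function(model, mm, p) {
  switch(model,
    gdd = core_gdd(mm, p$t_th, p$gdd_c, p$t0 %||% 1L),
    ngd = core_ngd(mm, p$t_th, p$ngd_c, p$t0 %||% 1L),
    bbgc_woody = core_bbgc_woody(mm, p$t_th, p$a, p$b,
                                 p$gate_s %||% 39300, p$offset %||% 15L,
                                 p$window %||% 11L),
    bbgc_grass = core_bbgc_grass(mm, p$t_th, p$c, p$d, p$k,
                                 p$offset %||% 15L, p$window %||% 11L),
    ncd_gdd = core_ncd_gdd(mm, p$t_th_chill, p$t_th_forc, p$g, p$h, p$w))
}

# Structure-aware starting points for families whose critical value is a
# parametric function of site climate. The zero-SSE basin of such families
# is extremely narrow (a ~1% error in the critical sum shifts onset by
# days), so a coarse grid cell rarely falls inside it; regressing the
# accumulated forcing implied by the observed onsets on its covariate lands
# a start inside or next to the basin, and the pattern search polishes it.
# Starts are clamped to the declared bounds and compete with the grid best
# on the same objective.
structure_starts <- function(model, mm, obs_vec, free, fixed, grids) {
  ok <- !is.na(obs_vec)
  starts <- list()
  clamp <- function(v, nm) {
    min(max(v, free[[nm]]$lower), free[[nm]]$upper)
  }
  if (model == "bbgc_woody" && all(c("a", "b") %in% names(free))) {
    offset <- fixed$offset %||% 15L
    window <- fixed$window %||% 11L
    t_th_vals <- if ("t_th" %in% names(free)) grids$t_th else fixed$t_th
    cross <- pmin(pmax(obs_vec[ok] + offset, 1L), YEAR_DAYS)
    for (t_th in t_th_vals) {
      cum <- soil_excess_cum(mm, t_th, window)
      crit <- cum[cbind(cross, which(ok))]
      use <- crit > 0
      if (sum(use) < 3L) next
      co <- stats::coef(stats::lm(log(crit[use]) ~ mm$t_avg[ok][use]))
      st <- c(a = clamp(co[[1]], "a"), b = clamp(co[[2]], "b"))
      if ("t_th" %in% names(free)) st <- c(t_th = t_th, st)
      starts[[length(starts) + 1L]] <- st[names(free)]
    }
  }
  if (model == "ncd_gdd" && all(c("g", "h") %in% names(free))) {
    w_vals <- if ("w" %in% names(free)) grids$w else fixed$w
    cross <- obs_vec[ok]
    cols <- which(ok)
    # onset at DOY 1 only tells us the critical forcing was already met
    use0 <- cross > 1L
    if (sum(use0) >= 3L) {
      gdd <- mm_memo(mm, sprintf("forccum_%.10g", fixed$t_th_forc),
                     function() {
                       col_cumsum(pmax(mm$tmean[yr_rows(), , drop = FALSE] -
                                         fixed$t_th_forc, 0))
                     })
      ncd <- mm_memo(mm, sprintf("ncd_%.10g", fixed$t_th_chill), function() {
        col_cumsum((mm$tmean < fixed$t_th_chill) * 1L)[yr_rows(), ,
                                                       drop = FALSE]
      })
      crit <- gdd[cbind(cross[use0], cols[use0])]
      ncd_at <- ncd[cbind(cross[use0], cols[use0])]
      for (w in w_vals) {
        x <- exp(w * ncd_at)
        if (stats::sd(x) == 0) next
        co <- stats::coef(stats::lm(crit ~ x))
        st <- c(g = clamp(co[[1]], "g"), h = clamp(co[[2]], "h"))
        if ("w" %in% names(free)) st <- c(st, w = w)
        starts[[length(starts) + 1L]] <- st[names(free)]
      }
    }
  }
  starts
}

#' Calibrate a phenology model on training records
#'
#' Minimises [bgs_sse()] over the free parameters: a coarse grid scan over
#' the declared bounds picks the best cell (ties resolved to the smallest
#' critical-sum/day-count value, then the smallest base temperature), then a
#' deterministic coordinate pattern search halves its steps until the
#' continuous steps fall below `1e-4` of each parameter range and integer
#' parameters have no improving unit neighbour. The objective never
#' increases across refinement.
#'
#' @param observations BGS tibble of training records (`pixel_id`, `year`,
#'   `bgs_doy`; `NA` = missing observation).
#' @param met Met tibble covering every training pixel-year.
#' @param model One of `"gdd"`, `"ngd"`, `"bbgc_woody"`, `"bbgc_grass"`,
#'   `"ncd_gdd"`.
#' @param free Named list of free parameters, each
#'   `list(lower=, upper=, n=, integer=)`; `NULL` uses the family default
#'   (see Details in the package vignette).
#' @param fixed Named list overriding the remaining parameters (defaults:
#'   `t0 = 1` for GDD/NGD; grass `t_th = -5`; chilling bases
#'   `t_th_chill = 0`, `t_th_forc = -5`; the structural constants
#'   `gate_s = 39300`, `offset = 15`, `window = 11`).
#' @param sites Sites tibble (latitude for the woody day-length gate).
#' @param penalty_days Days charged per missing prediction (default 60).
#' @param max_sweeps Cap on refinement sweeps (default 200).
#' @return A `pheno_fit` object: fitted `params`, `sse`, `n_train`,
#'   `n_missing_pred`, `converged`, an evaluation count and a per-sweep
#'   `trace`. Methods: `print()`, `tidy()`, `glance()`, `autoplot()`.
#' @export
calibrate_model <- function(observations, met, model, free = NULL,
                            fixed = list(), sites = NULL, penalty_days = 60,
                            max_sweeps = 200L) {
  model <- match.arg(model, model_families)
  free <- free %||% default_free(model)
  if (length(free) == 0L) stop("free must name at least one parameter",
                               call. = FALSE)
  for (nm in names(free)) {
    fp <- free[[nm]]
    if (!all(is.finite(c(fp$lower, fp$upper))) || fp$upper < fp$lower ||
        (fp$n %||% 1) < 1) {
      stop("invalid bounds/grid for free parameter ", nm, call. = FALSE)
    }
  }
  fixed <- utils::modifyList(default_fixed(model), fixed)

  mm <- met_matrix(met, sites)
  obs <- dplyr::arrange(observations, .data$pixel_id, .data$year)
  pos <- match(paste(mm$keys$pixel_id, mm$keys$year),
               paste(obs$pixel_id, obs$year))
  obs_vec <- obs$bgs_doy[pos]
  n_train <- sum(!is.na(obs_vec))
  if (n_train < 1L) {
    stop("no non-missing training observations", call. = FALSE)
  }

  n_eval <- 0L
  sse_memo <- new.env(parent = emptyenv())
  objective <- function(vals) {
    key <- paste(sprintf("%.12g", vals), collapse = "|")
    hit <- sse_memo[[key]]
    if (!is.null(hit)) return(hit)
    p <- utils::modifyList(fixed, as.list(vals))
    pred <- predict_core(model, mm, p)
    s <- sse_vec(pred, obs_vec, penalty_days)
    n_eval <<- n_eval + 1L
    sse_memo[[key]] <- s
    s
  }

  is_int <- vapply(free, function(f) isTRUE(f$integer), logical(1))
  grids <- purrr::imap(free, function(f, nm) {
    g <- seq(f$lower, f$upper, length.out = f$n %||% 1)
    if (isTRUE(f$integer)) g <- unique(as.integer(round(g)))
    g
  })
  grid <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  grid_sse <- vapply(seq_len(nrow(grid)), function(i) {
    objective(stats::setNames(as.numeric(grid[i, ]), names(free)))
  }, numeric(1))
  ord <- do.call(order, c(list(grid_sse),
                          lapply(tie_priority(model, names(free)),
                                 function(nm) grid[[nm]])))
  best <- stats::setNames(as.numeric(grid[ord[1L], ]), names(free))
  best_sse <- grid_sse[ord[1L]]

  for (st in structure_starts(model, mm, obs_vec, free, fixed, grids)) {
    s <- objective(st)
    if (s < best_sse) {
      best <- st
      best_sse <- s
    }
  }

  lower <- vapply(free, `[[`, numeric(1), "lower")
  upper <- vapply(free, `[[`, numeric(1), "upper")
  step <- vapply(names(free), function(nm) {
    g <- grids[[nm]]
    if (length(g) > 1L) diff(g[1:2]) else (upper[nm] - lower[nm]) / 2
  }, numeric(1))
  step[is_int] <- pmax(1, round(step[is_int]))
  tol <- pmax((upper - lower) * 1e-4, 1e-9)

  trace <- list(tibble::tibble(sweep = 0L, sse = best_sse))
  sweep <- 0L
  converged <- FALSE
  while (sweep < max_sweeps) {
    sweep <- sweep + 1L
    improved <- FALSE
    for (nm in names(free)) {
      if (step[[nm]] <= 0) next
      for (cand_val in c(best[[nm]] - step[[nm]], best[[nm]] + step[[nm]])) {
        cand_val <- min(max(cand_val, lower[[nm]]), upper[[nm]])
        if (is_int[[nm]]) cand_val <- round(cand_val)
        if (cand_val == best[[nm]]) next
        cand <- best
        cand[[nm]] <- cand_val
        s <- objective(cand)
        if (s < best_sse) {
          best <- cand
          best_sse <- s
          improved <- TRUE
        }
      }
    }
    trace[[length(trace) + 1L]] <- tibble::tibble(sweep = sweep,
                                                  sse = best_sse)
    if (!improved) {
      step[!is_int] <- step[!is_int] / 2
      step[is_int] <- floor(step[is_int] / 2)
      if (all(step[!is_int] < tol[!is_int]) && all(step[is_int] < 1)) {
        converged <- TRUE
        break
      }
    }
  }

  final <- utils::modifyList(fixed, as.list(best))
  pred <- predict_core(model, mm, final)
  structure(list(
    model = model,
    params = final,
    free = names(free),
    sse = best_sse,
    n_train = n_train,
    n_missing_pred = sum(!is.na(obs_vec) & is.na(pred)),
    n_eval = n_eval,
    penalty_days = penalty_days,
    trace = dplyr::bind_rows(trace),
    converged = converged),
    class = "pheno_fit")
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat("<pheno_fit> model:", x$model, "\n")
  est <- unlist(x$params[x$free])
  cat("  fitted: ",
      paste(sprintf("%s = %.6g", names(est), est), collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  SSE = %.4g days^2 over %d records (%d missing predictions)\n",
              x$sse, x$n_train, x$n_missing_pred))
  cat(sprintf("  %d objective evaluations; converged: %s\n",
              x$n_eval, x$converged))
  invisible(x)
}

#' Tidy a calibrated phenology fit
#'
#' @param x A `pheno_fit` from [calibrate_model()].
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`, `fitted`
#'   (whether the parameter was free in the optimisation).
#' @method tidy pheno_fit
#' @export
tidy.pheno_fit <- function(x, ...) {
  est <- x$params[vapply(x$params, is.numeric, logical(1))]
  tibble::tibble(term = names(est),
                 estimate = as.numeric(unlist(est)),
                 fitted = names(est) %in% x$free)
}

#' One-row summary of a calibrated phenology fit
#'
#' @inheritParams tidy.pheno_fit
#' @return One-row tibble: `model`, `sse`, `n_train`, `n_missing_pred`,
#'   `n_eval`, `converged`.
#' @method glance pheno_fit
#' @export
glance.pheno_fit <- function(x, ...) {
  tibble::tibble(model = x$model, sse = x$sse, n_train = x$n_train,
                 n_missing_pred = x$n_missing_pred, n_eval = x$n_eval,
                 converged = x$converged)
}
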