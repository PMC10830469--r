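#' Normalize a raw turbidity trace
#'
#' Applies the two standard turbidity normalizations: the first point is
#' subtracted to remove the background (`od_bg`), and the background-free
#' signal is divided by its maximum to express it as fraction of the clot
#' (`od_frac`). Traces with no positive signal are flagged `degenerate`.
#'
#' @param time_s Time points, s.
#' @param od_raw Raw optical density readings (405 nm).
#' @return A tibble with `time_s`, `od_raw`, `od_bg`, `od_frac`,
#'   `degenerate`.
#' @export
normalize_turbidity <- function(time_s, od_raw) {
  od_bg <- od_raw - od_raw[1]
  m <- max(od_bg)
  degenerate <- !(is.finite(m) && m > 0)
  od_frac <- if (degenerate) rep(NA_real_, length(od_bg)) else od_bg / m
  tibble::tibble(time_s = time_s, od_raw = od_raw, od_bg = od_bg,
                 od_frac = od_frac, degenerate = degenerate)
}

#' Read a plate-reader turbidity export
#'
#' Reads a delimited text export with a time column (seconds) followed by
#' one optical-density column per well, and applies the two standard
#' normalizations: subtraction of the first point (`od_bg`, removes the
#' background) and division by the maximum (`od_frac`, expresses the signal
#' as fraction of the clot). Wells with no positive signal are flagged
#' `degenerate` and get `NA` fractions.
#'
#' @param path Path to a comma/tab-delimited file with a header row.
#' @return A long tibble: `well`, `time_s`, `od_raw`, `od_bg`, `od_frac`,
#'   `degenerate`.
#' @export
read_plate_export <- function(path) {
  raw <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  if (ncol(raw) < 2L) {
    stop("plate export needs a time column and at least one well column",
         call. = FALSE)
  }
  tcol <- raw[[1]]
  if (!is.numeric(tcol)) {
    stop("plate export: non-numeric time column", call. = FALSE)
  }
  if (is.unsorted(tcol, strictly = TRUE)) {
    stop("plate export: time column must be strictly increasing", call. = FALSE)
  }
  wells <- names(raw)[-1]
  bad <- wells[!vapply(raw[-1], is.numeric, TRUE)]
  if (length(bad)) {
    stop("plate export: non-numeric optical density in well(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(wells, function(w) {
    dplyr::mutate(normalize_turbidity(tcol, raw[[w]]), well = w,
                  .before = 1)
  })
}

#' Extract clot formation/degradation parameters from a turbidity curve
#'
#' Quantifies a biphasic clotting-then-lysis optical density curve with the
#' seven standard parameters. On the rising (formation) phase, up to and
#' including the curve maximum: the clotting lag time (first time the clot
#' fraction reaches 5%), the formation rate (least-squares slope of the
#' fraction over the 20-80% window, per minute) and the time to 50% clot
#' formation (fraction closest to 0.5, earlier time on ties). At the peak:
#' the maximum optical density (background-subtracted). On the falling
#' (lysis) phase after the maximum: the lysis lag time (first time the
#' fraction drops to 0.95, i.e. 5% degradation of the fully formed clot),
#' the time to 50% lysis (fraction closest to 0.5) and degradation rates as
#' least-squares slopes of the fraction over the 20-80%, 20-50% and 50-80%
#' degradation ranges (fractions 0.2-0.8 etc. of maximum), reported as
#' positive fractions of clot per minute.
#'
#' @param curve A data frame for one well with columns `time_s` and either
#'   `od_frac`/`od_bg` (from [read_plate_export()] or [synth_turbidity()])
#'   or a raw `od_raw` column to normalize first.
#' @return A one-row tibble: `clot_lag_s`, `formation_rate`, `t50_clot_s`,
#'   `max_od`, `lysis_lag_s`, `t50_lysis_s`, `deg_rate_20_80`,
#'   `deg_rate_20_50`, `deg_rate_50_80`, `lysis_available`.
#' @examples
#' curve <- synth_turbidity(t_clot = 600, tau_clot = 60, t_lysis = 4000,
#'                          tau_lysis = 200, seed = 1)
#' turbidity_metrics(curve)
#' @export
turbidity_metrics <- function(curve) {
  if (!("od_frac" %in% names(curve))) {
    stopifnot(all(c("time_s", "od_raw") %in% names(curve)))
    curve <- normalize_turbidity(curve$time_s, curve$od_raw)
  }
  if (("degenerate" %in% names(curve) && isTRUE(curve$degenerate[1])) ||
      all(!is.finite(curve$od_frac))) {
    stop("degenerate curve: no positive signal to normalize", call. = FALSE)
  }
  tm <- curve$time_s
  fr <- curve$od_frac
  imax <- which.max(fr)
  rise_t <- tm[seq_len(imax)]
  rise_f <- fr[seq_len(imax)]
  fall_t <- tm[seq.int(imax, length(tm))]
  fall_f <- fr[seq.int(imax, length(tm))]

  if (imax == 1L || fr[1] > 0.5) {
    stop("curve is not biphasic: it starts at or near its maximum instead of rising",
         call. = FALSE)
  }
  clot_lag <- first_time_at_least(rise_t, rise_f, 0.05)
  t50_clot <- rise_t[which.min(abs(rise_f - 0.5))]
  if (is.na(clot_lag) || t50_clot < clot_lag) {
    stop("curve is not biphasic: no formation phase before the maximum",
         call. = FALSE)
  }
  lysis_available <- any(fall_f <= 0.95)
  if (lysis_available) {
    lysis_lag <- fall_t[which(fall_f <= 0.95)[1]]
    t50_lysis <- fall_t[which.min(abs(fall_f - 0.5))]
    deg <- function(lo, hi) {
      s <- interval_slope(fall_t, fall_f, lo, hi)
      if (is.na(s)) NA_real_ else abs(60 * s)
    }
    d2080 <- deg(0.2, 0.8)
    d2050 <- deg(0.5, 0.8) # 20-50% degradation = od_frac 0.5..0.8
    d5080 <- deg(0.2, 0.5) # 50-80% degradation = od_frac 0.2..0.5
  } else {
    lysis_lag <- t50_lysis <- d2080 <- d2050 <- d5080 <- NA_real_
  }
  tibble::tibble(
    clot_lag_s = clot_lag,
    formation_rate = 60 * interval_slope(rise_t, rise_f, 0.2, 0.8),
    t50_clot_s = t50_clot,
    max_od = if ("od_bg" %in% names(curve)) max(curve$od_bg) else NA_real_,
    lysis_lag_s = lysis_lag,
    t50_lysis_s = t50_lysis,
    deg_rate_20_80 = d2080,
    deg_rate_20_50 = d2050,
    deg_rate_50_80 = d5080,
    lysis_available = lysis_available
  )
}

#' Fit a decaying exponential to degradation rate vs fibrinogen
#'
#' Fits `y = A * exp(-k * x)` by nonlinear least squares with a
#' deterministic log-linear initialization (`lm(log(y) ~ x)`), as used to
#' summarise how the clot degradation rate falls with increasing fibrinogen
#' concentration.
#'
#' @param data Optional data frame holding the variables.
#' @param x,y Fibrinogen concentrations (mg/mL) and rates (fraction/min),
#'   or column names in `data`.
#' @return An object of class `decay_fit` with `amplitude`, `decay_constant`
#'   (per mg/mL), `fitted`, `residuals` and the input data; supports
#'   [generics::tidy()], [generics::glance()] and `predict()`.
#' @examples
#' fit <- fit_decay(x = c(0.25, 0.5, 1, 2), y = exp(-2 * c(0.25, 0.5, 1, 2)))
#' tidy(fit)
#' @export
fit_decay <- function(data = NULL, x, y) {
  if (!is.null(data)) {
    x <- data[[deparse(substitute(x))]]
    y <- data[[deparse(substitute(y))]]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("fit_decay needs at least 3 points", call. = FALSE)
  if (any(y <= 0)) stop("fit_decay needs positive rates", call. = FALSE)
  init <- coef(lm(log(y) ~ x))
  degenerate <- FALSE
  if (sd(y) / mean(y) < 1e-12) {
    # constant rates: no decay to estimate
    A <- mean(y)
    k <- 0
    fitted <- rep(A, length(y))
    degenerate <- TRUE
  } else {
    # scaleOffset lets the relative-offset criterion converge on
    # zero-residual (exact) data
    fit <- nls(y ~ A * exp(-k * x),
               start = list(A = exp(unname(init[1])), k = -unname(init[2])),
               control = stats::nls.control(maxiter = 200, scaleOffset = 1))
    A <- unname(coef(fit)["A"])
    k <- unname(coef(fit)["k"])
    fitted <- as.numeric(stats::fitted(fit))
  }
  structure(
    list(
      amplitude = A, decay_constant = k,
      data = tibble::tibble(x = x, y = y),
      fitted = fitted, residuals = y - fitted,
      rss = sum((y - fitted)^2), degenerate = degenerate
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y = %.4g * exp(-%.4g x), RSS %.3g on %d points%s\n",
              x$amplitude, x$decay_constant, x$rss, nrow(x$data),
              if (x$degenerate) " (degenerate: constant data)" else ""))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "decay_constant"),
    estimate = c(x$amplitude, x$decay_constant)
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$data),
    rss = x$rss,
    sigma = sqrt(x$rss / max(1, nrow(x$data) - 2)),
    degenerate = x$degenerate
  )
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  object$amplitude * exp(-object$decay_constant * x)
}

#' Region-wise pore statistics over time
#'
#' For a table of pore sizes measured at several clot regions over several
#' timepoints: the variance of pore size across regions at each timepoint
#' (a heterogeneity measure), and per region the rate of pore change as the
#' least-squares slope of pore size against time (um/s).
#'
#' @param table A data frame with columns `region`, `time_s`, `pore_um`.
#' @return A list of two tibbles: `by_timepoint` (`time_s`, `variance`,
#'   `sd`, `n_regions`; variance `NA` with fewer than 2 regions) and
#'   `by_region` (`region`, `rate_um_s`, `n_timepoints`).
#' @export
pore_table_stats <- function(table) {
  stopifnot(all(c("region", "time_s", "pore_um") %in% names(table)))
  by_tp <- dplyr::summarise(
    dplyr::group_by(table, .data$time_s),
    variance = if (dplyr::n() >= 2) var(.data$pore_um) else NA_real_,
    sd = sqrt(variance),
    n_regions = dplyr::n(),
    .groups = "drop"
  )
  by_rg <- dplyr::summarise(
    dplyr::group_by(table, .data$region),
    rate_um_s = if (dplyr::n() >= 2) {
      unname(coef(lm(.data$pore_um ~ .data$time_s))[2])
    } else NA_real_,
    n_timepoints = dplyr::n(),
    .groups = "drop"
  )
  list(by_timepoint = by_tp, by_region = by_rg)
}

#' Generate a synthetic biphasic turbidity curve
#'
#' Builds a clot-formation/lysis optical density curve as
#' `baseline + amplitude * logistic((t - t_clot)/tau_clot) *
#' (1 - logistic((t - t_lysis)/tau_lysis))` plus Gaussian noise, sampled on
#' the standard plate-reader grid (every 15 s over 4 h by default). Used to
#' test parameter recovery of [turbidity_metrics()].
#'
#' @param t_clot,tau_clot Formation midpoint (s) and time scale (s).
#' @param t_lysis,tau_lysis Lysis midpoint and time scale; `t_lysis` must
#'   exceed `t_clot`.
#' @param amplitude,baseline Optical density scale and offset.
#' @param noise_sd Gaussian noise SD (OD units).
#' @param duration_s,dt_s Sampling window and interval.
#' @param seed Optional seed.
#' @return A curve tibble as from [read_plate_export()] (single well).
#' @export
synth_turbidity <- function(t_clot, tau_clot, t_lysis, tau_lysis,
                            amplitude = 1, baseline = 0.05, noise_sd = 0,
                            duration_s = 4 * 3600, dt_s = 15, seed = NULL) {
  if (t_lysis <= t_clot) {
    stop("`t_lysis` must exceed `t_clot` (the clot forms before it lyses)",
         call. = FALSE)
  }
  if (amplitude < 0 || tau_clot <= 0 || tau_lysis <= 0) {
    stop("amplitude must be non-negative and time scales positive",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  tm <- seq(0, duration_s, by = dt_s)
  od <- baseline + amplitude * stats::plogis((tm - t_clot) / tau_clot) *
    (1 - stats::plogis((tm - t_lysis) / tau_lysis))
  if (noise_sd > 0) od <- od + stats::rnorm(length(tm), sd = noise_sd)
  normalize_turbidity(tm, od)
}
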