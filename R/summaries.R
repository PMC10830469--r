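first_time_at_least <- function(time, frac, threshold) {
  i <- which(frac >= threshold)[1]
  if (is.na(i)) NA_real_ else time[i]
}

# OLS slope of y on x restricted to y in [lo, hi] (closed interval);
# NA when fewer than 2 points fall in the window.
interval_slope <- function(x, y, lo, hi) {
  sel <- y >= lo & y <= hi
  if (sum(sel) < 2L || length(unique(x[sel])) < 2L) return(NA_real_)
  unname(coef(lm(y[sel] ~ x[sel]))[2])
}

#' Lysis summary metrics of a degradation curve
#'
#' From a fraction-degraded time series, extracts the lysis lag time (first
#' record with at least 5% of the clot degraded), the times to 20, 50 and
#' 80% lysis (defined the same way, no interpolation), and the degradation
#' rates over the 20-80%, 20-50% and 50-80% intervals as the slope of a
#' least-squares linear regression fit to the records whose fraction lies
#' in the interval, converted to fraction of clot per minute.
#'
#' @param curve A data frame with columns `time_s` and `degraded_fraction`
#'   (e.g. `sim$records`), or a `lysis_sim`.
#' @return A one-row tibble: `lag_s`, `t20_s`, `t50_s`, `t80_s`,
#'   `rate_20_80`, `rate_20_50`, `rate_50_80` (fraction/min) and `complete`
#'   (did the curve reach 80%?). Thresholds never reached give `NA`.
#' @examples
#' curve <- tibble::tibble(time_s = seq(0, 1000, 10),
#'                         degraded_fraction = pmin(1, seq(0, 1000, 10) / 1000))
#' lysis_metrics(curve)
#' @export
lysis_metrics <- function(curve) {
  if (inherits(curve, "lysis_sim")) curve <- curve$records
  stopifnot(all(c("time_s", "degraded_fraction") %in% names(curve)))
  tm <- curve$time_s
  fr <- curve$degraded_fraction
  if (is.unsorted(tm, strictly = TRUE)) {
    stop("record times must be strictly increasing", call. = FALSE)
  }
  if (any(diff(fr) < -1e-12)) {
    stop("degraded fraction must be non-decreasing", call. = FALSE)
  }
  tibble::tibble(
    lag_s = first_time_at_least(tm, fr, 0.05),
    t20_s = first_time_at_least(tm, fr, 0.20),
    t50_s = first_time_at_least(tm, fr, 0.50),
    t80_s = first_time_at_least(tm, fr, 0.80),
    rate_20_80 = 60 * interval_slope(tm, fr, 0.20, 0.80),
    rate_20_50 = 60 * interval_slope(tm, fr, 0.20, 0.50),
    rate_50_80 = 60 * interval_slope(tm, fr, 0.50, 0.80),
    complete = any(fr >= 0.80)
  )
}

#' Fold change between two metric values
#'
#' @param a,b Numeric values (e.g. a thick/dense metric over its thin/loose
#'   counterpart). Vectorised.
#' @return `a / b`; `NA` where the denominator is zero or either value is
#'   not finite.
#' @examples
#' fold_change(3.424e-4, 1.613e-5) # ratio of the loose and dense time steps
#' @export
fold_change <- function(a, b) {
  out <- a / b
  out[!is.finite(a) | !is.finite(b) | b == 0] <- NA_real_
  out
}

#' Pore expansion across degradation checkpoints
#'
#' Measures the scan-line pore profile ([measure_pores()]) on the intact
#' masks snapshotted at the first records reaching each degradation
#' checkpoint (by default 5, 20, 50 and 80%), the percent change of the
#' mean pore relative to the initial spacing, and the rate of pore change
#' (um/s) between consecutive checkpoints.
#'
#' @param sim A `lysis_sim` run with snapshot fractions covering the
#'   checkpoints, or a snapshots tibble from one.
#' @param clot Optional pre-built [build_lattice()] for the sim's scenario.
#' @return A tibble with one row per available checkpoint: `target`,
#'   `time_s`, `attained`, `mean_pore_um`, `percent_change`, `n_gaps` and
#'   `rate_um_s` (NA for the first checkpoint).
#' @export
pore_expansion <- function(sim, clot = NULL) {
  snaps <- if (inherits(sim, "lysis_sim")) sim$snapshots else sim
  if (is.null(clot)) {
    stopifnot(inherits(sim, "lysis_sim"))
    clot <- build_lattice(sim$spec)
  }
  if (nrow(snaps) == 0L) {
    stop("simulation has no snapshot masks; rerun with `snapshot_fractions`",
         call. = FALSE)
  }
  rows <- purrr::pmap(snaps, function(target, time_s, attained, intact_mask) {
    c2 <- clot
    c2$intact <- as.logical(intact_mask)
    prof <- measure_pores(c2)
    tibble::tibble(
      target = target, time_s = time_s, attained = attained,
      mean_pore_um = prof$mean_gap,
      percent_change = prof$percent_change,
      n_gaps = prof$n_gaps
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$target)
  out$rate_um_s <- c(NA_real_, diff(out$mean_pore_um) / diff(out$time_s))
  out
}

#' Transit-time statistics
#'
#' tPA transit time is the time a molecule spends in transit between
#' fibers: from the moment it starts moving freely — kinetic unbinding
#' from an intact fiber, forced unbinding onto a small degradation product
#' (the 1/k_off waiting period is part of the episode), or release from a
#' large degradation product at its previously assigned unbinding time —
#' until it next binds a fiber.
#'
#' @param sim A `lysis_sim`, or its `transits` tibble.
#' @return A list with `episodes` (tibble, durations in minutes appended),
#'   `mean_transit_min`, `n_episodes` and `available`.
#' @export
transit_stats <- function(sim) {
  tr <- if (inherits(sim, "lysis_sim")) sim$transits else sim
  if (nrow(tr) == 0L) {
    return(list(episodes = tr, mean_transit_min = NA_real_,
                n_episodes = 0L, available = FALSE))
  }
  tr$duration_min <- tr$duration_s / 60
  list(
    episodes = tr,
    mean_transit_min = mean(tr$duration_min),
    n_episodes = nrow(tr),
    available = TRUE
  )
}

#' Aggregate per-replicate metrics as mean and SD
#'
#' @param metrics A data frame with one row per replicate; grouping columns
#'   are preserved.
#' @param ... Optional grouping columns (tidy-select), e.g. `scenario`.
#' @return A long tibble: one row per (group, metric) with `mean`, `sd`
#'   (sample SD, NA with fewer than 2 replicates) and `n`.
#' @examples
#' replicate_aggregate(tibble::tibble(t50_s = c(2, 4)))
#' @export
replicate_aggregate <- function(metrics, ...) {
  groups <- rlang::enquos(...)
  long <- tidyr::pivot_longer(
    metrics,
    cols = dplyr::where(is.numeric) & !c(!!!groups),
    names_to = "metric", values_to = "value"
  )
  long <- dplyr::group_by(long, !!!groups, .data$metric)
  dplyr::summarise(
    long,
    mean = mean(.data$value, na.rm = TRUE),
    sd = if (sum(!is.na(.data$value)) >= 2) sd(.data$value, na.rm = TRUE) else NA_real_,
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
}
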