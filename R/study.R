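#' Run the full scenario study at desk scale
#'
#' Runs every canonical scenario ([scenario_catalog()]) at a reduced
#' lattice size and collects the quantities the study design compares:
#' per-replicate lysis metrics, pore sizes at the 5/20/50/80% degradation
#' checkpoints, and mean tPA transit times. All scenarios are shrunk by the
#' same factor (so the largest clot has about `max_fibers` fibers),
#' preserving the published fiber-count and tPA:fibrin ratios between
#' scenarios; pore size, fiber diameter and time steps keep their physical
#' values, so the scaled clots are smaller pieces of the same networks.
#'
#' @param max_fibers Target fiber count for the largest scenario.
#' @param n_replicates Independent replicates per scenario.
#' @param seed Base seed; replicate `k` of scenario `s` uses a seed derived
#'   from it deterministically.
#' @param record_interval Record interval for the scaled runs, s.
#' @param bind_prob Binding probability on fiber contact.
#' @param kinetics_thin,kinetics_thick Kinetics models for the two fiber
#'   diameters; default the parametric surrogates ([default_kinetics()]).
#' @param scenarios Optional character vector of scenario names to run.
#' @param quiet Suppress per-run progress messages.
#' @return A list of tibbles: `metrics` (one row per scenario x replicate,
#'   lysis metrics plus transit summary), `pores` (one row per scenario x
#'   replicate x checkpoint) and `scenarios` (the scaled specs and scenario
#'   classes).
#' @export
run_scaled_study <- function(max_fibers = 3000,
                             n_replicates = 10,
                             seed = 1,
                             record_interval = 10,
                             bind_prob = 1,
                             kinetics_thin = default_kinetics(72.7),
                             kinetics_thick = default_kinetics(145.4),
                             scenarios = NULL,
                             quiet = TRUE) {
  catalog <- scenario_catalog()
  if (!is.null(scenarios)) {
    missing <- setdiff(scenarios, catalog$name)
    if (length(missing)) stop("unknown scenario(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    catalog <- catalog[catalog$name %in% scenarios, ]
  }
  factor <- max_fibers / max(catalog$n_fibers_grid)
  factor <- min(1, factor)

  metrics_rows <- list()
  pore_rows <- list()
  scen_rows <- list()
  for (s in seq_len(nrow(catalog))) {
    spec <- scale_scenario(catalog$spec[[s]], factor,
                           record_interval = record_interval)
    kin <- if (catalog$fiber_diameter[s] < 100) kinetics_thin else kinetics_thick
    scen_rows[[s]] <- tibble::tibble(
      scenario = catalog$name[s],
      pore_class = catalog$pore_class[s],
      diameter_class = catalog$diameter_class[s],
      ratio_class = catalog$ratio_class[s],
      fixed_concentration = catalog$fixed_concentration[s],
      n_fibers = spec$n_fibers,
      n_tpa = spec$n_tpa,
      pore_size = spec$pore_size,
      spec = list(spec)
    )
    clot <- build_lattice(spec)
    for (k in seq_len(n_replicates)) {
      rep_seed <- as.integer((as.double(seed) * 1009 + s * 101 + k) %% 2147483647)
      sim <- simulate_lysis(spec, kin, bind_prob = bind_prob, seed = rep_seed)
      if (!quiet) {
        message(sprintf("%s rep %d: %.0f s simulated, final fraction %.2f",
                        catalog$name[s], k, max(sim$records$time_s),
                        max(sim$records$degraded_fraction)))
      }
      lm_row <- lysis_metrics(sim)
      ts <- transit_stats(sim)
      metrics_rows[[length(metrics_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(scenario = catalog$name[s], replicate = k,
                       pore_class = catalog$pore_class[s],
                       diameter_class = catalog$diameter_class[s],
                       ratio_class = catalog$ratio_class[s],
                       fixed_concentration = catalog$fixed_concentration[s]),
        lm_row,
        tibble::tibble(mean_transit_min = ts$mean_transit_min,
                       n_transits = ts$n_episodes,
                       truncated = sim$truncated)
      )
      pe <- pore_expansion(sim, clot = clot)
      pe <- dplyr::mutate(pe, scenario = catalog$name[s], replicate = k,
                          pore_class = catalog$pore_class[s],
                          diameter_class = catalog$diameter_class[s],
                          .before = 1)
      pore_rows[[length(pore_rows) + 1L]] <- pe
    }
  }
  list(
    metrics = dplyr::bind_rows(metrics_rows),
    pores = dplyr::bind_rows(pore_rows),
    scenarios = dplyr::bind_rows(scen_rows)
  )
}

#' Summarise a scaled study into the headline pore/transit quantities
#'
#' Computes, from a [run_scaled_study()] result: the percent change in mean
#' pore size at the 50% degradation checkpoint averaged over replicates and
#' scenarios; the increase in mean pore size between the 5% and 80%
#' checkpoints for loose and dense networks; and the mean tPA transit time
#' for loose and dense networks, in minutes.
#'
#' @param study A [run_scaled_study()] result.
#' @return A named list of scalars: `pct_change_at_50`, `pore_growth_loose_um`,
#'   `pore_growth_dense_um`, `transit_loose_min`, `transit_dense_min`, plus
#'   the per-scenario breakdown tibbles.
#' @export
study_headlines <- function(study) {
  p50 <- dplyr::filter(study$pores, .data$target == 0.5)
  by_scen_50 <- dplyr::summarise(
    dplyr::group_by(p50, .data$scenario),
    pct = mean(.data$percent_change), .groups = "drop"
  )

  growth <- tidyr::pivot_wider(
    dplyr::filter(study$pores, .data$target %in% c(0.05, 0.8)),
    id_cols = c("scenario", "replicate", "pore_class"),
    names_from = "target", values_from = "mean_pore_um"
  )
  growth$delta_um <- growth[["0.8"]] - growth[["0.05"]]
  by_scen_growth <- dplyr::summarise(
    dplyr::group_by(growth, .data$scenario, .data$pore_class),
    delta_um = mean(.data$delta_um, na.rm = TRUE), .groups = "drop"
  )
  class_growth <- function(cls) {
    mean(by_scen_growth$delta_um[by_scen_growth$pore_class == cls])
  }

  by_scen_transit <- dplyr::summarise(
    dplyr::group_by(study$metrics, .data$scenario, .data$pore_class),
    transit_min = mean(.data$mean_transit_min, na.rm = TRUE), .groups = "drop"
  )
  class_transit <- function(cls) {
    mean(by_scen_transit$transit_min[by_scen_transit$pore_class == cls])
  }

  list(
    pct_change_at_50 = mean(by_scen_50$pct),
    pore_growth_loose_um = class_growth("loose"),
    pore_growth_dense_um = class_growth("dense"),
    transit_loose_min = class_transit("loose"),
    transit_dense_min = class_transit("dense"),
    by_scenario_pct50 = by_scen_50,
    by_scenario_growth = by_scen_growth,
    by_scenario_transit = by_scen_transit
  )
}
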