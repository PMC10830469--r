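#' Place tPA molecules uniformly at random on the lattice nodes
#'
#' Internal lysis starts with the lytic enzyme already trapped inside the
#' clot: each molecule is assigned a uniformly random lattice node (one
#' uniform draw per molecule, `floor(u * n_nodes)`, the same protocol the
#' simulation engine uses for its own initialization, so a shared seed gives
#' identical placements).
#'
#' @param clot A [build_lattice()] object.
#' @param n_tpa Number of molecules.
#' @return A tibble with columns `molecule`, `node`, `i`, `j`, `state`.
#' @export
initialize_tpa <- function(clot, n_tpa) {
  stopifnot(inherits(clot, "lattice_clot"))
  n_tpa <- as.integer(n_tpa)
  if (is.na(n_tpa) || n_tpa < 0L) {
    stop("`n_tpa` must be a non-negative count", call. = FALSE)
  }
  nnodes <- clot$nx * clot$ny
  node <- integer(n_tpa)
  for (m in seq_len(n_tpa)) {
    node[m] <- as.integer(min(floor(stats::runif(1) * nnodes), nnodes - 1))
  }
  tibble::tibble(
    molecule = seq_len(n_tpa),
    node = node + 1L,
    i = node %% clot$nx,
    j = node %/% clot$nx,
    state = "UNBOUND"
  )
}

kinetics_for_engine <- function(kinetics) {
  stopifnot(inherits(kinetics, "kinetics_model"))
  list(
    type_code = if (kinetics$type == "empirical") 1L else 0L,
    unbind = as.numeric(kinetics$unbind),
    lysis = as.numeric(kinetics$lysis),
    mean_unbind_s = as.numeric(kinetics$mean_unbind_s),
    mean_lysis_s = as.numeric(kinetics$mean_lysis_s),
    lysis_prob = as.numeric(kinetics$lysis_prob),
    forced_unbind_prob = as.numeric(kinetics$forced_unbind_prob),
    koff_wait = as.numeric(kinetics$koff_wait)
  )
}

#' Run one internal-lysis simulation
#'
#' Advances the clot in synchronous time steps of `spec$time_step`: tPA
#' molecules random-walk on the lattice nodes (reflecting in-plane walls),
#' bind an adjacent intact fiber with probability `bind_prob` per step of
#' contact, draw an unbinding time and a single-fiber lysis time from the
#' kinetics model, and either kinetically unbind, get forcibly ejected onto
#' a freely diffusing small fibrin degradation product (probability q, then
#' a 1/k_off waiting time before rebinding), or ride a large degradation
#' product when their fiber breaks up (mobile only through degraded
#' positions, released at the previously assigned unbinding time). A fiber
#' degrades at the earliest of its drawn lysis times. The degradation state
#' is recorded every `spec$record_interval` seconds and full edge masks are
#' snapshotted at the first records reaching each of `snapshot_fractions`.
#'
#' Event scheduling, the RNG draw protocol and the fast-forwarding of
#' long FDP rides are documented in the methods vignette; with the same
#' seed a run is bit-identical.
#'
#' @param spec A [scenario_spec()].
#' @param kinetics A `kinetics_model`; its fiber diameter should match the
#'   scenario's.
#' @param bind_prob Probability of binding per step spent at a node with at
#'   least one adjacent intact fiber. Default 1 (bind on first contact).
#' @param max_time Hard time cap in seconds (guards non-lytic kinetics);
#'   runs reaching it are flagged `truncated`.
#' @param snapshot_fractions Degradation fractions at which to store intact
#'   masks.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first.
#' @param mixing_threshold_steps Rides on FDPs longer than this many steps
#'   have their release position sampled from the stationary law of the
#'   corresponding walk instead of being stepped explicitly; `Inf` forces
#'   exact per-step hopping.
#' @param keep_transits Record transit episodes: from the moment a molecule
#'   starts moving freely (kinetic unbinding from an intact fiber, forced
#'   unbinding onto a small degradation product — the 1/k_off wait counts —
#'   or release from a large degradation product at the previously assigned
#'   unbinding time) until its next binding.
#' @return An object of class `lysis_sim`: list with `records` (tibble
#'   `time_s`, `degraded_fraction`), `snapshots` (tibble `target`, `time_s`,
#'   `attained`, plus list-column `intact_mask`), `transits` (tibble
#'   `molecule`, `start_s`, `end_s`, `duration_s`), `edge_degrade_time_s`,
#'   `molecules` (final states), `counters`, `truncated`, `spec`.
#' @examples
#' spec <- scenario_spec("demo", 72.7, 1.0135, n_tpa = 20, grid_nx = 8,
#'                       grid_ny = 8, record_interval = 10)
#' sim <- simulate_lysis(spec, default_kinetics(72.7), seed = 1)
#' tail(sim$records)
#' @export
simulate_lysis <- function(spec, kinetics,
                           bind_prob = 1,
                           max_time = 1e6,
                           snapshot_fractions = c(0.05, 0.2, 0.5, 0.8),
                           seed = NULL,
                           mixing_threshold_steps = 2e4,
                           keep_transits = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(kinetics, "kinetics_model"))
  if (!isTRUE(all.equal(spec$fiber_diameter, kinetics$fiber_diameter))) {
    stop("scenario and kinetics fiber diameters disagree (",
         spec$fiber_diameter, " vs ", kinetics$fiber_diameter, " nm)",
         call. = FALSE)
  }
  nonlytic <- (kinetics$type == "exponential" && kinetics$lysis_prob <= 0) ||
    (kinetics$type == "empirical" && !any(is.finite(kinetics$lysis)))
  if (nonlytic && !is.finite(max_time)) {
    stop("kinetics can never lyse a fiber; a finite `max_time` is required",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  raw <- .run_engine(
    nx = spec$grid_nx, ny = spec$grid_ny, n_tpa = spec$n_tpa,
    dt = spec$time_step, record_interval = spec$record_interval,
    max_time = max_time, bind_prob = bind_prob,
    mix_threshold = mixing_threshold_steps,
    snapshot_fracs = as.numeric(snapshot_fractions),
    kinetics_in = kinetics_for_engine(kinetics),
    keep_transits = keep_transits
  )
  n_snap <- length(raw$snapshot_time)
  snapshots <- tibble::tibble(
    target = raw$snapshot_target[seq_len(n_snap)],
    time_s = raw$snapshot_time,
    attained = raw$snapshot_attained,
    intact_mask = raw$snapshot_masks[seq_len(n_snap)]
  )
  structure(
    list(
      records = tibble::tibble(
        time_s = raw$record_time,
        degraded_fraction = raw$record_frac
      ),
      snapshots = snapshots,
      transits = tibble::tibble(
        molecule = as.integer(raw$transit_mol),
        start_s = raw$transit_start,
        end_s = raw$transit_end,
        duration_s = raw$transit_end - raw$transit_start
      ),
      edge_degrade_time_s = raw$edge_degrade_time,
      molecules = tibble::tibble(
        molecule = seq_len(spec$n_tpa),
        init_node = as.integer(raw$init_nodes),
        state = c("UNBOUND", "BOUND", "ON_LARGE_FDP",
                  "WAITING_SMALL_FDP")[raw$final_state + 1L],
        node = as.integer(raw$final_node),
        edge = as.integer(raw$final_edge)
      ),
      counters = c(n_binds = raw$n_binds, n_forced = raw$n_forced,
                   n_steps = raw$n_steps),
      truncated = raw$truncated,
      spec = spec,
      bind_prob = bind_prob
    ),
    class = "lysis_sim"
  )
}

#' @export
print.lysis_sim <- function(x, ...) {
  fin <- x$records$degraded_fraction[nrow(x$records)]
  cat(sprintf(
    "<lysis_sim> %s: %d records to t = %.5g s, final degraded fraction %.3f%s\n",
    x$spec$name, nrow(x$records), max(x$records$time_s), fin,
    if (x$truncated) " (truncated)" else ""
  ))
  invisible(x)
}

#' Run independent replicates of a scenario
#'
#' Runs `n_replicates` independent simulations, seeding replicate `k` with
#' `base_seed + k - 1` (kept below 2^31).
#'
#' @inheritParams simulate_lysis
#' @param n_replicates Number of replicates (default from the spec).
#' @param base_seed Integer seed for the first replicate.
#' @param ... Passed to [simulate_lysis()].
#' @return A list of `lysis_sim` objects with a `replicate` attribute each.
#' @export
simulate_replicates <- function(spec, kinetics,
                                n_replicates = spec$n_replicates,
                                base_seed = 1L, ...) {
  purrr::map(seq_len(n_replicates), function(k) {
    seed <- (as.double(base_seed) + k - 1) %% 2147483647
    sim <- simulate_lysis(spec, kinetics, seed = as.integer(seed), ...)
    attr(sim, "replicate") <- k
    sim
  })
}
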