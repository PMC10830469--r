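fast_spec <- function(nx = 5, ny = 5, n_tpa = 10, dt = 0.1,
                      record_interval = 1, pore = 1) {
  scenario_spec("test", 72.7, pore, n_tpa = n_tpa, grid_nx = nx, grid_ny = ny,
                time_step = dt, record_interval = record_interval)
}

test_that("initial tPA placement is uniform over nodes", {
  clot <- build_lattice(nx = 93, ny = 93)
  set.seed(1)
  pos <- initialize_tpa(clot, 1e4)
  expect_identical(nrow(pos), 10000L)
  counts <- tabulate(pos$node, nbins = 93 * 93)
  # low expected counts per cell: the chi-square statistic is still well
  # approximated by its asymptotic law with ~8.6k cells
  test <- suppressWarnings(chisq.test(counts))
  expect_gt(test$p.value, 0.01)
  # engine uses the same placement protocol and seed stream
  spec <- scenario_spec("u", 72.7, 1, n_tpa = 1e4, grid_nx = 93, grid_ny = 93,
                        time_step = 0.1, record_interval = 1)
  sim <- simulate_lysis(spec, default_kinetics(72.7), max_time = 0, seed = 1)
  expect_identical(sim$molecules$init_node, pos$node)
})

test_that("initialize_tpa validates its arguments", {
  clot <- build_lattice(nx = 3, ny = 3)
  expect_error(initialize_tpa(clot, -1), "non-negative")
  expect_identical(nrow(initialize_tpa(clot, 0)), 0L)
})

test_that("no tPA means no degradation; molecules are conserved throughout", {
  spec <- fast_spec(n_tpa = 0)
  sim <- simulate_lysis(spec, default_kinetics(72.7), max_time = 20, seed = 2)
  expect_true(all(sim$records$degraded_fraction == 0))
  expect_true(sim$truncated)

  spec2 <- fast_spec(n_tpa = 25)
  sim2 <- simulate_lysis(spec2, default_kinetics(72.7, mean_unbind_s = 1,
                                                 mean_lysis_s = 2),
                         seed = 3)
  expect_identical(nrow(sim2$molecules), 25L)
  expect_true(all(sim2$molecules$state %in%
                    c("UNBOUND", "BOUND", "ON_LARGE_FDP", "WAITING_SMALL_FDP")))
  # degraded fraction is monotone and reaches 1 with lytic kinetics
  expect_true(all(diff(sim2$records$degraded_fraction) >= 0))
  expect_equal(max(sim2$records$degraded_fraction), 1)
  expect_false(sim2$truncated)
})

test_that("bind_prob = 0 prevents all binding and degradation", {
  spec <- fast_spec(n_tpa = 20)
  sim <- simulate_lysis(spec, default_kinetics(72.7), bind_prob = 0,
                        max_time = 30, seed = 4)
  expect_identical(unname(sim$counters["n_binds"]), 0)
  expect_true(all(sim$records$degraded_fraction == 0))
  expect_true(all(sim$molecules$state == "UNBOUND"))
})

test_that("the same seed gives bit-identical runs; different seeds differ", {
  spec <- fast_spec(n_tpa = 15)
  kin <- default_kinetics(72.7, mean_unbind_s = 2, mean_lysis_s = 3)
  a <- simulate_lysis(spec, kin, seed = 5)
  b <- simulate_lysis(spec, kin, seed = 5)
  c <- simulate_lysis(spec, kin, seed = 6)
  expect_identical(a$records, b$records)
  expect_identical(a$edge_degrade_time_s, b$edge_degrade_time_s)
  expect_identical(a$transits, b$transits)
  expect_false(identical(a$edge_degrade_time_s, c$edge_degrade_time_s))
})

test_that("free molecules diffuse with mean squared displacement ~ k * spacing^2", {
  # pure random walk (bind_prob = 0) on a large grid, far from the walls
  spec <- scenario_spec("msd", 72.7, 1, n_tpa = 3000, grid_nx = 201,
                        grid_ny = 201, time_step = 1, record_interval = 100)
  k_steps <- 100
  sim <- simulate_lysis(spec, default_kinetics(72.7), bind_prob = 0,
                        max_time = k_steps, seed = 7)
  start <- sim$molecules$init_node - 1L
  end <- sim$molecules$node - 1L
  dx <- (end %% 201) - (start %% 201)
  dy <- (end %/% 201) - (start %/% 201)
  msd <- mean(dx^2 + dy^2)
  # reflecting-boundary correction is negligible at this size/time
  expect_lt(abs(msd - k_steps) / k_steps, 0.1)
})

test_that("single-node clot reproduces the hand-computed event sequence", {
  # one z-fiber, one molecule, deterministic kinetics: bind at t = dt,
  # lysis 2 s later applied at the next boundary, unbinding at t = 6
  spec <- scenario_spec("tiny", 72.7, 1, n_tpa = 1, grid_nx = 1, grid_ny = 1,
                        time_step = 1, record_interval = 1)
  kin <- degenerate_kinetics(unbind_s = 5, lysis_s = 2)
  sim <- simulate_lysis(spec, kin, seed = 8)
  expect_equal(sim$records$time_s, c(0, 1, 2, 3))
  expect_equal(sim$records$degraded_fraction, c(0, 0, 0, 1))
  expect_equal(sim$edge_degrade_time_s, 3)
})

test_that("forced-unbinding branch frequency matches q over many binds", {
  # small clot, non-lytic kinetics, fast unbinding and shortened waiting so
  # molecules cycle quickly through bind/unbind events
  for (d in c(72.7, 145.4)) {
    q <- if (d == 72.7) 0.0852 else 0.0729129
    kin <- default_kinetics(d, mean_unbind_s = 0.3, lysis_prob = 1)
    kin$lysis_prob <- 0 # never lyse: every bind is observed on an intact fiber
    kin$koff_wait <- 0.2
    spec <- scenario_spec("q", d, 1, n_tpa = 150, grid_nx = 5, grid_ny = 5,
                          time_step = 0.1, record_interval = 50)
    sim <- simulate_lysis(spec, kin, max_time = 400, seed = round(d))
    n <- unname(sim$counters["n_binds"])
    x <- unname(sim$counters["n_forced"])
    expect_gt(n, 1e5)
    se <- sqrt(q * (1 - q) / n)
    expect_lt(abs(x / n - q), 3 * se)
  }
})

test_that("mean time to 50% lysis is non-increasing in the tPA count", {
  kin <- default_kinetics(72.7, mean_unbind_s = 3, mean_lysis_s = 5)
  t50 <- sapply(c(4, 16, 64), function(n_tpa) {
    spec <- scenario_spec("mono", 72.7, 1, n_tpa = n_tpa, grid_nx = 11,
                          grid_ny = 11, time_step = 0.05, record_interval = 1)
    sims <- simulate_replicates(spec, kin, n_replicates = 6, base_seed = 20)
    mean(sapply(sims, function(s) lysis_metrics(s)$t50_s))
  })
  expect_true(all(diff(t50) <= 0))
})

test_that("engine matches the independent discrete-event oracle exactly", {
  # exact stream equivalence on small lattices: per-step stepping
  # (mixing_threshold_steps = Inf) against the R oracle coded from the
  # documented draw protocol
  cases <- list(
    list(nx = 1, ny = 1, n_tpa = 1, kin = degenerate_kinetics(unbind_s = 5, lysis_s = 2)),
    list(nx = 3, ny = 3, n_tpa = 4, kin = degenerate_kinetics(unbind_s = 1.5, lysis_s = 0.7)),
    list(nx = 3, ny = 3, n_tpa = 6,
         kin = degenerate_kinetics(unbind_s = 0.4, lysis_s = 2.5,
                                   forced_unbind_prob = 0.5)),
    list(nx = 3, ny = 2, n_tpa = 5,
         kin = default_kinetics(72.7, mean_unbind_s = 1, mean_lysis_s = 1.2,
                                lysis_prob = 0.7)),
    list(nx = 2, ny = 3, n_tpa = 3,
         kin = default_kinetics(145.4, mean_unbind_s = 0.8, mean_lysis_s = 2))
  )
  for (cs in seq_along(cases)) {
    cc <- cases[[cs]]
    cc$kin$koff_wait <- 1.3 # short waiting keeps the oracle affordable
    spec <- scenario_spec("oracle", cc$kin$fiber_diameter, 1, n_tpa = cc$n_tpa,
                          grid_nx = cc$nx, grid_ny = cc$ny, time_step = 0.5,
                          record_interval = 1)
    seed <- 100 + cs
    sim <- simulate_lysis(spec, cc$kin, max_time = 60, seed = seed,
                          mixing_threshold_steps = Inf)
    set.seed(seed)
    ora <- oracle_run(nx = cc$nx, ny = cc$ny, n_tpa = cc$n_tpa, dt = 0.5,
                      record_interval = 1, max_time = 60, bind_prob = 1,
                      kin = cc$kin)
    expect_equal(sim$records$time_s, ora$record_time, info = paste("case", cs))
    expect_equal(sim$records$degraded_fraction, ora$record_frac,
                 info = paste("case", cs))
    expect_equal(sim$edge_degrade_time_s, ora$edge_degrade_time,
                 info = paste("case", cs))
    expect_identical(nrow(sim$transits), nrow(ora$transits),
                     info = paste("case", cs))
    if (nrow(ora$transits) > 0) {
      expect_equal(
        unname(as.matrix(sim$transits[, c("molecule", "start_s", "end_s")])),
        unname(ora$transits), info = paste("case", cs)
      )
    }
    states <- c(U = "UNBOUND", B = "BOUND", L = "ON_LARGE_FDP",
                W = "WAITING_SMALL_FDP")
    expect_identical(sim$molecules$state, unname(states[ora$final_state]),
                     info = paste("case", cs))
    expect_equal(sim$molecules$edge, ora$final_edge, info = paste("case", cs))
  }
})

test_that("fast-forwarded FDP rides preserve the degradation dynamics", {
  # the acceleration may only change molecule positions' sampling, never the
  # recorded degradation curve of molecules that stay put; compare summary
  # distributions between exact and accelerated runs across replicates
  spec <- fast_spec(nx = 7, ny = 7, n_tpa = 12, dt = 0.05)
  kin <- default_kinetics(72.7, mean_unbind_s = 2, mean_lysis_s = 1)
  kin$koff_wait <- 2
  t50_exact <- sapply(1:8, function(k) {
    lysis_metrics(simulate_lysis(spec, kin, seed = 200 + k,
                                 mixing_threshold_steps = Inf))$t50_s
  })
  t50_fast <- sapply(1:8, function(k) {
    lysis_metrics(simulate_lysis(spec, kin, seed = 200 + k,
                                 mixing_threshold_steps = 10))$t50_s
  })
  expect_lt(abs(mean(t50_exact) - mean(t50_fast)),
            3 * sd(t50_exact) / sqrt(8) + 3 * sd(t50_fast) / sqrt(8) + 1)
})

test_that("degenerate large-FDP riders are released at their assigned unbind time", {
  # a molecule whose fiber degrades before its unbinding time rides the FDP
  # and starts its transit only at the previously assigned unbind time
  spec <- scenario_spec("ride", 72.7, 1, n_tpa = 1, grid_nx = 1, grid_ny = 2,
                        time_step = 1, record_interval = 1)
  kin <- degenerate_kinetics(unbind_s = 7, lysis_s = 2)
  sim <- simulate_lysis(spec, kin, seed = 9, max_time = 60)
  # first bind at t = 1, fiber degrades at t = 3 (lysis 2 s), rider released
  # at t = 8 (bind + unbind 7); an intact fiber is always adjacent on this
  # 2-node clot, so the first transit episode is exactly (8, 9)
  expect_equal(min(sim$edge_degrade_time_s, na.rm = TRUE), 3)
  expect_gte(nrow(sim$transits), 1)
  expect_equal(sim$transits$start_s[1], 8)
  expect_equal(sim$transits$end_s[1], 9)
})
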