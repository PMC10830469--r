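trapezoid_curve <- function() {
  tm <- seq(0, 4000, by = 15)
  od <- ifelse(tm <= 1000, tm / 1000,
               ifelse(tm <= 2000, 1, 1 - (tm - 2000) / 2000))
  normalize_turbidity(tm, 0.1 + 0.9 * od) # baseline and scale are removed
}

test_that("trapezoid curve metrics match the piecewise-linear closed form", {
  m <- turbidity_metrics(trapezoid_curve())
  # analytic half-formation time is 500 s; 495 s is the closest 15 s sample
  expect_equal(m$t50_clot_s, 495)
  expect_lt(abs(m$t50_clot_s - 500), 15)
  expect_equal(m$lysis_lag_s, 2100)
  expect_equal(m$t50_lysis_s, 3000)
  # linear fall 1 -> 0 over 2000 s: |slope| = 5e-4/s = 0.03/min in every window
  expect_equal(m$deg_rate_20_80, 0.03)
  expect_equal(m$deg_rate_20_50, 0.03)
  expect_equal(m$deg_rate_50_80, 0.03)
  expect_equal(m$formation_rate, 0.06) # rise 0 -> 1 over 1000 s
  expect_equal(m$max_od, 0.9)
  expect_true(m$lysis_available)
})

test_that("time-reversed and degenerate curves are rejected", {
  # a partially lysed curve played backwards starts above half-formation:
  # lysis before formation violates the biphasic ordering
  tr <- trapezoid_curve()
  part <- tr[tr$time_s <= 2800, ] # fall truncated at od_frac = 0.6
  rev_curve <- tibble::tibble(time_s = part$time_s, od_frac = rev(part$od_frac),
                              od_bg = rev(part$od_bg))
  expect_error(turbidity_metrics(rev_curve), "biphasic")
  # a pure-decay raw trace loses its signal in background subtraction
  decay <- normalize_turbidity(tr$time_s, 1 - tr$od_raw)
  expect_error(turbidity_metrics(decay), "degenerate")
  flat <- normalize_turbidity(seq(0, 300, 15), rep(0.3, 21))
  expect_error(turbidity_metrics(flat), "degenerate")
})

test_that("monotone (never-lysing) curves flag degradation fields unavailable", {
  tm <- seq(0, 3600, 15)
  curve <- normalize_turbidity(tm, plogis((tm - 600) / 120))
  m <- turbidity_metrics(curve)
  expect_false(m$lysis_available)
  expect_true(is.na(m$t50_lysis_s))
  expect_true(is.na(m$deg_rate_20_80))
  expect_false(is.na(m$t50_clot_s))
})

test_that("metrics are invariant to uniform OD scaling (except max_od)", {
  tr <- trapezoid_curve()
  scaled <- normalize_turbidity(tr$time_s, 7.5 * tr$od_raw)
  a <- turbidity_metrics(tr)
  b <- turbidity_metrics(scaled)
  frac_cols <- setdiff(names(a), c("max_od"))
  expect_equal(a[frac_cols], b[frac_cols])
  expect_equal(b$max_od, 7.5 * a$max_od)
})

test_that("normalization is idempotent and anchors the first point at zero", {
  tr <- trapezoid_curve()
  again <- normalize_turbidity(tr$time_s, tr$od_bg)
  expect_equal(again$od_bg, tr$od_bg)
  expect_equal(again$od_frac, tr$od_frac)
  expect_equal(tr$od_bg[1], 0)
  expect_equal(max(tr$od_frac), 1)
})

test_that("plate exports parse into per-well normalized curves", {
  path <- withr::local_tempfile(fileext = ".csv")
  tm <- seq(0, 4 * 3600, by = 15)
  set.seed(21)
  a <- synth_turbidity(900, 120, 6000, 400, seed = 21)$od_raw
  b <- rep(0.2, length(tm))
  readr::write_csv(tibble::tibble(time_s = tm, A1 = a, B1 = b), path)
  curves <- read_plate_export(path)
  expect_identical(length(tm), 961L) # 4 h at 15 s
  expect_setequal(unique(curves$well), c("A1", "B1"))
  expect_equal(nrow(curves), 2 * 961)
  a1 <- curves[curves$well == "A1", ]
  expect_equal(max(a1$od_frac), 1)
  expect_true(all(curves$degenerate[curves$well == "B1"]))
  # malformed exports fail with a located error
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time_s = c(0, 30, 15), A1 = 1:3), bad)
  expect_error(read_plate_export(bad), "increasing")
})

test_that("logistic-product curves recover their parameters within one sample", {
  # analytic oracle: evaluate the noiseless generator on a 0.01 s grid and
  # extract the same quantities from that dense curve
  cases <- list(c(600, 60, 4000, 200), c(1200, 150, 9000, 500),
                c(300, 40, 2500, 120))
  for (p in cases) {
    curve <- synth_turbidity(p[1], p[2], p[3], p[4], noise_sd = 0)
    m <- turbidity_metrics(curve)
    dense_t <- seq(0, 4 * 3600, by = 0.01)
    f <- plogis((dense_t - p[1]) / p[2]) * (1 - plogis((dense_t - p[3]) / p[4]))
    f <- f / max(f)
    imax <- which.max(f)
    t50c_oracle <- dense_t[which.min(abs(f[1:imax] - 0.5))]
    fall <- seq(imax, length(dense_t))
    lag_oracle <- dense_t[fall[which(f[fall] <= 0.95)[1]]]
    t50l_oracle <- dense_t[fall[which.min(abs(f[fall] - 0.5))]]
    expect_lt(abs(m$t50_clot_s - t50c_oracle), 15 + 1e-9)
    expect_lt(abs(m$lysis_lag_s - lag_oracle), 15 + 1e-9)
    expect_lt(abs(m$t50_lysis_s - t50l_oracle), 15 + 1e-9)
  }
})

test_that("synthetic curves are seed-reproducible and validate their inputs", {
  a <- synth_turbidity(600, 60, 4000, 200, noise_sd = 0.01, seed = 33)
  b <- synth_turbidity(600, 60, 4000, 200, noise_sd = 0.01, seed = 33)
  expect_identical(a, b)
  expect_error(synth_turbidity(4000, 60, 600, 200), "exceed")
  zero <- synth_turbidity(600, 60, 4000, 200, amplitude = 0)
  expect_true(zero$degenerate[1])
})

test_that("exponential decay fits recover exact parameters to 6 significant figures", {
  x <- c(0.25, 0.5, 1, 2)
  fit <- fit_decay(x = x, y = 1 * exp(-2 * x))
  expect_equal(fit$decay_constant, 2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  td <- tidy(fit)
  expect_identical(td$term, c("amplitude", "decay_constant"))
  gl <- glance(fit)
  expect_identical(gl$nobs, 4L)
  expect_lt(gl$rss, 1e-12)
  expect_equal(predict(fit, tibble::tibble(x = 0)), 1, tolerance = 1e-6)
})

test_that("constant rates give a flagged zero decay constant", {
  fit <- fit_decay(x = c(0.25, 0.5, 1, 2), y = rep(0.4, 4))
  expect_equal(fit$decay_constant, 0)
  expect_true(fit$degenerate)
  expect_error(fit_decay(x = 1:3, y = c(1, -1, 1)), "positive")
  expect_error(fit_decay(x = 1:2, y = c(1, 2)), "3 points")
})

test_that("noisy decay data recover the generating constant within 5%", {
  set.seed(44)
  x <- c(0.23, 0.70, 1.2, 2.1)
  khat <- replicate(100, {
    y <- 0.8 * exp(-2.7 * x) * (1 + rnorm(4, sd = 0.05))
    fit_decay(x = x, y = abs(y))$decay_constant
  })
  expect_lt(abs(median(khat) - 2.7) / 2.7, 0.05)
})

test_that("pore region tables yield per-timepoint variance and per-region rates", {
  tab <- tidyr::expand_grid(region = 1:3, time_s = c(0, 200, 400))
  tab$pore_um <- with(tab, 1 + region * 0.5 + time_s * 0.01 * region)
  st <- pore_table_stats(tab)
  # spreadsheet check at t = 400: pores are 1+0.5r+4r = 1+4.5r
  expect_equal(st$by_timepoint$variance[st$by_timepoint$time_s == 400],
               var(1 + 4.5 * (1:3)))
  expect_equal(st$by_region$rate_um_s, 0.01 * (1:3))
  # all regions equal: zero variance
  eq <- tibble::tibble(region = 1:4, time_s = 0, pore_um = 2)
  expect_equal(pore_table_stats(eq)$by_timepoint$variance, 0)
  # linear growth 1 -> 5 um over 400 s: rate 0.01 um/s
  lin <- tibble::tibble(region = 1, time_s = c(0, 400), pore_um = c(1, 5))
  expect_equal(pore_table_stats(lin)$by_region$rate_um_s, 0.01)
  # single region at a timepoint: variance unavailable
  single <- tibble::tibble(region = 1, time_s = c(0, 1), pore_um = c(1, 2))
  expect_true(all(is.na(pore_table_stats(single)$by_timepoint$variance)))
})
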