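# Independent discrete-event oracle for the lattice engine, written in plain
# R directly against the documented RNG draw protocol (see src/engine.cpp
# header and the methods vignette). Used on tiny lattices only: with the same
# seed it must reproduce the engine's records, per-edge degradation times,
# transit log and final molecule states exactly.

oracle_edge_geometry <- function(nx, ny) {
  ex <- (nx - 1L) * ny
  ey <- nx * (ny - 1L)
  E <- ex + ey + nx * ny
  end_a <- integer(E)
  end_b <- integer(E)
  for (e in 0:(E - 1L)) {
    if (e < ex) {
      i <- e %% (nx - 1L)
      j <- e %/% (nx - 1L)
      end_a[e + 1L] <- i + j * nx
      end_b[e + 1L] <- (i + 1L) + j * nx
    } else if (e < ex + ey) {
      r <- e - ex
      i <- r %% nx
      j <- r %/% nx
      end_a[e + 1L] <- i + j * nx
      end_b[e + 1L] <- i + (j + 1L) * nx
    } else {
      end_a[e + 1L] <- end_b[e + 1L] <- e - ex - ey
    }
  }
  incident <- vector("list", nx * ny)
  for (j in 0:(ny - 1L)) {
    for (i in 0:(nx - 1L)) {
      nd <- i + j * nx
      inc <- integer()
      if (i > 0L) inc <- c(inc, (i - 1L) + j * (nx - 1L))
      if (i < nx - 1L) inc <- c(inc, i + j * (nx - 1L))
      if (j > 0L) inc <- c(inc, ex + i + (j - 1L) * nx)
      if (j < ny - 1L) inc <- c(inc, ex + i + j * nx)
      inc <- c(inc, ex + ey + nd)
      incident[[nd + 1L]] <- inc
    }
  }
  list(E = E, ex = ex, ey = ey, end_a = end_a, end_b = end_b,
       incident = incident)
}

oracle_draw_empirical <- function(x) {
  u <- runif(1)
  n <- length(x)
  if (n == 1L) return(x)
  h <- u * (n - 1)
  lo <- min(floor(h), n - 2)
  frac <- h - lo
  if (frac == 0) x[lo + 1] else x[lo + 1] + frac * (x[lo + 2] - x[lo + 1])
}

oracle_draw_unbind <- function(kin) {
  if (kin$type == "empirical") {
    oracle_draw_empirical(kin$unbind)
  } else {
    -kin$mean_unbind_s * log1p(-runif(1))
  }
}

oracle_draw_lysis <- function(kin) {
  if (kin$type == "empirical") {
    return(oracle_draw_empirical(kin$lysis))
  }
  if (kin$lysis_prob < 1 && runif(1) >= kin$lysis_prob) return(Inf)
  -kin$mean_lysis_s * log1p(-runif(1))
}

oracle_ceil_steps <- function(t, dt) {
  if (!is.finite(t)) return(Inf)
  max(0, ceiling(t / dt - 1e-9))
}

# Full per-step oracle (no fast-forwarding: equivalent to the engine with
# mixing_threshold_steps = Inf). Molecule states: "U", "B", "L", "W".
oracle_run <- function(nx, ny, n_tpa, dt, record_interval, max_time,
                       bind_prob, kin) {
  geo <- oracle_edge_geometry(nx, ny)
  E <- geo$E
  nnodes <- nx * ny
  intact <- rep(TRUE, E)
  edge_sched <- rep(Inf, E)   # scheduled degradation boundary (step index)
  edge_time <- rep(NA_real_, E)

  state <- rep("U", n_tpa)
  node <- integer(n_tpa)
  edge <- rep(NA_integer_, n_tpa)     # 0-based edge id
  release <- rep(Inf, n_tpa)
  forced <- rep(FALSE, n_tpa)
  tstart <- rep(NA_real_, n_tpa)      # boundary step when movement started

  for (m in seq_len(n_tpa)) {
    node[m] <- min(floor(runif(1) * nnodes), nnodes - 1)
  }

  rec <- max(1, round(record_interval / dt))
  max_step <- oracle_ceil_steps(max_time, dt)
  wait_steps <- oracle_ceil_steps(1 / 0.036, dt)
  if (!is.null(kin$koff_wait)) wait_steps <- oracle_ceil_steps(kin$koff_wait, dt)

  adj_degraded <- function(e) {
    nds <- unique(c(geo$end_a[e + 1L], geo$end_b[e + 1L]))
    cand <- unlist(lapply(nds, function(nd) geo$incident[[nd + 1L]]))
    cand <- sort(unique(cand[cand != e & !intact[cand + 1L]]))
    cand
  }

  rec_time <- c()
  rec_frac <- c()
  tr <- list()
  n_deg <- 0L
  step <- 0

  repeat {
    # degradations scheduled at or before this boundary, ascending then by id
    due <- which(intact & edge_sched <= step)
    if (length(due)) {
      due <- due[order(edge_sched[due], due)]
      for (eidx in due) {
        intact[eidx] <- FALSE
        n_deg <- n_deg + 1L
        edge_time[eidx] <- edge_sched[eidx] * dt
        hit <- which(state == "B" & edge == (eidx - 1L))
        state[hit] <- "L" # transit opens at the later release, not at breakup
      }
    }
    # releases
    for (m in seq_len(n_tpa)) {
      if (release[m] > step) next
      if (state[m] == "B") {
        if (forced[m]) {
          state[m] <- "W" # transit opens at boarding; includes the wait
          tstart[m] <- release[m]
          release[m] <- step + wait_steps
        } else {
          state[m] <- "U"
          tstart[m] <- release[m]
          release[m] <- Inf
        }
        edge[m] <- NA_integer_
      } else if (state[m] == "L") {
        e <- edge[m]
        a <- geo$end_a[e + 1L]
        b <- geo$end_b[e + 1L]
        if (a != b) {
          node[m] <- if (runif(1) < 0.5) a else b
        } else {
          node[m] <- a
        }
        state[m] <- "U"
        tstart[m] <- step
        release[m] <- Inf
        edge[m] <- NA_integer_
      } else if (state[m] == "W") {
        state[m] <- "U"
        release[m] <- Inf
      }
    }
    frac <- n_deg / E
    if (step %% rec == 0) {
      rec_time <- c(rec_time, step * dt)
      rec_frac <- c(rec_frac, frac)
      if (n_deg == E) break
    }
    if (step >= max_step) break

    # movement
    for (m in seq_len(n_tpa)) {
      if (state[m] %in% c("U", "W")) {
        dir <- min(floor(runif(1) * 4), 3)
        i <- node[m] %% nx
        j <- node[m] %/% nx
        if (dir == 0 && i < nx - 1) i <- i + 1
        else if (dir == 1 && i > 0) i <- i - 1
        else if (dir == 2 && j < ny - 1) j <- j + 1
        else if (dir == 3 && j > 0) j <- j - 1
        node[m] <- i + j * nx
      } else if (state[m] == "L") {
        cand <- adj_degraded(edge[m])
        if (length(cand)) {
          pick <- min(floor(runif(1) * length(cand)), length(cand) - 1)
          edge[m] <- cand[pick + 1L]
        }
      }
    }
    # binding
    for (m in seq_len(n_tpa)) {
      if (state[m] != "U") next
      cand <- geo$incident[[node[m] + 1L]]
      cand <- cand[intact[cand + 1L]]
      k <- length(cand)
      if (k == 0L) next
      if (bind_prob < 1 && runif(1) >= bind_prob) next
      pick <- min(floor(runif(1) * k), k - 1)
      e <- cand[pick + 1L]
      state[m] <- "B"
      edge[m] <- e
      if (!is.na(tstart[m])) {
        tr[[length(tr) + 1L]] <- c(m, tstart[m] * dt, (step + 1) * dt)
      }
      tstart[m] <- NA_real_
      t_u <- oracle_draw_unbind(kin)
      release[m] <- (step + 1) + oracle_ceil_steps(t_u, dt)
      forced[m] <- runif(1) < kin$forced_unbind_prob
      t_l <- oracle_draw_lysis(kin)
      if (is.finite(t_l)) {
        dstep <- (step + 1) + oracle_ceil_steps(t_l, dt)
        if (dstep < edge_sched[e + 1L]) edge_sched[e + 1L] <- dstep
      }
    }
    step <- step + 1
  }

  transits <- if (length(tr)) do.call(rbind, tr) else matrix(numeric(), ncol = 3)
  list(
    record_time = rec_time,
    record_frac = rec_frac,
    edge_degrade_time = edge_time,
    transits = transits,
    final_state = state,
    final_node = node + 1L,
    final_edge = ifelse(is.na(edge), NA_integer_, edge + 1L)
  )
}

# helper: kinetics with a single deterministic unbind/lysis time, expressed
# through the empirical interface (degenerate one-sample CDFs)
degenerate_kinetics <- function(fiber_diameter = 72.7, unbind_s, lysis_s,
                                forced_unbind_prob = 1e-12) {
  path_u <- tempfile(fileext = ".tsv")
  writeLines(c("unbind_time_s\tlysis_time_s",
               paste(unbind_s, ifelse(is.finite(lysis_s), lysis_s, "inf"),
                     sep = "\t")),
             path_u)
  load_kinetics(path_u, fiber_diameter,
                forced_unbind_prob = forced_unbind_prob)
}
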