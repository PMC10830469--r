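#' Number of edges of the model lattice
#'
#' The clot is a 3D square lattice one fiber thick in the out-of-plane
#' dimension: every node carries one out-of-plane (z) fiber, and in-plane
#' fibers join 4-neighbour nodes. The edge count is
#' `ny*(nx-1) + nx*(ny-1) + nx*ny = 3*nx*ny - nx - ny`.
#'
#' @param nx,ny Node counts in the two in-plane dimensions. Vectorised.
#' @return Integer edge count(s).
#' @examples
#' lattice_edge_count(93, 93) # 25761, the thin/loose clot
#' @export
lattice_edge_count <- function(nx, ny) {
  as.integer(3 * as.numeric(nx) * as.numeric(ny) - as.numeric(nx) - as.numeric(ny))
}

#' Build the model clot lattice
#'
#' Constructs the fibrin network: a 3D square lattice one fiber thick
#' out-of-plane, with reflecting boundaries in the two in-plane dimensions
#' and periodic boundaries out-of-plane (so an out-of-plane hop returns to
#' the same node and molecule motion is effectively in-plane). Each lattice
#' edge represents one fibrin fiber and is intact at construction.
#'
#' Nodes are indexed `(i, j)` with `i` in `0..nx-1`, `j` in `0..ny-1`.
#' Edges are ordered x-edges first (`(i,j)-(i+1,j)`), then y-edges
#' (`(i,j)-(i,j+1)`), then one z-edge per node; this ordering is shared with
#' the simulation engine.
#'
#' @param spec A [scenario_spec()], or `NULL` to give `nx`, `ny`, `spacing`
#'   directly.
#' @param nx,ny Node counts (used when `spec` is `NULL`).
#' @param spacing Lattice spacing (pore size), um.
#' @return An object of class `lattice_clot`: list with `nx`, `ny`,
#'   `spacing`, an `edges` tibble (`edge`, `orientation`, `i`, `j`) and a
#'   logical `intact` vector.
#' @examples
#' clot <- build_lattice(nx = 4, ny = 4, spacing = 1)
#' nrow(clot$edges)
#' @export
build_lattice <- function(spec = NULL, nx = NULL, ny = NULL, spacing = 1) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "scenario_spec"))
    nx <- spec$grid_nx
    ny <- spec$grid_ny
    spacing <- spec$pore_size
  }
  nx <- as.integer(nx)
  ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 1L || ny < 1L) {
    stop("grid dimensions must be positive integers", call. = FALSE)
  }
  if (!is.numeric(spacing) || spacing <= 0) {
    stop("`spacing` must be positive", call. = FALSE)
  }
  ex <- if (nx > 1L) {
    tibble::tibble(
      orientation = "x",
      i = rep(0:(nx - 2L), times = ny),
      j = rep(0:(ny - 1L), each = nx - 1L)
    )
  } else {
    tibble::tibble(orientation = character(), i = integer(), j = integer())
  }
  ey <- if (ny > 1L) {
    tibble::tibble(
      orientation = "y",
      i = rep(0:(nx - 1L), times = ny - 1L),
      j = rep(0:(ny - 2L), each = nx)
    )
  } else {
    tibble::tibble(orientation = character(), i = integer(), j = integer())
  }
  ez <- tibble::tibble(
    orientation = "z",
    i = rep(0:(nx - 1L), times = ny),
    j = rep(0:(ny - 1L), each = nx)
  )
  edges <- dplyr::bind_rows(ex, ey, ez)
  edges$edge <- seq_len(nrow(edges))
  edges <- edges[, c("edge", "orientation", "i", "j")]
  stopifnot(nrow(edges) == lattice_edge_count(nx, ny))
  structure(
    list(
      nx = nx, ny = ny, spacing = spacing,
      edges = edges,
      intact = rep(TRUE, nrow(edges)),
      boundary = c(in_plane = "reflecting", out_of_plane = "periodic")
    ),
    class = "lattice_clot"
  )
}

#' @export
print.lattice_clot <- function(x, ...) {
  cat(sprintf(
    "<lattice_clot> %d x %d nodes, spacing %.4g um, %d edges (%d intact)\n",
    x$nx, x$ny, x$spacing, length(x$intact), sum(x$intact)
  ))
  invisible(x)
}

#' Mark edges of a lattice as degraded
#'
#' @param clot A [build_lattice()] object.
#' @param edges Integer edge indices to degrade.
#' @return The updated `lattice_clot`.
#' @export
degrade_edges <- function(clot, edges) {
  stopifnot(inherits(clot, "lattice_clot"))
  edges <- as.integer(edges)
  if (any(is.na(edges)) || any(edges < 1L) || any(edges > length(clot$intact))) {
    stop("edge indices out of range", call. = FALSE)
  }
  clot$intact[edges] <- FALSE
  clot
}

# Gaps (in units of the lattice spacing) along one scan line with intact
# pattern `v`. Gaps lie between consecutive intact crossings; a run of
# degraded crossings bounded by intact ones of length k contributes k + 1
# spacings, and runs touching the clot boundary are truncated there. On a
# fully intact line every gap is one spacing.
line_gaps <- function(v) {
  m <- length(v)
  idx <- which(v)
  if (length(idx) == 0L) {
    return(m + 1)
  }
  c(idx[1L], diff(idx), m - idx[length(idx)] + 1L)
}

#' Measure the pore-size profile of a (partially degraded) lattice
#'
#' Traverses evenly spaced horizontal and vertical scan lines across the
#' clot and records the distance between intact fibers. A horizontal line
#' runs between two node rows and crosses the perpendicular (y-oriented)
#' in-plane edges of that row gap; a vertical line runs between two node
#' columns and crosses the x-oriented edges. Out-of-plane (z) fibers do not
#' intersect in-plane scan lines and are excluded. Each gap between
#' consecutive intact crossings contributes `(k + 1) * spacing` where `k`
#' is the number of consecutive degraded crossings between them; runs that
#' touch the clot boundary are measured to the boundary.
#'
#' @param clot A [build_lattice()] object, possibly with degraded edges.
#' @return An object of class `pore_profile`: list with a `gaps` tibble
#'   (`line_type`, `line_index`, `gap_um`), `mean_gap` (um), `n_gaps` and
#'   `percent_change` relative to the intact spacing.
#' @examples
#' clot <- build_lattice(nx = 5, ny = 5, spacing = 1)
#' measure_pores(clot)$mean_gap # 1 on an intact lattice
#' @export
measure_pores <- function(clot) {
  stopifnot(inherits(clot, "lattice_clot"))
  nx <- clot$nx
  ny <- clot$ny
  e <- clot$edges
  intact <- clot$intact
  gap_list <- list()

  # horizontal lines: between rows j and j+1, crossing the nx y-edges there
  if (ny > 1L) {
    ysel <- e$orientation == "y"
    yi <- e$i[ysel]
    yj <- e$j[ysel]
    yint <- intact[ysel]
    for (j in 0:(ny - 2L)) {
      row <- yint[yj == j][order(yi[yj == j])]
      g <- line_gaps(row)
      gap_list[[length(gap_list) + 1L]] <- tibble::tibble(
        line_type = "horizontal", line_index = j, gap_um = g * clot$spacing
      )
    }
  }
  # vertical lines: between columns i and i+1, crossing the ny x-edges there
  if (nx > 1L) {
    xsel <- e$orientation == "x"
    xi <- e$i[xsel]
    xj <- e$j[xsel]
    xint <- intact[xsel]
    for (i in 0:(nx - 2L)) {
      col <- xint[xi == i][order(xj[xi == i])]
      g <- line_gaps(col)
      gap_list[[length(gap_list) + 1L]] <- tibble::tibble(
        line_type = "vertical", line_index = i, gap_um = g * clot$spacing
      )
    }
  }
  if (length(gap_list) == 0L) {
    stop("lattice has no scan-line crossings (needs nx > 1 or ny > 1)",
         call. = FALSE)
  }
  gaps <- dplyr::bind_rows(gap_list)
  mean_gap <- mean(gaps$gap_um)
  structure(
    list(
      gaps = gaps,
      mean_gap = mean_gap,
      n_gaps = nrow(gaps),
      percent_change = 100 * (mean_gap - clot$spacing) / clot$spacing,
      spacing = clot$spacing
    ),
    class = "pore_profile"
  )
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf(
    "<pore_profile> mean gap %.4g um over %d gaps (%+.1f%% vs intact)\n",
    x$mean_gap, x$n_gaps, x$percent_change
  ))
  invisible(x)
}
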