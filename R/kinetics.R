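CANONICAL_FORCED_UNBIND <- c("72.7" = 0.0852, "145.4" = 0.0729129)
DEFAULT_KOFF <- 0.036 # 1/k_off is the small-FDP waiting time, ~27.78 s

new_kinetics_model <- function(fiber_diameter, type, unbind, lysis,
                               mean_unbind_s, mean_lysis_s, lysis_prob,
                               forced_unbind_prob, koff) {
  if (is.null(forced_unbind_prob)) {
    forced_unbind_prob <-
      unname(CANONICAL_FORCED_UNBIND[as.character(fiber_diameter)])
    if (is.na(forced_unbind_prob)) {
      stop("no canonical forced-unbinding probability for diameter ",
           fiber_diameter, " nm; supply `forced_unbind_prob` explicitly",
           call. = FALSE)
    }
  }
  if (forced_unbind_prob <= 0 || forced_unbind_prob >= 1) {
    stop("`forced_unbind_prob` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      fiber_diameter = fiber_diameter,
      type = type,
      unbind = unbind,
      lysis = lysis,
      mean_unbind_s = mean_unbind_s,
      mean_lysis_s = mean_lysis_s,
      lysis_prob = lysis_prob,
      forced_unbind_prob = forced_unbind_prob,
      koff_wait = 1 / koff
    ),
    class = "kinetics_model"
  )
}

#' Parametric single-fiber kinetics surrogate
#'
#' Single-fiber kinetics drive the clot-scale simulation: every binding
#' event draws an unbinding time (how long the tPA molecule stays attached)
#' and a lysis time (when, or whether, that initiation degrades the fiber).
#' The reference source for these draws is an empirical CDF generated by a
#' detailed microscale model of a single fiber cross-section (see
#' [load_kinetics()]); this function provides a parametric stand-in when no
#' such files are available: exponential unbinding and lysis-time
#' distributions with the given means, each initiation lytic with
#' probability `lysis_prob` (otherwise censored, i.e. the fiber never
#' degrades from that initiation).
#'
#' The forced-unbinding probability q (the chance that an initiation ejects
#' the tPA onto a small fibrin degradation product instead of letting it
#' kinetically unbind) and the small-FDP waiting time 1/k_off are physical
#' constants of the model: q = 0.0852 for 72.7 nm fibers, 0.0729129 for
#' 145.4 nm fibers, and k_off = 0.036 so 1/k_off ~ 27.78 s.
#'
#' The default means are uncalibrated surrogates chosen on physical grounds
#' (see the methods vignette): mean unbinding 1/k_off, mean lysis 50 s for
#' thin and 100 s for thick fibers.
#'
#' @param fiber_diameter Fiber diameter in nm; 72.7 and 145.4 carry
#'   canonical q values, other diameters need `forced_unbind_prob`.
#' @param mean_unbind_s Mean kinetic unbinding time, s.
#' @param mean_lysis_s Mean single-fiber lysis time, s. Default 50 s below
#'   100 nm diameter, 100 s above.
#' @param lysis_prob Probability that an initiation is lytic, in (0, 1].
#' @param forced_unbind_prob Override for q (required for non-canonical
#'   diameters).
#' @param koff Unbinding rate constant; only 1/koff (the waiting time on a
#'   small FDP, seconds) is used.
#' @return A `kinetics_model` object.
#' @examples
#' default_kinetics(72.7)$forced_unbind_prob # 0.0852
#' @export
default_kinetics <- function(fiber_diameter,
                             mean_unbind_s = 1 / DEFAULT_KOFF,
                             mean_lysis_s = NULL,
                             lysis_prob = 1,
                             forced_unbind_prob = NULL,
                             koff = DEFAULT_KOFF) {
  if (is.null(mean_lysis_s)) {
    mean_lysis_s <- if (fiber_diameter < 100) 50 else 100
  }
  if (mean_unbind_s <= 0 || mean_lysis_s <= 0) {
    stop("mean times must be positive", call. = FALSE)
  }
  if (lysis_prob <= 0 || lysis_prob > 1) {
    stop("`lysis_prob` must lie in (0, 1]", call. = FALSE)
  }
  new_kinetics_model(
    fiber_diameter = fiber_diameter, type = "exponential",
    unbind = numeric(), lysis = numeric(),
    mean_unbind_s = mean_unbind_s, mean_lysis_s = mean_lysis_s,
    lysis_prob = lysis_prob, forced_unbind_prob = forced_unbind_prob,
    koff = koff
  )
}

#' Load empirical single-fiber kinetics from a sample file
#'
#' Reads microscale-model output samples: a plain-text file with a header
#' row naming the columns (`unbind_time_s`, `lysis_time_s`) and one numeric
#' sample per line. Censored lysis outcomes (initiations from which the
#' fiber never degrades) are encoded with the sentinel `inf`. Sampling from
#' the resulting model uses inverse-transform sampling on the sorted
#' samples with linear interpolation between order statistics.
#'
#' @param path Path to the sample file (whitespace- or tab-separated).
#' @param fiber_diameter Fiber diameter the samples belong to, nm.
#' @param forced_unbind_prob,koff See [default_kinetics()].
#' @return A `kinetics_model` object with `type = "empirical"`.
#' @examples
#' # a small synthetic sample file ships with the package
#' path <- system.file("extdata", "kinetics_thin_synthetic.tsv",
#'                     package = "porelysis")
#' load_kinetics(path, fiber_diameter = 72.7)
#' @export
load_kinetics <- function(path, fiber_diameter,
                          forced_unbind_prob = NULL, koff = DEFAULT_KOFF) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2L) {
    stop("kinetics file ", path, ": needs a header row and at least one sample",
         call. = FALSE)
  }
  header <- strsplit(trimws(lines[1L]), "[\t ,]+")[[1L]]
  allowed <- c("unbind_time_s", "lysis_time_s")
  if (!all(header %in% allowed) || anyDuplicated(header)) {
    stop("kinetics file ", path, ": header must name distinct columns among ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  cols <- stats::setNames(rep(list(numeric()), length(header)), header)
  for (ln in seq.int(2L, length(lines))) {
    fields <- strsplit(trimws(lines[ln]), "[\t ,]+")[[1L]]
    if (length(fields) > length(header)) {
      stop("kinetics file ", path, ", line ", ln, ": more fields than columns",
           call. = FALSE)
    }
    for (k in seq_along(fields)) {
      tok <- fields[k]
      if (tok %in% c("", "NA")) next
      if (tolower(tok) %in% c("inf", "+inf", "infinity")) {
        if (header[k] != "lysis_time_s") {
          stop("kinetics file ", path, ", line ", ln,
               ": censoring sentinel only allowed in lysis_time_s",
               call. = FALSE)
        }
        val <- Inf
      } else {
        val <- suppressWarnings(as.numeric(tok))
        if (is.na(val)) {
          stop("kinetics file ", path, ", line ", ln,
               ": unreadable token '", tok, "'", call. = FALSE)
        }
        if (val < 0) {
          stop("kinetics file ", path, ", line ", ln,
               ": negative sample ", val, call. = FALSE)
        }
      }
      cols[[header[k]]] <- c(cols[[header[k]]], val)
    }
  }
  unbind <- sort(cols[["unbind_time_s"]])
  lysis <- sort(cols[["lysis_time_s"]])
  if (!length(unbind) && !length(lysis)) {
    stop("kinetics file ", path, ": no samples found", call. = FALSE)
  }
  new_kinetics_model(
    fiber_diameter = fiber_diameter, type = "empirical",
    unbind = unbind, lysis = lysis,
    mean_unbind_s = if (length(unbind)) mean(unbind) else NA_real_,
    mean_lysis_s = if (length(lysis)) mean(lysis[is.finite(lysis)]) else NA_real_,
    lysis_prob = if (length(lysis)) mean(is.finite(lysis)) else NA_real_,
    forced_unbind_prob = forced_unbind_prob, koff = koff
  )
}

#' @export
print.kinetics_model <- function(x, ...) {
  cat(sprintf(
    "<kinetics_model> %s, fiber %.1f nm\n  q (forced unbind) %.5g | 1/k_off %.4g s\n",
    x$type, x$fiber_diameter, x$forced_unbind_prob, x$koff_wait
  ))
  if (x$type == "empirical") {
    cat(sprintf("  %d unbind samples | %d lysis samples (%.1f%% lytic)\n",
                length(x$unbind), length(x$lysis), 100 * x$lysis_prob))
  } else {
    cat(sprintf("  exponential: mean unbind %.4g s | mean lysis %.4g s | lytic prob %.3g\n",
                x$mean_unbind_s, x$mean_lysis_s, x$lysis_prob))
  }
  invisible(x)
}

# Inverse-transform sample at uniform variates `u` from sorted samples `x`
# with linear interpolation between order statistics: h = u*(n-1), value
# interpolates x[floor(h)+1] and x[floor(h)+2]. Interpolation involving the
# censoring sentinel Inf yields Inf. Same convention as the C++ engine.
empirical_inverse <- function(x, u) {
  n <- length(x)
  if (n == 0L) stop("no samples to draw from", call. = FALSE)
  if (n == 1L) return(rep(x, length(u)))
  h <- u * (n - 1)
  lo <- pmin(floor(h), n - 2)
  frac <- h - lo
  a <- x[lo + 1]
  b <- x[lo + 2]
  out <- a + frac * (b - a)
  # censored sentinels: interpolation touching Inf is Inf (never NaN), and
  # a draw landing exactly on a finite order statistic keeps its value
  out[frac == 0] <- a[frac == 0]
  out[is.infinite(a) | (frac > 0 & is.infinite(b))] <- Inf
  out
}

#' Draw single-fiber kinetic times
#'
#' `sample_unbind_time()` draws tPA unbinding times; `sample_lysis_time()`
#' draws fiber lysis times, returning `Inf` for censored (never-lysing)
#' initiations. Draws consume R's global random number stream, so a prior
#' `set.seed()` makes them reproducible. Empirical models use
#' inverse-transform sampling with linear interpolation between order
#' statistics; exponential models invert the exponential CDF
#' (`-mean * log(1 - u)`). For parametric models with `lysis_prob < 1` a
#' censoring uniform is drawn first and the lysis time only if the
#' initiation is lytic.
#'
#' @param model A `kinetics_model`.
#' @param n Number of draws.
#' @return Numeric vector of times in seconds (`Inf` = censored).
#' @export
sample_unbind_time <- function(model, n = 1) {
  stopifnot(inherits(model, "kinetics_model"))
  u <- stats::runif(n)
  if (model$type == "empirical") {
    empirical_inverse(model$unbind, u)
  } else {
    -model$mean_unbind_s * log1p(-u)
  }
}

#' @rdname sample_unbind_time
#' @export
sample_lysis_time <- function(model, n = 1) {
  stopifnot(inherits(model, "kinetics_model"))
  if (model$type == "empirical") {
    empirical_inverse(model$lysis, stats::runif(n))
  } else {
    out <- numeric(n)
    for (k in seq_len(n)) {
      lytic <- model$lysis_prob >= 1 || stats::runif(1) < model$lysis_prob
      out[k] <- if (lytic) -model$mean_lysis_s * log1p(-stats::runif(1)) else Inf
    }
    out
  }
}
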