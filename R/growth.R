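#' Default specific lactate production rate (pmol/cell/day)
#'
#' Literature-typical value for cultured HEK-lineage cells, shipped as an
#' overridable package default for the lactate-based growth estimator. This
#' is a modelling constant, not a measured study value.
#'
#' @export
DEFAULT_Q_LAC <- 5

#' Default specific metabolic rates (pmol/cell/day)
#'
#' Signed per-cell daily rates for the four tracked analytes: negative values
#' are consumed (glucose, glutamine), positive produced (lactate, ammonium).
#' Typical-magnitude defaults for mammalian perfusion culture; overridable
#' everywhere they are used.
#'
#' @return Named numeric vector (`glucose`, `lactate`, `glutamine`,
#'   `ammonium`).
#' @export
default_metabolic_rates <- function() {
  c(glucose = -6, lactate = DEFAULT_Q_LAC, glutamine = -1.0, ammonium = 0.5)
}

#' Default feed-media concentrations (mM)
#'
#' Fresh-media analyte concentrations used as the perfusion feed: glucose-rich,
#' glutamine-supplemented, lactate- and ammonium-free.
#'
#' @return Named numeric vector.
#' @export
default_feed_concentrations <- function() {
  c(glucose = 25, lactate = 0, glutamine = 4, ammonium = 0)
}

ANALYTES <- c("glucose", "lactate", "glutamine", "ammonium")

#' Metabolite time series under perfusion
#'
#' Daily (or finer) measurements of glucose, lactate, glutamine and ammonium
#' in a perfused, well-mixed culture volume, together with the per-interval
#' media feed rate.
#'
#' @param times Strictly increasing sampling times (days from seeding).
#' @param glucose,lactate,glutamine,ammonium Concentrations (mM); `NA` marks
#'   a missed measurement.
#' @param perfusion_rate Media feed rate per time point (mL/day), scalar or
#'   vector.
#' @param system_volume_mL Total well-mixed media volume (mL).
#' @return Object of class `metabolite_series`: a data.frame with one row per
#'   time point and attribute `system_volume_mL`.
#' @export
metabolite_series <- function(times, glucose = NA_real_, lactate = NA_real_,
                              glutamine = NA_real_, ammonium = NA_real_,
                              perfusion_rate = 0, system_volume_mL) {
  n <- length(times)
  if (n < 1) stop("times must be non-empty")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.finite(system_volume_mL) || system_volume_mL <= 0) {
    stop("system_volume_mL must be > 0")
  }
  df <- data.frame(time = as.numeric(times),
                   glucose = rep_len(glucose, n),
                   lactate = rep_len(lactate, n),
                   glutamine = rep_len(glutamine, n),
                   ammonium = rep_len(ammonium, n),
                   perfusion_rate = rep_len(perfusion_rate, n))
  for (a in ANALYTES) {
    if (any(df[[a]] < 0, na.rm = TRUE)) stop(a, " concentrations must be >= 0")
  }
  if (any(df$perfusion_rate < 0)) stop("perfusion_rate must be >= 0")
  structure(df, system_volume_mL = as.numeric(system_volume_mL),
            class = c("metabolite_series", "data.frame"))
}

# pmol -> umol; concentrations are mM = umol/mL
PMOL_PER_UMOL <- 1e6

#' Estimate viable cells from lactate accumulation under perfusion
#'
#' Well-mixed washout mass balance: over each sampling interval the lactate
#' production rate is `P = V * dC/dt + Q * (C - feed_lactate)` (chemostat
#' balance: accumulation plus net washout), and the viable cell number is
#' `P / q_lac`. This reconstructs, from first principles, the kind of
#' lactate-and-perfusion-rate growth prediction used for hollow-fiber
#' cultures; it is a mass-balance model, not any vendor's proprietary
#' algorithm.
#'
#' Differencing is forward (left-endpoint) by default, the exact discrete
#' inverse of the package simulator's explicit update; `"centered"` trades
#' that exactness for noise averaging on real data. Intervals touching a
#' missing (`NA`) lactate value yield `NA` cells.
#'
#' @param series A [metabolite_series()] with a lactate column.
#' @param q_lac Specific lactate production rate (pmol/cell/day), > 0.
#' @param feed_lactate Lactate concentration of the feed media (mM),
#'   default 0 (fresh media).
#' @param diff `"forward"` (default) or `"centered"` differencing.
#' @param smooth_window Optional odd moving-average window applied to the
#'   estimated cell series (0 = no smoothing).
#' @return Object of class `growth_estimate` with `times`, `cells`
#'   (floored at 0), `q_lac` and `method`.
#' @export
estimate_cells_from_lactate <- function(series, q_lac = DEFAULT_Q_LAC,
                                        feed_lactate = 0,
                                        diff = c("forward", "centered"),
                                        smooth_window = 0) {
  diff <- match.arg(diff)
  if (!is.finite(q_lac) || q_lac <= 0) stop("q_lac must be > 0")
  n <- nrow(series)
  if (n < 2) stop("insufficient data: at least two time points required")
  V <- attr(series, "system_volume_mL")
  t <- series$time
  C <- series$lactate
  Q <- series$perfusion_rate
  if (diff == "forward") {
    i <- seq_len(n - 1)
    dCdt <- (C[i + 1] - C[i]) / (t[i + 1] - t[i])
    P <- V * dCdt + Q[i] * (C[i] - feed_lactate)   # umol/day
    est_t <- t[i]
  } else {
    dCdt <- numeric(n)
    dCdt[1] <- (C[2] - C[1]) / (t[2] - t[1])
    dCdt[n] <- (C[n] - C[n - 1]) / (t[n] - t[n - 1])
    if (n > 2) {
      m <- 2:(n - 1)
      dCdt[m] <- (C[m + 1] - C[m - 1]) / (t[m + 1] - t[m - 1])
    }
    P <- V * dCdt + Q * (C - feed_lactate)
    est_t <- t
  }
  cells <- pmax(0, P / q_lac * PMOL_PER_UMOL)
  if (smooth_window > 1) {
    w <- as.integer(smooth_window)
    if (w %% 2 == 0) stop("smooth_window must be odd")
    sm <- stats::filter(cells, rep(1 / w, w), sides = 2)
    cells <- ifelse(is.na(sm), cells, as.numeric(sm))
  }
  structure(list(times = est_t, cells = cells, q_lac = q_lac,
                 method = paste0("lactate mass balance (", diff, ")")),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("Growth estimate from lactate balance (q_lac = %.2f pmol/cell/day)\n",
              x$q_lac))
  cat(sprintf("  %d time points, final estimate %.3g cells\n",
              length(x$times), x$cells[length(x$cells)]))
  invisible(x)
}

#' @export
plot.growth_estimate <- function(x, ...) {
  plot(x$times, x$cells, type = "b", xlab = "day", ylab = "estimated cells",
       main = "Lactate-balance growth estimate", ...)
  invisible(x)
}

#' Simulate perfusion metabolite time courses
#'
#' Explicit forward difference-equation integration of a well-mixed perfused
#' volume: per interval, each analyte changes by its cell-specific
#' production/consumption (signed rate x cells / volume) plus perfusion
#' dilution toward the feed concentration. Concentrations are clamped at 0;
#' Gaussian measurement noise, when requested, is added last.
#'
#' @param growth_curve data.frame with columns `time` (days) and `cells`.
#' @param rates Named signed specific rates (pmol/cell/day); defaults from
#'   [default_metabolic_rates()].
#' @param perfusion_rate Feed rate (mL/day), scalar or per time point.
#' @param feed Named feed concentrations (mM); defaults from
#'   [default_feed_concentrations()].
#' @param volume_mL Well-mixed system volume (mL).
#' @param initial Named initial concentrations (mM); defaults to the feed.
#' @param noise_sd Gaussian measurement noise SD (mM), scalar or named per
#'   analyte; 0 disables.
#' @param seed RNG seed, required when `noise_sd > 0`.
#' @return A [metabolite_series()].
#' @export
simulate_metabolites <- function(growth_curve, rates = default_metabolic_rates(),
                                 perfusion_rate = 0,
                                 feed = default_feed_concentrations(),
                                 volume_mL = 2000, initial = NULL,
                                 noise_sd = 0, seed = NULL) {
  if (!all(c("time", "cells") %in% names(growth_curve))) {
    stop("growth_curve needs 'time' and 'cells' columns")
  }
  if (!is.finite(volume_mL) || volume_mL <= 0) stop("volume_mL must be > 0")
  if (any(!is.finite(rates))) stop("rates must be finite")
  t <- growth_curve$time
  N <- growth_curve$cells
  n <- length(t)
  Q <- rep_len(perfusion_rate, n)
  if (any(Q < 0)) stop("perfusion_rate must be >= 0")
  if (is.null(initial)) initial <- feed
  noise <- if (length(noise_sd) == 1) {
    stats::setNames(rep(noise_sd, 4), ANALYTES)
  } else noise_sd
  conc <- matrix(NA_real_, n, 4, dimnames = list(NULL, ANALYTES))
  conc[1, ] <- initial[ANALYTES]
  for (i in seq_len(n - 1)) {
    dt <- t[i + 1] - t[i]
    for (a in ANALYTES) {
      prod <- rates[[a]] * N[i] / PMOL_PER_UMOL / volume_mL      # mM/day
      dil <- (Q[i] / volume_mL) * (conc[i, a] - feed[[a]])
      conc[i + 1, a] <- max(0, conc[i, a] + dt * (prod - dil))
    }
  }
  if (any(noise > 0)) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    set.seed(seed)
    for (a in ANALYTES) {
      # measured concentrations cannot be negative, so clamp after noise too
      conc[, a] <- pmax(0, conc[, a] + stats::rnorm(n, 0, noise[[a]]))
    }
  }
  metabolite_series(times = t, glucose = conc[, "glucose"],
                    lactate = conc[, "lactate"],
                    glutamine = conc[, "glutamine"],
                    ammonium = conc[, "ammonium"],
                    perfusion_rate = Q, system_volume_mL = volume_mL)
}

#' Read a metabolite series from CSV
#'
#' Expected columns: `day`, `glucose_mM`, `lactate_mM`, `glutamine_mM`,
#' `ammonium_mM`, `perfusion_mL_per_day`, and either a constant
#' `system_volume_mL` column or the volume given as an argument.
#'
#' @param path CSV path.
#' @param system_volume_mL Volume override (mL); required when the file has
#'   no volume column.
#' @return A [metabolite_series()].
#' @export
read_metabolite_csv <- function(path, system_volume_mL = NULL) {
  df <- utils::read.csv(path)
  if (is.null(system_volume_mL)) {
    if (!("system_volume_mL" %in% names(df))) {
      stop("system_volume_mL column or argument required")
    }
    system_volume_mL <- df$system_volume_mL[1]
  }
  metabolite_series(times = df$day, glucose = df$glucose_mM,
                    lactate = df$lactate_mM, glutamine = df$glutamine_mM,
                    ammonium = df$ammonium_mM,
                    perfusion_rate = df$perfusion_mL_per_day,
                    system_volume_mL = system_volume_mL)
}

#' Write a metabolite series to CSV
#'
#' @param series A [metabolite_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metabolite_csv <- function(series, path) {
  df <- data.frame(day = series$time,
                   glucose_mM = series$glucose,
                   lactate_mM = series$lactate,
                   glutamine_mM = series$glutamine,
                   ammonium_mM = series$ammonium,
                   perfusion_mL_per_day = series$perfusion_rate,
                   system_volume_mL = attr(series, "system_volume_mL"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
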