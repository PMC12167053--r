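#' Units required to hit a target output
#'
#' Smallest integer number of vessels/systems whose crude yield, after the
#' compounded downstream recovery, meets the requested post-DSP vector-genome
#' output. The downstream recovery is a single end-to-end scalar (default
#' assumption 30% from harvested lysate through to drug-product formulation).
#'
#' @param target_vg Requested post-DSP vector genomes (>= 0).
#' @param per_unit_yield_vg Expected crude vector genomes per unit (> 0).
#' @param dsp_recovery End-to-end downstream recovery fraction in (0, 1].
#' @return Integer unit count, the smallest `n` with
#'   `n * per_unit_yield_vg * dsp_recovery >= target_vg`.
#' @examples
#' required_units(1e14, 2.45e13, 0.30)  # 14 CellSTACK-10 units
#' @export
required_units <- function(target_vg, per_unit_yield_vg, dsp_recovery) {
  if (!is.finite(per_unit_yield_vg) || per_unit_yield_vg <= 0) {
    stop("per_unit_yield_vg must be > 0")
  }
  if (!is.finite(dsp_recovery) || dsp_recovery <= 0 || dsp_recovery > 1) {
    stop("dsp_recovery must be in (0, 1]")
  }
  if (!is.finite(target_vg) || target_vg < 0) stop("target_vg must be >= 0")
  if (target_vg == 0) return(0L)
  eff <- per_unit_yield_vg * dsp_recovery
  # relative float tolerance so exact integer multiples resolve exactly
  tol <- 1 - 1e-12
  n <- ceiling(target_vg / eff * tol)
  while (n > 0 && (n - 1) * eff >= target_vg * tol) n <- n - 1
  if (n * eff < target_vg * tol) n <- n + 1
  as.integer(n)
}

#' Doses obtainable from a batch
#'
#' Whole doses formulated from a crude batch after downstream recovery, at a
#' fixed vector-genome dose size.
#'
#' @param total_vg Crude vector genomes in the batch.
#' @param dsp_recovery Downstream recovery fraction.
#' @param dose_vg Vector genomes per dose (> 0).
#' @return Integer dose count, `floor(total_vg * dsp_recovery / dose_vg)`.
#' @examples
#' doses_from_batch(6.81e13, 0.30, 1.5e11)  # 136 doses at an ocular dose size
#' @export
doses_from_batch <- function(total_vg, dsp_recovery, dose_vg) {
  if (!is.finite(dose_vg) || dose_vg <= 0) stop("dose_vg must be > 0")
  x <- total_vg * dsp_recovery / dose_vg
  n <- floor(x)
  if (x - n > 1 - 1e-9) n <- n + 1  # float guard for exact multiples
  as.integer(n)
}

# Resource demand of running n units of a platform in one production.
production_resources <- function(n, platform, facility) {
  mscs <- if (platform$units_per_msc_session > 0) {
    ceiling(n / platform$units_per_msc_session)
  } else 0
  incubators <- if (platform$units_per_incubator > 0) {
    ceiling(n / platform$units_per_incubator)
  } else 0
  operators <- if (platform$operators_per_production > 0) {
    platform$operators_per_production
  } else if (platform$systems_per_operator_pair > 0) {
    2 * ceiling(n / platform$systems_per_operator_pair)
  } else {
    facility$operators_per_msc * mscs
  }
  area <- n * platform$footprint_m2 +
    mscs * facility$msc_footprint_m2 +
    incubators * facility$incubator_footprint_m2 +
    operators * facility$operator_space_m2
  list(mscs = mscs, incubators = incubators, operators = operators, area = area)
}

# Which constraints fail for n units in one production; empty means feasible.
production_violations <- function(n, platform, facility) {
  r <- production_resources(n, platform, facility)
  v <- character()
  if (r$mscs > facility$max_mscs) v <- c(v, "MSC capacity")
  if (r$area > facility$area_m2) v <- c(v, "facility area")
  v
}

# Max units a single production can hold (0 if even one unit is infeasible).
production_capacity <- function(platform, facility, upper) {
  cap <- 0L
  for (n in seq_len(upper)) {
    if (length(production_violations(n, platform, facility))) break
    cap <- n
  }
  cap
}

#' Split a batch into facility-feasible productions
#'
#' Greedy packing: each production takes the maximum unit count that
#' simultaneously satisfies the facility-area constraint (equipment
#' footprints + MSC/incubator footprints + reserved operator space), the MSC
#' throughput cap, and the staffing rule. Productions within a batch run
#' sequentially in the same facility, so calendar time multiplies with the
#' production count.
#'
#' @param units Total vessel/system count for the batch (>= 0).
#' @param platform A [platform_spec()].
#' @param process The platform's [process_definition()].
#' @param facility A [facility_config()].
#' @return An object of class `batch_plan` with fields `platform`,
#'   `units_required`, `productions` (data.frame: production, units, days),
#'   `total_days`, `operators_assigned`, `mscs_used`, `incubators_used`,
#'   `area_used_m2` (peak concurrent area).
#' @export
plan_batches <- function(units, platform, process, facility) {
  units <- as.integer(units)
  if (is.na(units) || units < 0) stop("units must be >= 0")
  dur <- process$batch_duration_days
  if (units == 0) {
    return(structure(list(
      platform = platform$name, units_required = 0L,
      productions = data.frame(production = integer(), units = integer(),
                               days = integer()),
      total_days = 0L, operators_assigned = 0L, mscs_used = 0L,
      incubators_used = 0L, area_used_m2 = 0), class = "batch_plan"))
  }
  cap <- production_capacity(platform, facility, units)
  if (cap == 0L) {
    v <- production_violations(1L, platform, facility)
    stop(sprintf("capacity error: facility cannot host one %s unit (binding: %s)",
                 platform$name, paste(v, collapse = ", ")))
  }
  sizes <- integer()
  remaining <- units
  while (remaining > 0L) {
    take <- min(cap, remaining)
    sizes <- c(sizes, take)
    remaining <- remaining - take
  }
  res <- lapply(sizes, production_resources, platform = platform,
                facility = facility)
  structure(list(
    platform = platform$name,
    units_required = units,
    productions = data.frame(production = seq_along(sizes), units = sizes,
                             days = rep(dur, length(sizes))),
    total_days = as.integer(length(sizes) * dur),
    operators_assigned = max(vapply(res, `[[`, numeric(1), "operators")),
    mscs_used = max(vapply(res, `[[`, numeric(1), "mscs")),
    incubators_used = max(vapply(res, `[[`, numeric(1), "incubators")),
    area_used_m2 = max(vapply(res, `[[`, numeric(1), "area"))
  ), class = "batch_plan")
}

# Minimal production count by dynamic programming over unit counts; used as
# an independent oracle against the greedy packing in tests.
min_productions_oracle <- function(units, platform, facility) {
  if (units == 0L) return(0L)
  cap <- production_capacity(platform, facility, units)
  if (cap == 0L) return(NA_integer_)
  best <- rep(NA_integer_, units + 1L)  # best[u+1] = min productions for u units
  best[1L] <- 0L
  for (u in seq_len(units)) {
    opts <- vapply(seq_len(min(u, cap)), function(s) best[u - s + 1L], integer(1))
    best[u + 1L] <- 1L + min(opts, na.rm = TRUE)
  }
  best[units + 1L]
}

#' Cost-of-goods report for a planned batch
#'
#' Sums the four direct cost components over a batch plan: raw materials
#' (per-unit lines scale with the total unit count, per-batch lines are
#' provisioned once per production), labor (step hours x operators x rate,
#' repeated per production), facility occupancy (calendar days x day rate) and
#' QC (whole analytical plates at the catalog's sharing capacity). Open
#' manipulations are counted the same way and reported as the process-risk
#' metric.
#'
#' @param plan A [plan_batches()] result.
#' @param process The matching [process_definition()].
#' @param catalog A [cost_catalog()].
#' @param facility A [facility_config()].
#' @return An object of class `cog_report` with the plan, the four cost
#'   components, `total_cost`, `open_steps`, `production_days` and
#'   `operator_hours`.
#' @export
cost_of_batch <- function(plan, process, catalog, facility) {
  units <- plan$units_required
  p <- nrow(plan$productions)
  p_eff <- max(1L, p)  # per-batch lines are provisioned at least once
  materials <- 0
  open_per_unit <- 0
  open_per_batch <- 0
  labor_hours <- 0
  qc_per_run <- 0
  for (s in process$steps) {
    for (m in s$materials) {
      item <- catalog$items[[m$item]]
      if (is.null(item)) {
        stop(sprintf("dangling reference: material id '%s' not in catalog", m$item))
      }
      scale <- if (identical(m$basis, "per_batch")) p_eff else units
      materials <- materials + m$quantity * item$unit_cost * scale
    }
    open_per_unit <- open_per_unit + s$open_manipulations_per_unit
    open_per_batch <- open_per_batch + s$open_manipulations_per_batch
    labor_hours <- labor_hours + s$duration_hours * s$operators
    qc_per_run <- qc_per_run + s$qc_samples
  }
  labor_hours <- labor_hours * p
  labor <- labor_hours * facility$operator_cost_per_hour
  facility_cost <- plan$total_days * facility$facility_cost_per_day
  qc_samples <- qc_per_run * p
  qc <- if (qc_samples > 0) {
    ceiling(qc_samples / catalog$qc_samples_per_plate) * catalog$qc_cost_per_plate
  } else 0
  open_steps <- open_per_unit * units + open_per_batch * p_eff
  structure(list(
    plan = plan,
    materials_cost = materials,
    labor_cost = labor,
    facility_cost = facility_cost,
    qc_cost = qc,
    total_cost = materials + labor + facility_cost + qc,
    open_steps = as.integer(round(open_steps)),
    production_days = plan$total_days,
    operator_hours = labor_hours
  ), class = "cog_report")
}

#' Run the full cost model for one platform and target
#'
#' Convenience chain `required_units()` -> `plan_batches()` ->
#' `cost_of_batch()` on a loaded scenario.
#'
#' @param scenario An `aav_scenario` from [load_scenario()] or
#'   [gen_reference_scenario()].
#' @param platform Platform name present in the scenario.
#' @param target_vg Post-DSP vector-genome target.
#' @param dsp_recovery End-to-end downstream recovery (default 0.30).
#' @return A `cog_report`.
#' @export
run_cog <- function(scenario, platform, target_vg, dsp_recovery = 0.30) {
  p <- scenario$platforms[[platform]]
  if (is.null(p)) stop("unknown platform: ", platform)
  pd <- scenario$processes[[platform]]
  if (is.null(pd)) stop("no process defined for platform: ", platform)
  n <- required_units(target_vg, p$yield_vg_per_unit, dsp_recovery)
  plan <- plan_batches(n, p, pd, scenario$facility)
  cost_of_batch(plan, pd, scenario$catalog, scenario$facility)
}

#' Platform comparison across a target-output sweep
#'
#' Runs the cost model for every platform at every sweep point and expresses
#' cost, open-step and production-time metrics as fold changes relative to a
#' reference platform (reference / reference is exactly 1). Fold changes are
#' invariant under global rescaling of catalog prices.
#'
#' @param scenario An `aav_scenario`.
#' @param reference Reference platform name.
#' @param sweep Numeric vector of post-DSP vector-genome targets.
#' @param dsp_recovery End-to-end downstream recovery (default 0.30).
#' @return A `comparison_table`: data.frame with one row per (target,
#'   platform) holding absolute metrics (`total_cost`, `open_steps`,
#'   `production_days`, `operator_hours`, `units`, `productions`) and fold
#'   changes (`fold_cost`, `fold_open_steps`, `fold_days`) against the
#'   reference.
#' @export
compare_platforms <- function(scenario, reference, sweep, dsp_recovery = 0.30) {
  if (!(reference %in% names(scenario$processes))) {
    stop("reference platform not in scenario: ", reference)
  }
  if (!length(sweep) || any(!is.finite(sweep)) || any(sweep <= 0)) {
    stop("sweep must be non-empty and positive")
  }
  platforms <- names(scenario$processes)
  rows <- list()
  for (tv in sweep) {
    reports <- lapply(platforms, function(pl) {
      tryCatch(run_cog(scenario, pl, tv, dsp_recovery),
               error = function(e) {
                 stop(sprintf("[platform %s, target %.3g] %s", pl, tv,
                              conditionMessage(e)), call. = FALSE)
               })
    })
    names(reports) <- platforms
    ref <- reports[[reference]]
    for (pl in platforms) {
      r <- reports[[pl]]
      rows[[length(rows) + 1L]] <- data.frame(
        target_vg = tv, platform = pl,
        units = r$plan$units_required,
        productions = nrow(r$plan$productions),
        total_cost = r$total_cost,
        open_steps = r$open_steps,
        production_days = r$production_days,
        operator_hours = r$operator_hours,
        fold_cost = r$total_cost / ref$total_cost,
        fold_open_steps = r$open_steps / ref$open_steps,
        fold_days = r$production_days / ref$production_days)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf("Batch plan: %d x %s in %d production(s), %d days\n",
              x$units_required, x$platform, nrow(x$productions), x$total_days))
  if (nrow(x$productions)) {
    cat(sprintf("  peak: %.1f m^2, %d MSC(s), %d incubator(s), %d operators\n",
                x$area_used_m2, x$mscs_used, x$incubators_used,
                x$operators_assigned))
  }
  invisible(x)
}

#' @export
print.cog_report <- function(x, ...) {
  cat(sprintf("CoG report: %s (%d units, %d production(s))\n",
              x$plan$platform, x$plan$units_required, nrow(x$plan$productions)))
  cat(sprintf("  materials %10.1f\n  labor     %10.1f\n  facility  %10.1f\n  QC        %10.1f\n",
              x$materials_cost, x$labor_cost, x$facility_cost, x$qc_cost))
  cat(sprintf("  total     %10.1f cost units\n", x$total_cost))
  cat(sprintf("  open steps %d, production days %d, operator hours %.0f\n",
              x$open_steps, x$production_days, x$operator_hours))
  invisible(x)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("Platform comparison (reference: %s)\n", attr(x, "reference")))
  df <- as.data.frame(x)
  df$target_vg <- sprintf("%.3g", df$target_vg)
  for (cl in c("fold_cost", "fold_open_steps", "fold_days")) {
    df[[cl]] <- sprintf("%.2f", df[[cl]])
  }
  print(df[, c("target_vg", "platform", "units", "productions", "fold_cost",
               "fold_open_steps", "fold_days")], row.names = FALSE)
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param x A `comparison_table`.
#' @param path Output CSV path (UTF-8, header row, '.' decimal separator).
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
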