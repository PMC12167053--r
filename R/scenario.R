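#' Platform specification
#'
#' Describes one production vessel or system: its growth surface, working
#' volume, expected per-unit crude yield, and the operational parameters that
#' drive scheduling (microbial-safety-cabinet throughput, incubator packing,
#' crew rules, footprint).
#'
#' @param name Text identifier, e.g. `"Quantum"`, `"CS10"`.
#' @param surface_area_cm2 Growth surface area per unit (cm^2).
#' @param working_volume_mL Harvest/media volume per unit (mL).
#' @param yield_vg_per_unit Expected crude vector genomes per unit per batch.
#' @param yield_vp_per_unit Expected total particles per unit per batch
#'   (optional, `NA` if unknown).
#' @param footprint_m2 Floor or bench area occupied by one unit (m^2).
#' @param units_per_msc_session Maximum units manipulated per MSC session;
#'   0 means the platform never occupies an MSC.
#' @param units_per_incubator Units per 168 L incubator; 0 for self-contained
#'   systems that need no incubator.
#' @param systems_per_operator_pair Units operable by a fixed two-person crew
#'   (e.g. 10 hollow-fiber systems per 2 operators); 0 disables the crew rule,
#'   in which case staffing follows the facility's operators-per-MSC rule.
#' @param operators_per_production Fixed operator head-count per production,
#'   overriding both crew and per-MSC rules when > 0.
#' @param is_closed Logical; whether routine processing is closed-system.
#'
#' @return An object of class `platform_spec`.
#' @export
platform_spec <- function(name, surface_area_cm2, working_volume_mL,
                          yield_vg_per_unit, yield_vp_per_unit = NA_real_,
                          footprint_m2, units_per_msc_session = 0,
                          units_per_incubator = 0,
                          systems_per_operator_pair = 0,
                          operators_per_production = 0,
                          is_closed = FALSE) {
  x <- structure(list(
    name = as.character(name),
    surface_area_cm2 = as.numeric(surface_area_cm2),
    working_volume_mL = as.numeric(working_volume_mL),
    yield_vg_per_unit = as.numeric(yield_vg_per_unit),
    yield_vp_per_unit = as.numeric(yield_vp_per_unit),
    footprint_m2 = as.numeric(footprint_m2),
    units_per_msc_session = as.numeric(units_per_msc_session),
    units_per_incubator = as.numeric(units_per_incubator),
    systems_per_operator_pair = as.numeric(systems_per_operator_pair),
    operators_per_production = as.numeric(operators_per_production),
    is_closed = isTRUE(is_closed)
  ), class = "platform_spec")
  f <- validate_platform_spec(x)
  if (length(f)) stop("invalid platform_spec: ", paste(f, collapse = "; "))
  x
}

validate_platform_spec <- function(x, path = sprintf("platforms[%s]", x$name)) {
  f <- character()
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) f[[length(f) + 1L]] <<- sprintf("%s.%s: %s", path, field, msg)
  }
  chk(nzchar(x$name), "name", "must be non-empty")
  chk(is.finite(x$surface_area_cm2) && x$surface_area_cm2 > 0,
      "surface_area_cm2", "must be > 0")
  chk(is.finite(x$working_volume_mL) && x$working_volume_mL > 0,
      "working_volume_mL", "must be > 0")
  chk(is.finite(x$yield_vg_per_unit) && x$yield_vg_per_unit >= 0,
      "yield_vg_per_unit", "must be >= 0")
  chk(x$units_per_msc_session >= 0, "units_per_msc_session", "must be >= 0")
  chk(is.finite(x$footprint_m2) && x$footprint_m2 >= 0, "footprint_m2", "must be >= 0")
  f
}

#' One step of a production schedule
#'
#' A day-indexed process step carrying its labor, MSC occupancy, open
#' (non-closed-system) manipulation counts, consumed materials and QC sampling.
#' Material lines reference the cost catalog by item id and carry a basis flag:
#' `"per_unit"` quantities scale with the vessel count, `"per_batch"`
#' quantities are provisioned once per production run of the schedule.
#'
#' @param name Step name.
#' @param day Integer day offset from batch start (day 0 = first activity).
#' @param duration_hours Active labor time for the step.
#' @param operators Operators required concurrently.
#' @param msc_sessions Number of MSC occupancies.
#' @param open_manipulations_per_unit Open manipulations per vessel unit.
#' @param open_manipulations_per_batch Open manipulations independent of unit
#'   count.
#' @param materials List of material lines, each a list with elements `item`
#'   (catalog id), `quantity` and `basis` (`"per_unit"` or `"per_batch"`).
#' @param qc_samples QC samples generated by the step.
#'
#' @return An object of class `process_step`.
#' @export
process_step <- function(name, day, duration_hours = 0, operators = 0,
                         msc_sessions = 0, open_manipulations_per_unit = 0,
                         open_manipulations_per_batch = 0, materials = list(),
                         qc_samples = 0) {
  structure(list(
    name = as.character(name), day = as.integer(day),
    duration_hours = as.numeric(duration_hours),
    operators = as.numeric(operators),
    msc_sessions = as.numeric(msc_sessions),
    open_manipulations_per_unit = as.numeric(open_manipulations_per_unit),
    open_manipulations_per_batch = as.numeric(open_manipulations_per_batch),
    materials = materials, qc_samples = as.numeric(qc_samples)
  ), class = "process_step")
}

validate_process_step <- function(s, path = "step", catalog_ids = NULL) {
  f <- character()
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) f[[length(f) + 1L]] <<- sprintf("%s.%s: %s", path, field, msg)
  }
  chk(nzchar(s$name), "name", "must be non-empty")
  chk(!is.na(s$day) && s$day >= 0L, "day", "must be >= 0")
  chk(s$duration_hours >= 0, "duration_hours", "must be >= 0")
  chk(s$operators >= 0, "operators", "must be >= 0")
  chk(s$msc_sessions >= 0, "msc_sessions", "must be >= 0")
  chk(s$open_manipulations_per_unit >= 0, "open_manipulations_per_unit", "must be >= 0")
  chk(s$open_manipulations_per_batch >= 0, "open_manipulations_per_batch", "must be >= 0")
  chk(s$qc_samples >= 0, "qc_samples", "must be >= 0")
  for (i in seq_along(s$materials)) {
    m <- s$materials[[i]]
    mp <- sprintf("%s.materials[%d]", path, i)
    if (is.null(m$item) || !nzchar(m$item)) {
      f[[length(f) + 1L]] <- sprintf("%s.item: missing id", mp)
    } else if (!is.null(catalog_ids) && !(m$item %in% catalog_ids)) {
      f[[length(f) + 1L]] <- sprintf("%s.item: dangling reference '%s' not in catalog", mp, m$item)
    }
    if (is.null(m$quantity) || !is.finite(as.numeric(m$quantity)) || m$quantity < 0) {
      f[[length(f) + 1L]] <- sprintf("%s.quantity: must be >= 0", mp)
    }
    if (is.null(m$basis) || !(m$basis %in% c("per_unit", "per_batch"))) {
      f[[length(f) + 1L]] <- sprintf("%s.basis: must be 'per_unit' or 'per_batch'", mp)
    }
  }
  f
}

#' Production schedule for one platform
#'
#' Ordered, day-indexed list of [process_step()]s. Steps are sorted by day;
#' insertion order is preserved among steps sharing a day (stable ordering, so
#' reports are reproducible). `batch_duration_days` is derived as
#' `max(day) + 1`.
#'
#' @param platform Name of the platform the schedule belongs to.
#' @param steps Non-empty list of [process_step()] objects.
#'
#' @return An object of class `process_definition`.
#' @export
process_definition <- function(platform, steps) {
  if (!length(steps)) stop("process_definition: steps must be non-empty")
  days <- vapply(steps, function(s) as.integer(s$day), integer(1))
  steps <- steps[order(days)]  # radix order: stable within equal days
  structure(list(
    platform = as.character(platform),
    steps = steps,
    batch_duration_days = max(days) + 1L
  ), class = "process_definition")
}

#' Check a production schedule against its invariants
#'
#' Returns findings instead of raising: one human-readable finding per
#' violated step invariant (negative day, negative counts, malformed or
#' dangling material lines). An empty character vector means the schedule is
#' valid.
#'
#' @param pd A [process_definition()].
#' @param catalog Optional [cost_catalog()]; when given, material ids are
#'   checked against it.
#' @return Character vector of findings (empty when valid).
#' @export
validate_schedule <- function(pd, catalog = NULL) {
  ids <- if (!is.null(catalog)) names(catalog$items) else NULL
  f <- character()
  if (!length(pd$steps)) {
    return(sprintf("process[%s].steps: must be non-empty", pd$platform))
  }
  for (i in seq_along(pd$steps)) {
    f <- c(f, validate_process_step(
      pd$steps[[i]],
      path = sprintf("process[%s].steps[%d]", pd$platform, i),
      catalog_ids = ids))
  }
  f
}

#' Facility configuration
#'
#' Cleanroom capacity and cost parameters shared by all platforms: total area,
#' reserved space per operator, MSC and incubator footprints, the MSC cap and
#' the GMP staffing rule, plus currency-free labor and facility day rates.
#'
#' @param area_m2 Total cleanroom/bench area (m^2); default 60.
#' @param operator_space_m2 Reserved floor area per operator (m^2); default 2.
#' @param msc_footprint_m2 Area per microbial safety cabinet (m^2).
#' @param incubator_footprint_m2 Area per 168 L incubator (m^2).
#' @param operator_cost_per_hour Currency-free labor rate.
#' @param facility_cost_per_day Currency-free facility day rate.
#' @param max_mscs Maximum concurrent MSCs; default 3.
#' @param operators_per_msc GMP staffing rule: operators per occupied MSC;
#'   default 2.
#' @return An object of class `facility_config`.
#' @export
facility_config <- function(area_m2 = 60, operator_space_m2 = 2,
                            msc_footprint_m2 = 3, incubator_footprint_m2 = 1,
                            operator_cost_per_hour = 0,
                            facility_cost_per_day = 0,
                            max_mscs = 3, operators_per_msc = 2) {
  x <- structure(list(
    area_m2 = as.numeric(area_m2),
    operator_space_m2 = as.numeric(operator_space_m2),
    msc_footprint_m2 = as.numeric(msc_footprint_m2),
    incubator_footprint_m2 = as.numeric(incubator_footprint_m2),
    operator_cost_per_hour = as.numeric(operator_cost_per_hour),
    facility_cost_per_day = as.numeric(facility_cost_per_day),
    max_mscs = as.integer(max_mscs),
    operators_per_msc = as.integer(operators_per_msc)
  ), class = "facility_config")
  f <- validate_facility_config(x)
  if (length(f)) stop("invalid facility_config: ", paste(f, collapse = "; "))
  x
}

validate_facility_config <- function(x, path = "facility") {
  f <- character()
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) f[[length(f) + 1L]] <<- sprintf("%s.%s: %s", path, field, msg)
  }
  chk(is.finite(x$area_m2) && x$area_m2 > 0, "area_m2", "must be > 0")
  for (fld in c("operator_space_m2", "msc_footprint_m2", "incubator_footprint_m2",
                "operator_cost_per_hour", "facility_cost_per_day")) {
    chk(is.finite(x[[fld]]) && x[[fld]] >= 0, fld, "must be >= 0")
  }
  chk(x$max_mscs >= 0, "max_mscs", "must be >= 0")
  chk(x$operators_per_msc >= 0, "operators_per_msc", "must be >= 0")
  f
}

#' Cost catalog
#'
#' Map from material item id to a currency-free unit cost, plus the QC
#' plate-sharing parameters: analytical costs are shared by assuming each QC
#' plate is filled to capacity, so a batch pays per whole plate.
#'
#' @param items Named list; each element a list with `unit_cost` (>= 0) and a
#'   free-text `unit` label.
#' @param qc_cost_per_plate Cost of one full analytical plate.
#' @param qc_samples_per_plate Plate capacity used for cost sharing (>= 1).
#' @return An object of class `cost_catalog`.
#' @export
cost_catalog <- function(items = list(), qc_cost_per_plate = 0,
                         qc_samples_per_plate = 96) {
  x <- structure(list(
    items = items,
    qc_cost_per_plate = as.numeric(qc_cost_per_plate),
    qc_samples_per_plate = as.numeric(qc_samples_per_plate)
  ), class = "cost_catalog")
  f <- validate_cost_catalog(x)
  if (length(f)) stop("invalid cost_catalog: ", paste(f, collapse = "; "))
  x
}

validate_cost_catalog <- function(x, path = "catalog") {
  f <- character()
  for (id in names(x$items)) {
    uc <- x$items[[id]]$unit_cost
    if (is.null(uc) || !is.finite(as.numeric(uc)) || uc < 0) {
      f[[length(f) + 1L]] <- sprintf("%s.items[%s].unit_cost: must be >= 0", path, id)
    }
  }
  if (!is.finite(x$qc_cost_per_plate) || x$qc_cost_per_plate < 0) {
    f[[length(f) + 1L]] <- sprintf("%s.qc_cost_per_plate: must be >= 0", path)
  }
  if (!is.finite(x$qc_samples_per_plate) || x$qc_samples_per_plate < 1) {
    f[[length(f) + 1L]] <- sprintf("%s.qc_samples_per_plate: must be >= 1", path)
  }
  f
}

#' Validate a full scenario
#'
#' Runs every component validator plus cross-reference checks (each process
#' names a known platform; every material id resolves in the catalog).
#'
#' @param scenario A scenario list as returned by [load_scenario()].
#' @return Character vector of findings with field paths (empty when valid).
#' @export
validate_scenario <- function(scenario) {
  f <- character()
  for (p in scenario$platforms) f <- c(f, validate_platform_spec(p))
  f <- c(f, validate_facility_config(scenario$facility))
  f <- c(f, validate_cost_catalog(scenario$catalog))
  for (pd in scenario$processes) {
    if (!(pd$platform %in% names(scenario$platforms))) {
      f <- c(f, sprintf("process[%s].platform: unknown platform '%s'",
                        pd$platform, pd$platform))
    }
    f <- c(f, validate_schedule(pd, scenario$catalog))
  }
  f
}

SCENARIO_SCHEMA_VERSION <- 1L

#' Load a scenario configuration
#'
#' Reads a YAML (or JSON-equivalent) scenario file holding platform
#' specifications, production schedules, the facility configuration and the
#' cost catalog, validates every invariant and cross-reference, and returns
#' the structured scenario. Validation failures are reported together with
#' their field paths.
#'
#' @param path Path to a scenario YAML file with a `schema_version` key.
#' @return A list of class `aav_scenario` with elements `platforms` (named
#'   list of [platform_spec()]), `processes` (named by platform), `facility`
#'   and `catalog`.
#' @seealso [write_scenario()], [gen_reference_scenario()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version)) stop("scenario: missing schema_version")
  if (raw$schema_version > SCENARIO_SCHEMA_VERSION) {
    stop("scenario: unsupported schema_version ", raw$schema_version)
  }
  as_num <- function(x, default = 0) if (is.null(x)) default else as.numeric(x)
  platforms <- list()
  for (p in raw$platforms) {
    if (is.null(p$name)) stop("platforms[]: missing field 'name'")
    for (req in c("surface_area_cm2", "working_volume_mL", "yield_vg_per_unit",
                  "footprint_m2")) {
      if (is.null(p[[req]])) {
        stop(sprintf("platforms[%s]: missing field '%s'", p$name, req))
      }
    }
    platforms[[p$name]] <- platform_spec(
      name = p$name,
      surface_area_cm2 = p$surface_area_cm2,
      working_volume_mL = p$working_volume_mL,
      yield_vg_per_unit = p$yield_vg_per_unit,
      yield_vp_per_unit = as_num(p$yield_vp_per_unit, NA_real_),
      footprint_m2 = p$footprint_m2,
      units_per_msc_session = as_num(p$units_per_msc_session),
      units_per_incubator = as_num(p$units_per_incubator),
      systems_per_operator_pair = as_num(p$systems_per_operator_pair),
      operators_per_production = as_num(p$operators_per_production),
      is_closed = isTRUE(p$is_closed))
  }
  catalog <- cost_catalog(
    items = {
      it <- list()
      for (item in raw$catalog$items) {
        if (is.null(item$id)) stop("catalog.items[]: missing field 'id'")
        it[[item$id]] <- list(unit_cost = as.numeric(item$unit_cost),
                              unit = if (is.null(item$unit)) "" else item$unit)
      }
      it
    },
    qc_cost_per_plate = as_num(raw$catalog$qc_cost_per_plate),
    qc_samples_per_plate = as_num(raw$catalog$qc_samples_per_plate, 96))
  fac <- raw$facility
  facility <- facility_config(
    area_m2 = as_num(fac$area_m2, 60),
    operator_space_m2 = as_num(fac$operator_space_m2, 2),
    msc_footprint_m2 = as_num(fac$msc_footprint_m2, 3),
    incubator_footprint_m2 = as_num(fac$incubator_footprint_m2, 1),
    operator_cost_per_hour = as_num(fac$operator_cost_per_hour),
    facility_cost_per_day = as_num(fac$facility_cost_per_day),
    max_mscs = as_num(fac$max_mscs, 3),
    operators_per_msc = as_num(fac$operators_per_msc, 2))
  processes <- list()
  for (pr in raw$processes) {
    if (is.null(pr$steps) || !length(pr$steps)) {
      stop(sprintf("process[%s].steps: must be non-empty",
                   if (is.null(pr$platform)) "?" else pr$platform))
    }
    steps <- lapply(pr$steps, function(s) {
      process_step(
        name = s$name, day = s$day,
        duration_hours = as_num(s$duration_hours),
        operators = as_num(s$operators),
        msc_sessions = as_num(s$msc_sessions),
        open_manipulations_per_unit = as_num(s$open_manipulations_per_unit),
        open_manipulations_per_batch = as_num(s$open_manipulations_per_batch),
        materials = if (is.null(s$materials)) list() else s$materials,
        qc_samples = as_num(s$qc_samples))
    })
    processes[[pr$platform]] <- process_definition(pr$platform, steps)
  }
  scenario <- structure(list(platforms = platforms, processes = processes,
                             facility = facility, catalog = catalog),
                        class = "aav_scenario")
  findings <- validate_scenario(scenario)
  if (length(findings)) {
    stop("scenario validation failed:\n  ", paste(findings, collapse = "\n  "))
  }
  scenario
}

#' Write a scenario configuration to YAML
#'
#' Inverse of [load_scenario()]: emits a normalized, deterministic YAML
#' document (fields in canonical order) so that load/write round trips are
#' byte-stable.
#'
#' @param scenario A scenario of class `aav_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  doc <- scenario_to_list(scenario)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

scenario_to_list <- function(scenario) {
  plats <- lapply(unname(scenario$platforms), function(p) {
    list(name = p$name,
         surface_area_cm2 = p$surface_area_cm2,
         working_volume_mL = p$working_volume_mL,
         yield_vg_per_unit = p$yield_vg_per_unit,
         yield_vp_per_unit = if (is.na(p$yield_vp_per_unit)) NULL else p$yield_vp_per_unit,
         footprint_m2 = p$footprint_m2,
         units_per_msc_session = p$units_per_msc_session,
         units_per_incubator = p$units_per_incubator,
         systems_per_operator_pair = p$systems_per_operator_pair,
         operators_per_production = p$operators_per_production,
         is_closed = p$is_closed)
  })
  procs <- lapply(unname(scenario$processes), function(pd) {
    list(platform = pd$platform,
         steps = lapply(pd$steps, function(s) {
           list(name = s$name, day = as.integer(s$day),
                duration_hours = s$duration_hours,
                operators = s$operators,
                msc_sessions = s$msc_sessions,
                open_manipulations_per_unit = s$open_manipulations_per_unit,
                open_manipulations_per_batch = s$open_manipulations_per_batch,
                qc_samples = s$qc_samples,
                materials = lapply(s$materials, function(m) {
                  list(item = m$item, quantity = m$quantity, basis = m$basis)
                }))
         }))
  })
  items <- lapply(names(scenario$catalog$items), function(id) {
    list(id = id,
         unit_cost = scenario$catalog$items[[id]]$unit_cost,
         unit = scenario$catalog$items[[id]]$unit)
  })
  list(schema_version = SCENARIO_SCHEMA_VERSION,
       platforms = plats,
       facility = unclass(scenario$facility),
       catalog = list(qc_cost_per_plate = scenario$catalog$qc_cost_per_plate,
                      qc_samples_per_plate = scenario$catalog$qc_samples_per_plate,
                      items = items),
       processes = procs)
}

#' @export
print.aav_scenario <- function(x, ...) {
  cat("AAV production scenario\n")
  cat(sprintf("  platforms: %s\n", paste(names(x$platforms), collapse = ", ")))
  for (p in x$platforms) {
    cat(sprintf("    %-14s %8.0f cm^2  %.3g vg/unit  %s\n", p$name,
                p$surface_area_cm2, p$yield_vg_per_unit,
                if (p$is_closed) "closed" else "open"))
  }
  cat(sprintf("  facility: %.1f m^2, %d MSC max, %d operators/MSC\n",
              x$facility$area_m2, x$facility$max_mscs,
              x$facility$operators_per_msc))
  cat(sprintf("  catalog: %d items\n", length(x$catalog$items)))
  invisible(x)
}
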