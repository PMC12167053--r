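#' Reference three-platform scenario
#'
#' Deterministically builds the shipped comparison scenario: a closed
#' hollow-fiber bioreactor (Quantum), a 36-layer flask system (HYPERStack36)
#' and a 10-layer flask system (CS10), with the study's operational
#' assumptions — mean crude yields of 6.81e13 / 1.26e14 / 2.45e13 vg per
#' unit, a 60 m^2 facility with 2.0 m^2 reserved per operator, ten
#' hollow-fiber systems per two operators and one MSC on 6.0 m^2 of bench,
#' six flask units per MSC with at most three MSCs and a five-operator flask
#' crew, and one flask unit per 168 L incubator.
#'
#' All monetary values come from a FIXTURE price catalog of round,
#' currency-free cost units; no prices were measured in any study, so the
#' catalog is an invented but internally consistent set of relative costs.
#'
#' @param path Optional path; when given, the scenario is also written as
#'   YAML via [write_scenario()] (byte-identical across calls).
#' @return An `aav_scenario`.
#' @export
gen_reference_scenario <- function(path = NULL) {
  platforms <- list(
    Quantum = platform_spec(
      name = "Quantum", surface_area_cm2 = 21000, working_volume_mL = 1200,
      yield_vg_per_unit = 6.81e13, yield_vp_per_unit = 4.92e14,
      footprint_m2 = 0.6, units_per_msc_session = 10, units_per_incubator = 0,
      systems_per_operator_pair = 10, operators_per_production = 0,
      is_closed = TRUE),
    HYPERStack36 = platform_spec(
      name = "HYPERStack36", surface_area_cm2 = 18000,
      working_volume_mL = 3600, yield_vg_per_unit = 1.26e14,
      footprint_m2 = 0, units_per_msc_session = 6, units_per_incubator = 1,
      systems_per_operator_pair = 0, operators_per_production = 5,
      is_closed = FALSE),
    CS10 = platform_spec(
      name = "CS10", surface_area_cm2 = 6360, working_volume_mL = 1000,
      yield_vg_per_unit = 2.45e13, footprint_m2 = 0,
      units_per_msc_session = 6, units_per_incubator = 1,
      systems_per_operator_pair = 0, operators_per_production = 5,
      is_closed = FALSE))

  # FIXTURE catalog — round currency-free numbers, not from any study
  catalog <- cost_catalog(
    items = list(
      quantum_kit = list(unit_cost = 250, unit = "kit"),
      media_L = list(unit_cost = 5, unit = "L"),
      cs10_flask = list(unit_cost = 60, unit = "flask"),
      hs36_flask = list(unit_cost = 300, unit = "flask"),
      transfection_mix = list(unit_cost = 30, unit = "unit-dose"),
      lysis_buffer_L = list(unit_cost = 8, unit = "L"),
      bag_set = list(unit_cost = 40, unit = "set"),
      gowning = list(unit_cost = 25, unit = "session")),
    qc_cost_per_plate = 960, qc_samples_per_plate = 96)

  facility <- facility_config(
    area_m2 = 60, operator_space_m2 = 2, msc_footprint_m2 = 3,
    incubator_footprint_m2 = 1, operator_cost_per_hour = 50,
    facility_cost_per_day = 500, max_mscs = 3, operators_per_msc = 2)

  mat <- function(item, quantity, basis = "per_unit") {
    list(item = item, quantity = quantity, basis = basis)
  }
  quantum_steps <- list(
    process_step("seed and attach", day = 0, duration_hours = 4, operators = 2,
                 msc_sessions = 1, open_manipulations_per_unit = 1,
                 open_manipulations_per_batch = 1,
                 materials = list(mat("quantum_kit", 1), mat("media_L", 10),
                                  mat("gowning", 1, "per_batch")),
                 qc_samples = 1),
    process_step("expansion feed 1", day = 1, duration_hours = 2, operators = 2,
                 materials = list(mat("media_L", 5))),
    process_step("expansion feed 2", day = 2, duration_hours = 2, operators = 2,
                 materials = list(mat("media_L", 5))),
    process_step("expansion feed 3", day = 3, duration_hours = 2, operators = 2,
                 materials = list(mat("media_L", 5))),
    process_step("transfection", day = 4, duration_hours = 4, operators = 2,
                 msc_sessions = 1, open_manipulations_per_unit = 1,
                 materials = list(mat("transfection_mix", 1), mat("media_L", 5)),
                 qc_samples = 1),
    process_step("production perfusion 1", day = 5, duration_hours = 2,
                 operators = 2, materials = list(mat("media_L", 10))),
    process_step("production perfusion 2", day = 6, duration_hours = 2,
                 operators = 2, materials = list(mat("media_L", 10))),
    process_step("production perfusion 3", day = 7, duration_hours = 2,
                 operators = 2, materials = list(mat("media_L", 10))),
    process_step("in situ lysis and harvest", day = 8, duration_hours = 4,
                 operators = 2, open_manipulations_per_batch = 1,
                 materials = list(mat("lysis_buffer_L", 2), mat("bag_set", 1)),
                 qc_samples = 3))

  flask_expansion <- function(days) {
    lapply(seq_along(days), function(i) {
      process_step(sprintf("expansion passage %d", i), day = days[i],
                   duration_hours = 4, operators = 3, msc_sessions = 2,
                   open_manipulations_per_unit = 1,
                   materials = list(mat("media_L", 3)))
    })
  }
  cs10_steps <- c(
    list(process_step("thaw and seed train", day = 0, duration_hours = 3,
                      operators = 2, msc_sessions = 1,
                      open_manipulations_per_batch = 4,
                      materials = list(mat("media_L", 2, "per_batch"),
                                       mat("gowning", 1, "per_batch")),
                      qc_samples = 1)),
    flask_expansion(c(2, 4, 6, 8, 10)),
    list(
      process_step("seed CS10 vessels", day = 12, duration_hours = 6,
                   operators = 5, msc_sessions = 3,
                   open_manipulations_per_unit = 2,
                   materials = list(mat("cs10_flask", 1), mat("media_L", 20)),
                   qc_samples = 1),
      process_step("transfection", day = 14, duration_hours = 6, operators = 5,
                   msc_sessions = 3, open_manipulations_per_unit = 2,
                   materials = list(mat("transfection_mix", 1),
                                    mat("media_L", 5)),
                   qc_samples = 1),
      process_step("media exchange", day = 15, duration_hours = 4,
                   operators = 5, msc_sessions = 3,
                   open_manipulations_per_unit = 1,
                   materials = list(mat("media_L", 20))),
      process_step("harvest and lyse", day = 17, duration_hours = 8,
                   operators = 5, msc_sessions = 3,
                   open_manipulations_per_unit = 3,
                   materials = list(mat("lysis_buffer_L", 1),
                                    mat("bag_set", 1, "per_batch")),
                   qc_samples = 3)))
  hs36_steps <- c(
    list(process_step("thaw and seed train", day = 0, duration_hours = 3,
                      operators = 2, msc_sessions = 1,
                      open_manipulations_per_batch = 4,
                      materials = list(mat("media_L", 2, "per_batch"),
                                       mat("gowning", 1, "per_batch")),
                      qc_samples = 1)),
    flask_expansion(c(2, 4, 6, 8)),
    list(
      process_step("seed HYPERStack vessels", day = 10, duration_hours = 6,
                   operators = 5, msc_sessions = 3,
                   open_manipulations_per_unit = 2,
                   materials = list(mat("hs36_flask", 1), mat("media_L", 60)),
                   qc_samples = 1),
      process_step("transfection", day = 12, duration_hours = 6, operators = 5,
                   msc_sessions = 3, open_manipulations_per_unit = 2,
                   materials = list(mat("transfection_mix", 1),
                                    mat("media_L", 10)),
                   qc_samples = 1),
      process_step("media exchange", day = 13, duration_hours = 4,
                   operators = 5, msc_sessions = 3,
                   open_manipulations_per_unit = 1,
                   materials = list(mat("media_L", 20))),
      process_step("harvest and lyse", day = 15, duration_hours = 8,
                   operators = 5, msc_sessions = 3,
                   open_manipulations_per_unit = 3,
                   materials = list(mat("lysis_buffer_L", 1),
                                    mat("bag_set", 1, "per_batch")),
                   qc_samples = 3)))

  scenario <- structure(list(
    platforms = platforms,
    processes = list(
      Quantum = process_definition("Quantum", quantum_steps),
      HYPERStack36 = process_definition("HYPERStack36", hs36_steps),
      CS10 = process_definition("CS10", cs10_steps)),
    facility = facility, catalog = catalog), class = "aav_scenario")
  findings <- validate_scenario(scenario)
  if (length(findings)) {
    stop("internal error: reference scenario invalid: ",
         paste(findings, collapse = "; "))
  }
  if (!is.null(path)) write_scenario(scenario, path)
  scenario
}

#' Generate a synthetic designed-experiment data set
#'
#' Builds a face-centred CCD over the given factors and draws responses from
#' a known quadratic truth surface plus optional Gaussian noise, keeping the
#' truth record for recovery testing.
#'
#' @param truth Coefficient vector in the canonical coded-term order
#'   (intercept, linear, squares, interactions) of [fit_quadratic()].
#' @param factors List of [factor_def()]; default [lysis_factors()].
#' @param n_center Center replicates (default 3).
#' @param noise_sd Response noise SD; requires `seed` when > 0.
#' @param seed RNG seed.
#' @return List with `design` (`ccd_design`), `responses`, `truth` and
#'   `noise_sd`.
#' @export
gen_doe_dataset <- function(truth, factors = lysis_factors(), n_center = 3,
                            noise_sd = 0, seed = NULL) {
  design <- ccd_face_centered(factors, n_center = n_center)
  mm <- quadratic_model_matrix(design$coded)
  if (length(truth) != ncol(mm)) {
    stop(sprintf("truth must have %d coefficients (canonical quadratic order)",
                 ncol(mm)))
  }
  responses <- drop(mm %*% truth)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    set.seed(seed)
    responses <- responses + stats::rnorm(length(responses), 0, noise_sd)
  }
  list(design = design, responses = responses, truth = truth,
       noise_sd = noise_sd)
}

#' Generate a synthetic perfusion growth run
#'
#' Logistic expansion to a plateau (default 5e9 cells over an 8-day process,
#' inflection mid-run so metabolic rates visibly accelerate after day 4),
#' with matching metabolite time courses from [simulate_metabolites()] under
#' a linearly ramping daily perfusion schedule.
#'
#' @param plateau_cells Logistic carrying capacity (default 5e9).
#' @param days Process length in days (default 8; daily sampling).
#' @param seed RNG seed for measurement noise.
#' @param growth_rate Logistic rate (1/day, default 1.2).
#' @param volume_mL Well-mixed system volume (default 2000 mL).
#' @param noise_sd Metabolite measurement noise SD (mM, default 0).
#' @param rates,feed Passed to [simulate_metabolites()].
#' @return List with `growth` (data.frame `time`, `cells`), `series`
#'   (a [metabolite_series()]) and the `q_lac` the simulation used.
#' @export
gen_growth_run <- function(plateau_cells = 5e9, days = 8, seed = 1,
                           growth_rate = 1.2, volume_mL = 2000, noise_sd = 0,
                           rates = default_metabolic_rates(),
                           feed = default_feed_concentrations()) {
  if (plateau_cells <= 0) stop("plateau_cells must be > 0")
  t <- 0:days
  t_mid <- days / 2  # inflection at mid-run
  cells <- plateau_cells / (1 + exp(-growth_rate * (t - t_mid)))
  growth <- data.frame(time = t, cells = cells)
  perfusion <- seq(200, 1600, length.out = length(t))
  series <- simulate_metabolites(
    growth, rates = rates, perfusion_rate = perfusion, feed = feed,
    volume_mL = volume_mL, noise_sd = noise_sd,
    seed = if (noise_sd > 0) seed else NULL)
  list(growth = growth, series = series, q_lac = unname(rates[["lactate"]]))
}
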