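# Shared fixtures built in code: a minimal platform/facility pair whose
# per-production capacity can be dialed exactly, and a one-step process.

tiny_platform <- function(units_per_msc_session = 6, footprint_m2 = 0,
                          units_per_incubator = 0, operators_per_production = 0,
                          systems_per_operator_pair = 0) {
  platform_spec(name = "tiny", surface_area_cm2 = 100, working_volume_mL = 10,
                yield_vg_per_unit = 1e12, footprint_m2 = footprint_m2,
                units_per_msc_session = units_per_msc_session,
                units_per_incubator = units_per_incubator,
                systems_per_operator_pair = systems_per_operator_pair,
                operators_per_production = operators_per_production)
}

tiny_facility <- function(area_m2 = 60, max_mscs = 3, operators_per_msc = 2,
                          msc_footprint_m2 = 3, incubator_footprint_m2 = 1,
                          operator_cost_per_hour = 10,
                          facility_cost_per_day = 100) {
  facility_config(area_m2 = area_m2, max_mscs = max_mscs,
                  operators_per_msc = operators_per_msc,
                  msc_footprint_m2 = msc_footprint_m2,
                  incubator_footprint_m2 = incubator_footprint_m2,
                  operator_cost_per_hour = operator_cost_per_hour,
                  facility_cost_per_day = facility_cost_per_day)
}

one_step_process <- function(platform = "tiny", materials = list(),
                             duration_hours = 0, operators = 0,
                             open_per_unit = 0, open_per_batch = 0,
                             qc_samples = 0, day = 0) {
  process_definition(platform, list(process_step(
    "only", day = day, duration_hours = duration_hours, operators = operators,
    open_manipulations_per_unit = open_per_unit,
    open_manipulations_per_batch = open_per_batch,
    materials = materials, qc_samples = qc_samples)))
}

# Independent packing oracle: minimal number of productions covering `units`
# when each production's size must come from `feasible_sizes`; exhaustive
# shortest-path over unit counts, independent of the package's greedy fill.
brute_min_productions <- function(units, feasible_sizes) {
  if (units == 0) return(0L)
  if (!length(feasible_sizes)) return(NA_integer_)
  best <- rep(NA_integer_, units + 1L)
  best[1L] <- 0L
  for (u in seq_len(units)) {
    for (s in feasible_sizes) {
      if (s <= u && !is.na(best[u - s + 1L])) {
        cand <- 1L + best[u - s + 1L]
        if (is.na(best[u + 1L]) || cand < best[u + 1L]) best[u + 1L] <- cand
      }
    }
  }
  best[units + 1L]
}
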