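#' Vendor-nominal platform surface areas (cm^2)
#'
#' Named constants used by the equivalence arithmetic: the hollow-fiber
#' bioreactor's 2.1 m^2 membrane surface expressed in cm^2, and the nominal
#' growth areas of the two multilayer flask comparators. The flask areas are
#' vendor catalog values, not experimental measurements.
#'
#' @format Named numeric vector with elements `Quantum`, `CS10`,
#'   `HYPERStack36`.
#' @export
PLATFORM_SURFACE_CM2 <- c(Quantum = 21000, CS10 = 6360, HYPERStack36 = 18000)

#' Reference per-unit crude yields (vector genomes)
#'
#' Mean crude vector-genome output per vessel/system per batch used by the
#' cost model: measured for the hollow-fiber system, extrapolated from 2D
#' flask titers for the flask platforms (linear scale-up assumption).
#'
#' @format Named numeric vector with elements `Quantum`, `CS10`,
#'   `HYPERStack36`.
#' @export
PLATFORM_YIELD_VG <- c(Quantum = 6.81e13, CS10 = 2.45e13, HYPERStack36 = 1.26e14)

#' Total quantity from a titer and a volume
#'
#' @param titer_per_mL Concentration (quantity per mL), >= 0.
#' @param volume_mL Volume (mL), >= 0.
#' @return `titer_per_mL * volume_mL`.
#' @examples
#' total_yield(5.81e10, 1172)  # ~6.81e13 vg from a ~1.2 L harvest
#' @export
total_yield <- function(titer_per_mL, volume_mL) {
  if (any(titer_per_mL < 0) || any(volume_mL < 0)) {
    stop("titer and volume must be >= 0")
  }
  titer_per_mL * volume_mL
}

#' Full-particle ratio
#'
#' Percentage of total capsids that contain a vector genome: 100 x vg / vp.
#' Genome-containing particles are a subset of total particles, so vg must
#' not exceed vp.
#'
#' @param vg_total Total vector genomes (qPCR).
#' @param vp_total Total particles (ELISA), > 0.
#' @param report If `"integer"`, round to the nearest whole percent
#'   (reporting convention); `"raw"` returns the unrounded percentage.
#' @return Percentage in \[0, 100\].
#' @examples
#' full_particle_ratio(6.81e13, 4.92e14)  # 14
#' @export
full_particle_ratio <- function(vg_total, vp_total,
                                report = c("integer", "raw")) {
  report <- match.arg(report)
  if (any(vp_total <= 0)) stop("vp_total must be > 0")
  if (any(vg_total > vp_total)) {
    stop("inconsistent titers: vg_total exceeds vp_total")
  }
  pct <- 100 * vg_total / vp_total
  if (report == "integer") round(pct) else pct
}

#' Unit-operation product recovery
#'
#' Percentage of product carried through one downstream step. Values above
#' 100% are permitted (assay noise around complete recovery) but flagged via
#' the `over_recovery` attribute.
#'
#' @param product_out Product quantity leaving the step.
#' @param product_in Product quantity entering the step, > 0.
#' @return Percentage, with logical attribute `over_recovery`.
#' @export
step_recovery <- function(product_out, product_in) {
  if (any(product_in <= 0)) stop("product_in must be > 0")
  pct <- 100 * product_out / product_in
  attr(pct, "over_recovery") <- pct > 100
  pct
}

#' Impurity clearance across a unit operation
#'
#' Percent reduction of an impurity (host-cell protein, total DNA, turbidity):
#' 100 x (in - out) / in. Out > in gives a negative clearance, returned with
#' a flag rather than an error.
#'
#' @param impurity_in Impurity quantity entering, > 0.
#' @param impurity_out Impurity quantity leaving, >= 0.
#' @param report `"integer"` (nearest whole percent, the reporting
#'   convention) or `"raw"`.
#' @return Percent reduction, with logical attribute `negative_clearance`.
#' @examples
#' clearance(1.8e7, 2.0e6)  # 89 (% total-DNA clearance)
#' @export
clearance <- function(impurity_in, impurity_out, report = c("integer", "raw")) {
  report <- match.arg(report)
  if (any(impurity_in <= 0)) stop("impurity_in must be > 0")
  if (any(impurity_out < 0)) stop("impurity_out must be >= 0")
  pct <- 100 * (impurity_in - impurity_out) / impurity_in
  out <- if (report == "integer") round(pct) else pct
  attr(out, "negative_clearance") <- pct < 0
  out
}

#' Compounded recovery across unit operations
#'
#' Product of per-step recovery fractions; the end-to-end downstream recovery
#' the cost model applies as a single scalar. The empty chain is the identity
#' (1.0).
#'
#' @param step_recoveries Numeric vector of fractions, each in \[0, 1.5\]
#'   (mild over-recovery tolerated).
#' @return Single fraction.
#' @examples
#' compound_recovery(c(0.9, 0.9, 0.62, 0.74, 0.81))  # ~0.30 end-to-end
#' @export
compound_recovery <- function(step_recoveries) {
  if (!length(step_recoveries)) return(1.0)
  if (any(step_recoveries < 0) || any(step_recoveries > 1.5)) {
    stop("step recoveries must lie in [0, 1.5]")
  }
  prod(step_recoveries)
}

#' Equivalence ratio between two quantities
#'
#' Ratio a / b with a reporting rounding, used for platform-equivalence
#' statements such as surface-area or yield multiples ("how many flasks equal
#' one bioreactor").
#'
#' @param quantity_a Numerator.
#' @param quantity_b Denominator, > 0.
#' @param digits Decimal places for the reported ratio; `0` gives
#'   nearest-integer reporting.
#' @return Rounded ratio, with the unrounded value in attribute `raw`.
#' @examples
#' equivalence_ratio(21000, 6360, digits = 1)      # 3.3 (surface areas)
#' equivalence_ratio(6.81e13, 2.45e13, digits = 0) # 3   (yields)
#' @export
equivalence_ratio <- function(quantity_a, quantity_b, digits = 1) {
  if (any(quantity_b <= 0)) stop("quantity_b must be > 0")
  raw <- quantity_a / quantity_b
  out <- round(raw, digits = digits)
  attr(out, "raw") <- raw
  out
}

#' Retentate volume after tangential-flow concentration
#'
#' Volume remaining after an ultrafiltration volume-reduction step expressed
#' as a volumetric reduction factor (VRF).
#'
#' @param volume_in_mL Feed volume (mL), > 0.
#' @param vrf Volumetric reduction factor, >= 1.
#' @return Retentate volume in mL, `volume_in_mL / vrf`.
#' @examples
#' vrf_volumes(1200, 5)  # 240 mL after a 5-fold reduction
#' @export
vrf_volumes <- function(volume_in_mL, vrf) {
  if (any(!is.finite(volume_in_mL)) || any(volume_in_mL <= 0)) {
    stop("volume_in_mL must be > 0")
  }
  if (any(!is.finite(vrf)) || any(vrf < 1)) stop("vrf must be >= 1")
  volume_in_mL / vrf
}

#' Harvest record
#'
#' One crude-harvest measurement: volume, genome titer (qPCR), total-particle
#' titer (ELISA) and lysed-cell count. Genome-containing particles are a
#' subset of total particles, so `vg_per_mL <= vp_per_mL` when both are given.
#'
#' @param volume_mL Harvest volume (mL), > 0.
#' @param vg_per_mL Vector-genome titer (vg/mL).
#' @param vp_per_mL Total-particle titer (vp/mL), optional.
#' @param cells_lysed Lysed cell count, optional.
#' @return An object of class `harvest_record` with derived totals `vg_total`
#'   and `vp_total`.
#' @export
harvest_record <- function(volume_mL, vg_per_mL, vp_per_mL = NA_real_,
                           cells_lysed = NA_real_) {
  if (!is.finite(volume_mL) || volume_mL <= 0) stop("volume_mL must be > 0")
  if (vg_per_mL < 0 || (!is.na(vp_per_mL) && vp_per_mL < 0)) {
    stop("titers must be >= 0")
  }
  if (!is.na(vp_per_mL) && vg_per_mL > vp_per_mL) {
    stop("vg_per_mL must not exceed vp_per_mL")
  }
  structure(list(volume_mL = volume_mL, vg_per_mL = vg_per_mL,
                 vp_per_mL = vp_per_mL, cells_lysed = cells_lysed,
                 vg_total = total_yield(vg_per_mL, volume_mL),
                 vp_total = if (is.na(vp_per_mL)) NA_real_ else
                   total_yield(vp_per_mL, volume_mL)),
            class = "harvest_record")
}

#' Recovery/clearance table for a chain of unit operations
#'
#' Reads unit-operation records (one row per downstream step: product in/out
#' plus any number of impurity in/out column pairs) and derives per-step
#' recovery, per-impurity clearance and the compounded chain recovery.
#'
#' @param records A data.frame with columns `name`, `product_in`,
#'   `product_out`, and optionally pairs `<impurity>_in` / `<impurity>_out`;
#'   or a path to such a CSV.
#' @return A data.frame of class `mass_balance_report`: per step, recovery
#'   percent, over-recovery flag, and integer-percent clearance per impurity;
#'   attribute `compound_recovery` holds the chain product of recovery
#'   fractions.
#' @export
mass_balance_report <- function(records) {
  if (is.character(records)) {
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  }
  need <- c("name", "product_in", "product_out")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  rec <- step_recovery(records$product_out, records$product_in)
  out <- data.frame(name = records$name,
                    recovery_pct = as.numeric(rec),
                    over_recovery = attr(rec, "over_recovery"))
  in_cols <- grep("_in$", names(records), value = TRUE)
  in_cols <- setdiff(in_cols, "product_in")
  for (ic in in_cols) {
    imp <- sub("_in$", "", ic)
    oc <- paste0(imp, "_out")
    if (!(oc %in% names(records))) next
    cl <- mapply(function(i, o) {
      if (is.na(i) || is.na(o) || i <= 0) NA_real_
      else as.numeric(clearance(i, o))
    }, records[[ic]], records[[oc]])
    out[[paste0(imp, "_clearance_pct")]] <- cl
  }
  attr(out, "compound_recovery") <- compound_recovery(
    records$product_out / records$product_in)
  class(out) <- c("mass_balance_report", "data.frame")
  out
}

#' @export
print.mass_balance_report <- function(x, ...) {
  cat("Downstream mass-balance report\n")
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("compounded recovery: %.3f\n", attr(x, "compound_recovery")))
  invisible(x)
}
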