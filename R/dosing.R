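#' Patient insulin parameters
#'
#' @param tdd_units Total daily insulin dose, units/day (> 0). May be omitted
#'   when `icr_g_per_unit` is given directly.
#' @param icr_g_per_unit Insulin-to-carbohydrate ratio, grams of carbohydrate
#'   covered by one unit of insulin (> 0). Defaults to the 500 rule
#'   `500 / tdd_units`.
#' @param dose_increment_units Pen/pump delivery increment in units; the total
#'   dose is rounded to the nearest multiple. `0` (default) disables rounding.
#' @return An object of class `patient_params`.
#' @examples
#' patient_params(tdd_units = 31.77)          # ICR 15.74 g/U via the 500 rule
#' patient_params(icr_g_per_unit = 10)
#' @export
patient_params <- function(tdd_units = NULL, icr_g_per_unit = NULL,
                           dose_increment_units = 0) {
  if (is.null(icr_g_per_unit)) {
    if (is.null(tdd_units)) {
      stop("supply tdd_units or icr_g_per_unit", call. = FALSE)
    }
    icr_g_per_unit <- compute_icr(tdd_units)
  }
  if (!is.numeric(icr_g_per_unit) || icr_g_per_unit <= 0 || !is.finite(icr_g_per_unit)) {
    stop("icr_g_per_unit must be a positive finite number", call. = FALSE)
  }
  if (!is.numeric(dose_increment_units) || dose_increment_units < 0) {
    stop("dose_increment_units must be >= 0", call. = FALSE)
  }
  structure(
    list(tdd_units = if (is.null(tdd_units)) NA_real_ else as.numeric(tdd_units),
         icr_g_per_unit = as.numeric(icr_g_per_unit),
         dose_increment_units = as.numeric(dose_increment_units)),
    class = "patient_params"
  )
}

#' @export
print.patient_params <- function(x, ...) {
  cat(sprintf("Patient: TDD %s U/day, ICR 1 U per %.4g g carbohydrate%s\n",
              if (is.na(x$tdd_units)) "?" else format(x$tdd_units),
              x$icr_g_per_unit,
              if (x$dose_increment_units > 0)
                sprintf(", %.2g U dose increment", x$dose_increment_units) else ""))
  invisible(x)
}

#' Insulin-to-carbohydrate ratio from the 500 rule
#'
#' ICR (grams of carbohydrate per unit of insulin) estimated as
#' `500 / tdd_units`.
#'
#' @param tdd_units Total daily insulin dose, units/day (> 0).
#' @return ICR in g/U.
#' @examples
#' compute_icr(50)     # 10 g/U
#' compute_icr(31.77)  # ~15.74 g/U
#' @export
compute_icr <- function(tdd_units) {
  if (!is.numeric(tdd_units) || any(!is.finite(tdd_units)) || any(tdd_units <= 0)) {
    stop("tdd_units must be positive and finite", call. = FALSE)
  }
  500 / tdd_units
}

# round-half-up to integer (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Count fat-protein units in a meal
#'
#' One fat-protein unit (FPU) is a fixed block of protein+fat energy that is
#' dosed like 10 g of carbohydrate: 200 kcal in the modified algorithm,
#' 100 kcal in the original Pankowska equation.
#'
#' @param m A [meal()].
#' @param kcal_per_fpu Energy per FPU in kcal (> 0); 200 for the modified
#'   algorithm (default), 100 for Pankowska.
#' @param mode `"rounded"` (half-up to the nearest whole FPU, the clinical
#'   convention; default) or `"fractional"`.
#' @return FPU count (integer-valued in rounded mode).
#' @examples
#' fpu_count(hpfm_meal())                  # 2 FPU (362.5 kcal / 200)
#' fpu_count(npm_meal())                   # 1 FPU (281 kcal / 200)
#' fpu_count(npm_meal(), mode = "fractional")
#' @export
fpu_count <- function(m, kcal_per_fpu = 200, mode = c("rounded", "fractional")) {
  mode <- match.arg(mode)
  if (!is.numeric(kcal_per_fpu) || kcal_per_fpu <= 0) {
    stop("kcal_per_fpu must be positive", call. = FALSE)
  }
  raw <- protein_fat_energy(m) / kcal_per_fpu
  if (mode == "rounded") round_half_up(raw) else raw
}

new_bolus_result <- function(algorithm, m, params, carb_equivalent_g,
                             fpu_raw, fpu_counted, carb_units, fpu_units) {
  total <- carb_units + fpu_units
  structure(
    list(algorithm = algorithm, meal = m$name,
         carb_equivalent_g = carb_equivalent_g,
         fpu_raw = fpu_raw, fpu_counted = fpu_counted,
         carb_units = carb_units, fpu_units = fpu_units,
         total_units = round_dose(total, params$dose_increment_units),
         total_units_unrounded = total,
         icr_g_per_unit = params$icr_g_per_unit),
    class = "bolus_result"
  )
}

#' @export
print.bolus_result <- function(x, ...) {
  cat(sprintf("%s bolus for meal '%s' (ICR 1 U : %.4g g)\n",
              x$algorithm, x$meal, x$icr_g_per_unit))
  cat(sprintf("  carb equivalent : %.4g g (%.4g FPU counted, %.4g raw)\n",
              x$carb_equivalent_g, x$fpu_counted, x$fpu_raw))
  cat(sprintf("  carb units      : %.3f U\n", x$carb_units))
  cat(sprintf("  fat/protein add : %.3f U\n", x$fpu_units))
  cat(sprintf("  total dose      : %.3f U\n", x$total_units))
  invisible(x)
}

#' Carbohydrate-counting mealtime bolus
#'
#' Standard prandial dosing: carbohydrate grams divided by the
#' insulin-to-carbohydrate ratio. Fat and protein are ignored.
#'
#' @param m A [meal()].
#' @param params A [patient_params()].
#' @return A `bolus_result`.
#' @examples
#' cc_bolus(npm_meal(), patient_params(icr_g_per_unit = 15.74))
#' @export
cc_bolus <- function(m, params) {
  stopifnot(inherits(m, "meal"), inherits(params, "patient_params"))
  cu <- m$carb_g / params$icr_g_per_unit
  new_bolus_result("CC", m, params, carb_equivalent_g = m$carb_g,
                   fpu_raw = 0, fpu_counted = 0, carb_units = cu, fpu_units = 0)
}

#' Fat-protein-unit mealtime bolus
#'
#' Dosing that covers fat and protein: each counted FPU is added to the
#' carbohydrate mass as a 10-g carbohydrate equivalent, and the sum is divided
#' by the ICR. `kcal_per_fpu = 200` gives the modified FPU algorithm,
#' `100` the original Pankowska equation (see [pankowska_bolus()]).
#'
#' @inheritParams fpu_count
#' @param params A [patient_params()].
#' @return A `bolus_result` with the dose split into its carbohydrate part
#'   (equal to [cc_bolus()]) and the fat/protein add-on.
#' @examples
#' p <- patient_params(icr_g_per_unit = 15.74)
#' fpu_bolus(npm_meal(), p)              # (53 + 10)/15.74 U
#' pankowska_bolus(hpfm_meal(), p)
#' @export
fpu_bolus <- function(m, params, kcal_per_fpu = 200,
                      mode = c("rounded", "fractional")) {
  stopifnot(inherits(m, "meal"), inherits(params, "patient_params"))
  mode <- match.arg(mode)
  counted <- fpu_count(m, kcal_per_fpu, mode)
  raw <- protein_fat_energy(m) / kcal_per_fpu
  ceq <- m$carb_g + 10 * counted
  total <- ceq / params$icr_g_per_unit
  cu <- m$carb_g / params$icr_g_per_unit
  alg <- if (kcal_per_fpu == 100) "FPU_PANKOWSKA" else "FPU_MODIFIED"
  new_bolus_result(alg, m, params, carb_equivalent_g = ceq,
                   fpu_raw = raw, fpu_counted = counted,
                   carb_units = cu, fpu_units = total - cu)
}

#' @rdname fpu_bolus
#' @export
pankowska_bolus <- function(m, params, mode = c("rounded", "fractional")) {
  fpu_bolus(m, params, kcal_per_fpu = 100, mode = mode)
}

#' Ratio of the FPU dose to the carbohydrate-counting dose
#'
#' `(carb_g + 10 * fpu_count) / carb_g`; the ICR cancels, so the ratio
#' depends on the meal alone.
#'
#' @inheritParams fpu_count
#' @return Dimensionless dose ratio (>= 1).
#' @examples
#' dose_ratio(hpfm_meal())   # (35 + 20)/35
#' @export
dose_ratio <- function(m, kcal_per_fpu = 200, mode = c("rounded", "fractional")) {
  stopifnot(inherits(m, "meal"))
  if (m$carb_g == 0) stop("dose ratio undefined for a zero-carbohydrate meal", call. = FALSE)
  (m$carb_g + 10 * fpu_count(m, kcal_per_fpu, mode)) / m$carb_g
}

#' Round a dose to a delivery increment
#'
#' Rounds half-up to the nearest multiple of `increment`; `increment = 0`
#' returns the dose unchanged.
#'
#' @param units Dose in insulin units.
#' @param increment Delivery increment in units (>= 0).
#' @return Rounded dose.
#' @examples
#' round_dose(4.003, 0.5)
#' round_dose(3.367, 1)
#' @export
round_dose <- function(units, increment) {
  if (!is.numeric(increment) || length(increment) != 1L || increment < 0) {
    stop("increment must be a single number >= 0", call. = FALSE)
  }
  if (increment == 0) return(units)
  round_half_up(units / increment) * increment
}
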